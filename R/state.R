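#' Network state on the lattice
#'
#' Holds the five coupled fields at one instant: synaptic input `U`, SFA
#' current `V`, STF efficacy `f`, recurrent STD efficacy `p`, and feedforward
#' STD efficacy `g`. The default construction is the silent fixed point
#' `U = V = 0`, `f = f_min`, `p = g = 1`, which is the unique resting state of
#' the short-term dynamics at zero activity.
#'
#' @param grid A `cann_grid`.
#' @param params A `cann_params` (supplies `f_min`).
#' @param t Initial time (ms).
#' @return An object of class `cann_state`.
#' @export
network_state <- function(grid, params, t = 0) {
  z <- matrix(0, grid$n_side, grid$n_side)
  structure(
    list(t = t, U = z, V = z, f = z + params$f_min, p = z + 1, g = z + 1,
         grid = grid),
    class = "cann_state"
  )
}

#' Seed a bump state
#'
#' Places the Gaussian bump template at `q` in the synaptic-input field. The
#' adaptation field can be pre-loaded at a fraction of its equilibrium
#' `m*[U]_+`, optionally centered at `q + v_offset`: a small spatial offset
#' breaks the rotational symmetry of the seed, which selects a drift
#' direction when the parameters support a traveling wave (the perfectly
#' symmetric seed is an equilibrium of the deterministic dynamics even when
#' unstable).
#'
#' @param grid A `cann_grid`.
#' @param params A `cann_params`.
#' @param q Length-2 bump center.
#' @param amplitude Peak of `U`; default the bare-network seed amplitude
#'   ([bump_seed_amplitude()]).
#' @param sfa_fraction Fraction of the SFA equilibrium loaded into `V`
#'   (default 0: `V = 0`).
#' @param v_offset Length-2 displacement of the seeded `V` field relative to
#'   `q` (radians).
#' @param equilibrate Seed the synaptic efficacies `f` and `p` at their
#'   clamped equilibria for the seeded activity (default `TRUE`): the seed
#'   then represents a bump that has been active for a while, rather than
#'   one dropped into naive synapses. With all amplitudes zero this reduces
#'   to `f = f_min`, `p = 1`.
#' @param t Initial time (ms).
#' @return A `cann_state`.
#' @export
seed_bump_state <- function(grid, params, q = c(0, 0), amplitude = NULL,
                            sfa_fraction = 0, v_offset = c(0, 0),
                            equilibrate = TRUE, t = 0) {
  if (is.null(amplitude)) {
    amplitude <- bump_seed_amplitude(params, resolve_rho(params, grid))
  }
  s <- network_state(grid, params, t = t)
  s$U <- bump_template(grid, params$a, q = q, amplitude = amplitude)
  if (equilibrate) {
    r <- firing_rate(s$U, params$k, resolve_rho(params, grid), grid)
    s$f <- (params$f_min + params$alpha * r) / (1 + params$alpha * r)
    s$p <- 1 / (1 + params$beta * s$f * r)
  }
  if (sfa_fraction > 0 || any(v_offset != 0)) {
    s$V <- sfa_fraction * params$m *
      bump_template(grid, params$a, q = q + v_offset, amplitude = amplitude)
  }
  s
}

#' @export
print.cann_state <- function(x, ...) {
  cat(sprintf("<cann_state> t=%g ms, %dx%d nodes, max U=%.4g\n",
              x$t, x$grid$n_side, x$grid$n_side, max(x$U)))
  invisible(x)
}
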