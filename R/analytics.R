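#' Gaussian bump template
#'
#' The stationary synaptic-input profile of the bare network,
#' \deqn{U(x) = A_u \exp\!\left(-\frac{|x - q|^2}{4 a^2}\right),}
#' evaluated with nearest-image displacements so the template wraps on the
#' torus. The peak position `q` is a free parameter of the attractor family.
#'
#' @param grid A `cann_grid`.
#' @param a Width parameter (radians); for templates of the model's stationary
#'   states this is the interaction range.
#' @param q Length-2 peak position.
#' @param amplitude Peak value `A_u >= 0`.
#' @return Matrix field on the grid.
#' @export
bump_template <- function(grid, a, q = c(0, 0), amplitude = 1) {
  stopifnot(inherits(grid, "cann_grid"))
  if (amplitude < 0) stop("`amplitude` must be >= 0", call. = FALSE)
  dx2 <- torus_diff(grid$x - q[1], grid$length)^2
  dy2 <- torus_diff(grid$x - q[2], grid$length)^2
  amplitude * exp(-outer(dx2, dy2, `+`) / (4 * a^2))
}

#' Critical inhibition strength for bump existence
#'
#' Below
#' \deqn{k_c = \frac{\rho (J_0 f_{min})^2}{32 \pi a^2}}
#' the bare network (all short-term amplitudes zero, so the facilitation
#' variable rests at its floor `f_min`) holds a continuous family of Gaussian
#' bump states; above it only the silent state survives.
#'
#' @param rho Neuronal density.
#' @param J0 Coupling strength.
#' @param f_min STF floor (the resting synaptic efficacy of the bare network).
#' @param a Interaction range (radians).
#' @return The critical inhibition strength `k_c`.
#' @export
critical_inhibition <- function(rho, J0, f_min, a) {
  if (any(c(rho, J0, f_min, a) <= 0)) {
    stop("all arguments of critical_inhibition() must be positive", call. = FALSE)
  }
  rho * (J0 * f_min)^2 / (32 * pi * a^2)
}

#' Bare-network stationary bump amplitude
#'
#' Self-consistency of the Gaussian bump ansatz with the divisively
#' normalized firing rate gives a quadratic for the amplitude `A_u`:
#' `2*pi*a^2*k*rho*A^2 - (rho*Jbar/2)*A + 1 = 0` with `Jbar = J0*f_min`.
#' For `0 < k < k_c` the larger root is the stable amplitude; at `k = 0` the
#' equation is linear with root `2/(rho*Jbar)`; for `k >= k_c` no bump exists
#' and `NA` is returned.
#'
#' @param params A `cann_params`.
#' @param rho Numeric density (use [resolve_rho()]).
#' @return The stable amplitude, or `NA_real_` when `k >= k_c`.
#' @export
stationary_amplitude <- function(params, rho) {
  Jbar <- params$J0 * params$f_min
  if (params$k == 0) return(2 / (rho * Jbar))
  A2 <- 2 * pi * params$a^2 * params$k * rho
  A1 <- rho * Jbar / 2
  disc <- A1^2 - 4 * A2
  if (disc < 0) return(NA_real_)
  (A1 + sqrt(disc)) / (2 * A2)
}

#' Seed amplitude for bump-persistence runs
#'
#' Returns the stable stationary amplitude when one exists. When the bare
#' bump does not exist at this inhibition but facilitation is present
#' (`alpha > 0`), the amplitude of the fully facilitated network (`f = 1`)
#' is tried instead — a bump seeded there can sustain itself once `f` has
#' risen. Failing both, the vertex of the bare amplitude map,
#' `J0*f_min / (8*pi*a^2*k)`, is returned; it lies between the stable and
#' unstable roots whenever a bare bump exists, so a run seeded here persists
#' exactly when the dynamics admit one.
#'
#' @inheritParams stationary_amplitude
#' @return Positive seed amplitude.
#' @export
bump_seed_amplitude <- function(params, rho) {
  A <- stationary_amplitude(params, rho)
  if (!is.na(A)) return(A)
  if (params$alpha > 0) {
    p1 <- params
    p1$f_min <- 1
    A <- stationary_amplitude(p1, rho)
    if (!is.na(A)) return(A)
  }
  params$J0 * params$f_min / (8 * pi * params$a^2 * params$k)
}

#' Traveling-wave existence condition
#'
#' With spike-frequency adaptation the static bump destabilizes into a
#' self-sustained traveling wave when the adaptation strength exceeds the
#' ratio of the synaptic to the adaptation time constant: `m > tau/tau_v`
#' (strict; equality counts as static).
#'
#' @param m SFA amplitude.
#' @param tau Synaptic time constant (ms).
#' @param tau_v SFA time constant (ms).
#' @return Logical.
#' @export
traveling_wave_condition <- function(m, tau, tau_v) {
  if (tau <= 0 || tau_v <= 0) stop("time constants must be positive", call. = FALSE)
  m > tau / tau_v
}

#' Anticipative-tracking condition
#'
#' A moving stimulus is tracked with the bump leading the stimulus when the
#' stimulus speed is positive but below the intrinsic traveling-wave speed:
#' `0 < v_ext < v_int` (strict).
#'
#' @param v_ext Stimulus speed.
#' @param v_int Intrinsic wave speed (>= 0), in the same units as `v_ext`.
#' @return Logical.
#' @export
anticipation_condition <- function(v_ext, v_int) {
  if (v_int < 0) stop("`v_int` must be >= 0", call. = FALSE)
  v_ext > 0 && v_ext < v_int
}
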