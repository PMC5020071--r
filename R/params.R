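#' Model parameters of the multi-time-scale CANN
#'
#' Collects the constants of the neural-field dynamics: the synaptic input
#' equation (time constant `tau`, density `rho`, coupling `J0`, interaction
#' range `a`, divisive inhibition `k`), short-term facilitation (`alpha`,
#' floor `f_min`, `tau_f`), recurrent short-term depression (`beta`, `tau_d`),
#' feedforward short-term depression (`eta`, `tau_g`) and spike-frequency
#' adaptation (`m`, `tau_v`). Times are in milliseconds, space in radians.
#'
#' `rho` may be left `NA`, meaning "match the simulation lattice": it is then
#' resolved as `n_side^2 / length^2` (one neuron per lattice cell), which makes
#' density-weighted sums Riemann approximations of the continuum integrals and
#' renders results grid-size robust.
#'
#' @param tau Synaptic time constant (ms).
#' @param rho Neuronal density (neurons per unit area); `NA` = grid-matched.
#' @param J0 Recurrent coupling strength.
#' @param a Interaction range (radians).
#' @param k Global (divisive) inhibition strength.
#' @param alpha STF amplitude; `f_min` STF floor in `(0, 1]`; `tau_f` its time
#'   constant (ms).
#' @param f_min STF floor.
#' @param tau_f STF time constant (ms).
#' @param beta Recurrent STD amplitude; `tau_d` its time constant (ms).
#' @param tau_d Recurrent STD time constant (ms).
#' @param eta Feedforward STD amplitude; `tau_g` its time constant (ms).
#' @param tau_g Feedforward STD time constant (ms).
#' @param m SFA amplitude; `tau_v` its time constant (ms).
#' @param tau_v SFA time constant (ms).
#' @return An object of class `cann_params` (a validated named list).
#' @examples
#' p <- model_params(J0 = 0.5, k = 0.12, alpha = 20)
#' @export
model_params <- function(tau = 1, rho = NA_real_, J0 = 0.05, a = 0.5,
                         k = 0.01, alpha = 0, f_min = 0.1, tau_f = 10,
                         beta = 0, tau_d = 400, eta = 0, tau_g = 3500,
                         m = 0, tau_v = 80) {
  p <- list(tau = tau, rho = rho, J0 = J0, a = a, k = k,
            alpha = alpha, f_min = f_min, tau_f = tau_f,
            beta = beta, tau_d = tau_d, eta = eta, tau_g = tau_g,
            m = m, tau_v = tau_v)
  validate_params(p)
  structure(p, class = "cann_params")
}

validate_params <- function(p) {
  num1 <- function(v) is.numeric(v) && length(v) == 1L && !is.nan(v)
  for (nm in names(p)) {
    if (!num1(p[[nm]])) stop(sprintf("parameter `%s` must be a single number", nm),
                             call. = FALSE)
  }
  for (nm in c("tau", "tau_f", "tau_d", "tau_g", "tau_v", "a")) {
    if (p[[nm]] <= 0) stop(sprintf("`%s` must be strictly positive", nm),
                           call. = FALSE)
  }
  for (nm in c("alpha", "beta", "eta", "m", "k", "J0")) {
    if (p[[nm]] < 0) stop(sprintf("`%s` must be non-negative", nm), call. = FALSE)
  }
  if (!is.na(p$rho) && p$rho <= 0) stop("`rho` must be positive", call. = FALSE)
  if (p$f_min <= 0 || p$f_min > 1) stop("`f_min` must lie in (0, 1]", call. = FALSE)
  invisible(p)
}

#' Resolve the neuronal density for a given lattice
#'
#' @param params A `cann_params`.
#' @param grid A `cann_grid`.
#' @return The numeric density: `params$rho` if set, else
#'   `n_side^2 / length^2`.
#' @export
resolve_rho <- function(params, grid) {
  if (is.na(params$rho)) grid$n_side^2 / grid$length^2 else params$rho
}

#' Check the separation of time scales
#'
#' The concurrent-computation regime requires
#' `tau << tau_f << tau_v << tau_d << tau_g`. Each successive ratio is
#' compared against `factor`; a warning lists the ratios that fail.
#'
#' @param params A `cann_params`.
#' @param factor Minimal acceptable ratio between successive time constants.
#' @param warn Emit a warning when the ordering fails?
#' @return Logical: `TRUE` if all ratios are at least `factor` (invisibly).
#' @export
check_timescales <- function(params, factor = 5, warn = TRUE) {
  ts <- c(tau = params$tau, tau_f = params$tau_f, tau_v = params$tau_v,
          tau_d = params$tau_d, tau_g = params$tau_g)
  ratios <- ts[-1] / ts[-length(ts)]
  bad <- ratios < factor
  ok <- !any(bad)
  if (!ok && warn) {
    lab <- paste(sprintf("%s/%s = %.3g", names(ts)[-1][bad],
                         names(ts)[-length(ts)][bad], ratios[bad]),
                 collapse = ", ")
    warning(sprintf(
      "time scales are not well separated (ratio < %g): %s", factor, lab),
      call. = FALSE)
  }
  invisible(ok)
}

#' External input specification
#'
#' A Gaussian input of strength `A_amp` and width set by the interaction range
#' (the exponent carries `4 a^2`), switched on at `t_on` and off at `t_off`,
#' whose center moves from `origin` at speed `v_ext` along direction `theta`.
#'
#' @param A_amp Input strength (>= 0).
#' @param v_ext Stimulus speed. Interpreted according to `speed_unit` and
#'   stored internally in radians/ms.
#' @param theta Moving direction (radians).
#' @param t_on,t_off Onset and offset times (ms), `t_off > t_on`. Use
#'   `t_off = Inf` for a sustained input.
#' @param origin Length-2 position of the stimulus center at `t_on`.
#' @param speed_unit `"per_s"` (default; radians per second, the usual way
#'   stimulus speeds are quoted) or `"per_ms"`.
#' @return An object of class `cann_input` with `v_ext` in radians/ms.
#' @examples
#' input_spec(A_amp = 0.15, v_ext = 0.8)          # 0.8 rad/s moving input
#' input_spec(A_amp = 0.15, t_on = 0, t_off = 50) # transient static input
#' @export
input_spec <- function(A_amp = 0, v_ext = 0, theta = 0, t_on = 0, t_off = Inf,
                       origin = c(0, 0), speed_unit = c("per_s", "per_ms")) {
  speed_unit <- match.arg(speed_unit)
  if (!is.numeric(A_amp) || A_amp < 0) stop("`A_amp` must be >= 0", call. = FALSE)
  if (!(t_off > t_on)) stop("`t_off` must exceed `t_on`", call. = FALSE)
  if (length(origin) != 2L) stop("`origin` must have length 2", call. = FALSE)
  v <- if (speed_unit == "per_s") v_ext / 1000 else v_ext
  structure(
    list(A_amp = A_amp, v_ext = v, theta = theta, t_on = t_on, t_off = t_off,
         origin = as.numeric(origin)),
    class = "cann_input"
  )
}

#' Bundled parameter presets
#'
#' Two operating points used throughout the package:
#' \describe{
#'   \item{`"fig1"`}{Single-feature benchmark network: `J0 = 0.05`, `a = 0.5`,
#'     `tau = 1` ms, all short-term amplitudes zero and `f_min = 1` (synapses
#'     at full baseline efficacy). Its bump-existence boundary sits at
#'     `k_c = rho * J0^2 / (32 * pi * a^2)`, about 0.0253 at the preset
#'     density, so the marked operating points `(k, m) = (0.01, 2.5)`
#'     (traveling waves) and `(0.0249, 0.5)` (marginal, plateau decay) lie
#'     where the phase diagram places them.}
#'   \item{`"fig2"`}{Combined-dynamics network implementing persistent
#'     activity, adaptation and anticipative tracking concurrently:
#'     `J0 = 0.5`, `f_min = 0.1`, `alpha = 20`, `beta = 100`, `eta = 40`,
#'     `m = 2.5 * tau/tau_v`, `k = 0.12`, `tau = 1`, `tau_f = 10`,
#'     `tau_v = 80`, `tau_d = 400`, `tau_g = 3500` ms, stimulus strength
#'     `A_amp = 0.15`.}
#' }
#'
#' Both presets pin the neuronal density to the reference 100x100 lattice
#' over `(-pi, pi]^2` (`rho = (100/(2*pi))^2`, about 253.3) rather than
#' leaving it grid-matched: the inhibition values above are only meaningful
#' at that density, and pinning it keeps coarser simulation lattices at the
#' same physical operating point.
#'
#' @param name Preset name, `"fig1"` or `"fig2"`.
#' @return A list with elements `model` (`cann_params`), `input`
#'   (`cann_input`) and `sim` (list of `n_side`, `length`, `dt`, `t_end`,
#'   `record_every`, `snapshot_every`).
#' @export
preset <- function(name = c("fig1", "fig2")) {
  name <- match.arg(name)
  sim <- list(n_side = 100L, length = 2 * pi, dt = 0.1, t_end = 2000,
              record_every = 1, snapshot_every = NA_real_)
  rho_ref <- (100 / (2 * pi))^2   # reference lattice density, 100x100 over (-pi, pi]^2
  if (name == "fig1") {
    list(
      model = model_params(tau = 1, rho = rho_ref, J0 = 0.05, a = 0.5, k = 0.01,
                           alpha = 0, f_min = 1, tau_f = 10,
                           beta = 0, tau_d = 400, eta = 0, tau_g = 3500,
                           m = 0, tau_v = 80),
      input = input_spec(A_amp = 0.1, v_ext = 0, t_on = 0, t_off = Inf),
      sim = sim
    )
  } else {
    tau <- 1; tau_v <- 80
    list(
      model = model_params(tau = tau, rho = rho_ref, J0 = 0.5, a = 0.5, k = 0.12,
                           alpha = 20, f_min = 0.1, tau_f = 10,
                           beta = 100, tau_d = 400, eta = 40, tau_g = 3500,
                           m = 2.5 * tau / tau_v, tau_v = tau_v),
      input = input_spec(A_amp = 0.15, v_ext = 0, t_on = 0, t_off = Inf),
      sim = sim
    )
  }
}

#' @export
print.cann_params <- function(x, ...) {
  cat("<cann_params>\n")
  cat(sprintf("  tau=%g ms  rho=%s  J0=%g  a=%g  k=%g\n", x$tau,
              if (is.na(x$rho)) "grid-matched" else format(x$rho), x$J0, x$a, x$k))
  cat(sprintf("  STF: alpha=%g f_min=%g tau_f=%g | STD(rec): beta=%g tau_d=%g\n",
              x$alpha, x$f_min, x$tau_f, x$beta, x$tau_d))
  cat(sprintf("  STD(ff): eta=%g tau_g=%g | SFA: m=%g tau_v=%g\n",
              x$eta, x$tau_g, x$m, x$tau_v))
  invisible(x)
}
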