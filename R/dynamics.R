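#' Divisively normalized firing rate
#'
#' \deqn{r(x) = \frac{[U(x)]_+^2}{1 + k\,\rho \sum_{x'} [U(x')]_+^2\,\Delta A}}
#' The rate grows quadratically with the rectified synaptic input and
#' saturates through normalization by total network activity (shunting
#' inhibition of strength `k`). For any `U` and `k > 0` the total rate
#' `rho * sum(r) * cell_area` is bounded by `1/k`.
#'
#' @param U Synaptic-input field (matrix).
#' @param k Inhibition strength.
#' @param rho Neuronal density.
#' @param grid A `cann_grid`.
#' @return Rate field, same shape as `U`.
#' @export
firing_rate <- function(U, k, rho, grid) {
  Up <- pmax(U, 0)
  u2 <- Up * Up
  u2 / (1 + k * rho * sum(u2) * grid$cell_area)
}

#' External input field at a given time
#'
#' Gaussian stimulus of peak `A_amp` and exponent `-|x - c(t)|^2 / (4 a^2)`,
#' with center `c(t) = origin + v_ext (t - t_on) (\cos\theta, \sin\theta)`
#' wrapped on the torus; identically zero outside `[t_on, t_off]`.
#'
#' @param input A `cann_input`.
#' @param t Time (ms).
#' @param grid A `cann_grid`.
#' @param a Width parameter (radians); the model uses its interaction range.
#' @return Input field matrix (zero outside the stimulation interval).
#' @export
external_input <- function(input, t, grid, a) {
  if (input$A_amp == 0 || t < input$t_on || t > input$t_off) {
    return(matrix(0, grid$n_side, grid$n_side))
  }
  ctr <- input_center(input, t)
  dx2 <- torus_diff(grid$x - ctr[1], grid$length)^2
  dy2 <- torus_diff(grid$x - ctr[2], grid$length)^2
  input$A_amp * exp(-outer(dx2, dy2, `+`) / (4 * a^2))
}

#' Stimulus center at time t
#'
#' @param input A `cann_input`.
#' @param t Time (ms); must lie within the stimulation interval for the
#'   center to be meaningful.
#' @param length Domain extent used for wrapping.
#' @return Length-2 position wrapped into `(-length/2, length/2]`.
#' @export
input_center <- function(input, t, length = 2 * pi) {
  dt <- t - input$t_on
  torus_diff(input$origin + input$v_ext * dt *
               c(cos(input$theta), sin(input$theta)), length)
}

#' Time derivatives of the coupled fields
#'
#' Evaluates the right-hand sides of the neural-field system:
#' \deqn{\tau \dot U = -U + \rho \int J\, f\,p\,r - V + g\,I_{ext}}
#' \deqn{\tau_f \dot f = f_{min} - f + \alpha (1 - f) r}
#' \deqn{\tau_d \dot p = 1 - p - \beta f p r}
#' \deqn{\tau_g \dot g = 1 - g - \eta g I_{ext}}
#' \deqn{\tau_v \dot V = -V + m [U]_+}
#' The presynaptic efficacies enter the recurrent drive as the product
#' `f * p * r`, and the same product appears in the depletion term of `p`.
#'
#' @param state A `cann_state`.
#' @param params A `cann_params`.
#' @param kernel A `cann_kernel` built on the same grid with `params$J0`,
#'   `params$a`.
#' @param I_ext Input field matrix on the same grid (e.g. from
#'   [external_input()]).
#' @return List of matrices `dU`, `df`, `dp`, `dg`, `dV`, plus the rate field
#'   `r` used.
#' @export
derivatives <- function(state, params, kernel, I_ext) {
  grid <- state$grid
  if (!identical(dim(I_ext), dim(state$U))) {
    stop("`I_ext` is not on the state's grid", call. = FALSE)
  }
  if (nrow(kernel$K) != grid$n_side) {
    stop("kernel grid does not match the state's grid", call. = FALSE)
  }
  rho <- resolve_rho(params, grid)
  r <- firing_rate(state$U, params$k, rho, grid)
  drive <- rho * circular_convolve(kernel, state$f * state$p * r, grid$cell_area)
  Up <- pmax(state$U, 0)
  list(
    dU = (-state$U + drive - state$V + state$g * I_ext) / params$tau,
    df = (params$f_min - state$f + params$alpha * (1 - state$f) * r) / params$tau_f,
    dp = (1 - state$p - params$beta * state$f * state$p * r) / params$tau_d,
    dg = (1 - state$g - params$eta * state$g * I_ext) / params$tau_g,
    dV = (-state$V + params$m * Up) / params$tau_v,
    r = r
  )
}

# Enforce a field bound: excursions within `tol` are clipped (round-off),
# larger ones abort with a hint that dt is too large.
enforce_bounds <- function(x, lo, hi, name, dt, tol = 1e-12) {
  mn <- min(x); mx <- max(x)
  if (mn < lo - tol || mx > hi + tol) {
    stop(sprintf(
      "integration instability: field `%s` left [%g, %g] (range [%g, %g]) at dt = %g; reduce dt",
      name, lo, hi, mn, mx, dt), call. = FALSE)
  }
  if (mn < lo || mx > hi) x <- pmin(pmax(x, lo), hi)
  x
}

#' Advance the state by one forward-Euler step
#'
#' @param state A `cann_state`.
#' @param params A `cann_params`.
#' @param kernel A `cann_kernel` for the current `J0`, `a`.
#' @param input A `cann_input` (evaluated at the state's current time).
#' @param dt Step size (ms); must not exceed `dt_max_ratio * tau`.
#' @param dt_max_ratio Maximal admissible `dt / tau` (default 0.2).
#' @param I_ext Optional precomputed input field for the state's current
#'   time (an optimization used by [simulate_cann()] for static stimuli);
#'   computed from `input` when `NULL`.
#' @return The advanced `cann_state` at `t + dt`. The efficacy bounds
#'   `f in [f_min, 1]`, `p, g in [0, 1]` are asserted; excursions beyond
#'   1e-12 abort with an integration-instability error.
#' @export
step_state <- function(state, params, kernel, input, dt,
                       dt_max_ratio = 0.2, I_ext = NULL) {
  if (dt > params$tau * dt_max_ratio) {
    stop(sprintf("dt = %g exceeds %g * tau; reduce dt or raise dt_max_ratio",
                 dt, dt_max_ratio), call. = FALSE)
  }
  if (is.null(I_ext)) I_ext <- external_input(input, state$t, state$grid, params$a)
  d <- derivatives(state, params, kernel, I_ext)
  state$U <- state$U + dt * d$dU
  state$V <- state$V + dt * d$dV
  state$f <- enforce_bounds(state$f + dt * d$df, params$f_min, 1, "f", dt)
  state$p <- enforce_bounds(state$p + dt * d$dp, 0, 1, "p", dt)
  state$g <- enforce_bounds(state$g + dt * d$dg, 0, 1, "g", dt)
  state$t <- state$t + dt
  state
}
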