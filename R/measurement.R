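#' Measurement thresholds
#'
#' Tunable thresholds used when reducing trajectories to observables.
#'
#' @param eps_silent Amplitude below which the network counts as silent.
#'   Default 1e-3, i.e. one thousandth of the reference stimulus-strength
#'   scale of order 1 used across the presets.
#' @param eps_drift Center drift speed (radians/ms) separating a static bump
#'   from a traveling wave.
#' @param eps_mod Minimal modulation depth (first-Fourier-mode magnitude over
#'   total mass) for a bump center to be defined; near-uniform fields return
#'   an undefined center.
#' @param eps_lock Maximal deviation (radians) of the bump-to-stimulus
#'   separation from its window mean for the bump to count as locked.
#' @param theta_off Relative amplitude threshold defining the end of the
#'   decaying plateau (fraction of the post-offset reference level).
#' @param theta_bg Relative threshold on the adaptation decay (fraction of
#'   the onset peak counting as "faded to background").
#' @param theta_track Minimal window amplitude, as a multiple of the
#'   stimulus strength `A_amp`, for a bump to count as surviving in tracking
#'   runs: a self-sustained bump is recurrently amplified above the
#'   feedforward drive, while the passive ripple left after bump collapse
#'   sits well below it (on the bundled presets, ~1.7x vs ~0.2x `A_amp`).
#' @return A named list of class `cann_thresholds`.
#' @export
measure_thresholds <- function(eps_silent = 1e-3, eps_drift = 1e-4,
                               eps_mod = 0.05, eps_lock = 0.1,
                               theta_off = 0.5, theta_bg = 0.1,
                               theta_track = 1) {
  structure(list(eps_silent = eps_silent, eps_drift = eps_drift,
                 eps_mod = eps_mod, eps_lock = eps_lock,
                 theta_off = theta_off, theta_bg = theta_bg,
                 theta_track = theta_track),
            class = "cann_thresholds")
}

#' Bump center via the first circular Fourier mode
#'
#' The center of mass of a field on the torus is read off, per axis, from the
#' phase of the first Fourier mode of the (rectified) field — the circular
#' mean weighted by activity, which is wrap-correct across the periodic seam.
#' The center is undefined (`NA`) when the peak is below `eps_silent` or the
#' modulation depth of the first mode is below `eps_mod` (near-uniform
#' field).
#'
#' @param field Non-negative matrix field on the grid (rectify beforehand if
#'   needed).
#' @param grid A `cann_grid`.
#' @param thresholds A [measure_thresholds()] list.
#' @return Length-2 numeric center in `(-length/2, length/2]^2`, or
#'   `c(NA, NA)` when undefined.
#' @export
bump_center <- function(field, grid, thresholds = measure_thresholds()) {
  w <- pmax(field, 0)
  tot <- sum(w)
  if (tot <= 0 || max(w) < thresholds$eps_silent) return(c(NA_real_, NA_real_))
  kx <- 2 * pi / grid$length
  ph <- exp(1i * kx * grid$x)
  zx <- sum(rowSums(w) * ph)
  zy <- sum(colSums(w) * ph)
  if (Mod(zx) / tot < thresholds$eps_mod || Mod(zy) / tot < thresholds$eps_mod) {
    return(c(NA_real_, NA_real_))
  }
  c(Arg(zx), Arg(zy)) / kx
}

# Unwrap a center path on the torus into cumulative displacements per axis.
unwrap_path <- function(xy, length) {
  n <- nrow(xy)
  dx <- torus_diff(xy[-1, 1] - xy[-n, 1], length)
  dy <- torus_diff(xy[-1, 2] - xy[-n, 2], length)
  cbind(xy[1, 1] + c(0, cumsum(dx)), xy[1, 2] + c(0, cumsum(dy)))
}

traj_window <- function(traj, window) {
  tb <- traj$table
  span <- tb$time[nrow(tb)] - tb$time[1]
  if (is.null(window)) window <- 0.3 * span
  if (span < window) {
    stop("trajectory is shorter than the analysis window", call. = FALSE)
  }
  tb[tb$time >= tb$time[nrow(tb)] - window, , drop = FALSE]
}

#' Classify the end state of a trajectory
#'
#' Labels the terminal regime over the last `window` ms:
#' `"silent"` if the terminal amplitude is below `eps_silent`;
#' otherwise `"traveling_wave"` if the mean center drift speed exceeds
#' `eps_drift`, else `"static_bump"`. A run that ends silent but spent at
#' least 30% of its duration above half its peak amplitude is labelled
#' `"metastable"` (a plateau that eventually collapsed).
#'
#' @param traj A `cann_trajectory`.
#' @param window Classification window (ms); default the last 30% of the run.
#' @param thresholds A [measure_thresholds()] list.
#' @return List of class `cann_endstate`: `label`, `terminal_amplitude`,
#'   `drift_speed` (NA when no defined center path).
#' @export
classify_endstate <- function(traj, window = NULL,
                              thresholds = measure_thresholds()) {
  tb <- traj$table
  win <- traj_window(traj, window)
  term_amp <- win$amplitude[nrow(win)]
  out <- list(label = NA_character_, terminal_amplitude = term_amp,
              drift_speed = NA_real_)
  if (term_amp < thresholds$eps_silent) {
    peak <- max(tb$amplitude)
    frac_high <- mean(tb$amplitude > 0.5 * peak)
    out$label <- if (peak >= thresholds$eps_silent && frac_high >= 0.3)
      "metastable" else "silent"
  } else {
    ok <- !is.na(win$center_x)
    if (sum(ok) >= 3) {
      out$drift_speed <- path_speed(win$time[ok],
                                    cbind(win$center_x[ok], win$center_y[ok]),
                                    traj$grid$length)
    }
    out$label <- if (!is.na(out$drift_speed) &&
                     out$drift_speed > thresholds$eps_drift)
      "traveling_wave" else "static_bump"
  }
  structure(out, class = "cann_endstate")
}

path_speed <- function(times, xy, length) {
  un <- unwrap_path(xy, length)
  n <- nrow(un)
  steps <- sqrt(rowSums((un[-1, , drop = FALSE] - un[-n, , drop = FALSE])^2))
  arc <- c(0, cumsum(steps))
  if (length(times) == 2) {
    return(abs(arc[2] / (times[2] - times[1])))
  }
  unname(stats::coef(stats::lm(arc ~ times))[2])
}

#' Lifetime of the decaying plateau after stimulus offset
#'
#' The plateau level is referenced at `t_offset + ref_delay` (by default
#' `5 * tau_f`, after the facilitation rebound; pass `ref_delay = 0` for
#' facilitation-free networks, whose decay can start immediately); the
#' lifetime `T_life` is the time from `t_offset` until the amplitude first
#' falls below `theta_off` times that level (linear interpolation of the
#' crossing). `held` reports whether the activity outlived the stimulus by
#' at least `5 * tau_f`. The definition is invariant to uniform rescaling of
#' the amplitude trace.
#'
#' @param traj A `cann_trajectory` (or compatible object with a `table`).
#' @param t_offset Stimulus offset time (ms), inside the trajectory.
#' @param tau_f STF time constant (ms) used for the reference delay and the
#'   `held` cutoff.
#' @param thresholds A [measure_thresholds()] list (`theta_off`,
#'   `eps_silent`).
#' @param ref_delay Delay (ms) after `t_offset` at which the plateau level
#'   is read.
#' @return List of class `cann_persistence`: `T_life` (ms), `plateau_level`,
#'   `held`, `censored` (`TRUE` when the amplitude never crossed the
#'   threshold before the end of the run).
#' @export
plateau_lifetime <- function(traj, t_offset, tau_f,
                             thresholds = measure_thresholds(),
                             ref_delay = 5 * tau_f) {
  tb <- traj$table
  if (t_offset < tb$time[1] || t_offset > tb$time[nrow(tb)]) {
    stop("`t_offset` lies outside the trajectory", call. = FALSE)
  }
  amp_at <- function(t) stats::approx(tb$time, tb$amplitude, xout = t,
                                      rule = 2)$y
  t_ref <- min(t_offset + ref_delay, tb$time[nrow(tb)])
  level <- amp_at(t_ref)
  res <- list(T_life = 0, plateau_level = level, held = FALSE, censored = FALSE)
  if (level < thresholds$eps_silent) {
    class(res) <- "cann_persistence"
    return(res)
  }
  thr <- thresholds$theta_off * level
  post <- tb[tb$time >= t_ref, , drop = FALSE]
  below <- which(post$amplitude < thr)
  if (length(below) == 0) {
    res$T_life <- tb$time[nrow(tb)] - t_offset
    res$censored <- TRUE
  } else {
    i <- below[1]
    if (i == 1) {
      t_cross <- post$time[1]
    } else {
      a1 <- post$amplitude[i - 1]; a2 <- post$amplitude[i]
      t_cross <- post$time[i - 1] +
        (thr - a1) / (a2 - a1) * (post$time[i] - post$time[i - 1])
    }
    res$T_life <- t_cross - t_offset
  }
  res$held <- res$T_life >= 5 * tau_f
  class(res) <- "cann_persistence"
  res
}

#' Speed of a traveling bump
#'
#' Unwraps the recorded center path on the torus and returns the
#' least-squares slope of arc length against time over the analysis window.
#' The result is unsigned (a speed).
#'
#' @param traj A `cann_trajectory`.
#' @param window Window (ms) at the end of the run; default the last 30%.
#' @return Speed in radians/ms.
#' @export
wave_speed <- function(traj, window = NULL) {
  win <- traj_window(traj, window)
  if (anyNA(win$center_x) || nrow(win) < 3) {
    stop("undefined bump centers in the analysis window", call. = FALSE)
  }
  path_speed(win$time, cbind(win$center_x, win$center_y), traj$grid$length)
}

#' Signed separation between bump and moving stimulus
#'
#' Over the stationary window (default: the last 30% of the run) the
#' nearest-image separation between the bump center and the stimulus center
#' is projected onto the motion direction and averaged. Positive `S` means
#' the bump leads the stimulus (anticipation, `S * v_ext > 0`); negative `S`
#' means it lags. If the bump has died (window amplitude below `eps_silent`,
#' or below `theta_track * A_amp` — only the passive input-driven
#' ripple left), never locked to the stimulus (separation deviating from its
#' mean by more than `eps_lock`), or has no defined center, the result is
#' `S = 0` with `tracked = FALSE` so the two zero cases remain
#' distinguishable.
#'
#' @param traj A `cann_trajectory` recorded with an active moving input.
#' @param input The `cann_input` used (must have `v_ext != 0`).
#' @param window Stationary window (ms); default the last 30%.
#' @param thresholds A [measure_thresholds()] list.
#' @return List of class `cann_tracking`: `S` (radians), `tracked`, `v_int`
#'   (`NA` here; filled by experiment drivers that also measure the intrinsic
#'   speed).
#' @export
tracking_separation <- function(traj, input, window = NULL,
                                thresholds = measure_thresholds()) {
  if (input$v_ext == 0) stop("`input` must have a nonzero speed", call. = FALSE)
  win <- traj_window(traj, window)
  res <- list(S = 0, tracked = FALSE, v_int = NA_real_)
  class(res) <- "cann_tracking"
  dead <- anyNA(win$center_x) ||
    any(win$amplitude < thresholds$eps_silent) || anyNA(win$input_x) ||
    mean(win$amplitude) < thresholds$theta_track * input$A_amp
  if (dead) return(res)
  L <- traj$grid$length
  rel_x <- torus_diff(win$center_x - win$input_x, L)
  rel_y <- torus_diff(win$center_y - win$input_y, L)
  dev <- sqrt((rel_x - mean(rel_x))^2 + (rel_y - mean(rel_y))^2)
  if (max(dev) > thresholds$eps_lock) return(res)
  res$S <- mean(rel_x * cos(input$theta) + rel_y * sin(input$theta))
  res$tracked <- TRUE
  res
}
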