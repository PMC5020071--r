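#' Persistent-activity protocol
#'
#' Applies a static transient stimulus (or, with `protocol = "seeded"`,
#' starts directly from a seeded bump with no input) and measures the
#' decaying plateau after offset. With short-term facilitation, a stimulus of
#' duration on the order of `tau_f` facilitates the recurrent synapses enough
#' to retain activity after offset; a much shorter stimulus leaves a response
#' that fades rapidly.
#'
#' @param params A `cann_params`.
#' @param stim_duration Stimulus duration (ms); ignored for the seeded
#'   protocol.
#' @param A_amp Stimulus strength.
#' @param t_end Run length (ms); default covers several recurrent-depression
#'   time constants after offset.
#' @param grid A `cann_grid`; default 64 nodes per axis.
#' @param dt Euler step (ms).
#' @param protocol `"transient"` (stimulate, then release) or `"seeded"`
#'   (start from the bump template at the stationary seed amplitude, offset
#'   time 0).
#' @param thresholds A [measure_thresholds()] list.
#' @param record_every Recording cadence (ms).
#' @return List with `result` (a `cann_persistence`) and `trajectory`.
#' @export
run_persistent_activity <- function(params, stim_duration = 5 * params$tau_f,
                                    A_amp = 0.15, t_end = NULL,
                                    grid = build_grid(64), dt = 0.1 * params$tau,
                                    protocol = c("transient", "seeded"),
                                    thresholds = measure_thresholds(),
                                    record_every = 1) {
  protocol <- match.arg(protocol)
  if (protocol == "transient" && stim_duration <= 0) {
    stop("`stim_duration` must be positive", call. = FALSE)
  }
  if (is.null(t_end)) {
    t_end <- (if (protocol == "transient") stim_duration else 0) +
      6 * max(params$tau_d, params$tau_v)
  }
  if (protocol == "transient") {
    input <- input_spec(A_amp = A_amp, t_on = 0, t_off = stim_duration)
    state <- network_state(grid, params)
    t_offset <- stim_duration
  } else {
    input <- input_spec(A_amp = 0)
    state <- seed_bump_state(grid, params)
    t_offset <- 0
  }
  traj <- simulate_cann(state, params, input, t_end = t_end, dt = dt,
                        record_every = record_every, thresholds = thresholds)
  # the facilitation rebound needs skipping only when facilitation is present
  ref_delay <- if (params$alpha > 0) 5 * params$tau_f else 0
  list(result = plateau_lifetime(traj, t_offset, params$tau_f, thresholds,
                                 ref_delay = ref_delay),
       trajectory = traj)
}

#' Adaptation protocol
#'
#' Applies a sustained static stimulus for the whole run. The network first
#' responds strongly (facilitation), then the response attenuates — through
#' adaptation and recurrent depression at intermediate times and, decisively,
#' through feedforward depression on the `tau_g` scale — until activity
#' approaches background although the stimulus is unchanged.
#'
#' @inheritParams run_persistent_activity
#' @param t_end Run length (ms); a warning is emitted below `3 * tau_g`
#'   (decay not fully covered).
#' @return List with `result` (class `cann_adaptation`: `peak_amplitude`,
#'   `peak_time`, `terminal_amplitude`, `decay_duration` — onset to first
#'   drop below `theta_bg * peak` — and `decayed`) and `trajectory`.
#' @export
run_adaptation <- function(params, A_amp = 0.15, t_end = 3 * params$tau_g,
                           grid = build_grid(64), dt = 0.1 * params$tau,
                           thresholds = measure_thresholds(),
                           record_every = 1) {
  if (t_end < 3 * params$tau_g) {
    warning("t_end < 3 * tau_g: the adaptation decay may not complete",
            call. = FALSE)
  }
  input <- input_spec(A_amp = A_amp, t_on = 0, t_off = Inf)
  traj <- simulate_cann(network_state(grid, params), params, input,
                        t_end = t_end, dt = dt, record_every = record_every,
                        thresholds = thresholds)
  tb <- traj$table
  i_pk <- which.max(tb$amplitude)
  peak <- tb$amplitude[i_pk]
  thr <- thresholds$theta_bg * peak
  post <- tb[seq(i_pk, nrow(tb)), , drop = FALSE]
  below <- which(post$amplitude < thr)
  decayed <- length(below) > 0
  decay_duration <- if (decayed) post$time[below[1]] else tb$time[nrow(tb)]
  res <- structure(
    list(peak_amplitude = peak, peak_time = tb$time[i_pk],
         terminal_amplitude = tb$amplitude[nrow(tb)],
         decay_duration = decay_duration, decayed = decayed),
    class = "cann_adaptation")
  list(result = res, trajectory = traj)
}

#' Tracking protocol with a moving stimulus
#'
#' Applies a stimulus moving at `v_ext` for the whole run, seeding the bump
#' at the stimulus start position (the stationary tracking process, not the
#' capture transient, is of interest). Returns the signed separation between
#' bump and stimulus over the stationary window: `S * v_ext > 0` is
#' anticipative tracking, `S * v_ext < 0` is lagging, and `tracked = FALSE`
#' with `S = 0` means the bump died or never locked (at very low speeds the
#' recurrent depression suppresses the bump before it moves away).
#'
#' @inheritParams run_persistent_activity
#' @param v_ext Stimulus speed (radians per second by default; see
#'   `speed_unit`).
#' @param theta Motion direction (radians).
#' @param speed_unit `"per_s"` or `"per_ms"`.
#' @param t_end Run length (ms).
#' @return List with `result` (a `cann_tracking`) and `trajectory`.
#' @export
run_tracking <- function(params, v_ext, theta = 0, A_amp = 0.15,
                         t_end = 4000, grid = build_grid(64),
                         dt = 0.1 * params$tau,
                         speed_unit = c("per_s", "per_ms"),
                         thresholds = measure_thresholds(),
                         record_every = 2) {
  speed_unit <- match.arg(speed_unit)
  if (v_ext < 0) stop("`v_ext` must be >= 0", call. = FALSE)
  input <- input_spec(A_amp = A_amp, v_ext = v_ext, theta = theta,
                      t_on = 0, t_off = Inf, origin = c(0, 0),
                      speed_unit = speed_unit)
  state <- seed_bump_state(grid, params, q = c(0, 0))
  traj <- simulate_cann(state, params, input, t_end = t_end, dt = dt,
                        record_every = record_every, thresholds = thresholds)
  list(result = tracking_separation(traj, input, thresholds = thresholds),
       trajectory = traj)
}

#' Intrinsic traveling-wave speed
#'
#' Seeds a bump with a slightly offset adaptation field (to select a drift
#' direction), runs the network input-free, and measures the asymptotic
#' center speed. Returns 0 without simulating when the traveling-wave
#' condition `m > tau/tau_v` fails.
#'
#' @inheritParams run_persistent_activity
#' @param t_end Run length (ms).
#' @param v_offset Length-2 spatial offset of the seeded adaptation field
#'   (radians).
#' @return Intrinsic speed `v_int` in radians/ms. If the run classifies as a
#'   static bump although the analytic condition holds (a tolerance-level
#'   inconsistency near the boundary), the measured drift is returned with a
#'   warning.
#' @export
measure_intrinsic_speed <- function(params, grid = build_grid(64),
                                    t_end = NULL, dt = 0.1 * params$tau,
                                    v_offset = c(0.1, 0),
                                    thresholds = measure_thresholds()) {
  if (!traveling_wave_condition(params$m, params$tau, params$tau_v)) {
    return(0)
  }
  if (is.null(t_end)) t_end <- max(1500, 20 * params$tau_v)
  state <- seed_bump_state(grid, params, sfa_fraction = 1, v_offset = v_offset)
  traj <- simulate_cann(state, params, input_spec(A_amp = 0), t_end = t_end,
                        dt = dt, record_every = 2, thresholds = thresholds)
  cls <- classify_endstate(traj, thresholds = thresholds)
  if (cls$label != "traveling_wave") {
    warning(sprintf(
      "traveling-wave condition holds (m*tau_v/tau = %.3g) but the run classified as %s; returning the measured drift",
      params$m * params$tau_v / params$tau, cls$label), call. = FALSE)
    if (is.na(cls$drift_speed)) return(0)
  }
  wave_speed(traj)
}

set_param <- function(params, name, value) {
  if (!name %in% names(params)) {
    stop(sprintf("unknown model parameter `%s`", name), call. = FALSE)
  }
  params[[name]] <- value
  validate_params(params)
  params
}

run_phase_cell <- function(params, grid, protocol, t_end, dt, stim_duration,
                           A_amp, thresholds) {
  if (protocol == "seeded") {
    state <- seed_bump_state(grid, params, sfa_fraction = 1,
                             v_offset = c(0.1, 0))
    input <- input_spec(A_amp = 0)
  } else {
    state <- network_state(grid, params)
    input <- input_spec(A_amp = A_amp, t_on = 0, t_off = stim_duration)
  }
  traj <- simulate_cann(state, params, input, t_end = t_end, dt = dt,
                        record_every = 2, thresholds = thresholds)
  classify_endstate(traj, thresholds = thresholds)
}

#' Two-parameter phase-diagram sweep
#'
#' Classifies the network end state on a lattice of two model parameters.
#' Cells are visited in deterministic row-major order and can be cached
#' across calls by parameter tuple (pass an environment as `cache` to make a
#' sweep resumable). Two protocols: `"seeded"` cells start from the bump
#' template and run input-free (regime diagrams of the intrinsic dynamics);
#' `"transient"` cells apply a transient stimulus to a silent network
#' (response diagrams, e.g. for finite-lifetime persistent activity).
#'
#' @param base Base `cann_params`.
#' @param axis1,axis2 Lists `list(name = <param>, values = <numeric>)`.
#' @param protocol `"seeded"` or `"transient"`.
#' @param t_end,dt Simulation length and step (ms).
#' @param stim_duration,A_amp Transient-protocol stimulus settings.
#' @param grid A `cann_grid`.
#' @param thresholds A [measure_thresholds()] list.
#' @param cache Optional environment used to memoise cells by parameter
#'   tuple.
#' @return Object of class `cann_phase_diagram`: `axis1`, `axis2`, `labels`
#'   (character matrix `|axis1| x |axis2|`), `base`, `protocol`.
#' @export
sweep_phase_diagram <- function(base, axis1, axis2,
                                protocol = c("seeded", "transient"),
                                t_end = 2000, dt = 0.1 * base$tau,
                                stim_duration = 5 * base$tau_f, A_amp = 0.15,
                                grid = build_grid(64),
                                thresholds = measure_thresholds(),
                                cache = NULL) {
  protocol <- match.arg(protocol)
  labels <- matrix(NA_character_, length(axis1$values), length(axis2$values),
                   dimnames = list(format(axis1$values), format(axis2$values)))
  for (i in seq_along(axis1$values)) {
    for (j in seq_along(axis2$values)) {
      p <- set_param(base, axis1$name, axis1$values[i])
      p <- set_param(p, axis2$name, axis2$values[j])
      key <- paste(axis1$name, axis1$values[i], axis2$name, axis2$values[j],
                   protocol, sep = "|")
      if (!is.null(cache) && !is.null(cache[[key]])) {
        labels[i, j] <- cache[[key]]
        next
      }
      cls <- run_phase_cell(p, grid, protocol, t_end, dt, stim_duration,
                            A_amp, thresholds)
      labels[i, j] <- cls$label
      if (!is.null(cache)) cache[[key]] <- cls$label
    }
  }
  structure(list(axis1 = axis1, axis2 = axis2, labels = labels, base = base,
                 protocol = protocol),
            class = "cann_phase_diagram")
}

#' @export
print.cann_phase_diagram <- function(x, ...) {
  cat(sprintf("<cann_phase_diagram> %s x %s (%d x %d cells), protocol %s\n",
              x$axis1$name, x$axis2$name, nrow(x$labels), ncol(x$labels),
              x$protocol))
  print(table(x$labels))
  invisible(x)
}

#' Plateau lifetime across a parameter ladder
#'
#' Runs the persistence protocol for each value of one model parameter and
#' tabulates the plateau lifetime. Near the stability boundary the lifetime
#' grows with the time constant of the dominant negative feedback (adaptation
#' `tau_v` in the adaptation-only network, recurrent depression `tau_d` in
#' the full model).
#'
#' @param base Base `cann_params`.
#' @param vary List `list(name = <param>, values = <numeric>)`.
#' @param stim_duration Stimulus duration (ms) for the transient protocol.
#' @param protocol `"transient"` or `"seeded"` (see
#'   [run_persistent_activity()]).
#' @param t_end Run length (ms); `NULL` = per-value default.
#' @param ... Passed to [run_persistent_activity()].
#' @return data.frame with columns `value`, `T_life`, `held`, `censored`.
#' @export
sweep_lifetime <- function(base, vary, stim_duration = 5 * base$tau_f,
                           protocol = "transient", t_end = NULL, ...) {
  rows <- lapply(vary$values, function(v) {
    p <- set_param(base, vary$name, v)
    out <- run_persistent_activity(p, stim_duration = stim_duration,
                                   protocol = protocol, t_end = t_end, ...)
    data.frame(value = v, T_life = out$result$T_life, held = out$result$held,
               censored = out$result$censored)
  })
  do.call(rbind, rows)
}

#' Depression-free reduction of a parameter set
#'
#' Returns the same parameters with both short-term depression channels
#' switched off (`beta = 0`, `eta = 0`), leaving facilitation and adaptation
#' untouched. The intrinsic traveling-wave speed is a property of this
#' reduction: once a bump tracks a moving stimulus it keeps leaving the
#' synapses it has depressed, so its motion is governed by the
#' depression-free circuit, while the free-running full model loses its bump
#' to slow recurrent depression instead of sustaining a wave.
#'
#' @param params A `cann_params`.
#' @return A `cann_params` with `beta = eta = 0`.
#' @export
depression_free <- function(params) {
  params$beta <- 0
  params$eta <- 0
  params
}

#' Tracking separation across stimulus speeds
#'
#' Runs the tracking protocol for each speed and tabulates the signed
#' separation `S`, the product `S * v_ext`, and the lock flag; the intrinsic
#' wave speed of the same parameters is measured once and attached.
#'
#' @param base A `cann_params`.
#' @param v_ext_values Stimulus speeds (radians/s).
#' @param ... Passed to [run_tracking()].
#' @return data.frame with columns `v_ext` (rad/s), `S` (radians),
#'   `S_v_ext`, `tracked`; attribute `v_int` (radians/ms), measured on the
#'   depression-free reduction of `base` (see [depression_free()]).
#' @export
sweep_tracking <- function(base, v_ext_values, ...) {
  rows <- lapply(v_ext_values, function(v) {
    out <- run_tracking(base, v_ext = v, ...)
    data.frame(v_ext = v, S = out$result$S,
               S_v_ext = out$result$S * v / 1000, tracked = out$result$tracked)
  })
  tab <- if (length(rows)) do.call(rbind, rows) else
    data.frame(v_ext = numeric(), S = numeric(), S_v_ext = numeric(),
               tracked = logical())
  attr(tab, "v_int") <- measure_intrinsic_speed(depression_free(base))
  tab
}

#' Bisect the bump-existence boundary in the inhibition strength
#'
#' For the bare network the Gaussian bump exists below a critical inhibition
#' `k_c`. Each probe seeds the bump template at the saddle-node vertex
#' amplitude and runs input-free for `t_end`; the run counts as persisting
#' when the terminal amplitude stays above a fraction of the seed. Bisection
#' narrows the persist/decay boundary to a relative width `rel_tol`.
#'
#' @param params A `cann_params` (amplitudes need not be zero, but the
#'   boundary has its closed form only for the bare network).
#' @param grid A `cann_grid`.
#' @param k_lo,k_hi Initial bracket; defaults bracket the analytic `k_c` by a
#'   factor of 2 on each side. The bracket is validated (persist at `k_lo`,
#'   decay at `k_hi`).
#' @param t_end Run length per probe (ms); default `2000 * tau`.
#' @param dt Euler step (ms).
#' @param rel_tol Relative bracket width at which bisection stops.
#' @param persist_frac Fraction of the seed amplitude defining persistence.
#' @return List: `k_c_hat` (bracket midpoint), `bracket`, `n_runs`, and
#'   `constant` — the recovered dimensionless boundary constant
#'   `rho * (J0 * f_min)^2 / (k_c_hat * pi * a^2)`.
#' @export
estimate_critical_inhibition <- function(params, grid = build_grid(64),
                                         k_lo = NULL, k_hi = NULL,
                                         t_end = 2000 * params$tau,
                                         dt = 0.1 * params$tau,
                                         rel_tol = 0.02,
                                         persist_frac = 0.2) {
  rho <- resolve_rho(params, grid)
  kc0 <- critical_inhibition(rho, params$J0, params$f_min, params$a)
  if (is.null(k_lo)) k_lo <- kc0 / 2
  if (is.null(k_hi)) k_hi <- kc0 * 2
  kernel <- interaction_kernel(grid, params$J0, params$a)
  n_runs <- 0L
  persists <- function(k) {
    p <- set_param(params, "k", k)
    amp0 <- bump_seed_amplitude(p, rho)
    state <- seed_bump_state(grid, p, amplitude = amp0)
    traj <- simulate_cann(state, p, input_spec(A_amp = 0), t_end = t_end,
                          dt = dt, record_every = t_end / 20, kernel = kernel)
    n_runs <<- n_runs + 1L
    tb <- traj$table
    tb$amplitude[nrow(tb)] > persist_frac * amp0
  }
  if (!persists(k_lo)) stop("no persisting bump at k_lo; widen the bracket",
                            call. = FALSE)
  if (persists(k_hi)) stop("bump still persists at k_hi; widen the bracket",
                           call. = FALSE)
  while ((k_hi - k_lo) / ((k_hi + k_lo) / 2) > rel_tol) {
    k_mid <- (k_hi + k_lo) / 2
    if (persists(k_mid)) k_lo <- k_mid else k_hi <- k_mid
  }
  k_hat <- (k_hi + k_lo) / 2
  list(k_c_hat = k_hat, bracket = c(k_lo, k_hi), n_runs = n_runs,
       constant = rho * (params$J0 * params$f_min)^2 /
         (k_hat * pi * params$a^2))
}

#' Bisect the traveling-wave onset in the adaptation strength
#'
#' For a network with adaptation only, the static bump gives way to a
#' traveling wave as the adaptation amplitude `m` crosses `tau/tau_v`. Each
#' probe seeds a bump with a small adaptation-field offset and classifies the
#' terminal drift; bisection locates the onset `m_hat`.
#'
#' @param params A `cann_params` with `alpha = beta = eta = 0` and a small
#'   `k` (well below the bump-existence boundary).
#' @param grid A `cann_grid`.
#' @param m_lo,m_hi Initial bracket; defaults 0.25 and 4 times `tau/tau_v`.
#' @param t_end Run length per probe (ms); default `60 * tau_v`. Near the
#'   onset the seed's drift transient relaxes at rate `(1 - m*tau_v/tau)/tau_v`,
#'   so the run must cover several such relaxation times for sub-onset
#'   probes to settle back below the drift threshold.
#' @param dt Euler step (ms).
#' @param rel_tol Relative bracket width at which bisection stops.
#' @param eps_drift Drift-speed threshold (radians/ms) defining "traveling";
#'   at the default run length, sub-onset transients decay one to two orders
#'   of magnitude below it while the slowest true waves stay an order of
#'   magnitude above.
#' @return List: `m_hat`, `bracket`, `n_runs`, and `onset_ratio` =
#'   `m_hat * tau_v / tau` (1 at the analytic onset).
#' @export
estimate_wave_onset <- function(params, grid = build_grid(64),
                                m_lo = NULL, m_hi = NULL,
                                t_end = 60 * params$tau_v,
                                dt = 0.1 * params$tau, rel_tol = 0.03,
                                eps_drift = 1e-4) {
  m_c0 <- params$tau / params$tau_v
  if (is.null(m_lo)) m_lo <- 0.25 * m_c0
  if (is.null(m_hi)) m_hi <- 4 * m_c0
  kernel <- interaction_kernel(grid, params$J0, params$a)
  thr <- measure_thresholds(eps_drift = eps_drift)
  n_runs <- 0L
  travels <- function(m) {
    p <- set_param(params, "m", m)
    state <- seed_bump_state(grid, p, sfa_fraction = 1, v_offset = c(0.1, 0))
    traj <- simulate_cann(state, p, input_spec(A_amp = 0), t_end = t_end,
                          dt = dt, record_every = 2, kernel = kernel,
                          thresholds = thr)
    n_runs <<- n_runs + 1L
    classify_endstate(traj, thresholds = thr)$label == "traveling_wave"
  }
  if (travels(m_lo)) stop("already traveling at m_lo; widen the bracket",
                          call. = FALSE)
  if (!travels(m_hi)) stop("still static at m_hi; widen the bracket",
                           call. = FALSE)
  while ((m_hi - m_lo) / ((m_hi + m_lo) / 2) > rel_tol) {
    m_mid <- (m_hi + m_lo) / 2
    if (travels(m_mid)) m_hi <- m_mid else m_lo <- m_mid
  }
  m_hat <- (m_hi + m_lo) / 2
  list(m_hat = m_hat, bracket = c(m_lo, m_hi), n_runs = n_runs,
       onset_ratio = m_hat * params$tau_v / params$tau)
}

#' Synthetic fixtures with known ground truth
#'
#' Deterministic, seed-reproducible objects for exercising the measurement
#' operators: a bump field with a stated center, an amplitude trace with a
#' stated plateau lifetime, and a center path drifting at a stated speed
#' (crossing the periodic seam). Each carries its ground truth as an
#' attribute `truth`.
#'
#' @param kind `"bump_state"`, `"plateau_trace"` or `"drifting_trace"`.
#' @param params Named list of fixture parameters. `bump_state`: `q`,
#'   `amplitude`, `a`, `n_side`, `noise` (relative sd of multiplicative
#'   noise). `plateau_trace`: `level`, `t_offset`, `plateau` (ms of flat
#'   plateau after offset), `fall` (ms of linear fall), `dt`.
#'   `drifting_trace`: `speed` (rad/ms), `theta`, `origin`, `t_end`, `dt`.
#' @param seed Integer seed for any randomness.
#' @return The fixture object (a field-plus-grid list or a
#'   `cann_trajectory`-compatible object) with attribute `truth`.
#' @export
make_fixture <- function(kind = c("bump_state", "plateau_trace",
                                  "drifting_trace"),
                         params = list(), seed = 1L) {
  kind <- match.arg(kind)
  set.seed(seed)
  defaults <- switch(kind,
    bump_state = list(q = c(0.5, -0.8), amplitude = 1, a = 0.5, n_side = 32,
                      noise = 0),
    plateau_trace = list(level = 2, t_offset = 50, plateau = 500, fall = 10,
                         dt = 1),
    drifting_trace = list(speed = 0.01, theta = 0, origin = c(3, 0),
                          t_end = 1000, dt = 2)
  )
  prm <- utils::modifyList(defaults, params)
  if (kind == "bump_state") {
    grid <- build_grid(prm$n_side)
    field <- bump_template(grid, prm$a, q = prm$q, amplitude = prm$amplitude)
    if (prm$noise > 0) {
      field <- field * (1 + prm$noise * stats::rnorm(length(field)))
    }
    out <- list(field = field, grid = grid)
    attr(out, "truth") <- list(center = prm$q)
    return(out)
  }
  if (kind == "plateau_trace") {
    times <- seq(0, prm$t_offset + prm$plateau + prm$fall + 50, by = prm$dt)
    amp <- ifelse(times <= prm$t_offset + prm$plateau, prm$level,
                  pmax(0, prm$level *
                         (1 - (times - prm$t_offset - prm$plateau) / prm$fall)))
    tab <- data.frame(time = times, amplitude = amp, center_x = 0,
                      center_y = 0, total_rate = amp, input_x = NA_real_,
                      input_y = NA_real_)
    out <- structure(list(table = tab, snapshots = list(),
                          grid = build_grid(8), dt = prm$dt),
                     class = "cann_trajectory")
    # analytic crossing of theta_off = 0.5: halfway down the linear fall
    attr(out, "truth") <- list(T_life = prm$plateau + prm$fall / 2)
    return(out)
  }
  times <- seq(0, prm$t_end, by = prm$dt)
  L <- 2 * pi
  cx <- torus_diff(prm$origin[1] + prm$speed * times * cos(prm$theta), L)
  cy <- torus_diff(prm$origin[2] + prm$speed * times * sin(prm$theta), L)
  tab <- data.frame(time = times, amplitude = 1, center_x = cx, center_y = cy,
                    total_rate = 1, input_x = NA_real_, input_y = NA_real_)
  out <- structure(list(table = tab, snapshots = list(), grid = build_grid(8),
                        dt = prm$dt),
                   class = "cann_trajectory")
  attr(out, "truth") <- list(speed = prm$speed)
  out
}
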