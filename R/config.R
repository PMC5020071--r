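#' Load and resolve a run configuration
#'
#' A run configuration has four blocks: `model` (fields of [model_params()]),
#' `input` (fields of [input_spec()]; `v_ext` in radians/s), `sim`
#' (`n_side`, `length`, `dt`, `t_end`, `record_every`, `snapshot_every`) and
#' `protocol` (free-form driver options). Resolution order: preset, then the
#' YAML file, then `key=value` overrides with dotted paths
#' (e.g. `"model.k=0.2"`). Unknown keys and out-of-range values raise
#' descriptive errors; a time-scale ordering violation only warns.
#'
#' @param path Optional YAML file.
#' @param preset Optional preset name (`"fig1"`, `"fig2"`); see [preset()].
#' @param overrides Character vector of `block.field=value` assignments.
#' @return Object of class `cann_config`: list with `model` (`cann_params`),
#'   `input` (`cann_input`), `sim`, `protocol`.
#' @examples
#' cfg <- load_config(preset = "fig2", overrides = c("model.k=0.2"))
#' cfg$model$k
#' @export
load_config <- function(path = NULL, preset = NULL, overrides = character()) {
  raw <- list(model = list(), input = list(), sim = list(), protocol = list())
  if (!is.null(preset)) {
    pr <- preset(preset)
    raw$model <- unclass(pr$model)
    raw$input <- input_as_list(pr$input)
    raw$sim <- pr$sim
  }
  if (!is.null(path)) {
    if (!file.exists(path)) stop(sprintf("config file `%s` not found", path),
                                 call. = FALSE)
    y <- yaml::read_yaml(path)
    bad <- setdiff(names(y), names(raw))
    if (length(bad)) stop(sprintf("unknown config block(s): %s",
                                  paste(bad, collapse = ", ")), call. = FALSE)
    for (b in names(y)) raw[[b]] <- utils::modifyList(raw[[b]], y[[b]])
  }
  for (ov in overrides) {
    kv <- strsplit(ov, "=", fixed = TRUE)[[1]]
    if (length(kv) != 2) stop(sprintf("malformed override `%s`", ov),
                              call. = FALSE)
    pathy <- strsplit(kv[1], ".", fixed = TRUE)[[1]]
    if (length(pathy) != 2 || !pathy[1] %in% names(raw)) {
      stop(sprintf("override `%s` must be <block>.<field>=<value>", ov),
           call. = FALSE)
    }
    val <- utils::type.convert(kv[2], as.is = TRUE)
    raw[[pathy[1]]][[pathy[2]]] <- val
  }
  resolve_config(raw)
}

input_as_list <- function(input) {
  list(A_amp = input$A_amp, v_ext = input$v_ext * 1000, theta = input$theta,
       t_on = input$t_on, t_off = input$t_off, origin = input$origin)
}

sim_defaults <- function() {
  list(n_side = 64L, length = 2 * pi, dt = 0.1, t_end = 2000,
       record_every = 1, snapshot_every = NA_real_)
}

resolve_config <- function(raw) {
  known_model <- names(formals(model_params))
  bad <- setdiff(names(raw$model), known_model)
  if (length(bad)) stop(sprintf("unknown model field(s): %s",
                                paste(bad, collapse = ", ")), call. = FALSE)
  model <- do.call(model_params, raw$model)

  known_input <- setdiff(names(formals(input_spec)), "speed_unit")
  bad <- setdiff(names(raw$input), known_input)
  if (length(bad)) stop(sprintf("unknown input field(s): %s",
                                paste(bad, collapse = ", ")), call. = FALSE)
  inp <- raw$input
  if (!is.null(inp$t_off) && is.character(inp$t_off)) inp$t_off <- Inf
  input <- do.call(input_spec, c(inp, list(speed_unit = "per_s")))

  sim <- utils::modifyList(sim_defaults(), raw$sim)
  bad <- setdiff(names(sim), names(sim_defaults()))
  if (length(bad)) stop(sprintf("unknown sim field(s): %s",
                                paste(bad, collapse = ", ")), call. = FALSE)
  if (sim$dt <= 0 || sim$t_end <= 0) {
    stop("sim `dt` and `t_end` must be positive", call. = FALSE)
  }
  check_timescales(model)
  structure(list(model = model, input = input, sim = sim,
                 protocol = raw$protocol),
            class = "cann_config")
}

#' Write a resolved configuration to YAML
#'
#' The written file round-trips through [load_config()] to an identical
#' configuration, and is echoed into every CLI output directory so a run can
#' be reproduced exactly.
#'
#' @param config A `cann_config`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_config <- function(config, path) {
  out <- list(model = unclass(config$model),
              input = input_as_list(config$input),
              sim = config$sim,
              protocol = config$protocol)
  out$input$t_off <- if (is.infinite(out$input$t_off)) ".inf" else
    out$input$t_off
  yaml::write_yaml(out, path, precision = 15)
  invisible(path)
}

#' Write a trajectory table as CSV
#'
#' Fixed column order (`time`, `amplitude`, `center_x`, `center_y`,
#' `total_rate`, `input_x`, `input_y`), comma separator, `.` decimal, UTF-8,
#' header row, 9 significant digits.
#'
#' @param traj A `cann_trajectory` (or any object with a compatible
#'   `table`).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(traj, path) {
  tb <- traj$table
  cols <- c("time", "amplitude", "center_x", "center_y", "total_rate",
            "input_x", "input_y")
  tb <- tb[, cols]
  fmt <- as.data.frame(lapply(tb, function(col) {
    ifelse(is.na(col), "NA", sprintf("%.9g", col))
  }))
  names(fmt) <- cols
  utils::write.csv(fmt, path, row.names = FALSE, quote = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a trajectory table written by [write_trajectory()]
#'
#' @param path CSV file path.
#' @param grid Optional `cann_grid` to attach (defaults to a 64-node grid).
#' @return A `cann_trajectory`-compatible object (table plus grid).
#' @export
read_trajectory <- function(path, grid = build_grid(64)) {
  tb <- utils::read.csv(path)
  structure(list(table = tb, snapshots = list(), grid = grid, dt = NA_real_),
            class = "cann_trajectory")
}
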