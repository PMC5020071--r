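# Shared fixtures: small lattices and fast parameter sets.

# Reference density of the 100x100 lattice over (-pi, pi]^2, used by the
# bundled presets; pinning it makes coarse test lattices sit at the same
# physical operating point.
rho_ref <- (100 / (2 * pi))^2

# Bare network (no short-term dynamics) well inside the bump regime:
# k_c = rho*(J0*f_min)^2/(32*pi*a^2) ~ 0.0252 at the reference density.
bare_params <- function(k = 0.01, ...) {
  model_params(tau = 1, rho = rho_ref, J0 = 0.05, a = 0.5, k = k,
               alpha = 0, f_min = 1, ...)
}

# Construct a minimal trajectory-like object from a summary table.
traj_stub <- function(table, grid = build_grid(8)) {
  structure(list(table = table, snapshots = list(), grid = grid,
                 dt = NA_real_),
            class = "cann_trajectory")
}

make_table <- function(times, amplitude, center_x = 0, center_y = 0,
                       input_x = NA_real_, input_y = NA_real_) {
  data.frame(time = times, amplitude = amplitude, center_x = center_x,
             center_y = center_y, total_rate = amplitude,
             input_x = input_x, input_y = input_y)
}

# Brute-force circular weighted mean over all nodes (independent of the
# collapsed-axis FFT-phase implementation in bump_center).
circular_mean_center <- function(field, grid) {
  kx <- 2 * pi / grid$length
  zx <- sum(field * exp(1i * kx * grid$X))
  zy <- sum(field * exp(1i * kx * grid$Y))
  c(Arg(zx), Arg(zy)) / kx
}

# O(n^4) direct evaluation of the interaction sum, as an oracle for the
# FFT-based circular convolution.
direct_convolve <- function(grid, J0, a, field) {
  n <- grid$n_side
  out <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    dx <- torus_diff(grid$x[i] - grid$X, grid$length)
    dy <- torus_diff(grid$x[j] - grid$Y, grid$length)
    K <- J0 / (2 * pi * a^2) * exp(-(dx^2 + dy^2) / (2 * a^2))
    out[i, j] <- sum(K * field) * grid$cell_area
  }
  out
}
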