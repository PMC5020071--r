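test_that("the silent fixed point is preserved exactly by the integrator", {
  g <- build_grid(16)
  p <- model_params(alpha = 10, beta = 50, eta = 20, m = 1)
  kern <- interaction_kernel(g, p$J0, p$a)
  s0 <- network_state(g, p)
  s <- s0
  for (i in 1:50) s <- step_state(s, p, kern, input_spec(A_amp = 0), dt = 0.1)
  expect_identical(s$U, s0$U)
  expect_identical(s$f, s0$f)
  expect_identical(s$p, s0$p)
  expect_identical(s$g, s0$g)
  expect_identical(s$V, s0$V)
})

test_that("oversized steps are refused and instabilities are named", {
  g <- build_grid(16)
  p <- bare_params()
  kern <- interaction_kernel(g, p$J0, p$a)
  s <- network_state(g, p)
  expect_error(step_state(s, p, kern, input_spec(), dt = 0.5), "dt")
  # a pathological depression amplitude drives p far below 0 in one step
  pbad <- model_params(rho = rho_ref, J0 = 0.05, f_min = 1, k = 0.01,
                       beta = 1e7, tau_d = 1)
  kern2 <- interaction_kernel(g, pbad$J0, pbad$a)
  sb <- seed_bump_state(g, pbad, amplitude = 2, equilibrate = FALSE)
  expect_error(
    step_state(sb, pbad, kern2, input_spec(A_amp = 0), dt = 0.2),
    "instability.*`p`")
})

test_that("bound preservation holds along a driven trajectory", {
  g <- build_grid(32)
  p <- preset("fig2")$model
  p$tau_g <- 100                      # let g move visibly within a short run
  inp <- input_spec(A_amp = 0.15, v_ext = 0, t_on = 0, t_off = 150)
  traj <- simulate_cann(network_state(g, p), p, inp, t_end = 300,
                        record_every = 10, snapshot_every = 50)
  rho <- resolve_rho(p, g)
  for (s in traj$snapshots) {
    expect_true(all(s$f >= p$f_min - 1e-12 & s$f <= 1 + 1e-12))
    expect_true(all(s$p >= -1e-12 & s$p <= 1 + 1e-12))
    expect_true(all(s$g >= -1e-12 & s$g <= 1 + 1e-12))
    expect_true(all(s$V >= -1e-15))
    r <- firing_rate(s$U, p$k, rho, g)
    expect_true(all(r >= 0))
    expect_lt(rho * sum(r) * g$cell_area, 1 / p$k)
  }
  expect_gt(length(traj$snapshots), 3)
})

test_that("Euler integration converges at first order in dt", {
  g <- build_grid(32)
  p <- bare_params(k = 0.015)
  kern <- interaction_kernel(g, p$J0, p$a)
  inp <- input_spec(A_amp = 0)
  # compare mid-transient (the relaxed bump is a fixed point of the Euler map
  # for any dt, so terminal states carry no discretization signal)
  run <- function(dt) {
    s <- seed_bump_state(g, p, amplitude = 0.6 * stationary_amplitude(p, rho_ref))
    n <- round(5 / dt)
    for (i in seq_len(n)) s <- step_state(s, p, kern, inp, dt)
    s$U
  }
  U_ref <- run(0.0125)
  e <- sapply(c(0.2, 0.1, 0.05), function(dt) max(abs(run(dt) - U_ref)))
  # error ~ C*(dt - dt_ref): successive halvings give ratios near 2.33
  expect_gt(e[1] / e[2], 1.8)
  expect_lt(e[1] / e[2], 3.0)
  expect_gt(e[2] / e[3], 1.8)
  expect_lt(e[2] / e[3], 3.0)
})

test_that("trajectories are translation-equivariant and 4-fold rotation symmetric", {
  g <- build_grid(32)
  p <- model_params(rho = rho_ref, J0 = 0.05, f_min = 1, k = 0.02,
                    m = 0.05, tau_v = 40)   # SFA on: genuinely moving fields
  kern <- interaction_kernel(g, p$J0, p$a)
  inp <- input_spec(A_amp = 0)
  shift <- 5L                               # lattice sites
  run_from <- function(s) {
    for (i in 1:300) s <- step_state(s, p, kern, inp, dt = 0.1)
    s
  }
  s1 <- seed_bump_state(g, p, q = c(0, 0), sfa_fraction = 1,
                        v_offset = c(2 * g$spacing, 0))
  roll <- function(M, by) M[((seq_len(32) - 1 - by) %% 32) + 1, , drop = FALSE]
  s2 <- s1
  for (nm in c("U", "V", "f", "p", "g")) s2[[nm]] <- roll(s1[[nm]], shift)
  f1 <- run_from(s1); f2 <- run_from(s2)
  expect_equal(roll(f1$U, shift), f2$U, tolerance = 1e-9)
  expect_equal(roll(f1$V, shift), f2$V, tolerance = 1e-9)
  # rotating the initial state by 90 degrees rotates the trajectory
  rot <- function(M) t(M[nrow(M):1, , drop = FALSE])
  s3 <- s1
  for (nm in c("U", "V", "f", "p", "g")) s3[[nm]] <- rot(s1[[nm]])
  f3 <- run_from(s3)
  expect_equal(rot(f1$U), f3$U, tolerance = 1e-9)
})

test_that("simulation bookkeeping and determinism", {
  g <- build_grid(16)
  p <- bare_params()
  inp <- input_spec(A_amp = 0)
  s <- network_state(g, p)
  tr <- simulate_cann(s, p, inp, t_end = 5, dt = 0.1, record_every = 5)
  expect_equal(nrow(tr$table), 2L)
  expect_true(all(tr$table$amplitude == 0))

  sb <- seed_bump_state(g, p, amplitude = 1)
  t1 <- simulate_cann(sb, p, inp, t_end = 20, dt = 0.1, record_every = 1)
  t2 <- simulate_cann(sb, p, inp, t_end = 20, dt = 0.1, record_every = 1)
  expect_identical(t1$table, t2$table)
  expect_error(simulate_cann(sb, p, inp, t_end = 0), "t_end")
})
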