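test_that("firing rate rectifies, normalizes, and respects the 1/k bound", {
  g <- build_grid(16)
  U <- matrix(-abs(rnorm(256)), 16, 16)
  expect_true(all(firing_rate(U, k = 0.5, rho = 10, g) == 0))

  set.seed(7)
  for (i in 1:10) {
    U <- matrix(rnorm(256, sd = i), 16, 16)
    r0 <- firing_rate(U, k = 0, rho = 10, g)
    expect_equal(r0, pmax(U, 0)^2)
    k <- runif(1, 0.01, 2)
    r <- firing_rate(U, k = k, rho = 10, g)
    expect_true(all(r >= 0))
    expect_lt(10 * sum(r) * g$cell_area, 1 / k)
  }
})

test_that("external input peaks at the moving center and wraps", {
  g <- build_grid(32)
  a <- 0.5
  # static input: peak A_amp at the origin node, identical at all active times
  q <- c(g$x[10], g$x[20])
  inp <- input_spec(A_amp = 0.4, v_ext = 0, t_on = 5, t_off = 50, origin = q)
  I1 <- external_input(inp, 5, g, a)
  expect_equal(I1[10, 20], 0.4)
  expect_equal(max(I1), 0.4)
  expect_identical(I1, external_input(inp, 37.3, g, a))
  # zero outside the stimulation window
  expect_true(all(external_input(inp, 4.999, g, a) == 0))
  expect_true(all(external_input(inp, 50.001, g, a) == 0))
  # displacement 2a from the center -> A_amp * exp(-1); pick a = 2*spacing so
  # the node 4 lattice steps away sits exactly at distance 2a
  inp2 <- input_spec(A_amp = 1, v_ext = 0, t_on = 0, origin = c(g$x[10], g$x[20]))
  I2 <- external_input(inp2, 0, g, a = 2 * g$spacing)
  expect_equal(I2[14, 20], exp(-1), tolerance = 1e-12)
})

test_that("moving-input center advances and wraps on the torus", {
  inp <- input_spec(A_amp = 1, v_ext = 1, theta = 0, t_on = 0,
                    origin = c(pi - 0.1, 0), speed_unit = "per_ms")
  expect_equal(input_center(inp, 0), c(pi - 0.1, 0))
  ctr <- input_center(inp, 0.3)
  expect_equal(ctr[1], -pi + 0.2, tolerance = 1e-12)
})

test_that("the silent state is an exact fixed point of the derivatives", {
  g <- build_grid(16)
  p <- model_params(alpha = 3, beta = 40, eta = 10, m = 1, f_min = 0.3)
  kern <- interaction_kernel(g, p$J0, p$a)
  s <- network_state(g, p)
  d <- derivatives(s, p, kern, matrix(0, 16, 16))
  for (nm in c("dU", "df", "dp", "dg", "dV")) {
    expect_true(all(d[[nm]] == 0), label = nm)
  }
})

test_that("derivatives reject fields from a different lattice", {
  g <- build_grid(16)
  p <- model_params()
  kern <- interaction_kernel(g, p$J0, p$a)
  s <- network_state(g, p)
  expect_error(derivatives(s, p, kern, matrix(0, 8, 8)), "grid")
  kern8 <- interaction_kernel(build_grid(8), p$J0, p$a)
  expect_error(derivatives(s, p, kern8, matrix(0, 16, 16)), "kernel")
})

test_that("clamped-drive equilibria match the closed forms to < 0.1%", {
  # Hold U (hence r) and the input fixed; f, p, g, V must relax to
  # f* = (f_min + alpha*r)/(1 + alpha*r), p* = 1/(1 + beta*f*r),
  # g* = 1/(1 + eta*I), V* = m*[U]_+ within 10 time constants.
  g <- build_grid(8)
  p <- model_params(alpha = 5, beta = 30, eta = 8, m = 0.7, f_min = 0.2,
                    tau_f = 4, tau_d = 6, tau_v = 5, tau_g = 7, k = 0.1)
  kern <- interaction_kernel(g, p$J0, p$a)
  inp <- input_spec(A_amp = 0.3, v_ext = 0, t_on = 0, t_off = Inf,
                    origin = c(0, 0))
  s <- network_state(g, p)
  U0 <- bump_template(g, p$a, amplitude = 1.5)
  s$U <- U0
  dt <- 0.05
  n <- ceiling(10 * max(p$tau_f, p$tau_d, p$tau_g, p$tau_v) / dt)
  for (i in seq_len(n)) {
    s <- step_state(s, p, kern, inp, dt)
    s$U <- U0                       # clamp the drive
  }
  rho <- resolve_rho(p, g)
  r <- firing_rate(U0, p$k, rho, g)
  I <- external_input(inp, 1, g, p$a)
  f_star <- (p$f_min + p$alpha * r) / (1 + p$alpha * r)
  p_star <- 1 / (1 + p$beta * f_star * r)
  g_star <- 1 / (1 + p$eta * I)
  v_star <- p$m * pmax(U0, 0)
  expect_equal(s$f, f_star, tolerance = 1e-3)
  expect_equal(s$p, p_star, tolerance = 1e-3)
  expect_equal(s$g, g_star, tolerance = 1e-3)
  expect_equal(s$V, v_star, tolerance = 1e-3)
  # STF equilibrium endpoints: r = 0 -> f_min; r large -> 1
  expect_equal((p$f_min + p$alpha * 0) / (1 + p$alpha * 0), p$f_min)
  r_big <- 1e6
  expect_equal((p$f_min + p$alpha * r_big) / (1 + p$alpha * r_big), 1,
               tolerance = 1e-4)
})
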