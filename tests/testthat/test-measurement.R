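test_that("bump center matches the brute-force circular mean, incl. the seam", {
  g <- build_grid(32)
  # generic positions, including one straddling the -pi/pi seam
  for (q in list(c(0.5, -0.8), c(3.1, 0.2), c(-3.1, 3.1), c(1.0, -3.05))) {
    fld <- bump_template(g, 0.5, q = q, amplitude = 1)
    got <- bump_center(fld, g)
    expect_equal(torus_diff(got - q, g$length), c(0, 0),
                 tolerance = g$spacing)
    oracle <- circular_mean_center(fld, g)
    expect_equal(torus_diff(got - oracle, g$length), c(0, 0),
                 tolerance = 1e-6)
  }
  # random one-mode fields: phase estimate agrees with explicit averaging
  set.seed(11)
  for (i in 1:5) {
    q <- runif(2, -pi, pi)
    fld <- bump_template(g, 0.7, q = q) * (1 + 0.05 * matrix(runif(1024), 32))
    expect_equal(torus_diff(bump_center(fld, g) - circular_mean_center(fld, g),
                            g$length),
                 c(0, 0), tolerance = 1e-6)
  }
})

test_that("bump center is undefined for silent or near-uniform fields", {
  g <- build_grid(16)
  expect_true(all(is.na(bump_center(matrix(0, 16, 16), g))))
  expect_true(all(is.na(bump_center(matrix(1, 16, 16), g))))   # no spatial mode
  expect_true(all(is.na(bump_center(matrix(1e-5, 16, 16) +
                                      1e-6 * bump_template(g, 0.5), g))))
})

test_that("end states are classified by amplitude and drift", {
  # silent: identically-zero trajectory
  tz <- traj_stub(make_table(seq(0, 100, 5), 0))
  expect_equal(classify_endstate(tz)$label, "silent")
  # static bump: constant amplitude, fixed center
  ts <- traj_stub(make_table(seq(0, 100, 5), 1.5, center_x = 0.3))
  expect_equal(classify_endstate(ts)$label, "static_bump")
  # traveling: center advancing at twice the drift threshold
  thr <- measure_thresholds()
  times <- seq(0, 1000, 5)
  v <- 2 * thr$eps_drift
  tw <- traj_stub(make_table(times, 1.5,
                             center_x = torus_diff(v * times, 2 * pi)))
  expect_equal(classify_endstate(tw)$label, "traveling_wave")
  # metastable: long plateau then collapse
  amp <- ifelse(times < 800, 1, 0)
  tm <- traj_stub(make_table(times, amp))
  expect_equal(classify_endstate(tm)$label, "metastable")
  # error when the window exceeds the trajectory
  expect_error(classify_endstate(tz, window = 500), "window")
})

test_that("classification is stable under 2x subsampling", {
  times <- seq(0, 1000, 5)
  thr <- measure_thresholds()
  tw <- traj_stub(make_table(times, 1.5,
                             center_x = torus_diff(3 * thr$eps_drift * times,
                                                   2 * pi)))
  half <- traj_stub(tw$table[seq(1, nrow(tw$table), 2), ])
  expect_equal(classify_endstate(tw)$label, classify_endstate(half)$label)
})

test_that("plateau lifetime crosses at the stated threshold", {
  # flat plateau 500 ms then linear fall over 10 ms: crossing of half level
  # occurs mid-fall -> T_life = 505 ms
  fx <- make_fixture("plateau_trace",
                     list(level = 2, t_offset = 50, plateau = 500, fall = 10))
  res <- plateau_lifetime(fx, 50, tau_f = 4)
  expect_equal(res$T_life, attr(fx, "truth")$T_life, tolerance = 1e-6)
  expect_true(res$held)
  # invariance under uniform amplitude rescaling
  fx2 <- fx; fx2$table$amplitude <- fx2$table$amplitude * 7.3
  expect_equal(plateau_lifetime(fx2, 50, tau_f = 4)$T_life, res$T_life)
  # immediate collapse -> lifetime ~ 0, not held
  tb <- make_table(seq(0, 200, 1), c(rep(2, 51), rep(0, 150)))
  res0 <- plateau_lifetime(traj_stub(tb), 50, tau_f = 10)
  expect_equal(res0$T_life, 0)
  expect_false(res0$held)
  expect_error(plateau_lifetime(fx, 1e5, 4), "outside")
})

test_that("wave speed unwraps seam crossings and is unsigned", {
  fx <- make_fixture("drifting_trace",
                     list(speed = 0.01, origin = c(3, 0), t_end = 1000))
  expect_equal(wave_speed(fx), 0.01, tolerance = 1e-4)
  # reversal leaves the speed unchanged
  rev_fx <- fx
  rev_fx$table$center_x <- rev(rev_fx$table$center_x)
  rev_fx$table$center_y <- rev(rev_fx$table$center_y)
  expect_equal(wave_speed(rev_fx), 0.01, tolerance = 1e-4)
  # invariance under rigid torus translation of the path
  sh_fx <- fx
  sh_fx$table$center_x <- torus_diff(sh_fx$table$center_x + 2.5, 2 * pi)
  expect_equal(wave_speed(sh_fx), wave_speed(fx), tolerance = 1e-10)
  # static path
  st <- traj_stub(make_table(seq(0, 100, 5), 1, center_x = 1.1))
  expect_equal(wave_speed(st), 0, tolerance = 1e-12)
  # undefined centers are an error
  bad <- traj_stub(make_table(seq(0, 100, 5), 1, center_x = NA_real_))
  expect_error(wave_speed(bad), "undefined")
})

test_that("tracking separation carries the lead/lag sign convention", {
  times <- seq(0, 1000, 5)
  v <- 0.002  # rad/ms
  inp <- input_spec(A_amp = 0.15, v_ext = v, theta = 0, t_on = 0,
                    speed_unit = "per_ms")
  ix <- torus_diff(v * times, 2 * pi)
  lead <- traj_stub(make_table(times, 1, center_x = torus_diff(ix + 0.05, 2 * pi),
                               input_x = ix, input_y = 0))
  res <- tracking_separation(lead, inp)
  expect_true(res$tracked)
  expect_equal(res$S, 0.05, tolerance = 1e-10)
  lag <- traj_stub(make_table(times, 1, center_x = torus_diff(ix - 0.05, 2 * pi),
                              input_x = ix, input_y = 0))
  resl <- tracking_separation(lag, inp)
  expect_equal(resl$S, -0.05, tolerance = 1e-10)
  expect_lt(resl$S * v, 0)                   # lagging
  ontop <- traj_stub(make_table(times, 1, center_x = ix, input_x = ix,
                                input_y = 0))
  rest <- tracking_separation(ontop, inp)
  expect_true(rest$tracked)
  expect_equal(rest$S, 0)
  # a dead bump reports S = 0 with tracked = FALSE
  dead <- traj_stub(make_table(times, 0.001, center_x = ix, input_x = ix,
                               input_y = 0))
  resd <- tracking_separation(dead, inp)
  expect_false(resd$tracked)
  expect_equal(resd$S, 0)
  expect_error(tracking_separation(lead, input_spec(A_amp = 1, v_ext = 0)),
               "speed")
})

test_that("fixtures reproduce their stated ground truth", {
  fx <- make_fixture("bump_state", list(q = c(2.9, -3.0)), seed = 5)
  ctr <- bump_center(fx$field, fx$grid)
  expect_equal(torus_diff(ctr - attr(fx, "truth")$center, 2 * pi), c(0, 0),
               tolerance = fx$grid$spacing)
  # seed-reproducible with noise
  fa <- make_fixture("bump_state", list(noise = 0.1), seed = 9)
  fb <- make_fixture("bump_state", list(noise = 0.1), seed = 9)
  expect_identical(fa$field, fb$field)
  dr <- make_fixture("drifting_trace", list(speed = 0.004, theta = pi / 3))
  expect_equal(wave_speed(dr), 0.004, tolerance = 1e-4)
  expect_error(make_fixture("nope"), "arg")
})
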