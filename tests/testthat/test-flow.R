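test_that("cycle normalization rescales time only", {
  t <- seq(0, 0.48, length.out = 20)[1:19]
  w <- flow_waveform(0, t, -sin(2 * pi * t / 0.48), T = 0.48)
  wn <- normalize_cycle(w, 0.53)
  expect_equal(wn$T, 0.53)
  expect_equal(wn$t, t * 0.53 / 0.48, tolerance = 1e-12)
  expect_identical(wn$Q, w$Q)          # extrema untouched
  expect_length(wn$Q, length(w$Q))

  # identity when T already matches; minimal 2-sample input stays valid
  expect_equal(normalize_cycle(w, 0.48)$t, w$t, tolerance = 1e-15)
  w2 <- flow_waveform(0, c(0, 0.2), c(-1, 1), T = 0.4)
  expect_equal(normalize_cycle(w2, 0.53)$T, 0.53)
  expect_error(normalize_cycle(w, -1), "positive")
})

test_that("spatio-temporal surface reconstructs a separable field", {
  waves <- sine_waveforms()
  f <- fit_spatiotemporal(waves)
  truth <- outer(f$z, f$t, function(z, tt) -0.3 * exp(-z / 150) * sin(2 * pi * tt / 0.53))
  rmse <- sqrt(mean((f$Q - truth)^2))
  expect_lt(rmse / 0.3, 0.01)

  # smoothing = "none" interpolates the inputs
  fn <- fit_spatiotemporal(waves, smoothing = "none", nt = 32)
  zl <- vapply(waves, function(w) w$level_z, numeric(1))
  for (i in seq_along(waves)) {
    row <- which.min(abs(fn$z - zl[i]))
    expect_lt(max(abs(fn$Q[row, ] - waves[[i]]$Q)), 1e-6)
  }

  # all-zero input gives an (essentially) all-zero surface
  zeros <- lapply(c(0, 100, 200), function(z) {
    flow_waveform(z, waves[[1]]$t, rep(0, length(waves[[1]]$t)), T = 0.53)
  })
  fz <- fit_spatiotemporal(zeros)
  expect_lt(max(abs(fz$Q)), 1e-10)

  # two levels, no smoothing: linear in z
  two <- sine_waveforms(zs = c(0, 100))
  f2 <- fit_spatiotemporal(two, smoothing = "none")
  mid <- which.min(abs(f2$z - 50))
  lin <- (f2$Q[1, ] * (f2$z[length(f2$z)] - f2$z[mid]) +
            f2$Q[length(f2$z), ] * (f2$z[mid] - f2$z[1])) / diff(range(f2$z))
  expect_equal(f2$Q[mid, ], lin, tolerance = 1e-8)

  # inconsistent time grids are rejected
  bad <- sine_waveforms()
  bad[[2]] <- flow_waveform(25, bad[[2]]$t * 0.9, bad[[2]]$Q, T = 0.53 * 0.9)
  expect_error(fit_spatiotemporal(bad), "common normalized time grid")
})

test_that("peaks, amplitude and sign symmetry behave as defined", {
  waves <- sine_waveforms(q0 = 0.21)
  f <- fit_spatiotemporal(waves, smoothing = "none")
  pk <- extract_peaks(f)
  expect_true(all(pk$Q_sys <= 0), info = "systole is caudal (negative)")
  expect_true(all(pk$Q_dia >= 0))
  expect_equal(pk$Q_a, pk$Q_dia - pk$Q_sys, tolerance = 1e-15)
  # pure sinusoid: amplitude is twice the peak
  expect_equal(pk$Q_a[1], 2 * 0.21, tolerance = 1e-3)

  # Q_a and SV are invariant under a global sign flip
  f_flip <- f; f_flip$Q <- -f$Q
  expect_equal(extract_peaks(f_flip)$Q_a, pk$Q_a, tolerance = 1e-15)
  expect_equal(stroke_volume(f_flip)$SV, stroke_volume(f)$SV, tolerance = 1e-15)
})

test_that("stroke volume matches the analytic rectified-sine integral", {
  waves <- sine_waveforms(q0 = 0.2, nt = 32)
  f <- fit_spatiotemporal(waves, smoothing = "none", nt = 32)
  sv <- stroke_volume(f)
  expect_equal(sv$SV[1], 2 * 0.2 * 0.53 / pi, tolerance = 0.005)

  # linear in |Q|; zero flow gives zero SV
  f2 <- f; f2$Q <- 2 * f$Q
  expect_equal(stroke_volume(f2)$SV, 2 * sv$SV, tolerance = 1e-12)
  f0 <- f; f0$Q[] <- 0
  expect_true(all(stroke_volume(f0)$SV == 0))
})

test_that("PWV recovers a constructed arrival-time slope", {
  zs <- seq(0, 300, by = 10)
  f <- travelling_field(arrival = 0.10 + zs / 1150, zs = zs)
  pw <- pulse_wave_velocity(f)
  expect_equal(pw$PWV, 1.15, tolerance = 1e-3)
  expect_false(pw$degenerate)

  # constant arrival times: flagged infinite, no crash
  fc <- travelling_field(arrival = rep(0.2, length(zs)), zs = zs)
  pwc <- pulse_wave_velocity(fc)
  expect_true(pwc$degenerate)
  expect_identical(pwc$PWV, Inf)

  expect_error(pulse_wave_velocity(travelling_field(c(0.1, 0.2), c(0, 10))),
               ">= 3")
})

test_that("PWV recovery is unbiased under arrival-time noise", {
  set.seed(42)
  zs <- c(0, 25, 55, 110, 180, 250)
  est <- replicate(200, {
    arr <- 0.10 + zs / 1150 + rnorm(length(zs), 0, 0.005)
    pulse_wave_velocity(travelling_field(arr, zs))$PWV
  })
  expect_lt(abs(mean(est) - 1.15) / 1.15, 0.05)
})
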