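test_that("anatomy has three disjoint non-empty muscles and is deterministic", {
  lab <- make_anatomy(128, seed = 1)
  expect_true(all(lab %in% 0:3))
  expect_true(all(c(1, 2, 3) %in% lab))
  expect_identical(lab, make_anatomy(128, seed = 1))
  # brute-force pairwise mask intersection
  masks <- lapply(1:3, function(k) lab == k)
  for (a in 1:2) for (b in (a + 1):3) {
    expect_identical(sum(masks[[a]] & masks[[b]]), 0L)
  }
  expect_false(identical(lab, make_anatomy(128, seed = 2)))
  expect_error(make_anatomy(16), class = "crcest_sizing_error")
})

test_that("creatine-free spectrum is symmetric; shifts act as translations", {
  offs <- c(-2.1, -1.8, -1.5, 1.5, 1.8, 2.1)
  z <- zspectrum_forward(offs, cr_amplitude = 0, b0_ppm = 0)
  expect_equal(z, rev(z))
  # shift equivariance, pointwise
  delta <- 0.17
  z_shift <- zspectrum_forward(offs, cr_amplitude = 0.05, b0_ppm = delta)
  z_ref <- zspectrum_forward(offs - delta, cr_amplitude = 0.05, b0_ppm = 0)
  expect_equal(z_shift, z_ref, tolerance = 1e-12)
})

test_that("model asymmetry at 1.8 ppm matches the two-pool algebra", {
  pools <- crcestr:::default_pools()
  A <- 0.06
  z <- zspectrum_forward(c(-1.8, 1.8), cr_amplitude = A)
  lhs <- (z[1] - z[2]) / z[1]
  # independent algebra on the stated model: the creatine line contributes
  # L_cr(0) at +1.8 and L_cr(3.6) at -1.8; the water line cancels in the
  # numerator
  L0 <- pools$cr_width_ppm^2 / pools$cr_width_ppm^2
  L36 <- pools$cr_width_ppm^2 / (pools$cr_width_ppm^2 + 3.6^2)
  D <- 1 - pools$water_depth *
    pools$water_width_ppm^2 / (pools$water_width_ppm^2 + 1.8^2)
  rhs <- A * (L0 - L36) / (D - A * L36)
  expect_equal(lhs, rhs, tolerance = 1e-12)
})

test_that("amplitude calibration round-trips the target asymmetry", {
  expect_equal(calibrate_cr_amplitude(0), 0)
  for (target in c(6.2, 8.9, 15.1)) {
    a <- calibrate_cr_amplitude(target)
    z <- zspectrum_forward(c(-1.8, 1.8), cr_amplitude = a)
    expect_equal(100 * (z[1] - z[2]) / z[1], target, tolerance = 1e-6)
  }
  expect_error(calibrate_cr_amplitude(-1), class = "crcest_calibration_error")
  expect_error(calibrate_cr_amplitude(55), class = "crcest_calibration_error")
})

test_that("calibration agrees with a bisection oracle on the forward model", {
  target <- 8.0
  measured <- function(a) {
    z <- zspectrum_forward(c(-1.8, 1.8), cr_amplitude = a)
    100 * (z[1] - z[2]) / z[1]
  }
  lo <- 0; hi <- 0.5
  for (i in 1:60) {
    mid <- (lo + hi) / 2
    if (measured(mid) < target) lo <- mid else hi <- mid
  }
  expect_equal(calibrate_cr_amplitude(target), (lo + hi) / 2,
               tolerance = 1e-8)
})

test_that("creatine time course obeys its closed form", {
  p <- cest_protocol()
  tc <- cr_time_course(6.2, 8.9, 138, p)
  expect_equal(tc$asym_pct[tc$time_s < 0], rep(6.2, 5))
  expect_equal(tc$asym_pct[tc$time_s == 0], 6.2 + 8.9)   # delta definition
  # closed form at t - t1 = tau
  p2 <- cest_protocol(post_duration_s = 138 * 2, frame_interval_s = 138,
                      n_baseline_frames = 1)
  tc2 <- cr_time_course(6.2, 8.9, 138, p2)
  expect_equal(tc2$asym_pct[tc2$time_s == 138], 6.2 + 8.9 / exp(1),
               tolerance = 1e-12)
  # asymptote
  expect_lt(abs(cr_time_course(6.2, 8.9, 50, p)$asym_pct[25] - 6.2), 1e-3)
  expect_error(cr_time_course(6, 8, -1, p))
})

test_that("noiseless nominal-field acquisition reproduces resting asymmetry", {
  proto <- short_protocol(matrix = 48)
  ph <- tissue_phantom(make_anatomy(48, 1))
  sim <- simulate_acquisition(ph, proto)
  expect_true(all(sim$cest$data >= 0 & sim$cest$data <= 1))
  for (m in c("LG", "MG", "Sol")) {
    truth <- ph$kinetics$rest_asym_pct[ph$kinetics$muscle == m]
    vox <- sim$label_map == crcestr:::MUSCLES[[m]]
    a <- raw_asym(sim$cest, frame = 1)
    expect_equal(mean(a[vox]), truth, tolerance = 1e-6)
  }
})

test_that("simulation is deterministic and noise has the requested sd", {
  proto <- short_protocol(matrix = 48)
  ph <- tissue_phantom(make_anatomy(48, 1), noise_sd = 0.01)
  s1 <- simulate_acquisition(ph, proto, seed = 7)
  s2 <- simulate_acquisition(ph, proto, seed = 7)
  expect_identical(s1$cest$data, s2$cest$data)
  expect_identical(s1$wassr$data, s2$wassr$data)

  ph0 <- tissue_phantom(make_anatomy(48, 1), noise_sd = 0)
  s0 <- simulate_acquisition(ph0, proto, seed = 7)
  res <- s1$cest$data - s0$cest$data
  expect_gt(length(res), 1e4)
  expect_equal(sd(res), 0.01, tolerance = 0.05)
})

test_that("WASSR spectra are symmetric about the local B0 shift", {
  # offsets at a 0.1 ppm pitch so b0 = 0.1 maps reflections onto grid points
  offs <- seq(-1, 1, by = 0.1)
  w <- wassr_fixture(0.1, offsets = offs)
  z <- w$data[1, 1, ]
  for (k in 1:8) {
    i_plus <- which(abs(offs - (0.1 + k * 0.1)) < 1e-9)
    i_minus <- which(abs(offs - (0.1 - k * 0.1)) < 1e-9)
    expect_equal(z[i_plus], z[i_minus], tolerance = 1e-10)
  }
})
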