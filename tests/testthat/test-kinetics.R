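test_that("ROI means equal single-voxel values and brute-force averages", {
  p <- short_protocol()
  nf <- p$n_baseline_frames + p$n_post_frames
  # single voxel
  maps <- array(rep(seq_len(nf), each = 4), c(2, 2, nf))
  lab <- matrix(c(1L, 0L, 0L, 0L), 2, 2)
  asym <- asym_fixture(maps, p)
  s <- roi_timeseries(asym, lab, "LG")
  expect_equal(s$value_pct, maps[1, 1, ])
  expect_equal(s$n_voxels, rep(1L, nf))
  # uniform value, any mask size
  maps2 <- array(4.2, c(4, 4, nf))
  lab2 <- matrix(1L, 4, 4)
  expect_equal(roi_timeseries(asym_fixture(maps2, p), lab2, "LG")$value_pct,
               rep(4.2, nf))
  # checkerboard of a and b in equal counts vs exhaustive sum
  a <- 3.1; b <- 7.7
  cb <- outer(1:4, 1:4, function(i, j) ifelse((i + j) %% 2 == 0, a, b))
  maps3 <- array(cb, c(4, 4, nf))
  s3 <- roi_timeseries(asym_fixture(maps3, p), lab2, "LG")
  brute <- sum(cb) / length(cb)
  expect_equal(s3$value_pct, rep(brute, nf))
  expect_equal(brute, (a + b) / 2)
  # empty muscle errors with the label name
  expect_error(roi_timeseries(asym, lab, "Sol"), "Sol",
               class = "crcest_data_error")
})

test_that("resting CrCEST is the baseline mean and is order-invariant", {
  p <- cest_protocol()
  s <- simulate_roi_series(6.2, 8.9, 138, p)
  expect_equal(resting_crcest(s), 6.2)
  s2 <- s
  s2$value_pct[1:5] <- c(5, 6, 7, 6, 6)
  expect_equal(resting_crcest(s2), 6.0)
  s3 <- s2
  s3$value_pct[1:5] <- c(6, 7, 6, 6, 5)   # permuted baselines
  expect_equal(resting_crcest(s3), resting_crcest(s2))
  expect_error(resting_crcest(s[s$time_s >= -48, ]),
               class = "crcest_data_error")
})

test_that("delta-CrCEST is the first post value minus resting", {
  p <- cest_protocol()
  s <- simulate_roi_series(6.2, 8.9, 138, p)
  expect_equal(delta_crcest(s), 8.9, tolerance = 1e-12)
  # definition identity
  expect_equal(delta_crcest(s),
               s$value_pct[s$time_s == 0] - resting_crcest(s))
  # arithmetic: resting 6.2, first post 11.4
  s2 <- s
  s2$value_pct[s2$time_s == 0] <- 11.4
  expect_equal(delta_crcest(s2, resting_pct = 6.2), 5.2)
  # zero change
  s3 <- s
  s3$value_pct[s3$time_s == 0] <- resting_crcest(s)
  expect_equal(delta_crcest(s3), 0)
  # a QC-dropped first post frame must not be silently substituted
  s4 <- s[s$time_s != 0, ]
  attr(s4, "all_times_s") <- attr(s, "all_times_s")
  expect_error(delta_crcest(s4), class = "crcest_data_error")
})

test_that("noiseless exponential series recover their time constants", {
  p <- cest_protocol()
  for (tau in c(274, 138)) {
    f <- fit_tau(simulate_roi_series(6.2, 8.9, tau, p))
    expect_lt(abs(f$tau_s - tau), 1)
    expect_equal(f$status, "ok")
    expect_equal(f$asymptote_pct, 6.2, tolerance = 0.1)
  }
})

test_that("fit matches the closed-form solution of exact 3-point data", {
  # exact exponential sampled at 4 equally spaced points; the closed form
  # from any 3 consecutive points determines tau algebraically
  a <- 6.0; b <- 9.0; tau <- 210; h <- 24
  p <- cest_protocol(n_baseline_frames = 1, post_duration_s = 4 * h)
  s <- simulate_roi_series(a, b, tau, p)
  v <- s$value_pct[s$time_s >= 0][1:3]
  r <- (v[3] - v[2]) / (v[2] - v[1])
  tau_cf <- -h / log(r)
  f <- fit_tau(s)
  expect_equal(f$tau_s, tau_cf, tolerance = 1e-6 * tau_cf)
  expect_equal(tau_cf, tau, tolerance = 1e-9)
})

test_that("dropping one interior frame barely moves a noiseless fit", {
  p <- cest_protocol()
  s <- simulate_roi_series(6.2, 8.9, 200, p)
  full <- fit_tau(s)$tau_s
  post_idx <- which(s$time_s > 0 & s$time_s < max(s$time_s))
  for (i in post_idx) {
    s_gap <- s[-i, ]
    attr(s_gap, "all_times_s") <- attr(s, "all_times_s")
    expect_lt(abs(fit_tau(s_gap)$tau_s - full) / full, 0.01)
  }
})

test_that("degenerate series fail loudly or flag fit_failed", {
  p <- cest_protocol(post_duration_s = 72)   # 3 post frames only
  expect_error(fit_tau(simulate_roi_series(6, 8, 100, p)),
               class = "crcest_data_error")
  # flat series: no exercise response, amplitude pinned at zero
  s <- simulate_roi_series(6.2, 0, 100, cest_protocol())
  f <- fit_tau(s)
  expect_equal(f$status, "fit_failed")
  expect_true(nzchar(f$diagnostics))   # diagnostic message is carried along
})

test_that("noisy parameter recovery: median relative tau error below 10%", {
  set.seed(11)
  p <- cest_protocol()
  taus <- runif(200, 50, 400)
  err <- vapply(taus, function(tau) {
    f <- fit_tau(simulate_roi_series(6.2, 8.9, tau, p, noise_sd = 0.3))
    abs(f$tau_s - tau) / tau
  }, numeric(1))
  expect_lt(median(err), 0.10)
  err0 <- vapply(taus[1:20], function(tau) {
    f <- fit_tau(simulate_roi_series(6.2, 8.9, tau, p))
    abs(f$tau_s - tau) / tau
  }, numeric(1))
  expect_lt(max(err0), 0.01)
})

test_that("plausibility filter sets statuses at the 24/1000 s bounds", {
  p <- cest_protocol()
  mk <- function(tau) apply_plausibility_filter(
    fit_tau(simulate_roi_series(6.2, 8.9, tau, p)))
  expect_equal(mk(20)$status, "excluded_low")
  expect_equal(mk(1200)$status, "excluded_high")
  expect_equal(mk(274)$status, "ok")
  # idempotent, and order-independent with respect to the fit values
  f <- mk(1200)
  f2 <- apply_plausibility_filter(f)
  expect_identical(f, f2)
  expect_equal(f2$tau_s, f$tau_s)
  expect_error(apply_plausibility_filter(f, lo = 1000, hi = 24),
               class = "crcest_schema_error")
})

test_that("tidy and glance summarise a fit; autoplot returns a ggplot", {
  f <- fit_tau(simulate_roi_series(6.2, 8.9, 138, cest_protocol()))
  td <- tidy(f)
  expect_s3_class(td, "tbl_df")
  expect_equal(nrow(td), 1)
  expect_true(all(c("tau_s", "status", "rss") %in% names(td)))
  expect_true(glance(f)$converged)
  expect_s3_class(autoplot(f), "ggplot")
})

test_that("pinning the asymptote constrains the fit as configured", {
  p <- cest_protocol()
  s <- simulate_roi_series(6.2, 8.9, 200, p)
  f_free <- fit_tau(s)
  f_pin <- fit_tau(s, pin_asymptote = 6.2)
  expect_equal(f_pin$asymptote_pct, 6.2)
  expect_lt(abs(f_pin$tau_s - 200), 1)
  expect_lt(abs(f_free$tau_s - f_pin$tau_s), 1)
})
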