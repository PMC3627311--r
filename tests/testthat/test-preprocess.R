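test_that("mbll_convert solves the two-wavelength system and matches a brute-force solve", {
  E <- extinction_coefficients("hitachi")
  # zero OD maps to zero hemoglobin
  z <- mbll_convert(rep(0, 5), rep(0, 5), E)
  expect_true(all(z$oxy == 0) && all(z$deoxy == 0))

  # property: random invertible matrices and random Hb pairs, against an
  # independent per-sample solve()
  set.seed(21)
  for (i in 1:25) {
    E <- matrix(stats::runif(4, 0.2, 3), 2, 2)
    if (abs(det(E)) < 0.05) next
    oxy <- stats::rnorm(10)
    deoxy <- stats::rnorm(10)
    od1 <- E[1, 1] * oxy + E[1, 2] * deoxy
    od2 <- E[2, 1] * oxy + E[2, 2] * deoxy
    got <- suppressWarnings(mbll_convert(od1, od2, E))
    oracle <- vapply(seq_along(od1), function(k)
      solve(E, c(od1[k], od2[k])), numeric(2))
    expect_equal(got$oxy, oracle[1, ], tolerance = 1e-12)
    expect_equal(got$deoxy, oracle[2, ], tolerance = 1e-12)
  }

  expect_error(mbll_convert(1:3, 1:4, E), "identical shape")
})

test_that("band-pass rejects DC, keeps the passband, and attenuates the stopband", {
  fs <- 10
  tt <- seq(0, 300, by = 1 / fs)

  expect_lt(max(abs(bandpass(rep(3, length(tt)), fs))), 1e-6)

  mid <- sin(2 * pi * 0.1 * tt)
  g_mid <- max(abs(bandpass(mid, fs)[500:2500]))
  expect_gte(g_mid, 0.9)

  fast <- sin(2 * pi * 3 * tt)
  g_fast <- max(abs(bandpass(fast, fs)[500:2500]))
  expect_lte(g_fast, 0.1)

  expect_error(bandpass(mid, fs = 1), "too low")

  # matrix input filters column-wise
  m <- cbind(mid, fast)
  fm <- bandpass(m, fs)
  expect_equal(dim(fm), dim(m))
})

test_that("artifact detection flags fast large excursions, not slow ramps", {
  lay <- build_layout()
  sch <- make_fixed_schedule(n_targets = 8)
  fs <- 10

  clean <- simulate_recording(sch, lay, NULL, quiet_noise(0.005), fs = fs,
                              seed = 1)
  m0 <- detect_artifacts(clean)
  expect_equal(nrow(m0$events), 0)
  expect_true(all(!m0$flags))

  # a 2.0 mM*mm step exceeds the 1.5 mM*mm / 100 ms criterion
  art <- data.frame(time_s = 100, kind = "step", magnitude = 2.0,
                    width_s = NA, hemisphere = "left")
  hit <- simulate_recording(sch, lay, NULL, quiet_noise(0.005),
                            artifacts = art, fs = fs, seed = 1)
  m1 <- detect_artifacts(hit)
  ev <- m1$events[m1$events$probe == "left", ]
  expect_gte(nrow(ev), 1)
  expect_true(any(ev$start_s <= 100 & ev$end_s >= 100))
  # probe-level assessment: the right pad stays clean
  expect_false(any(m1$events$probe == "right"))

  # a 1.4 mM*mm ramp over 10 s never moves 1.5 within any 100 ms window
  ramp <- clean
  tt <- ramp$time_s
  ramp$oxy <- ramp$oxy + 1.4 * pmin(pmax((tt - 50) / 10, 0), 1)
  m2 <- detect_artifacts(ramp)
  expect_equal(nrow(m2$events), 0)

  # translation invariance: adding a constant changes nothing
  shifted <- hit
  shifted$oxy <- shifted$oxy + 10
  m3 <- detect_artifacts(shifted)
  expect_equal(m3$events, m1$events)

  # calibration: white noise well below threshold flags < 1% of samples
  wn <- simulate_recording(sch, lay, NULL, white_noise(0.05), fs = fs,
                           seed = 9)
  m4 <- detect_artifacts(wn)
  expect_lt(mean(m4$flags), 0.01)
})

test_that("artifact weights zero exactly the flagged stretches", {
  fs <- 10
  n <- 1000
  mask <- new_artifact_mask(
    data.frame(probe = "left", start_s = 10, end_s = 10.5, major = FALSE),
    n = n, fs = fs, probes = c("left", "right"))

  w <- artifact_weights(mask, "left", pad_samples = 0)
  expect_equal(sum(w == 0), ceiling(0.5 * fs))
  expect_true(all(artifact_weights(mask, "right") == 1))

  # padding widens the zero run symmetrically
  wp <- artifact_weights(mask, "left", pad_samples = 2)
  expect_equal(sum(wp == 0), ceiling(0.5 * fs) + 4)

  # overlapping events merge into one zero run
  m2 <- new_artifact_mask(
    data.frame(probe = "left", start_s = c(10, 10.3), end_s = c(10.5, 10.9)),
    n = n, fs = fs, probes = "left")
  w2 <- artifact_weights(m2, "left", pad_samples = 0)
  zero_runs <- rle(w2 == 0)
  expect_equal(sum(zero_runs$values), 1)

  # empty mask: all ones
  m3 <- new_artifact_mask(
    data.frame(probe = character(), start_s = numeric(), end_s = numeric()),
    n = n, fs = fs, probes = "left")
  expect_true(all(artifact_weights(m3, "left") == 1))
})

test_that("baseline-shift boxcars step at major-artifact offsets and are independent", {
  fs <- 10
  n <- 3000  # 300 s
  ev <- data.frame(probe = "left", start_s = c(99.5, 200), end_s = c(100, 200.4),
                   major = c(TRUE, TRUE))
  mask <- new_artifact_mask(ev, n = n, fs = fs, probes = "left")
  B <- baseline_shift_regressors(mask, "left")
  expect_equal(ncol(B), 2)
  tt <- (seq_len(n) - 1) / fs
  expect_equal(B[, 1], as.numeric(tt >= 100))
  expect_equal(qr(B)$rank, 2)

  # minor events contribute no boxcar
  mask2 <- new_artifact_mask(
    data.frame(probe = "left", start_s = 10, end_s = 10.2, major = FALSE),
    n = n, fs = fs, probes = "left")
  expect_equal(ncol(baseline_shift_regressors(mask2, "left")), 0)
})

test_that("major artifacts are classified by excursion or duration", {
  lay <- build_layout()
  sch <- make_fixed_schedule(n_targets = 8)
  # 4.0 mM*mm step: excursion > 2 x threshold -> major
  big <- simulate_recording(sch, lay, NULL, quiet_noise(0.005),
                            artifacts = data.frame(time_s = 100, kind = "step",
                                                   magnitude = 4.0),
                            fs = 10, seed = 2)
  mb <- detect_artifacts(big)
  expect_true(any(mb$events$major))

  # 1.8 mM*mm spike of 0.2 s: above threshold but neither major criterion
  small <- simulate_recording(sch, lay, NULL, quiet_noise(0.005),
                              artifacts = data.frame(time_s = 100,
                                                     kind = "spike",
                                                     magnitude = 1.8,
                                                     width_s = 0.2),
                              fs = 10, seed = 2)
  ms <- detect_artifacts(small)
  expect_gte(nrow(ms$events), 1)
  expect_false(any(ms$events$major))
})
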