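test_that("FIR design has the configured bin bank per condition with disjoint bins", {
  sch <- make_fixed_schedule(n_targets = 8)
  fs <- 10
  fd <- fir_design(sch, fs)
  expect_equal(ncol(fd$X), 20 * 2)
  expect_equal(sum(grepl("^cluster_bin", colnames(fd$X))), 20)
  expect_equal(sum(grepl("^duration_bin", colnames(fd$X))), 20)

  # bin k of a single onset covers exactly [onset+k, onset+k+1)
  one <- make_fixed_schedule(n_targets = 2, baseline_s = 30,
                             conditions = c("cluster", "duration"))
  fo <- fir_design(one, fs)
  onset <- one$blocks$onset_s[one$blocks$kind == "target" &
                                one$blocks$condition == "cluster"]
  tt <- (seq_len(fo$n) - 1) / fs
  b3 <- fo$X[, "cluster_bin3"]
  expect_equal(which(b3 == 1), which(tt >= onset + 3 & tt < onset + 4))
  expect_equal(sum(b3), fs * 1)

  # bins of one condition are mutually orthogonal (disjoint support)
  Xc <- fo$X[, grepl("^cluster_bin", colnames(fo$X))]
  G <- crossprod(Xc)
  expect_true(all(G[upper.tri(G)] == 0))

  # a FIR window longer than the inter-onset gap warns
  crowded <- make_fixed_schedule(n_targets = 4, baseline_s = 9)
  expect_warning(fir_design(crowded, fs, n_bins = 25), "inter-onset gap")
})

test_that("FIR reconstruction recovers the injected response waveform", {
  lay <- build_layout()
  sch <- make_fixed_schedule(n_targets = 8, baseline_s = 15)
  fs <- 10
  amp <- 0.1
  eff <- effect_spec(lay, c(cluster = amp, duration = amp))
  fd <- fir_design(sch, fs)

  # ground truth: the block regressor averaged within each 1-s bin after onset
  reg <- condition_regressor(sch, "cluster", fs, fd$n)
  onsets <- sch$blocks$onset_s[sch$blocks$kind == "target" &
                                 sch$blocks$condition == "cluster"]
  tt <- (seq_len(fd$n) - 1) / fs
  truth <- vapply(0:19, function(k) {
    sel <- rep(FALSE, fd$n)
    for (o in onsets) sel <- sel | (tt >= o + k & tt < o + k + 1)
    amp * mean(reg[sel])
  }, numeric(1))

  # noiseless: bin betas trace the waveform almost exactly
  rec0 <- simulate_recording(sch, lay, eff, noise = NULL, fs = fs)
  est0 <- reconstruct(rec0, fd, channels = 4)
  got0 <- est0$oxy[est0$condition == "cluster" & est0$hemisphere == "left"]
  expect_gt(stats::cor(got0, truth), 0.99)
  expect_equal(attr(est0, "n_bins"), 20)
  expect_equal(est0$total, est0$oxy + est0$deoxy)

  # zero input gives zero betas
  z <- simulate_recording(sch, lay, NULL, NULL, fs = fs)
  ez <- reconstruct(z, fd, channels = 4)
  expect_true(all(abs(ez$total) < 1e-12))

  # noise at amplitude/5: recovery correlation still > 0.95
  recn <- simulate_recording(sch, lay, eff, white_noise(amp / 5), fs = fs,
                             seed = 23)
  estn <- reconstruct(recn, fd, channels = c(4, 6, 7))
  gotn <- estn$oxy[estn$condition == "cluster" & estn$hemisphere == "left" &
                     estn$channel == 4]
  expect_gt(stats::cor(gotn, truth), 0.95)
})

test_that("ROI peak takes the windowed maximum absolute total-Hb across ROI channels", {
  # hand-built estimate: one subject, two channels, one condition
  est <- expand.grid(channel = c(4, 6), hemisphere = c("left", "right"),
                     condition = "cluster", bin = 0:19,
                     stringsAsFactors = FALSE)
  est$t0_s <- est$bin
  est$oxy <- 0
  est$deoxy <- 0
  est$total <- 0
  est$total[est$channel == 4 & est$hemisphere == "left" & est$bin == 1] <- -0.4
  est$total[est$channel == 4 & est$hemisphere == "left" & est$bin == 3] <- 0.2
  est$total[est$channel == 6 & est$hemisphere == "left" & est$bin == 5] <- 0.3
  # a larger peak outside the 0-9 s window must be ignored
  est$total[est$channel == 4 & est$hemisphere == "left" & est$bin == 12] <- 0.9
  est$total[est$channel == 4 & est$hemisphere == "right" & est$bin == 2] <- 0.1
  class(est) <- c("hrf_estimate", "data.frame")
  attr(est, "n_bins") <- 20

  pk <- roi_peak(est, roi = c(4, 6), window_s = c(0, 9))
  left <- pk[pk$hemisphere == "left", ]
  expect_equal(left$peak, 0.4)          # max |total| across channels & bins
  expect_equal(left$peak_signed, -0.4)  # sign retained for reporting
  expect_equal(left$channel, 4)
  right <- pk[pk$hemisphere == "right", ]
  expect_equal(right$peak, 0.1)

  # single-channel ROI
  pk4 <- roi_peak(est, roi = 4, window_s = c(0, 9))
  expect_equal(pk4$peak[pk4$hemisphere == "left"], 0.4)

  expect_error(roi_peak(est, roi = 99), "no channels")
})

test_that("laterality index satisfies its algebraic identities", {
  expect_equal(laterality_index(1, 1), 0)
  expect_equal(laterality_index(2, 1), 1 / 3)
  expect_equal(laterality_index(1, 0), 1)
  expect_equal(laterality_index(0, 1), -1)
  expect_true(is.na(laterality_index(0, 0)))

  set.seed(3)
  L <- stats::runif(50, 0, 2)
  R <- stats::runif(50, 0, 2)
  li <- laterality_index(L, R)
  expect_true(all(li >= -1 & li <= 1))
  expect_equal(laterality_index(R, L), -li)                 # antisymmetry
  expect_equal(laterality_index(3.7 * L, 3.7 * R), li)      # scale invariance
})

test_that("left-dominant simulated cohorts yield positive group-mean laterality", {
  lay <- build_layout()
  fs <- 5
  n_cohorts <- 100
  n_sub <- 15
  set.seed(77)
  pos <- 0
  for (c in seq_len(n_cohorts)) {
    lis <- vapply(seq_len(n_sub), function(s) {
      sch <- make_fixed_schedule(n_targets = 4, baseline_s = 15)
      eff <- effect_spec(lay, c(cluster = 0.1, duration = 0.1),
                         left_scale = 2)  # left amplitude twice the right
      rec <- simulate_recording(sch, lay, eff, white_noise(0.03), fs = fs)
      fd <- fir_design(sch, fs, nrow(rec$oxy))
      est <- reconstruct(rec, fd, channels = c(4, 6, 7))
      pk <- roi_peak(est, lay)
      li <- laterality_from_peaks(pk)
      mean(li$li)
    }, numeric(1))
    if (mean(lis) > 0) pos <- pos + 1
  }
  expect_gte(pos, 95)
})

test_that("group summaries match order-statistic quartiles and flag empty cells", {
  df <- data.frame(group = rep(c("3-5m", "6-7m"), each = 5),
                   condition = "cluster",
                   li = c(-1, -0.5, 0, 0.5, 1, 0.1, 0.2, 0.3, 0.4, 0.5))
  gs <- group_summary(df)
  g1 <- gs[gs$group == "3-5m", ]
  expect_equal(g1$mean, 0)
  expect_equal(g1$min, -1)
  expect_equal(g1$max, 1)
  # type-7 quartiles against a direct sort-based computation
  expect_equal(g1$q1, unname(stats::quantile(c(-1, -0.5, 0, 0.5, 1), 0.25)))
  expect_equal(g1$q3, unname(stats::quantile(c(-1, -0.5, 0, 0.5, 1), 0.75)))

  one <- data.frame(group = "g", condition = "c", li = 0.3)
  gone <- group_summary(one)
  expect_equal(gone$mean, 0.3)
  expect_equal(gone$q1, gone$q3)  # zero-width box for a single value

  mixed <- rbind(df, data.frame(group = "8-9m", condition = "cluster",
                                li = NA_real_))
  expect_warning(gm <- group_summary(mixed), "empty cell")
  expect_false("8-9m" %in% gm$group)
})
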