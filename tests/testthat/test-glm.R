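test_that("design matrix carries intercept, two condition columns, and minute-period detrends", {
  # 8 targets, 13.5 s baselines: 8*9 + 9*13.5 = 193.5 s -> 3 whole minutes
  sch <- make_fixed_schedule(n_targets = 8, baseline_s = 13.5)
  d <- build_design(sch, fs = 10)
  expect_equal(sum(grepl("^condition_", colnames(d$X))), 2)
  expect_equal(sum(grepl("^detrend_", colnames(d$X))), 4)  # periods 2,3 min
  expect_true("intercept" %in% colnames(d$X))
  expect_true(d$full_rank)

  # six whole minutes of session: sine+cosine pairs for periods 2..6 min
  sch6 <- make_fixed_schedule(n_targets = 16, target_s = 9, baseline_s = 13.5)
  expect_equal(floor(session_duration(sch6) / 60), 6)
  d6 <- build_design(sch6, fs = 8)
  expect_equal(sum(grepl("^detrend_", colnames(d6$X))), 10)

  # detrend columns are near-orthogonal to the intercept (zero mean)
  dt <- d6$X[, grepl("^detrend_", colnames(d6$X))]
  expect_lt(max(abs(colMeans(dt))), 1e-10)

  # sessions under 2 minutes carry no detrend columns, with a warning
  short <- make_fixed_schedule(n_targets = 4, baseline_s = 9)
  expect_warning(ds <- build_design(short, fs = 10), "shorter than 2 min")
  expect_equal(sum(grepl("^detrend_", colnames(ds$X))), 0)
})

test_that("a schedule without one condition's blocks is flagged rank-deficient", {
  sch <- make_fixed_schedule(n_targets = 4, conditions = c("cluster", "duration"))
  sch$blocks$condition[sch$blocks$kind == "target"] <- "cluster"
  d <- suppressWarnings(build_design(sch, fs = 10))
  expect_false(d$full_rank)
  expect_true(all(d$X[, "condition_duration"] == 0))
  y <- stats::rnorm(d$n)
  expect_error(fit_weighted(y, d), "condition_duration")
})

test_that("weighted least squares matches lm() with unit weights and handles edge cases", {
  sch <- make_fixed_schedule(n_targets = 8)
  d <- build_design(sch, fs = 10)
  set.seed(4)
  y <- 0.1 * d$X[, "condition_cluster"] - 0.04 * d$X[, "condition_duration"] +
    0.02 * d$X[, "detrend_sin_2min"] + stats::rnorm(d$n, 0, 0.05)

  f <- fit_weighted(y, d)
  oracle <- stats::lm(y ~ 0 + ., data = as.data.frame(d$X))
  expect_equal(unname(f$beta), unname(coef(oracle)), tolerance = 1e-10)
  expect_equal(unname(f$se), unname(sqrt(diag(vcov(oracle)))),
               tolerance = 1e-8)

  expect_error(fit_weighted(y, d, weights = rep(0, d$n)), "no usable samples")
  expect_error(fit_weighted(y[-1], d), "length")

  # zero-weighting a stretch ignores it: corrupt those samples freely
  w <- rep(1, d$n)
  w[100:200] <- 0
  y2 <- y
  y2[100:200] <- 50
  f2 <- fit_weighted(y2, d, weights = w)
  f2_ref <- fit_weighted(y, d, weights = w)
  expect_equal(f2$beta, f2_ref$beta)
  expect_true(all(is.na(f2$residuals[100:200])))
})

test_that("condition betas are recovered within 10% on seeded noisy simulations", {
  lay <- build_layout()
  sch <- make_fixed_schedule(n_targets = 8)
  fs <- 10
  eff <- effect_spec(lay, c(cluster = 0.1, duration = 0.1))
  rec <- simulate_recording(sch, lay, eff, quiet_noise(0.01), fs = fs,
                            seed = 17)
  d <- build_design(sch, fs, nrow(rec$oxy))
  for (jid in c(4, 6, 7)) {
    j <- which(rec$channels$id == jid & rec$channels$hemisphere == "left")
    f <- fit_weighted(rec$oxy[, j], d)
    expect_equal(unname(f$beta["condition_cluster"]), 0.1, tolerance = 0.1)
    expect_equal(unname(f$beta["condition_duration"]), 0.1, tolerance = 0.1)
  }
})

test_that("Monte-Carlo max-statistic correction finds strong responses and is monotone", {
  lay <- build_layout()
  sch <- make_fixed_schedule(n_targets = 8, baseline_s = 13.5)
  fs <- 5
  # response 5x the noise sd in the ROI channels
  eff <- effect_spec(lay, c(cluster = 0.25, duration = 0.25))
  rec <- simulate_recording(sch, lay, eff, white_noise(0.05), fs = fs,
                            seed = 31)
  d <- build_design(sch, fs, nrow(rec$oxy))
  resp <- responding_channels(rec, d, n_mc = 500, seed = 32)

  roi_left <- resp$responding[resp$channel %in% c(4, 6, 7) &
                                resp$hemisphere == "left"]
  expect_true(all(roi_left))
  expect_true(all(resp$p_corrected >= 0 & resp$p_corrected <= 1))

  # corrected p monotone decreasing in |r| within the family
  o <- order(abs(resp$r))
  expect_true(all(diff(resp$p_corrected[o]) <= 1e-12))

  # too-short sessions cannot honor the minimum circular shift
  tiny <- make_fixed_schedule(n_targets = 2, baseline_s = 9)
  rec2 <- simulate_recording(tiny, lay, NULL, white_noise(0.05), fs = 5,
                             seed = 1)
  d2 <- suppressWarnings(build_design(tiny, 5, nrow(rec2$oxy)))
  expect_error(responding_channels(rec2, d2, n_mc = 10, min_shift_s = 30),
               "too short")
})

# Independent oracle: textbook cell-mean sums of squares for a balanced
# two-factor within-subject design with one observation per cell.
rm_anova_oracle <- function(d, f1, f2) {
  y <- d$y
  A <- d[[f1]]; B <- d[[f2]]; S <- d$subject
  a <- length(unique(A)); b <- length(unique(B)); n <- length(unique(S))
  gm <- mean(y)
  mA <- tapply(y, A, mean); mB <- tapply(y, B, mean)
  mS <- tapply(y, S, mean)
  mAB <- tapply(y, list(A, B), mean)
  mAS <- tapply(y, list(A, S), mean)
  mBS <- tapply(y, list(B, S), mean)
  ssA <- n * b * sum((mA - gm)^2)
  ssB <- n * a * sum((mB - gm)^2)
  ssAB <- n * sum((sweep(sweep(mAB, 1, mA), 2, mB) + gm)^2)
  ssAS <- b * sum((sweep(sweep(mAS, 1, mA), 2, mS) + gm)^2)
  ssBS <- a * sum((sweep(sweep(mBS, 1, mB), 2, mS) + gm)^2)
  ssTot <- sum((y - gm)^2)
  ssS <- a * b * sum((mS - gm)^2)
  ssABS <- ssTot - ssA - ssB - ssAB - ssS - ssAS - ssBS
  list(
    FA = (ssA / (a - 1)) / (ssAS / ((a - 1) * (n - 1))),
    FB = (ssB / (b - 1)) / (ssBS / ((b - 1) * (n - 1))),
    FAB = (ssAB / ((a - 1) * (b - 1))) / (ssABS / ((a - 1) * (b - 1) * (n - 1)))
  )
}

test_that("repeated-measures ANOVA agrees with the hand-computed sums of squares", {
  set.seed(8)
  for (rep in 1:5) {
    d <- expand.grid(subject = 1:6, condition = c("cluster", "duration"),
                     hemisphere = c("left", "right"),
                     stringsAsFactors = FALSE)
    d$beta <- stats::rnorm(nrow(d), 0.05, 0.02) +
      0.03 * (d$condition == "duration") * (d$hemisphere == "left")
    tab <- anova_condition_hemisphere(d)
    d$y <- d$beta
    orc <- rm_anova_oracle(d, "condition", "hemisphere")
    expect_equal(tab$F[tab$effect == "condition"], orc$FA, tolerance = 1e-8)
    expect_equal(tab$F[tab$effect == "hemisphere"], orc$FB, tolerance = 1e-8)
    expect_equal(tab$F[tab$effect == "interaction"], orc$FAB, tolerance = 1e-8)
    expect_equal(tab$df1, rep(1, 3))
    expect_equal(tab$df2, rep(5, 3))
  }

  # identical values in every cell: all effects exactly zero
  flat <- expand.grid(subject = 1:4, condition = c("cluster", "duration"),
                      hemisphere = c("left", "right"),
                      stringsAsFactors = FALSE)
  flat$beta <- 0.2
  tabf <- anova_condition_hemisphere(flat)
  expect_equal(tabf$F, rep(0, 3))
  expect_equal(tabf$p, rep(1, 3))

  # empty cells and single subjects are rejected
  expect_error(anova_condition_hemisphere(flat[flat$hemisphere == "left", ]),
               "empty design cell")
  expect_error(anova_condition_hemisphere(flat[flat$subject == 1, ]),
               "at least 2 subjects")
})

test_that("a lateralized condition-specific effect yields a detectable interaction", {
  # left-only effect for one condition, effect 3x the between-measure noise
  set.seed(12)
  hits <- 0
  for (c in 1:100) {
    d <- expand.grid(subject = 1:15, condition = c("cluster", "duration"),
                     hemisphere = c("left", "right"),
                     stringsAsFactors = FALSE)
    d$beta <- stats::rnorm(nrow(d), 0, 0.02) +
      0.06 * (d$condition == "duration") * (d$hemisphere == "left")
    tab <- anova_condition_hemisphere(d)
    if (tab$p[tab$effect == "interaction"] < 0.05) hits <- hits + 1
  }
  expect_gte(hits, 80)
})
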