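#' Build the block-design GLM design matrix
#'
#' Columns: an intercept; one HRF-convolved boxcar regressor per target
#' condition (see [condition_regressor()]); sine and cosine detrend
#' regressors with periods of 2, 3, ..., n minutes up to the session
#' duration (none, with a warning, for sessions under 2 minutes); and any
#' supplied baseline-shift boxcars from [baseline_shift_regressors()].
#'
#' @param schedule A `nirs_schedule`.
#' @param fs Sampling rate, Hz.
#' @param n_samples Number of samples; defaults to the session length.
#' @param hrf List of [canonical_hrf()] parameter overrides.
#' @param baseline_boxcars Optional sample x event matrix of step
#'   regressors.
#' @param detrend If `FALSE`, omit the sine/cosine columns.
#' @return A `nirs_design`: list with `X` (named column matrix),
#'   `condition_cols`, `fs`, `n`, `full_rank`.
#' @examples
#' sch <- generate_infant_schedule(16, seed = 1)
#' d <- build_design(sch, fs = 10)
#' colnames(d$X)
#' @export
build_design <- function(schedule, fs, n_samples = NULL, hrf = list(),
                         baseline_boxcars = NULL, detrend = TRUE) {
  stopifnot(inherits(schedule, "nirs_schedule"), fs > 0)
  session_s <- session_duration(schedule)
  if (is.null(n_samples)) n_samples <- ceiling(session_s * fs)
  tt <- (seq_len(n_samples) - 1) / fs

  conds <- schedule$conditions
  cond_cols <- paste0("condition_", conds)
  Xc <- vapply(conds, function(cd)
    condition_regressor(schedule, cd, fs, n_samples, hrf), numeric(n_samples))
  colnames(Xc) <- cond_cols

  Xd <- NULL
  if (detrend) {
    max_min <- floor(session_s / 60 + 1e-9)
    if (max_min < 2) {
      warning("session shorter than 2 min; no detrend regressors added")
    } else {
      periods <- 2:max_min
      Xd <- do.call(cbind, lapply(periods, function(p) {
        m <- cbind(sin(2 * pi * tt / (60 * p)), cos(2 * pi * tt / (60 * p)))
        colnames(m) <- paste0(c("detrend_sin_", "detrend_cos_"), p, "min")
        m
      }))
      # center so the nuisance terms stay orthogonal to the intercept even
      # when the session spans a non-integer number of periods
      Xd <- sweep(Xd, 2, colMeans(Xd))
    }
  }

  if (!is.null(baseline_boxcars)) {
    baseline_boxcars <- as.matrix(baseline_boxcars)
    if (nrow(baseline_boxcars) != n_samples) {
      stop("baseline_boxcars must have ", n_samples, " rows")
    }
    if (ncol(baseline_boxcars) > 0 && is.null(colnames(baseline_boxcars))) {
      colnames(baseline_boxcars) <- paste0("baseline_shift_",
                                           seq_len(ncol(baseline_boxcars)))
    }
    if (ncol(baseline_boxcars) == 0) baseline_boxcars <- NULL
  }

  X <- cbind(intercept = rep(1, n_samples), Xc, Xd, baseline_boxcars)
  full_rank <- qr(X)$rank == ncol(X)
  structure(list(X = X, condition_cols = cond_cols, fs = fs, n = n_samples,
                 full_rank = full_rank),
            class = "nirs_design")
}

# Rank check on the weighted design; errors naming the collinear columns.
.check_rank <- function(Xw, cols) {
  q <- qr(Xw)
  p <- ncol(Xw)
  if (q$rank < p) {
    bad <- cols[q$pivot[(q$rank + 1):p]]
    stop("design is rank-deficient on the usable samples; collinear or ",
         "empty columns: ", paste(bad, collapse = ", "))
  }
  invisible(q)
}

#' Fit the artifact-weighted GLM for one channel
#'
#' Weighted least squares with 0/1 weights excluding artifacted samples.
#' Reports per-regressor betas and standard errors, standardized effects
#' `z = beta / se` for the condition regressors, and `r`: the Pearson
#' correlation — computed on the weight-1 samples only — between the
#' observed series and the fitted condition part of the model (the
#' "degree of correlation" that decides responding channels).
#'
#' @param y Observed series (mM*mm), length `design$n`.
#' @param design A [build_design()] result.
#' @param weights 0/1 vector from [artifact_weights()], or `NULL` for all
#'   ones.
#' @return A `channel_fit`: list with `beta`, `se`, `z`, `r`, `p_raw`
#'   (two-sided normal p of z, condition columns), `fitted`, `residuals`
#'   (NA at zero-weight samples), `n_used`, `df_residual`.
#' @export
fit_weighted <- function(y, design, weights = NULL) {
  stopifnot(inherits(design, "nirs_design"))
  X <- design$X
  n <- nrow(X)
  if (length(y) != n) stop("y must have length ", n)
  if (is.null(weights)) weights <- rep(1, n)
  if (length(weights) != n) stop("weights must have length ", n)
  idx <- weights > 0
  if (!any(idx)) stop("no usable samples: all weights are zero")

  Xu <- X[idx, , drop = FALSE]
  yu <- y[idx]
  .check_rank(Xu, colnames(X))

  fit <- stats::lm.fit(Xu, yu)
  beta <- fit$coefficients
  p <- ncol(X)
  df_resid <- sum(idx) - p
  if (df_resid <= 0) stop("not enough usable samples (", sum(idx),
                          ") for ", p, " regressors")
  sigma2 <- sum(fit$residuals^2) / df_resid
  XtXinv <- chol2inv(chol(crossprod(Xu)))
  se <- sqrt(diag(XtXinv) * sigma2)
  names(se) <- colnames(X)
  z <- beta / se

  cond <- design$condition_cols
  cond_pred <- X[, cond, drop = FALSE] %*% beta[cond]
  r <- if (stats::sd(cond_pred[idx]) > 0 && stats::sd(yu) > 0) {
    stats::cor(yu, cond_pred[idx])
  } else 0

  fitted <- as.numeric(X %*% beta)
  resid <- rep(NA_real_, n)
  resid[idx] <- yu - fitted[idx]

  structure(
    list(beta = beta, se = se, z = z, r = r,
         p_raw = 2 * stats::pnorm(-abs(z[cond])),
         fitted = fitted, residuals = resid,
         n_used = sum(idx), df_residual = df_resid,
         condition_cols = cond),
    class = "channel_fit"
  )
}

#' Fit every channel of a recording
#'
#' @param recording A `nirs_recording`.
#' @param design A `nirs_design`.
#' @param mask Optional `artifact_mask`; each channel uses the exclusion
#'   weights of its own probe (pad).
#' @param signal Which series to fit: `"oxy"`, `"deoxy"` or `"total"`.
#' @param pad_samples Passed to [artifact_weights()].
#' @return List with `fits` (per-channel `channel_fit`s) and `report`, a
#'   tidy data frame (channel, hemisphere, condition, beta, se, z, r,
#'   p_raw).
#' @export
fit_channels <- function(recording, design, mask = NULL,
                         signal = c("oxy", "deoxy", "total"),
                         pad_samples = 1) {
  signal <- match.arg(signal)
  Y <- switch(signal, oxy = recording$oxy, deoxy = recording$deoxy,
              total = total_hb(recording))
  ch <- recording$channels
  wts <- .probe_weights(mask, ch, nrow(Y), pad_samples)
  fits <- lapply(seq_len(ncol(Y)), function(j)
    fit_weighted(Y[, j], design, wts[[ch$hemisphere[j]]]))
  names(fits) <- colnames(Y)
  report <- do.call(rbind, lapply(seq_len(ncol(Y)), function(j) {
    f <- fits[[j]]
    data.frame(channel = ch$id[j], hemisphere = ch$hemisphere[j],
               condition = sub("^condition_", "", f$condition_cols),
               beta = unname(f$beta[f$condition_cols]),
               se = unname(f$se[f$condition_cols]),
               z = unname(f$z[f$condition_cols]),
               r = f$r, p_raw = unname(f$p_raw))
  }))
  rownames(report) <- NULL
  list(fits = fits, report = report, signal = signal)
}

.probe_weights <- function(mask, channels, n, pad_samples) {
  probes <- unique(channels$hemisphere)
  out <- lapply(probes, function(p) {
    if (is.null(mask)) rep(1, n) else artifact_weights(mask, p, pad_samples)
  })
  names(out) <- probes
  out
}

#' Responding channels by Monte-Carlo max-statistic correction
#'
#' Decides which channels responded to the stimulation, controlling the
#' family-wise error across channels in the Westfall-Young max-statistic
#' style.  The null distribution is built by circularly shifting each
#' channel's observed series by a uniform random offset of at least
#' `min_shift_s` seconds (breaking the alignment with the paradigm while
#' preserving the autocorrelation structure), refitting the GLM, and
#' retaining the maximum `|r|` across channels in each of `n_mc`
#' iterations.  The corrected p of a channel is the fraction of null
#' maxima at least as large as its observed `|r|`; corrected p-values are
#' therefore monotone in `|r|` within the family.
#'
#' A residual-resampling alternative (`null = "residual"`) permutes whole
#' blocks of residuals added back to the nuisance-only prediction.
#'
#' @param recording A `nirs_recording`.
#' @param design A `nirs_design`.
#' @param mask Optional `artifact_mask` (probe-level weights).
#' @param n_mc Number of Monte-Carlo iterations (study default 10,000).
#' @param alpha Two-sided family-wise level (default 0.05).
#' @param min_shift_s Minimum circular shift, seconds (default 30).
#' @param signal Series to test (default `"oxy"`).
#' @param null `"circular"` (default) or `"residual"`.
#' @param seed Optional integer seed for the resampling.
#' @param pad_samples Passed to [artifact_weights()].
#' @return Data frame (channel, hemisphere, r, p_corrected, responding)
#'   with the null max-|r| sample as attribute `"null_max"`.
#' @export
responding_channels <- function(recording, design, mask = NULL, n_mc = 10000,
                                alpha = 0.05, min_shift_s = 30,
                                signal = c("oxy", "deoxy", "total"),
                                null = c("circular", "residual"),
                                seed = NULL, pad_samples = 1) {
  signal <- match.arg(signal)
  null <- match.arg(null)
  if (!is.null(seed)) set.seed(seed)
  Y <- switch(signal, oxy = recording$oxy, deoxy = recording$deoxy,
              total = total_hb(recording))
  ch <- recording$channels
  n <- nrow(Y)
  fs <- design$fs
  X <- design$X
  cond <- design$condition_cols

  smin <- ceiling(min_shift_s * fs)
  if (n - smin < smin) {
    stop("session too short for the minimum circular shift of ",
         min_shift_s, " s")
  }
  valid_shifts <- smin:(n - smin)

  wts <- .probe_weights(mask, ch, n, pad_samples)
  nch <- ncol(Y)
  r_obs <- numeric(nch)
  Rnull <- matrix(NA_real_, n_mc, nch)

  # the design decomposition only depends on the probe's weights: cache it
  ci <- match(cond, colnames(X))
  solvers <- lapply(wts, function(w) {
    idx <- which(w > 0)
    Xu <- X[idx, , drop = FALSE]
    .check_rank(Xu, colnames(X))
    XtXinv <- chol2inv(chol(crossprod(Xu)))
    Pinv <- XtXinv %*% t(Xu)                     # p x n_used
    list(idx = idx, Xu = Xu,
         Pc = Pinv[ci, , drop = FALSE],          # 2 x n_used
         Xc = Xu[, ci, drop = FALSE])            # n_used x 2
  })

  for (j in seq_len(nch)) {
    sv <- solvers[[ch$hemisphere[j]]]
    idx <- sv$idx
    Xu <- sv$Xu
    Pc <- sv$Pc
    Xc <- sv$Xc

    y <- Y[, j]
    r_obs[j] <- .cond_cor(y[idx], Xc, Pc)

    if (null == "circular") {
      shifts <- sample(valid_shifts, n_mc, replace = TRUE)
      Rnull[, j] <- .null_r_circular(y, idx, n, shifts, Xc, Pc)
    } else {
      fitj <- stats::lm.fit(Xu, y[idx])
      nuis <- y[idx] - as.numeric(Xc %*% fitj$coefficients[ci])
      res <- fitj$residuals
      base <- nuis - res                          # nuisance-only prediction
      for (m in seq_len(n_mc)) {
        ys <- base + res[sample.int(length(res))]
        Rnull[m, j] <- .cond_cor(ys, Xc, Pc)
      }
    }
  }

  null_max <- apply(abs(Rnull), 1, max)
  p_corr <- vapply(r_obs, function(r) mean(null_max >= abs(r)), numeric(1))
  out <- data.frame(channel = ch$id, hemisphere = ch$hemisphere,
                    r = r_obs, p_corrected = p_corr,
                    responding = p_corr < alpha)
  rownames(out) <- NULL
  attr(out, "null_max") <- null_max
  out
}

# correlation between y and its fitted condition prediction
.cond_cor <- function(yu, Xc, Pc) {
  pred <- as.numeric(Xc %*% (Pc %*% yu))
  if (stats::sd(pred) == 0 || stats::sd(yu) == 0) return(0)
  stats::cor(yu, pred)
}

# vectorized null r over circular shifts: build the shifted-sample matrix
# restricted to the usable rows, then compute column-wise correlations
.null_r_circular <- function(y, idx, n, shifts, Xc, Pc, chunk = 500L) {
  m <- length(shifts)
  nu <- length(idx)
  out <- numeric(m)
  i0 <- idx - 1L
  for (a in seq(1L, m, by = chunk)) {
    b <- min(a + chunk - 1L, m)
    sh <- shifts[a:b]
    pos <- outer(i0, sh, function(i, s) ((i + s) %% n) + 1L)
    Ys <- matrix(y[pos], nu, length(sh))
    Bc <- Pc %*% Ys                               # 2 x mchunk
    Yh <- Xc %*% Bc                               # nu x mchunk
    out[a:b] <- .col_cor(Ys, Yh)
  }
  out
}

# column-wise Pearson correlation of two equal-shaped matrices
.col_cor <- function(A, B) {
  n <- nrow(A)
  ma <- colMeans(A)
  mb <- colMeans(B)
  sab <- colSums(A * B) / n - ma * mb
  va <- colSums(A^2) / n - ma^2
  vb <- colSums(B^2) / n - mb^2
  r <- sab / sqrt(pmax(va * vb, 0))
  r[!is.finite(r)] <- 0
  r
}

# Shared balanced 2x2 within-subject (repeated measures) ANOVA.
# Implementation: stats::aov with subject Error strata; degenerate strata
# with zero effect and zero error sums of squares report F = 0, p = 1.
.rm_anova_2x2 <- function(df, dv, f1, f2, subject) {
  for (v in c(dv, f1, f2, subject)) {
    if (!v %in% names(df)) stop("missing column: ", v)
  }
  d <- data.frame(y = df[[dv]],
                  A = factor(df[[f1]]), B = factor(df[[f2]]),
                  S = factor(df[[subject]]))
  if (nlevels(d$S) < 2) stop("need at least 2 subjects")
  if (nlevels(d$A) < 2 || nlevels(d$B) < 2) {
    stop("empty design cell: factors ", f1, " and ", f2,
         " each need at least 2 levels")
  }
  cells <- table(d$S, d$A, d$B)
  if (any(cells == 0)) stop("empty design cell: every subject needs every ",
                            f1, " x ", f2, " combination")
  if (any(cells != cells[1])) stop("unbalanced design: unequal cell counts")

  fit <- stats::aov(y ~ A * B + Error(S / (A * B)), data = d)
  sm <- summary(fit)
  rows <- list()
  for (stratum in names(sm)) {
    tab <- sm[[stratum]][[1]]
    terms <- trimws(rownames(tab))
    for (i in seq_len(nrow(tab))) {
      if (terms[i] == "Residuals") next
      ss_err <- tab["Residuals", "Sum Sq"]
      df_err <- tab["Residuals", "Df"]
      ss <- tab[i, "Sum Sq"]
      Fv <- tab[i, "F value"]
      pv <- tab[i, "Pr(>F)"]
      if (!is.finite(Fv)) {           # 0/0 strata: no effect, no error
        Fv <- 0
        pv <- 1
      }
      rows[[length(rows) + 1L]] <- data.frame(
        effect = terms[i], df1 = tab[i, "Df"], df2 = df_err,
        ss = ss, ss_error = ss_err, F = Fv, p = pv)
    }
  }
  out <- do.call(rbind, rows)
  out$effect <- sub("^A:B$", "interaction", out$effect)
  out$effect <- sub("^A$", f1, out$effect)
  out$effect <- sub("^B$", f2, out$effect)
  rownames(out) <- NULL
  out
}

#' Condition x Hemisphere repeated-measures ANOVA on channel betas
#'
#' The planned group analysis: beta values of responding channels (and
#' their hemispheric counterparts) enter a two-way within-subject ANOVA
#' with factors Condition (cluster, duration) and Hemisphere (left,
#' right).  A significant interaction is the signature of lateralized,
#' condition-specific responses.
#'
#' @param betas Data frame with columns `subject`, `condition`,
#'   `hemisphere`, `beta` — one value per subject x condition x hemisphere
#'   cell (balanced).
#' @return Data frame with `effect` (`condition`, `hemisphere`,
#'   `interaction`), `df1`, `df2`, `ss`, `ss_error`, `F`, `p`.
#' @export
anova_condition_hemisphere <- function(betas) {
  .rm_anova_2x2(betas, "beta", "condition", "hemisphere", "subject")
}

#' 2 x 2 within-subject ANOVA on GLM Z-scores (adult design)
#'
#' Tests the factorial manipulation of the adult follow-up: target-block
#' duration (short 9 s vs. long 15 s) by token variability (single vs.
#' multiple exemplars), using the standardized condition effects
#' (`z = beta / se`) from the channel GLM fits.
#'
#' @param z_scores Data frame with columns `subject`, `duration`,
#'   `tokens`, `z` — one value per subject x duration x tokens cell.
#' @return Data frame as in [anova_condition_hemisphere()].
#' @export
anova_2x2_within <- function(z_scores) {
  .rm_anova_2x2(z_scores, "z", "duration", "tokens", "subject")
}
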