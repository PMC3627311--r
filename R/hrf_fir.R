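#' FIR design matrix of time-shifted boxcars
#'
#' Shape-free reconstruction of the hemodynamic response: per condition, a
#' bank of `n_bins` one-second (by default) boxcar regressors, bin k being
#' 1 during `[onset + k*bin_s, onset + (k+1)*bin_s)` for every target-block
#' onset of that condition.  With the defaults this is 20 regressors per
#' condition covering post-onset shifts of 0-19 s; the bin count and width
#' are configurable.  For a single onset the bins have disjoint support and
#' are mutually orthogonal.
#'
#' @param schedule A `nirs_schedule`.
#' @param fs Sampling rate, Hz.
#' @param n_samples Number of samples; defaults to the session length.
#' @param n_bins Number of shifted boxcars per condition (default 20).
#' @param bin_s Bin width in seconds (default 1).
#' @param conditions Conditions to model (default: all in the schedule).
#' @return A `fir_design`: list with `X` (columns `<condition>_bin<k>`),
#'   `n_bins`, `bin_s`, `conditions`, `fs`, `n`.
#' @export
fir_design <- function(schedule, fs, n_samples = NULL, n_bins = 20,
                       bin_s = 1, conditions = schedule$conditions) {
  stopifnot(inherits(schedule, "nirs_schedule"), fs > 0, n_bins >= 1,
            bin_s > 0)
  if (is.null(n_samples)) n_samples <- ceiling(session_duration(schedule) * fs)
  tt <- (seq_len(n_samples) - 1) / fs
  b <- schedule$blocks
  tb <- b[b$kind == "target", ]
  gaps <- diff(sort(tb$onset_s))
  if (length(gaps) > 0 && n_bins * bin_s > min(gaps)) {
    warning("FIR window (", n_bins * bin_s, " s) exceeds the shortest ",
            "inter-onset gap (", min(gaps), " s); late bins overlap the ",
            "next block's response")
  }

  cols <- list()
  for (cd in conditions) {
    onsets <- tb$onset_s[!is.na(tb$condition) & tb$condition == cd]
    for (k in seq_len(n_bins) - 1L) {
      v <- numeric(n_samples)
      for (o in onsets) {
        v[tt >= o + k * bin_s - 1e-9 & tt < o + (k + 1) * bin_s - 1e-9] <- 1
      }
      cols[[paste0(cd, "_bin", k)]] <- v
    }
  }
  X <- do.call(cbind, cols)
  structure(list(X = X, n_bins = n_bins, bin_s = bin_s,
                 conditions = conditions, fs = fs, n = n_samples),
            class = "fir_design")
}

#' Reconstruct the hemodynamic response with the FIR model
#'
#' Least-squares fit of the FIR bank (plus an intercept) to each channel's
#' oxy- and deoxy-Hb series separately; the total-Hb response is the
#' bin-wise sum of the two.  The fitted bin betas trace the response
#' waveform in mM*mm per bin without assuming its shape.
#'
#' @param recording A `nirs_recording`.
#' @param fir A [fir_design()].
#' @param mask Optional `artifact_mask` for probe-level 0/1 weights.
#' @param channels Optional integer ids restricting which channels are fit.
#' @param pad_samples Passed to [artifact_weights()].
#' @return An `hrf_estimate`: data frame with `channel`, `hemisphere`,
#'   `condition`, `bin`, `t0_s` (bin start), `oxy`, `deoxy`, `total`;
#'   attributes `n_bins`, `bin_s`.
#' @export
reconstruct <- function(recording, fir, mask = NULL, channels = NULL,
                        pad_samples = 1) {
  stopifnot(inherits(recording, "nirs_recording"), inherits(fir, "fir_design"))
  ch <- recording$channels
  keep <- if (is.null(channels)) seq_len(nrow(ch)) else which(ch$id %in% channels)
  if (length(keep) == 0L) stop("no channels selected")
  X <- cbind(intercept = rep(1, fir$n), fir$X)
  wts <- .probe_weights(mask, ch, fir$n, pad_samples)

  rows <- lapply(keep, function(j) {
    w <- wts[[ch$hemisphere[j]]]
    idx <- w > 0
    Xu <- X[idx, , drop = FALSE]
    .check_rank(Xu, colnames(X))
    bo <- stats::lm.fit(Xu, recording$oxy[idx, j])$coefficients
    bd <- stats::lm.fit(Xu, recording$deoxy[idx, j])$coefficients
    do.call(rbind, lapply(fir$conditions, function(cd) {
      nm <- paste0(cd, "_bin", seq_len(fir$n_bins) - 1L)
      data.frame(channel = ch$id[j], hemisphere = ch$hemisphere[j],
                 condition = cd, bin = seq_len(fir$n_bins) - 1L,
                 t0_s = (seq_len(fir$n_bins) - 1L) * fir$bin_s,
                 oxy = unname(bo[nm]), deoxy = unname(bd[nm]),
                 total = unname(bo[nm] + bd[nm]))
    }))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  structure(out, n_bins = fir$n_bins, bin_s = fir$bin_s,
            class = c("hrf_estimate", "data.frame"))
}

#' Peak ROI response from an FIR estimate
#'
#' For each condition and hemisphere, the maximum absolute total-Hb beta
#' over the region-of-interest channels and the bins whose start falls in
#' the analysis window (default 0-9 s, half-open).  The signed beta at the
#' peak is retained alongside for reporting.
#'
#' @param estimate An [reconstruct()] result.
#' @param roi Integer channel ids of the ROI (e.g. `c(4, 6, 7)`), or a
#'   `nirs_layout` whose flagged ROI channels are used.
#' @param window_s Length-2 window on bin start times, seconds.
#' @return Data frame with `condition`, `hemisphere`, `peak` (absolute),
#'   `peak_signed`, `channel`, `t0_s`.
#' @export
roi_peak <- function(estimate, roi, window_s = c(0, 9)) {
  stopifnot(inherits(estimate, "hrf_estimate"))
  if (inherits(roi, "nirs_layout")) {
    roi <- unique(roi$channels$id[roi$channels$roi])
  }
  d <- estimate[estimate$channel %in% roi &
                  estimate$t0_s >= window_s[1] &
                  estimate$t0_s < window_s[2], ]
  if (nrow(d) == 0L) stop("ROI contains no channels/bins within the window")
  cells <- unique(d[, c("condition", "hemisphere")])
  out <- do.call(rbind, lapply(seq_len(nrow(cells)), function(i) {
    di <- d[d$condition == cells$condition[i] &
              d$hemisphere == cells$hemisphere[i], ]
    k <- which.max(abs(di$total))
    data.frame(condition = cells$condition[i],
               hemisphere = cells$hemisphere[i],
               peak = abs(di$total[k]), peak_signed = di$total[k],
               channel = di$channel[k], t0_s = di$t0_s[k])
  }))
  rownames(out) <- NULL
  out
}

#' Laterality index
#'
#' `(L - R) / (L + R)` of the left and right response magnitudes; positive
#' values indicate left dominance.  When both magnitudes are non-negative
#' and not both zero the index lies in `[-1, 1]`; `L + R = 0` is undefined
#' and reported as `NA`.
#'
#' @param L,R Response magnitudes (vectors recycle as usual).
#' @return Numeric laterality index/indices.
#' @examples
#' laterality_index(2, 1)  # 1/3
#' @export
laterality_index <- function(L, R) {
  li <- (L - R) / (L + R)
  li[(L + R) == 0] <- NA_real_
  li
}

#' Laterality indices from ROI peak values
#'
#' @param peaks A [roi_peak()] result covering both hemispheres.
#' @return Data frame with `condition`, `L`, `R`, `li`.
#' @export
laterality_from_peaks <- function(peaks) {
  conds <- unique(peaks$condition)
  out <- do.call(rbind, lapply(conds, function(cd) {
    L <- peaks$peak[peaks$condition == cd & peaks$hemisphere == "left"]
    R <- peaks$peak[peaks$condition == cd & peaks$hemisphere == "right"]
    if (length(L) != 1L || length(R) != 1L) {
      stop("need exactly one left and one right peak per condition")
    }
    data.frame(condition = cd, L = L, R = R, li = laterality_index(L, R))
  }))
  rownames(out) <- NULL
  out
}

#' Group descriptive statistics of laterality indices
#'
#' Mean, first and third quartile (linear-interpolation, type 7), and range
#' per group x condition cell — the statistics drawn as box (quartiles),
#' center line (mean) and whiskers (range) in the conventional laterality
#' figure.  Empty cells are omitted with a warning.
#'
#' @param li_table Data frame with columns `group`, `condition`, `li`.
#' @return Data frame with `group`, `condition`, `n`, `mean`, `q1`, `q3`,
#'   `min`, `max`.
#' @export
group_summary <- function(li_table) {
  for (v in c("group", "condition", "li")) {
    if (!v %in% names(li_table)) stop("missing column: ", v)
  }
  cells <- expand.grid(group = unique(li_table$group),
                       condition = unique(li_table$condition),
                       stringsAsFactors = FALSE)
  rows <- list()
  for (i in seq_len(nrow(cells))) {
    x <- li_table$li[li_table$group == cells$group[i] &
                       li_table$condition == cells$condition[i]]
    x <- x[is.finite(x)]
    if (length(x) == 0L) {
      warning("empty cell omitted: ", cells$group[i], " / ",
              cells$condition[i])
      next
    }
    q <- stats::quantile(x, c(0.25, 0.75), type = 7, names = FALSE)
    rows[[length(rows) + 1L]] <- data.frame(
      group = cells$group[i], condition = cells$condition[i],
      n = length(x), mean = mean(x), q1 = q[1], q3 = q[2],
      min = min(x), max = max(x))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
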