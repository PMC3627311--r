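#' Modified Beer-Lambert conversion of optical density to hemoglobin
#'
#' Solves the 2 x 2 linear system `E %*% c(oxy, deoxy) = c(od1, od2)` per
#' sample, recovering oxy- and deoxy-Hb concentration changes from the
#' optical-density changes at the two wavelengths.  Because the differential
#' pathlength is left unresolved, results are in mM*mm (concentration times
#' pathlength).
#'
#' @param od1,od2 Optical-density series (vectors or sample x channel
#'   matrices) at the first and second wavelength.
#' @param extinction 2 x 2 extinction matrix, rows in the same wavelength
#'   order as `od1`, `od2`; see [extinction_coefficients()].
#' @return List with `oxy` and `deoxy` in the same shape as the input.
#' @export
mbll_convert <- function(od1, od2, extinction = extinction_coefficients()) {
  .check_extinction(extinction)
  if (!identical(dim(od1), dim(od2)) || length(od1) != length(od2)) {
    stop("od1 and od2 must have identical shape")
  }
  inv <- solve(extinction)
  list(oxy = inv[1, 1] * od1 + inv[1, 2] * od2,
       deoxy = inv[2, 1] * od1 + inv[2, 2] * od2)
}

#' Convert a dual-wavelength OD object back to a hemoglobin recording
#'
#' @param od A `nirs_od` object (see [hb_to_optical_density()]).
#' @return A `nirs_recording` with `provenance = "converted"`.
#' @export
od_to_recording <- function(od) {
  stopifnot(inherits(od, "nirs_od"))
  hb <- mbll_convert(od$od1, od$od2, od$extinction)
  if (anyNA(hb$oxy) || anyNA(hb$deoxy)) {
    stop("conversion produced NaN/NA hemoglobin values")
  }
  structure(
    list(fs = od$fs, time_s = od$time_s, channels = od$channels,
         oxy = hb$oxy, deoxy = hb$deoxy, provenance = "converted",
         truth = NULL),
    class = "nirs_recording"
  )
}

#' Zero-phase Butterworth band-pass filter
#'
#' Third-order Butterworth high-pass and low-pass sections applied
#' forward-backward (`signal::filtfilt`) for zero phase distortion.  DC and
#' slow drift below `low` are removed; cardiac and sensor noise above
#' `high` are attenuated; passband gain is ~1.
#'
#' @param x Numeric vector or sample x channel matrix.
#' @param fs Sampling rate, Hz; must exceed `2 * high`.
#' @param low,high Band edges in Hz (defaults 0.02 and 0.7).
#' @return Filtered data, same shape as `x`.
#' @export
bandpass <- function(x, fs, low = 0.02, high = 0.7) {
  if (fs <= 2 * high) {
    stop("sampling rate ", fs, " Hz too low for a ", high,
         " Hz band edge (need fs > ", 2 * high, ")")
  }
  stopifnot(low > 0, high > low)
  hp <- signal::butter(3, low / (fs / 2), type = "high")
  lp <- signal::butter(3, high / (fs / 2), type = "low")
  f1 <- function(v) {
    v <- v - mean(v)
    signal::filtfilt(lp, signal::filtfilt(hp, v))
  }
  if (is.matrix(x)) apply(x, 2, f1) else f1(x)
}

# zero-phase high-pass only (drift/DC removal without smearing transients)
.highpass <- function(x, fs, low = 0.02) {
  hp <- signal::butter(3, low / (fs / 2), type = "high")
  f1 <- function(v) signal::filtfilt(hp, v - mean(v))
  if (is.matrix(x)) apply(x, 2, f1) else f1(x)
}

#' Detect motion artifacts on band-passed total hemoglobin
#'
#' Flags motion artifacts with the standard amplitude criterion: any
#' sliding window of `window_s` seconds in which band-passed total-Hb moves
#' by more than `threshold` mM*mm (window max minus min) is marked.
#' Artifacts are assessed at the level of probes (pads), not single
#' channels: a sample is excluded for a pad when any of its channels is
#' flagged.  Flagged runs closer than `merge_gap_s` are merged into one
#' event, and an event is classified *major* — triggering a baseline-shift
#' regressor downstream — when its peak excursion exceeds
#' `major_excursion_factor * threshold` or it lasts longer than
#' `major_duration_s`.
#'
#' The detection statistic is computed on total-Hb after drift removal with
#' the band's high-pass edge only.  Applying the band's 0.7 Hz low-pass
#' here would defeat the criterion: a third-order 0.7 Hz low-pass smears
#' any sub-second event over more than a second, capping its within-100 ms
#' excursion at roughly 15% of its amplitude, so even large spikes and
#' steps could never reach the threshold.  Set `lowpass_hz` to restore
#' full-band filtering if desired.
#'
#' The criterion is translation-invariant (the high-pass removes any
#' constant offset) and, by construction, insensitive to slow drifts whose
#' within-window excursion stays below threshold.
#'
#' @param recording A `nirs_recording`.
#' @param threshold Excursion threshold, mM*mm (default 1.5).
#' @param window_s Sliding-window width, seconds (default 0.1).
#' @param band Analysis band, Hz; detection high-passes at `band[1]`.
#' @param lowpass_hz Optional low-pass for the detection signal (default
#'   none; see Details).
#' @param merge_gap_s Events separated by less than this are merged.
#' @param major_excursion_factor,major_duration_s Major-event criteria.
#' @return An `artifact_mask`: list with `fs`, `n`, `probes`, `flags`
#'   (sample x probe logical matrix) and `events` (data frame `probe`,
#'   `start_s`, `end_s`, `peak_excursion`, `major`).
#' @export
detect_artifacts <- function(recording, threshold = 1.5, window_s = 0.1,
                             band = c(0.02, 0.7), lowpass_hz = NULL,
                             merge_gap_s = 0.5,
                             major_excursion_factor = 2,
                             major_duration_s = 1) {
  stopifnot(inherits(recording, "nirs_recording"), threshold > 0)
  fs <- recording$fs
  tot <- .highpass(total_hb(recording), fs, band[1])
  if (!is.null(lowpass_hz)) {
    lp <- signal::butter(3, lowpass_hz / (fs / 2), type = "low")
    tot <- if (is.matrix(tot)) apply(tot, 2, function(v)
      signal::filtfilt(lp, v)) else signal::filtfilt(lp, tot)
  }
  if (!is.matrix(tot)) tot <- matrix(tot, ncol = 1)
  n <- nrow(tot)
  k <- max(1L, floor(window_s * fs + 1e-9))  # window spans samples i..i+k

  probes <- unique(recording$channels$hemisphere)
  flags <- matrix(FALSE, n, length(probes), dimnames = list(NULL, probes))
  exc_probe <- matrix(0, n, length(probes), dimnames = list(NULL, probes))

  for (j in seq_len(ncol(tot))) {
    exc <- .window_excursion(tot[, j], k)          # length n - k
    hit <- which(exc > threshold)
    p <- recording$channels$hemisphere[j]
    for (i in hit) flags[i:(i + k), p] <- TRUE
    # track per-sample peak excursion for major classification
    idx <- seq_len(n - k)
    exc_probe[idx, p] <- pmax(exc_probe[idx, p], exc)
  }

  events <- .mask_events(flags, exc_probe, fs, merge_gap_s,
                         threshold * major_excursion_factor, major_duration_s)
  new_artifact_mask(events, n, fs, probes, flags)
}

# max - min over windows of k+1 consecutive samples
.window_excursion <- function(v, k) {
  n <- length(v)
  if (n <= k) return(numeric(0))
  idx <- seq_len(n - k)
  mx <- v[idx]
  mn <- v[idx]
  for (j in seq_len(k)) {
    s <- v[idx + j]
    mx <- pmax(mx, s)
    mn <- pmin(mn, s)
  }
  mx - mn
}

.mask_events <- function(flags, exc_probe, fs, merge_gap_s,
                         major_excursion, major_duration_s) {
  out <- list()
  for (p in colnames(flags)) {
    r <- rle(flags[, p])
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    on <- which(r$values)
    if (length(on) == 0L) next
    ev <- data.frame(start = starts[on], end = ends[on])
    # merge events separated by less than merge_gap_s
    if (nrow(ev) > 1) {
      keep <- ev[1, , drop = FALSE]
      for (i in 2:nrow(ev)) {
        gap <- (ev$start[i] - keep$end[nrow(keep)] - 1) / fs
        if (gap < merge_gap_s) {
          keep$end[nrow(keep)] <- ev$end[i]
        } else {
          keep <- rbind(keep, ev[i, ])
        }
      }
      ev <- keep
    }
    ev$probe <- p
    ev$start_s <- (ev$start - 1) / fs
    ev$end_s <- ev$end / fs        # half-open [start_s, end_s)
    ev$peak_excursion <- vapply(seq_len(nrow(ev)), function(i)
      max(exc_probe[ev$start[i]:ev$end[i], p]), numeric(1))
    ev$major <- ev$peak_excursion > major_excursion |
      (ev$end_s - ev$start_s) > major_duration_s
    out[[p]] <- ev[, c("probe", "start_s", "end_s", "peak_excursion", "major")]
  }
  if (length(out) == 0L) {
    return(data.frame(probe = character(), start_s = numeric(),
                      end_s = numeric(), peak_excursion = numeric(),
                      major = logical()))
  }
  ev <- do.call(rbind, out)
  rownames(ev) <- NULL
  ev
}

#' Construct an artifact mask directly from an event table
#'
#' Normally produced by [detect_artifacts()]; this constructor lets masks
#' be built from an externally curated event list (TSV of `probe`,
#' `start_s`, `end_s`, `major`).
#'
#' @param events Data frame with `probe`, `start_s`, `end_s` (half-open
#'   interval in seconds), optional `major` (default `FALSE`).
#' @param n Number of samples in the recording.
#' @param fs Sampling rate, Hz.
#' @param probes Probe (pad) labels.
#' @param flags Optional precomputed sample x probe logical matrix.
#' @return An `artifact_mask`.
#' @export
new_artifact_mask <- function(events, n, fs, probes, flags = NULL) {
  if (is.null(events$major)) events$major <- logical(nrow(events))
  if (is.null(events$peak_excursion))
    events$peak_excursion <- rep(NA_real_, nrow(events))
  if (is.null(flags)) {
    flags <- matrix(FALSE, n, length(probes), dimnames = list(NULL, probes))
    for (i in seq_len(nrow(events))) {
      idx <- .interval_samples(events$start_s[i], events$end_s[i], fs, n)
      flags[idx, events$probe[i]] <- TRUE
    }
  }
  structure(list(fs = fs, n = n, probes = probes, flags = flags,
                 events = events),
            class = "artifact_mask")
}

# samples whose time falls in [start_s, end_s)
.interval_samples <- function(start_s, end_s, fs, n) {
  i0 <- max(1L, floor(start_s * fs + 1e-9) + 1L)
  i1 <- min(n, ceiling(end_s * fs - 1e-9))
  if (i1 < i0) integer(0) else i0:i1
}

#' @export
print.artifact_mask <- function(x, ...) {
  cat(sprintf("<artifact_mask> %d samples @ %g Hz; %d event(s), %d major; %.2f%% flagged\n",
              x$n, x$fs, nrow(x$events), sum(x$events$major),
              100 * mean(x$flags)))
  invisible(x)
}

#' GLM exclusion weights from an artifact mask
#'
#' Builds the 0/1 per-sample weight vector that removes artifacted
#' stretches from the weighted least-squares fit: weight 0 over every
#' (merged) artifact event of the probe, padded by `pad_samples` on each
#' side, weight 1 elsewhere.
#'
#' @param mask An `artifact_mask`.
#' @param probe Probe label (default: first probe).
#' @param pad_samples Extra samples zeroed on each side of every event.
#' @return Numeric vector of 0/1 weights of length `mask$n`.
#' @export
artifact_weights <- function(mask, probe = mask$probes[1], pad_samples = 1) {
  stopifnot(inherits(mask, "artifact_mask"), probe %in% mask$probes)
  w <- rep(1, mask$n)
  ev <- mask$events[mask$events$probe == probe, , drop = FALSE]
  for (i in seq_len(nrow(ev))) {
    idx <- .interval_samples(ev$start_s[i], ev$end_s[i], mask$fs, mask$n)
    if (length(idx) == 0L) next
    idx <- max(1L, min(idx) - pad_samples):min(mask$n, max(idx) + pad_samples)
    w[idx] <- 0
  }
  w
}

#' Baseline-shift regressors after major artifacts
#'
#' One step (boxcar) regressor per major artifact event: 0 up to the event
#' end, 1 afterwards.  These columns absorb the baseline jumps that large
#' movements leave in the optical signal.
#'
#' @param mask An `artifact_mask`.
#' @param probe Probe label (default: first probe).
#' @return Sample x event numeric matrix (0 columns when no major events).
#' @export
baseline_shift_regressors <- function(mask, probe = mask$probes[1]) {
  stopifnot(inherits(mask, "artifact_mask"), probe %in% mask$probes)
  ev <- mask$events[mask$events$probe == probe & mask$events$major, ,
                    drop = FALSE]
  tt <- (seq_len(mask$n) - 1) / mask$fs
  out <- matrix(0, mask$n, nrow(ev))
  if (nrow(ev) > 0) {
    colnames(out) <- paste0("baseline_shift_", seq_len(nrow(ev)))
    for (i in seq_len(nrow(ev))) out[tt >= ev$end_s[i], i] <- 1
  }
  out
}
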