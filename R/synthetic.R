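#' Canonical double-gamma hemodynamic response
#'
#' The stereotyped impulse response used to predict block responses: a
#' gamma-density main lobe peaking at `peak_s` minus a later, smaller gamma
#' undershoot, normalized so the maximum equals 1.  The response is 0 at
#' stimulus onset (t = 0), 0 for negative t by convention, and has decayed
#' essentially to zero by 30 s with the defaults.
#'
#' @param t Time(s) in seconds since stimulus onset.
#' @param peak_s Mode of the main lobe (default 5.5 s).
#' @param undershoot_s Mode of the undershoot lobe (default 15 s).
#' @param dispersion_s Gamma dispersion (scale) in seconds.
#' @param ratio Peak-to-undershoot amplitude ratio (default 6).
#' @return Unitless amplitude(s), peak-normalized to 1.
#' @examples
#' canonical_hrf(c(0, 5.5, 30))
#' @export
canonical_hrf <- function(t, peak_s = 5.5, undershoot_s = 15,
                          dispersion_s = 1, ratio = 6) {
  stopifnot(peak_s > 0, undershoot_s > 0, dispersion_s > 0, ratio > 0)
  rate <- 1 / dispersion_s
  shape1 <- peak_s / dispersion_s + 1
  shape2 <- undershoot_s / dispersion_s + 1
  h <- function(tt) {
    stats::dgamma(tt, shape1, rate) - stats::dgamma(tt, shape2, rate) / ratio
  }
  grid <- seq(0, undershoot_s + 25, by = 0.01)
  pk <- max(h(grid))
  out <- numeric(length(t))
  pos <- t >= 0
  out[pos] <- h(t[pos]) / pk
  out
}

#' Condition regressor: block boxcar convolved with the canonical HRF
#'
#' Builds the predicted hemodynamic time course for one target condition by
#' convolving a 0/1 boxcar (1 during that condition's target blocks) with
#' the canonical HRF sampled at `1/fs`.  The result is normalized to peak 1
#' so that a GLM beta on this regressor is expressed directly in signal
#' units (mM*mm at the block-response peak).
#'
#' @param schedule A `nirs_schedule`.
#' @param condition Condition label present in the schedule.
#' @param fs Sampling rate, Hz.
#' @param n_samples Number of samples; defaults to the session length.
#' @param hrf List of [canonical_hrf()] parameter overrides.
#' @return Numeric vector of length `n_samples`.
#' @export
condition_regressor <- function(schedule, condition, fs, n_samples = NULL,
                                hrf = list()) {
  stopifnot(inherits(schedule, "nirs_schedule"), fs > 0)
  if (is.null(n_samples)) n_samples <- ceiling(session_duration(schedule) * fs)
  tt <- (seq_len(n_samples) - 1) / fs
  box <- numeric(n_samples)
  b <- schedule$blocks
  tb <- b[b$kind == "target" & !is.na(b$condition) & b$condition == condition, ]
  for (i in seq_len(nrow(tb))) {
    box[tt >= tb$onset_s[i] - 1e-9 & tt < tb$onset_s[i] + tb$duration_s[i] - 1e-9] <- 1
  }
  kern <- do.call(canonical_hrf,
                  c(list(t = seq(0, 32, by = 1 / fs)), hrf))
  conv <- stats::convolve(box, rev(kern), type = "open")[seq_len(n_samples)]
  mx <- max(abs(conv))
  if (mx > 0) conv <- conv / mx
  conv
}

#' Physiological noise model for synthetic recordings
#'
#' Additive noise emulating the main non-neural components of a continuous-
#' wave NIRS trace: white sensor noise, slow drift (sum of sinusoids with
#' periods of at least 60 s), a cardiac sinusoid (about 2.5 Hz in infants)
#' and a respiratory sinusoid (about 0.6 Hz).  Each oscillatory component
#' gets an independent random phase per channel.  All amplitudes are in
#' mM*mm and must be non-negative.
#'
#' @param white_sd White noise standard deviation.
#' @param drift_periods_s,drift_amps Slow-drift sinusoid periods (>= 60 s)
#'   and amplitudes.
#' @param cardiac_hz,cardiac_amp Cardiac frequency and amplitude.
#' @param resp_hz,resp_amp Respiratory frequency and amplitude.
#' @return A list of class `nirs_noise`.
#' @export
noise_model <- function(white_sd = 0.03,
                        drift_periods_s = c(120, 300),
                        drift_amps = c(0.05, 0.05),
                        cardiac_hz = 2.5, cardiac_amp = 0.01,
                        resp_hz = 0.6, resp_amp = 0.02) {
  stopifnot(white_sd >= 0, all(drift_amps >= 0), cardiac_amp >= 0,
            resp_amp >= 0, length(drift_periods_s) == length(drift_amps),
            all(drift_periods_s >= 60))
  structure(list(white_sd = white_sd, drift_periods_s = drift_periods_s,
                 drift_amps = drift_amps, cardiac_hz = cardiac_hz,
                 cardiac_amp = cardiac_amp, resp_hz = resp_hz,
                 resp_amp = resp_amp),
            class = "nirs_noise")
}

# one channel's noise realization
.gen_noise <- function(noise, tt) {
  n <- length(tt)
  out <- stats::rnorm(n, 0, noise$white_sd)
  comps <- rbind(
    cbind(1 / noise$drift_periods_s, noise$drift_amps),
    c(noise$cardiac_hz, noise$cardiac_amp),
    c(noise$resp_hz, noise$resp_amp)
  )
  for (i in seq_len(nrow(comps))) {
    if (comps[i, 2] > 0) {
      ph <- stats::runif(1, 0, 2 * pi)
      out <- out + comps[i, 2] * sin(2 * pi * comps[i, 1] * tt + ph)
    }
  }
  out
}

#' Ground-truth effect specification for the simulator
#'
#' Convenience constructor for the per-channel, per-condition response
#' amplitudes used by [simulate_recording()].  By default the response is
#' placed in the ROI channels of both hemispheres, the deoxy-Hb amplitude is
#' `deoxy_ratio` times the oxy-Hb amplitude (negative: the canonical
#' oxy-up / deoxy-down pattern), and left-hemisphere amplitudes are scaled
#' by `left_scale` to emulate lateralized responses.
#'
#' @param layout A `nirs_layout`.
#' @param oxy_amp Named numeric vector of oxy-Hb amplitudes (mM*mm) per
#'   condition, e.g. `c(cluster = 0.08, duration = 0.08)`.
#' @param deoxy_ratio Deoxy amplitude as a fraction of oxy (default -0.3).
#' @param left_scale Multiplier applied to left-hemisphere amplitudes.
#' @param channels `"roi"` (default) or `"all"`, or an integer vector of
#'   channel ids.
#' @return Data frame with columns `channel`, `hemisphere`, `condition`,
#'   `oxy`, `deoxy`.
#' @export
effect_spec <- function(layout, oxy_amp, deoxy_ratio = -0.3, left_scale = 1,
                        channels = "roi") {
  stopifnot(inherits(layout, "nirs_layout"), length(oxy_amp) >= 1,
            !is.null(names(oxy_amp)))
  ch <- layout$channels
  if (identical(channels, "roi")) {
    ch <- ch[ch$roi, ]
  } else if (!identical(channels, "all")) {
    ch <- ch[ch$id %in% channels, ]
  }
  if (nrow(ch) == 0L) stop("effect_spec: no channels selected")
  out <- do.call(rbind, lapply(names(oxy_amp), function(cond) {
    amp <- unname(oxy_amp[cond]) * ifelse(ch$hemisphere == "left", left_scale, 1)
    data.frame(channel = ch$id, hemisphere = ch$hemisphere,
               condition = cond, oxy = amp, deoxy = deoxy_ratio * amp)
  }))
  rownames(out) <- NULL
  out
}

#' Simulate a multichannel hemoglobin recording with known ground truth
#'
#' Per channel, the oxy-Hb trace is the sum over conditions of the ground-
#' truth amplitude times the HRF-convolved block regressor (see
#' [condition_regressor()]), plus physiological noise and injected motion
#' artifacts; the deoxy-Hb trace is built the same way from the deoxy
#' amplitudes with an independent noise realization.  Artifacts (spikes and
#' steps) are added to the oxy trace of every channel of the affected pad,
#' mimicking probe-level motion.
#'
#' @param schedule A `nirs_schedule` defining block timing.
#' @param layout A `nirs_layout`; all its channels are simulated.
#' @param effects Data frame as produced by [effect_spec()], or `NULL` for
#'   no response.
#' @param noise A [noise_model()], or `NULL` for noise-free traces.
#' @param artifacts Data frame with columns `time_s`, `kind` (`"spike"` or
#'   `"step"`), `magnitude` (mM*mm), `width_s` (spikes only) and optionally
#'   `hemisphere` (default `"left"`), or `NULL`.
#' @param fs Sampling rate, Hz; must exceed twice the cardiac frequency.
#' @param hrf List of [canonical_hrf()] parameter overrides.
#' @param seed Optional integer seed; identical seeds give identical output.
#' @return A `nirs_recording`: list with `fs`, `time_s`, `channels` (layout
#'   channel table), `oxy` and `deoxy` (sample x channel matrices, mM*mm,
#'   columns named `<hemisphere>_<id>`), `provenance = "synthetic"` and a
#'   `truth` record of everything injected.
#' @export
simulate_recording <- function(schedule, layout, effects = NULL, noise = NULL,
                               artifacts = NULL, fs = 10, hrf = list(),
                               seed = NULL) {
  stopifnot(inherits(schedule, "nirs_schedule"), inherits(layout, "nirs_layout"))
  if (fs <= 0) stop("sampling rate fs must be positive")
  if (!is.null(noise) && noise$cardiac_amp > 0 && fs <= 2 * noise$cardiac_hz) {
    stop("fs (", fs, " Hz) must exceed twice the cardiac frequency (",
         noise$cardiac_hz, " Hz)")
  }
  if (nrow(schedule$blocks) == 0L) stop("schedule is empty")
  if (!is.null(seed)) set.seed(seed)

  n <- ceiling(session_duration(schedule) * fs)
  tt <- (seq_len(n) - 1) / fs
  ch <- layout$channels
  nch <- nrow(ch)
  cn <- paste(ch$hemisphere, ch$id, sep = "_")

  conds <- schedule$conditions
  regs <- vapply(conds, function(cd)
    condition_regressor(schedule, cd, fs, n, hrf), numeric(n))

  oxy <- matrix(0, n, nch, dimnames = list(NULL, cn))
  deoxy <- matrix(0, n, nch, dimnames = list(NULL, cn))
  if (!is.null(effects)) {
    for (i in seq_len(nrow(effects))) {
      j <- which(ch$id == effects$channel[i] &
                   ch$hemisphere == effects$hemisphere[i])
      k <- match(effects$condition[i], conds)
      if (length(j) == 1L && !is.na(k)) {
        oxy[, j] <- oxy[, j] + effects$oxy[i] * regs[, k]
        deoxy[, j] <- deoxy[, j] + effects$deoxy[i] * regs[, k]
      }
    }
  }
  if (!is.null(noise)) {
    for (j in seq_len(nch)) {
      oxy[, j] <- oxy[, j] + .gen_noise(noise, tt)
      deoxy[, j] <- deoxy[, j] + .gen_noise(noise, tt)
    }
  }
  if (!is.null(artifacts) && nrow(artifacts) > 0) {
    if (is.null(artifacts$hemisphere)) artifacts$hemisphere <- "left"
    if (is.null(artifacts$width_s)) artifacts$width_s <- 0.1
    if (any(artifacts$time_s < 0 | artifacts$time_s > max(tt))) {
      stop("artifact times must lie within the session")
    }
    for (i in seq_len(nrow(artifacts))) {
      cols <- which(ch$hemisphere == artifacts$hemisphere[i])
      if (artifacts$kind[i] == "step") {
        add <- artifacts$magnitude[i] * (tt >= artifacts$time_s[i])
      } else {
        add <- artifacts$magnitude[i] *
          (tt >= artifacts$time_s[i] & tt < artifacts$time_s[i] + artifacts$width_s[i])
      }
      oxy[, cols] <- oxy[, cols] + add
    }
  }

  structure(
    list(fs = fs, time_s = tt, channels = ch, oxy = oxy, deoxy = deoxy,
         provenance = "synthetic",
         truth = list(effects = effects, noise = noise, artifacts = artifacts,
                      hrf = hrf, fs = fs, seed = seed)),
    class = "nirs_recording"
  )
}

#' Total hemoglobin of a recording
#' @param recording A `nirs_recording`.
#' @return Sample x channel matrix of oxy + deoxy.
#' @export
total_hb <- function(recording) {
  stopifnot(inherits(recording, "nirs_recording"))
  recording$oxy + recording$deoxy
}

#' @export
print.nirs_recording <- function(x, ...) {
  cat(sprintf("<nirs_recording> %d channels x %d samples @ %g Hz (%.1f s), %s\n",
              ncol(x$oxy), nrow(x$oxy), x$fs, nrow(x$oxy) / x$fs, x$provenance))
  invisible(x)
}

#' Extinction coefficient matrices for common instrument wavelength pairs
#'
#' Representative molar extinction coefficients (rows = wavelengths,
#' columns = oxy-Hb, deoxy-Hb) for the two instrument classes: 780/830 nm
#' continuous-wave systems and 670/850 nm systems.  Values follow standard
#' tabulated hemoglobin spectra at an arbitrary common scale — adequate for
#' the forward/inverse conversion, whose round trip is exact for any
#' invertible matrix — and can be overridden with any user-supplied 2 x 2
#' matrix.
#'
#' @param system `"hitachi"` (780/830 nm) or `"ucl"` (670/850 nm).
#' @return 2 x 2 numeric matrix with a `wavelengths_nm` attribute.
#' @export
extinction_coefficients <- function(system = c("hitachi", "ucl")) {
  system <- match.arg(system)
  if (system == "hitachi") {
    e <- matrix(c(0.735, 1.105,
                  1.058, 0.781), 2, 2, byrow = TRUE,
                dimnames = list(c("780", "830"), c("oxy", "deoxy")))
    attr(e, "wavelengths_nm") <- c(780, 830)
  } else {
    e <- matrix(c(0.320, 2.600,
                  1.097, 0.781), 2, 2, byrow = TRUE,
                dimnames = list(c("670", "850"), c("oxy", "deoxy")))
    attr(e, "wavelengths_nm") <- c(670, 850)
  }
  e
}

#' Forward model: hemoglobin changes to dual-wavelength optical density
#'
#' Applies the (modified Beer-Lambert) linear forward model
#' `OD = E %*% c(oxy, deoxy)` per sample and channel, producing the
#' optical-density changes an instrument would record at its two
#' wavelengths.  Inverse of [mbll_convert()]; the round trip is exact to
#' machine precision for any invertible extinction matrix.
#'
#' @param recording A `nirs_recording`.
#' @param extinction 2 x 2 extinction matrix (rows wavelengths, columns
#'   oxy/deoxy); see [extinction_coefficients()].
#' @return A list of class `nirs_od` with `od1`, `od2` (sample x channel
#'   matrices), `extinction`, `fs`, `time_s`, `channels`.
#' @export
hb_to_optical_density <- function(recording,
                                  extinction = extinction_coefficients()) {
  stopifnot(inherits(recording, "nirs_recording"))
  .check_extinction(extinction)
  structure(
    list(od1 = extinction[1, 1] * recording$oxy + extinction[1, 2] * recording$deoxy,
         od2 = extinction[2, 1] * recording$oxy + extinction[2, 2] * recording$deoxy,
         extinction = extinction, fs = recording$fs, time_s = recording$time_s,
         channels = recording$channels),
    class = "nirs_od"
  )
}

.check_extinction <- function(extinction, cond_warn = 1e3) {
  if (!is.matrix(extinction) || any(dim(extinction) != c(2, 2))) {
    stop("extinction must be a 2 x 2 matrix (wavelengths x {oxy, deoxy})")
  }
  d <- det(extinction)
  if (!is.finite(d) || abs(d) < .Machine$double.eps * 100) {
    stop("extinction matrix is singular; cannot separate oxy- and deoxy-Hb")
  }
  k <- kappa(extinction, exact = TRUE)
  if (k > cond_warn) {
    warning("extinction matrix is ill-conditioned (condition number ",
            format(k, digits = 3), "); hemoglobin estimates will be noisy")
  }
  invisible(TRUE)
}
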