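#' Emulate the adult 2 x 2 follow-up study and extract GLM Z-scores
#'
#' Runs the adult factorial manipulation in silico: each simulated subject
#' completes four counterbalanced sessions crossing target-block duration
#' (short 9 s vs. long 15 s) with token variability (single vs. multiple
#' exemplars).  The injected response amplitude mirrors the study's
#' empirical ordering — it grows with block duration and shrinks with token
#' variability — via `amp = base_amp * duration_gain^long * multi_gain^multi`,
#' modulated by a per-subject multiplicative gain.  Each session is
#' simulated on a single (left) temporal pad, fit with the artifact-weighted
#' GLM, and summarized as the maximum standardized effect
#' (`z = beta / se`) of the duration-change regressor across the auditory
#' ROI channels, matching the follow-up's focus on the vowel-duration
#' target blocks around the left auditory area.
#'
#' @param n_subjects Number of simulated adults (the study tested 8).
#' @param base_amp Oxy-Hb amplitude (mM*mm) in the short-single condition.
#' @param duration_gain Multiplier for long (15 s) blocks (> 1).
#' @param multi_gain Multiplier for multi-token sessions (< 1).
#' @param subject_sd SD of the lognormal per-subject gain.
#' @param noise A [noise_model()]; defaults to adult-like settings
#'   (cardiac ~1.2 Hz) compatible with `fs`.
#' @param fs Sampling rate, Hz.
#' @param n_per_condition Target blocks per change condition and session.
#' @param seed Optional integer seed.
#' @return Data frame with `subject`, `duration` (`"short"`/`"long"`),
#'   `tokens` (`"single"`/`"multi"`), `z` — ready for
#'   [anova_2x2_within()].
#' @export
simulate_adult_zscores <- function(n_subjects = 8, base_amp = 0.08,
                                   duration_gain = 1.5, multi_gain = 0.7,
                                   subject_sd = 0.2,
                                   noise = NULL, fs = 5,
                                   n_per_condition = 5, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(noise)) {
    noise <- noise_model(white_sd = 0.03, drift_amps = c(0.03, 0.03),
                         cardiac_hz = 1.2, cardiac_amp = 0.01,
                         resp_hz = 0.3, resp_amp = 0.015)
  }
  lay <- build_layout(2, 4, 30, hemispheres = "left")
  roi <- which(lay$channels$roi)
  sess <- expand.grid(dur = c("short", "long"), tok = c("single", "multi"),
                      stringsAsFactors = FALSE)

  rows <- list()
  for (s in seq_len(n_subjects)) {
    gain <- exp(stats::rnorm(1, 0, subject_sd))
    for (i in seq_len(nrow(sess))) {
      amp <- base_amp * gain *
        (if (sess$dur[i] == "long") duration_gain else 1) *
        (if (sess$tok[i] == "multi") multi_gain else 1)
      cond <- paste(sess$dur[i], sess$tok[i], sep = "-")
      sch <- generate_adult_schedule(cond, n_per_condition)
      eff <- effect_spec(lay, c(cluster = amp / 2, duration = amp))
      rec <- simulate_recording(sch, lay, eff, noise, fs = fs)
      des <- build_design(sch, fs, nrow(rec$oxy))
      z <- max(vapply(roi, function(j) {
        f <- fit_weighted(rec$oxy[, j], des)
        unname(f$z["condition_duration"])
      }, numeric(1)))
      rows[[length(rows) + 1L]] <- data.frame(
        subject = s, duration = sess$dur[i], tokens = sess$tok[i], z = z)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
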