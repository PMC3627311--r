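#' Full pipeline configuration
#'
#' Assembles the serializable configuration that, together with a seed,
#' determines every pipeline output.  Any element can be overridden; the
#' defaults reproduce the infant study conditions (2 x 4 pads at 25 mm,
#' 16 target blocks at SOA 1.5 s, 10 Hz sampling, 1.5 mM*mm / 100 ms
#' artifact criterion, 0.02-0.7 Hz band, 10,000 Monte-Carlo iterations,
#' 20 one-second FIR bins, ROI channels 4/6/7).
#'
#' @param layout,schedule,synth,artifact,glm,fir Named lists of stage
#'   parameter overrides.
#' @param seed Master integer seed; per-stage seeds are derived from it.
#' @param out_dir Optional output directory for [run_pipeline()].
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(layout = list(), schedule = list(),
                            synth = list(), artifact = list(),
                            glm = list(), fir = list(),
                            seed = 1L, out_dir = NULL) {
  merge <- function(def, over) {
    for (nm in names(over)) def[[nm]] <- over[[nm]]
    def
  }
  cfg <- list(
    layout = merge(list(rows = 2, cols = 4, spacing_mm = 25,
                        include_long = FALSE, roi_channels = c(4, 6, 7)),
                   layout),
    schedule = merge(list(design = "infant", n_target_blocks = 16,
                          soa = 1.5, target_s = 9,
                          baseline_jitter = c(9, 18),
                          token_mode = "multi",
                          adult_condition = "short-multi",
                          n_per_condition = 5),
                     schedule),
    synth = merge(list(fs = 10, oxy_amp = c(cluster = 0.08, duration = 0.08),
                       deoxy_ratio = -0.3, left_scale = 1,
                       channels = "roi", noise = list(), artifacts = NULL,
                       input_recording = NULL, input_events = NULL),
                  synth),
    artifact = merge(list(threshold = 1.5, window_s = 0.1,
                          band = c(0.02, 0.7), merge_gap_s = 0.5,
                          major_excursion_factor = 2, major_duration_s = 1,
                          pad_samples = 1),
                     artifact),
    glm = merge(list(n_mc = 10000, alpha = 0.05, min_shift_s = 30,
                     signal = "oxy", null = "circular"),
                glm),
    fir = merge(list(n_bins = 20, bin_s = 1, window_s = c(0, 9)), fir),
    seed = as.integer(seed), out_dir = out_dir
  )
  class(cfg) <- "pipeline_config"
  cfg
}

# per-stage seeds derived deterministically from the master seed
.stage_seed <- function(seed, stage) {
  offs <- c(schedule = 101L, simulate = 211L, mc = 307L)
  (as.integer(seed) + offs[[stage]]) %% .Machine$integer.max
}

#' Run the end-to-end change-detection pipeline
#'
#' Stages: build the probe layout; generate (or read) the stimulus
#' schedule; simulate (or read) the hemoglobin recording; detect motion
#' artifacts and derive exclusion weights and baseline-shift regressors;
#' fit the artifact-weighted GLM per channel; decide responding channels by
#' Monte-Carlo max-statistic correction; reconstruct the hemodynamic
#' response with the FIR model; extract ROI peaks and laterality indices.
#' The whole run is a pure function of (config, seed).  When
#' `config$out_dir` is set, stage outputs are written as TSV plus a JSON
#' manifest with the package version, seed, stage counts and file
#' checksums.
#'
#' @param config A [pipeline_config()].
#' @param seed Overrides `config$seed` when given.
#' @return A list with `layout`, `schedule`, `recording`, `mask`,
#'   `fit_report`, `responding`, `hrf`, `peaks`, `laterality`, `manifest`.
#' @export
run_pipeline <- function(config = pipeline_config(), seed = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  if (!is.null(seed)) config$seed <- as.integer(seed)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }

  lay <- stage("layout", do.call(build_layout, config$layout))

  sc <- config$schedule
  sch <- stage("schedule", {
    if (!is.null(config$synth$input_events)) {
      read_events(config$synth$input_events, soa = sc$soa)
    } else if (sc$design == "infant") {
      generate_infant_schedule(sc$n_target_blocks, sc$soa, sc$target_s,
                               sc$baseline_jitter,
                               token_mode = sc$token_mode,
                               seed = .stage_seed(config$seed, "schedule"))
    } else {
      generate_adult_schedule(sc$adult_condition, sc$n_per_condition, sc$soa,
                              seed = .stage_seed(config$seed, "schedule"))
    }
  })

  sy <- config$synth
  rec <- stage("recording", {
    if (!is.null(sy$input_recording)) {
      read_recording(sy$input_recording)
    } else {
      eff <- if (all(sy$oxy_amp == 0)) NULL else
        effect_spec(lay, sy$oxy_amp, sy$deoxy_ratio, sy$left_scale,
                    sy$channels)
      simulate_recording(sch, lay, eff, do.call(noise_model, sy$noise),
                         sy$artifacts, fs = sy$fs,
                         seed = .stage_seed(config$seed, "simulate"))
    }
  })

  af <- config$artifact
  mask <- stage("artifacts",
    detect_artifacts(rec, af$threshold, af$window_s, af$band,
                     af$merge_gap_s, af$major_excursion_factor,
                     af$major_duration_s))

  # baseline-shift boxcars: pool major events across probes so every
  # channel's design absorbs post-artifact baseline jumps
  bshift <- stage("artifacts", {
    bb <- do.call(cbind, lapply(mask$probes, function(p)
      baseline_shift_regressors(mask, p)))
    if (is.null(bb) || ncol(bb) == 0) NULL else bb
  })

  des <- stage("design",
    build_design(sch, rec$fs, nrow(rec$oxy), baseline_boxcars = bshift))

  gl <- config$glm
  fits <- stage("glm",
    fit_channels(rec, des, mask, signal = gl$signal,
                 pad_samples = af$pad_samples))
  resp <- stage("glm",
    responding_channels(rec, des, mask, n_mc = gl$n_mc, alpha = gl$alpha,
                        min_shift_s = gl$min_shift_s, signal = gl$signal,
                        null = gl$null,
                        seed = .stage_seed(config$seed, "mc"),
                        pad_samples = af$pad_samples))
  report <- merge(fits$report,
                  resp[, c("channel", "hemisphere", "p_corrected", "responding")],
                  by = c("channel", "hemisphere"), sort = FALSE)

  fr <- config$fir
  fdes <- stage("fir", fir_design(sch, rec$fs, nrow(rec$oxy),
                                  fr$n_bins, fr$bin_s))
  hrf_est <- stage("fir", reconstruct(rec, fdes, mask,
                                      pad_samples = af$pad_samples))
  peaks <- stage("laterality", roi_peak(hrf_est, lay, fr$window_s))
  li <- stage("laterality", laterality_from_peaks(peaks))

  manifest <- list(
    package = "nirschange",
    version = as.character(utils::packageVersion("nirschange")),
    seed = config$seed,
    config = config[setdiff(names(config), "out_dir")],
    counts = list(
      channels = nrow(rec$channels),
      samples = nrow(rec$oxy),
      blocks = nrow(sch$blocks),
      artifact_events = nrow(mask$events),
      samples_flagged = sum(mask$flags),
      channels_responding = sum(resp$responding)
    )
  )

  out <- list(layout = lay, schedule = sch, recording = rec, mask = mask,
              fit_report = report, responding = resp, hrf = hrf_est,
              peaks = peaks, laterality = li, manifest = manifest)

  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
    wr <- function(df, nm) {
      p <- file.path(config$out_dir, nm)
      utils::write.table(df, p, sep = "\t", quote = FALSE,
                         row.names = FALSE, fileEncoding = "UTF-8")
      p
    }
    files <- c(
      wr(report, "fit_report.tsv"),
      wr(as.data.frame(hrf_est), "hrf_estimates.tsv"),
      wr(li, "laterality.tsv"),
      wr(mask$events, "artifact_events.tsv"),
      write_events(sch, file.path(config$out_dir, "events.tsv"))
    )
    manifest$checksums <- as.list(tools::md5sum(files))
    names(manifest$checksums) <- basename(files)
    jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    out$manifest <- manifest
  }
  out
}

#' Read / write a hemoglobin recording as TSV
#'
#' Long-format UTF-8 TSV dialect with columns `time_s`, `channel_id`,
#' `hemisphere`, `oxy`, `deoxy` (mM*mm, '.' decimal separator).  The
#' sampling rate is inferred from the time column, which must be a regular
#' grid shared by all channels.
#'
#' @param recording A `nirs_recording`.
#' @param path File path.
#' @return `write_recording` returns `path` invisibly; `read_recording`
#'   returns a `nirs_recording` with `provenance = "measured"`.
#' @export
write_recording <- function(recording, path) {
  stopifnot(inherits(recording, "nirs_recording"))
  ch <- recording$channels
  n <- nrow(recording$oxy)
  df <- do.call(rbind, lapply(seq_len(nrow(ch)), function(j) {
    data.frame(time_s = recording$time_s, channel_id = ch$id[j],
               hemisphere = ch$hemisphere[j],
               oxy = recording$oxy[, j], deoxy = recording$deoxy[, j])
  }))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_recording
#' @export
read_recording <- function(path) {
  df <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                          fileEncoding = "UTF-8")
  need <- c("time_s", "channel_id", "hemisphere", "oxy", "deoxy")
  if (!all(need %in% names(df))) {
    stop("recording file ", path, " is missing columns: ",
         paste(setdiff(need, names(df)), collapse = ", "))
  }
  if (nrow(df) == 0L) stop("no samples: recording file ", path, " is empty")
  bad <- which(!is.finite(df$time_s) | !is.finite(df$oxy) |
                 !is.finite(df$deoxy))
  if (length(bad) > 0) {
    stop("malformed recording rows at line(s) ",
         paste(bad + 1L, collapse = ", "))
  }
  key <- paste(df$hemisphere, df$channel_id, sep = "_")
  keys <- unique(key)
  tt <- sort(unique(df$time_s))
  if (length(tt) < 2) stop("recording needs at least 2 time points")
  dt <- diff(tt)
  if (max(dt) - min(dt) > 1e-6) {
    stop("irregular sampling grid in ", path,
         "; resample to a fixed rate first")
  }
  fs <- 1 / stats::median(dt)
  n <- length(tt)
  oxy <- matrix(NA_real_, n, length(keys), dimnames = list(NULL, keys))
  deoxy <- oxy
  for (k in keys) {
    d <- df[key == k, ]
    if (nrow(d) != n) stop("channel ", k, " has ", nrow(d),
                           " samples; expected ", n)
    o <- order(d$time_s)
    oxy[, k] <- d$oxy[o]
    deoxy[, k] <- d$deoxy[o]
  }
  first <- match(keys, key)
  channels <- data.frame(id = df$channel_id[first],
                         hemisphere = df$hemisphere[first],
                         kind = "short", distance_mm = NA_real_,
                         roi = FALSE)
  structure(
    list(fs = fs, time_s = tt, channels = channels, oxy = oxy,
         deoxy = deoxy, provenance = "measured", truth = NULL),
    class = "nirs_recording"
  )
}
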