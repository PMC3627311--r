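# Per-phoneme mean durations (ms) of the three non-word stimuli, measured
# from the recorded tokens.  Word durations are the sums of these means;
# for /abuna/ and /abuuna/ the sum differs from the rounded per-word value
# by 0.1 ms (rounding of the per-phoneme means).
.phoneme_ms <- list(
  abuna  = c(a1 = 115.4, b = 88.8, u = 128.2, n = 99.9, a2 = 151.8),
  abna   = c(a1 = 112.1, b = 127.6, n = 78.1, a2 = 140.8),
  abuuna = c(a1 = 126.3, b = 88.8, uu = 369.1, n = 88.3, a2 = 150.0)
)

#' Stimulus word duration from phoneme metadata
#'
#' Total duration of a stimulus non-word in milliseconds, computed as the
#' sum of its mean phoneme durations (e.g. /abna/ = 112.1 + 127.6 + 78.1 +
#' 140.8 = 458.6 ms).
#'
#' @param word One of `"abuna"`, `"abna"`, `"abuuna"`.
#' @return Duration in milliseconds.
#' @export
word_duration <- function(word) {
  if (length(word) != 1L || !word %in% names(.phoneme_ms)) {
    stop("unknown stimulus word: ", paste(word, collapse = ", "),
         " (expected abuna, abna or abuuna)")
  }
  sum(.phoneme_ms[[word]])
}

# Admissible baseline-block durations: multiples of the SOA inside the
# jitter interval, so every block holds a whole number of token slots.
.baseline_grid <- function(jitter, soa) {
  ks <- seq(ceiling(jitter[1] / soa - 1e-9), floor(jitter[2] / soa + 1e-9))
  vals <- ks * soa
  vals <- vals[vals >= jitter[1] - 1e-9 & vals <= jitter[2] + 1e-9]
  if (length(vals) == 0L) {
    stop("baseline jitter interval [", jitter[1], ", ", jitter[2],
         "] s contains no multiple of the SOA (", soa, " s)")
  }
  vals
}

# target word of each condition; /abuna/ is always the background word
.target_word <- c(cluster = "abna", duration = "abuuna")

#' Token sequence for one stimulus block
#'
#' Fills a block with token onsets spaced exactly one SOA apart.  Baseline
#' blocks contain only the background word /abuna/.  Target blocks
#' interleave the condition's target word (/abna/ for cluster, /abuuna/ for
#' duration) with /abuna/ pseudo-randomly, under the constraints that both
#' words occur and no word repeats more than twice in a row.  In
#' `"multi"` token mode the three recorded exemplars of each word are cycled
#' pseudo-randomly with no immediate repetition of the same exemplar;
#' `"single"` mode always uses exemplar 1.
#'
#' @param kind `"baseline"` or `"target"`.
#' @param duration_s Block duration; must be a multiple of `soa`.
#' @param soa Stimulus onset asynchrony in seconds.
#' @param condition For target blocks, `"cluster"` or `"duration"`.
#' @param token_mode `"multi"` (3 exemplars per word) or `"single"`.
#' @param onset_s Block onset; token onsets are returned absolute.
#' @return Data frame with `onset_s`, `word`, `token_index`.
#' @export
token_sequence <- function(kind, duration_s, soa = 1.5, condition = NULL,
                           token_mode = c("multi", "single"), onset_s = 0) {
  kind <- match.arg(kind, c("baseline", "target"))
  token_mode <- match.arg(token_mode)
  n <- duration_s / soa
  if (abs(n - round(n)) > 1e-9) {
    stop("block duration ", duration_s, " s is not a multiple of the SOA (",
         soa, " s)")
  }
  n <- as.integer(round(n))

  if (kind == "baseline") {
    words <- rep("abuna", n)
  } else {
    condition <- match.arg(condition, names(.target_word))
    tw <- .target_word[[condition]]
    repeat {
      words <- sample(c(tw, "abuna"), n, replace = TRUE)
      runs <- rle(words)$lengths
      if (max(runs) <= 2 && (n < 2 || length(unique(words)) == 2)) break
    }
  }

  if (token_mode == "single") {
    idx <- rep(1L, n)
  } else {
    idx <- integer(n)
    idx[1] <- sample.int(3L, 1L)
    if (n > 1) {
      for (i in 2:n) idx[i] <- sample(setdiff(1:3, idx[i - 1]), 1L)
    }
  }

  data.frame(onset_s = onset_s + (seq_len(n) - 1) * soa,
             word = words, token_index = idx)
}

# Shared block/token assembly for infant and adult designs.
.assemble_schedule <- function(n_target_blocks, soa, target_s, baseline_jitter,
                               conditions, token_mode, design) {
  if (n_target_blocks %% length(conditions) != 0) {
    stop("n_target_blocks (", n_target_blocks,
         ") must be a multiple of the number of conditions (",
         length(conditions), ") to balance them")
  }
  grid <- .baseline_grid(baseline_jitter, soa)
  cond_seq <- sample(rep(conditions, n_target_blocks / length(conditions)))
  base_dur <- sample(grid, n_target_blocks + 1, replace = TRUE)

  kinds <- c(rbind(rep("baseline", n_target_blocks), rep("target", n_target_blocks)),
             "baseline")
  durs <- numeric(length(kinds))
  conds <- rep(NA_character_, length(kinds))
  bi <- 1L
  for (i in seq_along(kinds)) {
    if (kinds[i] == "baseline") {
      durs[i] <- base_dur[(i + 1) %/% 2]
    } else {
      durs[i] <- target_s
      conds[i] <- cond_seq[bi]
      bi <- bi + 1L
    }
  }
  onsets <- cumsum(c(0, durs[-length(durs)]))
  blocks <- data.frame(kind = kinds, condition = conds,
                       onset_s = onsets, duration_s = durs)

  tokens <- do.call(rbind, lapply(seq_len(nrow(blocks)), function(i) {
    tk <- token_sequence(blocks$kind[i], blocks$duration_s[i], soa,
                         condition = if (blocks$kind[i] == "target") blocks$condition[i],
                         token_mode = token_mode, onset_s = blocks$onset_s[i])
    tk$block <- i
    tk
  }))
  rownames(tokens) <- NULL

  structure(
    list(blocks = blocks, tokens = tokens, soa = soa,
         token_mode = token_mode, conditions = conditions, design = design),
    class = "nirs_schedule"
  )
}

#' Generate an infant change-detection block schedule
#'
#' Alternates jittered baseline blocks of the background word with
#' fixed-length target blocks of the two change conditions (cluster,
#' duration), beginning and ending with a baseline.  Baseline durations are
#' drawn uniformly from the multiples of the SOA inside the jitter interval
#' (9, 10.5, ..., 18 s by default), so a 9 s target block carries 6 tokens
#' and an 18 s baseline 12.  The condition sequence is a pseudo-random
#' permutation with exactly equal counts per condition.
#'
#' @param n_target_blocks Number of target blocks (16-30 in the infant
#'   design; must be even so the two conditions balance).
#' @param soa Stimulus onset asynchrony, seconds.
#' @param target_s Target block duration, seconds.
#' @param baseline_jitter Length-2 interval for baseline durations, seconds;
#'   its lower bound must be at least `target_s`.
#' @param conditions Target condition labels.
#' @param token_mode `"multi"` or `"single"` (see [token_sequence()]).
#' @param seed Optional integer seed for reproducibility.
#' @return A `nirs_schedule`: list with `blocks` (kind, condition, onset_s,
#'   duration_s) and `tokens` (onset_s, word, token_index, block).
#' @examples
#' sch <- generate_infant_schedule(16, seed = 1)
#' sum(sch$blocks$duration_s) / 60  # session length in minutes
#' @export
generate_infant_schedule <- function(n_target_blocks = 16, soa = 1.5,
                                     target_s = 9, baseline_jitter = c(9, 18),
                                     conditions = c("cluster", "duration"),
                                     token_mode = c("multi", "single"),
                                     seed = NULL) {
  token_mode <- match.arg(token_mode)
  stopifnot(n_target_blocks >= 1, soa > 0, target_s > 0,
            length(baseline_jitter) == 2, baseline_jitter[1] <= baseline_jitter[2])
  if (baseline_jitter[1] < target_s) {
    stop("infant design requires baseline jitter lower bound (",
         baseline_jitter[1], " s) >= target duration (", target_s, " s)")
  }
  if (!is.null(seed)) set.seed(seed)
  sch <- .assemble_schedule(n_target_blocks, soa, target_s, baseline_jitter,
                            conditions, token_mode, design = "infant")
  sch$seed <- seed
  sch
}

#' Generate an adult 2 x 2 follow-up schedule
#'
#' The adult factorial design crosses target-block duration (short = 9 s,
#' long = 15 s) with token variability (single exemplar vs. the three
#' exemplars per word).  Baselines are jittered within 9-18 s for the short
#' conditions and 15-22 s for the long conditions (quantized to SOA
#' multiples), and each of the two change conditions (cluster, duration)
#' appears `n_per_condition` times per session.
#'
#' @param condition One of `"short-single"`, `"long-single"`,
#'   `"short-multi"`, `"long-multi"`.
#' @param n_per_condition Target blocks per change condition (4-5).
#' @param soa Stimulus onset asynchrony, seconds.
#' @param seed Optional integer seed.
#' @return A `nirs_schedule` (see [generate_infant_schedule()]).
#' @export
generate_adult_schedule <- function(condition = c("short-single", "long-single",
                                                  "short-multi", "long-multi"),
                                    n_per_condition = 5, soa = 1.5,
                                    seed = NULL) {
  condition <- match.arg(condition)
  parts <- strsplit(condition, "-", fixed = TRUE)[[1]]
  target_s <- if (parts[1] == "short") 9 else 15
  jitter <- if (parts[1] == "short") c(9, 18) else c(15, 22)
  token_mode <- if (parts[2] == "single") "single" else "multi"
  if (!is.null(seed)) set.seed(seed)
  sch <- .assemble_schedule(2 * n_per_condition, soa, target_s, jitter,
                            c("cluster", "duration"), token_mode,
                            design = paste0("adult-", condition))
  sch$seed <- seed
  sch
}

#' Total session duration of a schedule
#' @param schedule A `nirs_schedule`.
#' @return Duration in seconds.
#' @export
session_duration <- function(schedule) {
  stopifnot(inherits(schedule, "nirs_schedule"))
  sum(schedule$blocks$duration_s)
}

#' @export
print.nirs_schedule <- function(x, ...) {
  nt <- sum(x$blocks$kind == "target")
  cat(sprintf("<nirs_schedule> %s design: %d target + %d baseline blocks, %.1f s (%.1f min)\n",
              x$design, nt, sum(x$blocks$kind == "baseline"),
              session_duration(x), session_duration(x) / 60))
  print(table(stats::na.omit(x$blocks$condition)))
  invisible(x)
}

#' Write / read a schedule as a BIDS-style events table
#'
#' The events file is a UTF-8 TSV with columns `onset_s`, `duration_s`,
#' `trial_type`, `word`, `token_index`.  Block rows use `trial_type`
#' `"baseline"` or the target condition label; individual stimulus tokens
#' are written as `trial_type = "token"` rows whose duration is the word
#' duration from [word_duration()].
#'
#' @param schedule A `nirs_schedule`.
#' @param path File path.
#' @return `write_events` returns `path` invisibly; `read_events` returns a
#'   `nirs_schedule` rebuilt from the file.
#' @export
write_events <- function(schedule, path) {
  stopifnot(inherits(schedule, "nirs_schedule"))
  b <- schedule$blocks
  blk <- data.frame(onset_s = b$onset_s, duration_s = b$duration_s,
                    trial_type = ifelse(b$kind == "baseline", "baseline", b$condition),
                    word = NA_character_, token_index = NA_integer_)
  tk <- schedule$tokens
  tok <- data.frame(onset_s = tk$onset_s,
                    duration_s = vapply(tk$word, word_duration, numeric(1)) / 1000,
                    trial_type = "token", word = tk$word,
                    token_index = tk$token_index)
  out <- rbind(blk, tok)
  out <- out[order(out$onset_s, out$trial_type != "token", decreasing = FALSE), ]
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8", na = "n/a")
  invisible(path)
}

#' @rdname write_events
#' @param soa SOA to record on the rebuilt schedule (not stored in the file).
#' @export
read_events <- function(path, soa = 1.5) {
  df <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                          na.strings = "n/a", fileEncoding = "UTF-8")
  need <- c("onset_s", "duration_s", "trial_type", "word", "token_index")
  if (!all(need %in% names(df))) {
    stop("events file ", path, " is missing columns: ",
         paste(setdiff(need, names(df)), collapse = ", "))
  }
  bad <- which(!is.finite(df$onset_s) | !is.finite(df$duration_s))
  if (length(bad) > 0) {
    stop("malformed events rows (non-numeric onset/duration) at line(s) ",
         paste(bad + 1L, collapse = ", "))  # +1 for the header line
  }
  if (nrow(df) == 0L) stop("no samples: events file ", path, " is empty")

  is_tok <- df$trial_type == "token"
  b <- df[!is_tok, ]
  b <- b[order(b$onset_s), ]
  if (any(diff(b$onset_s) < b$duration_s[-nrow(b)] - 1e-9)) {
    stop("events file ", path, " contains overlapping blocks")
  }
  kinds <- ifelse(b$trial_type == "baseline", "baseline", "target")
  if (any(kinds[-1] == kinds[-length(kinds)])) {
    stop("events file ", path, " blocks do not alternate baseline/target")
  }
  blocks <- data.frame(kind = kinds,
                       condition = ifelse(kinds == "baseline", NA_character_,
                                          b$trial_type),
                       onset_s = b$onset_s, duration_s = b$duration_s)
  tk <- df[is_tok, ]
  tk <- tk[order(tk$onset_s), ]
  block_of <- findInterval(tk$onset_s + 1e-9, blocks$onset_s)
  tokens <- data.frame(onset_s = tk$onset_s, word = tk$word,
                       token_index = as.integer(tk$token_index),
                       block = block_of)
  rownames(blocks) <- rownames(tokens) <- NULL
  conds <- unique(stats::na.omit(blocks$condition))
  structure(
    list(blocks = blocks, tokens = tokens, soa = soa,
         token_mode = if (all(tokens$token_index == 1L)) "single" else "multi",
         conditions = sort(conds), design = "file"),
    class = "nirs_schedule"
  )
}
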