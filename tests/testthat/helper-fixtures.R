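# Shared in-code fixtures for the test suite.

# A hand-built schedule with exact block durations (bypasses the random
# generator) -- kinds alternate baseline/target starting and ending with a
# baseline; conditions cycle cluster/duration over the target blocks.
make_fixed_schedule <- function(target_s = 9, baseline_s = 13.5,
                                n_targets = 8, soa = 1.5,
                                conditions = c("cluster", "duration")) {
  kinds <- c(rbind(rep("baseline", n_targets), rep("target", n_targets)),
             "baseline")
  durs <- ifelse(kinds == "baseline", baseline_s, target_s)
  conds <- rep(NA_character_, length(kinds))
  conds[kinds == "target"] <- rep_len(conditions, n_targets)
  onsets <- cumsum(c(0, durs[-length(durs)]))
  blocks <- data.frame(kind = kinds, condition = conds,
                       onset_s = onsets, duration_s = durs)
  # deterministic token fill without disturbing the ambient RNG stream
  old_seed <- if (exists(".Random.seed", .GlobalEnv))
    get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, .GlobalEnv), add = TRUE)
  tokens <- do.call(rbind, lapply(seq_len(nrow(blocks)), function(i) {
    set.seed(i)
    tk <- token_sequence(blocks$kind[i], blocks$duration_s[i], soa,
                         condition = if (blocks$kind[i] == "target") blocks$condition[i],
                         onset_s = blocks$onset_s[i])
    tk$block <- i
    tk
  }))
  structure(list(blocks = blocks, tokens = tokens, soa = soa,
                 token_mode = "multi", conditions = conditions,
                 design = "fixed"),
            class = "nirs_schedule")
}

# white-noise-only model (stationary; no oscillatory components)
white_noise <- function(sd = 0.05) {
  noise_model(white_sd = sd, drift_amps = c(0, 0), cardiac_amp = 0,
              resp_amp = 0)
}

# quiet noise so artifact/GLM fixtures stay artifact-free
quiet_noise <- function(sd = 0.01) white_noise(sd)
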