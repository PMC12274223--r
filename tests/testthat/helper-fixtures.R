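# Fixtures are generated in code; nothing is stored on disk.

# A bare sine signal (no ramps), for closed-form feature checks.
tone_signal <- function(freq = 440, dur_s = 1, sr = 16000, amp = 1) {
  audio_signal(amp * sin(2 * pi * freq * (0:(dur_s * sr - 1)) / sr), sr)
}

# Alternating voiced/silent interval table.
alternating_intervals <- function(voiced_ms, silent_ms) {
  n <- length(voiced_ms) + length(silent_ms)
  kind <- rep(c("voiced", "silent"), length.out = n)
  data.frame(kind = kind,
             duration_ms = as.numeric(rbind(voiced_ms,
                                            c(silent_ms, NA)))[seq_len(n)])
}

# The standard 5-burst fixture: 5 x 600-ms bursts, 4 x 300-ms silences.
five_burst_spec <- function(ambient = 0, amp = 0.8, seed = 1, hz = 500) {
  utterance_spec(alternating_intervals(rep(600, 5), rep(300, 4)),
                 voiced_hz = hz, voiced_amplitude = amp,
                 ambient_amplitude = ambient, seed = seed)
}

# Random utterance spec meeting the detectability guarantee, with durations
# at least twice their temporal thresholds. Clean specs exercise the exact
# 150-ms short/long boundary; noisy specs keep a guard band around it that
# covers the <= 5 ms boundary blur of the noise-gate expander.
random_utterance_spec <- function(seed) {
  withr::with_seed(seed, {
    noisy <- runif(1) < 0.5
    n_bursts <- sample(3:6, 1)
    voiced <- sample(seq(200, 800, by = 25), n_bursts, replace = TRUE)
    silent_pool <- if (noisy) c(seq(100, 140, by = 5), 150,
                                seq(165, 600, by = 5))
                   else c(seq(100, 150, by = 5), 150, seq(151, 600, by = 7))
    silent <- sample(silent_pool, n_bursts - 1, replace = TRUE)
    utterance_spec(alternating_intervals(voiced, silent),
                   voiced_hz = sample(c(440, 500), 1),
                   voiced_amplitude = runif(1, 0.3, 1),
                   ambient_amplitude = if (noisy) runif(1, 0.01, 0.05) else 0,
                   seed = seed)
  })
}

# Detect events the way a user would: denoise when ambient noise is present,
# normalize, detect.
detect_from_spec <- function(spec, config = detection_config()) {
  u <- make_synthetic_utterance(spec, config)
  sig <- u$signal
  if (spec$ambient_amplitude > 0) sig <- reduce_noise(sig)
  sig <- normalize_amplitude(sig)
  list(events = detect_events(sig, config), truth = u$truth)
}

# Hand-built event sequence from explicit durations (ms).
manual_events <- function(pause_ms, vocal_ms, config = detection_config()) {
  durs <- numeric(0); kinds <- character(0)
  n <- max(length(pause_ms), length(vocal_ms))
  for (i in seq_len(n)) {
    if (i <= length(vocal_ms)) { durs <- c(durs, vocal_ms[i]); kinds <- c(kinds, "vocal") }
    if (i <= length(pause_ms)) { durs <- c(durs, pause_ms[i]); kinds <- c(kinds, "pause") }
  }
  ends <- cumsum(durs) / 1000
  ev <- structure(data.frame(kind = kinds, subtype = "none",
                             start_s = c(0, head(ends, -1)), end_s = ends,
                             duration_ms = durs),
                  class = c("event_sequence", "data.frame"),
                  signal_duration_s = max(ends), config = config)
  split_pauses(ev, config)
}

# Minimal frame_series construction for label-rule tests.
manual_frames <- function(rmse, zcr, sr = 16000, window_n = 800, hop_n = 16) {
  starts <- 1L + (seq_along(rmse) - 1L) * hop_n
  structure(list(start_sample = starts,
                 times_s = (starts - 1 + window_n / 2) / sr,
                 rmse = rmse, zcr = as.integer(zcr),
                 segment_index = rep(1L, length(rmse)),
                 window_n = window_n, hop_n = hop_n, sample_rate = sr),
            class = "frame_series")
}

# Independent brute-force implementation of the frame labeling rule, used
# as the oracle for label_frames.
brute_force_labels <- function(rmse, zcr) {
  m <- mean(rmse)
  vapply(seq_along(rmse), function(i) {
    if (rmse[i] > m && zcr[i] > 0) "nonsilent"
    else if (rmse[i] < m && zcr[i] == 0) "silent"
    else if (zcr[i] == 0) "silent" else "nonsilent"
  }, "")
}

# Independent direct-formula oracle for the 13 metrics.
oracle_metrics <- function(pause_ms, pause_subtype, vocal_ms, word_count,
                           duration_s) {
  cv <- function(x) if (length(x) < 2) NA_real_ else sd(x) / mean(x)
  mn <- function(x) if (length(x) == 0) NA_real_ else mean(x)
  long <- pause_ms[pause_subtype == "long"]
  short <- pause_ms[pause_subtype == "short"]
  list(speech_rate_wpm = word_count * 60 / duration_s,
       total_pause_time_s = sum(pause_ms) / 1000,
       pause_count = length(pause_ms),
       mean_pause_ms = mn(pause_ms), mean_vocal_ms = mn(vocal_ms),
       pause_cv = cv(pause_ms), vocal_cv = cv(vocal_ms),
       mean_long_pause_ms = mn(long), mean_short_pause_ms = mn(short),
       long_pause_cv = cv(long), short_pause_cv = cv(short),
       long_pause_count = length(long), short_pause_count = length(short))
}

# Brute-force Benjamini-Hochberg step-up from the definition.
brute_force_bh <- function(p, q) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  thresh <- seq_len(m) * q / m
  k <- suppressWarnings(max(which(ps <= thresh)))
  reject <- logical(m)
  if (is.finite(k)) reject[o[seq_len(k)]] <- TRUE
  adj_sorted <- rev(cummin(rev(pmin(1, m * ps / seq_len(m)))))
  adj <- numeric(m); adj[o] <- adj_sorted
  list(reject = reject, adjusted = adj)
}

# Small covariate frame for statistics tests.
fake_covariates <- function(n_awns = 18, n_aws = 17, seed = 1) {
  withr::with_seed(seed, {
    n <- n_awns + n_aws
    data.frame(participant_id = sprintf("P%03d", 1:n),
               group = rep(c("AWNS", "AWS"), c(n_awns, n_aws)),
               sex = sample(c("male", "female"), n, TRUE),
               age = round(runif(n, 22, 62), 1),
               percent_ss = c(rep(NA, n_awns), round(runif(n_aws, 0.5, 25), 1)))
  })
}

# Write a 2-channel 16-bit PCM WAV (tests the multi-channel read path).
write_stereo_wav <- function(left, right, sr, path) {
  inter <- as.numeric(rbind(left, right))
  pcm <- as.integer(round(pmax(-1, pmin(1, inter)) * 32767))
  con <- file(path, "wb"); on.exit(close(con))
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + length(pcm) * 2L), con, size = 4, endian = "little")
  writeChar("WAVEfmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")
  writeBin(1L, con, size = 2, endian = "little")
  writeBin(2L, con, size = 2, endian = "little")
  writeBin(as.integer(sr), con, size = 4, endian = "little")
  writeBin(as.integer(sr * 4L), con, size = 4, endian = "little")
  writeBin(4L, con, size = 2, endian = "little")
  writeBin(16L, con, size = 2, endian = "little")
  writeChar("data", con, eos = NULL)
  writeBin(length(pcm) * 2L, con, size = 4, endian = "little")
  writeBin(pcm, con, size = 2, endian = "little")
  invisible(path)
}
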