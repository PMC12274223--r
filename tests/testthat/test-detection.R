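# The detector core: segmentation, short-time features, frame labeling,
# region extraction, event classification, pause splitting.

test_that("blind segmentation covers the signal with 3-s clips", {
  sr <- 16000
  seg_len <- function(dur_s) {
    sig <- audio_signal(numeric(dur_s * sr) + 0.1, sr)
    s <- segment_signal(sig)
    (s$end_sample - s$start_sample + 1) / sr
  }
  expect_equal(seg_len(9.0), rep(3, 3))
  expect_equal(seg_len(10.0), c(3, 3, 3, 1))
  # 20-ms remainder is below one window: absorbed into the previous segment
  expect_equal(seg_len(9.02), c(3, 3, 3.02))
  expect_error(segment_signal(audio_signal(numeric(100) + 1, sr)), "too short")
})

test_that("segments are consecutive, non-overlapping and exhaustive", {
  sig <- tone_signal(dur_s = 13.7)
  s <- segment_signal(sig)
  expect_equal(s$start_sample[1], 1)
  expect_equal(s$end_sample[nrow(s)], n_samples(sig))
  expect_equal(s$start_sample[-1], head(s$end_sample, -1) + 1)
})

test_that("short-time RMSE and ZCR match closed forms", {
  sr <- 16000
  cfg <- detection_config()
  const <- audio_signal(rep(0.5, 800), sr)
  f <- short_time_features(const, cfg)
  expect_equal(f$rmse, 0.5)
  expect_equal(f$zcr, 0L)

  sine <- tone_signal(freq = 440, dur_s = 0.05, amp = 1)
  fs <- short_time_features(sine, cfg)
  expect_lt(abs(fs$rmse[1] - 1 / sqrt(2)) / (1 / sqrt(2)), 0.01)
  expect_lt(abs(fs$zcr[1] - 2 * 440 * 0.05), 2)

  zero <- audio_signal(numeric(800), sr)
  fz <- short_time_features(zero, cfg)
  expect_equal(fz$rmse, 0)
  expect_equal(fz$zcr, 0L)
})

test_that("frames are emitted only where the full window fits", {
  sig <- audio_signal(rnorm(1000), 16000)  # 62.5 ms
  f <- short_time_features(sig)
  expect_equal(length(f$rmse), length(seq(1, 1000 - 800 + 1, by = 16)))
  expect_true(all(f$start_sample + f$window_n - 1 <= 1000))
  expect_true(all(f$zcr >= 0 & f$zcr <= f$window_n - 1))
})

test_that("transitions involving exact zero samples are not crossings", {
  sr <- 16000
  x <- rep(0, 800); x[100] <- 0.5; x[200] <- -0.5  # isolated nonzero samples
  f <- short_time_features(audio_signal(x, sr))
  expect_equal(f$zcr[1], 0L)
  x2 <- rep(0, 800); x2[100] <- 0.5; x2[101] <- -0.5  # adjacent opposite signs
  f2 <- short_time_features(audio_signal(x2, sr))
  expect_equal(f2$zcr[1], 1L)
})

test_that("frame labeling follows the dual-threshold rule with ZCR tie-break", {
  # the four RMSE x ZCR condition combinations around a mean of 0.4
  fr <- manual_frames(rmse = c(0.8, 0.0, 0.6, 0.2), zcr = c(12, 0, 0, 3))
  expect_equal(label_frames(fr),
               c("nonsilent", "silent", "silent", "nonsilent"))
  expect_error(label_frames(manual_frames(numeric(0), integer(0))), "empty")
})

test_that("frame labeling agrees with the brute-force rule everywhere", {
  withr::with_seed(99, {
    for (rep in 1:20) {
      n <- sample(5:50, 1)
      rmse <- round(runif(n, 0, 1), 2)       # rounding forces ties at the mean
      zcr <- sample(0:3, n, replace = TRUE)
      fr <- manual_frames(rmse, zcr)
      expect_equal(label_frames(fr), brute_force_labels(rmse, zcr))
    }
  })
})

test_that("region extraction run-length encodes labels and tiles the span", {
  # runs comfortably longer than one analysis window (as in real use)
  zcr <- rep(c(0L, 5L, 0L, 5L), c(150, 120, 140, 110))
  fr <- manual_frames(rmse = rep(0.5, length(zcr)), zcr = zcr)
  lab <- label_frames(fr)
  span <- c(1L, fr$start_sample[length(zcr)] + fr$window_n)
  reg <- frames_to_regions(lab, fr, span)
  expect_equal(reg$label, c("silent", "nonsilent", "silent", "nonsilent"))
  expect_equal(reg$start_sample[1], span[1])
  expect_equal(reg$end_sample[nrow(reg)], span[2])
  expect_equal(reg$start_sample[-1], head(reg$end_sample, -1))  # contiguous
  # silence-anchored boundaries: silent runs end at their last window end,
  # and begin at their first window start
  expect_equal(reg$end_sample[1], fr$start_sample[150] + fr$window_n)
  expect_equal(reg$start_sample[3], fr$start_sample[271])
})

test_that("uniform labels give a single spanning region", {
  fr <- manual_frames(rmse = rep(0.2, 8), zcr = rep(0L, 8))
  reg <- frames_to_regions(label_frames(fr), fr)
  expect_equal(nrow(reg), 1L)
  expect_equal(reg$label, "silent")
})

test_that("event classification applies temporal thresholds and absorption", {
  sr <- 16000
  cfg <- detection_config()
  mk <- function(labels, ms) {
    ends <- cumsum(ms * sr / 1000)
    data.frame(label = labels, start_sample = c(1, head(ends, -1) + 1),
               end_sample = ends + 1)
  }
  # all regions above threshold
  ev <- classify_events(mk(c("nonsilent", "silent", "nonsilent"),
                           c(500, 300, 400)), cfg, sr)
  expect_equal(ev$kind, c("vocal", "pause", "vocal"))
  expect_equal(ev$duration_ms, c(500, 300, 400), tolerance = 1e-6)

  # 40-ms silent gap absorbed, neighbors merged
  ev2 <- classify_events(mk(c("nonsilent", "silent", "nonsilent"),
                            c(500, 40, 500)), cfg, sr)
  expect_equal(ev2$kind, "vocal")
  expect_equal(ev2$duration_ms, 1040, tolerance = 1e-6)

  # symmetric case: 60-ms nonsilent island inside silence
  ev3 <- classify_events(mk(c("silent", "nonsilent", "silent"),
                            c(200, 60, 200)), cfg, sr)
  expect_equal(ev3$kind, "pause")
  expect_equal(ev3$duration_ms, 460, tolerance = 1e-6)

  # leading sub-threshold region merges rightward into the first event
  ev4 <- classify_events(mk(c("silent", "nonsilent"), c(30, 500)), cfg, sr)
  expect_equal(ev4$kind, "vocal")
  expect_equal(ev4$duration_ms, 530, tolerance = 1e-6)
})

test_that("pause subtypes split at an inclusive 150-ms boundary", {
  ev <- manual_events(pause_ms = c(120, 150, 151), vocal_ms = rep(500, 4))
  p <- ev[ev$kind == "pause", ]
  expect_equal(p$subtype, c("short", "short", "long"))
  bad <- manual_events(pause_ms = 200, vocal_ms = c(500, 500))
  bad$duration_ms[bad$kind == "pause"] <- 30
  expect_error(split_pauses(bad), "invariant")
})

test_that("detection recovers the five-burst fixture exactly", {
  res <- detect_from_spec(five_burst_spec(seed = 2))
  ev <- res$events
  expect_equal(sum(ev$kind == "vocal"), 5)
  expect_equal(sum(ev$kind == "pause"), 4)
  expect_true(all(ev$subtype[ev$kind == "pause"] == "long"))
  tol <- 0.05 / 2 + 0.001
  expect_true(all(abs(ev$start_s - res$truth$start_s) <= tol))
  expect_true(all(abs(ev$end_s - res$truth$end_s) <= tol))
})

test_that("80-ms silences are detected as short pauses", {
  spec <- utterance_spec(alternating_intervals(rep(600, 4), rep(80, 3)),
                         voiced_hz = 500, seed = 5)
  res <- detect_from_spec(spec)
  p <- res$events[res$events$kind == "pause", ]
  expect_equal(nrow(p), 3)
  expect_true(all(p$subtype == "short"))
})

test_that("pure silence yields a single degenerate pause event", {
  sig <- audio_signal(numeric(32000), 16000)
  ev <- detect_events(sig)
  expect_equal(nrow(ev), 1)
  expect_equal(ev$kind, "pause")
})

test_that("events spanning a 3-s segment boundary are not split", {
  # a 400-ms silence straddling the t = 3 s boundary
  spec <- utterance_spec(alternating_intervals(c(2800, 2800), 400),
                         voiced_hz = 500, seed = 6)
  res <- detect_from_spec(spec)
  ev <- res$events
  expect_equal(ev$kind, c("vocal", "pause", "vocal"))
  expect_equal(ev$duration_ms[2], 400, tolerance = 2)
})

test_that("vocal and pause events strictly alternate and counts differ by <= 1", {
  for (seed in c(31, 32, 33)) {
    res <- detect_from_spec(random_utterance_spec(seed))
    k <- res$events$kind
    expect_true(all(k[-1] != k[-length(k)]))
    expect_lte(abs(sum(k == "pause") - sum(k == "vocal")), 1)
  }
})

test_that("event durations tile the trimmed signal", {
  res <- detect_from_spec(five_burst_spec(seed = 9))
  dur <- attr(res$events, "signal_duration_s")
  expect_equal(sum(res$events$duration_ms) / 1000, dur, tolerance = 0.06)
})

test_that("detection is invariant to amplitude scaling", {
  u <- make_synthetic_utterance(five_burst_spec(seed = 10))
  ev1 <- detect_events(u$signal)
  scaled <- audio_signal(u$signal$samples * 0.31, u$signal$sample_rate)
  ev2 <- detect_events(scaled)
  expect_equal(as.data.frame(ev1), as.data.frame(ev2))
})

test_that("event tables round-trip through CSV", {
  res <- detect_from_spec(five_burst_spec(seed = 11))
  path <- withr::local_tempfile(fileext = ".csv")
  write_events(res$events, path, recording_id = "r1")
  back <- read_events(path)
  expect_equal(back$kind, res$events$kind)
  expect_equal(back$subtype, res$events$subtype)
  expect_equal(back$start_s, res$events$start_s, tolerance = 1e-6)
  expect_equal(back$duration_ms, res$events$duration_ms, tolerance = 1e-3)
})
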