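# ATAS event detection: blind 3-s segmentation, short-time RMSE/ZCR on a
# 50-ms window / 1-ms hop grid, per-segment dual-threshold frame labeling,
# run-length region extraction, temporal-threshold event classification, and
# the short/long pause split.

#' Detection configuration
#'
#' Parameters of the event detector. Defaults follow the standard analysis:
#' non-overlapping 3-s segments, 50-ms analysis windows advanced in 1-ms
#' hops, a 100-ms minimum for vocal events, a 50-ms minimum for pause
#' events, and a 150-ms boundary between short and long pauses (short pauses
#' span 50-150 ms inclusive; long pauses are strictly longer than 150 ms).
#'
#' @param segment_duration_s Blind segmentation length in seconds.
#' @param window_ms Short-time analysis window in milliseconds.
#' @param hop_ms Hop (step) between consecutive windows in milliseconds.
#' @param vocal_min_ms Non-silent regions must exceed this to become vocal
#'   events (strict inequality).
#' @param pause_min_ms Silent regions at or above this become pause events.
#' @param short_long_boundary_ms Pauses at or below this are short, above it
#'   long.
#' @param zcr_zero_tolerance Crossing counts at or below this are treated as
#'   "zero ZCR" (default 0: silence must have no crossings at all).
#' @return A `detection_config` list.
#' @export
detection_config <- function(segment_duration_s = 3.0, window_ms = 50,
                             hop_ms = 1, vocal_min_ms = 100,
                             pause_min_ms = 50, short_long_boundary_ms = 150,
                             zcr_zero_tolerance = 0) {
  if (!(window_ms > hop_ms && hop_ms > 0))
    stopf("need window_ms > hop_ms > 0")
  if (!(vocal_min_ms > pause_min_ms && pause_min_ms > 0))
    stopf("need vocal_min_ms > pause_min_ms > 0")
  if (!(short_long_boundary_ms > pause_min_ms))
    stopf("need short_long_boundary_ms > pause_min_ms")
  if (segment_duration_s * 1000 < window_ms)
    stopf("segment_duration_s must cover at least one analysis window")
  structure(list(segment_duration_s = segment_duration_s,
                 window_ms = window_ms, hop_ms = hop_ms,
                 vocal_min_ms = vocal_min_ms, pause_min_ms = pause_min_ms,
                 short_long_boundary_ms = short_long_boundary_ms,
                 zcr_zero_tolerance = zcr_zero_tolerance),
            class = "detection_config")
}

#' Blindly segment a signal into non-overlapping clips
#'
#' Cuts the signal into consecutive segments of `segment_duration_s`
#' seconds. A trailing remainder is kept as its own (shorter) segment when
#' it can hold at least one analysis window, and is absorbed into the
#' previous segment otherwise.
#'
#' @param signal An [audio_signal()].
#' @param config A [detection_config()].
#' @return A data frame with `segment_index`, `start_sample`, `end_sample`
#'   (1-based, inclusive).
#' @export
segment_signal <- function(signal, config = detection_config()) {
  stopifnot(inherits(signal, "audio_signal"))
  sr <- signal$sample_rate
  n <- n_samples(signal)
  win_n <- ms_to_samples(config$window_ms, sr)
  if (n < win_n)
    stopf("signal too short: %d samples < one %d-ms window", n, config$window_ms)
  seg_n <- as.integer(round(config$segment_duration_s * sr))
  starts <- seq(1L, n, by = seg_n)
  ends <- pmin(starts + seg_n - 1L, n)
  k <- length(starts)
  if (k > 1 && (ends[k] - starts[k] + 1L) < win_n) {
    ends[k - 1] <- ends[k]
    starts <- starts[-k]; ends <- ends[-k]
  }
  data.frame(segment_index = seq_along(starts),
             start_sample = starts, end_sample = ends)
}

#' Short-time RMS energy and zero-crossing rate
#'
#' Slides a `window_ms` window in `hop_ms` steps over the segment and emits
#' one frame per position at which the full window fits (no padding). Frame
#' RMSE is the square root of the mean squared amplitude in the window.
#' Frame ZCR counts strict sign changes: sample pairs with nonzero, opposite
#' signs. Transitions into or out of exact zero are not crossings, so an
#' all-zero (gated-silence) window has ZCR exactly 0.
#'
#' @param segment An [audio_signal()] (one blind segment).
#' @param config A [detection_config()].
#' @param segment_index Index recorded on the output frames.
#' @param offset_samples Sample offset of the segment within the full
#'   recording (0 for a standalone segment); times are reported on the
#'   recording clock.
#' @return A `frame_series` list: `start_sample` (window starts, 1-based on
#'   the recording), `times_s` (window centers in seconds), `rmse`, `zcr`,
#'   `segment_index`, plus the window/hop geometry.
#' @export
short_time_features <- function(segment, config = detection_config(),
                                segment_index = 1L, offset_samples = 0L) {
  stopifnot(inherits(segment, "audio_signal"))
  sr <- segment$sample_rate
  x <- segment$samples
  n <- length(x)
  win_n <- ms_to_samples(config$window_ms, sr)
  hop_n <- max(1L, ms_to_samples(config$hop_ms, sr))
  if (n < win_n)
    stopf("segment too short: %d samples < one %d-ms window", n, config$window_ms)

  starts <- seq.int(1L, n - win_n + 1L, by = hop_n)
  cs2 <- cumsum(c(0, x^2))
  rmse <- sqrt(pmax(0, cs2[starts + win_n] - cs2[starts]) / win_n)

  s <- sign(x)
  crossing <- c(0, as.numeric(s[-1] * s[-n] < 0))  # strict sign change at i
  cc <- cumsum(crossing)
  # crossings at positions start+1 .. start+win_n-1
  zcr <- cc[starts + win_n - 1L] - cc[starts]

  structure(list(start_sample = starts + as.integer(offset_samples),
                 times_s = (starts - 1 + as.integer(offset_samples) + win_n / 2) / sr,
                 rmse = rmse, zcr = as.integer(zcr),
                 segment_index = rep(as.integer(segment_index), length(starts)),
                 window_n = win_n, hop_n = hop_n, sample_rate = sr),
            class = "frame_series")
}

#' @export
print.frame_series <- function(x, ...) {
  cat(sprintf("<frame_series> %d frames (window %d, hop %d samples @ %d Hz)\n",
              length(x$rmse), x$window_n, x$hop_n, x$sample_rate))
  invisible(x)
}

#' Label frames as silent or non-silent
#'
#' Applies the dual-threshold rule within one blind segment: frames with
#' RMSE above the segment's mean RMSE and a non-zero ZCR are non-silent;
#' frames with RMSE below the mean and zero ZCR are silent. Frames matching
#' neither conjunction (e.g. loud but crossing-free, or RMSE exactly at the
#' mean) are resolved by the ZCR criterion alone, since zero ZCR is the
#' signature of gated silence.
#'
#' @param frames A `frame_series` from one segment (see
#'   [short_time_features()]).
#' @param zcr_zero_tolerance Crossing counts at or below this count as zero.
#' @return Character vector of `"silent"` / `"nonsilent"`, one per frame.
#' @export
label_frames <- function(frames, zcr_zero_tolerance = 0) {
  if (length(frames$rmse) == 0) stopf("empty frame series")
  m <- mean(frames$rmse)
  zcr_zero <- frames$zcr <= zcr_zero_tolerance
  lab <- character(length(frames$rmse))
  nonsil <- frames$rmse > m & !zcr_zero
  sil <- frames$rmse < m & zcr_zero
  lab[nonsil] <- "nonsilent"
  lab[sil] <- "silent"
  amb <- !nonsil & !sil
  lab[amb] <- ifelse(zcr_zero[amb], "silent", "nonsilent")
  lab
}

#' Collapse frame labels into contiguous labeled regions
#'
#' Run-length encodes the per-frame labels and places region boundaries on
#' the silence-anchored convention: the boundary entering a silent run sits
#' at that run's first window start, and the boundary leaving it at its last
#' window end. Because a window is labeled silent only when it lies wholly
#' inside silence, these anchors recover the true voiced/silent transition
#' points on clean signals to within one hop; regions tile the segment
#' exactly.
#'
#' @param labels Character labels from [label_frames()].
#' @param frames The matching `frame_series`.
#' @param span Optional `c(start_sample, end_sample)` of the segment on the
#'   recording clock; defaults to the span implied by the frames.
#' @return Data frame `label`, `start_sample`, `end_sample` (1-based;
#'   `end_sample` exclusive), contiguous and covering `span`.
#' @export
frames_to_regions <- function(labels, frames, span = NULL) {
  stopifnot(length(labels) == length(frames$rmse))
  win_n <- frames$window_n
  if (is.null(span))
    span <- c(frames$start_sample[1],
              frames$start_sample[length(labels)] + win_n)
  r <- rle(labels)
  k <- length(r$values)
  last <- cumsum(r$lengths)
  first <- c(1L, head(last, -1) + 1L)
  # boundary b[i] between run i and run i+1
  bounds <- numeric(k + 1)
  bounds[1] <- span[1]
  bounds[k + 1] <- span[2]
  if (k > 1) {
    for (i in 1:(k - 1)) {
      bounds[i + 1] <- if (r$values[i + 1] == "silent")
        frames$start_sample[first[i + 1]]     # entering silence: window start
      else
        frames$start_sample[last[i]] + win_n  # leaving silence: window end
    }
    bounds <- pmin(pmax(bounds, span[1]), span[2])
    bounds <- cummax(bounds)
  }
  out <- data.frame(label = r$values,
                    start_sample = bounds[-(k + 1)],
                    end_sample = bounds[-1])
  out[out$end_sample > out$start_sample, , drop = FALSE]
}

# Merge adjacent regions with identical labels (used after concatenating
# per-segment region lists, so events may span segment boundaries).
merge_same_label <- function(regions) {
  if (nrow(regions) <= 1) return(regions)
  keep_new <- c(TRUE, regions$label[-1] != regions$label[-nrow(regions)])
  grp <- cumsum(keep_new)
  data.frame(label = regions$label[keep_new],
             start_sample = tapply(regions$start_sample, grp, min),
             end_sample = tapply(regions$end_sample, grp, max),
             row.names = NULL)
}

#' Classify labeled regions into vocal and pause events
#'
#' Silent regions of at least `pause_min_ms` become pause events; non-silent
#' regions strictly longer than `vocal_min_ms` become vocal events.
#' Sub-threshold regions are absorbed into the running event on their left
#' (leading sub-threshold regions merge rightward into the first qualifying
#' event), and adjacent events of the same kind are then merged. A recording
#' with no qualifying region at all yields a single event of whichever label
#' occupies more total time.
#'
#' @param regions Data frame from [frames_to_regions()] (concatenated across
#'   segments), with `label`, `start_sample`, `end_sample`.
#' @param config A [detection_config()].
#' @param sample_rate Sampling rate used to convert samples to time.
#' @param signal_duration_s Total recording duration recorded on the result.
#' @return An `event_sequence`: data frame `kind`, `subtype`, `start_s`,
#'   `end_s`, `duration_ms` with the configuration and duration attached as
#'   attributes. Pause subtypes are filled in by [split_pauses()].
#' @export
classify_events <- function(regions, config = detection_config(),
                            sample_rate, signal_duration_s = NULL) {
  stopifnot(nrow(regions) >= 1)
  regions <- merge_same_label(regions)
  dur_ms <- (regions$end_sample - regions$start_sample) / sample_rate * 1000
  eps <- 1e-9
  qualifies <- ifelse(regions$label == "silent",
                      dur_ms >= config$pause_min_ms - eps,
                      dur_ms > config$vocal_min_ms + eps)

  ev <- list()
  pending_start <- NULL
  for (i in seq_len(nrow(regions))) {
    if (qualifies[i]) {
      start <- if (is.null(pending_start)) regions$start_sample[i] else pending_start
      pending_start <- NULL
      kind <- if (regions$label[i] == "silent") "pause" else "vocal"
      last <- length(ev)
      if (last > 0 && ev[[last]]$kind == kind) {
        ev[[last]]$end <- regions$end_sample[i]
      } else {
        ev[[last + 1]] <- list(kind = kind, start = start,
                               end = regions$end_sample[i])
      }
    } else {
      last <- length(ev)
      if (last > 0) ev[[last]]$end <- regions$end_sample[i]
      else if (is.null(pending_start)) pending_start <- regions$start_sample[i]
    }
  }
  if (length(ev) == 0) {
    # degenerate recording: nothing met a temporal threshold
    sil <- sum(dur_ms[regions$label == "silent"])
    nsil <- sum(dur_ms[regions$label == "nonsilent"])
    ev <- list(list(kind = if (sil >= nsil) "pause" else "vocal",
                    start = min(regions$start_sample),
                    end = max(regions$end_sample)))
  }

  start_s <- vapply(ev, function(e) (e$start - 1) / sample_rate, 0)
  end_s <- vapply(ev, function(e) (e$end - 1) / sample_rate, 0)
  out <- data.frame(kind = vapply(ev, `[[`, "", "kind"),
                    subtype = "none",
                    start_s = start_s, end_s = end_s,
                    duration_ms = (end_s - start_s) * 1000)
  if (is.null(signal_duration_s))
    signal_duration_s <- (max(regions$end_sample) - 1) / sample_rate
  structure(out, class = c("event_sequence", "data.frame"),
            signal_duration_s = signal_duration_s, config = config)
}

#' Split pause events into short and long subtypes
#'
#' Pauses with durations between `pause_min_ms` and
#' `short_long_boundary_ms` (both inclusive) are short; strictly longer
#' pauses are long. Vocal events are untouched.
#'
#' @param events An `event_sequence`.
#' @param config A [detection_config()].
#' @return The `event_sequence` with pause subtypes assigned.
#' @export
split_pauses <- function(events, config = detection_config()) {
  stopifnot(inherits(events, "event_sequence"))
  eps <- 1e-6
  is_pause <- events$kind == "pause"
  if (any(is_pause & events$duration_ms < config$pause_min_ms - eps))
    stopf("invariant violation: pause event shorter than pause_min_ms present")
  events$subtype[is_pause] <-
    ifelse(events$duration_ms[is_pause] <= config$short_long_boundary_ms + eps,
           "short", "long")
  events
}

#' Detect pause and vocal events in a preprocessed signal
#'
#' The full detector: blind segmentation, short-time RMSE/ZCR, per-segment
#' dual-threshold labeling, run-length region extraction with same-label
#' merging across segment boundaries, temporal-threshold event
#' classification, and the short/long pause split. Deterministic for fixed
#' input and configuration. The signal is expected to be denoised, trimmed
#' and peak-normalized, so that silence carries (near-)zero amplitude.
#'
#' @param signal A preprocessed [audio_signal()].
#' @param config A [detection_config()].
#' @return An `event_sequence` (see [classify_events()]).
#' @export
detect_events <- function(signal, config = detection_config()) {
  stopifnot(inherits(signal, "audio_signal"))
  segs <- segment_signal(signal, config)
  # Frames are computed over the whole signal so that windows straddle
  # segment boundaries (events must continue across the blind 3-s cuts);
  # each frame is thresholded against the mean RMSE of the segment holding
  # its window start.
  fr <- short_time_features(signal, config)
  seg_of <- findInterval(fr$start_sample, segs$start_sample)
  fr$segment_index <- seg_of
  lab <- character(length(seg_of))
  for (i in unique(seg_of)) {
    in_seg <- seg_of == i
    sub <- fr
    sub$rmse <- fr$rmse[in_seg]
    sub$zcr <- fr$zcr[in_seg]
    lab[in_seg] <- label_frames(sub, config$zcr_zero_tolerance)
  }
  regions <- frames_to_regions(lab, fr, span = c(1L, n_samples(signal) + 1L))
  ev <- classify_events(regions, config, signal$sample_rate,
                        signal_duration_s = duration_s(signal))
  split_pauses(ev, config)
}

#' @export
print.event_sequence <- function(x, ...) {
  cat(sprintf("<event_sequence> %d events (%d vocal, %d pause) over %.3f s\n",
              nrow(x), sum(x$kind == "vocal"), sum(x$kind == "pause"),
              attr(x, "signal_duration_s")))
  print.data.frame(head(as.data.frame(x), 10))
  if (nrow(x) > 10) cat(sprintf("... %d more events\n", nrow(x) - 10))
  invisible(x)
}

#' Write an event table to CSV
#'
#' Columns: `recording_id`, `kind`, `subtype`, `start_s`, `end_s`,
#' `duration_ms`, with times printed to millisecond precision or better.
#'
#' @param events An `event_sequence`.
#' @param path Output CSV path.
#' @param recording_id Identifier written on every row.
#' @return `path`, invisibly.
#' @export
write_events <- function(events, path, recording_id = "recording") {
  df <- data.frame(recording_id = recording_id, as.data.frame(events))
  df$start_s <- round(df$start_s, 6)
  df$end_s <- round(df$end_s, 6)
  df$duration_ms <- round(df$duration_ms, 3)
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read an event table written by [write_events()]
#'
#' @param path CSV path.
#' @param config Configuration attached to the result.
#' @return An `event_sequence`.
#' @export
read_events <- function(path, config = detection_config()) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("kind", "subtype", "start_s", "end_s", "duration_ms")
  if (!all(need %in% names(df)))
    stopf("event CSV is missing columns: %s",
          paste(setdiff(need, names(df)), collapse = ", "))
  structure(df[need], class = c("event_sequence", "data.frame"),
            signal_duration_s = max(df$end_s), config = config)
}
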