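# Audio container and preprocessing: load, denoise, trim, normalize.

#' Construct an audio signal
#'
#' The unit every preprocessing stage maps to itself: a mono amplitude
#' sequence plus its sampling rate. Sampling rates below 8 kHz are rejected
#' because the 50-ms analysis windows used downstream need at least a few
#' hundred samples to carry meaningful energy and zero-crossing statistics.
#'
#' @param samples Numeric vector of amplitudes (nominally in `[-1, 1]`).
#' @param sample_rate Sampling rate in Hz (integer, >= 8000).
#' @return An object of class `audio_signal` with elements `samples` and
#'   `sample_rate`.
#' @export
audio_signal <- function(samples, sample_rate) {
  if (!is.numeric(samples) || length(samples) < 1)
    stopf("empty audio: need at least one sample")
  if (anyNA(samples)) stopf("audio contains NA samples")
  sample_rate <- as.integer(round(sample_rate))
  if (length(sample_rate) != 1 || is.na(sample_rate) || sample_rate < 8000)
    stopf("unsupported sample rate %s Hz: rates below 8000 Hz are rejected",
          as.character(sample_rate))
  structure(list(samples = as.numeric(samples), sample_rate = sample_rate),
            class = "audio_signal")
}

#' Number of samples in a signal
#' @param signal An `audio_signal`.
#' @return Integer sample count.
#' @export
n_samples <- function(signal) length(signal$samples)

#' Duration of a signal in seconds
#' @param signal An `audio_signal`.
#' @return Duration in seconds (`n_samples / sample_rate`).
#' @export
duration_s <- function(signal) length(signal$samples) / signal$sample_rate

#' @export
print.audio_signal <- function(x, ...) {
  cat(sprintf("<audio_signal> %d samples @ %d Hz (%.3f s), peak %.4f\n",
              n_samples(x), x$sample_rate, duration_s(x),
              max(abs(x$samples))))
  invisible(x)
}

#' Load an audio recording
#'
#' Reads a PCM or IEEE-float WAV file, averages multi-channel input down to
#' mono, and scales samples to `[-1, 1]`.
#'
#' @param path Path to a WAV file.
#' @return An [audio_signal()].
#' @export
load_audio <- function(path) {
  wav <- read_wav(path)
  if (nrow(wav$samples) == 0) stopf("empty audio file: %s", path)
  mono <- rowMeans(wav$samples)
  audio_signal(mono, wav$sample_rate)
}

#' Write a signal to disk as 16-bit PCM WAV
#'
#' @param signal An [audio_signal()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_audio <- function(signal, path) {
  stopifnot(inherits(signal, "audio_signal"))
  write_wav(signal$samples, signal$sample_rate, path)
}

#' Trim a signal to a time interval
#'
#' Returns the sub-signal on `[start_s, end_s)`; used to clip extraneous
#' audio before the first and after the last word of the read passage.
#'
#' @param signal An [audio_signal()].
#' @param start_s,end_s Interval bounds in seconds,
#'   `0 <= start_s < end_s <= duration_s(signal)`.
#' @return The trimmed [audio_signal()].
#' @export
trim_audio <- function(signal, start_s, end_s) {
  stopifnot(inherits(signal, "audio_signal"))
  dur <- duration_s(signal)
  if (!is.numeric(start_s) || !is.numeric(end_s) ||
      start_s < 0 || end_s > dur + 1e-9 || start_s >= end_s)
    stopf("invalid trim bounds [%s, %s) for a %.3f-s signal",
          as.character(start_s), as.character(end_s), dur)
  sr <- signal$sample_rate
  i0 <- as.integer(floor(start_s * sr)) + 1L
  i1 <- min(as.integer(floor(end_s * sr + 1e-9)), n_samples(signal))
  audio_signal(signal$samples[i0:i1], sr)
}

#' Peak-normalize a signal
#'
#' Divides every sample by the maximum absolute amplitude so the peak is 1.
#' Shape is preserved exactly (the output is a positive scalar multiple of
#' the input); an identically-zero signal is a degenerate input and raises
#' an error.
#'
#' @param signal An [audio_signal()].
#' @return The normalized [audio_signal()].
#' @export
normalize_amplitude <- function(signal) {
  stopifnot(inherits(signal, "audio_signal"))
  peak <- max(abs(signal$samples))
  if (peak == 0) stopf("degenerate input: signal is identically zero")
  audio_signal(signal$samples / peak, signal$sample_rate)
}

# ---- spectral noise gating -------------------------------------------------

hann_window <- function(n) 0.5 - 0.5 * cos(2 * pi * (0:(n - 1)) / n)

# Short-time Fourier transform: columns are frames.
stft <- function(x, nfft, hop, win) {
  starts <- seq(1, length(x) - nfft + 1, by = hop)
  frames <- vapply(starts, function(s) x[s:(s + nfft - 1)] * win,
                   numeric(nfft))
  list(S = stats::mvfft(frames), starts = starts)
}

istft <- function(S, starts, nfft, win, n_out) {
  frames <- Re(stats::mvfft(S, inverse = TRUE)) / nfft
  y <- numeric(n_out)
  wsum <- numeric(n_out)
  for (j in seq_along(starts)) {
    idx <- starts[j]:(starts[j] + nfft - 1)
    keep <- idx <= n_out
    y[idx[keep]] <- y[idx[keep]] + frames[keep, j] * win[keep]
    wsum[idx[keep]] <- wsum[idx[keep]] + win[keep]^2
  }
  # avoid amplifying edge samples where the window overlap is negligible
  good <- wsum > 1e-2
  y[good] <- y[good] / wsum[good]
  y[!good] <- 0
  y
}

#' Locate the quietest stretch of a signal
#'
#' Finds the lowest-energy window of the given duration. Useful for
#' extracting a noise-only excerpt to pass to [reduce_noise()] as an
#' explicit profile (the automatic path inside [reduce_noise()] instead
#' pools the lowest-energy tenth of the short-time spectra, which stays
#' valid when no contiguous noise-only stretch of this length exists).
#'
#' @param signal An [audio_signal()].
#' @param duration_ms Window length in milliseconds (default 500).
#' @return Integer vector `c(start_sample, end_sample)` (1-based, inclusive).
#' @export
find_noise_period <- function(signal, duration_ms = 500) {
  n <- n_samples(signal)
  w <- min(ms_to_samples(duration_ms, signal$sample_rate), n)
  hop <- max(1L, w %/% 10L)
  cs <- cumsum(c(0, signal$samples^2))
  starts <- seq(1L, n - w + 1L, by = hop)
  energy <- cs[starts + w] - cs[starts]
  s <- starts[which.min(energy)]
  c(s, s + w - 1L)
}

#' Attenuate stationary ambient noise by spectral gating
#'
#' Estimates a per-frequency noise magnitude profile (from an explicit
#' noise-only recording, or from the automatically detected quietest 500-ms
#' stretch of the signal) and subtracts a gated version of it from the
#' short-time magnitude spectrum. A small absolute gate floor then flushes
#' residual amplitudes to exact zero, so that gated silence has a
#' zero-crossing rate of exactly zero -- the premise the event detector's
#' silence criterion relies on.
#'
#' @param signal An [audio_signal()].
#' @param strength Proportion of the full gate depth to apply, in `(0, 1]`.
#' @param noise_profile Optional [audio_signal()] containing noise only; must
#'   share the sample rate of `signal`.
#' @param nfft FFT size in samples; default is the power of two nearest a
#'   64-ms window.
#' @param gate_sd Number of noise-magnitude standard deviations added to the
#'   per-bin noise mean to form the gate threshold (default 2).
#' @param floor Absolute amplitude below which output samples are set to
#'   exactly zero (default `1e-4`, about the 16-bit quantization scale).
#' @return A denoised [audio_signal()] of identical length and rate.
#' @export
reduce_noise <- function(signal, strength = 1, noise_profile = NULL,
                         nfft = NULL, gate_sd = 2, floor = 1e-4) {
  stopifnot(inherits(signal, "audio_signal"))
  if (!is.numeric(strength) || strength <= 0 || strength > 1)
    stopf("strength must lie in (0, 1]")
  sr <- signal$sample_rate
  if (is.null(nfft)) nfft <- 2^round(log2(0.064 * sr))
  hop <- nfft %/% 4L
  n <- n_samples(signal)
  if (n < nfft)
    stopf("signal too short for noise gating: %d samples < one %d-sample analysis window",
          n, nfft)
  win <- hann_window(nfft)

  dec <- stft(signal$samples, nfft, hop, win)
  if (is.null(noise_profile)) {
    # noise-only frames detected automatically: the lowest-energy tenth of
    # the short-time spectra (robust to recordings with little silence)
    frame_energy <- colSums(Mod(dec$S)^2)
    noise_mag <- Mod(dec$S[, frame_energy <=
                             quantile(frame_energy, 0.1), drop = FALSE])
  } else {
    stopifnot(inherits(noise_profile, "audio_signal"))
    if (noise_profile$sample_rate != sr)
      stopf("noise profile sample rate (%d) differs from signal (%d)",
            noise_profile$sample_rate, sr)
    noise_x <- noise_profile$samples
    if (length(noise_x) < nfft) noise_x <- rep_len(noise_x, nfft)
    noise_mag <- Mod(stft(noise_x, nfft, hop, win)$S)
  }
  mu <- apply(noise_mag, 1, mean)
  sdv <- apply(noise_mag, 1, sd)
  sdv[is.na(sdv)] <- 0
  gate <- mu + gate_sd * sdv

  mag <- Mod(dec$S)
  new_mag <- pmax(mag - strength * gate, 0)
  scale <- ifelse(mag > 0, new_mag / mag, 0)
  y <- istft(dec$S * scale, dec$starts, nfft, win, n)

  # Downward-expander stage: stretches of the ORIGINAL signal whose local
  # (5-ms) RMS stays at the ambient level hold no speech, so their
  # subtraction residue is flushed to exact zero. This is what makes the
  # "gated silence has ZCR = 0" premise hold exactly.
  env <- local_rms(signal$samples, ms_to_samples(5, sr))
  noise_level <- if (is.null(noise_profile))
    stats::median(env[env <= quantile(env, 0.1)])
  else stats::median(local_rms(noise_x, ms_to_samples(5, sr)))
  # only expand when a noise floor clearly below the signal level exists;
  # otherwise (e.g. uninterrupted voicing) the stage must not engage
  if (noise_level < 0.25 * quantile(env, 0.95))
    y[env < pmax(2 * noise_level, 1e-6)] <- 0

  y[abs(y) < floor] <- 0
  audio_signal(y, sr)
}

# Centered local RMS over a w-sample window (edges use the available span).
local_rms <- function(x, w) {
  n <- length(x)
  h <- w %/% 2
  cs <- cumsum(c(0, x^2))
  lo <- pmax(seq_len(n) - h, 1L)
  hi <- pmin(seq_len(n) + h, n)
  sqrt((cs[hi + 1] - cs[lo]) / (hi - lo + 1))
}
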