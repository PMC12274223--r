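# Synthetic fixtures: (a) audio utterances built from alternating voiced
# bursts and silences with ground-truth event annotations, and (b) cohort
# metric tables with specified group structure, so detection, metrics,
# statistics and classifiers are testable without recordings.

#' Specify a synthetic utterance
#'
#' An ordered list of voiced and silent intervals plus the voiced model
#' (a pure tone by default, so the zero-crossing rate is analytically
#' predictable, or a white-noise burst for robustness checks) and an
#' ambient noise level. The detectability guarantee -- voiced amplitude
#' strictly greater than four times the ambient amplitude -- is enforced
#' here because the event-recovery properties are only claimed under it.
#'
#' @param intervals Data frame with columns `kind` (`"voiced"`/`"silent"`)
#'   and `duration_ms` (positive).
#' @param voiced_hz Tone frequency in Hz (default 440).
#' @param voiced_amplitude Peak amplitude of voiced intervals, in `(0, 1]`.
#' @param voiced_model `"tone"` or `"noise_burst"`.
#' @param ambient_amplitude Uniform ambient noise amplitude, in `[0, 0.5]`.
#' @param sample_rate Sampling rate in Hz (default 16000).
#' @param seed Integer seed making the waveform reproducible.
#' @return An `utterance_spec` list.
#' @export
utterance_spec <- function(intervals, voiced_hz = 440, voiced_amplitude = 0.8,
                           voiced_model = c("tone", "noise_burst"),
                           ambient_amplitude = 0, sample_rate = 16000,
                           seed = 1) {
  voiced_model <- match.arg(voiced_model)
  stopifnot(is.data.frame(intervals),
            all(c("kind", "duration_ms") %in% names(intervals)))
  if (!all(intervals$kind %in% c("voiced", "silent")))
    stopf("interval kinds must be voiced or silent")
  if (any(intervals$duration_ms <= 0)) stopf("interval durations must be positive")
  if (voiced_amplitude <= 0 || voiced_amplitude > 1)
    stopf("voiced amplitude must lie in (0, 1]")
  if (ambient_amplitude < 0 || ambient_amplitude > 0.5)
    stopf("ambient amplitude must lie in [0, 0.5]")
  if (voiced_amplitude <= 4 * ambient_amplitude)
    stopf("detectability requires voiced amplitude > 4 x ambient amplitude")
  structure(list(intervals = intervals, voiced_hz = voiced_hz,
                 voiced_amplitude = voiced_amplitude,
                 voiced_model = voiced_model,
                 ambient_amplitude = ambient_amplitude,
                 sample_rate = as.integer(sample_rate), seed = as.integer(seed)),
            class = "utterance_spec")
}

raised_cosine_ramp <- function(n) 0.5 - 0.5 * cos(pi * (seq_len(n) - 0.5) / n)

#' Synthesize an utterance with ground-truth events
#'
#' Concatenates the specified voiced and silent intervals (5-ms
#' raised-cosine onset/offset ramps inside each voiced interval prevent
#' click artifacts that would inflate the zero-crossing rate at
#' boundaries), adds uniform ambient noise, and records the ground truth:
#' each interval with its exact boundaries and the pause subtype its
#' duration implies under `config`. Bit-identical for a fixed spec.
#'
#' @param spec An [utterance_spec()].
#' @param config [detection_config()] used to assign ground-truth subtypes.
#' @return List `signal` (an [audio_signal()]) and `truth` (an
#'   `event_sequence` of ground-truth events; adjacent same-kind intervals
#'   are merged).
#' @export
make_synthetic_utterance <- function(spec, config = detection_config()) {
  stopifnot(inherits(spec, "utterance_spec"))
  sr <- spec$sample_rate
  lens <- vapply(spec$intervals$duration_ms, ms_to_samples, 0L, sample_rate = sr)
  n <- sum(lens)
  ramp_n <- min(ms_to_samples(5, sr), min(lens[spec$intervals$kind == "voiced"]) %/% 2)

  x <- with_local_seed(spec$seed, {
    pieces <- vector("list", nrow(spec$intervals))
    t0 <- 0L
    for (i in seq_len(nrow(spec$intervals))) {
      m <- lens[i]
      if (spec$intervals$kind[i] == "silent") {
        pieces[[i]] <- numeric(m)
      } else {
        burst <- if (spec$voiced_model == "tone") {
          # Phase is anchored per burst with the first sine zero a quarter
          # half-period inside it, so zero crossings reach both burst edges
          # and detected boundaries are not blurred by a crossing-free tail.
          z0 <- round(sr / (4 * spec$voiced_hz)) + 0.5
          spec$voiced_amplitude *
            sin(2 * pi * spec$voiced_hz * (seq_len(m) - z0) / sr)
        } else spec$voiced_amplitude * runif(m, -1, 1)
        env <- rep(1, m)
        env[seq_len(ramp_n)] <- raised_cosine_ramp(ramp_n)
        env[m - ramp_n + seq_len(ramp_n)] <- rev(raised_cosine_ramp(ramp_n))
        pieces[[i]] <- burst * env
      }
      t0 <- t0 + m
    }
    x <- unlist(pieces)
    if (spec$ambient_amplitude > 0)
      x <- x + runif(n, -spec$ambient_amplitude, spec$ambient_amplitude)
    x
  })

  ends <- cumsum(lens)
  starts <- c(0L, head(ends, -1))
  truth <- data.frame(kind = ifelse(spec$intervals$kind == "voiced",
                                    "vocal", "pause"),
                      subtype = "none",
                      start_s = starts / sr, end_s = ends / sr)
  # merge adjacent same-kind intervals
  grp <- cumsum(c(TRUE, truth$kind[-1] != truth$kind[-nrow(truth)]))
  truth <- data.frame(kind = tapply(truth$kind, grp, `[`, 1),
                      subtype = "none",
                      start_s = as.numeric(tapply(truth$start_s, grp, min)),
                      end_s = as.numeric(tapply(truth$end_s, grp, max)),
                      row.names = NULL)
  truth$duration_ms <- (truth$end_s - truth$start_s) * 1000
  truth <- structure(truth, class = c("event_sequence", "data.frame"),
                     signal_duration_s = n / sr, config = config)
  truth <- split_pauses(truth, config)
  list(signal = audio_signal(x, sr), truth = truth)
}

#' Specify a synthetic cohort
#'
#' Group sizes, per-metric generating moments, count dispersions, sex
#' ratios and age moments default to the descriptive statistics of the
#' study cohort (17 AWS, 18 AWNS reading a 236-word passage): e.g. speech
#' rate 163.12 +/- 23.43 wpm in AWNS versus 127.60 +/- 38.11 in AWS, and
#' long/short pause count dispersions of 0.18 and 0.13.
#'
#' @param n_awns,n_aws Group sizes (each at least 2).
#' @param moments Data frame with columns `metric`, `awns_mean`, `awns_sd`,
#'   `aws_mean`, `aws_sd` for the ten continuous metrics and the mean
#'   columns for counts; defaults to [default_cohort_moments()].
#' @param count_alpha Named dispersions (NB2 `alpha`) for the count
#'   metrics.
#' @param male_frac Named fractions of male participants per group.
#' @param age Named list per group: `mean`, `sd`, `min`, `max`.
#' @param ss_slope,ss_intercept,ss_sd Linear model generating `%SS` for AWS
#'   rows from long pause count, with Gaussian noise, clipped to
#'   `[0.1, 40]`.
#' @param seed Integer seed.
#' @return A `cohort_spec` list.
#' @export
cohort_spec <- function(n_awns = 18, n_aws = 17,
                        moments = default_cohort_moments(),
                        count_alpha = c(long_pause_count = 0.18,
                                        short_pause_count = 0.13),
                        male_frac = c(AWNS = 10 / 18, AWS = 12 / 17),
                        age = list(AWNS = list(mean = 31.78, sd = 9.95,
                                               min = 22, max = 63),
                                   AWS = list(mean = 39.59, sd = 14.45,
                                              min = 24, max = 62)),
                        ss_slope = 0.08, ss_intercept = 1, ss_sd = 1.5,
                        seed = 1) {
  if (n_awns < 2 || n_aws < 2) stopf("need at least 2 participants per group")
  if (any(c(moments$awns_sd, moments$aws_sd) <= 0, na.rm = TRUE))
    stopf("generating SDs must be positive")
  structure(list(n_awns = n_awns, n_aws = n_aws, moments = moments,
                 count_alpha = count_alpha, male_frac = male_frac, age = age,
                 ss_slope = ss_slope, ss_intercept = ss_intercept,
                 ss_sd = ss_sd, seed = as.integer(seed)),
            class = "cohort_spec")
}

#' Default generating moments for the synthetic cohort
#'
#' Mean and SD per metric and group (the study's descriptive statistics),
#' plus the physical lower/upper truncation bounds each metric must
#' respect (rates and CVs positive, subtype means inside their duration
#' thresholds).
#'
#' @return Data frame `metric`, `awns_mean`, `awns_sd`, `aws_mean`,
#'   `aws_sd`, `lower`, `upper`, `is_count`.
#' @export
default_cohort_moments <- function() {
  data.frame(
    metric = c("speech_rate_wpm", "total_pause_time_s", "pause_count",
               "mean_pause_ms", "mean_vocal_ms", "pause_cv", "vocal_cv",
               "mean_long_pause_ms", "mean_short_pause_ms", "long_pause_cv",
               "short_pause_cv", "long_pause_count", "short_pause_count"),
    awns_mean = c(163.12, 16.48, 58.00, 286.51, 1258.14, 0.89, 0.74,
                  450.99, 86.01, 0.53, 0.33, 31.11, 26.89),
    awns_sd = c(23.43, 4.68, 12.97, 62.15, 226.64, 0.11, 0.07,
                75.42, 5.36, 0.08, 0.03, 7.23, 8.74),
    aws_mean = c(127.60, 30.68, 86.47, 338.14, 1250.82, 0.90, 0.82,
                 484.02, 90.41, 0.61, 0.31, 55.12, 31.35),
    aws_sd = c(38.11, 22.40, 56.37, 84.40, 358.11, 0.16, 0.10,
               108.23, 6.57, 0.18, 0.04, 38.54, 18.35),
    lower = c(1, 0.01, 0, 50, 100, 0.01, 0.01, 150, 50, 0.01, 0.01, 0, 0),
    upper = c(Inf, Inf, Inf, Inf, Inf, Inf, Inf, Inf, 150, Inf, Inf, Inf, Inf),
    is_count = c(FALSE, FALSE, TRUE, FALSE, FALSE, FALSE, FALSE, FALSE,
                 FALSE, FALSE, FALSE, TRUE, TRUE)
  )
}

# Truncated-normal draws by rejection; errors if the window is infeasible.
rtruncnorm <- function(n, mean, sd, lower, upper) {
  p_in <- pnorm(upper, mean, sd) - pnorm(lower, mean, sd)
  if (p_in < 1e-6)
    stopf("infeasible truncation: N(%.3g, %.3g) on [%.3g, %.3g]",
          mean, sd, lower, upper)
  out <- numeric(0)
  while (length(out) < n) {
    draw <- rnorm(2 * n, mean, sd)
    out <- c(out, draw[draw > lower & draw < upper])
  }
  out[seq_len(n)]
}

#' Generate a synthetic cohort table
#'
#' Continuous metrics are drawn from truncated normals at the specified
#' group moments; long and short pause counts from negative binomials with
#' the specified means and dispersions, with the subtype-count identity
#' `pause_count = long + short` enforced by construction; `%SS` for AWS
#' rows follows the configured linear model in long pause count.
#' Deterministic for a fixed spec.
#'
#' In `"mechanistic"` mode each participant's metrics are instead computed
#' from a generated event sequence (log-normal vocal/long-pause durations,
#' truncated-normal short-pause durations, alternating vocal/pause order),
#' so within-participant metric correlations arise mechanically; the event
#' sequences are attached as `attr(result, "event_sequences")` for the
#' sequence classifier.
#'
#' @param spec A [cohort_spec()].
#' @param mode `"table"` (moment sampling; the default) or `"mechanistic"`.
#' @param word_count Passage word count used in mechanistic mode.
#' @return A `cohort_table` with `participant_id`, `group`, `sex`, `age`,
#'   `percent_ss` and the 13 metric columns.
#' @export
make_synthetic_cohort <- function(spec, mode = c("table", "mechanistic"),
                                  word_count = 236) {
  stopifnot(inherits(spec, "cohort_spec"))
  mode <- match.arg(mode)
  with_local_seed(spec$seed, {
    n <- c(AWNS = spec$n_awns, AWS = spec$n_aws)
    groups <- rep(names(n), n)
    ids <- sprintf("P%03d", seq_along(groups))
    sex <- unlist(lapply(names(n), function(g) {
      nm <- round(n[[g]] * spec$male_frac[[g]])
      sample(c(rep("male", nm), rep("female", n[[g]] - nm)))
    }))
    ages <- unlist(lapply(names(n), function(g) {
      a <- spec$age[[g]]
      round(rtruncnorm(n[[g]], a$mean, a$sd, a$min, a$max), 1)
    }))
    cov <- data.frame(participant_id = ids, group = groups, sex = sex,
                      age = ages, percent_ss = NA_real_)

    if (mode == "table") {
      mom <- spec$moments
      met <- as.data.frame(matrix(NA_real_, length(ids), nrow(mom),
                                  dimnames = list(NULL, mom$metric)))
      for (g in names(n)) {
        rows <- which(groups == g)
        mu_col <- if (g == "AWNS") "awns_mean" else "aws_mean"
        sd_col <- if (g == "AWNS") "awns_sd" else "aws_sd"
        for (j in seq_len(nrow(mom))) {
          nm <- mom$metric[j]
          if (nm == "pause_count") next  # enforced as long + short below
          if (mom$is_count[j]) {
            alpha <- spec$count_alpha[[nm]]
            met[rows, nm] <- rnbinom(length(rows), size = 1 / alpha,
                                     mu = mom[[mu_col]][j])
          } else {
            met[rows, nm] <- rtruncnorm(length(rows), mom[[mu_col]][j],
                                        mom[[sd_col]][j], mom$lower[j],
                                        mom$upper[j])
          }
        }
      }
      met$pause_count <- met$long_pause_count + met$short_pause_count
      out <- cbind(cov, met)
      ev_seqs <- NULL
    } else {
      mom <- spec$moments
      get_m <- function(nm, g, what) {
        j <- match(nm, mom$metric)
        mom[[paste0(if (g == "AWNS") "awns_" else "aws_", what)]][j]
      }
      ev_seqs <- list()
      met_rows <- list()
      for (i in seq_along(ids)) {
        g <- groups[i]
        alpha_l <- spec$count_alpha[["long_pause_count"]]
        alpha_s <- spec$count_alpha[["short_pause_count"]]
        n_long <- max(2L, rnbinom(1, size = 1 / alpha_l,
                                  mu = get_m("long_pause_count", g, "mean")))
        n_short <- max(2L, rnbinom(1, size = 1 / alpha_s,
                                   mu = get_m("short_pause_count", g, "mean")))
        long_d <- rlnorm_mc(n_long, get_m("mean_long_pause_ms", g, "mean"),
                            get_m("long_pause_cv", g, "mean"), lower = 151)
        short_d <- rtruncnorm(n_short, get_m("mean_short_pause_ms", g, "mean"),
                              get_m("short_pause_cv", g, "mean") *
                                get_m("mean_short_pause_ms", g, "mean"),
                              50, 150)
        pauses <- sample(c(long_d, short_d))
        n_voc <- length(pauses) + 1
        vocals <- rlnorm_mc(n_voc, get_m("mean_vocal_ms", g, "mean"),
                            get_m("vocal_cv", g, "mean"), lower = 101)
        durs <- as.numeric(rbind(vocals, c(pauses, NA)))
        durs <- durs[!is.na(durs)]
        kinds <- rep(c("vocal", "pause"), length.out = length(durs))
        ends <- cumsum(durs) / 1000
        starts <- c(0, head(ends, -1))
        ev <- structure(
          data.frame(kind = kinds, subtype = "none", start_s = starts,
                     end_s = ends, duration_ms = durs),
          class = c("event_sequence", "data.frame"),
          signal_duration_s = max(ends), config = detection_config())
        ev <- split_pauses(ev, detection_config())
        ev_seqs[[ids[i]]] <- ev
        met_rows[[i]] <- as.data.frame(unclass(
          compute_metrics(ev, word_count = word_count)))
      }
      out <- cbind(cov, do.call(rbind, met_rows))
    }

    aws_rows <- out$group == "AWS"
    out$percent_ss[aws_rows] <- pmin(40, pmax(0.1,
      spec$ss_intercept + spec$ss_slope * out$long_pause_count[aws_rows] +
        rnorm(sum(aws_rows), 0, spec$ss_sd)))
    class(out) <- c("cohort_table", "data.frame")
    if (!is.null(ev_seqs)) attr(out, "event_sequences") <- ev_seqs
    out
  })
}

# Log-normal draws matched to an arithmetic mean and CV, with a lower bound
# applied by rejection.
rlnorm_mc <- function(n, mean, cv, lower = 0) {
  s2 <- log(1 + cv^2)
  mu <- log(mean) - s2 / 2
  out <- numeric(0)
  while (length(out) < n) {
    d <- stats::rlnorm(2 * n + 10, mu, sqrt(s2))
    out <- c(out, d[d > lower])
  }
  out[seq_len(n)]
}
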