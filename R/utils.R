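# Internal helpers shared across modules.

#' Evaluate an expression under a fixed RNG seed, restoring the caller's state
#' @noRd
with_local_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  eval.parent(substitute(expr))
}

#' @noRd
stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

#' @noRd
is_count_vector <- function(x) {
  x <- x[!is.na(x)]
  length(x) > 0 && all(x >= 0) && all(abs(x - round(x)) < 1e-8)
}

# Milliseconds to (whole) samples at a given rate.
#' @noRd
ms_to_samples <- function(ms, sample_rate) as.integer(round(ms / 1000 * sample_rate))

#' @noRd
rms <- function(x) sqrt(mean(x^2))
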