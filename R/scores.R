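#' Convert an ML probability byte to a probability
#'
#' SAM ML tags encode per-call modification probabilities as bytes 0-255, where
#' byte `b` stands for the probability interval `[b/256, (b+1)/256)`. The
#' decoded value is the midpoint of that interval.
#'
#' @param b Integer vector of ML bytes (0-255).
#' @return Numeric vector of probabilities in (0, 1). Out-of-range bytes yield
#'   `NA` with a warning.
#' @examples
#' ml_byte_to_probability(c(0L, 128L, 255L))
#' @export
ml_byte_to_probability <- function(b) {
  b <- as.numeric(b)
  bad <- is.na(b) | b < 0 | b > 255 | b != floor(b)
  if (any(bad)) {
    warning(sum(bad), " ML byte(s) outside 0-255 rejected")
    b[bad] <- NA_real_
  }
  (b + 0.5) / 256
}

#' Convert a modification probability to a log likelihood ratio
#'
#' All importers normalize scores to the natural-log probability ratio
#' `ln(P(modified) / P(unmodified)) = ln(p / (1 - p))`. Probabilities are
#' clamped to `[eps, 1 - eps]` first so scores stay finite.
#'
#' @param p Numeric vector of probabilities.
#' @param eps Clamping bound, default `1e-6`.
#' @return Numeric vector of log likelihood ratios (LLR).
#' @seealso [llr_to_probability()] for the inverse.
#' @examples
#' probability_to_llr(c(0.5, 0.9))
#' @export
probability_to_llr <- function(p, eps = 1e-6) {
  if (any(!is.na(p) & (p < 0 | p > 1))) {
    stop("probabilities must lie in [0, 1]")
  }
  stats::qlogis(pmin(pmax(p, eps), 1 - eps))
}

#' Convert a log likelihood ratio back to a probability
#'
#' @param llr Numeric vector of log likelihood ratios.
#' @return Numeric vector of probabilities (the logistic transform of `llr`).
#' @export
llr_to_probability <- function(llr) stats::plogis(llr)

#' Two-sided score cutoffs for call classification
#'
#' Scores at or below `lo` are called unmodified, scores at or above `hi`
#' modified, and the band in between is ambiguous and excluded from
#' methylation fractions.
#'
#' @param lo Lower cutoff (UNMOD at `score <= lo`).
#' @param hi Upper cutoff (MOD at `score >= hi`); must exceed `lo`.
#' @return A `cutoff_config` object.
#' @examples
#' cutoff_config(-2, 2)
#' @export
cutoff_config <- function(lo = -2, hi = 2) {
  lo <- as.numeric(lo); hi <- as.numeric(hi)
  if (length(lo) != 1L || length(hi) != 1L || is.na(lo) || is.na(hi)) {
    stop("cutoffs must be single finite numbers")
  }
  if (lo >= hi) stop("invalid cutoffs: lo (", lo, ") must be < hi (", hi, ")")
  structure(list(lo = lo, hi = hi), class = "cutoff_config")
}

#' @export
print.cutoff_config <- function(x, ...) {
  cat(sprintf("cutoffs: UNMOD <= %g < AMBIG < %g <= MOD\n", x$lo, x$hi))
  invisible(x)
}

#' Classify scores against cutoffs
#'
#' Partition of the score axis: `score >= hi` is `"MOD"`, `score <= lo` is
#' `"UNMOD"`, anything strictly between is `"AMBIG"`.
#'
#' @param score Numeric vector of LLR scores.
#' @param cutoffs A [cutoff_config()].
#' @return Character vector in `{"MOD", "UNMOD", "AMBIG"}` (`NA` score gives
#'   `NA`).
#' @examples
#' classify_calls(c(-3, 0, 3), cutoff_config(-2, 2))
#' @export
classify_calls <- function(score, cutoffs = cutoff_config()) {
  stopifnot(inherits(cutoffs, "cutoff_config"))
  out <- rep(NA_character_, length(score))
  out[!is.na(score) & score >= cutoffs$hi] <- "MOD"
  out[!is.na(score) & score <= cutoffs$lo] <- "UNMOD"
  out[!is.na(score) & score > cutoffs$lo & score < cutoffs$hi] <- "AMBIG"
  out
}
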