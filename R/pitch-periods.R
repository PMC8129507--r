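# Ordered pitch-period container shared by the generator and the extractor.

#' Construct a pitch-period sequence
#'
#' Ordered durations of successive glottal cycles (the periods T_i, in
#' milliseconds) with one peak amplitude A_k per cycle and the onset time
#' of each cycle. Periods coming from different voiced stretches of the
#' same utterance carry a `segment` id so that perturbation statistics
#' never difference across a voicing gap.
#'
#' @param periods_ms positive cycle durations in ms.
#' @param amplitudes positive per-cycle peak amplitudes (dimensionless).
#' @param onset_s strictly increasing cycle onset times in seconds.
#' @param segment integer voiced-segment id per cycle (non-decreasing).
#' @return an object of class `pitch_periods`.
#' @export
pitch_periods <- function(periods_ms, amplitudes, onset_s = NULL,
                          segment = NULL) {
  periods_ms <- as.numeric(periods_ms)
  amplitudes <- as.numeric(amplitudes)
  n <- length(periods_ms)
  if (length(amplitudes) != n) {
    stop("periods and amplitudes must have equal length", call. = FALSE)
  }
  if (any(periods_ms <= 0) || any(amplitudes <= 0)) {
    stop("periods and amplitudes must be strictly positive", call. = FALSE)
  }
  if (is.null(onset_s)) onset_s <- cumsum(c(0, periods_ms[-n])) / 1000
  if (is.unsorted(onset_s, strictly = TRUE)) {
    stop("onset times must be strictly increasing", call. = FALSE)
  }
  if (is.null(segment)) segment <- rep(1L, n)
  structure(list(periods_ms = periods_ms, amplitudes = amplitudes,
                 onset_s = as.numeric(onset_s),
                 segment = as.integer(segment)),
            class = "pitch_periods")
}

#' @export
print.pitch_periods <- function(x, ...) {
  cat(sprintf(
    "<pitch_periods: %d cycles in %d segment(s), mean period %.3f ms (%.1f Hz)>\n",
    length(x$periods_ms), length(unique(x$segment)),
    mean(x$periods_ms), mean(1000 / x$periods_ms)))
  invisible(x)
}

#' @export
length.pitch_periods <- function(x) length(x$periods_ms)
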