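# shared constants
INTENSITY_REF <- 2e-5  # pressure-equivalent dB reference shared by generator and extractor

#' Round half away from zero
#'
#' Rounds to `digits` decimals with halves going away from zero, the
#' convention used when reporting feature and table values (e.g. 0.275
#' becomes 0.28). Base [round()] rounds half to even instead.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return rounded numeric vector.
#' @export
#' @examples
#' round_half_up(0.275, 2)  # 0.28
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

# Evaluate code under a fixed seed, restoring the caller's RNG state after.
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# Deterministic derived seed: fold indices into a Lehmer-style stream so
# sub-tasks (words, subjects, utterances) get distinct reproducible seeds
# that stay below 2^31.
sub_seed <- function(seed, ...) {
  s <- (abs(as.double(seed)) %% 2147483647) + 1
  for (k in c(...)) {
    s <- (s * 48271 + abs(as.double(k)) + 1) %% 2147483647
  }
  as.integer(s)
}

# "(1)-(3), (5)" style rendering of a set of ordinal ids, compressing
# consecutive runs the way the study tables do.
format_id_ranges <- function(ids) {
  ids <- sort(unique(as.integer(ids)))
  if (length(ids) == 0L) return("")
  brk <- c(0L, which(diff(ids) != 1L), length(ids))
  parts <- vapply(seq_len(length(brk) - 1L), function(i) {
    run <- ids[(brk[i] + 1L):brk[i + 1L]]
    if (length(run) == 1L) sprintf("(%d)", run)
    else sprintf("(%d)-(%d)", run[1L], run[length(run)])
  }, character(1))
  paste(parts, collapse = ", ")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stars <- function(p) {
  ifelse(p < 0.001, "***", ifelse(p < 0.01, "**", ifelse(p < 0.05, "*", "")))
}
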