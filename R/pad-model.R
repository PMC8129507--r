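# The PAD (pleasure-arousal-dominance) emotion space and its octant naming.
#
# Eight basic emotional states occupy the 2^3 sign octants of the PAD cube;
# a ninth label, neutral, is the benchmark state and carries no octant.
# Ordinal ids 1..9 follow the recording-protocol listing order.

.pad_emotions <- c("neutral", "exuberant", "bored", "dependent", "disdainful",
                   "relaxed", "anxious", "docile", "hostile")

.octant_map <- data.frame(
  emotion   = c("exuberant", "bored", "dependent", "disdainful",
                "relaxed", "anxious", "docile", "hostile"),
  pleasure  = c(+1, -1, +1, -1, +1, -1, +1, -1),
  arousal   = c(+1, -1, +1, -1, -1, +1, -1, +1),
  dominance = c(+1, -1, -1, +1, +1, -1, -1, +1),
  stringsAsFactors = FALSE
)

#' The nine emotional states in ordinal order
#'
#' Returns the nine emotion labels of the study design: `neutral` (the
#' benchmark state, ordinal id 1) followed by the eight PAD-octant states,
#' ids 2 through 9, in the recording-protocol listing order.
#'
#' @return character vector of length 9.
#' @seealso [emotion_ordinal()], [octant_to_emotion()]
#' @export
#' @examples
#' pad_emotions()
pad_emotions <- function() .pad_emotions

#' Ordinal id of an emotion label
#'
#' @param emotion character vector of emotion labels (lowercase).
#' @return integer vector of ids in 1..9; errors on unknown labels.
#' @export
#' @examples
#' emotion_ordinal("bored")  # 3
emotion_ordinal <- function(emotion) {
  id <- match(tolower(as.character(emotion)), .pad_emotions)
  if (anyNA(id)) {
    stop("unknown emotion label(s): ",
         paste(unique(emotion[is.na(id)]), collapse = ", "), call. = FALSE)
  }
  id
}

#' Construct a PAD sign octant
#'
#' An octant is a triple of signs on the pleasure, arousal and dominance
#' axes; each of the eight octants names one basic emotional state.
#' Neutral is not an octant.
#'
#' @param pleasure,arousal,dominance each exactly `+1` or `-1`.
#' @return an object of class `pad_octant`.
#' @export
#' @examples
#' pad_octant(+1, +1, +1)  # exuberant
pad_octant <- function(pleasure, arousal, dominance) {
  v <- c(pleasure = pleasure, arousal = arousal, dominance = dominance)
  if (!all(v %in% c(-1, 1))) {
    stop("each PAD sign must be exactly +1 or -1", call. = FALSE)
  }
  structure(as.integer(v), names = names(v), class = "pad_octant")
}

#' @export
print.pad_octant <- function(x, ...) {
  sgn <- ifelse(x > 0, "+", "-")
  cat(sprintf("%sP%sA%sD (%s)\n", sgn[1], sgn[2], sgn[3], octant_to_emotion(x)))
  invisible(x)
}

#' Map a PAD octant to its emotional state
#'
#' @param octant a [pad_octant()] (or a length-3 vector of signs).
#' @return the emotion label, e.g. `"exuberant"` for `(+,+,+)`.
#' @export
#' @examples
#' octant_to_emotion(pad_octant(-1, -1, -1))  # "bored"
octant_to_emotion <- function(octant) {
  v <- as.integer(unclass(octant))
  if (length(v) != 3L || !all(v %in% c(-1L, 1L))) {
    stop("octant must be three signs in {+1, -1}", call. = FALSE)
  }
  hit <- .octant_map$pleasure == v[1] & .octant_map$arousal == v[2] &
    .octant_map$dominance == v[3]
  .octant_map$emotion[hit]
}

#' Map an emotional state to its PAD octant
#'
#' The inverse of [octant_to_emotion()] on the eight octant emotions.
#' `neutral` is the reference state outside the octant set and maps to
#' `NULL`.
#'
#' @param emotion a single emotion label.
#' @return a [pad_octant()], or `NULL` for `"neutral"`.
#' @export
#' @examples
#' emotion_to_octant("hostile")  # -P +A +D
#' emotion_to_octant("neutral")  # NULL
emotion_to_octant <- function(emotion) {
  emotion <- tolower(as.character(emotion))
  stopifnot(length(emotion) == 1L)
  emotion_ordinal(emotion)  # validates the label
  if (emotion == "neutral") return(NULL)
  row <- .octant_map[.octant_map$emotion == emotion, ]
  pad_octant(row$pleasure, row$arousal, row$dominance)
}

# factor with the canonical ordinal level order
emotion_factor <- function(x) factor(as.character(x), levels = .pad_emotions)
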