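# Waveform container and WAV / annotation file I/O.

#' Construct a voice recording
#'
#' The atomic audio object: a mono sampled waveform with its rate and an
#' opaque provenance label. Samples must be finite, lie in \[-1, 1\] and
#' cover at least 0.1 s.
#'
#' @param samples numeric vector of samples in \[-1, 1\].
#' @param sample_rate sampling frequency in Hz.
#' @param source_id opaque label recorded for provenance.
#' @return an object of class `voice_recording`.
#' @export
voice_recording <- function(samples, sample_rate, source_id = "unknown") {
  samples <- as.numeric(samples)
  if (!is.numeric(sample_rate) || length(sample_rate) != 1L || sample_rate <= 0) {
    stop("sample_rate must be a single positive number", call. = FALSE)
  }
  if (!all(is.finite(samples))) stop("samples must all be finite", call. = FALSE)
  if (any(abs(samples) > 1)) {
    stop("samples must lie within [-1, 1]", call. = FALSE)
  }
  if (length(samples) < 0.1 * sample_rate) {
    stop("recording must be at least 0.1 s long", call. = FALSE)
  }
  structure(list(samples = samples, sample_rate = sample_rate,
                 source_id = as.character(source_id)),
            class = "voice_recording")
}

#' @export
print.voice_recording <- function(x, ...) {
  cat(sprintf("<voice_recording '%s': %.3f s at %g Hz>\n",
              x$source_id, length(x$samples) / x$sample_rate, x$sample_rate))
  invisible(x)
}

#' Duration of a recording in seconds
#' @param rec a [voice_recording()].
#' @return duration in seconds.
#' @export
recording_duration <- function(rec) length(rec$samples) / rec$sample_rate

#' Read a mono WAV file
#'
#' Parses a RIFF/WAVE file containing 16-bit PCM (format tag 1) or
#' IEEE-float (format tag 3) samples. Only mono audio is accepted; stereo
#' input is rejected explicitly rather than silently mixed down. Integer
#' samples are normalized by 1/32768, so a full-scale 16-bit sample reads
#' as 32767/32768.
#'
#' @param path path to a `.wav` file.
#' @param source_id provenance label; defaults to the file name.
#' @return a [voice_recording()].
#' @export
read_wav <- function(path, source_id = basename(path)) {
  con <- file(path, "rb")
  on.exit(close(con))
  hdr <- readChar(con, 4, useBytes = TRUE)
  if (!identical(hdr, "RIFF")) stop("not a RIFF file: ", path, call. = FALSE)
  invisible(readBin(con, "integer", 1, size = 4, endian = "little"))
  if (!identical(readChar(con, 4, useBytes = TRUE), "WAVE")) {
    stop("not a WAVE file: ", path, call. = FALSE)
  }
  fmt <- NULL
  data_raw <- NULL
  repeat {
    id <- readChar(con, 4, useBytes = TRUE)
    if (length(id) == 0L || nchar(id) < 4L) break
    size <- readBin(con, "integer", 1, size = 4, endian = "little")
    if (length(size) == 0L) stop("truncated WAV file: ", path, call. = FALSE)
    if (identical(id, "fmt ")) {
      body <- readBin(con, "raw", size)
      if (length(body) < 16L) stop("truncated WAV file: ", path, call. = FALSE)
      fmt <- list(
        audio_format = readBin(body[1:2], "integer", 1, size = 2,
                               endian = "little", signed = FALSE),
        channels = readBin(body[3:4], "integer", 1, size = 2,
                           endian = "little", signed = FALSE),
        sample_rate = readBin(body[5:8], "integer", 1, size = 4,
                              endian = "little"),
        bits = readBin(body[15:16], "integer", 1, size = 2,
                       endian = "little", signed = FALSE)
      )
    } else if (identical(id, "data")) {
      data_raw <- readBin(con, "raw", size)
      if (length(data_raw) < size) {
        stop("truncated WAV file: ", path, call. = FALSE)
      }
    } else {
      invisible(readBin(con, "raw", size))
    }
    if (!is.null(fmt) && !is.null(data_raw)) break
  }
  if (is.null(fmt) || is.null(data_raw)) {
    stop("truncated WAV file: ", path, call. = FALSE)
  }
  if (fmt$channels != 1L) {
    stop("stereo (or multi-channel) WAV input is not supported; ",
         "supply mono audio", call. = FALSE)
  }
  if (fmt$audio_format == 1L && fmt$bits == 16L) {
    n <- length(data_raw) %/% 2L
    samples <- readBin(data_raw, "integer", n, size = 2, endian = "little",
                       signed = TRUE) / 32768
  } else if (fmt$audio_format == 3L && fmt$bits %in% c(32L, 64L)) {
    sz <- fmt$bits %/% 8L
    n <- length(data_raw) %/% sz
    samples <- readBin(data_raw, "double", n, size = sz, endian = "little")
  } else {
    stop(sprintf("unsupported WAV codec (format %d, %d bit)",
                 fmt$audio_format, fmt$bits), call. = FALSE)
  }
  voice_recording(pmin(1, pmax(-1, samples)), fmt$sample_rate, source_id)
}

#' Write a recording as a 16-bit PCM mono WAV file
#'
#' @param rec a [voice_recording()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_wav <- function(rec, path) {
  stopifnot(inherits(rec, "voice_recording"))
  pcm <- as.integer(pmin(32767, pmax(-32768, round(rec$samples * 32768))))
  con <- file(path, "wb")
  on.exit(close(con))
  data_size <- 2L * length(pcm)
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + data_size), con, size = 4, endian = "little")
  writeChar("WAVE", con, eos = NULL)
  writeChar("fmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")
  writeBin(1L, con, size = 2, endian = "little")   # PCM
  writeBin(1L, con, size = 2, endian = "little")   # mono
  sr <- as.integer(round(rec$sample_rate))
  writeBin(sr, con, size = 4, endian = "little")
  writeBin(as.integer(sr * 2L), con, size = 4, endian = "little")  # byte rate
  writeBin(2L, con, size = 2, endian = "little")   # block align
  writeBin(16L, con, size = 2, endian = "little")  # bits
  writeChar("data", con, eos = NULL)
  writeBin(as.integer(data_size), con, size = 4, endian = "little")
  writeBin(pcm, con, size = 2, endian = "little")
  invisible(path)
}

#' Write and read word-boundary annotations
#'
#' Word boundaries travel with a recording as a sidecar tab-separated file
#' with columns `start_s`, `end_s`, `word_index`.
#'
#' @param boundaries a data frame (or 2-column matrix) of word start/end
#'   times in seconds.
#' @param path path of the `.tsv` sidecar.
#' @return `path` invisibly for the writer; a data frame with columns
#'   `start_s`, `end_s`, `word_index` for the reader.
#' @export
write_word_annotation <- function(boundaries, path) {
  b <- as.data.frame(boundaries)
  names(b)[1:2] <- c("start_s", "end_s")
  b$word_index <- seq_len(nrow(b))
  utils::write.table(b[, c("start_s", "end_s", "word_index")], path,
                     sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_word_annotation
#' @export
read_word_annotation <- function(path) {
  b <- utils::read.delim(path)
  need <- c("start_s", "end_s", "word_index")
  if (!all(need %in% names(b))) {
    stop("annotation file lacks columns: ",
         paste(setdiff(need, names(b)), collapse = ", "), call. = FALSE)
  }
  if (any(diff(b$start_s) <= 0) || any(b$end_s <= b$start_s)) {
    stop("word boundaries must be increasing and non-overlapping",
         call. = FALSE)
  }
  b[need]
}
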