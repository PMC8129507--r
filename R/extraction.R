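# Extraction of the seven acoustic features from a mono waveform:
# frame-wise normalized-autocorrelation pitch analysis, cycle-by-cycle
# period marking, then velocity, mean F0, F0 SD, intensity (dB),
# jitter%, shimmer% and HNR (dB).

#' Extraction configuration
#'
#' Analysis settings for the pitch-period detector and the frame-based
#' features. Defaults follow common practice for adult speech: a 75-600 Hz
#' pitch search band (covering the 118-315 Hz range of the study's cell
#' means with margin), 4.5 pitch-floor cycles per analysis frame, a 10 ms
#' hop, and a -25 dB silence floor relative to the utterance peak.
#'
#' @param f0_min,f0_max pitch search band, Hz.
#' @param voicing_threshold minimum normalized autocorrelation peak for a
#'   frame to count as voiced, in (0, 1).
#' @param frame_length analysis frame, s; default holds 4.5 cycles of
#'   `f0_min`.
#' @param hop frame hop, s.
#' @param silence_floor_db frame-energy floor relative to the utterance
#'   peak frame, dB (negative).
#' @param min_pause minimum silence run counted as a pause and excluded
#'   from speech time, s.
#' @param intensity_reference pressure-equivalent reference for dB
#'   intensity; samples are treated as Pa-equivalent. Shared with the
#'   generator so intensities round-trip.
#' @param hnr_cap_db upper cap on reported HNR, dB.
#' @return an object of class `extraction_config`.
#' @export
extraction_config <- function(f0_min = 75, f0_max = 600,
                              voicing_threshold = 0.45,
                              frame_length = 4.5 / f0_min, hop = 0.01,
                              silence_floor_db = -25, min_pause = 0.10,
                              intensity_reference = INTENSITY_REF,
                              hnr_cap_db = 60) {
  if (f0_min <= 0 || f0_max <= f0_min) {
    stop("need 0 < f0_min < f0_max", call. = FALSE)
  }
  if (voicing_threshold <= 0 || voicing_threshold >= 1) {
    stop("voicing_threshold must be in (0, 1)", call. = FALSE)
  }
  if (silence_floor_db >= 0) {
    stop("silence_floor_db must be negative (relative to peak)", call. = FALSE)
  }
  structure(list(f0_min = f0_min, f0_max = f0_max,
                 voicing_threshold = voicing_threshold,
                 frame_length = frame_length, hop = hop,
                 silence_floor_db = silence_floor_db, min_pause = min_pause,
                 intensity_reference = intensity_reference,
                 hnr_cap_db = hnr_cap_db),
            class = "extraction_config")
}

# Frame-level analysis shared by the detector, HNR, intensity and
# velocity: per frame the RMS, the normalized-autocorrelation peak value
# (rho, the harmonicity r') and its interpolated lag.
frame_analysis <- function(rec, cfg) {
  sr <- rec$sample_rate
  x <- rec$samples
  L <- round(cfg$frame_length * sr)
  hop <- max(1L, round(cfg$hop * sr))
  lag_min <- max(2L, floor(sr / cfg$f0_max))
  lag_max <- ceiling(sr / cfg$f0_min)
  if (lag_max + 2L >= L) {
    stop("pitch search band infeasible: frame holds fewer than one cycle ",
         "of f0_min at this sample rate", call. = FALSE)
  }
  starts <- seq(1L, max(1L, length(x) - L + 1L), by = hop)
  nfft <- stats::nextn(L + lag_max + 1L, 2)
  n_f <- length(starts)
  rms <- numeric(n_f)
  rho <- rep(NA_real_, n_f)
  lag_s <- rep(NA_real_, n_f)
  lags <- lag_min:lag_max
  for (j in seq_len(n_f)) {
    seg <- x[starts[j] + 0:(L - 1L)]
    e <- sum(seg^2)
    rms[j] <- sqrt(e / L)
    if (e <= 0) next
    X <- stats::fft(c(seg, numeric(nfft - L)))
    ac <- Re(stats::fft(Mod(X)^2, inverse = TRUE)) / nfft
    cs <- cumsum(seg^2)
    e1 <- cs[L - lags]
    e2 <- cs[L] - cs[lags]
    denom <- sqrt(e1 * e2)
    r <- ac[lags + 1L] / denom
    r[!is.finite(r)] <- 0
    # interior local maxima of r over the lag band
    n_r <- length(r)
    im <- which(r[-c(1L, n_r)] > r[-c(n_r - 1L, n_r)] &
                  r[-c(1L, n_r)] >= r[-c(1L, 2L)]) + 1L
    if (!length(im)) next
    # prefer the smallest lag among peaks comparable to the best one:
    # guards against octave errors when 2T also lies in the band
    best <- max(r[im])
    i0 <- im[r[im] >= 0.85 * best][1L]
    y1 <- r[i0 - 1L]; y2 <- r[i0]; y3 <- r[i0 + 1L]
    a2 <- (y1 - 2 * y2 + y3) / 2
    b <- (y3 - y1) / 2
    delta <- if (a2 < 0) max(-0.5, min(0.5, -b / (2 * a2))) else 0
    rho[j] <- y2 + b * delta + a2 * delta^2
    lag_s[j] <- (lags[i0] + delta) / sr
  }
  peak_rms <- max(rms)
  silent <- if (peak_rms > 0) {
    20 * log10(pmax(rms, .Machine$double.xmin) / peak_rms) <
      cfg$silence_floor_db
  } else rep(TRUE, n_f)
  voiced <- !silent & !is.na(rho) & rho >= cfg$voicing_threshold
  list(times = (starts - 1 + L / 2) / sr, rms = rms, rho = rho,
       lag_s = lag_s, voiced = voiced, silent = silent,
       frame_length_s = L / sr, hop_s = hop / sr, n_samples = length(x))
}

# Voiced frames whose analysis window does not straddle silence: silent
# frames are dilated by half a window so edge frames (partly silence,
# partly speech) are excluded from energy-sensitive statistics.  Falls
# back to the plain voiced mask when nothing survives.
core_voiced <- function(fa) {
  r <- max(1L, floor(fa$frame_length_s / fa$hop_s / 2))
  bad <- logical(length(fa$silent))
  for (j in which(fa$silent)) {
    bad[max(1L, j - r):min(length(bad), j + r)] <- TRUE
  }
  core <- fa$voiced & !bad
  if (any(core)) core else fa$voiced
}

# Parabolic refinement of a peak at integer sample i of pol * x:
# returns fractional position and interpolated amplitude.
refine_peak <- function(x, i, pol, lo, hi) {
  if (i <= lo || i >= hi) {
    return(list(pos = i, amp = pol * x[i]))
  }
  y1 <- pol * x[i - 1L]; y2 <- pol * x[i]; y3 <- pol * x[i + 1L]
  a2 <- (y1 - 2 * y2 + y3) / 2
  b <- (y3 - y1) / 2
  if (a2 >= 0) return(list(pos = i, amp = y2))
  d <- max(-0.5, min(0.5, -b / (2 * a2)))
  list(pos = i + d, amp = y2 + b * d + a2 * d^2)
}

# Cycle marking within one voiced region: anchored at the strongest
# glottal peak, walk outward locating one peak per predicted cycle
# (search window 0.7-1.3 local periods), with parabolic sub-sample
# refinement of both position and amplitude.
mark_cycles <- function(x, sr, from, to, period_at) {
  seg <- from:to
  anchor <- seg[which.max(abs(x[seg]))]
  pol <- if (x[anchor] >= 0) 1 else -1
  walk <- function(start, dir) {
    marks_pos <- numeric(0)
    marks_amp <- numeric(0)
    m <- start
    repeat {
      Tn <- period_at((m - 1) / sr) * sr
      w0 <- m + dir * round(0.7 * Tn)
      w1 <- m + dir * round(1.3 * Tn)
      w <- seq(min(w0, w1), max(w0, w1))
      w <- w[w >= from & w <= to]
      if (length(w) < 3L) break
      i <- w[which.max(pol * x[w])]
      if (pol * x[i] <= 0) break
      r <- refine_peak(x, i, pol, from, to)
      marks_pos <- c(marks_pos, r$pos)
      marks_amp <- c(marks_amp, r$amp)
      m <- i
    }
    list(pos = marks_pos, amp = marks_amp)
  }
  r0 <- refine_peak(x, anchor, pol, from, to)
  fw <- walk(anchor, +1L)
  bw <- walk(anchor, -1L)
  pos <- c(rev(bw$pos), r0$pos, fw$pos)
  amp <- c(rev(bw$amp), r0$amp, fw$amp)
  ok <- amp > 0
  list(pos = pos[ok], amp = amp[ok])
}

#' Detect pitch periods in a recording
#'
#' Frame-wise normalized autocorrelation locates voiced frames and their
#' period lag inside the `f0_min`-`f0_max` band (frames whose
#' autocorrelation peak falls below `voicing_threshold`, or whose energy
#' sits below the silence floor, are unvoiced). Voiced frames are then
#' stitched into a cycle-by-cycle period track by marking one glottal
#' peak per cycle, and the per-cycle peak amplitude is recorded.
#'
#' @param rec a [voice_recording()].
#' @param cfg an [extraction_config()].
#' @return a [pitch_periods()] sequence; the frame analysis is attached as
#'   attribute `"frames"` for reuse by [harmonicity_hnr()] and
#'   [intensity_db()].
#' @export
detect_pitch_periods <- function(rec, cfg = extraction_config()) {
  stopifnot(inherits(rec, "voice_recording"))
  fa <- frame_analysis(rec, cfg)
  if (!any(fa$voiced)) {
    stop("no voiced content detected", call. = FALSE)
  }
  sr <- rec$sample_rate
  x <- rec$samples
  runs <- rle(fa$voiced)
  ends <- cumsum(runs$lengths)
  starts_run <- ends - runs$lengths + 1L
  half <- fa$frame_length_s / 2
  periods <- amps <- onsets <- numeric(0)
  segment <- integer(0)
  seg_id <- 0L
  last_to <- 0L
  for (k in which(runs$values)) {
    i0 <- starts_run[k]; i1 <- ends[k]
    t0 <- fa$times[i0] - half
    t1 <- fa$times[i1] + half
    from <- max(1L, floor(t0 * sr) + 1L, last_to + 1L)
    to <- min(fa$n_samples, ceiling(t1 * sr))
    if (to - from < 3L) next
    last_to <- to
    idx <- i0:i1
    period_at <- if (length(idx) > 1L) {
      stats::approxfun(fa$times[idx], fa$lag_s[idx], rule = 2)
    } else {
      lag0 <- fa$lag_s[idx]
      function(t) rep(lag0, length(t))
    }
    mk <- mark_cycles(x, sr, from, to, period_at)
    if (length(mk$pos) < 2L) next
    p <- diff(mk$pos) / sr
    keep <- p > 0
    p <- p[keep]
    if (!length(p)) next
    seg_id <- seg_id + 1L
    periods <- c(periods, p * 1000)
    amps <- c(amps, mk$amp[-length(mk$amp)][keep])
    onsets <- c(onsets, (mk$pos[-length(mk$pos)][keep] - 1) / sr)
    segment <- c(segment, rep(seg_id, length(p)))
  }
  if (!length(periods)) {
    stop("no voiced content detected", call. = FALSE)
  }
  out <- pitch_periods(periods, amps, onsets, segment)
  attr(out, "frames") <- fa
  out
}

#' Mean pitch period
#'
#' Arithmetic mean of the cycle durations T_i, in ms.
#'
#' @param p a [pitch_periods()] sequence.
#' @return mean period, ms.
#' @export
#' @examples
#' mean_period(pitch_periods(c(10, 10.2, 10, 10.2, 10), rep(1, 5)))  # 10.08
mean_period <- function(p) {
  stopifnot(inherits(p, "pitch_periods"))
  if (length(p) < 1L) stop("empty period sequence", call. = FALSE)
  mean(p$periods_ms)
}

# adjacent pairs that do not straddle a voiced-segment boundary
.adjacent_pairs <- function(p) {
  if (length(p) < 2L) {
    stop("at least 2 pitch periods are required", call. = FALSE)
  }
  keep <- diff(p$segment) == 0L
  if (!any(keep)) {
    stop("no adjacent period pairs within a voiced segment", call. = FALSE)
  }
  keep
}

#' Absolute jitter
#'
#' Mean absolute difference between adjacent pitch periods,
#' `sum(|T_i - T_(i-1)|) / (N - 1)`, in ms. Pairs straddling a voicing
#' gap are excluded.
#'
#' @param p a [pitch_periods()] sequence with at least 2 periods.
#' @return absolute jitter, ms.
#' @export
jitter_absolute <- function(p) {
  stopifnot(inherits(p, "pitch_periods"))
  keep <- .adjacent_pairs(p)
  d <- abs(diff(p$periods_ms))
  sum(d[keep]) / sum(keep)
}

#' Jitter percentage
#'
#' `100 * jitter_absolute / mean_period`: the ratio of cycle-to-cycle
#' fundamental-frequency perturbation to the mean period.
#'
#' @inheritParams jitter_absolute
#' @return jitter, percent.
#' @export
#' @examples
#' p <- pitch_periods(c(10, 10.2, 10, 10.2, 10), rep(1, 5))
#' jitter_percent(p)  # 0.2 / 10.08 * 100 = 1.984...
jitter_percent <- function(p) {
  100 * jitter_absolute(p) / mean_period(p)
}

#' Shimmer percentage
#'
#' `100 * [sum(|A_k - A_(k-1)|) / (N - 1)] / mean(A)`: the ratio of
#' cycle-to-cycle amplitude perturbation to the mean amplitude. Pairs
#' straddling a voicing gap are excluded.
#'
#' @inheritParams jitter_absolute
#' @return shimmer, percent.
#' @export
#' @examples
#' p <- pitch_periods(rep(10, 4), c(1.0, 0.8, 1.0, 0.8))
#' shimmer_percent(p)  # 0.2 / 0.9 * 100 = 22.22...
shimmer_percent <- function(p) {
  stopifnot(inherits(p, "pitch_periods"))
  keep <- .adjacent_pairs(p)
  d <- abs(diff(p$amplitudes))
  100 * (sum(d[keep]) / sum(keep)) / mean(p$amplitudes)
}

#' Mean pitch
#'
#' Mean of the per-cycle instantaneous fundamental frequencies
#' `1000 / T_i(ms)`, in Hz. Note this is not `1 / mean_period`.
#'
#' @inheritParams jitter_absolute
#' @return mean F0, Hz.
#' @export
#' @examples
#' mean_pitch(pitch_periods(c(4, 5), c(1, 1)))  # mean(250, 200) = 225
mean_pitch <- function(p) {
  stopifnot(inherits(p, "pitch_periods"))
  if (length(p) < 1L) stop("empty period sequence", call. = FALSE)
  mean(1000 / p$periods_ms)
}

#' Pitch variability (F0 SD)
#'
#' Sample standard deviation (n - 1 denominator) of the per-cycle
#' instantaneous F0 values, in Hz.
#'
#' @inheritParams jitter_absolute
#' @return F0 SD, Hz.
#' @export
pitch_sd <- function(p) {
  stopifnot(inherits(p, "pitch_periods"))
  if (length(p) < 2L) {
    stop("at least 2 pitch periods are required", call. = FALSE)
  }
  stats::sd(1000 / p$periods_ms)
}

#' Harmonicity in dB from a normalized autocorrelation value
#'
#' `10 * log10(r / (1 - r))`: equal periodic and noise energy
#' (`r = 0.5`) gives 0 dB. `r` is clamped to at most `1 - 1e-6` and the
#' result capped at `cap_db`.
#'
#' @param r normalized autocorrelation at the period lag, in (0, 1).
#' @param cap_db upper cap, dB.
#' @return HNR, dB.
#' @export
#' @examples
#' harmonicity_db(0.5)   # 0
#' harmonicity_db(0.99)  # 19.956
harmonicity_db <- function(r, cap_db = 60) {
  r <- pmin(pmax(r, 1e-6), 1 - 1e-6)
  pmin(10 * log10(r / (1 - r)), cap_db)
}

#' Harmonics-to-noise ratio of a recording
#'
#' Per voiced frame, the normalized autocorrelation peak r' at the
#' detected period lag estimates the relative energy of the periodic
#' part; the frame HNR is `10 * log10(r' / (1 - r'))` and the utterance
#' HNR is the mean of the frame HNRs in the dB domain.
#'
#' @param rec a [voice_recording()].
#' @param p optionally the [detect_pitch_periods()] result for `rec`, to
#'   reuse its frame analysis.
#' @param cfg an [extraction_config()].
#' @return HNR, dB.
#' @export
harmonicity_hnr <- function(rec, p = NULL, cfg = extraction_config()) {
  fa <- attr(p, "frames") %||% frame_analysis(rec, cfg)
  if (!any(fa$voiced)) stop("no voiced frames", call. = FALSE)
  mean(harmonicity_db(fa$rho[core_voiced(fa)], cfg$hnr_cap_db))
}

#' Mean intensity in dB
#'
#' Energy mean over voiced frames of the frame power, expressed as
#' `20 * log10(RMS / intensity_reference)` with samples treated as
#' pressure-equivalent.
#'
#' @inheritParams harmonicity_hnr
#' @return intensity, dB.
#' @export
intensity_db <- function(rec, p = NULL, cfg = extraction_config()) {
  fa <- attr(p, "frames") %||% frame_analysis(rec, cfg)
  if (!any(fa$voiced)) {
    stop("no voiced frames above the silence floor", call. = FALSE)
  }
  10 * log10(mean(fa$rms[core_voiced(fa)]^2) / cfg$intensity_reference^2)
}

#' Speech velocity in seconds per word
#'
#' Average time per word: total speech duration divided by the word
#' count, with silences of at least `min_pause` excluded from the speech
#' time. When word boundaries are available (an annotated utterance) the
#' speech duration is the summed word spans; otherwise silences are found
#' by frame-energy segmentation at the silence floor.
#'
#' @param x an `annotated_utterance` or a [voice_recording()].
#' @param word_count number of words; taken from the annotation when
#'   present.
#' @param cfg an [extraction_config()].
#' @return velocity, s per word.
#' @export
speech_velocity <- function(x, word_count = NULL, cfg = extraction_config()) {
  if (inherits(x, "annotated_utterance")) {
    wc <- x$word_count
    dur <- sum(x$word_boundaries$end_s - x$word_boundaries$start_s)
    return(dur / wc)
  }
  stopifnot(inherits(x, "voice_recording"))
  if (is.null(word_count) || word_count < 1) {
    stop("word_count must be a positive integer", call. = FALSE)
  }
  # short non-overlapping energy windows (5 ms) so that pauses close to
  # min_pause are still resolvable; threshold relative to the peak window
  sr <- x$sample_rate
  win <- max(1L, round(0.005 * sr))
  n_w <- length(x$samples) %/% win
  if (n_w < 2L) stop("recording too short to segment", call. = FALSE)
  e <- rowsum(x$samples[seq_len(n_w * win)]^2,
              rep(seq_len(n_w), each = win))[, 1]
  peak <- max(e)
  if (peak <= 0) stop("fully silent input", call. = FALSE)
  silent <- 10 * log10(pmax(e, .Machine$double.xmin) / peak) <
    cfg$silence_floor_db
  if (all(silent)) stop("fully silent input", call. = FALSE)
  runs <- rle(silent)
  run_s <- runs$lengths * win / sr
  pause_s <- sum(run_s[runs$values & run_s >= cfg$min_pause])
  total_s <- length(x$samples) / sr
  (total_s - pause_s) / word_count
}

#' Extract the seven acoustic features of an utterance
#'
#' Composes pitch-period detection and the feature operations into one
#' vector: velocity (s/word), mean F0 (Hz), F0 SD (Hz), intensity (dB),
#' jitter (%), shimmer (%) and HNR (dB), plus the number of detected
#' periods and the voiced fraction for quality control. When fewer than 2
#' pitch periods are found the period-based features are marked undefined
#' (`NA`), never fabricated as zeros.
#'
#' @param x an `annotated_utterance` or a [voice_recording()].
#' @param word_count word count when `x` is a bare recording; `NULL`
#'   leaves velocity undefined.
#' @param cfg an [extraction_config()].
#' @return an object of class `acoustic_features`: a list with the seven
#'   features, `n_periods`, `voiced_fraction` and `source_id`.
#' @export
extract_features <- function(x, word_count = NULL,
                             cfg = extraction_config()) {
  rec <- if (inherits(x, "annotated_utterance")) x$recording else x
  stopifnot(inherits(rec, "voice_recording"))
  pp <- tryCatch(detect_pitch_periods(rec, cfg), error = function(e) {
    if (grepl("no voiced content", conditionMessage(e))) NULL else stop(e)
  })
  fa <- if (!is.null(pp)) attr(pp, "frames") else frame_analysis(rec, cfg)
  n_sp <- sum(!fa$silent)
  vf <- if (n_sp > 0) sum(fa$voiced) / n_sp else 0
  n_per <- if (is.null(pp)) 0L else length(pp)
  velocity <- if (inherits(x, "annotated_utterance")) {
    speech_velocity(x, cfg = cfg)
  } else if (!is.null(word_count)) {
    speech_velocity(rec, word_count, cfg)
  } else NA_real_
  if (n_per >= 2L) {
    out <- list(velocity = velocity, mean_f0 = mean_pitch(pp),
                f0_sd = pitch_sd(pp),
                intensity = intensity_db(rec, pp, cfg),
                jitter_pct = jitter_percent(pp),
                shimmer_pct = shimmer_percent(pp),
                hnr = harmonicity_hnr(rec, pp, cfg))
  } else {
    out <- list(velocity = velocity, mean_f0 = NA_real_, f0_sd = NA_real_,
                intensity = NA_real_, jitter_pct = NA_real_,
                shimmer_pct = NA_real_, hnr = NA_real_)
  }
  out$n_periods <- n_per
  out$voiced_fraction <- vf
  out$source_id <- rec$source_id
  structure(out, class = "acoustic_features")
}

#' @export
print.acoustic_features <- function(x, ...) {
  cat(sprintf("<acoustic_features '%s'>\n", x$source_id))
  fmt <- function(v, u) if (is.na(v)) "undefined" else sprintf("%.2f %s",
                                                              v, u)
  cat(sprintf("  velocity  %s\n", fmt(x$velocity, "s/word")))
  cat(sprintf("  mean F0   %s\n", fmt(x$mean_f0, "Hz")))
  cat(sprintf("  F0 SD     %s\n", fmt(x$f0_sd, "Hz")))
  cat(sprintf("  intensity %s\n", fmt(x$intensity, "dB")))
  cat(sprintf("  jitter    %s\n", fmt(x$jitter_pct, "%")))
  cat(sprintf("  shimmer   %s\n", fmt(x$shimmer_pct, "%")))
  cat(sprintf("  HNR       %s\n", fmt(x$hnr, "dB")))
  cat(sprintf("  QC: %d periods, voiced fraction %.2f\n",
              x$n_periods, x$voiced_fraction))
  invisible(x)
}

#' @export
as.data.frame.acoustic_features <- function(x, ...) {
  data.frame(source_id = x$source_id, velocity = x$velocity,
             mean_f0 = x$mean_f0, f0_sd = x$f0_sd, intensity = x$intensity,
             jitter_pct = x$jitter_pct, shimmer_pct = x$shimmer_pct,
             hnr = x$hnr, n_periods = x$n_periods,
             voiced_fraction = x$voiced_fraction,
             stringsAsFactors = FALSE)
}
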