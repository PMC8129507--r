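# Seeded synthesis of voiced utterances: a glottal pulse-train/harmonic
# source with controlled period jitter, per-cycle amplitude shimmer, a slow
# F0 contour, additive noise at a target harmonics-to-noise ratio, and
# silence gaps between words.

#' Specify a synthetic voice stimulus
#'
#' All parameters are in the units the feature extractor reports, so a
#' round trip through [extract_features()] recovers them
#' parameter-for-parameter: jitter is the expected consecutive-period
#' perturbation ratio, shimmer the analogous amplitude ratio, HNR the
#' periodic-to-noise energy ratio in dB, and intensity follows the shared
#' dB convention (reference 2e-5, samples treated as pressure-equivalent).
#'
#' @param mean_f0 mean fundamental frequency, Hz. Must lie within the
#'   default pitch search band (75-600 Hz).
#' @param f0_sd standard deviation of the slow F0 contour, Hz.
#' @param jitter_pct target jitter, percent (must be below 30).
#' @param shimmer_pct target shimmer, percent (must be below 30).
#' @param hnr_db target harmonics-to-noise ratio, dB; `Inf` disables noise.
#' @param intensity_db target intensity, dB (70 dB is the study's fixed
#'   input level).
#' @param n_words number of voiced word segments per utterance.
#' @param seconds_per_word duration of each voiced segment, s.
#' @param pause_fraction silent gap after each word as a fraction of
#'   `seconds_per_word`, in \[0, 1).
#' @param sample_rate sampling frequency, Hz.
#' @param harmonic_cutoff bandwidth of the harmonic source, Hz; harmonics
#'   above `min(harmonic_cutoff, 0.45 * sample_rate)` are dropped.
#' @param seed integer seed making the stimulus reproducible.
#' @return an object of class `voice_spec`.
#' @export
#' @examples
#' voice_spec(mean_f0 = 214.73, jitter_pct = 1, hnr_db = 25, seed = 1)
voice_spec <- function(mean_f0 = 200, f0_sd = 0, jitter_pct = 0,
                       shimmer_pct = 0, hnr_db = Inf, intensity_db = 70,
                       n_words = 9, seconds_per_word = 0.28,
                       pause_fraction = 0.4, sample_rate = 44100,
                       harmonic_cutoff = 8000, seed = 1) {
  if (mean_f0 < 75 || mean_f0 > 600) {
    stop("mean_f0 must lie within the 75-600 Hz pitch search band",
         call. = FALSE)
  }
  if (f0_sd < 0) stop("f0_sd must be non-negative", call. = FALSE)
  if (jitter_pct < 0 || jitter_pct > 30) {
    stop("jitter_pct must be in [0, 30] percent", call. = FALSE)
  }
  if (shimmer_pct < 0 || shimmer_pct > 30) {
    stop("shimmer_pct must be in [0, 30] percent", call. = FALSE)
  }
  if (n_words < 1) stop("n_words must be a positive integer", call. = FALSE)
  if (seconds_per_word <= 0) stop("seconds_per_word must be > 0", call. = FALSE)
  if (pause_fraction < 0 || pause_fraction >= 1) {
    stop("pause_fraction must be in [0, 1)", call. = FALSE)
  }
  structure(list(mean_f0 = mean_f0, f0_sd = f0_sd, jitter_pct = jitter_pct,
                 shimmer_pct = shimmer_pct, hnr_db = hnr_db,
                 intensity_db = intensity_db, n_words = as.integer(n_words),
                 seconds_per_word = seconds_per_word,
                 pause_fraction = pause_fraction, sample_rate = sample_rate,
                 harmonic_cutoff = harmonic_cutoff,
                 seed = as.integer(seed)),
            class = "voice_spec")
}

#' @export
print.voice_spec <- function(x, ...) {
  cat(sprintf(paste0(
    "<voice_spec: F0 %.1f Hz (SD %.1f), jitter %.2f%%, shimmer %.2f%%, ",
    "HNR %s dB, %d x %.2f s words, seed %d>\n"),
    x$mean_f0, x$f0_sd, x$jitter_pct, x$shimmer_pct,
    if (is.infinite(x$hnr_db)) "Inf" else sprintf("%.1f", x$hnr_db),
    x$n_words, x$seconds_per_word, x$seed))
  invisible(x)
}

# Slow F0 contour: a sum of M random sinusoids in the 0.5-3 Hz band with
# total variance f0_sd^2.  Smooth by construction, so contour variation
# (what F0 SD measures) stays separable from cycle-to-cycle jitter.
# Frequencies/phases are drawn from the current RNG stream.
f0_contour_fun <- function(mean_f0, f0_sd, n_components = 8) {
  if (f0_sd <= 0) return(function(t) rep(mean_f0, length(t)))
  freqs <- stats::runif(n_components, 0.5, 3)
  phases <- stats::runif(n_components, 0, 2 * pi)
  amp <- f0_sd * sqrt(2 / n_components)
  lo <- 0.6 * mean_f0
  hi <- 5 / 3 * mean_f0
  function(t) {
    f <- mean_f0 + amp * colSums(sin(outer(2 * pi * freqs, t) + phases))
    pmin(hi, pmax(lo, f))
  }
}

#' Synthesize a perturbed pitch-period sequence
#'
#' Generates cycle durations `T_i = (1 / f0_i) * (1 + eps_i)` where `f0_i`
#' follows the slow random contour with SD `f0_sd` and
#' `eps_i ~ Normal(0, sigma_j)` with `sigma_j = (jitter_pct / 100) *
#' sqrt(pi) / 2`, so that the expected consecutive-period statistic
#' `E|T_i - T_(i-1)| / E[T]` equals `jitter_pct / 100` (for iid normal X,
#' Y, `E|X - Y| = 2 * sigma / sqrt(pi)`). Per-cycle amplitudes are
#' `A_k = 1 + eta_k` with the analogous shimmer calibration. Deterministic
#' given the seed.
#'
#' @param spec a [voice_spec()].
#' @param duration voiced duration to fill, s (the last full cycle ends at
#'   or before it). Defaults to one word.
#' @param n_periods alternatively, an exact number of cycles.
#' @param seed RNG seed; defaults to `spec$seed`.
#' @return a [pitch_periods()] sequence.
#' @export
synthesize_period_sequence <- function(spec, duration = NULL, n_periods = NULL,
                                       seed = spec$seed) {
  stopifnot(inherits(spec, "voice_spec"))
  if (is.null(duration) && is.null(n_periods)) duration <- spec$seconds_per_word
  sigma_j <- spec$jitter_pct / 100 * sqrt(pi) / 2
  sigma_s <- spec$shimmer_pct / 100 * sqrt(pi) / 2
  with_seed(seed, {
    contour <- f0_contour_fun(spec$mean_f0, spec$f0_sd)
    cap <- if (!is.null(n_periods)) n_periods else
      ceiling((duration %||% 1) * spec$mean_f0 * 3 + 50)
    eps <- if (sigma_j > 0) stats::rnorm(cap, 0, sigma_j) else numeric(cap)
    periods <- numeric(cap)
    onsets <- numeric(cap)
    t <- 0
    n <- 0L
    repeat {
      Ti <- (1 + eps[n + 1L]) / contour(t)
      if (Ti <= 0) {
        stop("jitter perturbation produced a non-positive period; ",
             "reduce jitter_pct", call. = FALSE)
      }
      if (!is.null(duration) && t + Ti > duration * (1 + 1e-12)) break
      n <- n + 1L
      periods[n] <- Ti
      onsets[n] <- t
      t <- t + Ti
      if (!is.null(n_periods) && n >= n_periods) break
      if (n >= cap) break
    }
    if (n < 1L) {
      stop("duration too short to hold a single pitch period", call. = FALSE)
    }
    amps <- 1 + (if (sigma_s > 0) stats::rnorm(n, 0, sigma_s) else numeric(n))
    if (any(amps <= 0)) {
      stop("shimmer perturbation produced a non-positive amplitude; ",
           "reduce shimmer_pct", call. = FALSE)
    }
    pitch_periods(periods[seq_len(n)] * 1000, amps, onsets[seq_len(n)])
  })
}

#' Render a period sequence as a waveform
#'
#' Emits a glottal pulse train: one band-limited pulse per cycle, centered
#' exactly at the cycle onset instant and scaled by the cycle amplitude
#' `A_k`, so that the rendered peak spacing equals the period sequence
#' cycle-for-cycle and peak amplitudes equal `A_k` (jitter and shimmer
#' are injected in exactly the units the extractor measures). The pulse
#' shape is one nominal cycle of the first H harmonics of `mean_f0` with
#' 1/h amplitude roll-off (H capped by the spec's harmonic cutoff and by
#' Nyquist), Hann-tapered to zero at +-0.6 nominal cycles so pulse edges
#' are smooth. White Gaussian noise with power
#' `harmonic power / 10^(hnr_db / 10)` is added, and the waveform is
#' scaled so the extractor's intensity convention returns
#' `spec$intensity_db`. Any sample that would exceed full scale is an
#' error, never a silent clamp.
#'
#' @param periods a [pitch_periods()] sequence.
#' @param spec the [voice_spec()] supplying HNR, intensity, rates.
#' @param seed RNG seed for the noise; defaults to a seed derived from
#'   `spec$seed` (distinct from the period-sequence stream).
#' @return a [voice_recording()]; attributes `harmonic_rms` and
#'   `noise_rms` record the realized component levels for energy checks.
#' @export
render_waveform <- function(periods, spec, seed = sub_seed(spec$seed, 211L)) {
  stopifnot(inherits(periods, "pitch_periods"), inherits(spec, "voice_spec"))
  n_cyc <- length(periods)
  if (n_cyc < 1L) stop("period sequence is empty", call. = FALSE)
  sr <- spec$sample_rate
  Tsec <- periods$periods_ms / 1000
  # pulse instants: the peak of cycle k sits at its onset, shifted by half
  # a support so the first pulse is fully inside the rendering
  T0 <- 1 / spec$mean_f0
  half_sup <- 0.6 * T0
  pulse_t <- periods$onset_s + half_sup
  t_end <- pulse_t[n_cyc] + Tsec[n_cyc]
  n <- ceiling((t_end + half_sup) * sr)
  fmax <- min(spec$harmonic_cutoff, 0.45 * sr)
  H <- max(1L, floor(fmax * T0))
  h <- seq_len(H)
  x <- numeric(n)
  m <- ceiling(half_sup * sr)
  for (k in seq_len(n_cyc)) {
    ic <- round(pulse_t[k] * sr) + 1L
    idx <- max(1L, ic - m):min(n, ic + m)
    t_rel <- (idx - 1) / sr - pulse_t[k]
    w <- 0.5 * (1 + cos(pi * t_rel / half_sup))
    w[abs(t_rel) >= half_sup] <- 0
    s <- w * drop(cos(2 * pi * outer(t_rel, h / T0)) %*% (1 / h))
    x[idx] <- x[idx] + periods$amplitudes[k] * s
  }
  p_harm <- mean(x^2)
  noise_rms <- 0
  if (is.finite(spec$hnr_db)) {
    sigma_n <- sqrt(p_harm) * 10^(-spec$hnr_db / 20)
    noise <- with_seed(seed, stats::rnorm(n, 0, sigma_n))
    noise_rms <- sqrt(mean(noise^2))
    x <- x + noise
  }
  rms <- sqrt(mean(x^2))
  gain <- INTENSITY_REF * 10^(spec$intensity_db / 20) / rms
  if (max(abs(x)) * gain > 1) {
    stop("rendering would clip: peak amplitude exceeds full scale at the ",
         "requested intensity", call. = FALSE)
  }
  rec <- voice_recording(x * gain, sr, source_id = "synthetic")
  attr(rec, "harmonic_rms") <- sqrt(p_harm) * gain
  attr(rec, "noise_rms") <- noise_rms * gain
  rec
}

#' Synthesize a word-structured utterance
#'
#' Concatenates `n_words` voiced segments of `seconds_per_word` each,
#' separated by pure-silence gaps of `pause_fraction * seconds_per_word`,
#' recording the word boundaries. The total duration is
#' `n_words * seconds_per_word * (1 + pause_fraction)` to within one
#' sample.
#'
#' @param spec a [voice_spec()].
#' @param seed RNG seed; defaults to `spec$seed`.
#' @param source_id provenance label for the recording.
#' @return an object of class `annotated_utterance`: a list with elements
#'   `recording`, `word_count`, `word_boundaries` (data frame of start/end
#'   seconds) and `true_spec`.
#' @export
synthesize_utterance <- function(spec, seed = spec$seed,
                                 source_id = "synthetic") {
  stopifnot(inherits(spec, "voice_spec"))
  sr <- spec$sample_rate
  stride <- spec$seconds_per_word * (1 + spec$pause_fraction)
  total_n <- round(spec$n_words * stride * sr)
  word_n <- round(spec$seconds_per_word * sr)
  x <- numeric(total_n)
  starts <- integer(spec$n_words)
  for (w in seq_len(spec$n_words)) {
    p <- synthesize_period_sequence(spec, duration = spec$seconds_per_word,
                                    seed = sub_seed(seed, w, 1L))
    rec_w <- render_waveform(p, spec, seed = sub_seed(seed, w, 2L))
    s0 <- round((w - 1) * stride * sr)
    m <- min(length(rec_w$samples), word_n, total_n - s0)
    x[s0 + seq_len(m)] <- rec_w$samples[seq_len(m)]
    starts[w] <- s0
  }
  bounds <- data.frame(start_s = starts / sr,
                       end_s = (starts + word_n) / sr)
  structure(list(recording = voice_recording(x, sr, source_id),
                 word_count = spec$n_words,
                 word_boundaries = bounds,
                 true_spec = spec),
            class = "annotated_utterance")
}

#' @export
print.annotated_utterance <- function(x, ...) {
  cat(sprintf("<annotated_utterance: %d words, %.2f s total>\n",
              x$word_count, recording_duration(x$recording)))
  invisible(x)
}
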