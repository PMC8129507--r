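test_that("perturbation statistics match hand-evaluated values", {
  p <- pitch_periods(c(10, 10.2, 10, 10.2, 10), rep(1, 5))
  expect_equal(mean_period(p), 10.08)
  expect_equal(jitter_absolute(p), 0.2)
  expect_equal(jitter_percent(p), 100 * 0.2 / 10.08)
  expect_equal(mean_period(pitch_periods(5, 1)), 5)

  ps <- pitch_periods(rep(10, 4), c(1.0, 0.8, 1.0, 0.8))
  expect_equal(shimmer_percent(ps), 100 * 0.2 / 0.9)
  expect_equal(shimmer_percent(pitch_periods(rep(10, 4), rep(0.7, 4))), 0)

  expect_equal(mean_pitch(pitch_periods(c(4, 5), c(1, 1))), 225)
  expect_equal(mean_pitch(pitch_periods(rep(5, 3), rep(1, 3))), 200)
  expect_equal(pitch_sd(pitch_periods(c(5, 1000 / 210), c(1, 1))),
               sd(c(200, 210)))
})

test_that("vectorized statistics agree with loop oracles to 1e-12", {
  set.seed(41)
  for (rep in 1:20) {
    n <- sample(5:200, 1)
    periods <- runif(n, 2, 12)
    amps <- runif(n, 0.2, 2)
    p <- pitch_periods(periods, amps)
    expect_equal(mean_period(p), oracle_mean_period(periods),
                 tolerance = 1e-12)
    expect_equal(jitter_percent(p), oracle_jitter_percent(periods),
                 tolerance = 1e-12)
    expect_equal(shimmer_percent(p), oracle_shimmer_percent(amps),
                 tolerance = 1e-12)
  }
})

test_that("alternating periods reproduce the 2*delta*T closed form", {
  T0 <- 8
  for (delta in c(0.01, 0.05, 0.1)) {
    periods <- T0 * (1 + delta * rep_len(c(1, -1), 100))
    p <- pitch_periods(periods, rep(1, 100))
    expect_equal(jitter_absolute(p), 2 * delta * T0, tolerance = 1e-12)
    expect_equal(mean_period(p), T0, tolerance = 1e-12)
  }
})

test_that("scale invariances of the ratio statistics hold", {
  set.seed(7)
  periods <- runif(50, 4, 6)
  amps <- runif(50, 0.5, 1.5)
  p1 <- pitch_periods(periods, amps)
  p2 <- pitch_periods(2 * periods, 3 * amps)
  expect_equal(jitter_percent(p2), jitter_percent(p1))
  expect_equal(shimmer_percent(p2), shimmer_percent(p1))
  expect_equal(mean_period(p2), 2 * mean_period(p1))
})

test_that("jitter and shimmer are invariant under time reversal", {
  set.seed(13)
  p <- pitch_periods(runif(80, 4, 6), runif(80, 0.5, 1.5))
  pr <- reverse_periods(p)
  expect_equal(jitter_percent(pr), jitter_percent(p))
  expect_equal(shimmer_percent(pr), shimmer_percent(p))
})

test_that("perturbation statistics refuse fewer than two periods", {
  p1 <- pitch_periods(5, 1)
  expect_error(jitter_absolute(p1), "at least 2")
  expect_error(shimmer_percent(p1), "at least 2")
  expect_error(pitch_sd(p1), "at least 2")
})

test_that("harmonicity analytics follow the autocorrelation formula", {
  expect_equal(harmonicity_db(0.5), 0)
  expect_equal(harmonicity_db(0.99), 10 * log10(0.99 / 0.01),
               tolerance = 1e-12)
  expect_equal(harmonicity_db(0.99), 19.9563519, tolerance = 1e-7)
  expect_equal(harmonicity_db(1), 60, tolerance = 1e-6)  # capped
  expect_equal(harmonicity_db(0.9, cap_db = 5), 5)
})

test_that("a noiseless pulse train yields its exact period track", {
  sr <- 44100
  x <- numeric(sr)
  x[seq(1, sr, by = 441)] <- 0.9       # 100 Hz impulse train
  rec <- voice_recording(x, sr, "pulse100")
  pp <- detect_pitch_periods(rec)
  expect_true(all(abs(pp$periods_ms - 10) <= 1000 / sr))
  expect_lt(abs(mean_pitch(pp) - 100), 0.5)
})

test_that("aperiodic input is reported as unvoiced, not fabricated", {
  set.seed(3)
  rec <- voice_recording(runif(44100, -0.5, 0.5), 44100, "noise")
  expect_error(detect_pitch_periods(rec), "no voiced content")
  feats <- extract_features(rec, word_count = 3)
  expect_true(is.na(feats$mean_f0))
  expect_true(is.na(feats$jitter_pct))
  expect_equal(feats$n_periods, 0L)
})

test_that("infeasible pitch band configuration is a distinct error", {
  rec <- voiced_recording(seconds = 0.5)
  cfg <- extraction_config(f0_min = 75, f0_max = 600,
                           frame_length = 0.008)
  expect_error(detect_pitch_periods(rec, cfg), "infeasible")
})

test_that("mean F0, jitter, shimmer and HNR are recovered from synthetic audio", {
  # one seed per condition here; the 20-seed averages live with the
  # acceptance checks
  rec <- voiced_recording(mean_f0 = 214.73, f0_sd = 2, jitter_pct = 1,
                          hnr_db = 25, seconds = 2, seed = 11)
  pp <- detect_pitch_periods(rec)
  expect_lt(abs(mean_pitch(pp) / 214.73 - 1), 0.01)

  rec <- voiced_recording(mean_f0 = 137.12, f0_sd = 2, jitter_pct = 2,
                          hnr_db = 25, seconds = 2, seed = 12)
  pp <- detect_pitch_periods(rec)
  expect_lt(abs(mean_pitch(pp) / 137.12 - 1), 0.01)
  expect_lt(abs(jitter_percent(pp) / 2 - 1), 0.15)

  rec <- voiced_recording(mean_f0 = 200, shimmer_pct = 10, hnr_db = 25,
                          seconds = 2, seed = 13)
  pp <- detect_pitch_periods(rec)
  expect_lt(abs(shimmer_percent(pp) / 10 - 1), 0.15)

  rec <- voiced_recording(mean_f0 = 200, hnr_db = 10, seconds = 2,
                          seed = 14)
  expect_lt(abs(harmonicity_hnr(rec) - 10), 1)
})

test_that("extracted HNR falls and extracted jitter rises along injected grids", {
  jit <- vapply(c(0.5, 1, 2, 4, 8), function(j) {
    rec <- voiced_recording(mean_f0 = 200, jitter_pct = j, hnr_db = 25,
                            f0_sd = 1, seconds = 1.5, seed = 9)
    jitter_percent(detect_pitch_periods(rec))
  }, numeric(1))
  expect_true(all(diff(jit) > 0))

  hnr <- vapply(c(25, 20, 15, 10, 5), function(h) {
    rec <- voiced_recording(mean_f0 = 200, hnr_db = h, f0_sd = 1,
                            seconds = 1.5, seed = 9)
    harmonicity_hnr(rec)
  }, numeric(1))
  expect_true(all(diff(hnr) < 0))
})

test_that("intensity follows the shared dB convention and round-trips", {
  for (tgt in c(60, 70, 80)) {
    rec <- voiced_recording(mean_f0 = 200, hnr_db = 20,
                            seconds = 1.5, seed = tgt)
    rec$samples <- rec$samples *
      10^((tgt - 70) / 20)  # renderer default is 70 dB
    expect_lt(abs(intensity_db(rec) - tgt), 0.5)
  }
})

test_that("velocity divides speech time by words and skips pauses", {
  sp <- voice_spec(mean_f0 = 200, n_words = 9, seconds_per_word = 0.28,
                   pause_fraction = 0.4, seed = 6)
  utt <- synthesize_utterance(sp)
  expect_equal(speech_velocity(utt), 0.28)
  # energy segmentation on the bare recording: pauses of 0.112 s are
  # found within one hop of the truth
  v <- speech_velocity(utt$recording, word_count = 9)
  expect_lt(abs(v - 0.28), 0.08)
  # a long internal pause is excluded entirely
  sr <- 44100
  gap <- numeric(sr)  # 1 s of silence
  xx <- c(utt$recording$samples, gap, utt$recording$samples)
  rec2 <- voice_recording(xx, sr)
  v2 <- speech_velocity(rec2, word_count = 18)
  expect_lt(abs(v2 - v), 0.02)
  expect_error(speech_velocity(utt$recording, word_count = 0),
               "word_count")
})

test_that("extract_features composes a deterministic full vector", {
  sp <- voice_spec(mean_f0 = 190, f0_sd = 5, jitter_pct = 1.5,
                   shimmer_pct = 6, hnr_db = 18, n_words = 3,
                   seconds_per_word = 0.4, seed = 21)
  utt <- synthesize_utterance(sp)
  f1 <- extract_features(utt)
  f2 <- extract_features(utt)
  expect_identical(as.data.frame(f1), as.data.frame(f2))
  expect_equal(f1$velocity, 0.4)
  expect_lt(abs(f1$mean_f0 / 190 - 1), 0.01)
  expect_gt(f1$voiced_fraction, 0.5)
  expect_gt(f1$n_periods, 100)
})

test_that("zero-perturbation input reads as clean voice", {
  sp <- voiced_spec(mean_f0 = 200, seconds = 1.5, seed = 2)
  utt <- synthesize_utterance(sp)
  f <- extract_features(utt)
  expect_lt(f$jitter_pct, 0.1)
  expect_lt(f$shimmer_pct, 0.5)
  # measurement ceiling of the lag-interpolated autocorrelation sits far
  # above any voiced HNR of interest
  expect_gt(f$hnr, 30)
})
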