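test_that("zero perturbation gives exactly regular periods and amplitudes", {
  sp <- voiced_spec(mean_f0 = 200, seconds = 1)
  p <- synthesize_period_sequence(sp, duration = 1)
  expect_true(all(abs(p$periods_ms - 5) < 1e-12))
  expect_true(all(p$amplitudes == 1))
  expect_equal(length(p), 200L)
})

test_that("period and amplitude perturbations are calibrated to their targets", {
  # closed-form sigma = (target/100) * sqrt(pi)/2 makes the realized
  # consecutive-difference statistic equal the target; checked by
  # simulation across seeds for jitter and shimmer at 1, 2, 5 percent
  for (tgt in c(1, 2, 5)) {
    jv <- sv <- numeric(50)
    for (s in 1:50) {
      sp <- voiced_spec(mean_f0 = 200, jitter_pct = tgt, shimmer_pct = tgt,
                        seed = s)
      p <- synthesize_period_sequence(sp, n_periods = 5000)
      jv[s] <- jitter_percent(p)
      sv[s] <- shimmer_percent(p)
    }
    expect_lt(abs(mean(jv) / tgt - 1), 0.02)
    expect_lt(abs(mean(sv) / tgt - 1), 0.02)
  }
})

test_that("rendered periodic-to-noise energy ratio matches the HNR target", {
  for (tgt in c(5, 10, 20)) {
    rec <- voiced_recording(mean_f0 = 200, hnr_db = tgt, seconds = 3,
                            seed = tgt)
    ratio_db <- 20 * log10(attr(rec, "harmonic_rms") /
                             attr(rec, "noise_rms"))
    expect_lt(abs(ratio_db - tgt), 0.5)
  }
  rec <- voiced_recording(mean_f0 = 200, hnr_db = Inf, seconds = 1)
  expect_identical(attr(rec, "noise_rms"), 0)
})

test_that("synthesis is bit-deterministic given spec and seed", {
  sp <- voice_spec(mean_f0 = 180, f0_sd = 10, jitter_pct = 2,
                   shimmer_pct = 6, hnr_db = 15, n_words = 3,
                   seconds_per_word = 0.3, seed = 77)
  u1 <- synthesize_utterance(sp)
  u2 <- synthesize_utterance(sp)
  expect_identical(u1$recording$samples, u2$recording$samples)
  p1 <- synthesize_period_sequence(sp, seed = 5)
  p2 <- synthesize_period_sequence(sp, seed = 5)
  expect_identical(p1$periods_ms, p2$periods_ms)
  expect_identical(p1$amplitudes, p2$amplitudes)
})

test_that("utterances have the specified word structure and duration", {
  sp <- voice_spec(mean_f0 = 200, n_words = 9, seconds_per_word = 0.28,
                   pause_fraction = 0, seed = 2)
  utt <- synthesize_utterance(sp)
  expect_equal(utt$word_count, 9L)
  expect_equal(nrow(utt$word_boundaries), 9L)
  expect_lt(abs(recording_duration(utt$recording) - 2.52), 1 / 44100)
  sp2 <- voice_spec(mean_f0 = 200, n_words = 4, seconds_per_word = 0.3,
                    pause_fraction = 0.4, seed = 2)
  utt2 <- synthesize_utterance(sp2)
  expect_lt(abs(recording_duration(utt2$recording) - 4 * 0.3 * 1.4),
            1 / 44100)
  b <- utt2$word_boundaries
  expect_true(all(diff(b$start_s) > 0))
  expect_true(all(b$end_s > b$start_s))
  expect_true(all(b$end_s <= recording_duration(utt2$recording) + 1e-9))
})

test_that("out-of-range synthesis parameters are rejected", {
  expect_error(voice_spec(mean_f0 = 50), "75-600")
  expect_error(voice_spec(jitter_pct = 35), "jitter")
  expect_error(voice_spec(shimmer_pct = 31), "shimmer")
  expect_error(voice_spec(pause_fraction = 1), "pause_fraction")
})

test_that("emotion presets cover all 18 cells with the printed means", {
  p <- emotion_presets()
  expect_equal(nrow(p), 18L)
  expect_false(anyNA(p[, -(1:2)]))
  cell <- function(g, e, f) p[p$gender == g & p$emotion == e, f]
  expect_equal(cell("female", "neutral", "mean_f0"), 214.73)
  expect_equal(cell("male", "neutral", "mean_f0"), 137.12)
  expect_equal(cell("male", "bored", "seconds_per_word"), 0.48)
  expect_equal(cell("female", "docile", "hnr_db"), 15.97)
  expect_equal(cell("male", "anxious", "jitter_pct"), 5.70)
  expect_equal(cell("female", "disdainful", "shimmer_pct"), 15.55)
  # unprinted cells fall back to the per-gender pooled mean of the
  # printed cells of the same feature
  raw <- emotion_presets(fill = FALSE)
  f_printed <- raw$f0_sd[raw$gender == "female" & !is.na(raw$f0_sd)]
  expect_equal(cell("female", "neutral", "f0_sd"), mean(f_printed))
  expect_equal(cell("male", "relaxed", "intensity_db"), 70)
})

test_that("cohort ground truth reproduces the presets when scatter is zero", {
  presets <- emotion_presets(between_subject_sd = 0)
  specs <- emovoice:::cohort_specs(3, 3, presets, seed = 4)
  expect_equal(nrow(specs), 6L * 9L)
  for (g in c("female", "male")) {
    for (e in c("neutral", "bored", "anxious")) {
      got <- unique(specs$mean_f0[specs$gender == g & specs$emotion == e])
      want <- presets$mean_f0[presets$gender == g & presets$emotion == e]
      expect_equal(got, want)
    }
  }
})

test_that("cohort cell means approach the presets as subjects increase", {
  presets <- emotion_presets(between_subject_sd = 0.1)
  specs <- emovoice:::cohort_specs(200, 200, presets, seed = 8)
  for (g in c("female", "male")) {
    got <- mean(specs$mean_f0[specs$gender == g &
                                specs$emotion == "neutral"])
    want <- presets$mean_f0[presets$gender == g &
                              presets$emotion == "neutral"]
    # relative SE at n = 200 and 10% scatter is ~0.7%
    expect_lt(abs(got / want - 1), 0.03)
  }
})

test_that("generate_cohort returns the full design with ground truth", {
  cohort <- generate_cohort(2, 2, emotion_presets(between_subject_sd = 0),
                            seed = 1, n_words = 2)
  expect_length(cohort$utterances, 4L * 9L)
  expect_equal(nrow(cohort$truth), 4L * 9L * 7L)
  expect_setequal(unique(cohort$truth$feature),
                  c("velocity", "mean_f0", "f0_sd", "intensity",
                    "jitter_pct", "shimmer_pct", "hnr"))
})
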