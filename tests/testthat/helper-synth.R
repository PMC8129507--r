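# Stimulus builders shared across test files.

# one continuous voiced stretch (no word gaps), convenient for recovery
voiced_spec <- function(mean_f0 = 200, f0_sd = 0, jitter_pct = 0,
                        shimmer_pct = 0, hnr_db = Inf, seconds = 2,
                        seed = 1) {
  voice_spec(mean_f0 = mean_f0, f0_sd = f0_sd, jitter_pct = jitter_pct,
             shimmer_pct = shimmer_pct, hnr_db = hnr_db,
             n_words = 1, seconds_per_word = seconds, pause_fraction = 0,
             seed = seed)
}

voiced_recording <- function(..., seconds = 2, seed = 1) {
  sp <- voiced_spec(..., seconds = seconds, seed = seed)
  render_waveform(synthesize_period_sequence(sp, duration = seconds), sp)
}

reverse_periods <- function(p) {
  pitch_periods(rev(p$periods_ms), rev(p$amplitudes))
}
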