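# Per-(gender, emotion) synthesis presets taken from the study's printed
# cell means: seconds per word, mean F0, F0 SD, intensity, jitter%,
# shimmer% and HNR for each of the 18 gender x state cells.  Cells the
# study does not print fall back to the per-gender pooled mean of that
# feature's printed cells (intensity falls back to the 70 dB fixed input
# level instead).

.preset_cells <- local({
  emo <- c("neutral", "exuberant", "bored", "dependent", "disdainful",
           "relaxed", "anxious", "docile", "hostile")
  m <- function(f, male) matrix(c(f, male), ncol = 2,
                                dimnames = list(emo, c("female", "male")))
  list(
    seconds_per_word = m(
      c(0.29, 0.28, 0.52, 0.38, 0.29, 0.34, 0.26, 0.33, 0.28),
      c(0.26, 0.24, 0.48, 0.36, 0.25, 0.30, 0.21, 0.28, 0.24)),
    mean_f0 = m(
      c(214.73, 314.45, 214.73, 215.45, 188.35, 283.05, 309.57, 309.00, 279.94),
      c(137.12, 218.26, 134.03, 118.72, 138.03, 205.95, 218.30, 171.10, 169.62)),
    f0_sd = m(
      c(NA, 33.86, 37.20, 13.30, NA, NA, NA, NA, 37.57),
      c(NA, 21.25, 13.21, 20.75, NA, NA, NA, NA, 17.36)),
    intensity_db = m(
      c(NA, NA, 62.38, 64.68, NA, NA, NA, 65.78, NA),
      c(NA, NA, 69.65, 69.52, NA, NA, NA, 71.71, NA)),
    jitter_pct = m(
      c(1.93, 1.57, 1.97, 2.04, NA, 3.18, 2.87, 1.75, NA),
      c(4.19, 2.59, 2.33, 2.89, NA, 2.08, 5.70, 2.10, NA)),
    shimmer_pct = m(
      c(9.65, 8.03, 9.84, 8.38, 15.55, 12.30, 13.34, 0.28, 0.24),
      c(18.73, 9.24, 11.12, 12.93, 11.79, 10.48, 15.81, 0.33, 0.28)),
    hnr_db = m(
      c(13.08, 15.14, 11.42, 13.54, NA, 9.10, NA, 15.97, 14.93),
      c(8.19, 11.03, 12.99, 11.48, NA, 13.09, NA, 12.29, 12.01))
  )
})

#' Emotion synthesis presets for the 18 gender x state cells
#'
#' Returns the full preset table used to emulate the study cohort: one row
#' per (gender, emotional state) with the seven acoustic parameters of the
#' cell. Values are the printed per-cell means; where a cell mean is not
#' printed, the per-gender pooled mean of the printed cells of that
#' feature is used (intensity falls back to the 70 dB fixed recording
#' input level).
#'
#' @param between_subject_sd relative between-subject scatter applied by
#'   [generate_cohort()]: each simulated subject multiplies every
#'   parameter by its own persistent `1 + Normal(0, between_subject_sd)`
#'   factor.
#' @param fill if `FALSE`, unprinted cells are left `NA` instead of being
#'   filled with the pooled fallback.
#' @return a data frame of class `emotion_presets` with columns `gender`,
#'   `emotion`, `seconds_per_word`, `mean_f0`, `f0_sd`, `intensity_db`,
#'   `jitter_pct`, `shimmer_pct`, `hnr_db`.
#' @export
#' @examples
#' p <- emotion_presets()
#' subset(p, gender == "female" & emotion == "neutral")$mean_f0  # 214.73
emotion_presets <- function(between_subject_sd = 0.10, fill = TRUE) {
  cells <- .preset_cells
  if (fill) {
    cells <- lapply(names(cells), function(nm) {
      m <- cells[[nm]]
      for (g in colnames(m)) {
        if (anyNA(m[, g])) {
          fb <- if (nm == "intensity_db") 70 else mean(m[, g], na.rm = TRUE)
          m[is.na(m[, g]), g] <- fb
        }
      }
      m
    })
    names(cells) <- names(.preset_cells)
  }
  emo <- pad_emotions()
  out <- data.frame(
    gender = rep(c("female", "male"), each = length(emo)),
    emotion = rep(emo, 2),
    stringsAsFactors = FALSE
  )
  for (nm in names(cells)) {
    out[[nm]] <- c(cells[[nm]][, "female"], cells[[nm]][, "male"])
  }
  attr(out, "between_subject_sd") <- between_subject_sd
  class(out) <- c("emotion_presets", "data.frame")
  out
}

#' Build the voice spec for one preset cell
#'
#' @param presets an [emotion_presets()] table.
#' @param gender `"female"` or `"male"`.
#' @param emotion one of [pad_emotions()].
#' @param n_words,pause_fraction,sample_rate,seed utterance-level
#'   parameters passed to [voice_spec()].
#' @return a [voice_spec()] for that cell.
#' @export
preset_spec <- function(presets, gender, emotion, n_words = 9,
                        pause_fraction = 0.4, sample_rate = 44100, seed = 1) {
  row <- presets[presets$gender == gender & presets$emotion == emotion, ]
  if (nrow(row) != 1L) {
    stop("no preset for (", gender, ", ", emotion, ")", call. = FALSE)
  }
  voice_spec(mean_f0 = row$mean_f0, f0_sd = row$f0_sd,
             jitter_pct = row$jitter_pct, shimmer_pct = row$shimmer_pct,
             hnr_db = row$hnr_db, intensity_db = row$intensity_db,
             n_words = n_words, seconds_per_word = row$seconds_per_word,
             pause_fraction = pause_fraction, sample_rate = sample_rate,
             seed = seed)
}

# Per-subject parameter draws: every subject gets one persistent relative
# offset per parameter, shared across their nine emotions.  Deterministic
# given the seed; with between_subject_sd = 0 all same-gender subjects
# share the preset values exactly.
cohort_specs <- function(n_female, n_male, presets = emotion_presets(),
                         seed = 1) {
  if (n_female < 2 || n_male < 2) {
    stop("at least 2 subjects per gender are required", call. = FALSE)
  }
  sd_rel <- attr(presets, "between_subject_sd") %||% 0
  pars <- c("seconds_per_word", "mean_f0", "f0_sd", "intensity_db",
            "jitter_pct", "shimmer_pct", "hnr_db")
  subjects <- data.frame(
    subject_id = c(sprintf("F%02d", seq_len(n_female)),
                   sprintf("M%02d", seq_len(n_male))),
    gender = rep(c("female", "male"), c(n_female, n_male)),
    stringsAsFactors = FALSE
  )
  rows <- vector("list", nrow(subjects))
  for (i in seq_len(nrow(subjects))) {
    offs <- with_seed(sub_seed(seed, 97L, i), {
      o <- 1 + stats::rnorm(length(pars), 0, sd_rel)
      pmax(o, 0.1)
    })
    names(offs) <- pars
    block <- presets[presets$gender == subjects$gender[i],
                     c("emotion", pars)]
    for (p in pars) {
      if (p == "intensity_db") {
        # intensity scatter is relative on amplitude, i.e. an additive
        # dB shift, not a multiple of the dB number
        block[[p]] <- block[[p]] + 20 * log10(offs[[p]])
      } else {
        block[[p]] <- block[[p]] * offs[[p]]
      }
    }
    block$subject_id <- subjects$subject_id[i]
    block$gender <- subjects$gender[i]
    rows[[i]] <- block
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out[, c("subject_id", "gender", "emotion", pars)]
}

#' Generate a synthetic study cohort
#'
#' Simulates the study design: `n_female + n_male` subjects each producing
#' one utterance per emotional state (9 per subject). Every subject gets a
#' persistent random relative offset on each parameter (the preset table's
#' `between_subject_sd`), applied across all nine of their emotion specs;
#' one seeded utterance is then synthesized per (subject, emotion).
#'
#' @param n_female,n_male subjects per gender (at least 2 each).
#' @param presets an [emotion_presets()] table.
#' @param seed integer seed; the cohort is fully deterministic given it.
#' @param n_words,pause_fraction utterance structure shared by all cells.
#' @param keep_audio if `FALSE`, utterances are dropped after synthesis
#'   and only the ground-truth table is returned (saves memory for large
#'   cohorts; [run_study()] streams instead of keeping audio).
#' @return an object of class `voice_cohort`: list with `utterances` (a
#'   list of [synthesize_utterance()] results, named subject.emotion),
#'   `truth` (long ground-truth feature table with columns `subject_id`,
#'   `gender`, `emotion`, `feature`, `value`) and `specs`.
#' @export
generate_cohort <- function(n_female = 31, n_male = 31,
                            presets = emotion_presets(), seed = 1,
                            n_words = 9, pause_fraction = 0.4,
                            keep_audio = TRUE) {
  specs <- cohort_specs(n_female, n_male, presets, seed)
  utt <- if (keep_audio) vector("list", nrow(specs)) else NULL
  for (i in seq_len(nrow(specs))) {
    if (!keep_audio) break
    utt[[i]] <- synthesize_utterance(
      cohort_row_spec(specs[i, ], n_words, pause_fraction,
                      seed = sub_seed(seed, 11L, i)),
      source_id = paste0(specs$subject_id[i], ".", specs$emotion[i]))
  }
  if (keep_audio) {
    names(utt) <- paste0(specs$subject_id, ".", specs$emotion)
  }
  structure(list(utterances = utt, truth = cohort_truth(specs),
                 specs = specs, seed = seed),
            class = "voice_cohort")
}

# voice_spec for one row of a cohort_specs() table
cohort_row_spec <- function(row, n_words, pause_fraction, seed) {
  voice_spec(mean_f0 = row$mean_f0, f0_sd = row$f0_sd,
             jitter_pct = min(row$jitter_pct, 29.9),
             shimmer_pct = min(row$shimmer_pct, 29.9),
             hnr_db = row$hnr_db, intensity_db = row$intensity_db,
             n_words = n_words, seconds_per_word = row$seconds_per_word,
             pause_fraction = pause_fraction, seed = seed)
}

# long ground-truth table in extractor feature names
cohort_truth <- function(specs) {
  feats <- c(velocity = "seconds_per_word", mean_f0 = "mean_f0",
             f0_sd = "f0_sd", intensity = "intensity_db",
             jitter_pct = "jitter_pct", shimmer_pct = "shimmer_pct",
             hnr = "hnr_db")
  out <- do.call(rbind, lapply(names(feats), function(f) {
    data.frame(subject_id = specs$subject_id, gender = specs$gender,
               emotion = specs$emotion, feature = f,
               value = specs[[feats[[f]]]], stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' @export
print.voice_cohort <- function(x, ...) {
  ns <- length(unique(x$specs$subject_id))
  cat(sprintf("<voice_cohort: %d subjects x %d emotions (%d utterances%s)>\n",
              ns, length(unique(x$specs$emotion)), nrow(x$specs),
              if (is.null(x$utterances)) ", audio not kept" else ""))
  invisible(x)
}
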