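# End-to-end study pipeline: synthesize a cohort, extract features,
# analyze each feature with the mixed design, and render report tables.
# Also owns feature-table CSV and config YAML I/O and the CLI.

#' Study configuration
#'
#' A fully serializable description of one simulated study run: cohort
#' sizes, seed, preset scatter, extraction settings and statistics
#' options. A run is reproducible from the config alone.
#'
#' @param n_female,n_male subjects per gender.
#' @param seed integer master seed.
#' @param between_subject_sd relative between-subject parameter scatter.
#' @param n_words,pause_fraction utterance structure.
#' @param alpha significance level.
#' @param posthoc_method p-adjustment for post hoc comparisons.
#' @param correction sphericity correction, `"greenhouse-geisser"` or
#'   `"none"`.
#' @param qc_min_voiced utterances with a voiced fraction below this are
#'   flagged and excluded from the statistics.
#' @param extraction an [extraction_config()].
#' @param out_dir optional output directory for rendered reports.
#' @return an object of class `study_config`.
#' @export
study_config <- function(n_female = 31, n_male = 31, seed = 1,
                         between_subject_sd = 0.10, n_words = 9,
                         pause_fraction = 0.4, alpha = 0.05,
                         posthoc_method = "bonferroni",
                         correction = "greenhouse-geisser",
                         qc_min_voiced = 0.3,
                         extraction = extraction_config(),
                         out_dir = NULL) {
  structure(list(n_female = as.integer(n_female),
                 n_male = as.integer(n_male), seed = as.integer(seed),
                 between_subject_sd = between_subject_sd,
                 n_words = as.integer(n_words),
                 pause_fraction = pause_fraction, alpha = alpha,
                 posthoc_method = posthoc_method, correction = correction,
                 qc_min_voiced = qc_min_voiced, extraction = extraction,
                 out_dir = out_dir),
            class = "study_config")
}

#' Write and read a study configuration as YAML
#'
#' @param cfg a [study_config()].
#' @param path path of the YAML file.
#' @return `path` invisibly for the writer; a [study_config()] for the
#'   reader.
#' @export
write_study_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "study_config"))
  lst <- unclass(cfg)
  lst$extraction <- unclass(lst$extraction)
  yaml::write_yaml(lst, path)
  invisible(path)
}

#' @rdname write_study_config
#' @export
read_study_config <- function(path) {
  lst <- yaml::read_yaml(path)
  ex <- do.call(extraction_config, lst$extraction %||% list())
  lst$extraction <- NULL
  cfg <- do.call(study_config, c(lst, list(extraction = ex)))
  cfg
}

#' Write and read a long feature table as CSV
#'
#' Stable column order `subject_id, gender, emotion, feature, value`;
#' undefined feature values are serialized as empty cells, never as 0.
#'
#' @param rows data frame with the five columns above.
#' @param path CSV path.
#' @return `path` invisibly for the writer; the validated data frame for
#'   the reader.
#' @export
write_feature_table <- function(rows, path) {
  need <- c("subject_id", "gender", "emotion", "feature", "value")
  if (!all(need %in% names(rows))) {
    stop("feature table lacks columns: ",
         paste(setdiff(need, names(rows)), collapse = ", "), call. = FALSE)
  }
  utils::write.csv(rows[, need], path, row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname write_feature_table
#' @export
read_feature_table <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("subject_id", "gender", "emotion", "feature", "value")
  if (!all(need %in% names(tab))) {
    stop("feature table lacks columns: ",
         paste(setdiff(need, names(tab)), collapse = ", "), call. = FALSE)
  }
  tab$value <- as.numeric(tab$value)
  tab[, need]
}

.study_features <- c("velocity", "mean_f0", "f0_sd", "intensity",
                     "jitter_pct", "shimmer_pct", "hnr")

#' Run the full simulated study
#'
#' Generates the synthetic cohort (streaming: each utterance is
#' synthesized, measured and discarded), assembles the long feature
#' table, applies the voiced-fraction QC gate, and fits the mixed design
#' with simple main effects and post hoc orderings for each of the seven
#' features. Deterministic given the config.
#'
#' @param cfg a [study_config()].
#' @param presets an [emotion_presets()] table; its scatter is taken from
#'   `cfg$between_subject_sd`.
#' @return an object of class `study_report`: per-feature analyses
#'   (`$features`, each with `fit`, `simple`, `posthoc`), the measured
#'   `$feature_table`, the ground `$truth` table, `$qc`, and `$config`.
#' @export
run_study <- function(cfg = study_config(), presets = NULL) {
  stopifnot(inherits(cfg, "study_config"))
  if (is.null(presets)) {
    presets <- emotion_presets(between_subject_sd = cfg$between_subject_sd)
  }
  specs <- cohort_specs(cfg$n_female, cfg$n_male, presets, cfg$seed)
  meas <- vector("list", nrow(specs))
  for (i in seq_len(nrow(specs))) {
    utt <- synthesize_utterance(
      cohort_row_spec(specs[i, ], cfg$n_words, cfg$pause_fraction,
                      seed = sub_seed(cfg$seed, 11L, i)),
      source_id = paste0(specs$subject_id[i], ".", specs$emotion[i]))
    meas[[i]] <- as.data.frame(extract_features(utt, cfg = cfg$extraction))
  }
  meas <- do.call(rbind, meas)
  qc_fail <- meas$voiced_fraction < cfg$qc_min_voiced | meas$n_periods < 2
  qc <- data.frame(source_id = meas$source_id,
                   n_periods = meas$n_periods,
                   voiced_fraction = meas$voiced_fraction,
                   excluded = qc_fail, stringsAsFactors = FALSE)
  tab <- do.call(rbind, lapply(.study_features, function(f) {
    data.frame(subject_id = specs$subject_id, gender = specs$gender,
               emotion = specs$emotion, feature = f, value = meas[[f]],
               stringsAsFactors = FALSE)
  }))
  keep <- !qc_fail[match(paste0(tab$subject_id, ".", tab$emotion),
                         meas$source_id)]
  tab_kept <- tab[keep, , drop = FALSE]
  fits <- lapply(.study_features, function(f) {
    fit <- mixed_anova(tab_kept, feature = f, alpha = cfg$alpha,
                       correction = cfg$correction)
    list(fit = fit,
         simple = simple_main_effects(fit, alpha = cfg$alpha,
                                      method = cfg$posthoc_method),
         posthoc = posthoc_pairwise(fit, scope = "pooled",
                                    alpha = cfg$alpha,
                                    method = cfg$posthoc_method))
  })
  names(fits) <- .study_features
  structure(list(features = fits, feature_table = tab,
                 truth = cohort_truth(specs), qc = qc, config = cfg,
                 seed = cfg$seed),
            class = "study_report")
}

#' @export
print.study_report <- function(x, ...) {
  cat(sprintf("<study_report: %d + %d subjects, %d utterances (%d excluded by QC), seed %d>\n",
              x$config$n_female, x$config$n_male, nrow(x$qc),
              sum(x$qc$excluded), x$seed))
  for (f in names(x$features)) {
    a <- x$features[[f]]$fit$anova
    cat(sprintf("  %-11s gender F %8.2f%-3s state F %8.2f%-3s interaction F %8.2f%s\n",
                f, a$F[1], stars(a$p[1]), a$F[2], stars(a$p[2]),
                a$F[3], stars(a$p[3])))
  }
  invisible(x)
}

#' Render a study report as text tables
#'
#' Produces the marginal-means grid, the ANOVA abstract and the
#' simple-main-effects tables for every feature, with significance stars
#' and `(i) > (j)` post hoc notation, values rounded half away from zero
#' to 2 decimals. Pure: the report is not modified. When `dir` is given,
#' the text and per-feature CSV tables are written there.
#'
#' @param report a [run_study()] result.
#' @param dir optional output directory.
#' @return character vector of report lines, invisibly when `dir` is
#'   given.
#' @export
render_report <- function(report, dir = NULL) {
  stopifnot(inherits(report, "study_report"))
  lines <- character(0)
  add <- function(...) lines <<- c(lines, sprintf(...))
  for (f in names(report$features)) {
    fit <- report$features[[f]]$fit
    simple <- report$features[[f]]$simple
    ph <- report$features[[f]]$posthoc
    add("==== %s ====", f)
    add("Cell and marginal means:")
    cm <- fit$cell_means
    mm <- marginal_means(cm)
    add("  %-11s %8s %8s %8s", "State", colnames(cm)[1], colnames(cm)[2],
        "Marginal")
    for (s in rownames(cm)) {
      add("  %-11s %8.2f %8.2f %8.2f", s,
          round_half_up(cm[s, 1], 2), round_half_up(cm[s, 2], 2),
          round_half_up(mm$state[s], 2))
    }
    add("  %-11s %8.2f %8.2f %8.2f", "Marginal",
        round_half_up(mm$gender[1], 2), round_half_up(mm$gender[2], 2),
        round_half_up(mm$grand, 2))
    add("ANOVA abstract:")
    a <- fit$anova
    for (r in seq_len(nrow(a))) {
      add("  %-14s SS %10.2f  Df %7.2f  MS %10.2f  %s", a$effect[r],
          round_half_up(a$SS[r], 2), round_half_up(a$df_corr[r], 2),
          round_half_up(a$MS[r], 2),
          if (is.na(a$F[r])) "" else
            sprintf("F %.2f%s", round_half_up(a$F[r], 2), stars(a$p[r])))
    }
    pooled_no <- posthoc_notation(ph)
    add("Post hoc (pooled): %s",
        if (length(pooled_no)) paste(pooled_no, collapse = "; ") else "")
    add("Simple main effects:")
    for (g in names(simple$state_within_gender)) {
      r <- simple$state_within_gender[[g]]
      no <- posthoc_notation(r$posthoc)
      add("  state within %-7s F %8.2f%-3s %s", g, round_half_up(r$F, 2),
          stars(r$p),
          if (length(no)) paste(no, collapse = "; ") else "")
    }
    for (s in names(simple$gender_within_state)) {
      r <- simple$gender_within_state[[s]]
      add("  gender within %-10s F %8.2f%-3s %s", s,
          round_half_up(r$F, 2), stars(r$p), r$direction)
    }
    add("")
  }
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    writeLines(lines, file.path(dir, "report.txt"))
    write_feature_table(report$feature_table,
                        file.path(dir, "feature_table.csv"))
    write_feature_table(report$truth, file.path(dir, "truth.csv"))
    anova_all <- do.call(rbind, lapply(names(report$features), function(f) {
      a <- report$features[[f]]$fit$anova
      a$feature <- f
      a
    }))
    utils::write.csv(anova_all, file.path(dir, "anova.csv"),
                     row.names = FALSE, na = "")
    utils::write.csv(report$qc, file.path(dir, "qc.csv"),
                     row.names = FALSE, na = "")
    return(invisible(lines))
  }
  lines
}

# ---------------------------------------------------------------- CLI ----

cli_usage <- function() {
  paste(
    "usage: emovoice <command> [options]",
    "",
    "commands:",
    "  synth   --preset GENDER,EMOTION --n-subjects K --seed S --out DIR",
    "  extract WAV [--words N] [--annotation TSV] [--out CSV]",
    "  analyze CSV [--feature NAME] [--alpha A] [--out DIR]",
    "  report  CSV [--alpha A] --out DIR",
    "  run     [--config YAML] [--seed S] [--n-female K] [--n-male K] --out DIR",
    sep = "\n")
}

cli_opts <- function(argv, allowed = character()) {
  opts <- list(positional = character(0))
  i <- 1L
  while (i <= length(argv)) {
    a <- argv[[i]]
    if (startsWith(a, "--")) {
      key <- substring(a, 3)
      if (!key %in% allowed) {
        stop("usage: unknown option --", key, call. = FALSE)
      }
      if (i == length(argv) || startsWith(argv[[i + 1L]], "--")) {
        stop("usage: missing value for --", key, call. = FALSE)
      }
      opts[[gsub("-", "_", key)]] <- argv[[i + 1L]]
      i <- i + 2L
    } else {
      opts$positional <- c(opts$positional, a)
      i <- i + 1L
    }
  }
  opts
}

#' Command-line entry point
#'
#' Subcommands: `synth` (write synthetic preset utterances as WAV plus
#' annotation sidecars and a ground-truth CSV), `extract` (one feature
#' row from a WAV), `analyze` / `report` (mixed-design statistics from a
#' feature-table CSV), and `run` (the full pipeline). Intended to be
#' called by the `inst/exec/emovoice` script; returns the exit status
#' instead of quitting so it can be driven in-process.
#'
#' @param argv character vector of arguments (excluding the program
#'   name).
#' @return integer exit status, invisibly: 0 on success, 1 on a runtime
#'   error, 2 on a usage error.
#' @export
cli_main <- function(argv = commandArgs(trailingOnly = TRUE)) {
  known <- c("synth", "extract", "analyze", "report", "run", "help",
             "--help")
  if (!length(argv) || !argv[[1L]] %in% known) {
    message(cli_usage())
    return(invisible(2L))
  }
  cmd <- argv[[1L]]
  if (cmd %in% c("help", "--help")) {
    message(cli_usage())
    return(invisible(0L))
  }
  allowed <- switch(cmd,
                    synth = c("preset", "n-subjects", "seed", "out"),
                    extract = c("words", "annotation", "out"),
                    analyze = c("feature", "alpha", "out"),
                    report = c("feature", "alpha", "out"),
                    run = c("config", "seed", "n-female", "n-male", "out"))
  status <- tryCatch({
    opts <- cli_opts(argv[-1L], allowed)
    switch(cmd,
           synth = cli_synth(opts),
           extract = cli_extract(opts),
           analyze = cli_analyze(opts, render = FALSE),
           report = cli_analyze(opts, render = TRUE),
           run = cli_run(opts))
    0L
  }, error = function(e) {
    message("error: ", conditionMessage(e))
    if (grepl("^usage", conditionMessage(e))) {
      message(cli_usage())
      2L
    } else 1L
  })
  invisible(status)
}

cli_req <- function(opts, key) {
  v <- opts[[key]]
  if (is.null(v)) stop("usage: missing required --", gsub("_", "-", key),
                       call. = FALSE)
  v
}

cli_synth <- function(opts) {
  preset <- strsplit(cli_req(opts, "preset"), ",")[[1L]]
  if (length(preset) != 2L) {
    stop("usage: --preset must be GENDER,EMOTION", call. = FALSE)
  }
  n_sub <- as.integer(opts$n_subjects %||% "1")
  seed <- as.integer(opts$seed %||% "1")
  out <- cli_req(opts, "out")
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  presets <- emotion_presets()
  truth <- vector("list", n_sub)
  for (s in seq_len(n_sub)) {
    spec <- preset_spec(presets, preset[1L], preset[2L],
                        seed = sub_seed(seed, s))
    utt <- synthesize_utterance(spec,
                                source_id = sprintf("%s_%s_%02d",
                                                    preset[1L], preset[2L],
                                                    s))
    base <- file.path(out, utt$recording$source_id)
    write_wav(utt$recording, paste0(base, ".wav"))
    write_word_annotation(utt$word_boundaries, paste0(base, ".tsv"))
    truth[[s]] <- data.frame(source_id = utt$recording$source_id,
                             gender = preset[1L], emotion = preset[2L],
                             mean_f0 = spec$mean_f0,
                             jitter_pct = spec$jitter_pct,
                             shimmer_pct = spec$shimmer_pct,
                             hnr_db = spec$hnr_db,
                             stringsAsFactors = FALSE)
  }
  utils::write.csv(do.call(rbind, truth), file.path(out, "truth.csv"),
                   row.names = FALSE)
  message("wrote ", n_sub, " utterance(s) to ", out)
}

cli_extract <- function(opts) {
  if (!length(opts$positional)) stop("usage: extract needs a WAV path",
                                     call. = FALSE)
  rec <- read_wav(opts$positional[[1L]])
  wc <- if (!is.null(opts$words)) as.integer(opts$words) else NULL
  x <- rec
  if (!is.null(opts$annotation)) {
    b <- read_word_annotation(opts$annotation)
    x <- structure(list(recording = rec, word_count = nrow(b),
                        word_boundaries = b, true_spec = NULL),
                   class = "annotated_utterance")
  }
  feats <- extract_features(x, word_count = wc)
  df <- as.data.frame(feats)
  if (!is.null(opts$out)) {
    utils::write.csv(df, opts$out, row.names = FALSE, na = "")
  } else {
    utils::write.csv(df, stdout(), row.names = FALSE, na = "")
  }
}

cli_analyze <- function(opts, render) {
  if (!length(opts$positional)) {
    stop("usage: analyze needs a feature-table CSV", call. = FALSE)
  }
  tab <- read_feature_table(opts$positional[[1L]])
  alpha <- as.numeric(opts$alpha %||% "0.05")
  feats <- if (!is.null(opts$feature)) opts$feature else
    unique(tab$feature)
  out <- opts$out
  if (!is.null(out)) dir.create(out, recursive = TRUE,
                                showWarnings = FALSE)
  for (f in feats) {
    fit <- mixed_anova(tab, feature = f, alpha = alpha)
    if (render) {
      rep_lines <- utils::capture.output({
        print(fit)
        print(simple_main_effects(fit))
      })
      if (!is.null(out)) {
        writeLines(rep_lines, file.path(out, paste0(f, "_report.txt")))
      } else writeLines(rep_lines)
    }
    if (!is.null(out)) {
      utils::write.csv(fit$anova, file.path(out, paste0(f, "_anova.csv")),
                       row.names = FALSE, na = "")
    } else if (!render) {
      utils::write.csv(fit$anova, stdout(), row.names = FALSE, na = "")
    }
  }
}

cli_run <- function(opts) {
  cfg <- if (!is.null(opts$config)) read_study_config(opts$config)
  else study_config()
  if (!is.null(opts$seed)) cfg$seed <- as.integer(opts$seed)
  if (!is.null(opts$n_female)) cfg$n_female <- as.integer(opts$n_female)
  if (!is.null(opts$n_male)) cfg$n_male <- as.integer(opts$n_male)
  out <- cli_req(opts, "out")
  report <- run_study(cfg)
  render_report(report, dir = out)
  message("report written to ", out)
}
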