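# Two-way mixed-design (split-plot) ANOVA: one between-subjects factor
# (gender) crossed with one within-subjects factor (emotional state),
# subject as random block.  Classical cell-means algebra with
# Greenhouse-Geisser sphericity correction, partial omega-squared effect
# sizes, simple main effects and pairwise post hoc orderings.

#' Fit the two-way mixed-design ANOVA
#'
#' Fits the split-plot decomposition for one feature of a long feature
#' table: between stratum `SS_gender` against subjects-within-gender,
#' within stratum `SS_state` and `SS_interaction` against
#' state-by-subjects-within-gender, with Greenhouse-Geisser epsilon
#' applied to the within-stratum degrees of freedom. Subjects missing any
#' state are dropped listwise with a warning.
#'
#' @param data long data frame with columns `subject_id`, `gender`,
#'   `emotion`, `value` and optionally `feature`.
#' @param feature when `data` has a `feature` column, which feature to
#'   analyze.
#' @param alpha significance level used by reporting methods.
#' @param correction `"greenhouse-geisser"` (default) or `"none"`.
#' @return an object of class `mixed_anova`; see [print.mixed_anova()],
#'   [summary.mixed_anova()], [simple_main_effects()],
#'   [posthoc_pairwise()].
#' @export
#' @examples
#' tab <- expand.grid(subject_id = sprintf("S%02d", 1:8),
#'                    emotion = pad_emotions(), stringsAsFactors = FALSE)
#' tab$gender <- ifelse(tab$subject_id <= "S04", "female", "male")
#' set.seed(1); tab$value <- rnorm(nrow(tab))
#' fit <- mixed_anova(tab)
#' fit
mixed_anova <- function(data, feature = NULL, alpha = 0.05,
                        correction = c("greenhouse-geisser", "none")) {
  correction <- match.arg(correction)
  data <- as.data.frame(data)
  if (!is.null(feature) && "feature" %in% names(data)) {
    data <- data[data$feature == feature, , drop = FALSE]
    if (!nrow(data)) stop("no rows for feature '", feature, "'",
                          call. = FALSE)
  }
  need <- c("subject_id", "gender", "emotion", "value")
  if (!all(need %in% names(data))) {
    stop("feature table lacks columns: ",
         paste(setdiff(need, names(data)), collapse = ", "), call. = FALSE)
  }
  emo <- as.character(data$emotion)
  levels_emo <- if (all(unique(emo) %in% pad_emotions())) {
    intersect(pad_emotions(), unique(emo))
  } else sort(unique(emo))
  sid <- as.character(data$subject_id)
  subjects <- unique(sid)
  Y <- matrix(NA_real_, length(subjects), length(levels_emo),
              dimnames = list(subjects, levels_emo))
  Y[cbind(match(sid, subjects), match(emo, levels_emo))] <- data$value
  gender <- data$gender[match(subjects, sid)]
  # nesting check: a subject must belong to exactly one gender
  gl <- tapply(as.character(data$gender), sid, function(g)
    length(unique(g)))
  if (any(gl > 1L)) {
    stop("subject(s) appear under more than one gender: ",
         paste(names(gl)[gl > 1L], collapse = ", "), call. = FALSE)
  }
  complete <- stats::complete.cases(Y)
  if (!all(complete)) {
    warning("dropping ", sum(!complete),
            " subject(s) with incomplete within-design: ",
            paste(subjects[!complete], collapse = ", "), call. = FALSE)
    Y <- Y[complete, , drop = FALSE]
    gender <- gender[complete]
  }
  fit <- mixed_anova_fit(Y, as.character(gender), alpha = alpha,
                         correction = correction)
  fit$feature <- feature
  fit$call <- match.call()
  fit
}

#' Low-level mixed-design ANOVA on a subject-by-state matrix
#'
#' The computational core behind [mixed_anova()], convenient for
#' simulation studies: rows are subjects, columns the within-subject
#' states, `groups` the between-subjects factor. Balanced groups use the
#' exact classical decomposition; unbalanced groups fall back to an
#' unweighted-cell-means analysis with the harmonic mean group size
#' (type-III-equivalent weighting).
#'
#' @param Y numeric matrix, subjects x states, no missing values.
#' @param groups character/factor of length `nrow(Y)`.
#' @param alpha significance level stored for reporting.
#' @param correction `"greenhouse-geisser"` or `"none"`.
#' @return an object of class `mixed_anova`.
#' @export
mixed_anova_fit <- function(Y, groups, alpha = 0.05,
                            correction = c("greenhouse-geisser", "none")) {
  correction <- match.arg(correction)
  Y <- as.matrix(Y)
  groups <- as.character(groups)
  stopifnot(nrow(Y) == length(groups), !anyNA(Y))
  glev <- sort(unique(groups))
  G <- length(glev)
  k <- ncol(Y)
  if (k < 2L) stop("need at least 2 within-subject states", call. = FALSE)
  n_g <- table(factor(groups, glev))
  if (any(n_g < 2L)) {
    stop("each group needs at least 2 subjects", call. = FALSE)
  }
  n_subj <- nrow(Y)
  balanced <- length(unique(n_g)) == 1L
  grand <- mean(Y)
  subj_means <- rowMeans(Y)
  cell <- rowsum(Y, groups) / as.vector(n_g)        # G x k cell means
  group_means <- rowMeans(cell)
  SS_total <- sum((Y - grand)^2)
  SS_between <- k * sum((subj_means - grand)^2)
  SS_subj <- k * sum((subj_means - group_means[match(groups, glev)])^2)
  if (balanced) {
    n <- n_g[[1L]]
    state_means <- colMeans(Y)
    SS_gender <- n * k * sum((group_means - grand)^2)
    SS_state <- n * G * sum((colMeans(cell) - grand)^2)
    inter_resid <- sweep(sweep(cell, 1, group_means), 2, colMeans(cell)) +
      grand
    SS_inter <- n * sum(inter_resid^2)
  } else {
    n_h <- 1 / mean(1 / as.vector(n_g))
    gg <- mean(cell)
    SS_gender <- n_h * k * sum((group_means - gg)^2)
    SS_state <- n_h * G * sum((colMeans(cell) - gg)^2)
    inter_resid <- sweep(sweep(cell, 1, group_means), 2, colMeans(cell)) +
      gg
    SS_inter <- n_h * sum(inter_resid^2)
  }
  # residual within stratum, exact in both cases
  fitted_within <- cell[match(groups, glev), , drop = FALSE] +
    (subj_means - group_means[match(groups, glev)])
  SS_err <- sum((Y - fitted_within)^2)
  df <- c(gender = G - 1, state = k - 1, inter = (G - 1) * (k - 1),
          subj = n_subj - G, err = (n_subj - G) * (k - 1))
  MS <- c(SS_gender, SS_state, SS_inter, SS_subj, SS_err) / df
  eps <- if (correction == "greenhouse-geisser") {
    S <- pooled_within_cov(Y, groups, glev)
    greenhouse_geisser_epsilon(S)
  } else 1
  F_gender <- unname(MS[1] / MS[4])
  F_state <- unname(MS[2] / MS[5])
  F_inter <- unname(MS[3] / MS[5])
  df_corr <- df
  df_corr["state"] <- df["state"] * eps
  df_corr["inter"] <- df["inter"] * eps
  df_corr["err"] <- df["err"] * eps
  p <- c(
    gender = stats::pf(F_gender, df[["gender"]], df[["subj"]],
                       lower.tail = FALSE),
    state = stats::pf(F_state, df_corr[["state"]], df_corr[["err"]],
                      lower.tail = FALSE),
    inter = stats::pf(F_inter, df_corr[["inter"]], df_corr[["err"]],
                      lower.tail = FALSE)
  )
  n_obs <- n_subj * k
  omega <- c(
    gender = omega_sq_partial(SS_gender, df[["gender"]], MS[[4]], n_obs),
    state = omega_sq_partial(SS_state, df[["state"]], MS[[5]], n_obs),
    inter = omega_sq_partial(SS_inter, df[["inter"]], MS[[5]], n_obs)
  )
  tab <- data.frame(
    effect = c("gender", "state", "gender:state", "block", "error"),
    SS = c(SS_gender, SS_state, SS_inter, SS_subj, SS_err),
    df = as.numeric(df),
    df_corr = as.numeric(c(df["gender"], df_corr["state"],
                           df_corr["inter"], df["subj"], df_corr["err"])),
    MS = as.numeric(MS),
    F = c(F_gender, F_state, F_inter, NA, NA),
    p = c(p[["gender"]], p[["state"]], p[["inter"]], NA, NA),
    omega_sq = c(omega[["gender"]], omega[["state"]], omega[["inter"]],
                 NA, NA),
    stringsAsFactors = FALSE
  )
  cm <- t(cell)  # k x G, states in rows
  structure(list(anova = tab, epsilon_gg = eps,
                 cell_means = cm, marginal_means = marginal_means(cm),
                 Y = Y, groups = groups, group_levels = glev,
                 emotions = colnames(Y) %||%
                   paste0("state", seq_len(k)),
                 alpha = alpha, correction = correction,
                 feature = NULL),
            class = "mixed_anova")
}

# pooled within-group covariance of the subject-by-state matrix
pooled_within_cov <- function(Y, groups, glev = sort(unique(groups))) {
  S <- 0
  for (g in glev) {
    Yg <- Y[groups == g, , drop = FALSE]
    S <- S + (nrow(Yg) - 1) * stats::cov(Yg)
  }
  S / (nrow(Y) - length(glev))
}

#' Greenhouse-Geisser sphericity epsilon
#'
#' `epsilon = (sum(lambda))^2 / ((k - 1) * sum(lambda^2))` where `lambda`
#' are the eigenvalues of the double-centered within-subject covariance
#' matrix; clamped to `[1 / (k - 1), 1]`. Compound-symmetric covariance
#' gives 1 (sphericity holds); a rank-1 covariance gives the lower bound.
#'
#' @param S k x k within-subject sample covariance matrix.
#' @return the epsilon estimate.
#' @export
greenhouse_geisser_epsilon <- function(S) {
  S <- as.matrix(S)
  k <- ncol(S)
  stopifnot(nrow(S) == k, k >= 2)
  H <- diag(k) - 1 / k
  C <- H %*% S %*% H
  lambda <- eigen(C, symmetric = TRUE, only.values = TRUE)$values
  lambda <- pmax(lambda, 0)
  denom <- (k - 1) * sum(lambda^2)
  if (denom <= .Machine$double.eps * sum(lambda)^2 || sum(lambda) <= 0) {
    warning("degenerate within-subject covariance; ",
            "epsilon set to the lower bound", call. = FALSE)
    return(1 / (k - 1))
  }
  min(1, max(1 / (k - 1), sum(lambda)^2 / denom))
}

omega_sq_partial <- function(SS_eff, df_eff, MS_err, n_obs) {
  max(0, (SS_eff - df_eff * MS_err) / (SS_eff + (n_obs - df_eff) * MS_err))
}

#' Partial omega-squared of a fitted effect
#'
#' `(SS_eff - df_eff * MS_err) / (SS_eff + (n_obs - df_eff) * MS_err)`,
#' floored at 0, with the effect's own error stratum (the block mean
#' square for gender, the within-stratum error for state and the
#' interaction).
#'
#' @param fit a [mixed_anova()] object.
#' @param effect `"gender"`, `"state"` or `"gender:state"`.
#' @return partial omega-squared.
#' @export
omega_squared <- function(fit, effect = c("gender", "state",
                                          "gender:state")) {
  stopifnot(inherits(fit, "mixed_anova"))
  effect <- match.arg(effect)
  fit$anova$omega_sq[fit$anova$effect == effect]
}

#' Unweighted marginal means of a gender-by-state cell-mean table
#'
#' State marginal = unweighted mean of the gender cell means; gender
#' marginal = unweighted mean of that gender's state cell means.
#'
#' @param cell_means states x genders matrix (or data frame) of cell
#'   means; a single cell degenerates to itself.
#' @return list with `state`, `gender` and `grand` components.
#' @export
#' @examples
#' cm <- matrix(c(0.52, 0.48), 1, 2,
#'              dimnames = list("bored", c("female", "male")))
#' marginal_means(cm)$state  # 0.50
marginal_means <- function(cell_means) {
  m <- as.matrix(cell_means)
  if (anyNA(m)) stop("missing cells in the cell-mean table", call. = FALSE)
  list(state = rowMeans(m), gender = colMeans(m), grand = mean(m))
}

#' @export
print.mixed_anova <- function(x, ...) {
  cat("Two-way mixed-design ANOVA",
      if (!is.null(x$feature)) paste0(" of ", x$feature), "\n", sep = "")
  cat(sprintf("  %d subjects (%s), %d states; Greenhouse-Geisser eps = %.3f\n",
              nrow(x$Y),
              paste(sprintf("%s n=%d", x$group_levels,
                            as.integer(table(factor(x$groups,
                                                    x$group_levels)))),
                    collapse = ", "),
              ncol(x$Y), x$epsilon_gg))
  tab <- x$anova
  out <- data.frame(
    Variable = c("Gender", "State", "Gender X state", "Block", "Error"),
    SS = round_half_up(tab$SS, 2),
    Df = round_half_up(tab$df_corr, 2),
    MS = round_half_up(tab$MS, 2),
    F = ifelse(is.na(tab$F), "",
               paste0(round_half_up(tab$F, 2), stars(tab$p))),
    p = ifelse(is.na(tab$p), "", format.pval(tab$p, digits = 3)),
    omega_sq = ifelse(is.na(tab$omega_sq), "",
                      round_half_up(tab$omega_sq, 2))
  )
  print(out, row.names = FALSE)
  invisible(x)
}

#' Summarize a mixed-design fit
#'
#' Adds simple main effects and the pooled post hoc ordering to the
#' ANOVA table.
#'
#' @param object a [mixed_anova()] fit.
#' @param ... passed to [simple_main_effects()].
#' @return an object of class `summary.mixed_anova`.
#' @export
summary.mixed_anova <- function(object, ...) {
  structure(list(fit = object,
                 simple = simple_main_effects(object, ...),
                 posthoc = posthoc_pairwise(object, scope = "pooled")),
            class = "summary.mixed_anova")
}

#' @export
print.summary.mixed_anova <- function(x, ...) {
  print(x$fit)
  cat("\n")
  print(x$simple)
  cat("\nPooled post hoc ordering: ",
      paste(posthoc_notation(x$posthoc), collapse = "; "), "\n", sep = "")
  invisible(x)
}

#' @export
coef.mixed_anova <- function(object, ...) object$cell_means

#' @export
fitted.mixed_anova <- function(object, ...) {
  gi <- match(object$groups, object$group_levels)
  cell <- t(object$cell_means)  # G x k
  cell[gi, , drop = FALSE] +
    (rowMeans(object$Y) - rowMeans(cell)[gi])
}

#' @export
residuals.mixed_anova <- function(object, ...) {
  object$Y - fitted(object)
}

#' @export
plot.mixed_anova <- function(x, ...) {
  cm <- x$cell_means
  graphics::matplot(seq_len(nrow(cm)), cm, type = "b", pch = 19,
                    lty = 1, xaxt = "n", xlab = "emotional state",
                    ylab = x$feature %||% "cell mean", ...)
  graphics::axis(1, at = seq_len(nrow(cm)), labels = rownames(cm),
                 las = 2, cex.axis = 0.8)
  graphics::legend("topleft", legend = colnames(cm), col = seq_len(ncol(cm)),
                   lty = 1, pch = 19, bty = "n")
  invisible(x)
}

# one-group repeated-measures ANOVA with its own GG correction
rm_anova_one_group <- function(Yg, correction = "greenhouse-geisser") {
  n <- nrow(Yg)
  k <- ncol(Yg)
  grand <- mean(Yg)
  col_m <- colMeans(Yg)
  row_m <- rowMeans(Yg)
  SS_state <- n * sum((col_m - grand)^2)
  SS_err <- sum((Yg - outer(row_m, rep(1, k)) -
                   outer(rep(1, n), col_m) + grand)^2)
  df1 <- k - 1
  df2 <- (n - 1) * (k - 1)
  eps <- if (correction == "greenhouse-geisser" && n > 1) {
    greenhouse_geisser_epsilon(stats::cov(Yg))
  } else 1
  F_val <- (SS_state / df1) / (SS_err / df2)
  list(SS = SS_state, df1 = df1, df2 = df2, eps = eps,
       MS = SS_state / df1, F = F_val,
       p = stats::pf(F_val, df1 * eps, df2 * eps, lower.tail = FALSE))
}

#' Simple main effects of the mixed design
#'
#' State-within-gender: a one-way repeated-measures ANOVA per gender with
#' its own Greenhouse-Geisser correction and a within-gender post hoc
#' ordering. Gender-within-state: an independent two-sample comparison
#' per emotional state (Welch by default), with the direction and both
#' means reported when significant.
#'
#' @param fit a [mixed_anova()] object.
#' @param alpha significance level for reporting directions.
#' @param gender_test `"welch"` (default) or `"pooled"` variance
#'   two-sample test.
#' @param method post hoc p adjustment passed to [posthoc_pairwise()].
#' @return an object of class `simple_effects`.
#' @export
simple_main_effects <- function(fit, alpha = fit$alpha,
                                gender_test = c("welch", "pooled"),
                                method = "bonferroni") {
  stopifnot(inherits(fit, "mixed_anova"))
  gender_test <- match.arg(gender_test)
  glev <- fit$group_levels
  state_within <- lapply(glev, function(g) {
    Yg <- fit$Y[fit$groups == g, , drop = FALSE]
    res <- rm_anova_one_group(Yg, fit$correction)
    res$posthoc <- posthoc_pairwise(fit, scope = g, alpha = alpha,
                                    method = method)
    res
  })
  names(state_within) <- glev
  emo <- fit$emotions
  gw <- lapply(seq_along(emo), function(s) {
    vals <- split(fit$Y[, s], factor(fit$groups, glev))
    tt <- stats::t.test(vals[[1]], vals[[2]],
                        var.equal = gender_test == "pooled")
    m <- vapply(vals, mean, numeric(1))
    hi <- which.max(m)
    lo <- which.min(m)
    list(emotion = emo[s], F = unname(tt$statistic^2),
         df = unname(tt$parameter), p = tt$p.value,
         means = m,
         direction = if (tt$p.value < alpha && m[hi] != m[lo]) {
           sprintf("%s (M = %s) > %s (M = %s)",
                   tools_title(glev[hi]), format(round_half_up(m[hi], 2)),
                   tools_title(glev[lo]), format(round_half_up(m[lo], 2)))
         } else "")
  })
  names(gw) <- emo
  structure(list(state_within_gender = state_within,
                 gender_within_state = gw, alpha = alpha,
                 feature = fit$feature),
            class = "simple_effects")
}

tools_title <- function(x) {
  paste0(toupper(substring(x, 1, 1)), substring(x, 2))
}

#' @export
print.simple_effects <- function(x, ...) {
  cat("Simple main effects",
      if (!is.null(x$feature)) paste0(" of ", x$feature), "\n", sep = "")
  cat("State within gender:\n")
  for (g in names(x$state_within_gender)) {
    r <- x$state_within_gender[[g]]
    cat(sprintf("  %-7s SS %.2f  Df %.2f  MS %.2f  F %.2f%s  %s\n",
                tools_title(g), r$SS, r$df1 * r$eps, r$MS, r$F,
                stars(r$p),
                paste(posthoc_notation(r$posthoc), collapse = "; ")))
  }
  cat("Gender within state:\n")
  for (s in names(x$gender_within_state)) {
    r <- x$gender_within_state[[s]]
    cat(sprintf("  %-10s F %.2f%s  %s\n", tools_title(s), r$F,
                stars(r$p), r$direction))
  }
  invisible(x)
}

#' Pairwise post hoc comparisons of the emotional states
#'
#' All state pairs are compared with paired t tests over the subjects in
#' scope (one gender or pooled), p-values adjusted by the configured
#' method (Bonferroni by default). Significant pairs are reported as
#' directional orderings `(i) > (j)` using the ordinal emotion ids.
#'
#' @param fit a [mixed_anova()] object.
#' @param scope `"pooled"` or one of the gender levels.
#' @param alpha significance level.
#' @param method a [stats::p.adjust()] method.
#' @return an object of class `posthoc_pairs`: a data frame of all pairs
#'   with raw and adjusted p-values and directions.
#' @export
posthoc_pairwise <- function(fit, scope = "pooled", alpha = fit$alpha,
                             method = "bonferroni") {
  stopifnot(inherits(fit, "mixed_anova"))
  Y <- if (identical(scope, "pooled")) fit$Y else {
    if (!scope %in% fit$group_levels) {
      stop("scope must be \"pooled\" or one of: ",
           paste(fit$group_levels, collapse = ", "), call. = FALSE)
    }
    fit$Y[fit$groups == scope, , drop = FALSE]
  }
  emo <- fit$emotions
  ids <- if (all(emo %in% pad_emotions())) emotion_ordinal(emo)
  else seq_along(emo)
  pairs <- utils::combn(seq_along(emo), 2)
  res <- apply(pairs, 2, function(ij) {
    i <- ij[1]; j <- ij[2]
    d <- Y[, i] - Y[, j]
    p <- if (stats::sd(d) == 0) 1 else stats::t.test(d)$p.value
    c(i = i, j = j, mean_i = mean(Y[, i]), mean_j = mean(Y[, j]), p = p)
  })
  res <- as.data.frame(t(res))
  res$p_adj <- stats::p.adjust(res$p, method = method)
  out <- data.frame(
    id_i = ids[res$i], id_j = ids[res$j],
    emotion_i = emo[res$i], emotion_j = emo[res$j],
    mean_i = res$mean_i, mean_j = res$mean_j,
    p = res$p, p_adj = res$p_adj,
    significant = res$p_adj < alpha & res$mean_i != res$mean_j,
    stringsAsFactors = FALSE
  )
  structure(out, class = c("posthoc_pairs", "data.frame"),
            alpha = alpha, method = method, scope = scope)
}

#' Render a post hoc result in the `(i) > (j)` table notation
#'
#' For each state that significantly exceeds others, one string
#' `"(i) > (j1)-(j2), ..."` with consecutive ids compressed into ranges.
#' An all-equal result renders as an empty character vector.
#'
#' @param ph a [posthoc_pairwise()] result.
#' @return character vector, one entry per dominating state.
#' @export
posthoc_notation <- function(ph) {
  sig <- ph[ph$significant, , drop = FALSE]
  if (!nrow(sig)) return(character(0))
  winner <- ifelse(sig$mean_i > sig$mean_j, sig$id_i, sig$id_j)
  loser <- ifelse(sig$mean_i > sig$mean_j, sig$id_j, sig$id_i)
  out <- vapply(sort(unique(winner)), function(w) {
    sprintf("(%d) > %s", w, format_id_ranges(loser[winner == w]))
  }, character(1))
  unname(out)
}
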