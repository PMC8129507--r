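random_balanced <- function(n, k = 9, seed = 1) {
  set.seed(seed)
  Y <- matrix(rnorm(2 * n * k), 2 * n, k)
  colnames(Y) <- pad_emotions()[seq_len(k)]
  list(Y = Y, g = rep(c("female", "male"), each = n))
}

long_table <- function(Y, g, subjects = sprintf("S%02d", seq_len(nrow(Y)))) {
  data.frame(subject_id = rep(subjects, ncol(Y)),
             gender = rep(g, ncol(Y)),
             emotion = rep(colnames(Y), each = nrow(Y)),
             value = as.vector(Y), stringsAsFactors = FALSE)
}

test_that("split-plot sums of squares match the brute-force oracle", {
  d <- random_balanced(3, k = 2, seed = 10)   # tiny 2 x 2 x (3 subjects)
  fit <- mixed_anova_fit(d$Y, d$g)
  ss <- oracle_split_plot_ss(d$Y, d$g)
  expect_equal(fit$anova$SS, with(ss, c(gender, state, inter, subj, err)),
               tolerance = 1e-12)
  expect_equal(sum(fit$anova$SS), ss$total, tolerance = 1e-12)

  d <- random_balanced(5, k = 9, seed = 11)
  fit <- mixed_anova_fit(d$Y, d$g)
  ss <- oracle_split_plot_ss(d$Y, d$g)
  expect_equal(fit$anova$SS, with(ss, c(gender, state, inter, subj, err)),
               tolerance = 1e-12)
  expect_lt(abs(sum(fit$anova$SS) / ss$total - 1), 1e-10)
})

test_that("F statistics match the base aov split-plot reference", {
  for (seed in 1:10) {
    d <- random_balanced(sample(3:8, 1), k = sample(c(3, 5, 9), 1),
                         seed = 100 + seed)
    fit <- mixed_anova_fit(d$Y, d$g)
    df <- data.frame(y = as.vector(d$Y),
                     subj = factor(rep(seq_len(nrow(d$Y)), ncol(d$Y))),
                     g = factor(rep(d$g, ncol(d$Y))),
                     s = factor(rep(colnames(d$Y), each = nrow(d$Y))))
    a <- summary(stats::aov(y ~ g * s + Error(subj / s), data = df))
    f_ref <- c(a[[1]][[1]]["g", "F value"],
               a[[2]][[1]]["s", "F value"],
               a[[2]][[1]]["g:s", "F value"])
    expect_equal(fit$anova$F[1:3], f_ref, tolerance = 1e-6)
  }
})

test_that("uncorrected degrees of freedom follow the design", {
  d <- random_balanced(31, k = 9, seed = 3)
  fit <- mixed_anova_fit(d$Y, d$g)
  expect_equal(fit$anova$df, c(1, 8, 8, 60, 480))
  expect_gte(fit$epsilon_gg, 1 / 8)
  expect_lte(fit$epsilon_gg, 1)
})

test_that("a 2-level within factor in one group reduces to the paired t-test", {
  set.seed(20)
  Y <- matrix(rnorm(24), 12, 2)
  f <- emovoice:::rm_anova_one_group(Y, correction = "none")
  tt <- t.test(Y[, 1], Y[, 2], paired = TRUE)
  expect_equal(f$F, unname(tt$statistic)^2, tolerance = 1e-12)
  expect_equal(f$p, tt$p.value, tolerance = 1e-12)
})

test_that("Greenhouse-Geisser epsilon has its analytic boundary values", {
  k <- 9
  expect_equal(greenhouse_geisser_epsilon(diag(k) * 0.5 + 0.5), 1)
  v <- rnorm(k)
  expect_warning(e1 <- greenhouse_geisser_epsilon(outer(v, v) * 0 + 1e-300),
                 "degenerate")
  expect_equal(e1, 1 / (k - 1))
  expect_equal(greenhouse_geisser_epsilon(outer(v, v)), 1 / (k - 1))
  # random Wishart covariance: matches the naive eigenvalue formula
  set.seed(31)
  for (i in 1:5) {
    X <- matrix(rnorm(30 * k), 30, k) %*% matrix(rnorm(k * k), k)
    S <- cov(X)
    H <- diag(k) - 1 / k
    lam <- eigen(H %*% S %*% H, symmetric = TRUE)$values
    naive <- sum(lam)^2 / ((k - 1) * sum(lam^2))
    expect_equal(greenhouse_geisser_epsilon(S), naive, tolerance = 1e-10)
  }
})

test_that("partial omega-squared floors at zero and grows with effect size", {
  d <- random_balanced(10, k = 9, seed = 40)
  fit0 <- mixed_anova_fit(d$Y, d$g)
  expect_gte(omega_squared(fit0, "state"), 0)
  omegas <- vapply(c(0, 0.5, 1.5), function(es) {
    set.seed(41)
    Y <- d$Y + outer(ifelse(d$g == "female", 1, -1),
                     seq(-es, es, length.out = 9))
    omega_squared(mixed_anova_fit(Y, d$g), "gender:state")
  }, numeric(1))
  expect_true(all(diff(omegas) > 0))
  expect_lt(omegas[1], 0.05)
})

test_that("mixed_anova accepts long tables and drops incomplete subjects", {
  d <- random_balanced(4, k = 9, seed = 50)
  tab <- long_table(d$Y, d$g)
  fit <- mixed_anova(tab)
  expect_equal(fit$anova$F, mixed_anova_fit(d$Y, d$g)$anova$F)
  # remove one observation: its subject is dropped with a warning
  tab2 <- tab[-5, ]
  expect_warning(fit2 <- mixed_anova(tab2), "incomplete")
  expect_equal(nrow(fit2$Y), 7)
  # a subject under two genders is an error
  tab3 <- tab
  tab3$gender[tab3$subject_id == "S01" & tab3$emotion == "bored"] <- "male"
  expect_error(mixed_anova(tab3), "more than one gender")
  expect_error(mixed_anova_fit(d$Y[1:3, ], c("f", "f", "m")),
               "at least 2 subjects")
})

test_that("simple main effects report directions that flip with the labels", {
  d <- random_balanced(8, k = 9, seed = 60)
  Y <- d$Y
  Y[d$g == "female", ] <- Y[d$g == "female", ] + 2
  fit <- mixed_anova_fit(Y, d$g)
  sme <- simple_main_effects(fit)
  dirs <- vapply(sme$gender_within_state, function(r) r$direction,
                 character(1))
  expect_true(all(grepl("^Female", dirs[dirs != ""])))
  # swap genders: every direction flips
  g2 <- ifelse(d$g == "female", "male", "female")
  sme2 <- simple_main_effects(mixed_anova_fit(Y, g2))
  dirs2 <- vapply(sme2$gender_within_state, function(r) r$direction,
                  character(1))
  expect_true(all(grepl("^Male", dirs2[dirs2 != ""])))
  expect_equal(dirs != "", dirs2 != "")
  # per-gender repeated-measures test carries its own epsilon
  for (g in c("female", "male")) {
    r <- sme$state_within_gender[[g]]
    expect_gte(r$eps, 1 / 8)
    expect_lte(r$eps, 1)
  }
})

test_that("post hoc pairs are adjusted, directional and consistent", {
  d <- random_balanced(8, k = 9, seed = 70)
  Y <- d$Y
  Y[, 3] <- Y[, 3] + 5   # bored clearly above everything
  fit <- mixed_anova_fit(Y, d$g)
  ph <- posthoc_pairwise(fit, scope = "pooled")
  expect_true(all(ph$p_adj >= ph$p))
  expect_true(all(ph$p_adj <= 1))
  # no pair in both directions
  key <- paste(pmin(ph$id_i, ph$id_j), pmax(ph$id_i, ph$id_j))
  expect_false(any(duplicated(key)))
  no <- posthoc_notation(ph)
  expect_true(any(grepl("^\\(3\\) > ", no)))
  # all-equal means give an empty result
  Yc <- matrix(rep(rnorm(nrow(Y)), 9), nrow(Y), 9,
               dimnames = dimnames(Y))
  ph0 <- posthoc_pairwise(mixed_anova_fit(Yc, d$g), scope = "pooled")
  expect_length(posthoc_notation(ph0), 0)
})

test_that("marginal means are the unweighted cell-mean averages", {
  cm <- matrix(c(0.52, 0.48), 1, 2,
               dimnames = list("bored", c("female", "male")))
  expect_equal(unname(marginal_means(cm)$state), 0.50)
  one <- matrix(3.7, 1, 1, dimnames = list("neutral", "female"))
  mm <- marginal_means(one)
  expect_equal(unname(mm$state), 3.7)
  expect_equal(unname(mm$gender), 3.7)
  expect_error(marginal_means(matrix(c(1, NA), 1, 2)), "missing cells")
})

test_that("unbalanced groups fall back to unweighted cell means", {
  set.seed(80)
  Y <- matrix(rnorm(11 * 5), 11, 5)
  colnames(Y) <- pad_emotions()[1:5]
  g <- rep(c("female", "male"), c(6, 5))
  fit <- mixed_anova_fit(Y, g)
  expect_true(all(is.finite(fit$anova$F[1:3])))
  expect_true(all(fit$anova$SS >= 0))
})

test_that("model methods expose means, fitted values and residuals", {
  d <- random_balanced(5, k = 9, seed = 90)
  fit <- mixed_anova_fit(d$Y, d$g)
  expect_equal(dim(coef(fit)), c(9L, 2L))
  expect_equal(fitted(fit) + residuals(fit), d$Y, ignore_attr = TRUE)
  # residual sum of squares equals the within-error stratum
  expect_equal(sum(residuals(fit)^2),
               fit$anova$SS[fit$anova$effect == "error"],
               tolerance = 1e-10)
  expect_output(print(fit), "Gender X state")
  expect_output(print(summary(fit)), "Simple main effects")
})
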