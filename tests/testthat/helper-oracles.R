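# Naive loop-based reference implementations of the perturbation
# statistics and of the split-plot sums of squares, kept deliberately
# independent of the package's vectorized code paths.

oracle_mean_period <- function(periods) {
  s <- 0
  for (t in periods) s <- s + t
  s / length(periods)
}

oracle_jitter_absolute <- function(periods) {
  s <- 0
  for (i in 2:length(periods)) s <- s + abs(periods[i] - periods[i - 1])
  s / (length(periods) - 1)
}

oracle_jitter_percent <- function(periods) {
  100 * oracle_jitter_absolute(periods) / oracle_mean_period(periods)
}

oracle_shimmer_percent <- function(amps) {
  s <- 0
  for (k in 2:length(amps)) s <- s + abs(amps[k] - amps[k - 1])
  100 * (s / (length(amps) - 1)) / oracle_mean_period(amps)
}

# Brute-force split-plot sums of squares from explicit sums over cell and
# marginal means (balanced design only).
oracle_split_plot_ss <- function(Y, groups) {
  glev <- sort(unique(groups))
  n <- sum(groups == glev[1])
  k <- ncol(Y)
  G <- length(glev)
  grand <- mean(Y)
  SS <- list(total = 0, gender = 0, state = 0, inter = 0, subj = 0,
             err = 0)
  cell <- matrix(0, G, k)
  for (g in seq_along(glev)) {
    for (s in seq_len(k)) cell[g, s] <- mean(Y[groups == glev[g], s])
  }
  gmean <- rowMeans(cell)
  smean <- colMeans(cell)
  for (g in seq_along(glev)) {
    SS$gender <- SS$gender + n * k * (gmean[g] - grand)^2
    for (s in seq_len(k)) {
      SS$inter <- SS$inter +
        n * (cell[g, s] - gmean[g] - smean[s] + grand)^2
    }
  }
  for (s in seq_len(k)) SS$state <- SS$state + n * G * (smean[s] - grand)^2
  for (i in seq_len(nrow(Y))) {
    g <- match(groups[i], glev)
    mi <- mean(Y[i, ])
    SS$subj <- SS$subj + k * (mi - gmean[g])^2
    for (s in seq_len(k)) {
      SS$total <- SS$total + (Y[i, s] - grand)^2
      SS$err <- SS$err + (Y[i, s] - mi - cell[g, s] + gmean[g])^2
    }
  }
  lapply(SS, unname)
}
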