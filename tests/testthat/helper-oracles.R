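# Independent oracles used to cross-check the package implementations.
# These deliberately share no code with the package internals.

# Brute-force O(N^2) sample-entropy oracle (Richman-Moorman counting).
sampen_oracle <- function(x, m = 2, r) {
  n <- length(x)
  nt <- n - m
  B <- 0
  A <- 0
  for (i in 1:(nt - 1)) {
    js <- (i + 1):nt
    dmax <- abs(x[i] - x[js])
    if (m > 1) for (k in 1:(m - 1)) dmax <- pmax(dmax, abs(x[i + k] - x[js + k]))
    bm <- dmax <= r
    B <- B + sum(bm)
    A <- A + sum(bm & (abs(x[i + m] - x[js + m]) <= r))
  }
  if (B == 0 || A == 0) return(NA_real_)
  -log(A / B)
}

# Exact two-sided Mann-Whitney p-value by full enumeration of all
# C(na+nb, na) rank assignments (no ties assumed).
wilcox_exact_oracle <- function(a, b) {
  na <- length(a)
  nb <- length(b)
  rk <- rank(c(a, b))
  u_obs <- sum(rk[seq_len(na)]) - na * (na + 1) / 2
  combos <- combn(na + nb, na)
  rk_all <- rank(seq_len(na + nb))  # 1..n, no ties
  u_all <- colSums(matrix(rk_all[combos], nrow = na)) - na * (na + 1) / 2
  if (u_obs <= na * nb / 2) min(1, 2 * mean(u_all <= u_obs))
  else min(1, 2 * mean(u_all >= u_obs))
}

# Rank-transform-then-Pearson Spearman oracle (average ranks for ties).
spearman_oracle <- function(x, y) {
  stats::cor(rank(x, ties.method = "average"), rank(y, ties.method = "average"))
}

# Kolmogorov-Smirnov two-sample statistic (suppress the ties warning).
ks_stat <- function(x, y) {
  suppressWarnings(stats::ks.test(x, y)$statistic)
}

# A small synthetic metadata-only cohort table with feature columns, for
# statistics tests that do not need simulated signals.
make_meta_cohort <- function(n_sg = 40, n_mg = 40, seed = 1,
                             ga_max_sg = 37, sg_term = 0) {
  set.seed(seed)
  ga_sg <- runif(n_sg, 26, ga_max_sg)
  ga_mg <- runif(n_mg, 26, 37)
  df <- data.frame(
    recording_id = sprintf("R%03d", seq_len(n_sg + n_mg + sg_term)),
    woman_id = sprintf("W%03d", seq_len(n_sg + n_mg + sg_term)),
    ga_wog = c(ga_sg, ga_mg, runif(sg_term, 38.5, 41.5)),
    gestation_type = c(rep("SG", n_sg), rep("MG", n_mg), rep("SG", sg_term)),
    stage_label = c(rep("routine", n_sg + n_mg),
                    sample(c("TNL", "APL"), sg_term, replace = TRUE)),
    stringsAsFactors = FALSE)
  df$median_ppa <- 1 + 0.1 * (df$ga_wog - 26) + rnorm(nrow(df), 0, 0.2)
  df$median_khe <- 4 + 0.3 * (df$ga_wog - 26) + rnorm(nrow(df), 0, 0.5)
  df$median_mdf <- 0.5 + rnorm(nrow(df), 0, 0.03)
  df$median_sampen <- 1.2 - 0.03 * (df$ga_wog - 26) + rnorm(nrow(df), 0, 0.1)
  df
}
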