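# Independent oracles, deliberately written from scratch with explicit
# loops and sum formulas so they share no code path with the package.

# Brute-force k-of-m classification: enumerates parameters, recomputes the
# control mean/SD from first principles, and compares values directly.
brute_force_labels <- function(cohort_df, param_dirs, k = 4,
                               sd_multiplier = 1, timepoint = "post_trauma") {
  df <- cohort_df[cohort_df$timepoint == timepoint, , drop = FALSE]
  ctrl <- df[df$group == "control", , drop = FALSE]
  labels <- character(nrow(df))
  counts <- integer(nrow(df))
  for (i in seq_len(nrow(df))) {
    n_flags <- 0L
    for (p in names(param_dirs)) {
      x <- ctrl[[p]]
      n <- length(x)
      m <- sum(x) / n
      s <- sqrt(sum((x - m)^2) / (n - 1))
      v <- df[[p]][i]
      flagged <- switch(param_dirs[[p]],
        low_is_affected  = v < m - sd_multiplier * s,
        high_is_affected = v > m + sd_multiplier * s,
        two_sided = v < m - sd_multiplier * s | v > m + sd_multiplier * s)
      if (flagged) n_flags <- n_flags + 1L
    }
    counts[i] <- n_flags
    labels[i] <- if (n_flags >= k) "affected" else "unaffected"
  }
  data.frame(animal_id = df$animal_id, flag_count = counts, label = labels,
             stringsAsFactors = FALSE)
}

# Full hypergeometric enumeration of the two-sided Fisher p-value
# (minimum-likelihood rule, standard 1 + 1e-7 relative tolerance on the
# point-probability comparison).
fisher_enumeration_p <- function(tab) {
  a <- tab[1, 1]; b <- tab[1, 2]; c_ <- tab[2, 1]; d <- tab[2, 2]
  r1 <- a + b; c1 <- a + c_; n <- a + b + c_ + d
  support <- max(0, c1 - (n - r1)):min(r1, c1)
  probs <- vapply(support, function(x)
    exp(lchoose(r1, x) + lchoose(n - r1, c1 - x) - lchoose(n, c1)), 0)
  p_obs <- probs[match(a, support)]
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# random small cohort in the wide schema, IBP1 parameter names
random_cohort_df <- function(n_control, n_exposed, params,
                             timepoint = "post_trauma") {
  n <- n_control + n_exposed
  df <- data.frame(
    animal_id = sprintf("A%02d", seq_len(n)),
    group = rep(c("control", "exposed"), c(n_control, n_exposed)),
    timepoint = timepoint, stringsAsFactors = FALSE)
  for (p in params) df[[p]] <- round(stats::rnorm(n, 100, 15), 3)
  df
}
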