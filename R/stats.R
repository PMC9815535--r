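#' Fisher exact test on a 2x2 contingency table
#'
#' Exact hypergeometric test of association between cohort (rows) and
#' classification category (columns). The two-sided p-value follows the
#' minimum-likelihood convention: the sum of the probabilities of all
#' tables with the observed margins whose point probability does not
#' exceed that of the observed table. The odds ratio reported is the
#' sample odds ratio `a*d / (b*c)` (infinite when `b*c = 0` with
#' `a*d > 0`, undefined 0/0 reported as NaN).
#'
#' @param table 2x2 matrix of non-negative integer counts, or a length-4
#'   vector `c(a, b, c, d)` filled by row.
#' @param sided `"two_sided"` (default), `"less"` or `"greater"` (one-sided
#'   on the \[1,1\] cell).
#' @return List of class `"ibp_fisher"`: `p`, `odds_ratio`, `table`,
#'   `sided`.
#' @examples
#' fisher_exact_2x2(matrix(c(2, 14, 41, 31), 2, byrow = TRUE))$p  # 0.0017...
#' @export
fisher_exact_2x2 <- function(table, sided = c("two_sided", "less", "greater")) {
  sided <- match.arg(sided)
  if (!is.matrix(table)) table <- matrix(as.numeric(table), 2, byrow = TRUE)
  if (!all(dim(table) == 2)) stop("table must be 2x2")
  if (any(table < 0) || any(table != round(table)))
    stop("cells must be non-negative integers")
  if (all(rowSums(table) == 0) || all(colSums(table) == 0))
    stop("table has no observations")
  alternative <- switch(sided, two_sided = "two.sided", sided)
  p <- stats::fisher.test(table, alternative = alternative)$p.value
  num <- table[1, 1] * table[2, 2]
  den <- table[1, 2] * table[2, 1]
  or <- if (den == 0) { if (num == 0) NaN else Inf } else num / den
  structure(list(p = unname(p), odds_ratio = or, table = table, sided = sided),
            class = "ibp_fisher")
}

#' @export
print.ibp_fisher <- function(x, ...) {
  cat(sprintf("Fisher exact test (%s): p = %.4g, odds ratio = %.4g\n",
              x$sided, x$p, x$odds_ratio))
  invisible(x)
}

#' Normality-gated group comparison
#'
#' The omnibus-plus-post-hoc procedure used for every group-level contrast
#' of behavioral, expression and electrophysiological measures: each
#' group's distribution is tested with Shapiro-Wilk; if every group passes
#' at `alpha_normality` the comparison is parametric (one-way ANOVA,
#' pairwise Bonferroni-corrected t tests with pooled SD when the omnibus p
#' is significant), otherwise nonparametric (Kruskal-Wallis, Dunn's
#' rank-based pairwise test with Bonferroni multiplicity correction when
#' the omnibus p is significant). Post-hoc p-values are reported only when
#' the omnibus test rejects at `alpha`. No variance-homogeneity test is
#' applied.
#'
#' @param values_by_group Named list of numeric vectors, one per group
#'   (at least 2 groups, each with at least 3 observations).
#' @param alpha Omnibus significance level gating the post hoc (default
#'   0.05).
#' @param alpha_normality Per-group Shapiro-Wilk level (default 0.05).
#' @return List of class `"ibp_group_comparison"`: `groups`, `normality`
#'   (data frame: group, W, p), `gate_decision` (`"parametric"` or
#'   `"nonparametric"`), `omnibus` (test, statistic, df, p), `posthoc`
#'   (data frame group1/group2/p_adjusted, or NULL when the omnibus is not
#'   significant), `posthoc_method`, `alpha`, `alpha_normality`.
#' @export
compare_groups <- function(values_by_group, alpha = 0.05,
                           alpha_normality = 0.05) {
  stopifnot(is.list(values_by_group), length(values_by_group) >= 2)
  if (is.null(names(values_by_group)) || any(names(values_by_group) == ""))
    names(values_by_group) <- paste0("group", seq_along(values_by_group))
  sizes <- lengths(values_by_group)
  if (any(sizes < 3))
    stop("group(s) with fewer than 3 observations: ",
         paste(names(values_by_group)[sizes < 3], collapse = ", "))
  g <- names(values_by_group)
  values <- unlist(values_by_group, use.names = FALSE)
  groups <- factor(rep(g, sizes), levels = g)
  if (stats::var(values) == 0)
    stop("all observations identical across groups; comparison degenerate")

  normality <- do.call(rbind, lapply(g, function(gr) {
    v <- values_by_group[[gr]]
    if (stats::var(v) == 0)             # constant group: SW undefined, treat
      return(data.frame(group = gr, W = NA_real_, p = 0))  # as non-normal
    sw <- stats::shapiro.test(v)
    data.frame(group = gr, W = unname(sw$statistic), p = sw$p.value)
  }))
  parametric <- all(normality$p >= alpha_normality)

  if (parametric) {
    fit <- stats::aov(values ~ groups)
    an <- stats::anova(fit)
    omnibus <- list(test = "one-way ANOVA",
                    statistic = an[["F value"]][1],
                    df = unname(an[["Df"]]),
                    p = an[["Pr(>F)"]][1])
    posthoc_method <- "pairwise t (pooled SD), Bonferroni"
  } else {
    kw <- stats::kruskal.test(values, groups)
    omnibus <- list(test = "Kruskal-Wallis",
                    statistic = unname(kw$statistic),
                    df = unname(kw$parameter),
                    p = kw$p.value)
    posthoc_method <- "Dunn (Bonferroni)"
  }

  posthoc <- NULL
  if (!is.na(omnibus$p) && omnibus$p < alpha) {
    if (parametric) {
      pt <- stats::pairwise.t.test(values, groups, pool.sd = TRUE,
                                   p.adjust.method = "bonferroni")
      pm <- pt$p.value
      posthoc <- do.call(rbind, lapply(rownames(pm), function(r)
        do.call(rbind, lapply(colnames(pm), function(cn)
          if (!is.na(pm[r, cn]))
            data.frame(group1 = cn, group2 = r, p_adjusted = pm[r, cn])))))
    } else {
      posthoc <- dunn_test(values, groups)
    }
    rownames(posthoc) <- NULL
  }

  structure(list(groups = g, normality = normality,
                 gate_decision = if (parametric) "parametric" else "nonparametric",
                 omnibus = omnibus, posthoc = posthoc,
                 posthoc_method = posthoc_method,
                 alpha = alpha, alpha_normality = alpha_normality),
            class = "ibp_group_comparison")
}

#' Dunn's rank-based pairwise post-hoc test
#'
#' Pairwise z tests on mean ranks from the pooled (tie-corrected)
#' Kruskal-Wallis ranking, with Bonferroni correction over all pairs. The
#' z statistic for groups i, j is `(Rbar_i - Rbar_j) / sqrt((N(N+1)/12 -
#' T) (1/n_i + 1/n_j))` with tie term `T = sum(t^3 - t) / (12 (N - 1))`.
#'
#' @param values Numeric vector of all observations.
#' @param groups Factor of group membership, same length.
#' @return Data frame: `group1`, `group2`, `z`, `p_unadjusted`,
#'   `p_adjusted` (Bonferroni over all pairs, capped at 1).
#' @export
dunn_test <- function(values, groups) {
  groups <- droplevels(as.factor(groups))
  r <- rank(values)
  N <- length(values)
  ties <- table(values)
  tie_term <- sum(ties^3 - ties) / (12 * (N - 1))
  rbar <- tapply(r, groups, mean)
  n <- tapply(r, groups, length)
  g <- levels(groups)
  pairs <- utils::combn(g, 2)
  n_pairs <- ncol(pairs)
  out <- do.call(rbind, lapply(seq_len(n_pairs), function(i) {
    a <- pairs[1, i]; b <- pairs[2, i]
    se <- sqrt((N * (N + 1) / 12 - tie_term) * (1 / n[a] + 1 / n[b]))
    z <- (rbar[a] - rbar[b]) / se
    p <- 2 * stats::pnorm(-abs(z))
    data.frame(group1 = a, group2 = b, z = unname(z),
               p_unadjusted = unname(p),
               p_adjusted = unname(min(1, p * n_pairs)))
  }))
  rownames(out) <- NULL
  out
}

#' @export
print.ibp_group_comparison <- function(x, ...) {
  cat(sprintf("Group comparison (%s gate): %s\n", x$gate_decision,
              paste(x$groups, collapse = " / ")))
  cat(sprintf("  Shapiro-Wilk min p = %.4g (alpha_normality = %g)\n",
              min(x$normality$p), x$alpha_normality))
  cat(sprintf("  %s: statistic = %.4g, p = %.4g\n",
              x$omnibus$test, x$omnibus$statistic, x$omnibus$p))
  if (is.null(x$posthoc)) {
    cat("  no post hoc (omnibus p >= alpha)\n")
  } else {
    cat("  post hoc (", x$posthoc_method, "):\n", sep = "")
    for (i in seq_len(nrow(x$posthoc)))
      cat(sprintf("    %s vs %s: p_adj = %.4g\n", x$posthoc$group1[i],
                  x$posthoc$group2[i], x$posthoc$p_adjusted[i]))
  }
  invisible(x)
}

#' Per-group classification proportions
#'
#' Counts and percentages of each classification label within each group.
#' Percentages are computed over classifiable animals only; unclassifiable
#' records are counted separately. Percentages are reported raw and
#' rounded: to the nearest integer in general, to one decimal for the
#' control group (the reporting precision used for control base rates).
#'
#' @param classifications Classification data frame (from
#'   [profile_cohort()] or [predict.ibp()]) with columns `group`, `label`,
#'   or any data frame with those columns.
#' @param control_group Label whose percentages are rounded to one decimal.
#' @return List of class `"ibp_proportions"`: `table` (data frame: group,
#'   label, count, n_classifiable, percent_raw, percent_rounded) and
#'   `per_animal` (the classifiable input rows).
#' @export
proportion_summary <- function(classifications, control_group = "control") {
  stopifnot(all(c("group", "label") %in% names(classifications)))
  if (!nrow(classifications)) stop("no classifications supplied")
  cls <- classifications[classifications$label != "unclassifiable", ,
                         drop = FALSE]
  groups <- unique(classifications$group)
  tab <- do.call(rbind, lapply(groups, function(g) {
    sub <- cls[cls$group == g, , drop = FALSE]
    n <- nrow(sub)
    labels <- sort(unique(cls$label))
    do.call(rbind, lapply(labels, function(l) {
      cnt <- sum(sub$label == l)
      raw <- if (n > 0) 100 * cnt / n else NA_real_
      data.frame(group = g, label = l, count = cnt, n_classifiable = n,
                 percent_raw = raw,
                 percent_rounded = if (is.na(raw)) NA_real_
                                   else round(raw, if (g == control_group) 1 else 0))
    }))
  }))
  if (is.null(tab))                      # nothing classifiable at all
    tab <- data.frame(group = groups, label = NA_character_, count = 0L,
                      n_classifiable = 0L, percent_raw = NA_real_,
                      percent_rounded = NA_real_)
  rownames(tab) <- NULL
  structure(list(table = tab, per_animal = cls), class = "ibp_proportions")
}

#' @export
print.ibp_proportions <- function(x, ...) {
  t <- x$table
  for (g in unique(t$group)) {
    sub <- t[t$group == g, ]
    parts <- sprintf("%s %d/%d (%s%%)", sub$label, sub$count,
                     sub$n_classifiable,
                     ifelse(is.na(sub$percent_rounded), "NA",
                            format(sub$percent_rounded)))
    cat(sprintf("  %s: %s\n", g, paste(parts, collapse = ", ")))
  }
  invisible(x)
}
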