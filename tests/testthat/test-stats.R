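test_that("Fisher p equals hypergeometric enumeration on random tables", {
  set.seed(13)
  for (i in 1:80) {
    n <- sample(4:200, 1)
    a_ <- sample(0:n, 1); b_ <- sample(0:(n - a_), 1)
    c_ <- sample(0:(n - a_ - b_), 1); d_ <- n - a_ - b_ - c_
    tab <- matrix(c(a_, b_, c_, d_), 2, byrow = TRUE)
    if (all(rowSums(tab) == 0) || all(colSums(tab) == 0)) next
    expect_equal(fisher_exact_2x2(tab)$p, fisher_enumeration_p(tab),
                 tolerance = 1e-10)
  }
})

test_that("Fisher test is invariant under simultaneous row and column swaps", {
  tabs <- list(matrix(c(2, 14, 41, 31), 2, byrow = TRUE),
               matrix(c(26, 27, 13, 22), 2, byrow = TRUE),
               matrix(c(5, 5, 5, 5), 2, byrow = TRUE))
  for (tab in tabs) {
    p0 <- fisher_exact_2x2(tab)$p
    expect_equal(fisher_exact_2x2(tab[2:1, ])$p, p0)
    expect_equal(fisher_exact_2x2(tab[, 2:1])$p, p0)
    expect_equal(fisher_exact_2x2(tab[2:1, 2:1])$p, p0)
  }
  expect_equal(fisher_exact_2x2(c(5, 5, 5, 5))$p, 1)
  expect_equal(fisher_exact_2x2(c(5, 5, 5, 5))$odds_ratio, 1)
  expect_identical(fisher_exact_2x2(c(3, 0, 0, 3))$odds_ratio, Inf)
  expect_error(fisher_exact_2x2(c(-1, 2, 3, 4)), "non-negative")
})

test_that("normality gate routes to ANOVA or Kruskal-Wallis as appropriate", {
  set.seed(21)
  gaussian <- list(a = rnorm(20), b = rnorm(20), c = rnorm(20))
  cg <- compare_groups(gaussian)
  expect_identical(cg$gate_decision, "parametric")
  expect_identical(cg$omnibus$test, "one-way ANOVA")

  skewed <- list(a = rexp(20)^3, b = rexp(20)^3, c = rexp(20)^3)
  cg2 <- compare_groups(skewed)
  expect_identical(cg2$gate_decision, "nonparametric")
  expect_identical(cg2$omnibus$test, "Kruskal-Wallis")

  # one non-normal group is enough to fail the gate
  mixed <- list(a = rnorm(20), b = rep(c(0, 10), 10) + rnorm(20, sd = 1e-3))
  expect_identical(compare_groups(mixed)$gate_decision, "nonparametric")
})

test_that("post hoc appears only when the omnibus rejects, with valid p", {
  ident <- list(a = c(1, 2, 3), b = c(1, 2, 3), c = c(1, 2, 3))
  cg <- compare_groups(ident)
  expect_gt(cg$omnibus$p, 0.9)
  expect_null(cg$posthoc)

  set.seed(22)
  shifted <- list(control = rnorm(20), mid = rnorm(20),
                  far = rnorm(20, mean = 5))
  cg2 <- compare_groups(shifted)
  expect_lt(cg2$omnibus$p, 0.001)
  expect_false(is.null(cg2$posthoc))
  ph <- cg2$posthoc
  expect_true(all(ph$p_adjusted >= 0 & ph$p_adjusted <= 1))
  far_rows <- ph[ph$group1 == "far" | ph$group2 == "far", ]
  expect_true(all(far_rows$p_adjusted < 0.05))
  if ("p_unadjusted" %in% names(ph))
    expect_true(all(ph$p_adjusted >= ph$p_unadjusted - 1e-12))

  expect_error(compare_groups(list(a = 1:2, b = 1:5)), "fewer than 3")
  expect_error(compare_groups(list(a = rep(1, 5), b = rep(1, 5))),
               "degenerate|identical")
})

test_that("Dunn's test reproduces hand-computed rank arithmetic", {
  # three groups of 3 with no ties: pooled ranks 1..9, mean ranks 2, 5, 8
  # z(a,c) = (2 - 8) / sqrt((9*10/12) * (2/3)) = -6/sqrt(5)
  values <- c(1.1, 1.2, 1.3, 2.1, 2.2, 2.3, 3.1, 3.2, 3.3)
  groups <- factor(rep(c("a", "b", "c"), each = 3))
  d <- dunn_test(values, groups)
  ac <- d[d$group1 == "a" & d$group2 == "c", ]
  expect_equal(ac$z, -6 / sqrt(5), tolerance = 1e-12)
  expect_equal(ac$p_unadjusted, 2 * pnorm(-6 / sqrt(5)), tolerance = 1e-12)
  expect_equal(ac$p_adjusted, min(1, 3 * 2 * pnorm(-6 / sqrt(5))),
               tolerance = 1e-12)
  # tie correction: duplicate one value pair and recompute T by hand
  v2 <- c(1, 1, 2, 3, 4, 5, 6, 7, 8)
  d2 <- dunn_test(v2, groups)
  tie_term <- (2^3 - 2) / (12 * 8)
  se <- sqrt((9 * 10 / 12 - tie_term) * (2 / 3))
  rb <- tapply(rank(v2), groups, mean)
  expect_equal(d2$z[d2$group1 == "a" & d2$group2 == "b"],
               unname((rb["a"] - rb["b"]) / se), tolerance = 1e-12)
})

test_that("proportion summary computes counts and reporting precision", {
  cls <- data.frame(
    group = c(rep("exposed", 35), rep("control", 16)),
    label = c(rep("responder", 13), rep("non_responder", 22),
              rep("affected", 2), rep("unaffected", 14)))
  ps <- proportion_summary(cls)
  t <- ps$table
  resp <- t[t$group == "exposed" & t$label == "responder", ]
  expect_identical(resp$count, 13L)
  expect_equal(resp$percent_raw, 100 * 13 / 35)
  expect_equal(resp$percent_rounded, 37)
  ctrl <- t[t$group == "control" & t$label == "affected", ]
  expect_equal(ctrl$percent_rounded, 12.5)

  # unclassifiable records excluded from denominators but not lost
  cls2 <- rbind(cls, data.frame(group = "exposed", label = "unclassifiable"))
  t2 <- proportion_summary(cls2)$table
  expect_identical(t2$n_classifiable[t2$group == "exposed"][1], 35L)

  empty <- data.frame(group = "exposed", label = "unclassifiable")
  t3 <- proportion_summary(empty)$table
  expect_true(all(is.na(t3$percent_raw)) || nrow(t3) == 0)
})
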