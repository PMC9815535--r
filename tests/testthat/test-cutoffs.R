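prof <- ibp_profile("IBP1")
params <- prof$parameters_by_timepoint$post_trauma

one_param_cohort <- function(vals, group = "control") {
  df <- data.frame(animal_id = sprintf("C%d", seq_along(vals)),
                   group = group, timepoint = "post_trauma")
  for (p in params) df[[p]] <- vals
  as_cohort(df, prof)
}

test_that("cutoffs reproduce hand-computed mean, sample SD and bounds", {
  coh <- one_param_cohort(c(10, 12, 14, 16, 18))
  cuts <- compute_cutoffs(coh, prof, "post_trauma")
  expect_equal(cuts$control_mean, rep(14, 7))
  expect_equal(cuts$control_sd, rep(sqrt(10), 7), tolerance = 1e-12)
  expect_equal(cuts$control_sd[1], 3.16228, tolerance = 1e-5)
  low <- cuts[cuts$parameter == "wazm_total_distance", ]
  expect_equal(low$lower_cutoff, 10.83772, tolerance = 1e-5)
  expect_true(is.na(low$upper_cutoff))
  high <- cuts[cuts$parameter == "wazm_freezing", ]
  expect_equal(high$upper_cutoff, 14 + sqrt(10))
  expect_true(is.na(high$lower_cutoff))
  expect_identical(cuts$n_control[1], 5L)

  cuts2 <- compute_cutoffs(coh, prof, "post_trauma", sd_multiplier = 2)
  expect_equal(cuts2$lower_cutoff[1], 7.67544, tolerance = 1e-5)
})

test_that("degenerate and insufficient control sets are reported", {
  expect_warning(cuts <- compute_cutoffs(one_param_cohort(c(5, 5, 5)),
                                         prof, "post_trauma"),
                 "degenerate")
  expect_true(all(cuts$degenerate))
  expect_equal(cuts$lower_cutoff[1], cuts$control_mean[1])
  expect_error(compute_cutoffs(one_param_cohort(5), prof, "post_trauma"),
               "at least 2")
})

test_that("flagging is strict at the cutoff and direction-aware", {
  coh <- one_param_cohort(c(10, 12, 14, 16, 18))
  cuts <- compute_cutoffs(coh, prof, "post_trauma")
  rec <- function(v) setNames(as.list(rep(v, 7)), params)
  # exact arithmetic: make a cutoff representable by using multiplier 0
  cuts0 <- compute_cutoffs(coh, prof, "post_trauma", sd_multiplier = 0)
  fl <- flag_parameters(rec(14), cuts0)   # values equal to every cutoff
  expect_false(any(fl))                   # equality is never flagged
  fl_low <- flag_parameters(rec(13.9), cuts0)
  expect_true(all(fl_low[c("wazm_total_distance", "wazm_closed_distance",
                           "wazm_open_distance")]))
  expect_false(any(fl_low[c("wazm_closed_time", "wazm_freezing",
                            "epm_freezing", "epm_anxiety_index")]))
  fl_high <- flag_parameters(rec(14.1), cuts0)
  expect_true(all(fl_high[c("wazm_closed_time", "wazm_freezing",
                            "epm_freezing", "epm_anxiety_index")]))
  expect_false(any(fl_high[c("wazm_total_distance", "wazm_closed_distance",
                             "wazm_open_distance")]))
  expect_false(flag_parameters(rec(20), cuts)[["wazm_total_distance"]])
  expect_true(flag_parameters(rec(10), cuts)[["wazm_total_distance"]])
  expect_error(flag_parameters(rec(14)[-1], cuts), "unclassifiable")
})

test_that("k-of-m rule and responder criterion behave at the boundary", {
  f <- function(n_true) setNames(seq_len(7) <= n_true, params)
  expect_identical(classify_affectedness(f(4))$label, "affected")
  expect_identical(classify_affectedness(f(3))$label, "unaffected")
  expect_identical(classify_affectedness(f(0))$label, "unaffected")
  expect_identical(classify_response(f(3))$label, "responder")
  expect_identical(classify_response(f(4))$label, "non_responder")
  expect_identical(classify_response(f(0))$label, "responder")
  expect_identical(classify_response(f(0), f(7),
                                     mode = "recovered_count")$label,
                   "responder")
  expect_identical(classify_response(f(4), f(7),
                                     mode = "recovered_count")$label,
                   "non_responder")
  expect_error(classify_response(f(0), previously_affected = FALSE),
               "previously")
  expect_error(classify_response(f(0), mode = "recovered_count"),
               "pre_flags")
})

test_that("raising k or the SD multiplier is monotone", {
  set.seed(7)
  df <- random_cohort_df(10, 30, params)
  coh <- as_cohort(df, prof)
  prev_affected <- Inf
  for (k in 1:7) {
    fit <- ibp(coh, prof, k = k)
    n_aff <- sum(fit$classifications$label == "affected")
    expect_lte(n_aff, prev_affected)
    prev_affected <- n_aff
  }
  prev_flags <- Inf
  for (mult in c(0.5, 1, 1.5, 2)) {
    fit <- ibp(coh, prof, sd_multiplier = mult)
    n_flags <- sum(fit$classifications$flag_count)
    expect_lte(n_flags, prev_flags)
    prev_flags <- n_flags
  }
})

test_that("classification is invariant under joint affine rescaling", {
  set.seed(8)
  df <- random_cohort_df(8, 20, params)
  base <- ibp(as_cohort(df, prof), prof)$classifications
  df2 <- df
  scale <- runif(7, 0.2, 5); shift <- runif(7, -50, 50)
  for (j in seq_along(params))
    df2[[params[j]]] <- scale[j] * df[[params[j]]] + shift[j]
  rescaled <- ibp(as_cohort(df2, prof), prof)$classifications
  expect_identical(rescaled$label, base$label)
  expect_identical(rescaled$flag_count, base$flag_count)
})

test_that("plug-in cutoffs from small control groups inflate false positives", {
  # a finite control cohort (n = 16) scored against its own estimated
  # cutoffs shows a higher k-of-7 rate than the infinite-population value
  # P(Bin(7, pnorm(-1)) >= 4), here with the correlated-parameter model
  set.seed(4242)
  analytic <- 1 - pbinom(3, 7, pnorm(-1))
  n_aff <- 0L; n_tot <- 0L
  for (i in 1:1000) {
    s <- simulate_cohort(cohort_config(n_control = 16, n_exposed = 0,
                                       rho = 0.2, seed = 50000 + i))
    cls <- ibp(s$cohort, "IBP1")$classifications
    n_aff <- n_aff + sum(cls$label == "affected")
    n_tot <- n_tot + nrow(cls)
  }
  expect_gt(n_aff / n_tot, analytic)
})
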