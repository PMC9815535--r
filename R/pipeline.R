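#' Configuration for a full profiling pipeline run
#'
#' Exactly one of `cohort` (a data frame, `"ibp_cohort"`, or CSV path) and
#' `sim_config` (an `"ibp_sim_config"`) must be supplied.
#'
#' @param profile Profile id or `"ibp_profile"` object.
#' @param cohort Input cohort (both time points) or path to its CSV.
#' @param sim_config Synthetic-cohort configuration to generate the input
#'   instead.
#' @param responder_mode `"post_count"` or `"recovered_count"` (see
#'   [classify_response()]).
#' @param alpha,alpha_normality Significance levels for the group
#'   comparisons and the normality gate.
#' @param sd_multiplier Cutoff width in control SDs.
#' @param k Affectedness threshold.
#' @param control_group Control group label.
#' @param output_dir Optional directory; when given, [write_report()] is
#'   called on the result.
#' @param seed Seed forwarded to the simulator.
#' @return List of class `"ibp_pipeline_config"`.
#' @export
pipeline_config <- function(profile = "IBP1", cohort = NULL, sim_config = NULL,
                            responder_mode = c("post_count", "recovered_count"),
                            alpha = 0.05, alpha_normality = 0.05,
                            sd_multiplier = 1, k = 4,
                            control_group = "control",
                            output_dir = NULL, seed = 1L) {
  if (is.null(cohort) == is.null(sim_config))
    stop("supply exactly one of 'cohort' and 'sim_config'")
  structure(list(profile = profile, cohort = cohort, sim_config = sim_config,
                 responder_mode = match.arg(responder_mode),
                 alpha = alpha, alpha_normality = alpha_normality,
                 sd_multiplier = sd_multiplier, k = k,
                 control_group = control_group,
                 output_dir = output_dir, seed = seed),
            class = "ibp_pipeline_config")
}

#' Run the full two-time-point profiling pipeline
#'
#' Executes the complete analysis: per-time-point control-anchored cutoffs,
#' per-animal flagging and affected/unaffected classification at
#' post-trauma, responder/non-responder classification of the affected
#' animals at post-treatment, proportion summaries, the Fisher exact test
#' of the exposed vs control affectedness distribution, and normality-gated
#' group comparisons of every profile parameter across
#' control/affected/unaffected (post-trauma) and
#' control/responder/non-responder (post-treatment). Every decision
#' (cutoffs, exclusions, normality-gate outcomes) is recorded in the
#' report's log.
#'
#' @param config An `"ibp_pipeline_config"`.
#' @return List of class `"ibp_report"`: `profile_id`, `timepoints`,
#'   `fit_post_trauma` (the `"ibp"` object), `cutoffs_post_treatment`,
#'   `classifications` (per-animal, both time points; responder labels for
#'   previously affected animals), `proportions_post_trauma`,
#'   `proportions_response`, `proportions_control_post_treatment`,
#'   `fisher_affectedness`, `group_comparisons` (named list of
#'   `"ibp_group_comparison"` or skip records), `log`, `config`, and
#'   `truth` when simulated.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "ibp_pipeline_config"))
  profile <- if (is.character(config$profile)) ibp_profile(config$profile)
             else config$profile
  log <- character(0)
  note <- function(...) log <<- c(log, sprintf(...))

  truth <- NULL
  if (!is.null(config$sim_config)) {
    sim <- simulate_cohort(config$sim_config, profile, seed = config$seed)
    cohort <- sim$cohort
    truth <- sim$truth
    note("input: simulated cohort, seed %s", deparse(config$seed))
  } else if (is.character(config$cohort)) {
    cohort <- read_cohort(config$cohort, profile)
    note("input: %s", config$cohort)
  } else {
    cohort <- if (inherits(config$cohort, "ibp_cohort")) config$cohort
              else as_cohort(config$cohort, profile)
    note("input: in-memory cohort")
  }
  if (any(cohort$incomplete))
    note("excluded as unclassifiable: %s",
         paste(unique(cohort$animal_id[cohort$incomplete]), collapse = ", "))

  fit_pre <- ibp(cohort, profile, "post_trauma",
                 control_group = config$control_group,
                 sd_multiplier = config$sd_multiplier, k = config$k)
  note("post_trauma cutoffs from %d controls", fit_pre$cutoffs$n_control[1])

  cuts_post <- compute_cutoffs(cohort, profile, "post_treatment",
                               sd_multiplier = config$sd_multiplier,
                               control_group = config$control_group)
  cls_post <- profile_cohort(cohort, profile, "post_treatment", cuts_post,
                             k = config$k)
  note("post_treatment cutoffs from %d controls", cuts_post$n_control[1])

  pre <- fit_pre$classifications
  post <- cls_post$classifications
  affected_ids <- pre$animal_id[pre$label == "affected" &
                                pre$group != config$control_group]
  flag_cols_pre <- paste0("flag_", fit_pre$cutoffs$parameter)
  flag_cols_post <- paste0("flag_", cuts_post$parameter)

  for (id in affected_ids) {
    j <- which(post$animal_id == id)
    if (!length(j) || post$label[j] == "unclassifiable") {
      note("affected animal %s has no classifiable post_treatment record", id)
      next
    }
    pf <- unlist(post[j, flag_cols_post])
    names(pf) <- sub("^flag_", "", names(pf))
    i <- which(pre$animal_id == id)
    prf <- unlist(pre[i, flag_cols_pre])
    names(prf) <- sub("^flag_", "", names(prf))
    res <- classify_response(pf, prf, k = config$k, mode = config$responder_mode)
    post$label[j] <- res$label
  }

  resp <- post[post$animal_id %in% affected_ids &
               post$label %in% c("responder", "non_responder"), , drop = FALSE]
  proportions_response <- if (nrow(resp)) proportion_summary(resp) else NULL
  ctrl_post <- post[post$group == config$control_group, , drop = FALSE]
  proportions_control_post <- if (nrow(ctrl_post)) proportion_summary(ctrl_post)
                              else NULL

  comparisons <- list()
  add_comparisons <- function(df, cutoffs, labels, tag) {
    spec_names <- cutoffs$parameter
    raw <- as.data.frame(cohort)
    raw <- raw[raw$timepoint == cutoffs$timepoint[1] & !raw$incomplete, ,
               drop = FALSE]
    lab <- df$label
    lab[df$group == config$control_group] <- config$control_group
    keep <- lab %in% c(config$control_group, labels)
    for (p in spec_names) {
      key <- paste0(tag, ":", p)
      vals <- split(raw[[p]][match(df$animal_id[keep], raw$animal_id)],
                    factor(lab[keep], levels = c(config$control_group, labels)))
      comparisons[[key]] <<- tryCatch({
        cg <- compare_groups(vals, alpha = config$alpha,
                             alpha_normality = config$alpha_normality)
        note("%s: %s gate, omnibus p = %.4g", key, cg$gate_decision,
             cg$omnibus$p)
        cg
      }, error = function(e) {
        note("%s: skipped (%s)", key, conditionMessage(e))
        list(skipped = conditionMessage(e))
      })
    }
  }
  add_comparisons(pre, fit_pre$cutoffs, c("affected", "unaffected"),
                  "post_trauma")
  add_comparisons(post, cuts_post, c("responder", "non_responder"),
                  "post_treatment")

  report <- structure(list(
    profile_id = profile$profile_id,
    timepoints = c("post_trauma", "post_treatment"),
    fit_post_trauma = fit_pre,
    cutoffs_post_treatment = cuts_post,
    classifications = rbind_union(pre, post),
    proportions_post_trauma = fit_pre$proportions,
    proportions_response = proportions_response,
    proportions_control_post_treatment = proportions_control_post,
    fisher_affectedness = fit_pre$fisher,
    group_comparisons = comparisons,
    log = log, config = config, truth = truth), class = "ibp_report")

  if (!is.null(config$output_dir)) write_report(report, config$output_dir)
  report
}

# rbind tolerating different flag columns (profiles that swap parameters
# between time points); absent flags become NA
rbind_union <- function(a, b) {
  cols <- union(names(a), names(b))
  for (cn in setdiff(cols, names(a))) a[[cn]] <- NA
  for (cn in setdiff(cols, names(b))) b[[cn]] <- NA
  rbind(a[, cols], b[, cols])
}

#' @export
print.ibp_report <- function(x, ...) {
  cat("IBP pipeline report (", x$profile_id, ")\n", sep = "")
  cat("post_trauma classification:\n")
  print(x$proportions_post_trauma)
  if (!is.null(x$proportions_response)) {
    cat("treatment response among previously affected:\n")
    print(x$proportions_response)
  }
  for (g in names(x$fisher_affectedness)) {
    cat("affectedness vs control, group ", g, ": ", sep = "")
    print(x$fisher_affectedness[[g]])
  }
  invisible(x)
}

#' Fisher comparison of two classification distributions
#'
#' Builds the 2x2 table (cohort x category) from two 2-category count
#' pairs — e.g. the affected/unaffected or responder/non-responder splits
#' of two experiments — and runs [fisher_exact_2x2()].
#'
#' @param counts_a,counts_b Length-2 integer vectors `(category1,
#'   category2)`, or `"ibp_proportions"` objects whose `group` argument
#'   selects the row (the two labels, sorted, are the categories).
#' @param group When proportions objects are passed, the group whose
#'   counts to use (default the first).
#' @return An `"ibp_fisher"` result.
#' @examples
#' cross_experiment_comparison(c(26, 27), c(13, 22))$p  # 0.2842...
#' @export
cross_experiment_comparison <- function(counts_a, counts_b, group = NULL) {
  pick <- function(x) {
    if (inherits(x, "ibp_proportions")) {
      t <- x$table
      g <- if (is.null(group)) t$group[1] else group
      t <- t[t$group == g, , drop = FALSE]
      t <- t[order(t$label), ]
      if (nrow(t) != 2)
        stop("proportion summary does not expose exactly 2 categories")
      t$count
    } else {
      stopifnot(length(x) == 2)
      as.numeric(x)
    }
  }
  fisher_exact_2x2(rbind(pick(counts_a), pick(counts_b)))
}

#' Write a machine- and human-readable report bundle
#'
#' Writes, under `dir`: `per_animal.csv` (flags, counts and labels for
#' every record), `proportions.csv`, `tests.csv` (one row per statistical
#' test: test name, groups, statistic, p, adjusted p, gate decision),
#' `report.json` (the full nested bundle) and `summary.txt`.
#'
#' @param report An `"ibp_report"` from [run_pipeline()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  stopifnot(inherits(report, "ibp_report"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(dir)) stop("cannot create output directory ", dir)

  utils::write.csv(report$classifications,
                   file.path(dir, "per_animal.csv"), row.names = FALSE)

  props <- rbind(
    cbind(stage = "post_trauma", report$proportions_post_trauma$table),
    if (!is.null(report$proportions_response))
      cbind(stage = "response", report$proportions_response$table),
    if (!is.null(report$proportions_control_post_treatment))
      cbind(stage = "control_post_treatment",
            report$proportions_control_post_treatment$table))
  utils::write.csv(props, file.path(dir, "proportions.csv"), row.names = FALSE)

  tests <- list()
  for (g in names(report$fisher_affectedness)) {
    f <- report$fisher_affectedness[[g]]
    tests[[length(tests) + 1]] <- data.frame(
      test = "Fisher exact", measure = "affectedness",
      groups = paste(report$config$control_group, g, sep = " vs "),
      statistic = f$odds_ratio, p = f$p, p_adjusted = NA_real_,
      gate = NA_character_)
  }
  for (key in names(report$group_comparisons)) {
    cg <- report$group_comparisons[[key]]
    if (!inherits(cg, "ibp_group_comparison")) next
    tests[[length(tests) + 1]] <- data.frame(
      test = cg$omnibus$test, measure = key,
      groups = paste(cg$groups, collapse = "/"),
      statistic = cg$omnibus$statistic, p = cg$omnibus$p,
      p_adjusted = NA_real_, gate = cg$gate_decision)
    if (!is.null(cg$posthoc))
      for (i in seq_len(nrow(cg$posthoc)))
        tests[[length(tests) + 1]] <- data.frame(
          test = cg$posthoc_method, measure = key,
          groups = paste(cg$posthoc$group1[i], cg$posthoc$group2[i],
                         sep = " vs "),
          statistic = NA_real_, p = NA_real_,
          p_adjusted = cg$posthoc$p_adjusted[i], gate = cg$gate_decision)
  }
  tests <- if (length(tests)) do.call(rbind, tests) else
    data.frame(test = character(0))
  utils::write.csv(tests, file.path(dir, "tests.csv"), row.names = FALSE)

  json <- list(
    profile_id = report$profile_id,
    labels = stats::setNames(
      as.list(report$classifications$label),
      paste(report$classifications$animal_id,
            report$classifications$timepoint, sep = "@")),
    proportions = props,
    tests = tests,
    cutoffs_post_trauma = as.data.frame(report$fit_post_trauma$cutoffs),
    cutoffs_post_treatment = as.data.frame(report$cutoffs_post_treatment),
    log = report$log)
  jsonlite::write_json(json, file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  con <- file(file.path(dir, "summary.txt"), open = "wt")
  sink(con); on.exit({ sink(); close(con) })
  print(report)
  cat("\nLog:\n"); cat(paste0("  ", report$log, collapse = "\n"), "\n")
  invisible(dir)
}
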