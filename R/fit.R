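#' Fit an individual behavioral profiling classifier
#'
#' The model-fitting entry point of the package. "Fitting" an IBP consists
#' of estimating, from the control animals at one time point, the
#' per-parameter cutoffs (control mean +/- `sd_multiplier` control SDs in
#' the pathological direction); classification of any animal then follows
#' deterministically by the k-of-m flag rule. The returned object carries
#' the cutoff table (the model's coefficients), the classification of every
#' complete record of the supplied cohort (controls are scored against
#' their own plug-in cutoffs, as in the original design), the per-group
#' proportion summary, and the Fisher exact test comparing the
#' affected/unaffected split of each non-control group with the controls.
#'
#' @param data An `"ibp_cohort"` or a data frame coercible via
#'   [as_cohort()].
#' @param profile An `"ibp_profile"` object or a profile id (`"IBP1"`,
#'   `"IBP2"`).
#' @param timepoint Time point to classify at (default `"post_trauma"`).
#' @param control_group Group label anchoring the cutoffs (default
#'   `"control"`).
#' @param sd_multiplier Cutoff width in control SDs.
#' @param k Flags required for affectedness.
#' @param control_scoring How control animals themselves are scored:
#'   `"plug_in"` (default) uses the cutoffs estimated from the full control
#'   group; `"leave_one_out"` re-estimates the cutoffs without the animal
#'   being scored, removing its own influence on them. Non-control animals
#'   always use the full-control cutoffs.
#' @return An object of class `"ibp"`: list with `profile`, `timepoint`,
#'   `cutoffs` (`"ibp_cutoffs"`), `classifications` (per-animal data frame
#'   with `animal_id`, `group`, `flag_count`, `label` and one logical
#'   column per parameter flag), `proportions` (see
#'   [proportion_summary()]), `fisher` (named list of `"ibp_fisher"`
#'   results vs control, one per non-control group), `control_group`,
#'   `call`.
#' @seealso [predict.ibp()], [profile_cohort()], [run_pipeline()]
#' @examples
#' fit <- ibp(worked_example(), "IBP1")
#' summary(fit)
#' coef(fit)
#' @export
ibp <- function(data, profile = "IBP1",
                timepoint = c("post_trauma", "post_treatment"),
                control_group = "control",
                sd_multiplier = NULL, k = NULL,
                control_scoring = c("plug_in", "leave_one_out")) {
  control_scoring <- match.arg(control_scoring)
  if (is.character(profile)) profile <- ibp_profile(profile)
  stopifnot(inherits(profile, "ibp_profile"))
  timepoint <- match.arg(timepoint)
  if (!inherits(data, "ibp_cohort")) data <- as_cohort(data, profile)
  if (is.null(sd_multiplier)) sd_multiplier <- profile$sd_multiplier
  if (is.null(k)) k <- profile$k

  cutoffs <- compute_cutoffs(data, profile, timepoint,
                             sd_multiplier = sd_multiplier,
                             control_group = control_group)
  cls <- profile_cohort(data, profile, timepoint, cutoffs, k = k)

  if (control_scoring == "leave_one_out") {
    df <- as.data.frame(data)
    ctrl <- df[df$group == control_group & df$timepoint == timepoint &
               !df$incomplete, , drop = FALSE]
    for (id in ctrl$animal_id) {
      rest <- ctrl[ctrl$animal_id != id, , drop = FALSE]
      cuts_i <- compute_cutoffs(rest, profile, timepoint,
                                sd_multiplier = sd_multiplier,
                                control_group = control_group)
      fl <- flag_parameters(ctrl[ctrl$animal_id == id, , drop = FALSE], cuts_i)
      res <- classify_affectedness(fl, k = k)
      j <- which(cls$classifications$animal_id == id)
      cls$classifications[j, paste0("flag_", names(fl))] <- as.list(fl)
      cls$classifications$flag_count[j] <- res$flag_count
      cls$classifications$label[j] <- res$label
    }
    cls$proportions <- proportion_summary(cls$classifications)
  }

  groups <- setdiff(unique(cls$classifications$group), control_group)
  fisher <- lapply(groups, function(g) {
    tab <- classification_table(cls$classifications,
                                rows = c(control_group, g),
                                positive = "affected")
    fisher_exact_2x2(tab)
  })
  names(fisher) <- groups

  structure(list(profile = profile, timepoint = timepoint,
                 cutoffs = cutoffs,
                 classifications = cls$classifications,
                 proportions = cls$proportions,
                 fisher = fisher,
                 control_group = control_group,
                 control_scoring = control_scoring,
                 k = as.integer(k),
                 call = match.call()),
            class = "ibp")
}

#' Classify every record of a cohort at one time point
#'
#' Applies [flag_parameters()] and [classify_affectedness()] to every
#' complete record at the given time point — controls included — and
#' summarizes per-group proportions. Incomplete records are retained with
#' label `"unclassifiable"` and NA flag count.
#'
#' @param cohort An `"ibp_cohort"` data frame.
#' @param profile An `"ibp_profile"`.
#' @param timepoint Time point label.
#' @param cutoffs `"ibp_cutoffs"` computed from the concurrent controls at
#'   the same time point.
#' @param k Flags required for affectedness.
#' @return List with `classifications` (one row per record: `animal_id`,
#'   `group`, `timepoint`, one logical `flag_<param>` column per parameter,
#'   `flag_count`, `label`) and `proportions` ([proportion_summary()]
#'   output).
#' @export
profile_cohort <- function(cohort, profile, timepoint, cutoffs, k = profile$k) {
  stopifnot(inherits(cutoffs, "ibp_cutoffs"))
  if (cutoffs$timepoint[1] != timepoint)
    stop("cutoff table was computed at '", cutoffs$timepoint[1],
         "' but classification requested at '", timepoint, "'")
  df <- as.data.frame(cohort)
  df <- df[df$timepoint == timepoint, , drop = FALSE]
  params <- cutoffs$parameter
  for (p in setdiff(params, names(df))) df[[p]] <- NA_real_
  incomplete <- if ("incomplete" %in% names(df)) df$incomplete
                else rowSums(is.na(df[, params, drop = FALSE])) > 0

  # vectorized flagging: value strictly beyond the applicable cutoff(s)
  X <- t(as.matrix(df[, params, drop = FALSE]))
  lo <- ifelse(is.na(cutoffs$lower_cutoff), -Inf, cutoffs$lower_cutoff)
  up <- ifelse(is.na(cutoffs$upper_cutoff), Inf, cutoffs$upper_cutoff)
  flags <- t(X < lo | X > up)
  colnames(flags) <- paste0("flag_", params)
  flags[incomplete, ] <- NA
  flag_count <- as.integer(rowSums(flags))
  label <- ifelse(incomplete, "unclassifiable",
                  ifelse(flag_count >= k, "affected", "unaffected"))

  classifications <- data.frame(animal_id = df$animal_id, group = df$group,
                                timepoint = timepoint,
                                stringsAsFactors = FALSE)
  classifications <- cbind(classifications, as.data.frame(flags))
  classifications$flag_count <- flag_count
  classifications$label <- label
  rownames(classifications) <- NULL
  list(classifications = classifications,
       proportions = proportion_summary(classifications))
}

# 2x2 table rows x (positive, complement) from a classification data frame
classification_table <- function(classifications, rows,
                                 positive = "affected") {
  cls <- classifications[classifications$label != "unclassifiable", ,
                         drop = FALSE]
  negative <- setdiff(unique(cls$label), positive)
  t(vapply(rows, function(g) {
    sub <- cls[cls$group == g, , drop = FALSE]
    c(sum(sub$label == positive), sum(sub$label %in% negative))
  }, c(0, 0)))
}

#' @export
print.ibp <- function(x, ...) {
  cat(sprintf("Individual behavioral profiling fit (%s, %s)\n",
              x$profile$profile_id, x$timepoint))
  cat(sprintf("  rule: affected if >= %d of %d parameters beyond %.3g control SD\n",
              x$k, x$profile$m, x$cutoffs$sd_multiplier[1]))
  cat(sprintf("  cutoffs anchored on %d '%s' animals\n",
              x$cutoffs$n_control[1], x$control_group))
  print(x$proportions)
  invisible(x)
}

#' @export
summary.ibp <- function(object, ...) {
  structure(list(fit = object), class = "summary.ibp")
}

#' @export
print.summary.ibp <- function(x, ...) {
  print(x$fit)
  cat("\nCutoffs:\n")
  print(x$fit$cutoffs)
  for (g in names(x$fit$fisher)) {
    cat(sprintf("\nFisher exact test, affected/unaffected: %s vs %s\n",
                g, x$fit$control_group))
    print(x$fit$fisher[[g]])
  }
  invisible(x)
}

#' Cutoff table of a fitted IBP
#'
#' @param object An `"ibp"` fit.
#' @param ... Unused.
#' @return The `"ibp_cutoffs"` data frame (the model's coefficients).
#' @export
coef.ibp <- function(object, ...) object$cutoffs

#' Classify new animals with a fitted IBP
#'
#' Scores records of `newdata` at the fit's time point against the fit's
#' cutoff table. The cutoffs are not re-estimated; this is the plug-in
#' classification of fresh data.
#'
#' @param object An `"ibp"` fit.
#' @param newdata An `"ibp_cohort"` or data frame; defaults to the training
#'   classification.
#' @param ... Unused.
#' @return The per-animal classification data frame (see
#'   [profile_cohort()]).
#' @export
predict.ibp <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) return(object$classifications)
  if (!inherits(newdata, "ibp_cohort"))
    newdata <- as_cohort(newdata, object$profile)
  profile_cohort(newdata, object$profile, object$timepoint,
                 object$cutoffs, k = object$k)$classifications
}

#' Stacked classification bar plot
#'
#' One stacked bar per group showing the percentage of each classification
#' label (affected/unaffected or responder/non-responder), mirroring the
#' usual presentation of profiling outcomes.
#'
#' @param x An `"ibp"` fit.
#' @param main Plot title.
#' @param ... Passed to [graphics::barplot()].
#' @return Invisibly, the percentage matrix plotted.
#' @export
plot.ibp <- function(x, main = NULL, ...) {
  pr <- x$proportions
  tab <- table(factor(pr$per_animal$label), pr$per_animal$group)
  pct <- prop.table(tab, 2) * 100
  if (is.null(main))
    main <- sprintf("%s classification at %s", x$profile$profile_id, x$timepoint)
  graphics::barplot(pct, main = main, ylab = "% of group",
                    legend.text = rownames(pct),
                    col = grDevices::gray.colors(nrow(pct)), ...)
  invisible(pct)
}
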