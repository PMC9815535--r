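#' Control-anchored cutoffs for one time point
#'
#' For every parameter active in the profile at the given time point,
#' computes the control mean and sample standard deviation (denominator
#' n - 1) and derives the cutoff(s): `mean - mult * sd` for parameters
#' whose pathological direction is low, `mean + mult * sd` where it is
#' high, both for two-sided parameters. One control SD is the default
#' cutoff width. Cutoffs are re-estimated per time point from the
#' concurrent controls.
#'
#' @param controls An `"ibp_cohort"` (or plain data frame) containing only
#'   the control animals, or a full cohort plus `control_group` to subset.
#' @param profile An `"ibp_profile"`.
#' @param timepoint Time point whose parameter list and control records are
#'   used.
#' @param sd_multiplier Cutoff width in control SDs (default 1).
#' @param control_group If `controls` contains several groups, the label of
#'   the control group (default `"control"`).
#' @return A data frame of class `"ibp_cutoffs"`, one row per parameter:
#'   `parameter`, `timepoint`, `direction`, `control_mean`, `control_sd`,
#'   `sd_multiplier`, `lower_cutoff`, `upper_cutoff` (NA where not
#'   applicable), `n_control`, `degenerate` (zero control SD).
#' @examples
#' prof <- ibp_profile("IBP1")
#' ctrl <- worked_example()
#' cuts <- compute_cutoffs(ctrl, prof, "post_trauma")
#' @export
compute_cutoffs <- function(controls, profile,
                            timepoint = c("post_trauma", "post_treatment"),
                            sd_multiplier = profile$sd_multiplier,
                            control_group = "control") {
  stopifnot(inherits(profile, "ibp_profile"))
  timepoint <- match.arg(timepoint)
  df <- as.data.frame(controls)
  if ("group" %in% names(df) && any(df$group != control_group))
    df <- df[df$group == control_group, , drop = FALSE]
  if ("timepoint" %in% names(df))
    df <- df[df$timepoint == timepoint, , drop = FALSE]
  if ("incomplete" %in% names(df))
    df <- df[!df$incomplete, , drop = FALSE]

  spec <- profile_parameters(profile, timepoint)
  missing <- setdiff(spec$name, names(df))
  if (length(missing))
    stop("control records lack parameter(s): ", paste(missing, collapse = ", "))
  if (nrow(df) < 2)
    stop("need at least 2 complete control records at ", timepoint,
         "; got ", nrow(df))

  out <- spec[, c("name", "direction")]
  names(out)[1] <- "parameter"
  out$timepoint <- timepoint
  out$control_mean <- vapply(out$parameter, function(p) mean(df[[p]]), 0)
  out$control_sd <- vapply(out$parameter, function(p) stats::sd(df[[p]]), 0)
  out$sd_multiplier <- sd_multiplier
  out$lower_cutoff <- ifelse(out$direction %in% c("low_is_affected", "two_sided"),
                             out$control_mean - sd_multiplier * out$control_sd,
                             NA_real_)
  out$upper_cutoff <- ifelse(out$direction %in% c("high_is_affected", "two_sided"),
                             out$control_mean + sd_multiplier * out$control_sd,
                             NA_real_)
  out$n_control <- nrow(df)
  out$degenerate <- out$control_sd == 0
  if (any(out$degenerate))
    warning("zero control SD (degenerate cutoff) for: ",
            paste(out$parameter[out$degenerate], collapse = ", "))
  rownames(out) <- NULL
  class(out) <- c("ibp_cutoffs", "data.frame")
  out
}

#' @export
print.ibp_cutoffs <- function(x, digits = 4, ...) {
  cat(sprintf("IBP cutoffs at %s (n_control = %d, %.3g SD):\n",
              x$timepoint[1], x$n_control[1], x$sd_multiplier[1]))
  show <- as.data.frame(x)[, c("parameter", "direction", "control_mean",
                               "control_sd", "lower_cutoff", "upper_cutoff")]
  print(format(show, digits = digits), row.names = FALSE)
  invisible(x)
}

#' Flag one animal's parameters against a cutoff table
#'
#' A parameter is flagged (counted as affected) when the value is strictly
#' beyond the cutoff in the pathological direction: `value < lower_cutoff`
#' for low-is-affected, `value > upper_cutoff` for high-is-affected, either
#' for two-sided. A value exactly equal to a cutoff is not flagged.
#'
#' @param record A one-row data frame or named list/vector holding the
#'   animal's parameter values.
#' @param cutoffs An `"ibp_cutoffs"` table.
#' @return Named logical vector, one flag per cutoff-table parameter, or an
#'   error if any parameter is missing (no partial flag vectors).
#' @export
flag_parameters <- function(record, cutoffs) {
  stopifnot(inherits(cutoffs, "ibp_cutoffs"))
  vals <- if (is.data.frame(record)) {
    stopifnot(nrow(record) == 1)
    unlist(record[, intersect(cutoffs$parameter, names(record)), drop = FALSE])
  } else unlist(record)[intersect(cutoffs$parameter, names(unlist(record)))]
  missing <- setdiff(cutoffs$parameter, names(vals))
  if (length(missing) || anyNA(vals[cutoffs$parameter]))
    stop("record is unclassifiable: missing parameter(s): ",
         paste(union(missing,
                     cutoffs$parameter[is.na(vals[cutoffs$parameter])]),
               collapse = ", "))
  v <- as.numeric(vals[cutoffs$parameter])
  low <- !is.na(cutoffs$lower_cutoff) & v < cutoffs$lower_cutoff
  high <- !is.na(cutoffs$upper_cutoff) & v > cutoffs$upper_cutoff
  stats::setNames(low | high, cutoffs$parameter)
}

#' Affected / unaffected classification from a flag vector
#'
#' Applies the k-of-m rule: an animal flagged on at least `k` parameters is
#' labeled `"affected"`, otherwise `"unaffected"`.
#'
#' @param flags Complete named logical vector over the profile's parameters.
#' @param k Flags required for affectedness (default 4).
#' @return List of class `"ibp_classification"`: `flags`, `flag_count`,
#'   `label`, `k`, `m`.
#' @export
classify_affectedness <- function(flags, k = 4) {
  stopifnot(is.logical(flags), !anyNA(flags))
  fc <- sum(flags)
  structure(list(flags = flags, flag_count = fc,
                 label = if (fc >= k) "affected" else "unaffected",
                 k = as.integer(k), m = length(flags)),
            class = "ibp_classification")
}

#' Responder / non-responder classification after treatment
#'
#' Only animals labeled affected before treatment are eligible. Two
#' operationalizations of the recovery criterion are provided:
#' `"post_count"` (default) labels an animal responder when it shows fewer
#' than `k` affected parameters at the post-treatment time point;
#' `"recovered_count"` labels it responder when at least `k` of the m
#' post-treatment parameters are unflagged. With `k = 4`, `m = 7` the two
#' rules coincide; they differ only when `k != m - k + 1`.
#'
#' @param post_flags Complete named logical flag vector at post-treatment.
#' @param pre_flags Post-trauma flag vector (required for
#'   `"recovered_count"` bookkeeping; its affected status is what makes the
#'   animal eligible).
#' @param k Threshold (default 4).
#' @param mode `"post_count"` or `"recovered_count"`.
#' @param previously_affected Logical; set `FALSE` to signal an ineligible
#'   animal (raises an error).
#' @return List of class `"ibp_classification"` with label `"responder"` or
#'   `"non_responder"`.
#' @export
classify_response <- function(post_flags, pre_flags = NULL, k = 4,
                              mode = c("post_count", "recovered_count"),
                              previously_affected = TRUE) {
  mode <- match.arg(mode)
  stopifnot(is.logical(post_flags), !anyNA(post_flags))
  if (!isTRUE(previously_affected))
    stop("animal was not previously classified affected; responder status undefined")
  if (mode == "recovered_count" && is.null(pre_flags))
    stop("mode 'recovered_count' requires pre_flags")
  fc <- sum(post_flags)
  m <- length(post_flags)
  responder <- switch(mode,
                      post_count = fc < k,
                      recovered_count = (m - fc) >= k)
  structure(list(flags = post_flags, flag_count = fc,
                 label = if (responder) "responder" else "non_responder",
                 k = as.integer(k), m = m, mode = mode),
            class = "ibp_classification")
}

#' @export
print.ibp_classification <- function(x, ...) {
  cat(sprintf("%s (%d of %d parameters flagged, k = %d)\n",
              x$label, x$flag_count, x$m, x$k))
  invisible(x)
}
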