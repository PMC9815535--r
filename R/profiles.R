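#' Define a single profile parameter
#'
#' A parameter specification names one behavioral readout, the test it comes
#' from, and its pathological direction: the side of the control-derived
#' cutoff on which an animal is counted as affected for that parameter.
#'
#' @param name Parameter identifier. Normalized with [normalize_parameter_name()].
#' @param source_test Label of the behavioral test the readout comes from,
#'   one of `"WAZM"`, `"EPM"`, `"OFT"`, `"SRT"`.
#' @param direction One of `"low_is_affected"`, `"high_is_affected"`,
#'   `"two_sided"`.
#' @param units Free-text units (e.g. `"cm"`, `"s"`, `"%"`, `"index"`).
#' @return A one-row data frame of class `"ibp_parameter_spec"`.
#' @seealso [ibp_profile()]
#' @export
parameter_spec <- function(name, source_test, direction, units = "") {
  direction <- match.arg(direction,
                         c("low_is_affected", "high_is_affected", "two_sided"))
  source_test <- match.arg(source_test, c("WAZM", "EPM", "OFT", "SRT"))
  out <- data.frame(name = normalize_parameter_name(name),
                    source_test = source_test,
                    direction = direction,
                    units = units,
                    stringsAsFactors = FALSE)
  class(out) <- c("ibp_parameter_spec", class(out))
  out
}

# rbind a list of parameter_spec rows into one spec table, checking uniqueness
bind_specs <- function(specs) {
  tab <- do.call(rbind, lapply(specs, as.data.frame))
  if (anyDuplicated(tab$name))
    stop("duplicate parameter name in profile: ",
         paste(tab$name[duplicated(tab$name)], collapse = ", "))
  tab
}

#' Built-in individual behavioral profiling definitions
#'
#' Returns one of the two seven-parameter profiles shipped with the package.
#'
#' `"IBP1"` uses the same seven water-associated zero maze (WAZM) and
#' elevated plus maze (EPM) parameters at both time points: total WAZM
#' distance, closed-arm time, closed-arm distance, open-arm distance, total
#' WAZM freezing, total EPM freezing, and the EPM anxiety index.
#'
#' `"IBP2"` shares five parameters between time points (WAZM closed-arm
#' distance, open-arm time, open-arm distance, total freezing; social
#' preference index) and substitutes the two open field test (OFT)
#' parameters used post-trauma (total distance, center time) with two EPM
#' parameters post-treatment (total distance, anxiety index), because
#' control animals stop exploring an open field on re-exposure.
#'
#' Classification uses a k-of-m rule with `k = 4`, `m = 7`: an animal
#' flagged on at least `k` of the `m` parameters is labeled affected.
#'
#' Pathological directions are not spelled out readout-by-readout in the
#' source protocol ("either lower or higher than the cut-off"); the shipped
#' directions are inferred from the side on which affected groups deviate:
#' distances, open-arm/center times and the social preference index are
#' flagged low, freezing, closed-arm time and the anxiety index are flagged
#' high. Override any of them by editing the `parameters` table of the
#' returned object.
#'
#' @param profile_id `"IBP1"` or `"IBP2"`.
#' @param k Affectedness threshold (flags required); default 4.
#' @param sd_multiplier Cutoff width in control standard deviations; default 1.
#' @return An object of class `"ibp_profile"`: a list with elements
#'   `profile_id`, `parameters` (spec table of all parameters),
#'   `parameters_by_timepoint` (named list of parameter-name vectors for
#'   `"post_trauma"` and `"post_treatment"`), `k`, `m`, `sd_multiplier`.
#' @examples
#' p <- ibp_profile("IBP1")
#' p$m           # 7
#' p$k           # 4
#' profile_parameters(ibp_profile("IBP2"), "post_treatment")
#' @export
ibp_profile <- function(profile_id = c("IBP1", "IBP2"), k = 4, sd_multiplier = 1) {
  if (length(profile_id) == 1 && !profile_id %in% c("IBP1", "IBP2"))
    stop("unknown profile_id '", profile_id, "'; valid ids: IBP1, IBP2")
  profile_id <- match.arg(profile_id)

  wazm_low  <- function(nm) parameter_spec(nm, "WAZM", "low_is_affected", "cm")
  shared2 <- list(
    parameter_spec("wazm_closed_distance", "WAZM", "low_is_affected", "cm"),
    parameter_spec("wazm_open_time", "WAZM", "low_is_affected", "s"),
    parameter_spec("wazm_open_distance", "WAZM", "low_is_affected", "cm"),
    parameter_spec("wazm_freezing", "WAZM", "high_is_affected", "s"),
    parameter_spec("srt_preference_index", "SRT", "low_is_affected", "index")
  )

  if (profile_id == "IBP1") {
    specs <- list(
      wazm_low("wazm_total_distance"),
      parameter_spec("wazm_closed_time", "WAZM", "high_is_affected", "s"),
      wazm_low("wazm_closed_distance"),
      wazm_low("wazm_open_distance"),
      parameter_spec("wazm_freezing", "WAZM", "high_is_affected", "s"),
      parameter_spec("epm_freezing", "EPM", "high_is_affected", "s"),
      parameter_spec("epm_anxiety_index", "EPM", "high_is_affected", "%")
    )
    parameters <- bind_specs(specs)
    by_tp <- list(post_trauma = parameters$name,
                  post_treatment = parameters$name)
  } else {
    post_trauma_only <- list(
      parameter_spec("oft_total_distance", "OFT", "low_is_affected", "cm"),
      parameter_spec("oft_center_time", "OFT", "low_is_affected", "s")
    )
    post_treatment_only <- list(
      parameter_spec("epm_total_distance", "EPM", "low_is_affected", "cm"),
      parameter_spec("epm_anxiety_index", "EPM", "high_is_affected", "%")
    )
    parameters <- bind_specs(c(shared2, post_trauma_only, post_treatment_only))
    shared_names <- vapply(shared2, function(s) s$name, "")
    by_tp <- list(
      post_trauma = c(shared_names,
                      vapply(post_trauma_only, function(s) s$name, "")),
      post_treatment = c(shared_names,
                         vapply(post_treatment_only, function(s) s$name, ""))
    )
  }

  m <- length(by_tp$post_trauma)
  if (!(k >= 1 && k <= m)) stop("k must satisfy 1 <= k <= m = ", m)
  structure(list(profile_id = profile_id,
                 parameters = parameters,
                 parameters_by_timepoint = by_tp,
                 k = as.integer(k), m = as.integer(m),
                 sd_multiplier = sd_multiplier),
            class = "ibp_profile")
}

#' Parameters of a profile at one time point
#'
#' @param profile An `"ibp_profile"` object.
#' @param timepoint `"post_trauma"` or `"post_treatment"`.
#' @return The spec table (name, source_test, direction, units) for the
#'   ordered parameter list active at that time point.
#' @export
profile_parameters <- function(profile, timepoint = c("post_trauma", "post_treatment")) {
  stopifnot(inherits(profile, "ibp_profile"))
  timepoint <- match.arg(timepoint)
  nms <- profile$parameters_by_timepoint[[timepoint]]
  out <- profile$parameters[match(nms, profile$parameters$name), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' @export
print.ibp_profile <- function(x, ...) {
  cat("Individual behavioral profile:", x$profile_id, "\n")
  cat(sprintf("  rule: affected if >= %d of %d parameters beyond %.3g control SD\n",
              x$k, x$m, x$sd_multiplier))
  for (tp in names(x$parameters_by_timepoint)) {
    tab <- profile_parameters(x, tp)
    cat("  ", tp, ":\n", sep = "")
    for (i in seq_len(nrow(tab)))
      cat(sprintf("    %-22s %-4s %s\n", tab$name[i], tab$source_test[i],
                  tab$direction[i]))
  }
  invisible(x)
}

#' Write a profile definition to JSON
#'
#' Serializes a profile — id, per-time-point parameter lists with
#' directions and units, `k`, `m`, SD multiplier — so custom profiles
#' (e.g. with overridden directions) can be shared and re-read with
#' [read_profile()].
#'
#' @param profile An `"ibp_profile"`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_profile <- function(profile, path) {
  stopifnot(inherits(profile, "ibp_profile"))
  jsonlite::write_json(list(
    profile_id = profile$profile_id,
    parameters = profile$parameters,
    parameters_by_timepoint = profile$parameters_by_timepoint,
    k = profile$k, m = profile$m,
    sd_multiplier = profile$sd_multiplier),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read a profile definition from JSON
#'
#' Inverse of [write_profile()]; validates the k-of-m thresholds and that
#' every listed parameter resolves to exactly one spec with a declared
#' direction.
#'
#' @param path Path to a profile JSON file.
#' @return An `"ibp_profile"`.
#' @export
read_profile <- function(path) {
  js <- jsonlite::read_json(path, simplifyVector = TRUE)
  pars <- as.data.frame(js$parameters, stringsAsFactors = FALSE)
  if (anyDuplicated(pars$name))
    stop("duplicate parameter name in profile file")
  if (!all(pars$direction %in%
           c("low_is_affected", "high_is_affected", "two_sided")))
    stop("invalid direction in profile file")
  by_tp <- lapply(js$parameters_by_timepoint, unlist)
  for (tp in names(by_tp))
    if (!all(by_tp[[tp]] %in% pars$name))
      stop("time point '", tp, "' names a parameter with no spec")
  m <- length(by_tp[[1]])
  if (!(js$k >= 1 && js$k <= m)) stop("k must satisfy 1 <= k <= m")
  structure(list(profile_id = js$profile_id, parameters = pars,
                 parameters_by_timepoint = by_tp,
                 k = as.integer(js$k), m = as.integer(m),
                 sd_multiplier = js$sd_multiplier),
            class = "ibp_profile")
}
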