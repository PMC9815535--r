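#' Normalize a behavioral parameter name
#'
#' Case-folds and converts runs of spaces, hyphens and punctuation to single
#' underscores so that prose-style column headers ("Total distance traveled
#' in WAZM") and identifiers (`wazm_total_distance`) compare consistently.
#'
#' @param x Character vector of names.
#' @return Canonicalized character vector.
#' @export
normalize_parameter_name <- function(x) {
  x <- tolower(trimws(x))
  x <- gsub("[^a-z0-9]+", "_", x)
  gsub("^_+|_+$", "", x)
}

mandatory_cols <- c("animal_id", "group", "timepoint")

#' Assemble a cohort table from a data frame
#'
#' Validates a wide per-animal table (one row per animal and time point, one
#' column per behavioral parameter) against a profile: checks the mandatory
#' identifier columns, enforces uniqueness of (animal_id, timepoint), and
#' marks records that lack any active profile parameter as incomplete rather
#' than dropping them.
#'
#' @param data A data frame with columns `animal_id`, `group`, `timepoint`
#'   plus numeric parameter columns (wide), or long format with columns
#'   `parameter` and `value`.
#' @param profile An `"ibp_profile"` object used to decide completeness.
#' @param provenance Free-text origin (file path, generator seed) stored as
#'   an attribute.
#' @return The validated data frame with class `"ibp_cohort"`, parameter
#'   columns renamed to canonical names, and a logical column `incomplete`.
#' @export
as_cohort <- function(data, profile, provenance = "in-memory") {
  stopifnot(is.data.frame(data), inherits(profile, "ibp_profile"))
  data <- as.data.frame(data, stringsAsFactors = FALSE)
  idx <- match(mandatory_cols, normalize_parameter_name(names(data)))
  names(data)[idx[!is.na(idx)]] <- mandatory_cols[!is.na(idx)]
  missing_cols <- setdiff(mandatory_cols, names(data))
  if (length(missing_cols))
    stop("cohort table lacks mandatory column(s): ",
         paste(missing_cols, collapse = ", "))

  if (all(c("parameter", "value") %in% names(data))) {
    data <- pivot_long_cohort(data)
  }

  param_cols <- setdiff(names(data), c(mandatory_cols, "incomplete"))
  names(data)[match(param_cols, names(data))] <-
    normalize_parameter_name(param_cols)
  param_cols <- setdiff(names(data), c(mandatory_cols, "incomplete"))

  for (pc in param_cols) {
    v <- data[[pc]]
    if (!is.numeric(v)) {
      conv <- suppressWarnings(as.numeric(as.character(v)))
      bad <- which(!is.na(as.character(v)) & as.character(v) != "" & is.na(conv))
      if (length(bad))
        stop(sprintf("non-numeric value '%s' in column '%s', row %d",
                     as.character(v)[bad[1]], pc, bad[1]))
      conv[as.character(v) == ""] <- NA_real_
      data[[pc]] <- conv
    }
  }

  key <- paste(data$animal_id, data$timepoint, sep = "\r")
  if (anyDuplicated(key))
    stop("duplicate (animal_id, timepoint): ",
         paste(unique(sub("\r", " @ ", key[duplicated(key)])), collapse = ", "))

  data$incomplete <- !vapply(seq_len(nrow(data)), function(i) {
    tp <- data$timepoint[i]
    need <- profile$parameters_by_timepoint[[tp]]
    if (is.null(need)) return(TRUE)          # unknown time point: unusable
    all(need %in% param_cols) && !anyNA(unlist(data[i, need]))
  }, logical(1))

  attr(data, "provenance") <- provenance
  class(data) <- c("ibp_cohort", "data.frame")
  data
}

# long (animal_id, group, timepoint, parameter, value) -> wide
pivot_long_cohort <- function(data) {
  data$parameter <- normalize_parameter_name(data$parameter)
  wide <- stats::reshape(
    data[, c(mandatory_cols, "parameter", "value")],
    idvar = mandatory_cols, timevar = "parameter", direction = "wide")
  names(wide) <- sub("^value\\.", "", names(wide))
  rownames(wide) <- NULL
  wide
}

#' Read a cohort CSV
#'
#' Reads a wide or long behavioral cohort table and validates it against a
#' profile (see [as_cohort()] for the contract). Incomplete records are
#' flagged, never silently dropped; row order is preserved.
#'
#' @param path Path to a UTF-8 CSV with "." as decimal separator.
#' @param profile An `"ibp_profile"` object.
#' @return An `"ibp_cohort"` data frame.
#' @export
read_cohort <- function(path, profile) {
  data <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  as_cohort(data, profile, provenance = path)
}

#' Write a cohort CSV
#'
#' Inverse of [read_cohort()]: writes the wide canonical form (the
#' bookkeeping column `incomplete` is omitted).
#'
#' @param cohort An `"ibp_cohort"` data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  out <- as.data.frame(cohort)
  out$incomplete <- NULL
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @export
print.ibp_cohort <- function(x, ...) {
  cat(sprintf("IBP cohort: %d records (%d incomplete), groups: %s\n",
              nrow(x), sum(x$incomplete),
              paste(sort(unique(x$group)), collapse = ", ")))
  cat("provenance:", attr(x, "provenance"), "\n")
  NextMethod()
}
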