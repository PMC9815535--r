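#' Configuration for the synthetic cohort generator
#'
#' Defaults mirror the design the profiling analysis was built for: a small
#' control group (n = 16) anchoring the cutoffs, a large trauma-exposed
#' group (n = 93), a majority of exposed animals affected, and fewer than
#' half of the affected animals responding to treatment. The seven
#' behavioral parameters are modeled as an equicorrelated Gaussian vector:
#' one latent anxiety construct loads on every readout in its pathological
#' direction (a high-anxiety animal travels less and freezes more), so the
#' sign-aligned deviations of any two parameters correlate at `rho`; no
#' distributional
#' summaries are published for the real parameters, so the control means
#' and SDs default to round numbers and carry no empirical meaning.
#'
#' @param n_control Number of control animals (default 16).
#' @param n_exposed Number of trauma-exposed animals (default 93).
#' @param affected_fraction Probability an exposed animal is truly affected
#'   (default 0.6).
#' @param responder_fraction Probability a truly affected animal responds
#'   to treatment (default 0.4).
#' @param effect_size_delta Shift, in control-SD units, applied to each of
#'   an affected animal's shifted parameters in its pathological direction
#'   (default 2).
#' @param affected_param_count How many of the m parameters an affected
#'   animal shifts on: an integer or `"all"` (default 5, so the 4-of-7
#'   decision boundary is exercised rather than saturated).
#' @param rho Equicorrelation of the parameter vector, in \[0, 1)
#'   (default 0.2).
#' @param control_means,control_sds Scalars or vectors (recycled over the
#'   parameters, in profile order) of control-population means and SDs
#'   (defaults 100 and 15).
#' @param responder_residual_delta Residual shift (SD units) retained by
#'   responders after treatment; 0 (default) is complete reversion to the
#'   control distribution.
#' @param seed Integer seed making the cohort reproducible.
#' @return List of class `"ibp_sim_config"`.
#' @export
cohort_config <- function(n_control = 16, n_exposed = 93,
                          affected_fraction = 0.6, responder_fraction = 0.4,
                          effect_size_delta = 2, affected_param_count = 5,
                          rho = 0.2, control_means = 100, control_sds = 15,
                          responder_residual_delta = 0, seed = 1L) {
  stopifnot(n_control >= 2, n_exposed >= 0,
            affected_fraction >= 0, affected_fraction <= 1,
            responder_fraction >= 0, responder_fraction <= 1,
            effect_size_delta >= 0, all(control_sds > 0),
            responder_residual_delta >= 0)
  if (!(is.numeric(rho) && rho >= 0 && rho < 1))
    stop("rho must lie in [0, 1) for a positive-definite equicorrelation")
  structure(list(n_control = n_control, n_exposed = n_exposed,
                 affected_fraction = affected_fraction,
                 responder_fraction = responder_fraction,
                 effect_size_delta = effect_size_delta,
                 affected_param_count = affected_param_count,
                 rho = rho, control_means = control_means,
                 control_sds = control_sds,
                 responder_residual_delta = responder_residual_delta,
                 seed = as.integer(seed)),
            class = "ibp_sim_config")
}

# n x m standard-normal draws from a one-factor model: each column loads
# sqrt(rho) on a shared latent factor with column sign sgn (exact
# equicorrelation rho between the sign-aligned deviations, rho >= 0)
rmvn_equicorr <- function(n, m, rho, sgn = rep(1, m)) {
  shared <- stats::rnorm(n)
  z <- matrix(stats::rnorm(n * m), n, m)
  outer(shared, sgn * sqrt(rho)) + sqrt(1 - rho) * z
}

#' Generate a synthetic behavioral cohort with ground truth
#'
#' Draws a two-time-point cohort with the statistical structure the
#' profiling pipeline assumes: controls from an equicorrelated Gaussian at
#' both time points; exposed animals affected with probability
#' `affected_fraction`, shifted by `effect_size_delta` control SDs in each
#' shifted parameter's pathological direction at post-trauma; after
#' treatment, a `responder_fraction` of the affected animals revert to the
#' control distribution (up to `responder_residual_delta`) while
#' non-responders retain the full shift. For profiles whose parameter list
#' differs between time points, the shifted parameter positions (chosen
#' once per animal) index the ordered list of each time point, so shared
#' parameters stay aligned.
#'
#' @param config An `"ibp_sim_config"` from [cohort_config()].
#' @param profile Profile (object or id) whose parameter lists and
#'   directions shape the cohort (default `"IBP1"`).
#' @param seed Overrides `config$seed`.
#' @return List of class `"ibp_sim"`: `cohort` (an `"ibp_cohort"` with
#'   both time points), `truth` (data frame: `animal_id`, `group`,
#'   `true_affected`, `true_responder`, `shifted_params`), `config`,
#'   `profile`.
#' @examples
#' sim <- simulate_cohort(cohort_config(seed = 7))
#' table(sim$truth$true_affected, sim$truth$group)
#' @export
simulate_cohort <- function(config = cohort_config(), profile = "IBP1",
                            seed = config$seed) {
  stopifnot(inherits(config, "ibp_sim_config"))
  if (is.character(profile)) profile <- ibp_profile(profile)
  if (!is.null(seed)) set.seed(seed)

  tps <- names(profile$parameters_by_timepoint)
  m <- profile$m
  n_c <- config$n_control
  n_e <- config$n_exposed
  k_shift <- if (identical(config$affected_param_count, "all")) m
             else as.integer(config$affected_param_count)
  stopifnot(k_shift >= 1, k_shift <= m)

  ids <- c(sprintf("C%02d", seq_len(n_c)), sprintf("E%02d", seq_len(n_e)))
  group <- rep(c("control", "exposed"), c(n_c, n_e))
  affected <- c(rep(FALSE, n_c),
                stats::runif(n_e) < config$affected_fraction)
  responder <- ifelse(affected, stats::runif(n_c + n_e) < config$responder_fraction,
                      NA)
  shift_pos <- lapply(seq_len(n_c + n_e), function(i)
    if (affected[i]) sort(sample.int(m, k_shift)) else integer(0))

  make_tp <- function(tp) {
    spec <- profile_parameters(profile, tp)
    mu <- rep_len(config$control_means, m)
    sd <- rep_len(config$control_sds, m)
    sgn <- ifelse(spec$direction == "low_is_affected", -1, 1)
    z <- rmvn_equicorr(n_c + n_e, m, config$rho, sgn = sgn)
    x <- sweep(sweep(z, 2, sd, `*`), 2, mu, `+`)
    for (i in seq_len(n_c + n_e)) {
      if (!affected[i]) next
      d <- if (tp == "post_trauma") config$effect_size_delta
           else if (isTRUE(responder[i])) config$responder_residual_delta
           else config$effect_size_delta
      if (d > 0) {
        p <- shift_pos[[i]]
        x[i, p] <- x[i, p] + sgn[p] * d * sd[p]
      }
    }
    out <- data.frame(animal_id = ids, group = group, timepoint = tp,
                      stringsAsFactors = FALSE)
    xdf <- as.data.frame(x)
    names(xdf) <- spec$name
    cbind(out, xdf)
  }

  tabs <- lapply(tps, make_tp)
  all_params <- unique(unlist(lapply(tabs, function(t)
    setdiff(names(t), mandatory_cols))))
  tabs <- lapply(tabs, function(t) {
    for (p in setdiff(all_params, names(t))) t[[p]] <- NA_real_
    t[, c(mandatory_cols, all_params)]
  })
  cohort <- as_cohort(do.call(rbind, tabs), profile,
                      provenance = paste0("simulate_cohort(seed=", seed, ")"))

  truth <- data.frame(
    animal_id = ids, group = group, true_affected = affected,
    true_responder = responder,
    shifted_params = vapply(shift_pos, function(p)
      paste(profile$parameters_by_timepoint$post_trauma[p], collapse = ";"), ""),
    stringsAsFactors = FALSE)

  structure(list(cohort = cohort, truth = truth, config = config,
                 profile = profile),
            class = "ibp_sim")
}

#' @export
print.ibp_sim <- function(x, ...) {
  cat(sprintf(
    "Synthetic IBP cohort (%s, seed %s): %d controls, %d exposed (%d truly affected)\n",
    x$profile$profile_id, deparse(x$config$seed),
    x$config$n_control, x$config$n_exposed, sum(x$truth$true_affected)))
  invisible(x)
}

#' Hand-verifiable 12-animal worked example
#'
#' A fixed toy cohort (5 controls, 7 trauma-exposed animals, both time
#' points, IBP1 parameters) whose cutoffs and labels can be checked by
#' hand. Every parameter's control values are a permutation of
#' 10, 12, 14, 16, 18, so each cutoff is mean 14 plus or minus one sample
#' SD `sqrt(10) = 3.16228`: 10.83772 below, 17.16228 above. Animal E02 is
#' affected with exactly 5 flagged parameters; after treatment E02 and E03
#' are responders while E05 (all 7 flags retained) and E06 (4 retained)
#' are non-responders. The construction is deterministic; re-writing it
#' with [write_cohort()] is byte-stable.
#'
#' @return An `"ibp_cohort"` with 24 rows (12 animals x 2 time points).
#' @examples
#' fit <- ibp(worked_example(), "IBP1")
#' fit$proportions
#' @export
worked_example <- function() {
  prof <- ibp_profile("IBP1")
  params <- prof$parameters_by_timepoint$post_trauma
  base <- c(10, 12, 14, 16, 18)
  ctrl <- t(vapply(1:5, function(i)
    base[((i - 1 + seq_len(7) - 1) %% 5) + 1], numeric(7)))

  # exposed post-trauma rows; columns follow the IBP1 parameter order:
  # total dist, closed time, closed dist, open dist, wazm freeze,
  # epm freeze, anxiety index
  exp_pre <- rbind(
    E01 = c(14, 14, 14, 14, 14, 14, 14),        # 0 flags
    E02 = c(8, 20, 9, 14, 19, 18, 15),          # 5 flags
    E03 = c(10, 18, 10, 14, 18, 14, 14),        # 4 flags
    E04 = c(10, 18, 10, 14, 14, 14, 14),        # 3 flags
    E05 = c(8, 20, 8, 8, 20, 20, 20),           # 7 flags
    E06 = c(9, 19, 14, 9, 19, 14, 19),          # 5 flags
    E07 = c(10, 14, 14, 14, 14, 14, 14))        # 1 flag
  exp_post <- rbind(
    E01 = c(14, 14, 14, 14, 14, 14, 14),
    E02 = c(14, 14, 14, 14, 14, 14, 14),        # full remission -> responder
    E03 = c(10, 18, 14, 14, 14, 14, 14),        # 2 flags -> responder
    E04 = c(10, 18, 10, 14, 14, 14, 14),
    E05 = c(8, 20, 8, 8, 20, 20, 20),           # 7 flags -> non-responder
    E06 = c(9, 19, 14, 9, 19, 14, 14),          # 4 flags -> non-responder
    E07 = c(10, 14, 14, 14, 14, 14, 14))

  row_df <- function(vals, ids, grp, tp) {
    out <- data.frame(animal_id = ids, group = grp, timepoint = tp,
                      stringsAsFactors = FALSE)
    v <- as.data.frame(vals)
    names(v) <- params
    rownames(v) <- NULL
    cbind(out, v)
  }
  tab <- rbind(
    row_df(ctrl, sprintf("C%02d", 1:5), "control", "post_trauma"),
    row_df(exp_pre, rownames(exp_pre), "exposed", "post_trauma"),
    row_df(ctrl, sprintf("C%02d", 1:5), "control", "post_treatment"),
    row_df(exp_post, rownames(exp_post), "exposed", "post_treatment"))
  as_cohort(tab, prof, provenance = "worked_example()")
}
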