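#' Run the full discovery pipeline
#'
#' Orchestrates the discovery-cohort analysis end to end: complete-case
#' filtering on dimensions, interval and survival; shape-by-law model-grid
#' ranking by AIC; log-rank-optimised cutpoint under the winning
#' combination; SM-INVIGOR labelling with survival report; multivariate
#' confounder adjustment; feature screening and sequential selection of the
#' KNN surrogate. Every numeric output is reproducible from the cohort,
#' the options and the seed.
#'
#' @param cohort A \code{cohort_table} with paired dimensions and survival.
#' @param horizon_months AIC-ranking horizon (default 120).
#' @param min_group_frac Minimum per-arm fraction for the cutpoint search.
#' @param threshold_p Feature-screening admission threshold.
#' @param folds,repeats,budget Surrogate cross-validation / search control.
#' @param seed Integer seed for the surrogate stage.
#' @param adjusters Multivariate Cox adjusters.
#' @return A \code{discovery_result} list: \code{grid}, \code{best}
#'   (shape/law/threshold actually applied), \code{sm} (labelled cohort +
#'   survival report), \code{multivariate} (adjusted Cox), \code{screening},
#'   \code{surrogate} (frozen model) and \code{manifest} (options + seed).
#' @export
run_discovery <- function(cohort, horizon_months = 120,
                          min_group_frac = 0.10, threshold_p = 0.2,
                          folds = 5, repeats = 100, budget = 180,
                          seed = 1,
                          adjusters = c("grade", "age_years", "er_status")) {
  stopifnot(inherits(cohort, "cohort_table"))
  cohort <- complete_case_subset(cohort, c(
    "screen_dim_major", "screen_dim_minor", "diag_dim_major",
    "diag_dim_minor", "interval_days", "bcss_months", "event"))
  if (nrow(cohort) == 0L) stop("no complete-case records", call. = FALSE)

  grid <- rank_models(cohort, horizon_months = horizon_months,
                      min_group_frac = min_group_frac)
  best <- grid$best
  spec <- .spec_from_entry(best)
  # the applied threshold: from the winning dichotomised entry, or from a
  # fresh cutpoint search when the continuous form won
  if (best$form == "dichotomised") {
    threshold <- best$cutpoint
  } else {
    rr <- cohort_rates(cohort, shape = best$shape, spec = spec)
    cens <- administrative_censor(cohort$bcss_months, cohort$event,
                                  horizon_months)
    ok <- !is.na(rr$rate)
    threshold <- optimise_cutpoint(rr$rate[ok], cens$time[ok],
                                   cens$event[ok],
                                   min_group_frac = min_group_frac)$threshold
  }
  sm <- compute_sm_invigor(cohort, shape = best$shape, spec = spec,
                           threshold = threshold,
                           horizon_months = horizon_months)
  multi <- tryCatch(
    multivariate_adjustment(sm$cohort, adjusters = adjusters),
    error = function(e) NULL)

  lab_ok <- !is.na(sm$cohort$growth_group)
  fm <- surrogate_features(sm$cohort[lab_ok, , drop = FALSE])
  labels <- droplevels(sm$cohort$growth_group[lab_ok][fm$rows])
  screening <- screen_features(fm$x, labels, threshold_p = threshold_p)
  surrogate <- sequential_select(fm$x, labels, screening, budget = budget,
                                 folds = folds, repeats = repeats,
                                 seed = seed)
  structure(list(
    grid = grid,
    best = list(shape = best$shape, law = best$law, spec = spec,
                form = best$form, aic = best$aic, threshold = threshold),
    sm = sm,
    multivariate = multi,
    screening = screening,
    surrogate = surrogate,
    manifest = list(n = nrow(cohort), horizon_months = horizon_months,
                    min_group_frac = min_group_frac,
                    threshold_p = threshold_p, folds = folds,
                    repeats = repeats, budget = budget, seed = seed)
  ), class = "discovery_result")
}

.spec_from_entry <- function(entry) {
  switch(entry$law,
         exponential = growth_spec("exponential"),
         gompertz = growth_spec("gompertz", K = entry$K),
         growth_spec("power", alpha = entry$alpha))
}

#' @export
print.discovery_result <- function(x, ...) {
  cat("<discovery_result>\n")
  cat(sprintf("  winning model: %s / %s (%s form, AIC = %.3f)\n",
              x$best$shape, x$best$law, x$best$form, x$best$aic))
  cat(sprintf("  cutpoint: %.6g (n_slow = %d, n_fast = %d)\n",
              x$best$threshold,
              sum(x$sm$cohort$growth_group == "slow", na.rm = TRUE),
              sum(x$sm$cohort$growth_group == "fast", na.rm = TRUE)))
  cat(sprintf("  surrogate: KNN k = %d on [%s], CV accuracy = %.3f\n",
              x$surrogate$k, paste(x$surrogate$features, collapse = ", "),
              x$surrogate$cv_accuracy))
  invisible(x)
}

#' Run the validation pipeline
#'
#' Applies a frozen surrogate model to an independent cohort and produces
#' the KM / log-rank / adjusted Cox validation report.
#'
#' @param model A \code{surrogate_model}.
#' @param cohort The validation \code{cohort_table}.
#' @param confounders Adjusters for the multivariate Cox fit.
#' @param horizon_months Horizon for the survival-percentage summary.
#' @return The \code{\link{apply_surrogate}} result.
#' @export
run_validation <- function(model, cohort,
                           confounders = c("grade", "age_years",
                                           "er_status"),
                           horizon_months = 120) {
  apply_surrogate(model, cohort, confounders = confounders,
                  horizon_months = horizon_months)
}

#' Serialise a discovery report as JSON text
#'
#' A deterministic JSON rendering of the headline numbers of a discovery
#' run (model grid, winning combination, cutpoint, group survival,
#' multivariate HRs, screening table, surrogate configuration). Identical
#' inputs yield byte-identical text.
#'
#' @param result A \code{discovery_result}.
#' @param path Optional path; when given the JSON is written there.
#' @return The JSON string, invisibly when \code{path} is given.
#' @export
discovery_report_json <- function(result, path = NULL) {
  stopifnot(inherits(result, "discovery_result"))
  rep <- list(
    grid = result$grid$entries,
    best = result$best[c("shape", "law", "form", "aic", "threshold")],
    groups = list(
      n_slow = sum(result$sm$cohort$growth_group == "slow", na.rm = TRUE),
      n_fast = sum(result$sm$cohort$growth_group == "fast", na.rm = TRUE)),
    survival_at_horizon = as.list(result$sm$report$survival_at_horizon),
    logrank = result$sm$report$logrank[c("chi_square", "p_value")],
    multivariate = if (!is.null(result$multivariate)) list(
      hazard_ratios = as.list(result$multivariate$hazard_ratios),
      p_values = as.list(result$multivariate$p_values)),
    screening = result$screening$table,
    surrogate = list(features = result$surrogate$features,
                     k = result$surrogate$k,
                     cv_accuracy = result$surrogate$cv_accuracy),
    manifest = result$manifest)
  txt <- jsonlite::toJSON(rep, auto_unbox = TRUE, digits = NA,
                          dataframe = "rows", na = "null", pretty = TRUE)
  if (!is.null(path)) {
    writeLines(txt, path)
    return(invisible(as.character(txt)))
  }
  as.character(txt)
}
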