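#' Optimise the fast/slow growth-rate cutpoint by log-rank statistic
#'
#' Maximal-selection search for the rate threshold that best separates
#' survival: candidate thresholds are the midpoints between consecutive
#' distinct sorted rates, restricted so that each side retains at least
#' \code{min_group_frac} of the patients; the candidate maximising the
#' two-group log-rank chi-square wins, with ties broken towards the smaller
#' threshold. "Fast" means rate strictly greater than the threshold.
#'
#' The maximally selected p-value is optimistic (multiple testing over
#' candidates); the raw p is reported, and a permutation-adjusted p is
#' available via \code{n_perm}.
#'
#' @param rates Per-patient growth rates (no missing values).
#' @param time,event Survival outcome (months, 1/0).
#' @param min_group_frac Minimum fraction of patients per arm (default 0.10).
#' @param n_perm Number of permutations for the adjusted p-value (0 = skip).
#' @return A \code{cutpoint_result} list: \code{threshold},
#'   \code{chi_square}, \code{p_value} (raw), \code{p_perm} (or \code{NA}),
#'   \code{n_slow}, \code{n_fast}, \code{labels} (factor slow/fast) and the
#'   full \code{candidates} table (threshold, chi_square).
#' @export
optimise_cutpoint <- function(rates, time, event, min_group_frac = 0.10,
                              n_perm = 0) {
  stopifnot(length(rates) == length(time), length(event) == length(time),
            min_group_frac > 0, min_group_frac <= 0.5)
  if (anyNA(rates)) stop("rates must be non-missing", call. = FALSE)
  n <- length(rates)
  if (sum(event) < 1) stop("at least one event required", call. = FALSE)
  srt <- sort(unique(rates))
  if (length(srt) < 2L) {
    stop("all rates identical: no admissible cutpoint", call. = FALSE)
  }
  mids <- (srt[-1] + srt[-length(srt)]) / 2
  min_count <- ceiling(min_group_frac * n)
  n_below <- vapply(mids, function(th) sum(rates <= th), numeric(1))
  keep <- n_below >= min_count & (n - n_below) >= min_count
  mids <- mids[keep]
  if (!length(mids)) {
    stop("no admissible cutpoint under min_group_frac = ", min_group_frac,
         call. = FALSE)
  }
  prep <- .logrank_prepare(time, event)
  scan <- function(r) {
    vapply(mids, function(th) .logrank_chisq(prep, r > th)["chisq"],
           numeric(1))
  }
  chis <- scan(rates)
  best <- which.max(chis)               # which.max takes the first (smaller
  threshold <- mids[best]               # threshold) on exact ties
  labels <- factor(ifelse(rates > threshold, "fast", "slow"),
                   levels = c("slow", "fast"))
  p_perm <- NA_real_
  if (n_perm > 0) {
    exceed <- vapply(seq_len(n_perm), function(b) {
      max(scan(sample(rates))) >= chis[best]
    }, logical(1))
    p_perm <- (sum(exceed) + 1) / (n_perm + 1)
  }
  structure(list(
    threshold = threshold,
    chi_square = chis[best],
    p_value = stats::pchisq(chis[best], df = 1, lower.tail = FALSE),
    p_perm = p_perm,
    n_slow = sum(labels == "slow"),
    n_fast = sum(labels == "fast"),
    labels = labels,
    candidates = data.frame(threshold = mids, chi_square = chis)
  ), class = "cutpoint_result")
}

#' @export
print.cutpoint_result <- function(x, ...) {
  cat(sprintf(
    "<cutpoint_result> threshold = %.6g, chi2 = %.4f (p = %.4g), %d slow / %d fast\n",
    x$threshold, x$chi_square, x$p_value, x$n_slow, x$n_fast))
  invisible(x)
}

#' Rank every shape-by-law growth model by prognostic AIC
#'
#' For each of the 3 shape assumptions x 4 growth laws, per-patient rates
#' are computed and fed to univariate Cox models on 10-year survival in two
#' forms — the continuous rate, and the fast/slow dichotomisation at the
#' log-rank-optimised cutpoint — giving a 24-entry grid ranked by AIC
#' (lower is better). A (shape, law) whose rates are domain-invalid for more
#' than 10\% of patients is marked failed and excluded from ranking.
#'
#' @param cohort A \code{cohort_table} with dimensions, interval and
#'   survival present (apply \code{\link{complete_case_subset}} first).
#' @param horizon_months Administrative-censoring horizon for the univariate
#'   fits (default 120 = 10-year survival).
#' @param min_group_frac Minimum per-arm fraction for the cutpoint search.
#' @param grid Model grid (see \code{\link{default_model_grid}}).
#' @param sphere_rule Sphere diameter rule.
#' @param max_invalid_frac Failure threshold for a (shape, law) entry.
#' @return A \code{model_grid_result}: data frame \code{entries} sorted
#'   ascending by AIC with columns shape, law, alpha, K, form, aic, coef,
#'   hr, p, cutpoint, chi_square, n_slow, n_fast, failed, note; plus
#'   \code{best} (the winning row) and the call parameters.
#' @export
rank_models <- function(cohort, horizon_months = 120, min_group_frac = 0.10,
                        grid = default_model_grid(), sphere_rule = "mean",
                        max_invalid_frac = 0.10) {
  stopifnot(inherits(cohort, "cohort_table"))
  if (nrow(cohort) == 0L) stop("empty cohort", call. = FALSE)
  if (anyNA(cohort$bcss_months) || anyNA(cohort$event)) {
    stop("survival outcome missing for some records; apply ",
         "complete_case_subset first", call. = FALSE)
  }
  cens <- administrative_censor(cohort$bcss_months, cohort$event,
                                horizon_months)
  if (sum(cens$event) == 0) {
    stop("no events within the horizon: models cannot be ranked",
         call. = FALSE)
  }
  rows <- list()
  for (shape in grid$shapes) {
    for (law_name in names(grid$laws)) {
      spec <- grid$laws[[law_name]]
      rr <- cohort_rates(cohort, shape = shape, spec = spec,
                         sphere_rule = sphere_rule)
      invalid <- mean(is.na(rr$rate))
      base <- data.frame(shape = shape, law = law_name,
                         alpha = if (is.null(spec$alpha)) NA_real_ else spec$alpha,
                         K = if (is.null(spec$K)) NA_real_ else spec$K,
                         stringsAsFactors = FALSE)
      if (invalid > max_invalid_frac) {
        for (form in c("continuous", "dichotomised")) {
          rows[[length(rows) + 1L]] <- cbind(
            base, form = form, aic = NA_real_, coef = NA_real_,
            hr = NA_real_, p = NA_real_, cutpoint = NA_real_,
            chi_square = NA_real_, n_slow = NA_integer_,
            n_fast = NA_integer_, failed = TRUE,
            note = sprintf("%.0f%% of rates domain-invalid", 100 * invalid))
        }
        next
      }
      ok <- !is.na(rr$rate)
      rts <- rr$rate[ok]
      tm <- cens$time[ok]; ev <- cens$event[ok]
      cont <- tryCatch(
        fit_cox(tm, ev, data.frame(rate = rts)),
        error = function(e) conditionMessage(e))
      if (is.character(cont)) {
        rows[[length(rows) + 1L]] <- cbind(
          base, form = "continuous", aic = NA_real_, coef = NA_real_,
          hr = NA_real_, p = NA_real_, cutpoint = NA_real_,
          chi_square = NA_real_, n_slow = NA_integer_, n_fast = NA_integer_,
          failed = TRUE, note = cont)
      } else {
        rows[[length(rows) + 1L]] <- cbind(
          base, form = "continuous", aic = cont$aic,
          coef = unname(cont$coefficients[1]),
          hr = unname(cont$hazard_ratios[1]),
          p = unname(cont$p_values[1]), cutpoint = NA_real_,
          chi_square = NA_real_, n_slow = NA_integer_, n_fast = NA_integer_,
          failed = FALSE, note = NA_character_)
      }
      dich <- tryCatch({
        cp <- optimise_cutpoint(rts, tm, ev, min_group_frac = min_group_frac)
        fit <- fit_cox(tm, ev, data.frame(group = cp$labels))
        list(cp = cp, fit = fit)
      }, error = function(e) conditionMessage(e))
      if (is.character(dich)) {
        rows[[length(rows) + 1L]] <- cbind(
          base, form = "dichotomised", aic = NA_real_, coef = NA_real_,
          hr = NA_real_, p = NA_real_, cutpoint = NA_real_,
          chi_square = NA_real_, n_slow = NA_integer_, n_fast = NA_integer_,
          failed = TRUE, note = dich)
      } else {
        rows[[length(rows) + 1L]] <- cbind(
          base, form = "dichotomised", aic = dich$fit$aic,
          coef = unname(dich$fit$coefficients[1]),
          hr = unname(dich$fit$hazard_ratios[1]),
          p = unname(dich$fit$p_values[1]), cutpoint = dich$cp$threshold,
          chi_square = dich$cp$chi_square, n_slow = dich$cp$n_slow,
          n_fast = dich$cp$n_fast, failed = FALSE, note = NA_character_)
      }
    }
  }
  entries <- do.call(rbind, rows)
  entries <- entries[order(is.na(entries$aic), entries$aic), , drop = FALSE]
  rownames(entries) <- NULL
  if (all(entries$failed)) stop("every grid entry failed", call. = FALSE)
  structure(list(entries = entries,
                 best = entries[1, , drop = FALSE],
                 horizon_months = horizon_months,
                 min_group_frac = min_group_frac,
                 sphere_rule = sphere_rule),
            class = "model_grid_result")
}

#' @export
print.model_grid_result <- function(x, ...) {
  cat(sprintf("<model_grid_result> %d entries (horizon %g months)\n",
              nrow(x$entries), x$horizon_months))
  cat("best:", x$best$shape, "/", x$best$law, "/", x$best$form,
      sprintf("(AIC = %.3f)\n", x$best$aic))
  print(utils::head(x$entries[, c("shape", "law", "form", "aic", "hr", "p",
                                  "cutpoint")], 8))
  invisible(x)
}

#' Label a cohort with SM-INVIGOR fast/slow growth groups
#'
#' Applies a chosen shape, growth law and rate threshold to a cohort:
#' per-patient rates are computed, each patient is labelled fast iff rate is
#' strictly greater than the threshold, and (when survival is available and
#' both groups are populated) a KM / log-rank / univariate Cox report
#' comparing the groups is produced.
#'
#' @param cohort A \code{cohort_table}.
#' @param shape Shape assumption.
#' @param spec A \code{growth_spec}.
#' @param threshold Rate threshold (paper-unit mm3/day scale).
#' @param sphere_rule Sphere diameter rule.
#' @param horizon_months Horizon for the survival-percentage summary.
#' @return A list: \code{cohort} (input plus \code{rate} and
#'   \code{growth_group} columns), \code{threshold}, and \code{report}
#'   (KM curves, group survival at the horizon, log-rank, Cox) or NULL when
#'   no test is possible.
#' @export
compute_sm_invigor <- function(cohort, shape, spec, threshold,
                               sphere_rule = "mean", horizon_months = 120) {
  stopifnot(is.finite(threshold))
  rr <- cohort_rates(cohort, shape = shape, spec = spec,
                     sphere_rule = sphere_rule)
  labelled <- as.data.frame(cohort)
  labelled$rate <- rr$rate
  labelled$growth_group <- factor(
    ifelse(is.na(rr$rate), NA, ifelse(rr$rate > threshold, "fast", "slow")),
    levels = c("slow", "fast"))
  report <- NULL
  ok <- !is.na(labelled$growth_group) & !is.na(labelled$bcss_months) &
    !is.na(labelled$event)
  if (sum(ok) > 0 && nlevels(droplevels(labelled$growth_group[ok])) == 2) {
    tm <- labelled$bcss_months[ok]; ev <- labelled$event[ok]
    gr <- labelled$growth_group[ok]
    km <- km_estimate(tm, ev, gr)
    surv_at <- vapply(levels(gr), function(lv) {
      km_survival_at(km[km$group == lv, ], horizon_months)
    }, numeric(1))
    report <- list(
      km = km,
      survival_at_horizon = surv_at,
      horizon_months = horizon_months,
      logrank = logrank_test(tm, ev, gr),
      cox = fit_cox(tm, ev, data.frame(growth_group = gr)))
  } else if (sum(ok) > 0) {
    warning("all labelled patients fall in one group; no group comparison",
            call. = FALSE)
  }
  list(cohort = labelled, threshold = threshold, shape = shape, spec = spec,
       report = report)
}

#' Multivariate Cox adjustment of the growth-group label
#'
#' Fits the SM-INVIGOR label alongside clinicopathological adjusters
#' (default: grade, age and ER status, the confounders controlled for in the
#' discovery analysis) on full follow-up.
#'
#' @param labelled A data frame with \code{growth_group}, survival columns
#'   and the adjuster columns (output of \code{\link{compute_sm_invigor}}).
#' @param adjusters Character vector of adjuster column names; empty reduces
#'   to the univariate fit.
#' @return A \code{cox_fit}.
#' @export
multivariate_adjustment <- function(labelled,
                                    adjusters = c("grade", "age_years",
                                                  "er_status")) {
  stopifnot(is.data.frame(labelled), "growth_group" %in% names(labelled))
  unknown <- setdiff(adjusters, names(labelled))
  if (length(unknown)) {
    stop("adjuster column(s) not present: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  cols <- c("growth_group", adjusters)
  ok <- stats::complete.cases(labelled[, c(cols, "bcss_months", "event")])
  dat <- labelled[ok, , drop = FALSE]
  covs <- dat[, cols, drop = FALSE]
  covs[] <- lapply(covs, function(v) if (is.character(v)) factor(v) else v)
  fit_cox(dat$bcss_months, dat$event, covs)
}
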