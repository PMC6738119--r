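#' Kaplan-Meier product-limit estimate
#'
#' Thin wrapper over \code{survival::survfit} returning the curve as a plain
#' data frame, per group when \code{group} is supplied.
#'
#' @param time Follow-up times in months, non-negative.
#' @param event Event indicator (1 = event, 0 = censored).
#' @param group Optional grouping vector; one curve per level.
#' @return A data frame with columns \code{time}, \code{n_risk},
#'   \code{n_event}, \code{survival} (and \code{group} when grouped).
#' @export
km_estimate <- function(time, event, group = NULL) {
  stopifnot(length(time) == length(event), all(time >= 0),
            all(event %in% c(0, 1)))
  if (is.null(group)) {
    fit <- survival::survfit(survival::Surv(time, event) ~ 1)
    data.frame(time = fit$time, n_risk = fit$n.risk,
               n_event = fit$n.event, survival = fit$surv)
  } else {
    stopifnot(length(group) == length(time))
    if (any(table(group) == 0)) stop("empty group", call. = FALSE)
    g <- factor(group)
    res <- do.call(rbind, lapply(levels(g), function(lv) {
      sel <- g == lv
      cbind(group = lv, km_estimate(time[sel], event[sel]))
    }))
    rownames(res) <- NULL
    res
  }
}

#' Survival probability at a horizon from a KM curve
#'
#' @param km A data frame from \code{\link{km_estimate}} (ungrouped).
#' @param at Horizon in months.
#' @return \eqn{S(at)}: the last estimate at or before \code{at} (1 if no
#'   event time precedes it).
#' @export
km_survival_at <- function(km, at) {
  ev <- km[km$n_event > 0 & km$time <= at, , drop = FALSE]
  if (nrow(ev) == 0L) return(1)
  ev$survival[nrow(ev)]
}

#' Two-group log-rank test
#'
#' Native implementation of the standard (Mantel-Haenszel) two-group
#' log-rank test: at each distinct event time the observed events in group 1
#' are compared with the hypergeometric expectation given the risk sets, and
#' the standardised sum gives a chi-square statistic with 1 df. Implemented
#' directly (rather than via \code{survival::survdiff}) because the
#' log-rank-optimised cutpoint search needs a lean scan over many candidate
#' dichotomisations; \code{survdiff} is used as the independent cross-check
#' in the test suite.
#'
#' @param time Follow-up times, non-negative.
#' @param event Event indicator (1/0).
#' @param group Binary group membership (any two-level vector).
#' @return A list: \code{chi_square}, \code{p_value} (two-sided, from
#'   chi-square with 1 df), \code{observed} and \code{expected} events per
#'   group, \code{variance}.
#' @export
logrank_test <- function(time, event, group) {
  stopifnot(length(time) == length(event), length(group) == length(time))
  g <- factor(group)
  if (nlevels(g) != 2L) stop("group must have exactly two levels",
                             call. = FALSE)
  if (sum(event) == 0) stop("no events: log-rank statistic undefined",
                            call. = FALSE)
  prep <- .logrank_prepare(time, event)
  stat <- .logrank_chisq(prep, g == levels(g)[2L])
  chisq <- stat["chisq"]
  o2 <- stat["o1"]; e2 <- stat["e1"]
  tot <- sum(event)
  list(chi_square = unname(chisq),
       p_value = unname(stats::pchisq(chisq, df = 1, lower.tail = FALSE)),
       observed = stats::setNames(c(tot - o2, o2), levels(g)),
       expected = stats::setNames(c(tot - e2, e2), levels(g)),
       variance = unname(stat["v"]))
}

# Precompute the time-ordered structures shared by every candidate split:
# sorted times, distinct event times, risk-set and event counts, and index
# maps that let per-candidate quantities be computed with cumulative sums.
.logrank_prepare <- function(time, event) {
  n <- length(time)
  ord <- order(time)
  ts <- time[ord]; es <- event[ord] == 1
  ev_times <- unique(ts[es])
  # count of subjects with time strictly below each event time
  below <- findInterval(ev_times, ts, left.open = TRUE)
  n_at <- n - below
  ev_idx <- which(es)                       # sorted positions of events
  ev_group <- match(ts[ev_idx], ev_times)   # which distinct event time
  d_at <- tabulate(ev_group, nbins = length(ev_times))
  list(ord = ord, n = n, ev_times = ev_times, below = below,
       n_at = n_at, d_at = d_at, ev_idx = ev_idx, ev_group = ev_group)
}

# Log-rank chi-square for one binary membership vector (TRUE = group 1),
# given the precomputed structure. Fully vectorised: O(n) per candidate.
.logrank_chisq <- function(prep, member) {
  m <- member[prep$ord]
  cm <- cumsum(m)
  total1 <- cm[prep$n]
  n1 <- total1 - ifelse(prep$below > 0, cm[pmax(prep$below, 1L)], 0)
  d1 <- as.vector(rowsum(as.numeric(m[prep$ev_idx]), prep$ev_group,
                         reorder = TRUE))
  frac <- n1 / prep$n_at
  o1 <- sum(d1)
  e1 <- sum(prep$d_at * frac)
  ok <- prep$n_at > 1
  v <- sum((prep$d_at * frac * (1 - frac) *
              (prep$n_at - prep$d_at) / (prep$n_at - 1))[ok])
  chisq <- if (v > 0) (o1 - e1)^2 / v else 0
  c(chisq = chisq, o1 = o1, e1 = e1, v = v)
}

#' Administrative censoring at a fixed horizon
#'
#' Subjects followed beyond the horizon are censored there: \code{time}
#' truncated to the horizon, \code{event} set to 0. Events at exactly the
#' horizon are kept.
#'
#' @param time Follow-up times in months.
#' @param event Event indicator (1/0).
#' @param horizon_months Positive horizon, e.g. 120 for 10-year survival.
#' @return A list with censored \code{time} and \code{event}.
#' @export
administrative_censor <- function(time, event, horizon_months) {
  stopifnot(horizon_months > 0)
  over <- time > horizon_months
  time[over] <- horizon_months
  event[over] <- 0
  list(time = time, event = event)
}

#' Fit a Cox proportional-hazards model
#'
#' Delegates to \code{survival::coxph} with Efron tie handling; fixes the
#' reporting contract: AIC = 2k - 2 log partial likelihood, Wald p-values,
#' optional administrative censoring at a horizon before fitting.
#'
#' @param time Follow-up times in months.
#' @param event Event indicator (1/0).
#' @param covariates A data frame (or matrix) of covariates; factors allowed.
#' @param horizon_months Optional horizon: times are administratively
#'   censored there before fitting.
#' @return A \code{cox_fit} list: \code{coefficients}, \code{hazard_ratios},
#'   \code{log_partial_likelihood}, \code{aic}, \code{p_values}, \code{k}
#'   (number of estimated parameters), \code{score_test} (score chi-square
#'   at beta = 0) and the underlying \code{fit}.
#' @export
fit_cox <- function(time, event, covariates, horizon_months = NULL) {
  covariates <- as.data.frame(covariates)
  stopifnot(nrow(covariates) == length(time), length(event) == length(time))
  for (nm in names(covariates)) {
    v <- covariates[[nm]]
    u <- unique(v[!is.na(v)])
    if (length(u) <= 1L) {
      stop("covariate '", nm, "' is constant across subjects", call. = FALSE)
    }
  }
  if (!is.null(horizon_months)) {
    cens <- administrative_censor(time, event, horizon_months)
    time <- cens$time; event <- cens$event
  }
  if (sum(event) == 0) stop("no events: Cox model undefined", call. = FALSE)
  dat <- cbind(data.frame(.time = time, .event = event), covariates)
  fml <- stats::as.formula(paste(
    "survival::Surv(.time, .event) ~",
    paste(sprintf("`%s`", names(covariates)), collapse = " + ")))
  fit <- survival::coxph(fml, data = dat, ties = "efron")
  if (any(is.na(stats::coef(fit)))) {
    warning("collinear covariates: some coefficients not estimable",
            call. = FALSE)
  }
  beta <- stats::coef(fit)
  k <- sum(!is.na(beta))
  lnl <- fit$loglik[length(fit$loglik)]
  se <- sqrt(diag(fit$var))
  pv <- 2 * stats::pnorm(-abs(beta[!is.na(beta)] / se))
  structure(list(coefficients = beta,
                 hazard_ratios = exp(beta),
                 log_partial_likelihood = lnl,
                 aic = 2 * k - 2 * lnl,
                 p_values = pv,
                 k = k,
                 score_test = unname(fit$score),
                 n = fit$n, n_event = fit$nevent,
                 fit = fit),
            class = "cox_fit")
}

#' @export
print.cox_fit <- function(x, ...) {
  cat(sprintf("<cox_fit> n = %d, events = %d, lnL = %.4f, AIC = %.4f\n",
              x$n, x$n_event, x$log_partial_likelihood, x$aic))
  tab <- data.frame(coef = x$coefficients,
                    HR = x$hazard_ratios,
                    p = NA_real_)
  tab$p[!is.na(x$coefficients)] <- x$p_values
  print(round(tab, 4))
  invisible(x)
}
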