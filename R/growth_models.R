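#' Specify a tumour growth law
#'
#' Three growth laws are supported, each the solution of an autonomous ODE
#' for tumour volume \eqn{V(t)}:
#' \describe{
#'   \item{exponential}{\eqn{dV/dt = r V}, so \eqn{V(t) = V_0 e^{rt}}.}
#'   \item{power}{\eqn{dV/dt = r V^\alpha} with \eqn{\alpha \in (0,1)}, so
#'     \eqn{V(t) = (V_0^{1-\alpha} + (1-\alpha) r t)^{1/(1-\alpha)}}. The
#'     classic surface-limited exponent is 2/3; 1/2 is an empirically
#'     supported alternative.}
#'   \item{gompertz}{\eqn{dV/dt = r V \ln(K/V)} with carrying capacity
#'     \eqn{K}, so \eqn{V(t) = K (V_0/K)^{\exp(-rt)}}.}
#' }
#' Rates are per day. Power-law rates formally carry units
#' mm^(3(1-alpha))/day; the conventional "mm3/day" label is retained in the
#' unit descriptor for comparability with the mammography literature.
#'
#' @param law \code{"exponential"}, \code{"power"} or \code{"gompertz"}.
#' @param alpha Power-law exponent in (0, 1); required iff \code{law =
#'   "power"}.
#' @param K Gompertz carrying capacity in mm^3; required iff \code{law =
#'   "gompertz"}. Default 1e6 mm^3 (~1e12 cells at 1e9 cells/cm^3, the
#'   conventional lethal-burden bound).
#' @return A \code{growth_spec} object.
#' @export
growth_spec <- function(law = c("exponential", "power", "gompertz"),
                        alpha = NULL, K = NULL) {
  law <- match.arg(law)
  if (law == "power") {
    if (is.null(alpha)) stop("power law requires alpha", call. = FALSE)
    if (!is.numeric(alpha) || length(alpha) != 1L || alpha <= 0 || alpha >= 1)
      stop("alpha must be a single value in (0, 1)", call. = FALSE)
  } else if (!is.null(alpha)) {
    stop("alpha is only meaningful for the power law", call. = FALSE)
  }
  if (law == "gompertz") {
    if (is.null(K)) K <- 1e6
    if (!is.numeric(K) || length(K) != 1L || K <= 0)
      stop("K must be a single positive volume", call. = FALSE)
  } else if (!is.null(K)) {
    stop("K is only meaningful for the Gompertz law", call. = FALSE)
  }
  structure(list(law = law, alpha = alpha, K = K), class = "growth_spec")
}

#' @export
print.growth_spec <- function(x, ...) {
  cat("<growth_spec>", format(x, ...), "\n")
  invisible(x)
}

#' @export
format.growth_spec <- function(x, ...) {
  switch(x$law,
         exponential = "exponential",
         power = sprintf("power (alpha = %g)", x$alpha),
         gompertz = sprintf("gompertz (K = %g mm3)", x$K))
}

#' Unit descriptor for a growth rate
#'
#' @param spec A \code{growth_spec}.
#' @return A string: the formal unit plus the conventional "mm3/day" label
#'   used in the mammography literature.
#' @export
rate_units <- function(spec) {
  stopifnot(inherits(spec, "growth_spec"))
  switch(spec$law,
         exponential = "1/day",
         gompertz = "1/day",
         power = sprintf("mm^%g/day (reported as mm3/day)",
                         3 * (1 - spec$alpha)))
}

#' Forward-simulate tumour volume
#'
#' @param spec A \code{growth_spec}.
#' @param v0 Initial volume(s) in mm^3, positive.
#' @param r Growth rate(s) per day.
#' @param t Elapsed time(s) in days, non-negative.
#' @return Volume(s) at time \code{t}; \code{V(0) = v0} exactly.
#' @examples
#' forward_volume(growth_spec("exponential"), 100, log(2) / 100, 100) # 200
#' @export
forward_volume <- function(spec, v0, r, t) {
  stopifnot(inherits(spec, "growth_spec"))
  if (any(v0 <= 0)) stop("v0 must be positive", call. = FALSE)
  if (any(t < 0)) stop("t must be non-negative", call. = FALSE)
  switch(spec$law,
    exponential = v0 * exp(r * t),
    power = {
      om <- 1 - spec$alpha
      base <- v0^om + om * r * t
      if (any(base <= 0)) {
        stop("power-law volume regressed past zero (v0^(1-alpha) + ",
             "(1-alpha)*r*t <= 0)", call. = FALSE)
      }
      base^(1 / om)
    },
    gompertz = {
      if (any(v0 >= spec$K)) {
        stop("Gompertz requires v0 < K", call. = FALSE)
      }
      spec$K * (v0 / spec$K)^exp(-r * t)
    }
  )
}

#' Invert a growth law to a per-patient rate
#'
#' Closed-form inversion of \code{\link{forward_volume}} from one observed
#' volume pair: exponential \eqn{r = \ln(V_1/V_0)/\Delta t}; power
#' \eqn{r = (V_1^{1-\alpha} - V_0^{1-\alpha}) / ((1-\alpha)\Delta t)};
#' Gompertz \eqn{r = -\ln(\ln(K/V_1)/\ln(K/V_0))/\Delta t}.
#'
#' @param spec A \code{growth_spec}.
#' @param v0,v1 Screening and diagnostic volumes in mm^3, positive (both
#'   \code{< K} under Gompertz); vectors recycle.
#' @param dt Interval(s) in days, positive.
#' @return Rate(s) per day; exact inverse of the forward model, zero iff
#'   \code{v1 == v0}, negative (shrinkage) permitted.
#' @export
invert_rate <- function(spec, v0, v1, dt) {
  stopifnot(inherits(spec, "growth_spec"))
  if (any(v0 <= 0) || any(v1 <= 0)) {
    stop("volumes must be positive", call. = FALSE)
  }
  if (any(dt <= 0)) stop("dt must be positive", call. = FALSE)
  switch(spec$law,
    exponential = log(v1 / v0) / dt,
    power = {
      om <- 1 - spec$alpha
      (v1^om - v0^om) / (om * dt)
    },
    gompertz = {
      if (any(v0 >= spec$K) || any(v1 >= spec$K)) {
        stop("Gompertz requires v0 < K and v1 < K", call. = FALSE)
      }
      -log(log(spec$K / v1) / log(spec$K / v0)) / dt
    }
  )
}

#' Per-patient growth rates for a cohort
#'
#' Maps \code{\link{lesion_volume}} and \code{\link{invert_rate}} over a
#' cohort. Records failing the preconditions (missing dimensions,
#' non-positive interval, volumes outside the Gompertz domain) yield
#' \code{NA} rates with a per-record diagnostic, never silent drops.
#'
#' @param cohort A \code{cohort_table}.
#' @param shape Shape assumption passed to \code{\link{lesion_volume}}.
#' @param spec A \code{growth_spec}.
#' @param sphere_rule Sphere diameter rule (see \code{\link{lesion_volume}}).
#' @return A data frame with one row per record (order preserved):
#'   \code{patient_id}, \code{v0}, \code{v1}, \code{rate}, \code{note}
#'   (\code{NA} when clean, otherwise the diagnostic; negative rates are
#'   flagged "shrinkage"). Attributes \code{shape}, \code{spec} and
#'   \code{unit} record what produced the rates.
#' @export
cohort_rates <- function(cohort,
                         shape = c("sphere", "cylinder", "oblate_spheroid"),
                         spec = growth_spec("power", alpha = 0.5),
                         sphere_rule = "mean") {
  stopifnot(inherits(cohort, "cohort_table"), inherits(spec, "growth_spec"))
  shape <- match.arg(shape)
  n <- nrow(cohort)
  v0 <- v1 <- rate <- rep(NA_real_, n)
  note <- rep(NA_character_, n)
  for (i in seq_len(n)) {
    rec <- cohort[i, ]
    if (is.na(rec$screen_dim_major) || is.na(rec$screen_dim_minor) ||
        is.na(rec$diag_dim_major) || is.na(rec$diag_dim_minor)) {
      note[i] <- "missing dimension(s)"
      next
    }
    if (is.na(rec$interval_days) || rec$interval_days <= 0) {
      note[i] <- "interval_days not positive"
      next
    }
    v0[i] <- lesion_volume(rec$screen_dim_major, rec$screen_dim_minor,
                           shape, sphere_rule)
    v1[i] <- lesion_volume(rec$diag_dim_major, rec$diag_dim_minor,
                           shape, sphere_rule)
    r <- tryCatch(invert_rate(spec, v0[i], v1[i], rec$interval_days),
                  error = function(e) conditionMessage(e))
    if (is.character(r)) {
      note[i] <- r
    } else {
      rate[i] <- r
      if (r < 0) note[i] <- "shrinkage (negative rate)"
    }
  }
  structure(
    data.frame(patient_id = cohort$patient_id, v0 = v0, v1 = v1,
               rate = rate, note = note, stringsAsFactors = FALSE),
    shape = shape, spec = spec, sphere_rule = sphere_rule,
    unit = rate_units(spec))
}

#' Back-date tumour age from a bounded growth rate
#'
#' Solves \code{forward_volume(spec, v_inception, r, t) = v_diag} for
#' \code{t}: the time a tumour growing at rate \code{r} needs to reach the
#' diagnostic volume from an inception volume. With the power law the
#' inception volume may be zero, giving the age after which the tumour was
#' definitely present; exponential and Gompertz growth never leave zero, so
#' they require \code{v_inception > 0}.
#'
#' @param spec A \code{growth_spec}.
#' @param v_diag Diagnostic volume in mm^3, positive.
#' @param r Growth rate per day, positive.
#' @param v_inception Inception volume in mm^3, in \code{[0, v_diag]}.
#' @return Age in days.
#' @examples
#' # bounded slow-group power-law rate back-dates a mean diagnostic volume
#' tumour_age(growth_spec("power", alpha = 0.5), 5573, 0.04593)
#' @export
tumour_age <- function(spec, v_diag, r, v_inception = 0) {
  stopifnot(inherits(spec, "growth_spec"))
  if (any(r <= 0)) stop("r must be positive", call. = FALSE)
  if (any(v_diag <= 0)) stop("v_diag must be positive", call. = FALSE)
  if (any(v_inception < 0) || any(v_inception > v_diag)) {
    stop("v_inception must lie in [0, v_diag]", call. = FALSE)
  }
  switch(spec$law,
    power = {
      om <- 1 - spec$alpha
      (v_diag^om - v_inception^om) / (om * r)
    },
    exponential = {
      if (any(v_inception == 0)) {
        stop("exponential growth requires v_inception > 0", call. = FALSE)
      }
      log(v_diag / v_inception) / r
    },
    gompertz = {
      if (any(v_inception == 0)) {
        stop("Gompertz growth requires v_inception > 0", call. = FALSE)
      }
      if (any(v_diag >= spec$K)) stop("v_diag must be < K", call. = FALSE)
      -log(log(spec$K / v_diag) / log(spec$K / v_inception)) / r
    }
  )
}

#' The default shape-by-law model grid
#'
#' @return A list with \code{shapes} (the three shape assumptions) and
#'   \code{laws} (exponential, power alpha = 1/2, power alpha = 2/3,
#'   Gompertz), the 3 x 4 grid evaluated by \code{\link{rank_models}}.
#' @param K Gompertz carrying capacity for the grid (mm^3).
#' @export
default_model_grid <- function(K = 1e6) {
  list(
    shapes = c("sphere", "cylinder", "oblate_spheroid"),
    laws = list(
      exponential = growth_spec("exponential"),
      power_half = growth_spec("power", alpha = 0.5),
      power_two_thirds = growth_spec("power", alpha = 2 / 3),
      gompertz = growth_spec("gompertz", K = K)
    )
  )
}

#' Days-per-month conversion used throughout
#'
#' @return 30.44, the mean Gregorian month length in days.
#' @export
days_per_month <- function() 30.44
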