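#' Empirical natural-mortality estimators
#'
#' The classical indirect estimators of instantaneous natural mortality
#' \eqn{M} (1/yr) used for data-poor fish and shark stocks. Scalar
#' estimators depend on growth (`k`, `L_inf`), maturity age, longevity or
#' temperature; `m_peterson_wroblewski()` and `m_chen_watanabe()` are
#' age-dependent.
#'
#' Formulas:
#' * Pauly: \eqn{\ln M = -0.0152 - 0.279\ln L_\infty + 0.6543\ln k +
#'   0.463\ln T} (length in cm, temperature in deg C).
#' * Jensen: \eqn{M = 1.6k}, \eqn{M = 1.5k}, \eqn{M = 1.65/t_{mat}}.
#' * Rikhter & Efanov: \eqn{M = 1.521/t_{mat}^{0.72} - 0.155}.
#' * Hoenig (teleost): \eqn{\ln M = 1.46 - 1.01\ln t_{max}}; (cetacean):
#'   \eqn{\ln M = 0.941 - 0.873\ln t_{max}}.
#' * Hewitt & Hoenig: \eqn{M = 4.22/t_{max}}.
#' * Mollet & Cailliet: \eqn{M = -\ln(0.01)/t_{max}} (1% survivorship to
#'   `t_max`).
#' * Peterson & Wroblewski: \eqn{M = 1.92 w^{-0.25}} with w the wet weight
#'   in grams (the regression's native unit; the `W_kg` argument is
#'   converted internally).
#' * Chen & Watanabe: two-phase in age, see [m_chen_watanabe()].
#'
#' @param g A [growth_params()] object.
#' @param temp_C Mean annual water temperature (deg C), > 0.
#' @param k VBGF growth coefficient (1/yr).
#' @param t_mat Age at maturity (yr), > 0; fractional values allowed (and
#'   required to reproduce maturity-based estimates from an inverted growth
#'   curve).
#' @param t_max Maximum observed age (yr), > 0.
#' @param W_kg Wet weight (kg), vectorised.
#'
#' @return Instantaneous natural mortality (1/yr).
#' @seealso [natural_mortality_set()] to evaluate the whole family,
#'   [survival_from_Z()] for the survival conversion.
#' @name mortality_estimators
NULL

#' @rdname mortality_estimators
#' @export
m_pauly <- function(g, temp_C) {
  stopifnot(inherits(g, "growth_params"))
  if (!is.finite(temp_C) || temp_C <= 0)
    stop("Pauly estimator needs a positive water temperature")
  exp(-0.0152 - 0.279 * log(g$L_inf) + 0.6543 * log(g$k) +
        0.463 * log(temp_C))
}

#' @rdname mortality_estimators
#' @export
m_jensen1 <- function(k) {
  stopifnot(k > 0)
  1.6 * k
}

#' @rdname mortality_estimators
#' @export
m_jensen2 <- function(k) {
  stopifnot(k > 0)
  1.5 * k
}

#' @rdname mortality_estimators
#' @export
m_jensen3 <- function(t_mat) {
  stopifnot(t_mat > 0)
  1.65 / t_mat
}

#' @rdname mortality_estimators
#' @export
m_rikhter_efanov <- function(t_mat) {
  stopifnot(t_mat > 0)
  m <- 1.521 / t_mat^0.72 - 0.155
  if (m <= 0) {
    warning("Rikhter-Efanov estimate non-positive at t_mat = ", t_mat,
            "; flagged invalid (NA)")
    return(NA_real_)
  }
  m
}

#' @rdname mortality_estimators
#' @export
m_hoenig_teleost <- function(t_max) {
  stopifnot(t_max > 0)
  exp(1.46 - 1.01 * log(t_max))
}

#' @rdname mortality_estimators
#' @export
m_hoenig_cetacean <- function(t_max) {
  stopifnot(t_max > 0)
  exp(0.941 - 0.873 * log(t_max))
}

#' @rdname mortality_estimators
#' @export
m_hewitt_hoenig <- function(t_max) {
  stopifnot(t_max > 0)
  4.22 / t_max
}

#' @rdname mortality_estimators
#' @export
m_mollet_cailliet <- function(t_max) {
  stopifnot(t_max > 0)
  -log(0.01) / t_max
}

#' @rdname mortality_estimators
#' @export
m_peterson_wroblewski <- function(W_kg) {
  if (any(!is.finite(W_kg)) || any(W_kg <= 0))
    stop("weights must be positive and finite")
  1.92 * (1000 * W_kg)^-0.25
}

#' Chen & Watanabe two-phase age-dependent natural mortality
#'
#' Juvenile phase \eqn{M(t) = k / (1 - e^{-k (t - t_0)})} for integer ages
#' up to `floor(t_mat)`, senescent phase
#' \eqn{M(t) = \ln[(e^{k t_{max}} - e^{k t_0}) / (e^{k t} - e^{k t_0})] /
#' (t_{max} - t)} from the first integer age above `t_mat`. At exactly
#' `t = t_max` the senescent expression is 0/0; its analytic limit
#' \eqn{k e^{k t_{max}} / (e^{k t_{max}} - e^{k t_0})} is used so schedules
#' can cover the full 0..`t_max` grid. Ages beyond `t_max` are rejected.
#'
#' @param t Age (yr), vectorised.
#' @inheritParams mortality_estimators
#' @return Natural mortality at each age (1/yr).
#' @examples
#' g <- growth_params(136.4, 0.077, -3.27)
#' m_chen_watanabe(0:14, g, t_mat = 6.276, t_max = 14)
#' @export
m_chen_watanabe <- function(t, g, t_mat, t_max) {
  stopifnot(inherits(g, "growth_params"), t_mat > 0, t_max > t_mat)
  if (any(t < g$t0)) stop("age below t0")
  if (any(t > t_max)) stop("age beyond t_max in senescent branch")
  k <- g$k; t0 <- g$t0
  switch_age <- floor(t_mat) + 1  # first integer age above t_mat
  juv <- k / (1 - exp(-k * (t - t0)))
  sen <- ifelse(t < t_max,
                log((exp(k * t_max) - exp(k * t0)) /
                      (exp(k * t) - exp(k * t0))) / (t_max - t),
                k * exp(k * t_max) / (exp(k * t_max) - exp(k * t0)))
  ifelse(t < switch_age, juv, sen)
}

#' Evaluate the full family of natural-mortality estimators
#'
#' Computes up to eleven natural-mortality estimates from a life history:
#' nine scalar estimators plus the age-dependent Chen & Watanabe and (when a
#' length-weight relation is available) Peterson & Wroblewski schedules,
#' evaluated on integer ages `0..t_max_mortality`.
#'
#' @param lh A [life_history()] object.
#' @param t_max Longevity (yr) passed to the longevity-based estimators and
#'   used as the age grid upper bound; defaults to `lh$t_max_mortality`.
#' @return An object of class `mortality_set`: a list of estimates, each
#'   with elements `method`, `value` (scalar) or `age_values` (named by
#'   age), and `survival` (\eqn{e^{-M}}).
#' @examples
#' ms <- natural_mortality_set(porosus_profile())
#' as.data.frame(ms)
#' @export
natural_mortality_set <- function(lh, t_max = lh$t_max_mortality) {
  stopifnot(inherits(lh, "life_history"))
  g <- lh$growth
  ages <- 0:t_max
  est <- list(
    scalar_estimate("Pauly", m_pauly(g, lh$temp_C)),
    scalar_estimate("Rikhter & Efanov", m_rikhter_efanov(lh$t_mat)),
    scalar_estimate("Hewitt & Hoenig", m_hewitt_hoenig(t_max)),
    scalar_estimate("Hoenig-teleosts", m_hoenig_teleost(t_max)),
    scalar_estimate("Hoenig-cetaceans", m_hoenig_cetacean(t_max)),
    scalar_estimate("Jensen 1", m_jensen1(g$k)),
    scalar_estimate("Jensen 2", m_jensen2(g$k)),
    scalar_estimate("Jensen 3", m_jensen3(lh$t_mat)),
    scalar_estimate("Mollet & Cailliet", m_mollet_cailliet(t_max))
  )
  pw <- tryCatch(
    m_peterson_wroblewski(weight_at_age(ages, g, lh$length_weight)),
    elasmodem_no_length_weight = function(e) NULL,
    error = function(e) if (is.null(lh$length_weight)) NULL else stop(e))
  if (!is.null(pw))
    est <- c(est, list(age_estimate("Peterson & Wroblewski", ages, pw)))
  cw <- m_chen_watanabe(ages, g, lh$t_mat, t_max)
  est <- c(est, list(age_estimate("Chen & Watanabe", ages, cw)))
  est <- Filter(function(e) all(is.finite(e$survival)), est)
  structure(list(estimates = est,
                 inputs = list(t_max = t_max, t_mat = lh$t_mat,
                               temp_C = lh$temp_C,
                               has_length_weight = !is.null(pw))),
            class = "mortality_set")
}

scalar_estimate <- function(method, value) {
  list(method = method, value = value, age_values = NULL,
       survival = exp(-value))
}

age_estimate <- function(method, ages, values) {
  list(method = method, value = NULL,
       age_values = setNames(values, ages), survival = exp(-values))
}

#' @export
print.mortality_set <- function(x, ...) {
  cat("Natural-mortality estimates (", length(x$estimates), " methods, ",
      "t_max = ", x$inputs$t_max, ", t_mat = ",
      round(x$inputs$t_mat, 3), "):\n", sep = "")
  print(as.data.frame(x), row.names = FALSE, digits = 3)
  invisible(x)
}

#' Tidy table of a mortality set
#'
#' One row per method with columns `method`, `M` and `S`; age-dependent
#' methods are summarised as their range, mirroring the conventional
#' mortality-table layout of stock-assessment reports.
#'
#' @param x A `mortality_set`.
#' @param ... Unused.
#' @export
as.data.frame.mortality_set <- function(x, ...) {
  rows <- lapply(x$estimates, function(e) {
    if (is.null(e$age_values))
      data.frame(method = e$method,
                 M = sprintf("%.3f", e$value),
                 S = sprintf("%.3f", e$survival))
    else
      data.frame(method = e$method,
                 M = sprintf("%.3f-%.3f", max(e$age_values),
                             min(e$age_values)),
                 S = sprintf("%.3f-%.3f", min(e$survival),
                             max(e$survival)))
  })
  do.call(rbind, rows)
}

#' Average a set of natural-mortality estimates
#'
#' Arithmetic mean over methods. Age-dependent methods contribute, by
#' `strategy`: the mean of their age-indexed values over integer ages
#' (`"age-mean"`, default), the value at the midpoint age
#' (`"midpoint"`), or nothing (`"exclude-age-dependent"`).
#'
#' @param set A `mortality_set` from [natural_mortality_set()].
#' @param strategy Aggregation strategy for age-dependent methods.
#' @return Mean natural mortality (1/yr).
#' @export
aggregate_M <- function(set,
                        strategy = c("age-mean", "midpoint",
                                     "exclude-age-dependent")) {
  strategy <- match.arg(strategy)
  stopifnot(inherits(set, "mortality_set"))
  vals <- vapply(set$estimates, function(e) {
    if (!is.null(e$value)) return(e$value)
    switch(strategy,
           "age-mean" = mean(e$age_values),
           "midpoint" = unname(
             e$age_values[ceiling(length(e$age_values) / 2)]),
           "exclude-age-dependent" = NA_real_)
  }, numeric(1))
  vals <- vals[is.finite(vals)]
  if (!length(vals)) stop("no valid estimates to aggregate")
  mean(vals)
}

#' Survival fraction from an instantaneous mortality rate
#'
#' Ricker's conversion \eqn{S = e^{-Z}}.
#'
#' @param Z Instantaneous total (or natural) mortality (1/yr), >= 0.
#' @return Annual survival fraction in (0, 1].
#' @export
survival_from_Z <- function(Z) {
  if (any(Z < 0)) stop("negative mortality rate")
  exp(-Z)
}

#' Fishing mortality as the difference of total and natural mortality
#'
#' \eqn{F = Z - M}. A negative result is returned as-is but carries the
#' attribute `flag = "underexploitation-or-inconsistency"` since it implies
#' the M estimate exceeds total mortality.
#'
#' @param Z Total mortality (1/yr), >= 0.
#' @param M Natural mortality (1/yr), >= 0.
#' @return Fishing mortality (1/yr).
#' @export
fishing_mortality <- function(Z, M) {
  stopifnot(Z >= 0, M >= 0)
  f <- Z - M
  if (f < 0) attr(f, "flag") <- "underexploitation-or-inconsistency"
  f
}

#' Exploitation rate E = F/Z
#'
#' The fraction of total deaths attributable to fishing; values above 0.5
#' conventionally indicate overexploitation.
#'
#' @param F_mort Fishing mortality (1/yr).
#' @param Z Total mortality (1/yr), > 0.
#' @return Exploitation rate with attribute `classification` equal to
#'   `"overexploited"` (E > 0.5) or `"underexploited"` (E < 0.5) or
#'   `"at threshold"`.
#' @examples
#' exploitation_rate(0.395, 0.656)  # 0.602, overexploited
#' @export
exploitation_rate <- function(F_mort, Z) {
  if (Z <= 0) stop("Z must be positive")
  e <- F_mort / Z
  attr(e, "classification") <-
    if (e > 0.5) "overexploited" else if (e < 0.5) "underexploited"
    else "at threshold"
  e
}

#' Degree of overexploitation relative to the equilibrium fishing mortality
#'
#' \eqn{100 (F - F_{eq}) / F}: the percentage by which current fishing
#' mortality exceeds the level that would hold the population at
#' replacement (\eqn{\lambda = 1}).
#'
#' @param F_mort Current fishing mortality (1/yr), > 0.
#' @param F_eq Equilibrium fishing mortality (1/yr).
#' @return Percentage.
#' @examples
#' overexploitation_degree(0.417, 0.032)  # 92.3
#' @export
overexploitation_degree <- function(F_mort, F_eq) {
  if (F_mort <= 0) stop("F must be positive")
  100 * (F_mort - F_eq) / F_mort
}
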