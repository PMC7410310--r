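#' Von Bertalanffy growth parameters
#'
#' Container for the three-parameter von Bertalanffy growth function (VBGF)
#' \eqn{L(t) = L_\infty (1 - e^{-k (t - t_0)})} mapping age (yr) to expected
#' total length (cm).
#'
#' @param L_inf Asymptotic total length (cm), > 0.
#' @param k Brody growth coefficient (1/yr), > 0.
#' @param t0 Theoretical age at zero length (yr); typically negative.
#'
#' @return An object of class `growth_params`.
#' @examples
#' g <- growth_params(L_inf = 136.4, k = 0.077, t0 = -3.27)
#' length_at_age(0, g)
#' @export
growth_params <- function(L_inf, k, t0) {
  stopifnot(is.numeric(L_inf), is.numeric(k), is.numeric(t0),
            length(L_inf) == 1, length(k) == 1, length(t0) == 1)
  if (L_inf <= 0) stop("L_inf must be positive")
  if (k <= 0) stop("k must be positive")
  structure(list(L_inf = L_inf, k = k, t0 = t0), class = "growth_params")
}

#' @export
print.growth_params <- function(x, ...) {
  cat(sprintf("VBGF growth: L_inf = %.1f cm, k = %.4g /yr, t0 = %.3g yr\n",
              x$L_inf, x$k, x$t0))
  invisible(x)
}

#' Length-weight relationship parameters
#'
#' Allometric weight at length, \eqn{W = a L^b} with W in kg and L in cm.
#' Needed only by the Peterson & Wroblewski weight-based natural-mortality
#' estimator; all other components work without it.
#'
#' @param a Coefficient (kg per cm^b), > 0.
#' @param b Allometric exponent; values outside (2, 4) trigger a warning.
#'
#' @return An object of class `length_weight_params`.
#' @export
length_weight_params <- function(a, b) {
  stopifnot(is.numeric(a), is.numeric(b), length(a) == 1, length(b) == 1)
  if (a <= 0) stop("a must be positive")
  if (b <= 2 || b >= 4)
    warning("allometric exponent b = ", b, " outside the usual (2, 4) range")
  structure(list(a = a, b = b), class = "length_weight_params")
}

#' Life-history parameter set
#'
#' Bundles growth, maturity, longevity and fecundity parameters for a female
#' life table. Fecundity is expressed as mean annual female pups per mature
#' female (litter size x embryo sex ratio / reproductive cycle length), so a
#' biennial cycle is already averaged into `m_bar`.
#'
#' Two longevities can be carried: `t_max` drives the dimension of the
#' demographic projection matrix, while `t_max_mortality` (defaulting to
#' `t_max`) feeds the longevity-based natural-mortality estimators. They may
#' legitimately differ when the oldest fish in the catch exceeds the oldest
#' fish in the growth study.
#'
#' @param growth A [growth_params()] object.
#' @param L_mat Female length at maturity (cm); must be below `L_inf`.
#' @param t_mat Age at maturity (yr). If `NULL`, derived from `L_mat` via
#'   the inverted VBGF; may be fractional.
#' @param t_max Maximum age for demography (yr).
#' @param t_max_mortality Maximum age for longevity-based mortality
#'   estimators (yr); defaults to `t_max`.
#' @param m_bar Mean annual female pups per mature female (1/yr).
#' @param m_sd Standard deviation of `m_bar` (1/yr).
#' @param cycle_years Reproductive cycle length (yr), informational.
#' @param temp_C Mean annual water temperature (deg C), for the Pauly
#'   estimator.
#' @param length_weight Optional [length_weight_params()]; when absent the
#'   Peterson & Wroblewski estimator is unavailable.
#'
#' @return An object of class `life_history`.
#' @examples
#' lh <- porosus_profile()
#' lh$t_mat       # fractional maturity age from the inverted VBGF
#' @export
life_history <- function(growth, L_mat, t_mat = NULL, t_max,
                         t_max_mortality = t_max,
                         m_bar, m_sd = 0, cycle_years = 1,
                         temp_C = NA_real_, length_weight = NULL) {
  stopifnot(inherits(growth, "growth_params"))
  if (L_mat >= growth$L_inf) stop("L_mat must be below L_inf")
  if (is.null(t_mat)) t_mat <- age_at_length(L_mat, growth)
  if (t_mat <= 0 || t_mat >= t_max) stopifnot(t_mat > 0, t_mat < t_max)
  if (m_bar <= 0) stop("m_bar must be positive")
  if (m_sd < 0) stop("m_sd must be non-negative")
  if (!is.null(length_weight))
    stopifnot(inherits(length_weight, "length_weight_params"))
  structure(list(growth = growth, L_mat = L_mat, t_mat = t_mat,
                 t_max = t_max, t_max_mortality = t_max_mortality,
                 m_bar = m_bar, m_sd = m_sd, cycle_years = cycle_years,
                 temp_C = temp_C, length_weight = length_weight),
            class = "life_history")
}

#' @export
print.life_history <- function(x, ...) {
  print(x$growth)
  cat(sprintf("maturity: %.1f cm TL (t_mat = %.3f yr); longevity: %d yr (demography), %d yr (mortality)\n",
              x$L_mat, x$t_mat, as.integer(x$t_max),
              as.integer(x$t_max_mortality)))
  cat(sprintf("fecundity: %.2f +/- %.2f female pups/yr (cycle %g yr)\n",
              x$m_bar, x$m_sd, x$cycle_years))
  invisible(x)
}

#' Expected length at age (VBGF)
#'
#' @param t Age (yr), vectorised; must be >= `t0`.
#' @param g A [growth_params()] object.
#' @return Expected total length (cm); strictly increasing in `t` and
#'   bounded above by `L_inf`.
#' @examples
#' g <- growth_params(136.4, 0.077, -3.27)
#' length_at_age(0:12, g)
#' @export
length_at_age <- function(t, g) {
  stopifnot(inherits(g, "growth_params"), is.numeric(t))
  if (any(t < g$t0)) stop("age below t0 is outside the VBGF domain")
  g$L_inf * (1 - exp(-g$k * (t - g$t0)))
}

#' Age at length by the inverted VBGF
#'
#' Inverts the growth curve, \eqn{t = t_0 - \ln(1 - L/L_\infty)/k}.
#' Lengths at or above `L_inf` are unconvertible and raise an error rather
#' than being clamped; see [convertible_lengths()] for bulk screening.
#' Ages beyond the demographic longevity are returned as-is (they are valid
#' growth-curve ages); callers that care should compare against `t_max`.
#'
#' @param L Total length (cm), vectorised; in `[0, L_inf)`.
#' @inheritParams length_at_age
#' @return Age (yr), possibly fractional.
#' @examples
#' g <- growth_params(136.4, 0.077, -3.27)
#' age_at_length(71, g)   # ~6.28 yr
#' @export
age_at_length <- function(L, g) {
  stopifnot(inherits(g, "growth_params"), is.numeric(L))
  if (any(L < 0)) stop("negative length")
  if (any(L >= g$L_inf))
    stop("length >= L_inf is unconvertible by the inverted VBGF")
  g$t0 - log(1 - L / g$L_inf) / g$k
}

#' Screen lengths for VBGF convertibility
#'
#' @inheritParams age_at_length
#' @return Logical vector: `TRUE` where `0 <= L < L_inf`.
#' @export
convertible_lengths <- function(L, g) {
  stopifnot(inherits(g, "growth_params"))
  is.finite(L) & L >= 0 & L < g$L_inf
}

#' Expected weight at age
#'
#' Chains the VBGF with an allometric length-weight relation,
#' \eqn{W(t) = a L(t)^b} (kg).
#'
#' @inheritParams length_at_age
#' @param lw A [length_weight_params()] object; if `NULL` an error of class
#'   `elasmodem_no_length_weight` is raised so callers can treat the
#'   weight-based mortality estimator as unavailable.
#' @return Weight (kg).
#' @export
weight_at_age <- function(t, g, lw) {
  if (is.null(lw))
    stop(structure(class = c("elasmodem_no_length_weight", "error",
                             "condition"),
                   list(message = "no length-weight relation supplied",
                        call = sys.call())))
  stopifnot(inherits(lw, "length_weight_params"))
  lw$a * length_at_age(t, g)^lw$b
}
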