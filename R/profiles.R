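#' Smalltail shark (Carcharhinus porosus) life-history profile
#'
#' The canonical parameterisation for the northern-Brazil smalltail shark
#' stock: VBGF growth (L_inf = 136.4 cm TL, k = 0.077 /yr, t0 = -3.27 yr),
#' female maturity at 71 cm (6.28 yr by the inverted VBGF), maximum age 12
#' yr in the growth study but 14 yr in the catch sample (used by the
#' longevity-based mortality estimators), mean annual female fecundity
#' 1.48 +/- 0.57 pups (biennial litters of ~5.9 embryos at a 1:1 sex
#' ratio), and a mean water temperature of 28 deg C.
#'
#' The length-weight relation (W = 5e-6 L^3 kg) is a SYNTHETIC stand-in:
#' no weight data exist for this stock, and the generic carcharhinid cubic
#' is supplied only so the weight-based Peterson & Wroblewski estimator can
#' participate in the eleven-member mortality set. Set
#' `length_weight = FALSE` to drop it.
#'
#' @param length_weight `TRUE` (default) to attach the synthetic
#'   length-weight stand-in, `FALSE` to omit it.
#' @return A [life_history()] object.
#' @examples
#' porosus_profile()
#' @export
porosus_profile <- function(length_weight = TRUE) {
  g <- growth_params(L_inf = 136.4, k = 0.077, t0 = -3.27)
  life_history(
    growth = g, L_mat = 71, t_mat = NULL,  # derived: 6.276 yr
    t_max = 12, t_max_mortality = 14,
    m_bar = 1.48, m_sd = 0.57, cycle_years = 2, temp_C = 28,
    length_weight = if (isTRUE(length_weight))
      length_weight_params(a = 5e-6, b = 3.0) else NULL)
}

#' Total-mortality estimates for the smalltail shark stock
#'
#' The four total-mortality values estimated from the 1980s gillnet sample
#' (catch curves by length and by age; Beverton & Holt by length and by
#' age). The specimen-level sample is not available, so these enter the
#' stochastic analysis as a fixed support set rather than being recomputed.
#'
#' @return Named numeric vector of Z values (1/yr).
#' @export
porosus_Z_values <- function() {
  c(catch_curve_length = 0.677, catch_curve_age = 0.749,
    bh_length = 0.519, bh_age = 0.681)
}

#' Uncertainty specification for the smalltail shark analysis
#'
#' Builds the Monte Carlo sampling distributions from a life-history
#' profile: natural mortality drawn uniformly from the full estimator set
#' (nine scalars plus the age-dependent Chen & Watanabe and, when the
#' profile carries a length-weight relation, Peterson & Wroblewski, whose
#' schedules are recomputed for each draw's maturity/maximum age); total
#' mortality from [porosus_Z_values()] with p = 1/4 each; maturity age over
#' \{5, 6, 7\} and maximum age over \{11, 12, 13\} with probabilities
#' \{0.25, 0.5, 0.25\}; fecundity Normal(1.48, 0.57) truncated at zero.
#'
#' @param lh A [life_history()] object; defaults to [porosus_profile()].
#' @param Z_support Total-mortality support; defaults to
#'   [porosus_Z_values()].
#' @return An [uncertainty_spec()].
#' @export
porosus_uncertainty <- function(lh = porosus_profile(),
                                Z_support = porosus_Z_values()) {
  g <- lh$growth
  scalars <- list(
    m_pauly(g, lh$temp_C),
    m_rikhter_efanov(lh$t_mat),
    m_hewitt_hoenig(lh$t_max_mortality),
    m_hoenig_teleost(lh$t_max_mortality),
    m_hoenig_cetacean(lh$t_max_mortality),
    m_jensen1(g$k),
    m_jensen2(g$k),
    m_jensen3(lh$t_mat),
    m_mollet_cailliet(lh$t_max_mortality))
  age_dep <- list(
    chen_watanabe = function(t_mat, t_max)
      m_chen_watanabe(0:t_max, g, t_mat, t_max))
  if (!is.null(lh$length_weight)) {
    lw <- lh$length_weight
    age_dep$peterson_wroblewski <- function(t_mat, t_max)
      m_peterson_wroblewski(weight_at_age(0:t_max, g, lw))
  }
  uncertainty_spec(
    M_support = c(scalars, age_dep),
    Z_support = unname(Z_support),
    t_mat_support = floor(lh$t_mat) + (-1:1),
    t_mat_probs = c(0.25, 0.5, 0.25),
    t_max_support = lh$t_max + (-1:1),
    t_max_probs = c(0.25, 0.5, 0.25),
    m_mean = lh$m_bar, m_sd = lh$m_sd)
}

#' The three canonical fishing scenarios
#'
#' Scenario 1: no fishing (natural mortality only). Scenario 2: fishing
#' mortality from the age of recruitment to the gillnet gear (modal catch
#' age, 2 yr) - the scenario closest to the observed fishery. Scenario 3:
#' hypothetical fishery catching only mature fish (from 6 yr).
#'
#' @param recruit_age Gear recruitment age for scenario 2 (default 2).
#' @param maturity_age First exploited age for scenario 3 (default 6).
#' @return Named list of three [fishing_scenario()] objects.
#' @export
porosus_scenarios <- function(recruit_age = 2, maturity_age = 6) {
  list(no_fishing = fishing_scenario("1: no fishing"),
       recruitment = fishing_scenario("2: fishing from recruitment age",
                                      recruit_age),
       adult_only = fishing_scenario("3: fishing from maturity",
                                     maturity_age))
}

#' Canonical synthetic-catch configuration for the smalltail shark
#'
#' Emulates the 1980s Maranhao gillnet sample: n = 937 specimens, natural
#' mortality 0.261, fishing mortality 0.395 (so Z = 0.656) acting from the
#' recruitment age of 2 yr, partial selection of ages 0-1, VBGF growth of
#' the stock, and an 8% length-at-age CV (which places the length mode in
#' the 45-55 cm bin given the age-2 catch mode). Samples reproduce the
#' sample's qualitative signature: modal age 2, roughly 90% juveniles,
#' lengths from under 30 to over 110 cm.
#'
#' @param n Sample size (default 937).
#' @param seed Optional seed.
#' @return A [sim_config()].
#' @export
porosus_catch_config <- function(n = 937, seed = NULL) {
  sim_config(n = n, M = 0.261, F_mort = 0.395, t_c = 2,
             growth = growth_params(136.4, 0.077, -3.27),
             length_cv = 0.08, partial_recruitment = c(0.25, 0.5),
             t_max = 25, seed = seed)
}
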