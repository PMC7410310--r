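#' Uncertainty specification for the Monte Carlo analysis
#'
#' Describes the sampling distributions from which one parameter draw is
#' taken per Monte Carlo iteration:
#' * natural mortality: one member of `M_support` with equal probability;
#'   members are scalars, fixed age schedules, or functions
#'   `function(t_mat, t_max)` returning a schedule over ages `0..t_max`
#'   (used for age-dependent estimators so the schedule tracks the drawn
#'   ages);
#' * total mortality: one member of `Z_support` with probability
#'   `Z_probs` (equal by default);
#' * maturity and maximum age: discrete supports with their probabilities
#'   (conventionally the central value with p = 0.5 and one year either
#'   side with p = 0.25);
#' * annual female fecundity: Normal(`m_mean`, `m_sd`) truncated at zero,
#'   either by redraw (default) or by flooring negatives to zero.
#'
#' @param M_support List of natural-mortality members (see above).
#' @param Z_support Numeric vector of total-mortality values (1/yr).
#' @param Z_probs Probabilities for `Z_support`; equal by default.
#' @param t_mat_support,t_mat_probs Integer maturity-age support and
#'   probabilities.
#' @param t_max_support,t_max_probs Integer maximum-age support and
#'   probabilities.
#' @param m_mean,m_sd Fecundity distribution parameters (female pups/yr).
#' @param truncation `"redraw"` (resample until positive) or `"zero"`.
#' @return An object of class `uncertainty_spec`.
#' @seealso [porosus_uncertainty()] for the bundled smalltail-shark spec.
#' @export
uncertainty_spec <- function(M_support, Z_support,
                             Z_probs = NULL,
                             t_mat_support, t_mat_probs,
                             t_max_support, t_max_probs,
                             m_mean, m_sd,
                             truncation = c("redraw", "zero")) {
  truncation <- match.arg(truncation)
  stopifnot(length(M_support) >= 1, length(Z_support) >= 1,
            length(t_mat_support) == length(t_mat_probs),
            length(t_max_support) == length(t_max_probs),
            m_mean > 0, m_sd >= 0)
  if (is.null(Z_probs)) Z_probs <- rep(1 / length(Z_support),
                                       length(Z_support))
  for (p in list(Z_probs, t_mat_probs, t_max_probs))
    if (abs(sum(p) - 1) > 1e-9) stop("probabilities must sum to 1")
  structure(list(M_support = M_support, Z_support = Z_support,
                 Z_probs = Z_probs,
                 t_mat_support = as.integer(t_mat_support),
                 t_mat_probs = t_mat_probs,
                 t_max_support = as.integer(t_max_support),
                 t_max_probs = t_max_probs,
                 m_mean = m_mean, m_sd = m_sd, truncation = truncation),
            class = "uncertainty_spec")
}

resolve_M <- function(member, t_mat, t_max) {
  if (is.function(member)) {
    sched <- member(t_mat, t_max)
    stopifnot(length(sched) == t_max + 1)
    return(sched)
  }
  if (length(member) == 1) return(rep(member, t_max + 1))
  if (length(member) < t_max + 1)
    stop("fixed M schedule shorter than t_max + 1")
  member[seq_len(t_max + 1)]
}

#' Draw one parameter set from an uncertainty specification
#'
#' Components are drawn independently; the natural-mortality member is
#' resolved into an age schedule after the maturity and maximum ages are
#' known so age-dependent estimators track the drawn ages.
#'
#' @param spec An [uncertainty_spec()].
#' @return List with `M_index`, `M_x` (schedule over ages `0..t_max`),
#'   `Z`, `t_mat`, `t_max`, `m`.
#' @export
draw_parameters <- function(spec) {
  stopifnot(inherits(spec, "uncertainty_spec"))
  # index-based sampling: sample(x, 1) would misread length-1 supports
  t_mat <- spec$t_mat_support[sample.int(length(spec$t_mat_support), 1,
                                         prob = spec$t_mat_probs)]
  t_max <- spec$t_max_support[sample.int(length(spec$t_max_support), 1,
                                         prob = spec$t_max_probs)]
  i <- sample.int(length(spec$M_support), 1)
  Z <- spec$Z_support[sample.int(length(spec$Z_support), 1,
                                 prob = spec$Z_probs)]
  if (spec$m_sd == 0) {
    m <- spec$m_mean
  } else if (spec$truncation == "redraw") {
    repeat { m <- rnorm(1, spec$m_mean, spec$m_sd); if (m > 0) break }
  } else {
    m <- max(rnorm(1, spec$m_mean, spec$m_sd), 0)
  }
  list(M_index = i,
       M_x = resolve_M(spec$M_support[[i]], t_mat, t_max),
       Z = Z, t_mat = t_mat, t_max = t_max, m = m)
}

#' Monte Carlo propagation of parameter uncertainty
#'
#' Repeatedly draws parameters from `spec`, builds the Leslie matrix for
#' each fishing scenario from the same draw, and summarises the resulting
#' demographic parameters. Draws that fail to produce a valid matrix
#' (e.g. zero fecundity under the `"zero"` truncation policy) are rejected
#' and redrawn, with a count kept.
#'
#' The elasticity grouping boundary is held at the central maturity age
#' (`adult_age`) across draws so the juvenile/adult split is comparable
#' between iterations even though each draw's own maturity age varies.
#'
#' @param lh A [life_history()] object.
#' @param spec An [uncertainty_spec()].
#' @param scenarios A single [fishing_scenario()] or a named list of them;
#'   with a list, every scenario is evaluated on the same draws (so
#'   per-draw scenario comparisons are paired).
#' @param n Number of draws.
#' @param seed Optional RNG seed; seeded runs are bit-reproducible.
#' @param census Census convention for [build_leslie()].
#' @param adult_age Elasticity grouping boundary; defaults to
#'   `floor(lh$t_mat)`.
#' @param ci_level Confidence level for the percentile intervals.
#' @return For a single scenario, a `monte_carlo_result`: list with
#'   `draws` (data frame of per-draw `lambda`, `r`, `R0`, `T`, `e1`-`e3`
#'   and drawn parameters), `summary` (mean and percentile CI per
#'   parameter), `prop_increasing` (share of draws with \eqn{\lambda > 1}),
#'   `n`, `n_rejected`, `seed`. For a list of scenarios, a named list of
#'   such results sharing identical draws.
#' @examples
#' lh <- porosus_profile()
#' mc <- run_monte_carlo(lh, porosus_uncertainty(lh),
#'                       fishing_scenario("no fishing"), n = 50, seed = 1)
#' mc$summary
#' @export
run_monte_carlo <- function(lh, spec, scenarios, n = 1000, seed = NULL,
                            census = c("pre", "post"),
                            adult_age = floor(lh$t_mat), ci_level = 0.95) {
  census <- match.arg(census)
  stopifnot(inherits(lh, "life_history"), inherits(spec, "uncertainty_spec"),
            n >= 1)
  single <- inherits(scenarios, "fishing_scenario")
  if (single) scenarios <- list(scenarios)
  stopifnot(all(vapply(scenarios, inherits, TRUE, "fishing_scenario")))
  if (!is.null(seed)) set.seed(seed)

  cols <- c("lambda", "r", "R0", "T", "e1", "e2", "e3")
  res <- lapply(scenarios, function(s)
    matrix(NA_real_, n, length(cols), dimnames = list(NULL, cols)))
  par_rec <- data.frame(M_index = integer(n), Z = numeric(n),
                        t_mat = integer(n), t_max = integer(n),
                        m = numeric(n))
  n_rejected <- 0L
  for (i in seq_len(n)) {
    repeat {
      d <- draw_parameters(spec)
      row <- tryCatch(
        lapply(scenarios, function(sc) {
          mod <- build_leslie(lh, d$M_x, sc, Z = d$Z, m = d$m,
                              t_mat = d$t_mat, t_max = d$t_max,
                              census = census)
          s <- demographic_summary(mod, adult_age = adult_age)
          c(s$lambda, s$r, s$R0, s$T, s$e1, s$e2, s$e3)
        }),
        error = function(e) NULL)
      if (!is.null(row)) break
      n_rejected <- n_rejected + 1L
    }
    for (j in seq_along(scenarios)) res[[j]][i, ] <- row[[j]]
    par_rec[i, ] <- d[c("M_index", "Z", "t_mat", "t_max", "m")]
  }

  alpha <- (1 - ci_level) / 2
  out <- lapply(seq_along(scenarios), function(j) {
    draws <- cbind(as.data.frame(res[[j]]), par_rec)
    summ <- do.call(rbind, lapply(c("lambda", "r", "R0", "T"), function(p) {
      data.frame(parameter = p, mean = mean(draws[[p]]),
                 lower = unname(quantile(draws[[p]], alpha)),
                 upper = unname(quantile(draws[[p]], 1 - alpha)))
    }))
    structure(list(scenario = scenarios[[j]]$name, draws = draws,
                   summary = summ,
                   prop_increasing = mean(draws$lambda > 1),
                   n = n, n_rejected = n_rejected, seed = seed,
                   ci_level = ci_level),
              class = "monte_carlo_result")
  })
  names(out) <- names(scenarios)
  if (single) out[[1]] else out
}

#' @export
print.monte_carlo_result <- function(x, ...) {
  cat(sprintf("Monte Carlo (%d draws%s), scenario: %s\n", x$n,
              if (!is.null(x$seed)) paste0(", seed ", x$seed) else "",
              x$scenario))
  print(x$summary, row.names = FALSE, digits = 4)
  cat(sprintf("draws with lambda > 1: %.1f%%\n", 100 * x$prop_increasing))
  invisible(x)
}

#' Decline table from a Monte Carlo result
#'
#' Projects surviving and declined fractions at the requested horizons in
#' two modes: the point-value mode evaluates \eqn{e^{\bar r t}} at the
#' Monte Carlo mean `r` (and mean generation time for the `"3T"` horizon),
#' which is how decline figures are conventionally reported; the
#' distribution mode projects every draw and reports percentile intervals.
#'
#' @param mc A `monte_carlo_result`.
#' @param horizons Numeric years and/or the string `"3T"` (three times the
#'   generation time). Default `c(10, "3T")`.
#' @return List with `point` (data frame: horizon label, years, `N_t`,
#'   `D_t`) and `draws` (data frame with per-draw quantiles of `N_t`).
#' @export
decline_summary <- function(mc, horizons = c("10", "3T")) {
  stopifnot(inherits(mc, "monte_carlo_result"))
  r_bar <- mean(mc$draws$r)
  T_bar <- mean(mc$draws$T)
  alpha <- (1 - mc$ci_level) / 2
  rows <- lapply(as.character(horizons), function(h) {
    if (h == "3T") {
      yrs <- 3 * T_bar
      per_draw <- exp(mc$draws$r * 3 * mc$draws$T)
    } else {
      yrs <- as.numeric(h)
      per_draw <- exp(mc$draws$r * yrs)
    }
    point <- project_decline(r_bar, yrs)
    data.frame(horizon = h, years = yrs, N_t = point$N_t, D_t = point$D_t,
               N_median = median(per_draw),
               N_lower = unname(quantile(per_draw, alpha)),
               N_upper = unname(quantile(per_draw, 1 - alpha)))
  })
  tab <- do.call(rbind, rows)
  list(point = tab[c("horizon", "years", "N_t", "D_t")],
       draws = tab[c("horizon", "years", "N_median", "N_lower", "N_upper")])
}
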