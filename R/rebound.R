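#' Intrinsic rebound potential of productivity
#'
#' Two-step Smith-style rebound calculation: (1) find the replacement total
#' mortality \eqn{Z_{sus}} at which the life table is exactly at
#' replacement (\eqn{R_0 = 1}, \eqn{\lambda = 1}; reuses
#' [solve_equilibrium_Z()] with the constant Z applied to every age);
#' (2) the sustainable fishing mortality is \eqn{F_{sus} = Z_{sus} - M},
#' and under logistic surplus production a stock fished at MSY has
#' \eqn{r = 2 F_{sus}}, giving the rebound potential
#' \eqn{r_Z = 2 (Z_{sus} - M)}. The variant without the logistic factor of
#' two (`r_Z_no_factor`) is also returned, since usage varies between
#' authors.
#'
#' @param lh A [life_history()] object.
#' @param M Natural mortality (1/yr) used for \eqn{F_{sus} = Z_{sus} - M}.
#' @param ... Passed to [solve_equilibrium_Z()] (e.g. `t_max`, `census`).
#' @return An object of class `rebound_result`: list with `r_Z`,
#'   `r_Z_no_factor`, `Z_sus`, `F_sus` and a `method` note.
#' @examples
#' rebound_potential(porosus_profile(), M = 0.239)
#' @export
rebound_potential <- function(lh, M, ...) {
  stopifnot(inherits(lh, "life_history"), M >= 0)
  eq <- solve_equilibrium_Z(lh, ...)
  F_sus <- eq$Z_prime - M
  structure(list(r_Z = 2 * F_sus, r_Z_no_factor = F_sus,
                 Z_sus = eq$Z_prime, F_sus = F_sus,
                 method = paste("replacement-Z via lambda(Z)=1;",
                                "r_Z = 2*(Z_sus - M), logistic MSY factor")),
            class = "rebound_result")
}

#' @export
print.rebound_result <- function(x, ...) {
  cat(sprintf("rebound potential r_Z = %.4f /yr (Z_sus = %.4f, F_sus = %.4f)\n",
              x$r_Z, x$Z_sus, x$F_sus))
  cat("  [", x$method, "]\n", sep = "")
  invisible(x)
}

#' Extinction fishing mortality and maximum intrinsic growth rate
#'
#' Solves the density-independent, low-density Euler-Lotka recurrence in
#' its rearranged scalar form
#' \deqn{\lambda^{\alpha} - e^{-M} \lambda^{\alpha - 1} = l_\alpha\, m}
#' with \eqn{l_\alpha = e^{-M \alpha}} the survival to maturity under
#' natural mortality alone and \eqn{\alpha} the maturity age. The root
#' \eqn{\lambda_{max}} gives \eqn{r_{max} = \ln \lambda_{max}}, the maximum
#' intrinsic rate of increase, which equals the constant fishing mortality
#' beyond which the population cannot persist
#' (\eqn{F_{extinct} = r_{max}}).
#'
#' @param lh A [life_history()] object.
#' @param M Natural mortality (1/yr).
#' @param alpha Maturity age (yr); defaults to the fractional `lh$t_mat`.
#' @param m Annual female fecundity; defaults to `lh$m_bar`.
#' @param tol Residual tolerance of the root.
#' @return List with `r_max`, `F_extinct` (equal by definition),
#'   `lambda_max` and the achieved `residual`.
#' @examples
#' f_extinct(porosus_profile(), M = 0.239)
#' @export
f_extinct <- function(lh, M, alpha = lh$t_mat, m = lh$m_bar, tol = 1e-10) {
  stopifnot(inherits(lh, "life_history"), M >= 0, alpha > 0, m > 0)
  g <- function(lam) lam^alpha - exp(-M) * lam^(alpha - 1) - exp(-M * alpha) * m
  # g is increasing for lambda > e^-M and negative at that point: unique root
  lam <- uniroot(g, c(exp(-M), 10), tol = 1e-14)$root
  if (abs(g(lam)) > tol) stop("extinction-F solver did not converge")
  list(r_max = log(lam), F_extinct = log(lam), lambda_max = lam,
       residual = g(lam))
}
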