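#' Define a fishing scenario
#'
#' A scenario names the age range over which fishing mortality acts.
#' `recruit_age = NULL` means no fishing; otherwise fishing mortality
#' \eqn{F_x = \max(Z - M_x, 0)} is applied to all integer ages at or above
#' `recruit_age` when the matrix is built. An explicit per-age
#' `F_schedule` (ages 0..t_max) may be supplied instead.
#'
#' The three canonical scenarios of an exploited-shark analysis are
#' (1) no fishing, (2) fishing from the age of recruitment to the gear
#' (modal catch age), and (3) fishing only from the age at maturity.
#'
#' @param name Scenario label.
#' @param recruit_age First exploited integer age (yr), or `NULL`.
#' @param F_schedule Optional explicit fishing mortality per age (1/yr).
#' @return An object of class `fishing_scenario`.
#' @examples
#' fishing_scenario("gillnet recruitment", recruit_age = 2)
#' @export
fishing_scenario <- function(name, recruit_age = NULL, F_schedule = NULL) {
  if (!is.null(F_schedule) && any(F_schedule < 0))
    stop("F_schedule entries must be non-negative")
  structure(list(name = name, recruit_age = recruit_age,
                 F_schedule = F_schedule), class = "fishing_scenario")
}

scenario_F <- function(scenario, M_x, Z, ages) {
  if (!is.null(scenario$F_schedule)) {
    stopifnot(length(scenario$F_schedule) >= length(ages))
    return(scenario$F_schedule[seq_along(ages)])
  }
  if (is.null(scenario$recruit_age)) return(rep(0, length(ages)))
  if (is.null(Z)) stop("scenario with recruit_age needs a Z value")
  ifelse(ages >= scenario$recruit_age, pmax(Z - M_x, 0), 0)
}

#' Build an age-structured Leslie projection matrix
#'
#' Assembles the female-only projection matrix from a natural-mortality
#' schedule, a fishing scenario and the life history's fecundity. Annual
#' survivorship is \eqn{s_x = e^{-(M_x + F_x)}}; fecundity is `m` female
#' pups per female per year for every integer age at or above
#' `floor(t_mat)` and zero before.
#'
#' Under the default pre-breeding census the matrix has age classes
#' `1..t_max` and the fertility element of column \eqn{x} is
#' \eqn{f_x = s_0\, m_x}: females are counted just before the birth pulse,
#' so newborn first-year survival is folded into the fertility row
#' ("reproduction first, then survival"). The `"post"` census counts
#' newborns as age class 0 and uses \eqn{f_x = s_x\, m_{x+1}} over classes
#' `0..t_max`. Both constructions satisfy the Euler-Lotka identity
#' \eqn{\sum_x \lambda^{-x} l_x m_x = 1} at the dominant eigenvalue.
#'
#' @param lh A [life_history()] object.
#' @param M_x Natural mortality: a scalar or a vector over integer ages
#'   `0..t_max` (1/yr).
#' @param scenario A [fishing_scenario()]; default no fishing.
#' @param Z Total mortality (1/yr) from which the scenario derives
#'   \eqn{F_x = \max(Z - M_x, 0)}; required when the scenario fishes.
#' @param m Annual female fecundity; defaults to `lh$m_bar`.
#' @param t_mat Age at first reproduction; defaults to `floor(lh$t_mat)`.
#' @param t_max Last age class; defaults to `lh$t_max`.
#' @param census `"pre"` (default) or `"post"` breeding census.
#' @return An object of class `leslie_model` with the matrix `A`, the
#'   schedules `s_x`, `m_x`, `f_x` and `l_x` (cumulative survivorship from
#'   age 0), the age classes, and metadata.
#' @examples
#' lh <- porosus_profile()
#' mod <- build_leslie(lh, M_x = 0.261)
#' demographic_summary(mod)
#' @export
build_leslie <- function(lh, M_x, scenario = fishing_scenario("no fishing"),
                         Z = NULL, m = lh$m_bar,
                         t_mat = floor(lh$t_mat), t_max = lh$t_max,
                         census = c("pre", "post")) {
  census <- match.arg(census)
  stopifnot(inherits(lh, "life_history"),
            inherits(scenario, "fishing_scenario"))
  t_mat <- as.integer(t_mat); t_max <- as.integer(t_max)
  ages <- 0:t_max
  if (length(M_x) == 1) M_x <- rep(M_x, t_max + 1)
  if (length(M_x) < t_max + 1)
    stop("M_x schedule must cover ages 0..t_max")
  M_x <- M_x[seq_len(t_max + 1)]
  F_x <- scenario_F(scenario, M_x, Z, ages)
  s_x <- exp(-(M_x + F_x))
  if (any(s_x <= 0 | s_x >= 1))
    stop("survivorship outside (0,1); check mortality schedules")
  m_x <- ifelse(ages >= t_mat, m, 0)
  if (census == "pre") {
    A <- t_max
    mat <- matrix(0, A, A)
    f_x <- s_x[1] * m_x[2:(A + 1)]      # f_j = s_0 * m_j, classes 1..A
    mat[1, ] <- f_x
    for (j in seq_len(A - 1)) mat[j + 1, j] <- s_x[j + 1]
    classes <- 1:A
  } else {
    A <- t_max + 1
    mat <- matrix(0, A, A)
    f_x <- s_x * c(m_x[-1], 0)          # f_j = s_j * m_{j+1}, classes 0..A-1
    mat[1, ] <- f_x
    for (j in seq_len(A - 1)) mat[j + 1, j] <- s_x[j]
    classes <- 0:(A - 1)
  }
  l_x <- cumprod(c(1, s_x))[seq_len(t_max + 1)]  # l_0..l_t_max
  structure(list(A = mat, classes = classes, ages = ages,
                 s_x = s_x, m_x = m_x, f_x = f_x, l_x = l_x,
                 M_x = M_x, F_x = F_x, census = census,
                 t_mat = t_mat, t_max = t_max,
                 scenario = scenario$name),
            class = "leslie_model")
}

#' @export
print.leslie_model <- function(x, ...) {
  cat(sprintf("Leslie model (%s census, %d age classes, scenario: %s)\n",
              x$census, length(x$classes), x$scenario))
  s <- demographic_summary(x)
  cat(sprintf("lambda = %.4f  r = %.4f  R0 = %.3f  T = %.2f yr\n",
              s$lambda, s$r, s$R0, s$T))
  invisible(x)
}

#' Dominant eigenvalue and eigenvectors of a projection matrix
#'
#' Returns the dominant (largest real part) eigenvalue \eqn{\lambda}, the
#' right eigenvector `w` (stable age distribution, normalised to sum 1) and
#' the left eigenvector `v` (reproductive values, scaled so that
#' \eqn{v \cdot w = 1}).
#'
#' @param model A `leslie_model` or a plain non-negative square matrix.
#' @return List with `lambda`, `w`, `v`.
#' @export
dominant_eigen <- function(model) {
  A <- if (inherits(model, "leslie_model")) model$A else model
  stopifnot(is.matrix(A), nrow(A) == ncol(A))
  er <- eigen(A)
  i <- which.max(Re(er$values))
  lambda <- Re(er$values[i])
  if (lambda <= 0) stop("no positive dominant eigenvalue")
  w <- Re(er$vectors[, i])
  if (sum(w) < 0) w <- -w
  w <- w / sum(w)
  el <- eigen(t(A))
  j <- which.max(Re(el$values))
  v <- Re(el$vectors[, j])
  if (sum(v) < 0) v <- -v
  v <- v / sum(v * w)
  list(lambda = lambda, w = w, v = v)
}

#' Elasticity decomposition of the population growth rate
#'
#' Element-wise elasticities \eqn{e_{ij} = (a_{ij}/\lambda)\,
#' \partial\lambda/\partial a_{ij} = a_{ij} v_i w_j / (\lambda\, v\cdot w)},
#' which sum to 1 for any projection matrix, plus grouped sums: `e1` over
#' the fertility row, `e2` over juvenile survival transitions (ages below
#' `adult_age`) and `e3` over adult survival transitions. A finer
#' neonate / juvenile (1-5) / adult (6-8) / large adult (>= 9) stage split
#' of the survival elasticities is returned as `stage`.
#'
#' @param model A `leslie_model`.
#' @param adult_age First adult age class for the grouped sums; defaults to
#'   the model's integer maturity age.
#' @return List with the elasticity `matrix`, grouped `e1`, `e2`, `e3`, and
#'   `stage` sums.
#' @export
elasticities <- function(model, adult_age = model$t_mat) {
  stopifnot(inherits(model, "leslie_model"))
  eg <- dominant_eigen(model)
  E <- model$A * (eg$v %o% eg$w) / eg$lambda  # v.w already 1
  e1 <- sum(E[1, ])
  n <- nrow(E)
  sub <- E[cbind(2:n, 1:(n - 1))]
  from_age <- model$classes[1:(n - 1)]  # age of the surviving class
  e2 <- sum(sub[from_age < adult_age])
  e3 <- sum(sub[from_age >= adult_age])
  stage <- c(neonate = sum(sub[from_age == 0]),
             juvenile = sum(sub[from_age >= 1 & from_age <= 5]),
             adult = sum(sub[from_age >= 6 & from_age <= 8]),
             large_adult = sum(sub[from_age >= 9]))
  list(matrix = E, e1 = e1, e2 = e2, e3 = e3, stage = stage,
       lambda = eg$lambda)
}

#' Demographic summary of a Leslie model
#'
#' Computes the finite growth rate \eqn{\lambda} (dominant eigenvalue), the
#' intrinsic rate \eqn{r = \ln\lambda}, the net reproductive rate
#' \eqn{R_0 = \sum_x l_x m_x}, the generation time \eqn{T} (mean age of
#' mothers at the stable age distribution,
#' \eqn{\sum x \lambda^{-x} l_x m_x / \sum \lambda^{-x} l_x m_x}), the
#' stable age distribution, and the grouped elasticities.
#'
#' @param model A `leslie_model`.
#' @param adult_age Passed to [elasticities()].
#' @return An object of class `demographic_summary` (a list): `lambda`,
#'   `r`, `R0`, `T`, `T_R0` (the alternative \eqn{\ln R_0 / r}, `NA` at
#'   \eqn{r = 0}), `stable_age`, `e1`, `e2`, `e3`, `stage_elasticity`.
#' @export
demographic_summary <- function(model, adult_age = model$t_mat) {
  stopifnot(inherits(model, "leslie_model"))
  el <- elasticities(model, adult_age)
  lambda <- el$lambda
  x <- model$ages[-1]                  # 1..t_max
  lx <- model$l_x[-1]
  mx <- model$m_x[-1]
  R0 <- sum(lx * mx)
  wgt <- lambda^(-x) * lx * mx
  Tgen <- sum(x * wgt) / sum(wgt)
  r <- log(lambda)
  structure(list(lambda = lambda, r = r, R0 = R0, T = Tgen,
                 T_R0 = if (abs(r) > 1e-12) log(R0) / r else NA_real_,
                 stable_age = dominant_eigen(model)$w,
                 e1 = el$e1, e2 = el$e2, e3 = el$e3,
                 stage_elasticity = el$stage),
            class = "demographic_summary")
}

#' @export
print.demographic_summary <- function(x, ...) {
  cat(sprintf("lambda = %.4f (r = %.4f /yr), R0 = %.3f, T = %.2f yr\n",
              x$lambda, x$r, x$R0, x$T))
  cat(sprintf("elasticities: fertility %.3f, juvenile survival %.3f, adult survival %.3f\n",
              x$e1, x$e2, x$e3))
  invisible(x)
}

#' Equilibrium total mortality Z'
#'
#' Finds the constant total mortality that would hold the population
#' exactly at replacement (\eqn{\lambda = 1}, \eqn{r = 0}, \eqn{R_0 = 1})
#' by bisection on \eqn{\lambda(Z) - 1} to \eqn{|\lambda - 1| <} `tol`.
#' By default the constant Z replaces mortality at every age, including the
#' first-year survival inside the fertility term; `apply_from` restricts
#' replacement to ages at or above a recruitment age, with natural
#' mortality `M_below` acting before it.
#'
#' @param lh A [life_history()] object.
#' @param M_below Natural mortality for ages below `apply_from` (1/yr);
#'   only used when `apply_from > 0`.
#' @param apply_from First age at which the constant Z acts (default 0,
#'   i.e. all ages).
#' @param m,t_mat,t_max,census Passed to [build_leslie()].
#' @param tol Convergence tolerance on \eqn{|\lambda - 1|}.
#' @param upper Upper bracket for Z (1/yr).
#' @return List with `Z_prime`, `F_prime` (\eqn{Z' - M_{below}} when
#'   `M_below` is given, else `NA`), `lambda`, `R0`.
#' @examples
#' solve_equilibrium_Z(porosus_profile())$Z_prime
#' @export
solve_equilibrium_Z <- function(lh, M_below = NULL, apply_from = 0,
                                m = lh$m_bar, t_mat = floor(lh$t_mat),
                                t_max = lh$t_max,
                                census = c("pre", "post"),
                                tol = 1e-8, upper = 3) {
  census <- match.arg(census)
  lam <- function(Z) {
    M_x <- if (apply_from > 0) {
      stopifnot(!is.null(M_below))
      ifelse(0:t_max >= apply_from, Z, M_below)
    } else rep(Z, t_max + 1)
    mod <- build_leslie(lh, M_x, m = m, t_mat = t_mat, t_max = t_max,
                        census = census)
    dominant_eigen(mod)$lambda
  }
  lo <- 1e-6; hi <- upper
  if ((lam(lo) - 1) * (lam(hi) - 1) > 0)
    stop("no replacement bracket in (0, ", upper, "]; flagged infeasible")
  repeat {
    mid <- (lo + hi) / 2
    lm_ <- lam(mid)
    if (abs(lm_ - 1) < tol || (hi - lo) < 1e-12) break
    if (lm_ > 1) lo <- mid else hi <- mid
  }
  M_x <- if (apply_from > 0) ifelse(0:t_max >= apply_from, mid, M_below)
  else rep(mid, t_max + 1)
  mod <- build_leslie(lh, M_x, m = m, t_mat = t_mat, t_max = t_max,
                      census = census)
  list(Z_prime = mid,
       F_prime = if (!is.null(M_below)) mid - M_below else NA_real_,
       lambda = lm_, R0 = demographic_summary(mod)$R0)
}

#' Exponential decline projection
#'
#' Projects the surviving fraction \eqn{N_t = N_0 e^{rt}} (with
#' \eqn{N_0 = 1}) and the decline \eqn{D_t = 1 - e^{rt}} at horizon(s)
#' `t`.
#'
#' @param r Intrinsic population growth rate (1/yr).
#' @param t Horizon(s) in years, >= 0; vectorised.
#' @return Data frame with columns `horizon`, `N_t`, `D_t`.
#' @examples
#' project_decline(-0.285, c(10, 23.211))
#' @export
project_decline <- function(r, t) {
  stopifnot(is.numeric(r), length(r) == 1, all(t >= 0))
  N <- exp(r * t)
  data.frame(horizon = t, N_t = N, D_t = 1 - N)
}

#' Classify a three-generation decline against IUCN criterion E
#'
#' Criterion E (critically endangered) requires a quantitative analysis
#' showing at least a 50% probability of extinction in the wild within
#' three generations. This check uses the projected three-generation
#' decline fraction as a proxy for that probability, which overstates true
#' extinction risk for large populations; the returned `caveat` records
#' this.
#'
#' @param D_3T Projected decline fraction over three generations, in
#'   `[0, 1]`.
#' @param threshold Decline threshold (default 0.5); met inclusively.
#' @return List with `meets` (logical), `D_3T`, `threshold` and `caveat`.
#' @export
classify_criterion_E <- function(D_3T, threshold = 0.5) {
  stopifnot(D_3T >= 0, D_3T <= 1)
  list(meets = D_3T >= threshold, D_3T = D_3T, threshold = threshold,
       caveat = paste("projected decline used as a proxy for extinction",
                      "probability; no density dependence or demographic",
                      "stochasticity modelled"))
}
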