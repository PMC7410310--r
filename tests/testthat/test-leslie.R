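lh <- porosus_profile()

toy_lh <- function(m = 2) life_history(growth_params(100, 0.2, -1),
                                       L_mat = 30, t_mat = 1.2, t_max = 2,
                                       m_bar = m)

test_that("pre-breeding matrix assembles as expected on a 2-class toy", {
  # s = 0.5 everywhere, reproduction from age 1, m = 2
  mod <- build_leslie(toy_lh(), M_x = log(2), t_mat = 1, t_max = 2)
  expect_equal(mod$A[1, 1], 0.5 * 2)          # f_1 = s_0 * m_1 = 1.0
  expect_equal(mod$A[2, 1], 0.5)              # subdiagonal survival
  expect_equal(dim(mod$A), c(2, 2))
  # closed-form dominant root of lambda^2 - f1*lambda - s1*f2 = 0
  f1 <- mod$A[1, 1]; f2 <- mod$A[1, 2]; s1 <- mod$A[2, 1]
  lam_exact <- (f1 + sqrt(f1^2 + 4 * s1 * f2)) / 2
  expect_equal(dominant_eigen(mod)$lambda, lam_exact, tolerance = 1e-12)
})

test_that("fishing scenarios modify the survival schedule from recruit age", {
  sc2 <- fishing_scenario("rec2", recruit_age = 2)
  mod <- build_leslie(lh, M_x = 0.261, scenario = sc2, Z = 0.656)
  expect_equal(unname(mod$s_x[1:2]), rep(exp(-0.261), 2))   # 0.770
  expect_equal(unname(mod$s_x[3:13]), rep(exp(-0.656), 11)) # 0.519
  expect_equal(exp(-0.261), 0.770, tolerance = 5e-4)
  expect_equal(exp(-0.656), 0.519, tolerance = 5e-4)
  # all-zero F schedule identical to the unfished matrix
  mod0 <- build_leslie(lh, M_x = 0.261)
  modz <- build_leslie(lh, M_x = 0.261,
                       scenario = fishing_scenario("z", F_schedule = rep(0, 13)))
  expect_identical(mod0$A, modz$A)
  expect_error(build_leslie(lh, M_x = 0), "survivorship")
})

test_that("dominant eigenvalue matches Euler-Lotka and power iteration", {
  set.seed(42)
  for (i in 1:100) {
    mod <- random_leslie_model()
    lam <- dominant_eigen(mod)$lambda
    expect_equal(lam, power_iteration_lambda(mod$A), tolerance = 1e-6)
    if (i <= 25) {
      x <- mod$ages[-1]
      el <- euler_lotka_lambda(mod$l_x[-1], mod$m_x[-1], x)
      expect_equal(lam, el, tolerance = 1e-8)
    }
  }
})

test_that("eigenvector normalisation contracts hold", {
  mod <- build_leslie(lh, M_x = 0.261)
  eg <- dominant_eigen(mod)
  expect_equal(sum(eg$w), 1)
  expect_equal(sum(eg$v * eg$w), 1)
  expect_equal(as.numeric(mod$A %*% eg$w), eg$lambda * eg$w,
               tolerance = 1e-10)
})

test_that("elasticities sum to one and match finite differences", {
  set.seed(7)
  for (i in 1:100) {
    mod <- random_leslie_model()
    el <- elasticities(mod)
    expect_lt(abs(sum(el$matrix) - 1), 1e-9)
    expect_equal(el$e1 + el$e2 + el$e3, 1, tolerance = 1e-9)
  }
  for (i in 1:3) {
    mod <- random_leslie_model()
    el <- elasticities(mod)
    expect_equal(el$matrix, fd_elasticities(mod$A), tolerance = 1e-4)
  }
})

test_that("deterministic scenario summaries reproduce the reference stock", {
  # frozen from the Euler-Lotka oracle at mean parameters (M = 0.261)
  s1 <- demographic_summary(build_leslie(lh, 0.261))
  expect_equal(s1$lambda, 1.0153, tolerance = 1e-3)
  expect_equal(s1$R0, 1.129, tolerance = 1e-3)
  expect_equal(s1$T, 7.96, tolerance = 0.01)
  # grouped elasticities match the published decomposition to 3 decimals
  expect_equal(c(s1$e1, s1$e2, s1$e3), c(0.126, 0.628, 0.246),
               tolerance = 0.002)

  s2 <- demographic_summary(
    build_leslie(lh, 0.261, fishing_scenario("rec", 2), Z = 0.656))
  expect_lt(abs(s2$r - -0.285), 0.01)
  expect_equal(c(s2$e1, s2$e2, s2$e3), c(0.131, 0.654, 0.215),
               tolerance = 0.002)

  s3 <- demographic_summary(
    build_leslie(lh, 0.261, fishing_scenario("mat", 6), Z = 0.656))
  expect_equal(s3$lambda, 0.940, tolerance = 0.005)

  # both census conventions satisfy Euler-Lotka; lambdas agree closely
  s1p <- demographic_summary(build_leslie(lh, 0.261, census = "post"))
  expect_equal(s1p$lambda, s1$lambda, tolerance = 1e-6)

  # doubling fecundity doubles R0
  sdbl <- demographic_summary(build_leslie(lh, 0.261, m = 2 * lh$m_bar))
  expect_equal(sdbl$R0, 2 * s1$R0, tolerance = 1e-12)
})

test_that("equilibrium Z' satisfies replacement identities", {
  eq <- solve_equilibrium_Z(lh, M_below = 0.239)
  expect_equal(eq$Z_prime, 0.2762, tolerance = 1e-3)   # frozen (own oracle)
  expect_lt(abs(eq$lambda - 1), 1e-8)
  expect_lt(abs(eq$R0 - 1), 1e-6)
  expect_equal(eq$F_prime, eq$Z_prime - 0.239)
  # fixed point: a population already at replacement returns Z' = M
  mod <- build_leslie(lh, eq$Z_prime)
  expect_equal(dominant_eigen(mod)$lambda, 1, tolerance = 1e-7)
  # lambda = 1 iff R0 = 1 across a grid of Z
  for (Z in seq(0.15, 0.45, by = 0.05)) {
    s <- demographic_summary(build_leslie(lh, Z))
    expect_identical(s$lambda > 1, s$R0 > 1)
  }
  # infeasible bracket flagged
  tiny <- life_history(growth_params(100, 0.2, -1), L_mat = 30,
                       t_mat = 8, t_max = 10, m_bar = 0.01)
  expect_error(solve_equilibrium_Z(tiny), "infeasible")
})

test_that("lambda decreases with fishing: scenario ordering", {
  sc <- porosus_scenarios()
  for (M in c(0.15, 0.261, 0.35)) {
    l1 <- dominant_eigen(build_leslie(lh, M))$lambda
    l2 <- dominant_eigen(build_leslie(lh, M, sc$recruitment, Z = 0.656))$lambda
    l3 <- dominant_eigen(build_leslie(lh, M, sc$adult_only, Z = 0.656))$lambda
    expect_true(l1 >= l3 && l3 >= l2)
  }
})

test_that("decline projection and criterion E", {
  d <- project_decline(-0.285, 10)
  expect_equal(d$N_t, exp(-2.85), tolerance = 1e-12)
  expect_lt(abs(d$N_t - 0.058), 1e-3)
  expect_equal(d$N_t + d$D_t, 1)
  d2 <- project_decline(-0.068, 21.620)
  expect_equal(d2$N_t, 0.2299, tolerance = 5e-4)
  d0 <- project_decline(0, c(0, 10, 50))
  expect_equal(d0$N_t, rep(1, 3))
  expect_equal(d0$D_t, rep(0, 3))

  expect_true(classify_criterion_E(0.999)$meets)
  expect_false(classify_criterion_E(0.49)$meets)
  expect_true(classify_criterion_E(0.5)$meets)   # inclusive boundary
  expect_match(classify_criterion_E(0.6)$caveat, "proxy")
})
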