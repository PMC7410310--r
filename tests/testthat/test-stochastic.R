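lh <- porosus_profile()
spec <- porosus_uncertainty(lh)

degenerate_spec <- function(M = 0.261)
  uncertainty_spec(M_support = list(M), Z_support = 0.656,
                   t_mat_support = 6, t_mat_probs = 1,
                   t_max_support = 12, t_max_probs = 1,
                   m_mean = 1.48, m_sd = 0)

test_that("draw frequencies match the stated discrete distributions", {
  set.seed(123)
  n <- 2e4
  draws <- replicate(n, draw_parameters(spec), simplify = FALSE)
  mi <- vapply(draws, `[[`, 0L, "M_index")
  expect_length(spec$M_support, 11)
  expect_equal(as.numeric(table(mi)) / n, rep(1 / 11, 11),
               tolerance = 0.15)
  tm <- vapply(draws, `[[`, 0L, "t_mat")
  expect_equal(as.numeric(table(tm) / n), c(0.25, 0.5, 0.25),
               tolerance = 0.05)
  tx <- vapply(draws, `[[`, 0L, "t_max")
  expect_equal(sort(unique(tx)), c(11L, 12L, 13L))
  m <- vapply(draws, `[[`, 0, "m")
  expect_true(all(m > 0))                      # truncation at zero
  expect_equal(mean(m), 1.48, tolerance = 0.02)
  Z <- vapply(draws, `[[`, 0, "Z")
  expect_true(all(Z %in% porosus_Z_values()))
})

test_that("age-dependent M members resolve to full schedules per draw", {
  set.seed(4)
  d <- draw_parameters(spec)
  expect_length(d$M_x, d$t_max + 1)
  # function members track the drawn t_max
  sched <- spec$M_support[[10]](6, 13)
  expect_length(sched, 14)
})

test_that("degenerate spec reproduces the deterministic pipeline exactly", {
  mc <- run_monte_carlo(lh, degenerate_spec(), porosus_scenarios()$recruitment,
                        n = 5, seed = 9)
  det <- demographic_summary(
    build_leslie(lh, 0.261, porosus_scenarios()$recruitment, Z = 0.656))
  expect_equal(unique(mc$draws$lambda), det$lambda)
  expect_equal(unique(mc$draws$r), det$r)
  s <- mc$summary
  expect_equal(s$lower, s$upper)               # zero-width CIs
  expect_equal(s$mean[s$parameter == "lambda"], det$lambda)
})

test_that("seeded Monte Carlo runs are bit-reproducible", {
  a <- run_monte_carlo(lh, spec, porosus_scenarios()$no_fishing,
                       n = 40, seed = 11)
  b <- run_monte_carlo(lh, spec, porosus_scenarios()$no_fishing,
                       n = 40, seed = 11)
  expect_identical(a$draws, b$draws)
  c2 <- run_monte_carlo(lh, spec, porosus_scenarios()$no_fishing,
                        n = 40, seed = 12)
  expect_false(identical(a$draws$lambda, c2$draws$lambda))
})

test_that("scenario ordering holds on every shared draw", {
  mc <- run_monte_carlo(lh, spec, porosus_scenarios(), n = 150, seed = 3)
  l1 <- mc$no_fishing$draws$lambda
  l2 <- mc$recruitment$draws$lambda
  l3 <- mc$adult_only$draws$lambda
  expect_true(all(l1 >= l3 - 1e-12))
  expect_true(all(l3 >= l2 - 1e-12))
  # shared draws: parameter records identical across scenarios
  expect_identical(mc$no_fishing$draws$m, mc$recruitment$draws$m)
})

test_that("summaries bracket means and proportions are proportions", {
  mc <- run_monte_carlo(lh, spec, porosus_scenarios()$no_fishing,
                        n = 200, seed = 21)
  s <- mc$summary
  expect_true(all(s$lower <= s$mean & s$mean <= s$upper))
  expect_gte(mc$prop_increasing, 0)
  expect_lte(mc$prop_increasing, 1)
  expect_equal(mc$draws$r, log(mc$draws$lambda))
})

test_that("decline summary is internally consistent", {
  mc <- run_monte_carlo(lh, spec, porosus_scenarios()$recruitment,
                        n = 200, seed = 5)
  dc <- decline_summary(mc)
  pt <- dc$point
  expect_equal(pt$N_t + pt$D_t, rep(1, nrow(pt)))
  expect_equal(pt$N_t[pt$horizon == "10"],
               exp(10 * mean(mc$draws$r)), tolerance = 1e-12)
  expect_equal(pt$years[pt$horizon == "3T"], 3 * mean(mc$draws$T))
  # per-draw median near the point value for the 10-yr horizon
  expect_equal(dc$draws$N_median[dc$draws$horizon == "10"],
               pt$N_t[pt$horizon == "10"], tolerance = 0.5)
  # r = 0 projects no decline
  expect_equal(project_decline(0, 3 * 7.7)$D_t, 0)
})
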