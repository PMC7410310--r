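g <- porosus_growth()

test_that("age classes bin by floor and report juveniles", {
  rec <- data.frame(age = c(1.2, 1.9, 2.4), length_cm = NA)
  f <- build_age_frequency(rec, mode = "observed")
  expect_identical(f$counts, c("1" = 2L, "2" = 1L))
  expect_identical(f$modal_age, 1L)

  rec2 <- data.frame(age = c(rep(5.5, 10), rep(6.5, 10)))
  f2 <- build_age_frequency(rec2, mode = "observed", t_mat = 6)
  expect_equal(f2$juvenile_fraction, 0.5)

  # length conversion excludes unconvertible lengths with a count
  rec3 <- data.frame(length_cm = c(40, 50, 140))
  f3 <- build_age_frequency(rec3, g)
  expect_equal(f3$n, 2)
  expect_equal(f3$n_unconvertible, 1)
  expect_error(build_age_frequency(data.frame(length_cm = 150), g),
               "no convertible")
})

test_that("catch curve is exact on noiseless exponential compositions", {
  ages <- 2:10
  f <- age_frequency(setNames(1e5 * exp(-0.5 * ages), ages))
  est <- catch_curve_Z(f, start_age = 2, end_age = 10)
  expect_equal(est$Z, 0.5, tolerance = 1e-12)
  expect_equal(est$se, 0, tolerance = 1e-10)

  flat <- age_frequency(setNames(rep(100, 6), 0:5))
  expect_equal(catch_curve_Z(flat, 0, 5)$Z, 0, tolerance = 1e-12)

  expect_error(catch_curve_Z(age_frequency(c("1" = 5, "2" = 3)), 1, 2),
               "fewer than 3")
})

test_that("Beverton & Holt estimators match their closed forms", {
  f <- age_frequency(c("3" = 5, "4" = 5))   # midpoint mean age = 4
  expect_equal(bh_Z_age(f, t_prime = 2)$Z, 0.5)
  expect_error(bh_Z_age(age_frequency(c("2" = 10)), t_prime = 2,
                        midpoint = FALSE), "unbounded")

  rec <- data.frame(length_cm = c(70, 90))
  est <- bh_Z_length(rec, g, L_prime = 50)
  expect_equal(est$Z, 0.077 * (136.4 - 80) / 30, tolerance = 1e-12)
  expect_error(bh_Z_length(data.frame(length_cm = 40), g, 50), "no records")
  # L_bar near L_inf drives Z towards zero
  rec2 <- data.frame(length_cm = rep(136, 5))
  expect_lt(bh_Z_length(rec2, g, 50)$Z, 0.001)
})

test_that("estimators recover the generator's truth on average", {
  cc <- numeric(20); bh <- numeric(20)
  for (i in 1:20) {
    sim <- simulate_catch(sim_config(n = 5000, M = 0.261, F_mort = 0.395,
                                     t_c = 2, growth = g, length_cv = 0.08,
                                     seed = 200 + i))
    f <- build_age_frequency(sim$records, mode = "observed", t_mat = 6)
    expect_identical(f$modal_age, 2L)
    cc[i] <- suppressWarnings(catch_curve_Z(f, start_age = 2)$Z)
    bh[i] <- bh_Z_age(f, t_prime = 2)$Z
  }
  expect_lt(abs(mean(cc) - 0.656) / 0.656, 0.05)
  expect_lt(abs(mean(bh) - 0.656) / 0.656, 0.10)
  # catch curve and B&H agree within sampling error on the same structure
  expect_lt(abs(mean(cc) - mean(bh)) / mean(cc), 0.1)
})

test_that("summarize_catch reports the composition", {
  expect_identical(summarize_catch(data.frame())$n, 0)
  rec <- data.frame(length_cm = c(29.6, 120), sex = c("F", "M"))
  s <- summarize_catch(rec, g)
  expect_equal(s$length_range, c(29.6, 120))
  expect_equal(s$sex_ratio_F, 0.5)

  sim <- simulate_catch(porosus_catch_config(seed = 5))
  s2 <- summarize_catch(sim$records, g, t_mat = 6)
  expect_identical(s2$n, 937L)
  expect_true(s2$modal_age %in% 1:2)
  expect_gt(s2$juvenile_fraction, 0.85)
})
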