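g <- porosus_growth()
t_mat <- age_at_length(71, g)   # 6.2764

test_that("scalar estimators reproduce the reference mortality table", {
  # printed reference values (+/- 0.001), t_max = 14, t_mat inverted VBGF
  ref <- c(m_jensen1(0.077) - 0.123, m_jensen2(0.077) - 0.116,
           m_jensen3(t_mat) - 0.263, m_rikhter_efanov(t_mat) - 0.250,
           m_hoenig_teleost(14) - 0.300, m_hoenig_cetacean(14) - 0.256,
           m_hewitt_hoenig(14) - 0.301, m_mollet_cailliet(14) - 0.329)
  expect_true(all(abs(ref) < 0.001))
})

test_that("Pauly follows its log-linear structure; 28C gives 0.218", {
  expect_equal(m_pauly(g, 28), 0.2184, tolerance = 5e-4)
  expect_equal(m_pauly(g, 29), 0.2220, tolerance = 5e-4)
  g2 <- growth_params(g$L_inf, 2 * g$k, g$t0)
  expect_equal(m_pauly(g2, 28) / m_pauly(g, 28), 2^0.6543,
               tolerance = 1e-9)
  expect_error(m_pauly(g, -1), "temperature")
})

test_that("longevity/maturity estimators are positive and decreasing", {
  for (f in list(m_hoenig_teleost, m_hoenig_cetacean, m_hewitt_hoenig,
                 m_mollet_cailliet)) {
    v <- vapply(seq(4, 60, by = 2), f, numeric(1))
    expect_true(all(v > 0))
    expect_true(all(diff(v) < 0))
  }
  v <- vapply(seq(2, 20, by = 1), m_jensen3, numeric(1))
  expect_true(all(diff(v) < 0))
  v <- vapply(seq(2, 20, by = 1), m_rikhter_efanov, numeric(1))
  expect_true(all(diff(v) < 0))
  # boundary of validity: term1 = 0.155 makes the estimate vanish
  t_star <- (1.521 / 0.155)^(1 / 0.72)
  expect_warning(out <- m_rikhter_efanov(t_star + 1), "invalid")
  expect_true(is.na(out))
})

test_that("Peterson & Wroblewski works on the regression's gram scale", {
  expect_equal(m_peterson_wroblewski(0.001), 1.92)        # 1 g
  expect_equal(m_peterson_wroblewski(0.016), 0.96)        # 16 g
  w <- c(0.5, 1, 2, 5, 20)
  expect_true(all(diff(m_peterson_wroblewski(w)) < 0))
  expect_error(m_peterson_wroblewski(0), "positive")
})

test_that("Chen & Watanabe two-phase schedule behaves", {
  expect_equal(m_chen_watanabe(0, g, t_mat, 14), 0.346, tolerance = 0.001)
  expect_equal(m_chen_watanabe(1, g, t_mat, 14), 0.2748, tolerance = 1e-3)
  # juvenile branch tends to k far from t0
  expect_equal(m_chen_watanabe(150, g, t_mat = 200, t_max = 400), g$k,
               tolerance = 1e-4)
  # continuous at the t_max limit (0/0 resolved analytically)
  lim <- m_chen_watanabe(14, g, t_mat, 14)
  expect_equal(m_chen_watanabe(14 - 1e-7, g, t_mat, 14), lim,
               tolerance = 1e-5)
  expect_error(m_chen_watanabe(15, g, t_mat, 14), "t_max")
  # schedule decreasing across the branch switch
  sched <- m_chen_watanabe(0:14, g, t_mat, 14)
  expect_true(all(diff(sched) < 0))
})

test_that("natural_mortality_set assembles 11 methods (10 without weights)", {
  lh <- porosus_profile()
  ms <- natural_mortality_set(lh)
  expect_length(ms$estimates, 11)
  expect_s3_class(as.data.frame(ms), "data.frame")
  ms10 <- natural_mortality_set(porosus_profile(length_weight = FALSE))
  expect_length(ms10$estimates, 10)
  methods <- vapply(ms10$estimates, `[[`, "", "method")
  expect_false("Peterson & Wroblewski" %in% methods)
})

test_that("aggregate_M averages by strategy", {
  lh <- porosus_profile()
  ms <- natural_mortality_set(lh)
  # frozen: mean of the nine computed scalar estimates
  expect_equal(aggregate_M(ms, "exclude-age-dependent"), 0.23957,
               tolerance = 1e-4)
  am <- aggregate_M(ms, "age-mean")
  mp <- aggregate_M(ms, "midpoint")
  expect_true(am > 0.2 && am < 0.3)
  expect_false(identical(am, mp))
  # single-estimate set is its own mean
  one <- structure(list(estimates = list(list(method = "x", value = 0.2,
                                              age_values = NULL,
                                              survival = exp(-0.2)))),
                   class = "mortality_set")
  expect_equal(aggregate_M(one), 0.2)
})

test_that("survival and exploitation arithmetic", {
  expect_equal(survival_from_Z(0.749), 0.473, tolerance = 5e-4)
  expect_equal(survival_from_Z(0.656), 0.519, tolerance = 5e-4)
  expect_equal(survival_from_Z(0), 1)
  expect_error(survival_from_Z(-0.1), "negative")
  expect_equal(as.numeric(fishing_mortality(0.656, 0.261)), 0.395)
  expect_equal(as.numeric(fishing_mortality(0.271, 0.239)), 0.032)
  expect_equal(as.numeric(fishing_mortality(0.5, 0.5)), 0)
  expect_identical(attr(fishing_mortality(0.2, 0.3), "flag"),
                   "underexploitation-or-inconsistency")

  e <- exploitation_rate(0.395, 0.656)
  expect_equal(as.numeric(e), 0.602, tolerance = 5e-4)
  expect_identical(attr(e, "classification"), "overexploited")
  expect_equal(as.numeric(exploitation_rate(0, 1)), 0)
  # E > 0.5 iff F > M when Z = F + M
  for (F_m in c(0.1, 0.3, 0.6)) for (M in c(0.2, 0.3)) {
    e <- as.numeric(exploitation_rate(F_m, F_m + M))
    expect_identical(e > 0.5, F_m > M)
  }

  expect_equal(overexploitation_degree(0.417, 0.032), 92.3,
               tolerance = 0.05)
  expect_equal(overexploitation_degree(0.4, 0.4), 0)
  expect_equal(overexploitation_degree(0.4, 0), 100)
  expect_error(overexploitation_degree(0, 0.1), "positive")
})
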