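test_that("the difference formula inverts the forward mixture exactly", {
  set.seed(7)
  for (i in 1:25) {
    r0 <- runif(1, 0.5, 1)
    r2 <- runif(1, 0.05, 0.4)
    r1 <- runif(1, 0, 1 - r2)
    s <- inclusion_scheme(r0, r1, r2)
    basal <- runif(1, 10, 20)
    v <- runif(1, -5, 40)
    test <- basal / r0 * r1 + v * r2
    expect_equal(nutrient_energy(test, basal, s), v)
  }
})

test_that("difference-method arithmetic and degenerate schemes", {
  s <- inclusion_scheme(0.961, 0.6781, 0.27)
  expect_equal(nutrient_energy(15.13, 14.50, s), 18.1427, tolerance = 1e-4)
  # full substitution returns the test value untouched
  s1 <- inclusion_scheme(0.961, 0, 1)
  expect_equal(nutrient_energy(12.3, 99, s1), 12.3)
  # strictly increasing in test, decreasing in basal
  expect_gt(nutrient_energy(15.2, 14.5, s), nutrient_energy(15.1, 14.5, s))
  expect_lt(nutrient_energy(15.2, 14.6, s), nutrient_energy(15.2, 14.5, s))
})

test_that("scheme validation enforces the proportion domain", {
  expect_error(inclusion_scheme(0, 0.5, 0.3), "r0")
  expect_error(inclusion_scheme(0.9, 0.5, 0), "r2")
  expect_error(inclusion_scheme(0.9, 0.8, 0.3), "exceed 1")
  expect_error(inclusion_scheme(0.9, 1, 0.3), "r1")
})

test_that("schemes are read off the packaged formulation table", {
  schemes <- schemes_from_diets(nep_fixture("table1_diets"))
  expect_equal(schemes$T2$r0, 0.961)
  expect_equal(schemes$T2$r1, 0.6781)
  expect_equal(schemes$T2$r2, 0.27)
  expect_equal(schemes$T6$r2, 0.118)
  expect_equal(schemes$T5$r1, 0.9063)
})

test_that("nutrient efficiencies reproduce the published ratios", {
  # soybean oil: dj = DE/GE; casein: mj = ME/DE
  eff_oil <- nutrient_efficiencies(ge = 37.97, de = 36.49, me = 36.16,
                                   pd = 200, pd_free_ne = 1500,
                                   me_rate = 2000)
  expect_equal(eff_oil$dj, 0.961, tolerance = 1e-3)
  eff_cas <- nutrient_efficiencies(ge = 20.20, de = 19.18, me = 16.89,
                                   pd = 900, pd_free_ne = 600,
                                   me_rate = 1900)
  expect_equal(eff_cas$mj, 0.8806, tolerance = 1e-4)
  expect_equal(nutrient_efficiencies(10, 10, 9, 100, 800, 1000)$dj, 1)
})

test_that("the two kj conventions are consistent with the nested prediction", {
  me_rate <- 2000
  pd <- 240 # pj = 0.12
  pfn <- 1600
  cons <- nutrient_efficiencies(20, 18, 17, pd, pfn, me_rate)
  expect_equal(cons$kj * (1 - cons$pj) * me_rate, pfn)
  printed <- nutrient_efficiencies(20, 18, 17, pd, pfn, me_rate,
                                   kj_form = "printed")
  expect_equal(printed$kj, pfn / me_rate * (1 - 0.12))
  expect_error(nutrient_efficiencies(20, 18, 17, 2100, pfn, me_rate),
               "below 1")
})

test_that("the nested fit recovers constructed coefficients from any start", {
  x2 <- c(840, 860, 820, 850, 830, 845)
  pd <- c(100, 250, 400, 700, 950, 500)
  pfn <- c(1700, 1500, 1300, 900, 650, 1100)
  ld <- pfn - 0.96 * x2 + 0.35 * pd
  fit <- fit_kbr_nepd(ld, pfn, x2, pd)
  expect_true(fit$converged)
  expect_equal(fit$k_br, 0.96, tolerance = 1e-8)
  expect_equal(fit$ne_pd, 0.35, tolerance = 1e-8)
  expect_equal(max(abs(fit$residuals)), 0, tolerance = 1e-8)
  # affine model: one Newton step from any start gives the same answer
  for (start in list(c(0, 0), c(5, -3), c(-2, 10))) {
    alt <- fit_kbr_nepd(ld, pfn, x2, pd, init = start)
    expect_equal(alt$k_br, fit$k_br, tolerance = 1e-10)
    expect_equal(alt$ne_pd, fit$ne_pd, tolerance = 1e-10)
  }
})

test_that("the Newton solver equals the least-squares oracle on random instances", {
  set.seed(11)
  for (i in 1:20) {
    n <- sample(4:40, 1)
    x2 <- runif(n, 700, 1000)
    pd <- runif(n, 50, 1000)
    pfn <- runif(n, 500, 2000)
    ld <- pfn - runif(1, 0.5, 1.2) * x2 + runif(1, -0.5, 0.8) * pd +
      rnorm(n, 0, 50)
    fit <- fit_kbr_nepd(ld, pfn, x2, pd)
    oracle <- ols_nested_oracle(ld, pfn, x2, pd)
    expect_equal(fit$k_br, oracle[["k_br"]], tolerance = 1e-10)
    expect_equal(fit$ne_pd, oracle[["ne_pd"]], tolerance = 1e-10)
  }
})

test_that("collinear nested-model regressors raise a singular-system error", {
  expect_error(fit_kbr_nepd(ld = c(1, 2), pd_free_ne = c(5, 6),
                            x2 = c(100, 200), pd = c(50, 100)),
               "collinear")
  expect_error(fit_kbr_nepd(1, 2, 3, 4), "two observations")
})

test_that("lipid-deposition prediction evaluates the printed right-hand side", {
  expect_equal(predict_ld(kj = 1, pj = 0, me = 1234, fhp = 999, pd = 55,
                          k_br = 0, ne_pd = 0), 1234)
  expect_equal(predict_ld(kj = 0.95, pj = 0.12, me = 1591, fhp = 840,
                          pd = 191, k_br = 0.96, ne_pd = 0.35),
               590.526, tolerance = 1e-3)
  expect_equal(predict_ld(kj = 0.9, pj = 0.1, me = 1000, fhp = 0, pd = 0,
                          k_br = 0.96, ne_pd = 0.35), 0.9 * 0.9 * 1000)
  bad_fit <- structure(list(converged = FALSE), class = "nested_fit")
  expect_error(predict_ld(1, 0, 1, 1, 1, fit = bad_fit), "converge")
})
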