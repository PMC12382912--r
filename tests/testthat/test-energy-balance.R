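test_that("digestibility matches published nitrogen balance and edge cases", {
  expect_equal(attd(100, 0), 1)
  expect_equal(attd(100, 100), 0)
  # casein-diet crude protein digestibility from the nitrogen balance table
  expect_equal(attd(39.39, 3.94), 0.9000, tolerance = 0.001)
  expect_error(attd(0, 1), "positive")
  expect_error(attd(10, -1), "non-negative")
  expect_warning(bad <- attd(10, 12), "exceeds intake")
  expect_lt(bad, 0) # flagged, not clamped
})

test_that("digestibility is invariant to rescaling intake and output", {
  set.seed(42)
  for (i in 1:20) {
    nd <- runif(1, 1, 100)
    nf <- runif(1, 0, nd)
    k <- runif(1, 0.01, 50)
    expect_equal(attd(k * nd, k * nf), attd(nd, nf))
  }
})

test_that("nitrogen retention and net protein availability match the balance table", {
  expect_equal(nitrogen_retention(39.39, 3.94, 8.34), 27.11)
  expect_equal(nitrogen_retention(0, 0, 0), 0)
  expect_equal(nitrogen_retention(28.38, 3.71, 4.44), 20.23,
               tolerance = 0.02 / 20.23) # printed 20.22, input rounding
  expect_equal(net_protein_availability(39.39, 3.94, 8.34), 0.688,
               tolerance = 0.001)
  expect_equal(net_protein_availability(28.38, 3.71, 4.44), 0.713,
               tolerance = 0.001)
  expect_equal(net_protein_availability(10, 0, 0), 1)
  expect_error(net_protein_availability(0, 0, 0), "positive")
})

test_that("DE and ME deduct fecal, urinary and methane energy", {
  rec <- data.frame(ge_intake = 20, fecal_ge = 2, urinary_ge = 0.5,
                    ch4_energy = 0.1, dmi = 1)
  out <- de_me_values(rec)
  expect_equal(out$de, 18)
  expect_equal(out$me, 17.4)
  # no losses: DE = ME = GE intake
  rec0 <- data.frame(ge_intake = 20, fecal_ge = 0, urinary_ge = 0,
                     ch4_energy = 0, dmi = 2)
  out0 <- de_me_values(rec0)
  expect_equal(out0$de, 20)
  expect_equal(out0$me, 20)
  expect_equal(out0$me_density, 10)
  expect_error(de_me_values(data.frame(ge_intake = 1, fecal_ge = 0,
                                       urinary_ge = 0, ch4_energy = 0,
                                       dmi = 0)), "dmi")
  expect_message(de_me_values(data.frame(ge_intake = 1, fecal_ge = 0,
                                         urinary_ge = 0, ch4 = 10,
                                         dmi = 1)), "39.54")
})

test_that("basal-diet DE density is reproduced from GE, DM and digestibility", {
  diets <- nep_fixture("table1_diets")
  t5 <- nep_fixture("table5_digestibility")
  for (diet in c("T1", "T5")) {
    t6_de <- nep_fixture("table6_energy")
    ge_dm <- diets$ge[diets$diet == diet] / (diets$dm[diets$diet == diet] / 100)
    attd_ge <- t5[t5$item == "attd_ge", diet] / 100
    expected <- t6_de[t6_de$item == "de", diet]
    expect_equal(ge_dm * attd_ge, expected, tolerance = 0.01 / expected)
  }
})

test_that("heat production is the printed linear combination and is additive", {
  expect_equal(heat_production(0, 0, 0, 0), 0)
  expect_equal(heat_production(1, 0, 0, 0), 16.18)
  expect_equal(heat_production(500, 450, 2, 8), 10296.74)
  a <- c(300, 280, 1, 5)
  b <- c(150, 160, 0.5, 2)
  expect_equal(heat_production(a[1] + b[1], a[2] + b[2], a[3] + b[3],
                               a[4] + b[4]),
               heat_production(a[1], a[2], a[3], a[4]) +
                 heat_production(b[1], b[2], b[3], b[4]))
  expect_error(heat_production(-1, 0), "non-negative")
})

test_that("metabolic weight scales body weight to the power 0.6", {
  expect_equal(metabolic_weight(1), 1)
  expect_equal(metabolic_weight(32), 8)
  expect_equal(metabolic_weight(30.72), exp(0.6 * log(30.72)))
  expect_error(metabolic_weight(0), "positive")
})

test_that("partition turns retained nitrogen into protein energy on the metabolic scale", {
  # one pig with the casein-diet nitrogen balance and body weight
  rec <- data.frame(pig_id = "p1", diet_id = "T6", dmi = 0.889,
                    ge_intake = 18.5, fecal_ge = 2.0, urinary_ge = 0.55,
                    ch4_energy = 0.07, n_intake = 39.39, fecal_n = 3.94,
                    urinary_n = 8.34, bw_start = 30.72, bw_end = 30.72)
  part <- energy_partition(rec, thp = 9000, fhp = 6600)
  pd_expected <- 27.11 * 6.25 * 23.86 / 30.72^0.6
  expect_equal(part$pd, pd_expected)
  expect_equal(pd_expected, 518.03, tolerance = 0.5 / 518.03)
  # bookkeeping identities
  expect_equal(part$re, part$mei - part$thp)
  expect_equal(part$hi, part$thp - part$fhp)
  expect_equal(part$ld, part$re - part$pd)
  expect_equal(part$pd_free_ne, (part$mei - part$hi) - part$pd)
})

test_that("partition flags inverted heat production and zero weight", {
  rec <- data.frame(pig_id = "p", diet_id = "d", dmi = 1, ge_intake = 10,
                    fecal_ge = 1, urinary_ge = 0.1, ch4_energy = 0,
                    n_intake = 10, fecal_n = 1, urinary_n = 1,
                    bw_start = 30, bw_end = 30)
  expect_warning(energy_partition(rec, thp = 100, fhp = 200), "THP below FHP")
  rec$bw_start <- rec$bw_end <- 0
  expect_error(energy_partition(rec, 100, 50), "positive")
})
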