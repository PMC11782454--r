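test_that("speciation reproduces the predicted chemistry of the dosing table", {
  rep <- run_carbonate_report(c(0.0004, 0.04, 0.15, 0.30))
  # NaHCO3 dose, printed precision per row
  expect_equal(round(rep$nahco3_mM[1], 3), 0.168)
  expect_equal(round(rep$nahco3_mM[2:4], 1), c(16.8, 63.1, 126.2))
  # species, CA and TIC at 3 decimals
  expect_equal(round(rep$co2_mM, 3), c(0.012, 1.186, 4.446, 8.892))
  expect_equal(round(rep$hco3_mM, 3), c(0.167, 16.747, 62.801, 125.602))
  expect_equal(round(rep$co3_mM, 3), c(0.000, 0.037, 0.141, 0.281))
  expect_equal(round(rep$ca_mM, 3), c(0.168, 16.822, 63.082, 126.165))
  expect_equal(round(rep$tic_mM, 3), c(0.180, 17.970, 67.388, 134.775))
})

test_that("speciation obeys mass and alkalinity identities and monotonicity", {
  ps <- seq(0.001, 0.9, length.out = 25)
  sp <- speciate_at_ph(ps, 7.2)
  expect_equal(sp$tic, sp$co2 + sp$hco3 + sp$co3, tolerance = 1e-12)
  expect_equal(sp$ca, sp$hco3 + 2 * sp$co3, tolerance = 1e-12)
  expect_true(all(sp$co2 >= 0 & sp$hco3 >= 0 & sp$co3 >= 0))
  for (col in c("co2", "hco3", "co3", "ca", "tic"))
    expect_true(all(diff(sp[[col]]) > 0), info = col)
})

test_that("speciation handles boundary inputs", {
  z <- speciate_at_ph(0, 7.5)
  expect_equal(unlist(z[c("co2", "hco3", "co3", "ca", "tic")]),
               c(co2 = 0, hco3 = 0, co3 = 0, ca = 0, tic = 0))
  expect_error(speciate_at_ph(-0.1, 7.5), "non-negative")
  expect_error(speciate_at_ph(0.3, 15), "ph")
  # at ph = pKa1 the CO2/HCO3- ratio is 1
  sp <- speciate_at_ph(0.15, 6.35)
  expect_equal(sp$hco3, sp$co2, tolerance = 1e-12)
  expect_lt(abs(sp$co2 - 4.446), 1e-3)
})

test_that("equilibrium pH inverts the dose exactly (round trip)", {
  for (p in c(0.0004, 0.04, 0.15, 0.30)) {
    for (ph_target in c(6, 6.8, 7.5, 8.4, 9)) {
      dose <- nahco3_dose(p, ph_target)
      expect_lt(abs(equilibrium_ph(dose, p) - ph_target), 1e-6)
    }
  }
})

test_that("full charge balance gives the pH of an undosed CO2 solution", {
  # independent bisection oracle on ca + H = OH + HCO3- + 2 CO3^2-
  pars <- carbonate_params()
  f <- function(ph) {
    sp <- speciate_at_ph(0.30, ph, pars)
    1000 * 10^(-ph) - 1000 * 10^(ph - pars$pkw) - sp$ca
  }
  lo <- 2; hi <- 12
  for (i in 1:200) {
    mid <- (lo + hi) / 2
    if (sign(f(mid)) == sign(f(lo))) lo <- mid else hi <- mid
  }
  expect_equal(equilibrium_ph(0, 0.30, water = TRUE), (lo + hi) / 2,
               tolerance = 1e-9)
  expect_equal(equilibrium_ph(0, 0.30, water = TRUE), 4.20, tolerance = 1e-2)
  expect_error(equilibrium_ph(0, 0.30), "no sign change")
})

test_that("total sodium accounting matches the medium recipe", {
  doses <- nahco3_dose(c(0.0004, 0.04, 0.15, 0.30), 7.5)
  expect_equal(total_sodium(doses), c(32.2, 48.8, 95.1, 158.2))
  expect_equal(total_sodium(0, 17.3), 17.3)
  expect_error(total_sodium(-1), "dose")
})

test_that("Weiss solubility matches published evaluations and behaviour", {
  expect_equal(kh_weiss(303.15, 1.5), 0.02964, tolerance = 1e-2)
  expect_equal(kh_weiss(298.15, 0), 0.034, tolerance = 2e-2)
  temps <- seq(278, 308, by = 2)
  expect_true(all(diff(kh_weiss(temps, 0)) < 0))
  expect_warning(kh_weiss(320, 0), "fit range")
})

test_that("titration model matches an independent bisection oracle", {
  pars <- carbonate_params()
  oracle_ph <- function(acid, c0 = 20, na0 = 40, acid_conc = 1.0) {
    dil <- 1 / (1 + acid / (1000 * acid_conc))
    na <- na0 * dil; cl <- acid * dil; tic <- c0 * dil
    bal <- function(ph) {
      h <- 10^(-ph); ka1 <- 10^(-pars$pka1); ka2 <- 10^(-pars$pka2)
      den <- h^2 + h * ka1 + ka1 * ka2
      a1 <- h * ka1 / den; a2 <- ka1 * ka2 / den
      na + 1000 * h - cl - 1000 * 10^(ph - pars$pkw) - tic * (a1 + 2 * a2)
    }
    lo <- 0; hi <- 14
    for (i in 1:200) {
      mid <- (lo + hi) / 2
      if (sign(bal(mid)) == sign(bal(lo))) lo <- mid else hi <- mid
    }
    (lo + hi) / 2
  }
  grid <- c(0, 5, 10, 20, 25, 30, 35, 40, 45)
  tc <- simulate_titration(20, 1.0, grid)
  expect_equal(tc$ph, vapply(grid, oracle_ph, numeric(1)), tolerance = 1e-8)
  # curve monotone non-increasing; buffer midpoint of the second proton at pKa1
  expect_true(all(diff(tc$ph) <= 0))
  expect_lt(abs(tc$ph[grid == 30] - 6.35), 5e-3)
  expect_error(simulate_titration(20, 1.0, c(5, 1)), "increasing")
})

test_that("pKa fitting recovers generating constants", {
  grid <- seq(0, 55, by = 0.5)
  clean <- simulate_titration(20, 1.0, grid)
  f <- fit_pka(clean)
  expect_lt(abs(f$pka1 - 6.35), 5e-3)
  expect_lt(abs(f$pka2 - 10.15), 5e-3)

  alt <- simulate_titration(20, 1.0, grid,
                            params = carbonate_params(pka1 = 6.0, pka2 = 10.0))
  f2 <- fit_pka(alt)
  expect_lt(abs(f2$pka1 - 6.0), 5e-3)
  expect_lt(abs(f2$pka2 - 10.0), 5e-3)

  set.seed(7)
  noisy <- clean
  noisy$ph <- noisy$ph + rnorm(length(grid), 0, 0.02)
  f3 <- fit_pka(noisy)
  expect_lt(abs(f3$pka1 - 6.35), 0.02)
  expect_lt(abs(f3$pka2 - 10.15), 0.02)

  short <- simulate_titration(20, 1.0, seq(0, 25, by = 1))
  expect_error(fit_pka(short), "equivalence")
})
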