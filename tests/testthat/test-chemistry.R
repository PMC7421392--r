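test_that("protonated fraction follows the acid-base speciation law", {
  expect_equal(protonated_fraction(ph = 7, pka = 7), 0.5)
  # frozen direct evaluations of 10^(pka-ph)/(1+10^(pka-ph))
  expect_equal(protonated_fraction(ph = 7, pka = 3.8), 6.3055949e-4,
               tolerance = 1e-7)
  expect_equal(protonated_fraction(ph = 7, pka = 7.7), 0.8336625,
               tolerance = 1e-4 / 0.8336625)
  # strictly decreasing in pH, strictly increasing in pKa
  phs <- seq(2, 12, by = 0.5)
  expect_true(all(diff(protonated_fraction(phs, 7)) < 0))
  pkas <- seq(2, 12, by = 0.5)
  expect_true(all(diff(protonated_fraction(7, pkas)) > 0))
  expect_error(protonated_fraction(NA, 7), "finite")
  expect_error(protonated_fraction(7, Inf), "finite")
})

test_that("pKa from ratio inverts the speciation and rejects bad ratios", {
  expect_equal(pka_from_ratio(1, ph = 7), 7.0)
  expect_equal(pka_from_ratio(9, ph = 7), 7.9542425, tolerance = 1e-7)
  expect_equal(pka_from_ratio(0.1, ph = 7), 6.0)
  expect_error(pka_from_ratio(0, ph = 7), "> 0")
  expect_error(pka_from_ratio(-2, ph = 7), "> 0")
  # round trip at 1e-10
  for (pka in c(3.8, 5.5, 7.7, 9.2)) {
    f <- protonated_fraction(7, pka)
    expect_equal(pka_from_ratio(f / (1 - f), 7), pka, tolerance = 1e-10)
  }
})

test_that("equilibrium solver reproduces the coupled binding-protonation state", {
  p <- model_params(k_micro = 1.13e4, pka_free = 3.8, pka_bound = 7.7,
                    ph = 7, sp_fraction = 0, total_dye = 12e-6)
  # no sites: all dye free, split by the free pKa
  st0 <- solve_equilibrium(p, 0)
  expect_equal(st0$mc_free + st0$mch_free, 12e-6)
  expect_identical(st0$mc_bound, 0)
  expect_identical(st0$mch_bound, 0)

  st <- solve_equilibrium(p, 1e-4)
  # bound pool protonation is governed by the bound pKa
  expect_equal(st$mch_bound / (st$mc_bound + st$mch_bound),
               protonated_fraction(7, 7.7), tolerance = 1e-3)
  # total bound dye against the independent depletion oracle
  orc <- oracle_equilibrium(p, 1e-4)
  expect_equal(st$mc_bound + st$mch_bound,
               orc$mc_bound + orc$mch_bound, tolerance = 0.02)
  expect_equal(st$mc_bound + st$mch_bound, 1.02e-8, tolerance = 0.02)
  expect_error(solve_equilibrium(p, -1e-6), ">= 0")
})

test_that("mass is conserved and binding responds monotonically", {
  set.seed(11)
  for (i in 1:25) {
    p <- model_params(k_micro = 10^runif(1, 2, 6),
                      pka_free = runif(1, 2, 8), pka_bound = runif(1, 2, 10),
                      ph = runif(1, 4, 9), sp_fraction = runif(1),
                      total_dye = 10^runif(1, -7, -4))
    rna <- 10^runif(1, -6, -3)
    for (m in c("excess_sites", "depletion")) {
      st <- solve_equilibrium(p, rna, method = m)
      expect_equal(total_dye_of(st), p$total_dye, tolerance = 1e-12)
    }
  }
  # bound total non-decreasing in rna_bp and in k_micro
  p <- model_params(sp_fraction = 0.3)
  bound <- sapply(seq(0, 6e-4, length.out = 15), function(r) {
    st <- solve_equilibrium(p, r)
    st$mc_bound + st$mch_bound
  })
  expect_true(all(diff(bound) >= 0))
  bound_k <- sapply(10^seq(2, 6, by = 0.5), function(k) {
    st <- solve_equilibrium(model_params(k_micro = k, sp_fraction = 0.3),
                            2e-4)
    st$mc_bound + st$mch_bound
  })
  expect_true(all(diff(bound_k) >= 0))
})

test_that("excess-sites approximation matches the depletion solver when sites dominate", {
  set.seed(7)
  for (i in 1:20) {
    p <- model_params(k_micro = 10^runif(1, 3, 5),
                      pka_free = runif(1, 3, 5), pka_bound = runif(1, 6, 9),
                      ph = 7, sp_fraction = runif(1, 0, 0.8),
                      total_dye = 12.5e-6)
    rna <- 10^runif(1, -4.5, -3)
    a <- solve_equilibrium(p, rna, method = "excess_sites")
    d <- solve_equilibrium(p, rna, method = "depletion")
    bound_d <- d$mc_bound + d$mch_bound
    if (bound_d < 0.05 * rna) {
      expect_equal(a$mc_bound + a$mch_bound, bound_d, tolerance = 0.01)
    }
    # depletion solver agrees with the independent uniroot oracle
    orc <- oracle_equilibrium(p, rna)
    expect_equal(bound_d, orc$mc_bound + orc$mch_bound, tolerance = 1e-6)
  }
})

test_that("pH limits drive the free dye to a single protonation state", {
  p <- model_params(sp_fraction = 0)
  lo <- solve_equilibrium(model_params(ph = -20, sp_fraction = 0), 0)
  expect_equal(lo$mch_free, p$total_dye, tolerance = 1e-10)
  hi <- solve_equilibrium(model_params(ph = 30, sp_fraction = 0), 0)
  expect_equal(hi$mc_free, p$total_dye, tolerance = 1e-10)
})

test_that("microscopic constant is the macroscopic one per protonated-bound fraction", {
  expect_equal(micro_from_macro(5e3, 1), 5e3)
  expect_equal(micro_from_macro(8.62e3, 0.763), 1.130e4, tolerance = 0.005)
  expect_equal(micro_from_macro(8.62e3, 0.9), 9577.778, tolerance = 1e-6)
  expect_true(micro_from_macro(8.62e3, 0.5) >= 8.62e3)
  expect_error(micro_from_macro(8.62e3, 0), "\\(0, 1\\]")
  expect_error(micro_from_macro(-1, 0.5), "> 0")
})

test_that("model parameters validate and round-trip through the config format", {
  expect_error(model_params(k_micro = -1), "> 0")
  expect_error(model_params(sp_fraction = 1.2), "\\[0, 1\\]")
  expect_error(model_params(total_dye = 0), "> 0")
  # a bound pKa below the free pKa is unusual but must be solvable
  st <- solve_equilibrium(model_params(pka_free = 7.7, pka_bound = 3.8,
                                       sp_fraction = 0), 1e-4)
  expect_equal(total_dye_of(st), 12.5e-6, tolerance = 1e-12)

  p <- model_params(k_micro = 1.13e4, pka_free = 3.8, pka_bound = 7.7,
                    ph = 7, sp_fraction = 0.63, total_dye = 12.5e-6)
  path <- withr::local_tempfile(fileext = ".cfg")
  write_model_params(p, path)
  p2 <- read_model_params(path)
  expect_equal(unclass(p2), unclass(p))
  writeLines(c("k_micro: 1", "bogus: 2"), path)
  expect_error(read_model_params(path), "unknown config key")
})
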