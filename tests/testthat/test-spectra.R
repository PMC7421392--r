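test_that("constructed extinction basis satisfies the spectral constraints", {
  b <- default_basis
  eps <- b$eps
  g <- b$grid
  e_mc <- function(l) unname(eps[which(g == l), "mc_free"])
  e_mch <- function(l) unname(eps[which(g == l), "mch_free"])

  expect_equal(e_mc(432) / e_mc(512), 0.28, tolerance = 0.005 / 0.28)
  for (l in c(456, 395)) {
    expect_lt(abs(e_mc(l) - e_mch(l)) / e_mc(l), 0.005)
  }
  expect_true(all(eps[g >= 420, "sp"] < 0.01 * e_mc(512)))
  expect_true(all(eps >= 0))
})

test_that("degenerate and infeasible band configurations are handled", {
  # identical MC and MCH+ bands: curves equal everywhere
  cfg <- band_config(mch_center = 512,
                     mch_width = default_basis$bands$mc[["width"]],
                     mch_peak = default_basis$bands$mc[["peak"]])
  b <- build_extinction_basis(cfg)
  expect_equal(b$eps[, "mc_free"], b$eps[, "mch_free"])
  expect_error(build_extinction_basis(band_config(ratio_432_512 = 1.2)),
               "infeasible")
  expect_error(band_config(grid = c(400, 390, 380)), "ascending")
  expect_error(band_config(grid = seq(400, 650, 1)), "380-650")
})

test_that("simulated spectra obey Beer-Lambert linearity", {
  b <- default_basis
  zero <- simulate_spectrum(dye_state(), b)
  expect_true(all(zero$absorbance == 0))

  st <- dye_state(sp = 4e-6, mc_free = 5e-6, mch_free = 1e-6,
                  mc_bound = 1.5e-6, mch_bound = 1e-6)
  st2 <- dye_state(sp = 8e-6, mc_free = 1e-5, mch_free = 2e-6,
                   mc_bound = 3e-6, mch_bound = 2e-6)
  s1 <- simulate_spectrum(st, b)
  s2 <- simulate_spectrum(st2, b)
  expect_equal(s2$absorbance, 2 * s1$absorbance)
  # pathlength proportionality
  s_half <- simulate_spectrum(st, b, pathlength = 0.05)
  expect_equal(s_half$absorbance, 0.5 * s1$absorbance)
})

test_that("MC-only spectrum shows the characteristic 432/512 ratio", {
  b <- default_basis
  s_mc <- simulate_spectrum(dye_state(mc_free = 12.5e-6), b)
  expect_equal(ratio_432_512(s_mc), 0.28, tolerance = 0.005 / 0.28)
  s_mch <- simulate_spectrum(dye_state(mch_free = 12.5e-6), b)
  expect_gt(ratio_432_512(s_mch), 1)
  s_mix <- simulate_spectrum(dye_state(mc_free = 6.25e-6,
                                       mch_free = 6.25e-6), b)
  expect_gt(ratio_432_512(s_mix), ratio_432_512(s_mc))
  expect_lt(ratio_432_512(s_mix), ratio_432_512(s_mch))
})

test_that("432/512 ratio grows monotonically along a dsRNA titration", {
  b <- default_basis
  p <- model_params(sp_fraction = 0.63)
  ratios <- sapply(seq(0, 6e-4, length.out = 10), function(r) {
    ratio_432_512(simulate_spectrum(solve_equilibrium(p, r), b))
  })
  expect_true(all(diff(ratios) > 0))
})

test_that("absorbance at the isosbestic points is invariant to MC protonation", {
  b <- default_basis
  total <- 12.5e-6
  a456 <- a395 <- numeric(0)
  for (f in seq(0, 1, by = 0.1)) {
    s <- simulate_spectrum(dye_state(mc_free = (1 - f) * total,
                                     mch_free = f * total), b)
    a456 <- c(a456, s$absorbance[which(b$grid == 456)])
    a395 <- c(a395, s$absorbance[which(b$grid == 395)])
  }
  expect_lt(diff(range(a456)) / mean(a456), 0.005)
  expect_lt(diff(range(a395)) / mean(a395), 0.005)
})

test_that("spectral noise is seed-reproducible", {
  b <- default_basis
  st <- dye_state(mc_free = 1e-5)
  s1 <- simulate_spectrum(st, b, noise_sd = 0.002, seed = 42)
  s2 <- simulate_spectrum(st, b, noise_sd = 0.002, seed = 42)
  s3 <- simulate_spectrum(st, b, noise_sd = 0.002, seed = 43)
  expect_identical(s1$absorbance, s2$absorbance)
  expect_false(identical(s1$absorbance, s3$absorbance))
})

test_that("percent change at 512 nm measures loss against the reference", {
  b <- default_basis
  eps512 <- b$eps[which(b$grid == 512), "mc_free"]
  ref <- simulate_spectrum(dye_state(mc_free = 0.080 / (eps512 * 0.1)), b)
  expect_equal(ref$absorbance[which(b$grid == 512)], 0.080)
  expect_equal(percent_change_512(ref, ref), 0)
  zero <- simulate_spectrum(dye_state(), b)
  expect_equal(percent_change_512(ref, zero), 100)
  half <- ref
  half$absorbance <- ref$absorbance / 2
  expect_equal(percent_change_512(ref, half), 50.0)
  expect_error(percent_change_512(zero, ref), "degenerate")
  other <- dye_spectrum(seq(380, 650, 2), rep(0.1, 136))
  expect_error(percent_change_512(ref, other), "grids")
})

test_that("background subtraction is exact for the additive forward model", {
  b <- default_basis
  dye <- dye_state(mc_free = 8e-6, mch_free = 2e-6)
  rna_only <- dye_state(mc_bound = 1e-6, mch_bound = 3e-6)
  both <- dye_state(mc_free = 8e-6, mch_free = 2e-6,
                    mc_bound = 1e-6, mch_bound = 3e-6)
  s_both <- simulate_spectrum(both, b)
  s_blank <- simulate_spectrum(rna_only, b)
  s_dye <- simulate_spectrum(dye, b)
  expect_equal(subtract_background(s_both, s_blank)$absorbance,
               s_dye$absorbance)
  zero <- simulate_spectrum(dye_state(), b)
  expect_equal(subtract_background(s_dye, zero)$absorbance, s_dye$absorbance)
  expect_true(all(subtract_background(s_dye, s_dye)$absorbance == 0))
  expect_error(
    subtract_background(s_dye, dye_spectrum(seq(380, 650, 2), rep(0, 136))),
    "grids")
})
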