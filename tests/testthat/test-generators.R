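test_that("all generators are deterministic under a fixed seed", {
  t1 <- gen_titration(binding_fit(70, 8620), seed = 9)
  t2 <- gen_titration(binding_fit(70, 8620), seed = 9)
  expect_identical(t1, t2)
  expect_false(identical(
    t1, gen_titration(binding_fit(70, 8620), seed = 10)))

  k1 <- gen_kinetic_trace(seed = 9)
  expect_identical(k1, gen_kinetic_trace(seed = 9))

  p1 <- gen_panel(seed = 9)
  expect_identical(p1, gen_panel(seed = 9))

  c1 <- gen_decitabine_course(seed = 9)
  expect_identical(c1, gen_decitabine_course(seed = 9))

  # the caller's RNG stream is untouched
  set.seed(123)
  before <- rnorm(1)
  set.seed(123)
  invisible(gen_titration(binding_fit(70, 8620), seed = 9))
  expect_identical(rnorm(1), before)
})

test_that("noiseless generators realize their models exactly", {
  cc <- seq(0, 450e-6, length.out = 12)
  ser <- gen_titration(binding_fit(90.6, 11111), concentrations = cc,
                       noise_sd = 0)
  expect_equal(ser$delta_a_percent, binding_curve(cc, 90.6, 11111))
  expect_equal(max(ser$delta_a_percent), 75.5, tolerance = 0.001)

  tr <- gen_kinetic_trace(noise_frac = 0)
  expect_equal(nrow(tr), 145)
  expect_equal(tr$absorbance,
               relaxation_model(tr$time_h, 0.080, 0.080 * 0.26 / 0.37, 2))
  # 12 h = 6 tau: the last point sits within 0.3% of equilibrium
  a_eq <- 0.080 * 0.26 / 0.37
  expect_lt(abs(tr$absorbance[145] - a_eq) / a_eq, 0.003)
})

test_that("noisy titrations scatter around the isotherm at the stated sd", {
  ser <- gen_titration(binding_fit(90.6, 11111), noise_sd = 0.5, seed = 21,
                       n_replicates = 20)
  resid <- ser$delta_a_percent -
    binding_curve(ser$conc_molar, 90.6, 11111)
  expect_lt(abs(mean(resid)), 0.1)
  expect_equal(stats::sd(resid), 0.5, tolerance = 0.15)
})

test_that("short duplexes bind with a scaled association constant", {
  cc <- seq(0, 450e-6, length.out = 12)
  long <- gen_titration(binding_fit(70, 8620), concentrations = cc,
                        noise_sd = 0, duplex_length = 20)
  short <- gen_titration(binding_fit(70, 8620), concentrations = cc,
                         noise_sd = 0, duplex_length = 10)
  expect_equal(long$delta_a_percent, binding_curve(cc, 70, 8620))
  expect_equal(short$delta_a_percent, binding_curve(cc, 70, 8620 * 0.5))
  expect_true(all(short$delta_a_percent[-1] < long$delta_a_percent[-1]))
  expect_error(gen_titration(binding_fit(70, 8620),
                             concentrations = numeric(0)), "empty")
  expect_error(gen_titration(binding_fit(70, 8620), noise_sd = 0.5), "seed")
})

test_that("composition model validates fractions and weights", {
  expect_error(rna_composition(fractions = c(long_dsrna = 0.5,
                                             hairpin = 0.5, ssrna = 0.5)),
               "sum to 1")
  expect_error(rna_composition(weights = c(long_dsrna = 1, hairpin = 2,
                                           ssrna = 0)),
               "\\[0, 1\\]")
  expect_error(rna_composition(fractions = c(a = 0.5, b = 0.5)), "named")
  op <- treatment_operator("rnase_t1")
  expect_setequal(op$removes, c("ssrna", "hairpin"))
  expect_length(treatment_operator("none")$removes, 0)
  expect_setequal(treatment_operator("rnase_a")$removes,
                  c("long_dsrna", "hairpin", "ssrna"))
})

test_that("treatment operators set the effective site concentration", {
  comp <- rna_composition()
  # untreated: weighted sum over all classes
  ctrl <- gen_panel(comp, "none", noise_sd = 0)
  expect_equal(ctrl$effective_conc_molar[1],
               350e-6 * (0.08 * 1 + 0.80 * 0.3 + 0.12 * 0.02))
  # RNase T1 keeps only long dsRNA; no renormalization of survivors
  t1 <- gen_panel(comp, "rnase_t1", noise_sd = 0)
  expect_equal(t1$effective_conc_molar[1], 350e-6 * 0.08)
  # RNase A removes everything
  a <- gen_panel(comp, "rnase_a", noise_sd = 0)
  expect_equal(a$effective_conc_molar[1], 0)
  expect_equal(a$delta_a_percent, rep(0, 3))
  noisy_a <- gen_panel(comp, "rnase_a", seed = 31)
  expect_lt(max(abs(noisy_a$delta_a_percent)), 4 * 0.5)
  # no dsRNA at all + RNase T1: silent panel
  no_ds <- rna_composition(fractions = c(long_dsrna = 0, hairpin = 0.85,
                                         ssrna = 0.15))
  expect_equal(gen_panel(no_ds, "rnase_t1",
                         noise_sd = 0)$delta_a_percent, rep(0, 3))
})

test_that("induction course scales dsRNA before the RNase T1 operator", {
  course <- gen_decitabine_course(noise_sd = 0)
  eff <- tapply(course$effective_conc_molar, course$day, unique)
  expect_equal(as.numeric(eff[c("0", "1", "3", "5")]),
               350e-6 * 0.08 * c(1, 1, 2.5, 4))
  expect_error(gen_decitabine_course(
    induction_multipliers = c(1, 1, 2, 3), seed = 1), "named")
  expect_error(gen_decitabine_course(
    induction_multipliers = c("0" = 1, "5" = -2), seed = 1), "> 0")
})
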