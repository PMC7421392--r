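# Seeded synthetic-data generators. Every generator is an exact realization
# of the corresponding analysis model in the noiseless limit, is
# deterministic under a fixed seed, and leaves the caller's RNG state
# untouched.

#' Reference binding constants for characterized duplex RNAs
#'
#' The one-site isotherm parameters (saturation amplitude `b_max` in percent
#' and association constant `k` in M^-1, per-base concentrations)
#' characterized for this dye with synthetic duplexes in two solvent
#' conditions: a 9 mM Na+ / 1 mM cacodylate buffer at pH 7 (`buffer_1`) and
#' nuclease-free water at pH 7 (`buffer_2`, the more sensitive condition).
#' The `gc50/buffer_2` row is the default calibration for cellular samples.
#'
#' @return Data frame with columns `rna`, `buffer`, `b_max`, `k`.
#' @export
reference_binding_constants <- function() {
  data.frame(
    rna    = c("poly_gc", "poly_gc", "poly_au", "poly_au", "gc50", "gc50"),
    buffer = c("buffer_1", "buffer_2", "buffer_1", "buffer_2",
               "buffer_1", "buffer_2"),
    b_max  = c(25.1, 90.6, 14.2, 52.5, 20, 70),
    k      = c(7352, 11111, 3891, 7042, 5000, 8620)
  )
}

#' Generate a synthetic titration series
#'
#' Realizes [binding_curve()] at the requested concentrations with additive
#' Gaussian noise on the percent-change scale. Duplexes shorter than 20 bp
#' bind more weakly; an optional duplex length scales the association
#' constant by `short_k_factor` when below that threshold.
#'
#' @param truth A [binding_fit()] (or list with `b_max`, `k`) holding the
#'   generating parameters.
#' @param concentrations Per-base RNA concentrations (mol/L); default 12
#'   points from 0 to 450 uM.
#' @param noise_sd Gaussian noise sd in percentage points (default 0.5).
#' @param n_replicates Replicates per concentration (default 1).
#' @param seed Integer seed (required when `noise_sd > 0`).
#' @param condition Condition label carried into the series.
#' @param duplex_length Optional duplex length (bp).
#' @param short_k_factor K multiplier applied when `duplex_length < 20`
#'   (default 0.5).
#' @return A [titration_series()].
#' @export
gen_titration <- function(truth,
                          concentrations = seq(0, 450e-6, length.out = 12),
                          noise_sd = 0.5, n_replicates = 1L, seed = NULL,
                          condition = "", duplex_length = NULL,
                          short_k_factor = 0.5) {
  assert_finite_numeric(concentrations, "concentrations")
  if (!length(concentrations)) stop_invalid("empty concentration list")
  assert_finite_scalar(noise_sd, "noise_sd")
  if (noise_sd < 0) stop_invalid("`noise_sd` must be >= 0")
  if (noise_sd > 0 && is.null(seed)) {
    stop_invalid("`seed` is required when noise_sd > 0")
  }
  k <- truth$k
  if (!is.null(duplex_length) && duplex_length < 20) {
    k <- k * short_k_factor
  }
  conc <- rep(concentrations, times = n_replicates)
  rep_id <- rep(seq_len(n_replicates), each = length(concentrations))
  y <- binding_curve(conc, truth$b_max, k)
  if (noise_sd > 0) {
    y <- y + with_seed(seed, stats::rnorm(length(y), 0, noise_sd))
  }
  titration_series(conc, y, replicate = rep_id, condition = condition)
}

#' Generate a synthetic dark-relaxation kinetic trace
#'
#' Realizes [relaxation_model()] with multiplicative Gaussian noise. The
#' defaults emulate the dye's thermal relaxation at 512 nm: starting from
#' the photostationary state after UV (37% MC, 0.080 AU in a 1 mm cell) and
#' relaxing with a 2 h time constant to the dark equilibrium (26% MC, i.e.
#' 74% SP), sampled every 5 minutes over 12 h.
#'
#' @param a0 Initial absorbance (AU); default 0.080.
#' @param a_eq Equilibrium absorbance (AU); default `0.080 * 0.26 / 0.37`.
#' @param tau Time constant (hours); default 2.
#' @param times Sampling times (hours), strictly increasing; default every
#'   5 min over 12 h.
#' @param noise_frac Multiplicative Gaussian noise fraction (default 0.01).
#' @param seed Integer seed (required when `noise_frac > 0`).
#' @param wavelength Monitoring wavelength (nm); default 512.
#' @param replicate Replicate identifier.
#' @return A [kinetic_trace()].
#' @export
gen_kinetic_trace <- function(a0 = 0.080, a_eq = 0.080 * 0.26 / 0.37,
                              tau = 2, times = seq(0, 12, by = 5 / 60),
                              noise_frac = 0.01, seed = NULL,
                              wavelength = 512, replicate = 1L) {
  assert_finite_numeric(times, "times")
  if (is.unsorted(times, strictly = TRUE)) {
    stop_invalid("`times` must be strictly increasing")
  }
  assert_finite_scalar(noise_frac, "noise_frac")
  if (noise_frac < 0) stop_invalid("`noise_frac` must be >= 0")
  if (noise_frac > 0 && is.null(seed)) {
    stop_invalid("`seed` is required when noise_frac > 0")
  }
  y <- relaxation_model(times, a0, a_eq, tau)
  if (noise_frac > 0) {
    y <- y * (1 + with_seed(seed, stats::rnorm(length(y), 0, noise_frac)))
  }
  kinetic_trace(times, y, wavelength = wavelength, replicate = replicate)
}

#' RNA composition model for cellular total-RNA samples
#'
#' Describes a total-RNA population as three classes: long double-stranded
#' RNA, hairpin/structured RNA (rRNA-like, the bulk of total RNA), and
#' unstructured single-stranded RNA. Each class carries a binding weight
#' converting its per-base concentration into effective dye-binding site
#' concentration: long dsRNA is 1 by definition; structured rRNA-like RNA
#' contributes partially through its short duplex stretches; ssRNA and free
#' nucleotides contribute essentially nothing.
#'
#' @param fractions Named fractions (`long_dsrna`, `hairpin`, `ssrna`)
#'   summing to 1. Defaults 0.08 / 0.80 / 0.12, a HeLa-like population
#'   dominated by rRNA.
#' @param weights Named binding weights in `[0, 1]`; defaults 1 / 0.3 /
#'   0.02.
#' @return An `rna_composition` object.
#' @export
rna_composition <- function(fractions = c(long_dsrna = 0.08, hairpin = 0.80,
                                          ssrna = 0.12),
                            weights = c(long_dsrna = 1, hairpin = 0.3,
                                        ssrna = 0.02)) {
  classes <- c("long_dsrna", "hairpin", "ssrna")
  if (!setequal(names(fractions), classes) ||
      !setequal(names(weights), classes)) {
    stop_invalid("fractions and weights must be named %s",
                 paste(classes, collapse = ", "))
  }
  fractions <- fractions[classes]
  weights <- weights[classes]
  if (any(fractions < 0) || any(fractions > 1) ||
      abs(sum(fractions) - 1) > 1e-12) {
    stop_invalid("fractions must lie in [0, 1] and sum to 1")
  }
  if (any(weights < 0) || any(weights > 1)) {
    stop_invalid("weights must lie in [0, 1]")
  }
  structure(list(fractions = fractions, weights = weights),
            class = "rna_composition")
}

#' Nuclease treatment operator
#'
#' Which RNA classes a treatment eliminates: RNase T1 cleaves single
#' strands (removing ssRNA and fragmenting hairpin/rRNA-like RNA) while long
#' dsRNA survives; RNase A under these conditions removes everything.
#' Removal reduces the total effective site concentration; surviving
#' fractions are deliberately not renormalized.
#'
#' @param name `"none"`, `"rnase_t1"`, or `"rnase_a"`.
#' @return A `treatment_operator` with fields `name` and `removes`.
#' @export
treatment_operator <- function(name = c("none", "rnase_t1", "rnase_a")) {
  name <- match.arg(name)
  removes <- switch(name,
    none = character(),
    rnase_t1 = c("ssrna", "hairpin"),
    rnase_a = c("long_dsrna", "hairpin", "ssrna"))
  structure(list(name = name, removes = removes),
            class = "treatment_operator")
}

# Effective dye-binding site concentration of a (possibly treated)
# composition at a given total per-base RNA concentration.
effective_site_conc <- function(composition, treatment, total_rna_conc,
                                dsrna_multiplier = 1) {
  f <- composition$fractions
  f["long_dsrna"] <- f["long_dsrna"] * dsrna_multiplier
  surviving <- setdiff(names(f), treatment$removes)
  total_rna_conc * sum(f[surviving] * composition$weights[surviving])
}

#' Generate a synthetic RNA sample panel
#'
#' Simulates the percent absorbance change for replicate samples of a total
#' RNA population after an optional nuclease treatment. The effective
#' binding-site concentration is the assay RNA concentration times the
#' weighted sum of the surviving composition classes; the response is the
#' calibration isotherm at that concentration plus Gaussian noise.
#'
#' @param composition An [rna_composition()].
#' @param treatment A [treatment_operator()] or its name.
#' @param total_rna_conc Assay per-base RNA concentration (mol/L); default
#'   350e-6, the concentration all samples are normalized to.
#' @param calibration A [binding_fit()] used as generating truth (default
#'   `binding_fit(70, 8620)`).
#' @param n_replicates Number of replicates (default 3).
#' @param noise_sd Gaussian noise sd in percentage points (default 0.5).
#' @param seed Integer seed (required when `noise_sd > 0`).
#' @param label Sample label; defaults to the treatment name.
#' @return A [sample_panel()] carrying the true effective concentration.
#' @export
gen_panel <- function(composition = rna_composition(),
                      treatment = treatment_operator("none"),
                      total_rna_conc = 350e-6,
                      calibration = binding_fit(70, 8620),
                      n_replicates = 3L, noise_sd = 0.5, seed = NULL,
                      label = NULL) {
  if (is.character(treatment)) treatment <- treatment_operator(treatment)
  stopifnot(inherits(composition, "rna_composition"),
            inherits(treatment, "treatment_operator"))
  assert_finite_scalar(total_rna_conc, "total_rna_conc")
  if (total_rna_conc < 0) stop_invalid("`total_rna_conc` must be >= 0")
  if (noise_sd < 0) stop_invalid("`noise_sd` must be >= 0")
  if (noise_sd > 0 && is.null(seed)) {
    stop_invalid("`seed` is required when noise_sd > 0")
  }
  eff <- effective_site_conc(composition, treatment, total_rna_conc)
  mu <- binding_curve(eff, calibration$b_max, calibration$k)
  y <- rep(mu, n_replicates)
  if (noise_sd > 0) {
    y <- y + with_seed(seed, stats::rnorm(n_replicates, 0, noise_sd))
  }
  if (is.null(label)) label <- treatment$name
  sample_panel(sample = label, treatment = treatment$name,
               replicate = seq_len(n_replicates), delta_a_percent = y,
               effective_conc_molar = eff)
}

#' Generate a demethylating-agent induction time course
#'
#' Simulates the dsRNA induction experiment: cells sampled on given days
#' after treatment with a demethylating agent, total RNA treated with RNase
#' T1 to enrich long dsRNA, and the surviving material assayed at a common
#' concentration. The long-dsRNA fraction is scaled by a per-day induction
#' multiplier before the RNase T1 operator is applied; the defaults encode
#' no induction through day 1 and progressively stronger induction at days 3
#' and 5.
#'
#' @param composition Base [rna_composition()].
#' @param induction_multipliers Named positive multipliers of the long-dsRNA
#'   fraction, one per day; default `c("0" = 1, "1" = 1, "3" = 2.5,
#'   "5" = 4)`.
#' @param total_rna_conc,calibration,n_replicates,noise_sd As [gen_panel()].
#' @param seed Integer seed.
#' @return A data frame (classes `sample_panel`) with an additional `day`
#'   column, rows ordered by day.
#' @export
gen_decitabine_course <- function(composition = rna_composition(),
                                  induction_multipliers = c("0" = 1,
                                                            "1" = 1,
                                                            "3" = 2.5,
                                                            "5" = 4),
                                  total_rna_conc = 350e-6,
                                  calibration = binding_fit(70, 8620),
                                  n_replicates = 3L, noise_sd = 0.5,
                                  seed = NULL) {
  if (is.null(names(induction_multipliers)) ||
      any(!nzchar(names(induction_multipliers)))) {
    stop_invalid("`induction_multipliers` must be named by day")
  }
  if (any(induction_multipliers <= 0)) {
    stop_invalid("induction multipliers must be > 0")
  }
  if (noise_sd > 0 && is.null(seed)) {
    stop_invalid("`seed` is required when noise_sd > 0")
  }
  t1 <- treatment_operator("rnase_t1")
  days <- as.numeric(names(induction_multipliers))
  if (any(is.na(days))) stop_invalid("day keys must be numeric")
  ord <- order(days)

  panels <- with_seed(seed, lapply(ord, function(i) {
    eff <- effective_site_conc(composition, t1, total_rna_conc,
                               dsrna_multiplier = induction_multipliers[i])
    mu <- binding_curve(eff, calibration$b_max, calibration$k)
    y <- rep(mu, n_replicates)
    if (noise_sd > 0) y <- y + stats::rnorm(n_replicates, 0, noise_sd)
    out <- sample_panel(sample = sprintf("decitabine_day_%g", days[i]),
                        treatment = sprintf("decitabine_day_%g", days[i]),
                        replicate = seq_len(n_replicates),
                        delta_a_percent = y, effective_conc_molar = eff)
    out$day <- days[i]
    out
  }))
  out <- do.call(rbind, panels)
  class(out) <- c("sample_panel", "data.frame")
  out
}
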