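---
title: "Modelling a spiropyran-based colorimetric dsRNA assay"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling a spiropyran-based colorimetric dsRNA assay}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dsrnadye)
```

## The system

Spiropyrans are photochromic switches. The closed spiro form (SP) is
colorless, non-planar and inert toward nucleic acids. UV irradiation opens
the ring to the planar merocyanine (MC), which absorbs near 512 nm; MC can
be protonated to MCH⁺, which absorbs near 432 nm. Only the open forms
interact with double-stranded RNA: the planar dye intercalates between
stacked base pairs, and the intercalated environment strongly stabilizes the
protonated form. Mixing the dye with dsRNA therefore converts MC into
(mostly bound) MCH⁺, which is read out as a loss of 512 nm absorbance and a
rise of the 432/512 peak ratio. Because the percent change at 512 nm is a
saturating function of the per-base duplex concentration, the dye doubles as
a quantitation reagent for dsRNA in total-RNA extracts — including the
increase of endogenous dsRNA after demethylating-agent treatment.

`dsrnadye` implements this system end to end: the coupled
protonation–binding equilibrium, a constrained spectral forward model,
isotherm fitting, two-wavelength speciation, dark-relaxation kinetics, the
quantitation pipeline, and seeded generators that emulate each experiment.

## Equilibrium model

Five species are tracked: SP, free MC, free MCH⁺, bound MC and bound MCH⁺.
SP is treated as compositionally locked (`sp_fraction`): inter-conversion
between SP and MC is slow (hours) compared with a titration measurement
(minutes), so the open-form pool is fixed during a binding experiment.
The open pool obeys four linked equilibria:

* free protonation, governed by `pka_free` (3.8 — free MC barely protonates
  at pH 7);
* bound protonation, governed by `pka_bound` (7.7 — bound dye is ~83%
  protonated at pH 7);
* MCH⁺ + site ⇌ MCH⁺·site with the microscopic constant `k_micro`
  (1.13 × 10⁴ M⁻¹);
* MC + site ⇌ MC·site with `K_MC = k_micro · 10^(pka_free − pka_bound)`,
  the value forced by thermodynamic cycle closure.

Every base pair is an independent site and concentrations are per base,
matching how the binding constants were determined. The default solver uses
the excess-sites approximation (free sites ≈ total sites), appropriate
because the dye (12.5 µM) is far below the RNA concentrations used (up to
~600 µM) and binding is weak; a depletion-aware bisection solver
(`method = "depletion"`, relative tolerance 1e-10, ≤200 iterations) is kept
as the exact reference and the two agree to well under 1% whenever bound dye
is below 5% of sites.

```{r}
p <- model_params()
solve_equilibrium(p, rna_bp = 350e-6)
```

`pka_bound > pka_free` is expected for this chemistry but deliberately not
enforced: the solver is valid for any finite pair, and the inverted case is
exercised in the tests.

### Microscopic vs macroscopic constants

A titration fit sees the whole open-dye pool, so the fitted (macroscopic)
constant understates the affinity of the actual interacting species, MCH⁺.
`micro_from_macro()` uses the convention `k_micro = k_macro / f`, where `f`
is the fraction of bound dye that is protonated. The characterized constants
for this dye (8.62 × 10³ and 1.13 × 10⁴ M⁻¹) imply `f ≈ 0.763`, while the
bound pKa of 7.7 implies `f ≈ 0.834` at pH 7 and the reported ~90:10 bound
ratio implies `f ≈ 0.9`; these printed values are mutually inconsistent at
the few-percent level. The package takes no side: each quantity is computed
under its own documented convention and joint consistency is not forced.

## Spectral forward model

Published constraints — not full extinction curves — define the optics: the
MC extinction ratio ε(432)/ε(512) = 0.28, isosbestic points of the MC/MCH⁺
pair at 456 and 395 nm, and negligible SP absorbance above 420 nm.
`build_extinction_basis()` realizes the simplest shape family that can meet
them: one Gaussian band per species, with the MC width solved from the 0.28
ratio and the MCH⁺ amplitude and width solved in closed form so the two
curves cross exactly at both isosbestic wavelengths. The MC peak extinction
(≈1.73 × 10⁵ M⁻¹ cm⁻¹) is anchored so that 12.5 µM dye at the
photostationary composition (63:37 SP:MC after UV) reads 0.080 AU at 512 nm
in the default 1 mm cell.

Bound species inherit the free curves with a hypochromic factor (default
0.65) and red shift (default +10 nm) typical of intercalation. These two
numbers are placeholders — the measured bound-species extinction curves are
not published — so nothing quantitative downstream depends on them; they
only shape qualitative titration spectra. Spectral metrics
(`ratio_432_512()`, `percent_change_512()`) read the grid point nearest the
nominal wavelength, with no interpolation, which is exact on the default
1 nm grid (380–650 nm).

```{r}
basis <- build_extinction_basis()
mc_only <- simulate_spectrum(dye_state(mc_free = 12.5e-6), basis)
ratio_432_512(mc_only)
```

## Titration analysis

The readout follows a one-site rectangular hyperbola,
`ΔA%(c) = B_max · K · c / (1 + K · c)`, in the association-constant
parameterization (K in M⁻¹) so the fitted values are directly comparable to
the characterized constants (`reference_binding_constants()`). No
cooperativity term is included; the measured curves show simple saturation.
`fit_binding()` pools replicates into one residual vector and fits by
Levenberg–Marquardt on log-parameters, which enforces positivity without
constraints; starting values are data-driven (`B_max⁰ = 1.1·max ΔA`,
`K⁰ = 1/c_half`). On noiseless model data the generating parameters are
recovered to 1e-6 relative; standard errors come from the local quadratic
approximation, mapped by the delta method. Non-convergence and degenerate
series are flagged, never silent. `invert_binding()` is the closed-form
inverse used for quantitation.

A caveat established by simulation (and visible in the test suite): at the
instrument noise of ~0.5 percentage points, the tight recovery bounds
(median errors below 2% on B_max and 5% on K over 200 replicate titrations)
hold for the nuclease-free-water condition, where the curve approaches
saturation within the 0–450 µM design. The shallow Na⁺-buffer curves carry
intrinsically less information about the two parameters at the same noise
level, and their estimates scatter several-fold more. This is a property of
the experimental design, not of the fitting code.

## Dark-relaxation kinetics

In the dark, SP and MC interconvert thermally as a single first-order
process: `A(t) = a_eq + (a0 − a_eq)·exp(−t/τ)`. A bi-exponential variant was
considered and rejected — one time constant (2 h) describes the system, and
the equilibrium composition is 74:26 SP:MC. `fit_relaxation()` estimates
(a0, a_eq, τ) with τ on the log scale and converts the fitted equilibrium
absorbance into the equilibrium SP fraction via the MC extinction at the
monitoring wavelength. The generator defaults start at the photostationary
0.080 AU and relax to `0.080 · 0.26/0.37 ≈ 0.056` AU, sampled every 5
minutes over 12 h (145 points, six time constants) with 1% multiplicative
noise. At 432 nm, traces are flat in the presence of dsRNA (loss of MC is
balanced by the gain of MCH⁺ there); `equilibrium_shift_metric()` exploits
this by contrasting the equilibrium 432/512 ratios of control and treated
samples under a shared 432 nm value.

## Quantitation pipeline

`quantify_panel()` converts replicate percent changes (all samples
normalized to a common assay concentration, default 350 µM per base —
chosen because a pure random-sequence duplex saturates the dye there with
~70% change) into effective dsRNA concentrations via the calibration
isotherm. The default calibration is the 50% GC duplex in nuclease-free
water (`B_max = 70`, `K = 8620 M⁻¹`), the condition a random-sequence
cellular duplex population most resembles.

Uncertainty uses a nonparametric bootstrap over replicates (default 2000
resamples, seed mandatory), but not as raw percentile intervals: with the
typical three biological replicates, percentile intervals cover the truth
only ~80% of the time. Instead the interval is
`mean ± t(n−1) × SE_boot·√(n/(n−1))` on the percent-change scale — the
bootstrap standard error corrected for its small-n downward bias, with the
Student multiplier — mapped through the monotone calibration inverse.
Endpoints below zero clamp to zero; endpoints at or above saturation are
reported as unbounded, and a saturated sample mean is flagged explicitly.
Measured coverage on the generator's own conditions (200 seeded panels,
3 replicates, 0.5-point noise) is ~95%. Treatment groups are compared by
Welch two-sample t-tests on the replicate percent changes — deliberately
routine machinery.

## Synthetic data

The generators define the study conditions and are first-class, tested
code:

* `gen_titration()` — exact isotherm plus additive Gaussian noise (default
  0.5 percentage points); optional length effect multiplying K by 0.5 for
  duplexes under 20 bp, reflecting the weaker response of 10-mers.
* `gen_kinetic_trace()` — exact relaxation law plus 1% multiplicative
  noise.
* `gen_panel()` — a total-RNA population as three classes with binding
  weights: 80% hairpin/rRNA-like (weight 0.3), 12% ssRNA (weight 0.02), 8%
  long dsRNA (weight 1.0). The composition is a tunable placeholder, not a
  measured quantity: rRNA dominates real total RNA (>80%) and its short
  duplex stretches (~12 bp at most) respond only partially, while free
  nucleotides do not respond at all. RNase T1 removes the ssRNA and hairpin
  classes (long dsRNA survives), RNase A removes everything; survivors are
  deliberately not renormalized, since removal reduces the effective site
  pool.
* `gen_decitabine_course()` — scales the long-dsRNA fraction by per-day
  multipliers before the RNase T1 operator. The defaults (1, 1, 2.5, 4 for
  days 0/1/3/5) encode the qualitative biology of demethylation-induced
  dsRNA expression: no induction through day 1, clear induction by day 3,
  strongest at day 5. The exact multipliers are free parameters; only their
  ordering is meaningful.

Every generator is deterministic under a fixed seed and restores the
caller's RNG state. What the generators do **not** emulate: baseline drift
and stray light, pipetting error structure, RNA absorbance below 380 nm,
sequence-specific (AU- vs GC-step) binding beyond distinct K values, or
RNase kinetics. Passing tests therefore validate the analysis chain under
its own stated statistical assumptions, not instrument- or biology-level
fidelity.

## Numerical choices

* Equilibrium bisection: relative tolerance 1e-10, ≤200 iterations;
  `rna_bp = 0` short-circuits to the closed form with exactly zero bound
  species.
* Fits: `minpack.lm` Levenberg–Marquardt, `ftol = ptol = 1e-15`, ≤500
  iterations; positivity via log-parameterization; flagged failure objects
  (never exceptions) for degenerate data.
* Spectral metrics: nearest-grid-point lookup, ties broken toward the
  shorter wavelength.
* Two-wavelength decomposition: exact 2×2 solve; condition number above
  1e8 is an error; negative solved concentrations (possible under noise)
  clip to zero with a warning flag.
* CSVs are written with 17 significant digits so write/read round trips are
  bit-exact.

## Problem sizes

The validation suite uses 20-replicate recovery experiments for the
headline constants (titration K, relaxation τ, equilibrium SP fraction),
200-replicate experiments for distributional properties (median recovery
error, bootstrap coverage), and 25-case random sweeps for the equilibrium
invariants. These sizes put Monte Carlo error comfortably below the bands
being checked while keeping the full suite around ten seconds.

## Known limitations

* The photostationary and thermal SP fractions (0.63, 0.74) are inputs, not
  predictions: the extinction at the 254 nm irradiation wavelength is not
  available, so photokinetics are out of scope (quantum yields are recorded
  as documented constants only).
* Bound-species extinction magnitudes are placeholders (see above).
* The micro/macro/pKa conventions cannot be made jointly consistent with
  the printed values; see the equilibrium section.
* No McGhee–von Hippel neighbor-exclusion correction: at the weak-binding,
  site-excess regime of this assay the independent-site hyperbola is the
  appropriate (and the originally used) model.
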