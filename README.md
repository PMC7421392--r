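# dsrnadye

Analysis toolkit for a colorimetric double-stranded RNA (dsRNA) assay built
on a spiropyran photochromic switch. The closed spiropyran (SP) is inert and
colorless; its open merocyanine form (MC, 512 nm band) intercalates into
dsRNA base pairs and is thereby protonated to MCH⁺ (432 nm band). dsRNA in a
sample therefore shows up as a loss of 512 nm absorbance and a rise of the
432/512 peak ratio, and the size of the change measures how much duplex RNA
is present. The package is aimed at people modelling or running such
dye-based nucleic-acid assays: it provides the forward models (equilibrium
speciation, spectra, kinetics), the inference steps (isotherm fits,
two-wavelength speciation, relaxation fits, concentration estimates with
bootstrap intervals), and seeded synthetic-data generators so the whole
chain can be validated end to end.

## The models

**Binding/protonation equilibrium.** Five species (SP, MC, MCH⁺, MC·RNA,
MCH⁺·RNA) linked by the free pKa (3.8), the bound pKa (7.7), and the
microscopic association constant of MCH⁺ for a base-pair site
(K = 1.13 × 10⁴ M⁻¹), with cycle closure
K_MC = K_MCH · 10^(pKa_free − pKa_bound). Solved in closed form under the
excess-sites approximation, or exactly by bisection.

**Titration isotherm.** ΔA₅₁₂%(c) = B_max · K · c / (1 + K · c) with c the
per-base duplex concentration; fitted by Levenberg–Marquardt on
log-parameters, inverted in closed form for quantitation. Characterized
(B_max, K) pairs for poly GC / poly AU / 50% GC duplexes in two buffers ship
as `reference_binding_constants()`.

**Spectra.** Gaussian-band extinction curves constrained so that
ε_MC(432)/ε_MC(512) = 0.28, the MC/MCH⁺ isosbestic points sit exactly at 456
and 395 nm, and SP does not absorb in the visible.

**Kinetics.** First-order dark relaxation
A(t) = a_eq + (a0 − a_eq)·e^(−t/τ) with τ = 2 h and a 74:26 SP:MC
equilibrium as reference behavior.

## Worked example

Simulate a noisy calibration titration of the 50% GC duplex in
nuclease-free water, fit it, and use the fit to quantify an RNase-treated
sample panel:

```r
library(dsrnadye)

ser <- gen_titration(binding_fit(70, 8620), noise_sd = 0.5, seed = 11)
fit <- fit_binding(ser)
fit
#> One-site binding fit
#>   B_max: 70.15 % (se 0.702)
#>   K:     8493 M^-1 (se 259)
#>   RSS:   2.482 on 10 df

panel <- rbind(gen_panel(treatment = "none",     seed = 1),
               gen_panel(treatment = "rnase_t1", seed = 2),
               gen_panel(treatment = "rnase_a",  seed = 3))
quantify_panel(panel, fit, seed = 4)
#> dsRNA quantitation
#>   calibration: B_max 70.15 %, K 8493 M^-1
#>     sample treatment n mean_delta_a    sem conc_estimate conc_lower conc_upper
#> 1     none      none 3      34.3022 0.1554     1.127e-04  1.085e-04  1.170e-04
#> 2  rnase_a   rnase_a 3      -0.1659 0.1765     0.000e+00  0.000e+00  1.004e-06
#> 3 rnase_t1  rnase_t1 3      13.7562 0.3596     2.872e-05  2.477e-05  3.290e-05
```

Reading: the untreated total RNA responds strongly (34% change ≈ 113 µM
effective duplex per base). RNase T1 digests single-stranded and hairpin RNA
and leaves long dsRNA, so the signal drops to the long-duplex component
(~29 µM); RNase A digests everything and the estimate is zero within its
interval. Welch tests between the treatments are reported alongside.

Fitting a dark-relaxation trace recovers the thermal behavior of the switch:

```r
fit_relaxation(gen_kinetic_trace(seed = 5))
#> First-order relaxation fit
#>   a0:   0.07985 AU (se 0.00025)
#>   a_eq: 0.0562 AU (se 8.58e-05)
#>   tau:  2.03 h (se 0.0407)
#>   equilibrium SP fraction: 0.740
```

A thin command-line interface over the same functions is installed at
`inst/cli/dsrnadye` (`simulate-titration`, `fit-titration`, `fit-kinetics`,
`decompose`, `quantify`, `demo-decitabine`, `fixtures`).

See `vignettes/dsrna-photochrome-assay.Rmd` for the full model description,
parameter meanings and numerical choices.

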