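Package: dsrnadye
Title: Spiropyran Photochrome Spectroscopy for Double-Stranded RNA Detection
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Models and analyses for a colorimetric double-stranded RNA (dsRNA)
    assay built on the spiropyran/merocyanine photochromic switch. Provides the
    coupled protonation-binding equilibrium of the open merocyanine form with
    duplex RNA base pairs, a Beer-Lambert spectral forward model constrained by
    isosbestic points, hyperbolic binding-isotherm fitting of UV-Vis titrations,
    two-wavelength decomposition into neutral and protonated dye species with
    apparent pKa estimation, first-order thermal relaxation kinetics, and a
    quantitation workflow that converts percent absorbance changes into
    effective dsRNA concentrations with bootstrap uncertainty. Seeded
    generators produce synthetic titrations, kinetic traces and RNA sample
    panels (RNase treatments, demethylating-agent induction time courses) for
    end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    minpack.lm,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
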