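# Two-wavelength decomposition of absorbance into MC and MCH+ amounts, and
# the bound-ratio / apparent-pKa bookkeeping. SP contributes nothing at 432
# or 512 nm (enforced by the extinction basis), and bound and free forms of
# each protonation state are pooled, so two wavelengths determine the two
# concentrations exactly.

#' Two-wavelength absorbance reading
#'
#' @param a432,a512 Absorbances (AU) at 432 and 512 nm.
#' @param pathlength Path length (cm), `> 0`.
#' @return A `two_wavelength_reading` object.
#' @export
two_wavelength_reading <- function(a432, a512, pathlength = 0.1) {
  assert_finite_scalar(a432, "a432")
  assert_finite_scalar(a512, "a512")
  assert_finite_scalar(pathlength, "pathlength")
  if (pathlength <= 0) stop_invalid("`pathlength` must be > 0")
  structure(list(a432 = a432, a512 = a512, pathlength = pathlength),
            class = "two_wavelength_reading")
}

#' Extract a two-wavelength reading from a spectrum
#'
#' @param spectrum A [dye_spectrum()].
#' @return A [two_wavelength_reading()] at the grid points nearest 432 and
#'   512 nm.
#' @export
reading_from_spectrum <- function(spectrum) {
  two_wavelength_reading(absorbance_at(spectrum, 432),
                         absorbance_at(spectrum, 512),
                         pathlength = spectrum$pathlength)
}

#' Decompose a two-wavelength reading into MC and MCH+ concentrations
#'
#' Solves the 2x2 Beer-Lambert system at 432 and 512 nm using the free MC
#' and MCH+ extinction coefficients of the basis. Concentrations solved as
#' slightly negative (possible under noise) are clipped to zero with a
#' warning and flagged via the `clipped` attribute.
#'
#' @param reading A [two_wavelength_reading()].
#' @param basis An extinction basis from [build_extinction_basis()].
#' @return Named numeric vector `c(mc, mch)` of concentrations (mol/L), with
#'   attribute `clipped` (logical).
#' @examples
#' basis <- build_extinction_basis()
#' sp <- simulate_spectrum(dye_state(mc_free = 12e-6), basis)
#' decompose_species(reading_from_spectrum(sp), basis) # (12e-6, 0)
#' @export
decompose_species <- function(reading, basis) {
  stopifnot(inherits(reading, "two_wavelength_reading"),
            inherits(basis, "extinction_basis"))
  i432 <- nearest_index(basis$grid, 432)
  i512 <- nearest_index(basis$grid, 512)
  m <- unname(rbind(
    c(basis$eps[i432, "mc_free"], basis$eps[i432, "mch_free"]),
    c(basis$eps[i512, "mc_free"], basis$eps[i512, "mch_free"])))
  if (!all(is.finite(m)) || abs(det(m)) < .Machine$double.eps ||
      kappa(m, exact = TRUE) > 1e8) {
    stop_invalid("extinction matrix at 432/512 nm is singular or ill-conditioned")
  }
  conc <- unname(solve(m, c(reading$a432, reading$a512) / reading$pathlength))
  clipped <- any(conc < 0)
  if (clipped) {
    warning("negative solved concentration clipped to zero", call. = FALSE)
    conc <- pmax(conc, 0)
  }
  structure(c(mc = conc[1L], mch = conc[2L]), clipped = clipped)
}

#' Bound-species ratio and apparent pKa from MC/MCH+ concentrations
#'
#' Computes the MCH+:MC molar ratio and the apparent pKa it implies at the
#' given pH (`pka = ph + log10(ratio)`). With no neutral MC present, the
#' ratio is infinite and the pKa is undefined.
#'
#' @param mc_conc,mch_conc Concentrations (mol/L), `>= 0`, not both zero.
#' @param ph Solution pH.
#' @return List with `ratio` (MCH+:MC; `Inf` if `mc_conc` is 0) and `pka`
#'   (`NA` when the ratio is not positive and finite).
#' @examples
#' bound_ratio_and_pka(10, 90, ph = 7) # ratio 9, pKa ~7.95
#' @export
bound_ratio_and_pka <- function(mc_conc, mch_conc, ph) {
  assert_finite_scalar(mc_conc, "mc_conc")
  assert_finite_scalar(mch_conc, "mch_conc")
  if (mc_conc < 0 || mch_conc < 0) {
    stop_invalid("concentrations must be >= 0")
  }
  if (mc_conc == 0 && mch_conc == 0) {
    stop_invalid("both concentrations are zero")
  }
  if (mc_conc == 0) {
    warning("no neutral MC present: ratio infinite, pKa undefined",
            call. = FALSE)
    return(list(ratio = Inf, pka = NA_real_))
  }
  ratio <- mch_conc / mc_conc
  pka <- if (ratio > 0) pka_from_ratio(ratio, ph) else NA_real_
  list(ratio = ratio, pka = pka)
}
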