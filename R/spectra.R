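# Beer-Lambert spectral forward model. Per-species extinction curves are
# sums of Gaussian bands in wavelength, constructed to honor the measured
# constraints of the system: the MC 432/512 nm extinction ratio of 0.28, the
# two isosbestic points of the MC <-> MCH+ interconversion at 456 and 395 nm,
# and negligible SP absorbance in the visible.

SPECIES <- c("sp", "mc_free", "mch_free", "mc_bound", "mch_bound")

gaussian_band <- function(grid, center, width, peak) {
  peak * exp(-((grid - center)^2) / (2 * width^2))
}

#' Default band configuration for the extinction basis
#'
#' Returns the configuration consumed by [build_extinction_basis()]. The MC
#' band is centered at 512 nm; its peak extinction defaults to the value at
#' which a 12.5 uM solution, 37% of which is in the open MC form
#' (photostationary state after UV), reads 0.080 AU at 512 nm in a 1 mm
#' cuvette. The MCH+ band is centered at 432 nm; its amplitude and width are
#' not free here but solved by the constructor so the two isosbestic
#' crossings land exactly at 456 and 395 nm. Bound species inherit the free
#' curves with a hypochromic scaling (default 0.65) and a red shift (default
#' +10 nm) typical of intercalation.
#'
#' @param grid Wavelength grid (nm), ascending; default 380-650 at 1 nm.
#' @param mc_center,mc_peak MC band center (nm) and peak extinction
#'   (M^-1 cm^-1).
#' @param mch_center MCH+ band center (nm).
#' @param ratio_432_512 Target MC extinction ratio at 432 vs 512 nm.
#' @param isosbestic Two wavelengths (nm) where MC and MCH+ extinctions must
#'   be equal.
#' @param sp_center,sp_width,sp_peak SP band (UV tail; negligible above
#'   420 nm).
#' @param hypochromic Multiplicative extinction factor for bound species.
#' @param red_shift Band shift (nm) for bound species.
#' @param mch_width,mch_peak Optional explicit MCH+ band; when both are
#'   given the isosbestic solve is skipped and the band is used as-is.
#' @return A list of class `band_config`.
#' @export
band_config <- function(grid = seq(380, 650, by = 1),
                        mc_center = 512,
                        mc_peak = 0.080 / (12.5e-6 * 0.37 * 0.1),
                        mch_center = 432,
                        ratio_432_512 = 0.28,
                        isosbestic = c(456, 395),
                        sp_center = 330, sp_width = 28, sp_peak = 3e4,
                        hypochromic = 0.65, red_shift = 10,
                        mch_width = NULL, mch_peak = NULL) {
  assert_finite_numeric(grid, "grid")
  if (is.unsorted(grid, strictly = TRUE)) {
    stop_invalid("`grid` must be strictly ascending")
  }
  if (min(grid) > 380 || max(grid) < 650) {
    stop_invalid("`grid` must cover at least 380-650 nm")
  }
  structure(
    list(grid = grid, mc_center = mc_center, mc_peak = mc_peak,
         mch_center = mch_center, ratio_432_512 = ratio_432_512,
         isosbestic = isosbestic, sp_center = sp_center,
         sp_width = sp_width, sp_peak = sp_peak,
         hypochromic = hypochromic, red_shift = red_shift,
         mch_width = mch_width, mch_peak = mch_peak),
    class = "band_config"
  )
}

#' Construct per-species extinction curves satisfying the spectral constraints
#'
#' Builds Gaussian-band extinction curves for the five dye species. The MC
#' band width is solved from the 432/512 extinction ratio; the MCH+ band
#' amplitude and width are then solved in closed form so that the MC and
#' MCH+ curves cross exactly at both isosbestic wavelengths. An explicit
#' MCH+ band in the config bypasses the solve (used e.g. for the degenerate
#' identical-band case).
#'
#' @param config A [band_config()]; defaults to `band_config()`.
#' @return An `extinction_basis`: list with `grid` (nm) and `eps`, a matrix
#'   (length(grid) x 5) of extinction coefficients (M^-1 cm^-1) with columns
#'   `sp`, `mc_free`, `mch_free`, `mc_bound`, `mch_bound`, plus the band
#'   descriptors used.
#' @examples
#' basis <- build_extinction_basis()
#' basis$eps[basis$grid == 432, "mc_free"] /
#'   basis$eps[basis$grid == 512, "mc_free"] # 0.28
#' @export
build_extinction_basis <- function(config = band_config()) {
  stopifnot(inherits(config, "band_config"))
  grid <- config$grid

  # MC width from the 432/512 extinction ratio: for a Gaussian centered at
  # mc_center, eps(432)/eps(512) = exp(((512-c)^2 - (432-c)^2) / (2 w^2)).
  num <- (512 - config$mc_center)^2 - (432 - config$mc_center)^2
  lr <- log(config$ratio_432_512)
  if (!is.finite(lr) || num * lr <= 0) {
    stop_invalid(
      "infeasible constraints: no positive MC band width gives a 432/512 ratio of %g with center %g nm",
      config$ratio_432_512, config$mc_center)
  }
  mc_width <- sqrt(num / (2 * lr))
  eps_mc_at <- function(l) gaussian_band(l, config$mc_center, mc_width,
                                         config$mc_peak)

  if (is.null(config$mch_width) || is.null(config$mch_peak)) {
    # Solve the MCH+ Gaussian through the two isosbestic anchor points
    # (l1, eps_MC(l1)) and (l2, eps_MC(l2)).
    l1 <- config$isosbestic[1L]
    l2 <- config$isosbestic[2L]
    e1 <- eps_mc_at(l1)
    e2 <- eps_mc_at(l2)
    d1 <- l1 - config$mch_center
    d2 <- l2 - config$mch_center
    denom <- d2^2 - d1^2
    lr <- log(e1 / e2)
    if (!is.finite(lr) || lr * denom <= 0) {
      stop_invalid(paste("infeasible constraints: isosbestic anchors do not",
                         "admit a positive MCH+ band width"))
    }
    mch_width <- sqrt(denom / (2 * lr))
    mch_peak <- e1 * exp(d1^2 / (2 * mch_width^2))
  } else {
    mch_width <- config$mch_width
    mch_peak <- config$mch_peak
  }

  eps_sp <- gaussian_band(grid, config$sp_center, config$sp_width,
                          config$sp_peak)
  eps_mc <- gaussian_band(grid, config$mc_center, mc_width, config$mc_peak)
  eps_mch <- gaussian_band(grid, config$mch_center, mch_width, mch_peak)
  h <- config$hypochromic
  s <- config$red_shift
  eps_mc_b <- h * gaussian_band(grid, config$mc_center + s, mc_width,
                                config$mc_peak)
  eps_mch_b <- h * gaussian_band(grid, config$mch_center + s, mch_width,
                                 mch_peak)

  eps <- cbind(sp = eps_sp, mc_free = eps_mc, mch_free = eps_mch,
               mc_bound = eps_mc_b, mch_bound = eps_mch_b)
  basis <- structure(
    list(grid = grid, eps = eps,
         bands = list(
           sp = c(center = config$sp_center, width = config$sp_width,
                  peak = config$sp_peak),
           mc = c(center = config$mc_center, width = mc_width,
                  peak = config$mc_peak),
           mch = c(center = config$mch_center, width = mch_width,
                   peak = mch_peak)),
         hypochromic = h, red_shift = s,
         isosbestic = config$isosbestic),
    class = "extinction_basis"
  )
  validate_extinction_basis(basis, config)
  basis
}

validate_extinction_basis <- function(basis, config) {
  grid <- basis$grid
  eps <- basis$eps
  if (any(eps < 0)) stop_invalid("constraint failure: negative extinction")
  i432 <- nearest_index(grid, 432)
  i512 <- nearest_index(grid, 512)
  ratio <- eps[i432, "mc_free"] / eps[i512, "mc_free"]
  if (abs(ratio - config$ratio_432_512) > 0.005) {
    stop_invalid("constraint failure: MC 432/512 ratio %.4f != %.3f",
                 ratio, config$ratio_432_512)
  }
  degenerate <- !is.null(config$mch_width) && !is.null(config$mch_peak) &&
    isTRUE(all.equal(eps[, "mc_free"], eps[, "mch_free"]))
  if (!degenerate) {
    for (l in config$isosbestic) {
      i <- nearest_index(grid, l)
      rel <- abs(eps[i, "mc_free"] - eps[i, "mch_free"]) / eps[i, "mc_free"]
      if (rel > 0.005) {
        stop_invalid("constraint failure: isosbestic at %g nm off by %.3g%%",
                     l, 100 * rel)
      }
    }
  }
  vis <- grid >= 420
  if (any(eps[vis, "sp"] > 0.01 * eps[i512, "mc_free"])) {
    stop_invalid("constraint failure: SP absorbs above 420 nm")
  }
  invisible(basis)
}

#' @export
print.extinction_basis <- function(x, ...) {
  cat(sprintf("Extinction basis on %g-%g nm (%d points)\n",
              min(x$grid), max(x$grid), length(x$grid)))
  cat(sprintf("  MC band:   %.0f nm, width %.1f, peak %.4g\n",
              x$bands$mc["center"], x$bands$mc["width"], x$bands$mc["peak"]))
  cat(sprintf("  MCH+ band: %.0f nm, width %.1f, peak %.4g\n",
              x$bands$mch["center"], x$bands$mch["width"],
              x$bands$mch["peak"]))
  cat(sprintf("  isosbestic points: %s nm\n",
              paste(x$isosbestic, collapse = ", ")))
  invisible(x)
}

#' Construct an absorbance spectrum object
#'
#' @param wavelength_nm Ascending wavelength grid (nm).
#' @param absorbance Absorbance (AU) at each grid point.
#' @param pathlength Optical path length (cm).
#' @param label Free-text label.
#' @return A `dye_spectrum` object.
#' @export
dye_spectrum <- function(wavelength_nm, absorbance, pathlength = 0.1,
                         label = "") {
  assert_finite_numeric(wavelength_nm, "wavelength_nm")
  assert_finite_numeric(absorbance, "absorbance")
  if (length(wavelength_nm) != length(absorbance)) {
    stop_invalid("wavelength and absorbance lengths differ")
  }
  if (is.unsorted(wavelength_nm, strictly = TRUE)) {
    stop_invalid("wavelength grid must be strictly ascending")
  }
  assert_finite_scalar(pathlength, "pathlength")
  if (pathlength <= 0) stop_invalid("`pathlength` must be > 0")
  structure(list(wavelength_nm = wavelength_nm, absorbance = absorbance,
                 pathlength = pathlength, label = as.character(label)),
            class = "dye_spectrum")
}

#' @export
print.dye_spectrum <- function(x, ...) {
  cat(sprintf("Spectrum%s: %d points, %g-%g nm, path %g cm\n",
              if (nzchar(x$label)) paste0(" '", x$label, "'") else "",
              length(x$wavelength_nm), min(x$wavelength_nm),
              max(x$wavelength_nm), x$pathlength))
  invisible(x)
}

check_same_grid <- function(a, b) {
  if (length(a$wavelength_nm) != length(b$wavelength_nm) ||
      any(a$wavelength_nm != b$wavelength_nm)) {
    stop_invalid("spectra are on different wavelength grids")
  }
  invisible(TRUE)
}

#' Simulate a UV-Vis absorbance spectrum from a dye state
#'
#' Beer-Lambert forward model: absorbance at each grid wavelength is the
#' pathlength times the extinction-weighted sum over species, plus optional
#' additive Gaussian instrument noise.
#'
#' @param state A [dye_state()].
#' @param basis An [build_extinction_basis()] result.
#' @param pathlength Path length (cm); default 0.1 (1 mm cuvette).
#' @param noise_sd Standard deviation of additive Gaussian noise (AU); 0
#'   gives a deterministic spectrum.
#' @param seed Optional integer seed for the noise.
#' @param label Spectrum label.
#' @return A `dye_spectrum` on the basis grid.
#' @export
simulate_spectrum <- function(state, basis, pathlength = 0.1, noise_sd = 0,
                              seed = NULL, label = "") {
  stopifnot(inherits(state, "dye_state"), inherits(basis, "extinction_basis"))
  assert_finite_scalar(pathlength, "pathlength")
  assert_finite_scalar(noise_sd, "noise_sd")
  if (pathlength <= 0) stop_invalid("`pathlength` must be > 0")
  if (noise_sd < 0) stop_invalid("`noise_sd` must be >= 0")
  conc <- unlist(state[SPECIES])
  a <- as.numeric(basis$eps %*% conc) * pathlength
  if (noise_sd > 0) {
    a <- a + with_seed(seed, stats::rnorm(length(a), 0, noise_sd))
  }
  dye_spectrum(basis$grid, a, pathlength = pathlength, label = label)
}

# Absorbance at the grid point nearest a nominal wavelength.
absorbance_at <- function(spectrum, wavelength) {
  stopifnot(inherits(spectrum, "dye_spectrum"))
  spectrum$absorbance[nearest_index(spectrum$wavelength_nm, wavelength)]
}

#' Percent absorbance change at 512 nm relative to a reference spectrum
#'
#' The assay readout: `100 * (A_ref(512) - A_sample(512)) / A_ref(512)`,
#' positive when the sample has lost 512 nm absorbance (MC consumed by
#' protonation/intercalation).
#'
#' @param reference,sample `dye_spectrum` objects on the same grid.
#' @return Percent change (scalar).
#' @export
percent_change_512 <- function(reference, sample) {
  check_same_grid(reference, sample)
  a_ref <- absorbance_at(reference, 512)
  if (a_ref <= 0) {
    stop_invalid("degenerate reference: A(512) must be > 0")
  }
  100 * (a_ref - absorbance_at(sample, 512)) / a_ref
}

#' 432/512 nm absorbance peak ratio
#'
#' Ratio of the MCH+ band (432 nm) to the MC band (512 nm) absorbance. For a
#' pure-MC spectrum this equals the MC extinction ratio (~0.28); it grows as
#' dsRNA converts MC to MCH+.
#'
#' @param spectrum A `dye_spectrum`.
#' @return The ratio `A(432) / A(512)`.
#' @export
ratio_432_512 <- function(spectrum) {
  a512 <- absorbance_at(spectrum, 512)
  if (a512 <= 0) stop_invalid("degenerate spectrum: A(512) must be > 0")
  absorbance_at(spectrum, 432) / a512
}

#' Subtract a blank (background) spectrum
#'
#' Pointwise difference used to remove the RNA contribution from a dye+RNA
#' spectrum before analyzing the dye bands.
#'
#' @param sample,blank `dye_spectrum` objects on the same grid and
#'   pathlength.
#' @return A `dye_spectrum` of the difference.
#' @export
subtract_background <- function(sample, blank) {
  check_same_grid(sample, blank)
  if (sample$pathlength != blank$pathlength) {
    stop_invalid("spectra have different pathlengths")
  }
  dye_spectrum(sample$wavelength_nm, sample$absorbance - blank$absorbance,
               pathlength = sample$pathlength,
               label = if (nzchar(sample$label)) {
                 paste0(sample$label, " - blank")
               } else "")
}
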