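# Coupled protonation-binding equilibrium of the merocyanine photochrome
# with dsRNA base-pair sites.
#
# Species bookkeeping: the closed spiropyran (SP) is photochemically locked
# and inert toward RNA; the open merocyanine exists as the neutral form (MC,
# 512 nm band) and the protonated form (MCH+, 432 nm band). Both open forms
# can intercalate into a base-pair site, MCH+ with microscopic constant
# k_micro and MC with the thermodynamically linked constant
#   K_MC = k_micro * 10^(pka_free - pka_bound),
# which closes the binding/protonation cycle so that the protonated fraction
# of the bound pool is set by pka_bound alone.

#' Quantum yields of the photochromic interconversion
#'
#' Reported quantum yields for the ring-opening (SP to MC) and ring-closing
#' (MC to SP) photoreactions of this spiropyran. They are recorded as
#' documented constants only: the photostationary composition is always an
#' input (`sp_fraction`), never derived from these yields, because the
#' extinction coefficient at the irradiation wavelength is not available.
#'
#' @format Named numeric vector with elements `ring_opening` and
#'   `ring_closing`.
#' @export
quantum_yields <- c(ring_opening = 0.015, ring_closing = 0.014)

#' Thermodynamic parameter set for the dye-RNA system
#'
#' Bundles the thermodynamic and compositional parameters that determine the
#' equilibrium speciation of the dye in the presence of dsRNA.
#'
#' @param k_micro Microscopic association constant of MCH+ for a base-pair
#'   site (M^-1). Default 1.13e4, the characterized value for this dye.
#' @param pka_free pKa of free MCH+ in solution. Default 3.8.
#' @param pka_bound pKa of the intercalated complex. Default 7.7. A bound pKa
#'   above the free pKa is expected for this system (binding stabilizes the
#'   protonated form) but is not enforced; any finite pair is solved.
#' @param ph Solution pH. Default 7.
#' @param sp_fraction Mole fraction of dye locked in the closed SP form
#'   (0-1). 0.63 after UV irradiation (photostationary state), 0.74 at
#'   thermal equilibrium in the dark.
#' @param total_dye Total dye concentration (mol/L). Default 12.5e-6.
#' @return An object of class `model_params`.
#' @examples
#' p <- model_params()
#' solve_equilibrium(p, rna_bp = 350e-6)
#' @export
model_params <- function(k_micro = 1.13e4,
                         pka_free = 3.8,
                         pka_bound = 7.7,
                         ph = 7,
                         sp_fraction = 0.63,
                         total_dye = 12.5e-6) {
  assert_finite_scalar(k_micro, "k_micro")
  assert_finite_scalar(pka_free, "pka_free")
  assert_finite_scalar(pka_bound, "pka_bound")
  assert_finite_scalar(ph, "ph")
  assert_finite_scalar(sp_fraction, "sp_fraction")
  assert_finite_scalar(total_dye, "total_dye")
  if (k_micro <= 0) stop_invalid("`k_micro` must be > 0")
  if (sp_fraction < 0 || sp_fraction > 1) {
    stop_invalid("`sp_fraction` must lie in [0, 1]")
  }
  if (total_dye <= 0) stop_invalid("`total_dye` must be > 0")
  structure(
    list(k_micro = k_micro, pka_free = pka_free, pka_bound = pka_bound,
         ph = ph, sp_fraction = sp_fraction, total_dye = total_dye),
    class = "model_params"
  )
}

#' @export
print.model_params <- function(x, ...) {
  cat("Dye-RNA equilibrium parameters\n")
  cat(sprintf("  k_micro (MCH+ ~ bp site): %.4g M^-1\n", x$k_micro))
  cat(sprintf("  pKa free / bound:         %.3g / %.3g\n",
              x$pka_free, x$pka_bound))
  cat(sprintf("  pH:                       %.3g\n", x$ph))
  cat(sprintf("  SP fraction:              %.3g\n", x$sp_fraction))
  cat(sprintf("  total dye:                %.4g mol/L\n", x$total_dye))
  invisible(x)
}

#' Fraction of an acid-base pair in the protonated state
#'
#' Standard Henderson-Hasselbalch speciation: the mole fraction of the
#' protonated form at a given pH and pKa,
#' `10^(pka - ph) / (1 + 10^(pka - ph))`.
#'
#' @param ph Solution pH (finite scalar or vector).
#' @param pka Acid dissociation exponent (finite scalar or vector).
#' @return Protonated mole fraction in `[0, 1]`, strictly decreasing in `ph`
#'   and strictly increasing in `pka`.
#' @examples
#' protonated_fraction(ph = 7, pka = 7.7) # ~0.83: mostly MCH+ when bound
#' protonated_fraction(ph = 7, pka = 3.8) # ~6e-4: free dye stays neutral
#' @export
protonated_fraction <- function(ph, pka) {
  assert_finite_numeric(ph, "ph")
  assert_finite_numeric(pka, "pka")
  r <- 10^(pka - ph)
  r / (1 + r)
}

#' Apparent pKa from a protonated:neutral concentration ratio
#'
#' Inverse of [protonated_fraction()]: given the measured molar ratio of the
#' protonated to the neutral species at a known pH, returns the apparent pKa,
#' `ph + log10(ratio)`.
#'
#' @param protonated_to_neutral Positive concentration ratio MCH+:MC.
#' @param ph Solution pH.
#' @return Apparent pKa.
#' @examples
#' pka_from_ratio(9, ph = 7) # a 90:10 bound ratio implies pKa ~7.95
#' @export
pka_from_ratio <- function(protonated_to_neutral, ph) {
  assert_finite_numeric(protonated_to_neutral, "protonated_to_neutral")
  assert_finite_numeric(ph, "ph")
  if (any(protonated_to_neutral <= 0)) {
    stop_invalid("`protonated_to_neutral` must be > 0")
  }
  ph + log10(protonated_to_neutral)
}

#' Equilibrium speciation of the dye in the presence of dsRNA
#'
#' Solves the coupled protonation-binding equilibrium for the five dye
#' species (SP, free MC, free MCH+, bound MC, bound MCH+) at a given
#' per-base-pair RNA site concentration. Each base pair is treated as an
#' independent binding site. Two solvers are available:
#'
#' * `"excess_sites"` (default): free sites are approximated by the total
#'   site concentration. Appropriate for this assay, where dye (~12 uM) is
#'   far below the RNA concentrations used (up to ~600 uM per base) and
#'   binding is weak; the speciation then has a closed form.
#' * `"depletion"`: free sites are solved self-consistently from site
#'   conservation by bisection (relative tolerance 1e-10, at most 200
#'   iterations). Exact for any dye:site ratio; used as the reference the
#'   approximation is checked against.
#'
#' @param params A [model_params()] object.
#' @param rna_bp Per-base-pair RNA concentration (mol/L), `>= 0`.
#' @param method `"excess_sites"` or `"depletion"`.
#' @return A `dye_state` object: list with fields `sp`, `mc_free`,
#'   `mch_free`, `mc_bound`, `mch_bound` (all mol/L) summing to
#'   `params$total_dye`.
#' @examples
#' p <- model_params(sp_fraction = 0, total_dye = 12e-6)
#' st <- solve_equilibrium(p, rna_bp = 1e-4)
#' st$mch_bound / (st$mc_bound + st$mch_bound) # protonated fraction when bound
#' @export
solve_equilibrium <- function(params, rna_bp,
                              method = c("excess_sites", "depletion")) {
  stopifnot(inherits(params, "model_params"))
  assert_finite_scalar(rna_bp, "rna_bp")
  if (rna_bp < 0) stop_invalid("`rna_bp` must be >= 0")
  method <- match.arg(method)

  sp <- params$sp_fraction * params$total_dye
  d_open <- params$total_dye - sp           # open (MC + MCH+) pool
  r_free <- 10^(params$pka_free - params$ph)   # MCH+/MC ratio, free
  k_mch <- params$k_micro
  k_mc <- params$k_micro * 10^(params$pka_free - params$pka_bound)
  # Per-free-MC binding weight: each unit of free MC carries r_free of free
  # MCH+, k_mc*S of bound MC and k_mch*r_free*S of bound MCH+.
  k_eff <- k_mc + k_mch * r_free

  free_sites <- if (method == "excess_sites" || rna_bp == 0) {
    rna_bp
  } else {
    # Site conservation: S + bound(S) = rna_bp, with bound(S) monotone
    # increasing, so f(S) = S + bound(S) - rna_bp has a single root in
    # [0, rna_bp].
    bound_at <- function(s) d_open * k_eff * s / (1 + r_free + k_eff * s)
    lo <- 0
    hi <- rna_bp
    for (i in seq_len(200L)) {
      mid <- (lo + hi) / 2
      if (mid + bound_at(mid) > rna_bp) hi <- mid else lo <- mid
      if ((hi - lo) <= 1e-10 * rna_bp) break
    }
    (lo + hi) / 2
  }

  mc_free <- d_open / (1 + r_free + k_eff * free_sites)
  mch_free <- r_free * mc_free
  mc_bound <- k_mc * mc_free * free_sites
  mch_bound <- k_mch * r_free * mc_free * free_sites
  if (rna_bp == 0) {
    mc_bound <- 0
    mch_bound <- 0
  }
  dye_state(sp = sp, mc_free = mc_free, mch_free = mch_free,
            mc_bound = mc_bound, mch_bound = mch_bound)
}

#' Construct a dye speciation state
#'
#' @param sp,mc_free,mch_free,mc_bound,mch_bound Species concentrations
#'   (mol/L), all `>= 0`.
#' @return A `dye_state` object.
#' @export
dye_state <- function(sp = 0, mc_free = 0, mch_free = 0,
                      mc_bound = 0, mch_bound = 0) {
  vals <- c(sp = unname(sp), mc_free = unname(mc_free),
            mch_free = unname(mch_free), mc_bound = unname(mc_bound),
            mch_bound = unname(mch_bound))
  if (any(!is.finite(vals)) || any(vals < 0)) {
    stop_invalid("dye_state concentrations must be finite and >= 0")
  }
  structure(as.list(vals), class = "dye_state")
}

#' @export
print.dye_state <- function(x, ...) {
  cat("Dye speciation (mol/L)\n")
  for (nm in names(x)) cat(sprintf("  %-9s %.6g\n", nm, x[[nm]]))
  cat(sprintf("  total     %.6g\n", total_dye_of(x)))
  invisible(x)
}

#' Total dye concentration of a state
#' @param state A `dye_state`.
#' @return Sum of the five species concentrations (mol/L).
#' @export
total_dye_of <- function(state) {
  stopifnot(inherits(state, "dye_state"))
  state$sp + state$mc_free + state$mch_free + state$mc_bound + state$mch_bound
}

#' Microscopic binding constant from the macroscopic (observed) constant
#'
#' The macroscopic constant fitted from a titration describes association of
#' the total open-dye pool; the microscopic constant describes the actual
#' interacting species, MCH+. Because only a fraction of the bound pool is
#' protonated, the microscopic constant is the macroscopic one divided by
#' that fraction, and is therefore always at least as large.
#'
#' @param k_macro Observed (fitted) association constant (M^-1), `> 0`.
#' @param bound_protonated_fraction Fraction of bound dye present as MCH+,
#'   in `(0, 1]`.
#' @return Microscopic association constant (M^-1).
#' @examples
#' micro_from_macro(8.62e3, 0.763) # ~1.13e4
#' @export
micro_from_macro <- function(k_macro, bound_protonated_fraction) {
  assert_finite_numeric(k_macro, "k_macro")
  assert_finite_numeric(bound_protonated_fraction, "bound_protonated_fraction")
  if (any(k_macro <= 0)) stop_invalid("`k_macro` must be > 0")
  if (any(bound_protonated_fraction <= 0) ||
      any(bound_protonated_fraction > 1)) {
    stop_invalid("`bound_protonated_fraction` must lie in (0, 1]")
  }
  k_macro / bound_protonated_fraction
}

#' Read or write model parameters as a flat key-value config
#'
#' `write_model_params()` serializes a [model_params()] object to a plain
#' `key: value` text file; `read_model_params()` parses one back. Unknown
#' keys are rejected.
#'
#' @param params A `model_params` object.
#' @param path File path.
#' @return `read_model_params()` returns a `model_params` object;
#'   `write_model_params()` returns `path` invisibly.
#' @export
write_model_params <- function(params, path) {
  stopifnot(inherits(params, "model_params"))
  lines <- sprintf("%s: %.17g", names(params), unlist(params))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_model_params
#' @export
read_model_params <- function(path) {
  kv <- read_key_value(path)
  allowed <- c("k_micro", "pka_free", "pka_bound", "ph", "sp_fraction",
               "total_dye")
  unknown <- setdiff(names(kv), allowed)
  if (length(unknown)) {
    stop_invalid("unknown config key(s): %s", paste(unknown, collapse = ", "))
  }
  do.call(model_params, lapply(kv, as.numeric))
}

# Parse a flat "key: value" text file into a named character list.
read_key_value <- function(path) {
  if (!file.exists(path)) stop_invalid("config file not found: %s", path)
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  hit <- regexpr(":", lines, fixed = TRUE)
  if (any(hit < 0)) stop_invalid("malformed config line: %s",
                                 lines[which(hit < 0)[1L]])
  keys <- trimws(substr(lines, 1L, hit - 1L))
  vals <- trimws(substring(lines, hit + 1L))
  if (anyDuplicated(keys)) stop_invalid("duplicate config key")
  stats::setNames(as.list(vals), keys)
}
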