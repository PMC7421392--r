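# Hyperbolic (one-site) saturation analysis of UV-Vis titrations: percent
# absorbance change at 512 nm versus per-base dsRNA concentration. The
# association-constant parameterization matches how binding constants for
# this dye are reported (K in M^-1, concentrations per base).

#' One-site saturation binding isotherm
#'
#' Percent absorbance change as a rectangular hyperbola of ligand (per-base
#' dsRNA) concentration: `b_max * k * c / (1 + k * c)`. Zero at `c = 0`,
#' half-saturated at `c = 1/k`, approaching `b_max` at saturation.
#'
#' @param c Per-base RNA concentration (mol/L), `>= 0`; vectorized.
#' @param b_max Saturation amplitude (percent change).
#' @param k Association constant (M^-1).
#' @return Percent absorbance change.
#' @examples
#' binding_curve(450e-6, b_max = 90.6, k = 11111) # ~75.5
#' @export
binding_curve <- function(c, b_max, k) {
  assert_finite_numeric(c, "c")
  assert_finite_scalar(b_max, "b_max")
  assert_finite_scalar(k, "k")
  if (any(c < 0)) stop_invalid("`c` must be >= 0")
  b_max * k * c / (1 + k * c)
}

#' Construct a titration series
#'
#' @param concentrations Per-base RNA concentrations (mol/L), `>= 0`; at
#'   least 4 values including 0 are needed for fitting.
#' @param delta_a_percent Percent absorbance change at 512 nm, same length.
#' @param replicate Replicate identifier(s) (recycled).
#' @param condition Condition label, e.g. buffer and RNA type.
#' @return A data frame of class `titration_series` with columns
#'   `conc_molar`, `delta_a_percent`, `replicate`, `condition`.
#' @export
titration_series <- function(concentrations, delta_a_percent,
                             replicate = 1L, condition = "") {
  assert_finite_numeric(concentrations, "concentrations")
  assert_finite_numeric(delta_a_percent, "delta_a_percent")
  if (length(concentrations) != length(delta_a_percent)) {
    stop_invalid("concentration and response lengths differ")
  }
  if (any(concentrations < 0)) stop_invalid("concentrations must be >= 0")
  out <- data.frame(conc_molar = concentrations,
                    delta_a_percent = delta_a_percent,
                    replicate = rep_len(replicate, length(concentrations)),
                    condition = rep_len(as.character(condition),
                                        length(concentrations)))
  class(out) <- c("titration_series", "data.frame")
  out
}

#' Fit the one-site binding isotherm to a titration series
#'
#' Least-squares fit of [binding_curve()] to `(conc, %dA512)` points.
#' Replicates are pooled into a single residual vector. Both parameters are
#' kept positive by fitting on the log scale with Levenberg-Marquardt;
#' standard errors on the natural scale follow from the local quadratic
#' approximation (delta method). Starting values are data-driven:
#' `b_max0 = 1.1 * max(response)` and `k0 = 1/c_half`, where `c_half` is the
#' measured concentration whose response is nearest `b_max0 / 2`.
#'
#' @param series A [titration_series()] (or data frame with columns
#'   `conc_molar` and `delta_a_percent`).
#' @return A `binding_fit`: list with `b_max`, `k`, `se_b_max`, `se_k`,
#'   `rss`, `df`, `converged`, and `message` on failure.
#' @examples
#' s <- titration_series(seq(0, 450e-6, length.out = 12),
#'                       binding_curve(seq(0, 450e-6, length.out = 12),
#'                                     90.6, 11111))
#' fit_binding(s)
#' @export
fit_binding <- function(series) {
  if (!is.data.frame(series) ||
      !all(c("conc_molar", "delta_a_percent") %in% names(series))) {
    stop_invalid("`series` must have columns conc_molar and delta_a_percent")
  }
  conc <- series$conc_molar
  y <- series$delta_a_percent
  assert_finite_numeric(conc, "conc_molar")
  assert_finite_numeric(y, "delta_a_percent")
  if (length(conc) < 4L) stop_invalid("need at least 4 titration points")
  if (length(unique(conc[conc > 0])) < 3L) {
    stop_invalid("need at least 3 distinct nonzero concentrations")
  }
  if (max(y) <= 0 || stats::sd(y) == 0) {
    return(failed_binding_fit("degenerate response: no positive signal"))
  }

  b0 <- 1.1 * max(y)
  pos <- conc > 0
  c_half <- conc[pos][which.min(abs(y[pos] - b0 / 2))]
  k0 <- 1 / c_half

  fit <- tryCatch(
    minpack.lm::nlsLM(
      y ~ exp(lb) * exp(lk) * conc / (1 + exp(lk) * conc),
      data = data.frame(conc = conc, y = y),
      start = list(lb = log(b0), lk = log(k0)),
      control = minpack.lm::nls.lm.control(
        ftol = 1e-15, ptol = 1e-15, maxiter = 500)),
    error = function(e) e)
  if (inherits(fit, "error")) {
    return(failed_binding_fit(conditionMessage(fit)))
  }

  est <- stats::coef(fit)
  se_log <- tryCatch(summary(fit)$coefficients[, "Std. Error"],
                     error = function(e) c(lb = NA_real_, lk = NA_real_))
  b_max <- exp(est[["lb"]])
  k <- exp(est[["lk"]])
  structure(
    list(b_max = b_max, k = k,
         se_b_max = b_max * unname(se_log[1L]),
         se_k = k * unname(se_log[2L]),
         rss = sum(stats::resid(fit)^2),
         df = length(y) - 2L,
         converged = TRUE, message = ""),
    class = "binding_fit")
}

failed_binding_fit <- function(msg) {
  structure(
    list(b_max = NA_real_, k = NA_real_, se_b_max = NA_real_,
         se_k = NA_real_, rss = NA_real_, df = NA_integer_,
         converged = FALSE, message = msg),
    class = "binding_fit")
}

#' Construct a binding fit from known parameters
#'
#' Wraps literature or generator truth values as a `binding_fit` so they can
#' be used directly as a quantitation calibration.
#'
#' @param b_max Saturation amplitude (percent).
#' @param k Association constant (M^-1).
#' @return A converged `binding_fit` with `NA` standard errors.
#' @export
binding_fit <- function(b_max, k) {
  assert_finite_scalar(b_max, "b_max")
  assert_finite_scalar(k, "k")
  if (b_max <= 0 || k <= 0) stop_invalid("`b_max` and `k` must be > 0")
  structure(list(b_max = b_max, k = k, se_b_max = NA_real_, se_k = NA_real_,
                 rss = NA_real_, df = NA_integer_, converged = TRUE,
                 message = ""),
            class = "binding_fit")
}

#' @export
print.binding_fit <- function(x, ...) {
  if (!x$converged) {
    cat("Binding fit: NOT converged -", x$message, "\n")
    return(invisible(x))
  }
  cat("One-site binding fit\n")
  cat(sprintf("  B_max: %.4g %% (se %.3g)\n", x$b_max, x$se_b_max))
  cat(sprintf("  K:     %.4g M^-1 (se %.3g)\n", x$k, x$se_k))
  if (is.finite(x$rss)) cat(sprintf("  RSS:   %.4g on %d df\n", x$rss, x$df))
  invisible(x)
}

#' Invert the binding isotherm to a concentration
#'
#' Closed-form inverse of [binding_curve()]:
#' `c = delta_a / (k * (b_max - delta_a))`. Converts a measured percent
#' absorbance change into the effective per-base dsRNA concentration under a
#' given calibration.
#'
#' @param delta_a Percent change, `0 <= delta_a < b_max`; vectorized.
#' @param fit A converged `binding_fit` calibration.
#' @return Per-base concentration (mol/L).
#' @examples
#' invert_binding(75.5, binding_fit(90.6, 11111)) # ~4.5e-4
#' @export
invert_binding <- function(delta_a, fit) {
  stopifnot(inherits(fit, "binding_fit"))
  if (!isTRUE(fit$converged)) stop_invalid("calibration fit not converged")
  assert_finite_numeric(delta_a, "delta_a")
  if (any(delta_a < 0)) stop_invalid("`delta_a` must be >= 0")
  if (any(delta_a >= fit$b_max)) {
    stop_invalid("`delta_a` at or above saturation amplitude (%.4g)",
                 fit$b_max)
  }
  delta_a / (fit$k * (fit$b_max - delta_a))
}
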