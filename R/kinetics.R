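# Thermal SP <-> MC relaxation in the dark: a single first-order process.
# The dye relaxes from its initial (e.g. photostationary) composition toward
# the thermal equilibrium mixture; absorbance at a fixed wavelength follows
# a mono-exponential approach to its equilibrium value.

#' First-order relaxation model
#'
#' `A(t) = a_eq + (a0 - a_eq) * exp(-t / tau)`: absorbance relaxing from
#' `a0` at time zero toward the equilibrium value `a_eq` with time constant
#' `tau`.
#'
#' @param t Time (hours), `>= 0`; vectorized.
#' @param a0 Initial absorbance (AU).
#' @param a_eq Equilibrium absorbance (AU).
#' @param tau Relaxation time constant (hours), `> 0`.
#' @return Absorbance (AU).
#' @examples
#' relaxation_model(2, a0 = 0.080, a_eq = 0.056, tau = 2)
#' @export
relaxation_model <- function(t, a0, a_eq, tau) {
  assert_finite_numeric(t, "t")
  assert_finite_scalar(a0, "a0")
  assert_finite_scalar(a_eq, "a_eq")
  assert_finite_scalar(tau, "tau")
  if (any(t < 0)) stop_invalid("`t` must be >= 0")
  if (tau <= 0) stop_invalid("`tau` must be > 0")
  a_eq + (a0 - a_eq) * exp(-t / tau)
}

#' Construct a kinetic trace
#'
#' @param times Observation times (hours), strictly increasing, `>= 0`.
#' @param absorbance Absorbance (AU) at each time.
#' @param wavelength Monitoring wavelength (nm); default 512.
#' @param replicate Replicate identifier.
#' @return A data frame of class `kinetic_trace` with columns `time_h`,
#'   `absorbance`, `wavelength_nm`, `replicate`.
#' @export
kinetic_trace <- function(times, absorbance, wavelength = 512,
                          replicate = 1L) {
  assert_finite_numeric(times, "times")
  assert_finite_numeric(absorbance, "absorbance")
  if (length(times) != length(absorbance)) {
    stop_invalid("time and absorbance lengths differ")
  }
  if (any(times < 0)) stop_invalid("times must be >= 0")
  if (is.unsorted(times, strictly = TRUE)) {
    stop_invalid("times must be strictly increasing")
  }
  out <- data.frame(time_h = times, absorbance = absorbance,
                    wavelength_nm = rep_len(wavelength, length(times)),
                    replicate = rep_len(replicate, length(times)))
  class(out) <- c("kinetic_trace", "data.frame")
  out
}

#' Fit the first-order relaxation model to a kinetic trace
#'
#' Least-squares estimates of `(a0, a_eq, tau)`; `tau` is fitted on the log
#' scale so it stays positive. The equilibrium SP mole fraction is derived
#' from the fitted `a_eq`: at the monitoring wavelength only MC absorbs, so
#' `sp_fraction_eq = 1 - a_eq / (eps * pathlength * total_dye)`.
#'
#' @param trace A [kinetic_trace()] (or data frame with `time_h` and
#'   `absorbance`).
#' @param eps Extinction coefficient of MC at the monitoring wavelength
#'   (M^-1 cm^-1). Default is the basis default at 512 nm.
#' @param pathlength Path length (cm); default 0.1.
#' @param total_dye Total dye concentration (mol/L); default 12.5e-6.
#' @return A `relaxation_fit`: list with `a0`, `a_eq`, `tau`, standard
#'   errors, `sp_fraction_eq`, `rss`, `converged` and `message`.
#' @examples
#' t <- seq(0, 12, by = 1 / 12)
#' tr <- kinetic_trace(t, relaxation_model(t, 0.080, 0.0562, 2))
#' fit_relaxation(tr)$tau # 2
#' @export
fit_relaxation <- function(trace,
                           eps = 0.080 / (12.5e-6 * 0.37 * 0.1),
                           pathlength = 0.1,
                           total_dye = 12.5e-6) {
  if (!is.data.frame(trace) ||
      !all(c("time_h", "absorbance") %in% names(trace))) {
    stop_invalid("`trace` must have columns time_h and absorbance")
  }
  t <- trace$time_h
  y <- trace$absorbance
  assert_finite_numeric(t, "time_h")
  assert_finite_numeric(y, "absorbance")
  if (length(t) < 6L) stop_invalid("need at least 6 points")

  if (stats::sd(y) < 1e-12 + 1e-9 * abs(mean(y))) {
    return(failed_relaxation_fit(
      "constant trace: time constant unidentifiable"))
  }

  a0_0 <- y[1L]
  aeq_0 <- mean(y[t >= max(t) * 0.8])
  amp0 <- a0_0 - aeq_0
  if (abs(amp0) < 1e-12) amp0 <- diff(range(y))
  crossed <- which(abs(y - aeq_0) <= abs(amp0) / exp(1))
  tau0 <- if (length(crossed)) max(t[crossed[1L]], max(t) / 100) else max(t) / 3

  fit <- tryCatch(
    minpack.lm::nlsLM(
      y ~ a_eq + (a0 - a_eq) * exp(-t / exp(ltau)),
      data = data.frame(t = t, y = y),
      start = list(a0 = a0_0, a_eq = aeq_0, ltau = log(tau0)),
      control = minpack.lm::nls.lm.control(
        ftol = 1e-15, ptol = 1e-15, maxiter = 500)),
    error = function(e) e)
  if (inherits(fit, "error")) {
    return(failed_relaxation_fit(conditionMessage(fit)))
  }

  est <- stats::coef(fit)
  se <- tryCatch(summary(fit)$coefficients[, "Std. Error"],
                 error = function(e) rep(NA_real_, 3L))
  tau <- exp(est[["ltau"]])
  a_eq <- est[["a_eq"]]
  mc_frac_eq <- a_eq / (eps * pathlength * total_dye)
  out <- structure(
    list(a0 = est[["a0"]], a_eq = a_eq, tau = tau,
         se_a0 = unname(se[1L]), se_a_eq = unname(se[2L]),
         se_tau = tau * unname(se[3L]),
         sp_fraction_eq = 1 - mc_frac_eq,
         rss = sum(stats::resid(fit)^2),
         converged = TRUE, message = ""),
    class = "relaxation_fit")
  if (max(t) < tau) {
    out$message <- "trace spans less than one fitted time constant"
  }
  out
}

failed_relaxation_fit <- function(msg) {
  structure(
    list(a0 = NA_real_, a_eq = NA_real_, tau = NA_real_, se_a0 = NA_real_,
         se_a_eq = NA_real_, se_tau = NA_real_, sp_fraction_eq = NA_real_,
         rss = NA_real_, converged = FALSE, message = msg),
    class = "relaxation_fit")
}

#' @export
print.relaxation_fit <- function(x, ...) {
  if (!x$converged) {
    cat("Relaxation fit: NOT converged -", x$message, "\n")
    return(invisible(x))
  }
  cat("First-order relaxation fit\n")
  cat(sprintf("  a0:   %.4g AU (se %.3g)\n", x$a0, x$se_a0))
  cat(sprintf("  a_eq: %.4g AU (se %.3g)\n", x$a_eq, x$se_a_eq))
  cat(sprintf("  tau:  %.4g h (se %.3g)\n", x$tau, x$se_tau))
  cat(sprintf("  equilibrium SP fraction: %.3f\n", x$sp_fraction_eq))
  if (nzchar(x$message)) cat("  note:", x$message, "\n")
  invisible(x)
}

#' Shift in the equilibrium 432/512 ratio between two relaxed samples
#'
#' Contrasts the 432/512 absorbance ratios implied by the fitted equilibrium
#' absorbances of a control and a treated (e.g. dsRNA-containing) sample.
#' The 432 nm absorbance is taken as common to both samples (the loss of MC
#' at 432 is balanced by the gain of MCH+ there), so a positive value means
#' the treated sample settled with less MC, i.e. dsRNA shifted the
#' equilibrium toward MCH+.
#'
#' @param control,treated Converged `relaxation_fit` objects from 512 nm
#'   traces.
#' @param a432 Shared equilibrium absorbance at 432 nm (AU); default
#'   `0.28 * control$a_eq`, the pure-MC ratio applied to the control.
#' @return `a432/a_eq(treated) - a432/a_eq(control)`.
#' @export
equilibrium_shift_metric <- function(control, treated,
                                     a432 = 0.28 * control$a_eq) {
  stopifnot(inherits(control, "relaxation_fit"),
            inherits(treated, "relaxation_fit"))
  if (!isTRUE(control$converged) || !isTRUE(treated$converged)) {
    stop_invalid("both fits must have converged")
  }
  if (control$a_eq <= 0 || treated$a_eq <= 0) {
    stop_invalid("equilibrium absorbances must be > 0")
  }
  a432 / treated$a_eq - a432 / control$a_eq
}
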