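# dsRNA quantitation workflow: convert stock absorbance to per-base molar
# concentration, summarize percent absorbance changes per sample, invert the
# binding calibration to an effective dsRNA concentration with a bootstrap
# interval, and compare treatment groups.

#' Per-base RNA concentration from 260 nm absorbance
#'
#' Beer-Lambert conversion of a stock's 260 nm absorbance to per-base molar
#' concentration: `c = a260 / (eps260 * pathlength)`. Typical per-base
#' extinction coefficients: ~18,000 M^-1 cm^-1 for poly AU, ~13,000 for poly
#' GC, and ~15,000 as a generic dsRNA value for cellular samples.
#'
#' @param a260 Absorbance at 260 nm (AU), `>= 0`.
#' @param eps260 Per-base extinction coefficient at 260 nm (M^-1 cm^-1),
#'   `> 0`.
#' @param pathlength Path length (cm), `> 0`.
#' @return Per-base concentration (mol/L).
#' @examples
#' molar_from_absorbance(1.5, eps260 = 15000) # 1e-4 mol/L
#' @export
molar_from_absorbance <- function(a260, eps260 = 15000, pathlength = 1) {
  assert_finite_numeric(a260, "a260")
  assert_finite_scalar(eps260, "eps260")
  assert_finite_scalar(pathlength, "pathlength")
  if (any(a260 < 0)) stop_invalid("`a260` must be >= 0")
  if (eps260 <= 0) stop_invalid("`eps260` must be > 0")
  if (pathlength <= 0) stop_invalid("`pathlength` must be > 0")
  a260 / (eps260 * pathlength)
}

#' Construct a sample panel
#'
#' @param sample Sample labels.
#' @param treatment Treatment labels (e.g. `control`, `rnase_t1`,
#'   `rnase_a`, `decitabine_day_5`).
#' @param replicate Replicate indices, `>= 1`.
#' @param delta_a_percent Measured or simulated percent absorbance change at
#'   512 nm.
#' @param effective_conc_molar Optional known effective dsRNA per-base
#'   concentration (mol/L), carried by generators as ground truth.
#' @return A data frame of class `sample_panel`.
#' @export
sample_panel <- function(sample, treatment, replicate, delta_a_percent,
                         effective_conc_molar = NA_real_) {
  n <- length(delta_a_percent)
  assert_finite_numeric(delta_a_percent, "delta_a_percent")
  replicate <- rep_len(replicate, n)
  if (any(replicate < 1)) stop_invalid("replicate indices must be >= 1")
  out <- data.frame(sample = rep_len(as.character(sample), n),
                    treatment = rep_len(as.character(treatment), n),
                    replicate = replicate,
                    delta_a_percent = delta_a_percent,
                    effective_conc_molar = rep_len(effective_conc_molar, n))
  if (any(!is.na(out$effective_conc_molar) & out$effective_conc_molar < 0)) {
    stop_invalid("effective concentrations must be >= 0")
  }
  class(out) <- c("sample_panel", "data.frame")
  out
}

#' Quantify dsRNA content of a sample panel against a binding calibration
#'
#' For each sample (grouped by `sample` x `treatment`), computes the mean
#' and s.e.m. of the percent absorbance change over replicates, inverts the
#' calibration isotherm to an effective per-base dsRNA concentration, and
#' attaches a bootstrap confidence interval. The interval resamples
#' replicates (nonparametric, `n_boot` draws, seeded), uses the bootstrap
#' standard error with the small-sample t multiplier on the percent-change
#' scale, and maps the endpoints through the monotone calibration inverse;
#' endpoints below zero clamp to zero, endpoints at or above saturation are
#' reported as unbounded (`Inf`). Treatment groups are compared pairwise
#' with Welch two-sample t-tests on the replicate percent changes.
#'
#' @param panel A [sample_panel()] (or data frame with columns `sample`,
#'   `treatment`, `replicate`, `delta_a_percent`).
#' @param calibration A converged [binding_fit()] (default: the 50% GC
#'   duplex calibration in nuclease-free water, `b_max = 70`,
#'   `k = 8620 M^-1`).
#' @param n_boot Number of bootstrap resamples (default 2000).
#' @param seed Integer seed for the bootstrap (required when `n_boot > 0`).
#' @param conf Confidence level (default 0.95).
#' @return A `quant_result`: list with `samples` (per-sample data frame:
#'   `n`, `mean_delta_a`, `sem`, `conc_estimate`, `conc_lower`,
#'   `conc_upper`, `saturated`, `single_replicate`), `comparisons`
#'   (pairwise Welch tests between treatments), and `settings`.
#' @export
quantify_panel <- function(panel,
                           calibration = binding_fit(70, 8620),
                           n_boot = 2000, seed = NULL, conf = 0.95) {
  if (!is.data.frame(panel) ||
      !all(c("sample", "treatment", "replicate", "delta_a_percent") %in%
           names(panel))) {
    stop_invalid(
      "`panel` needs columns sample, treatment, replicate, delta_a_percent")
  }
  stopifnot(inherits(calibration, "binding_fit"))
  if (!isTRUE(calibration$converged)) {
    stop_invalid("calibration fit not converged")
  }
  if (n_boot > 0 && is.null(seed)) {
    stop_invalid("`seed` is required for the bootstrap interval")
  }

  inv <- function(da) {
    # Monotone inverse with clamping for out-of-range bootstrap endpoints.
    if (da <= 0) return(0)
    if (da >= calibration$b_max) return(Inf)
    invert_binding(da, calibration)
  }

  key <- interaction(panel$sample, panel$treatment, drop = TRUE, sep = " / ")
  groups <- split(panel, key)
  alpha <- 1 - conf

  rows <- with_seed(seed, lapply(groups, function(g) {
    x <- g$delta_a_percent
    n <- length(x)
    m <- mean(x)
    sem <- if (n > 1) stats::sd(x) / sqrt(n) else NA_real_
    saturated <- m >= calibration$b_max
    est <- inv(m)
    lo <- hi <- NA_real_
    if (n > 1 && n_boot > 0) {
      bm <- replicate(n_boot, mean(x[sample.int(n, n, replace = TRUE)]))
      # Bootstrap SE underestimates the sampling sd by sqrt((n-1)/n) at
      # small n; rescale and use the t multiplier for honest coverage.
      se_boot <- stats::sd(bm) * sqrt(n / (n - 1))
      tq <- stats::qt(1 - alpha / 2, df = n - 1)
      lo <- inv(m - tq * se_boot)
      hi <- inv(m + tq * se_boot)
    }
    data.frame(sample = g$sample[1L], treatment = g$treatment[1L],
               n = n, mean_delta_a = m, sem = sem,
               conc_estimate = est, conc_lower = lo, conc_upper = hi,
               saturated = saturated, single_replicate = n == 1L)
  }))
  samples <- do.call(rbind, rows)
  rownames(samples) <- NULL
  if (any(samples$saturated)) {
    warning("sample mean at or above calibration saturation; ",
            "estimate unbounded", call. = FALSE)
  }
  if (any(samples$single_replicate)) {
    warning("single-replicate sample: s.e.m. and interval undefined",
            call. = FALSE)
  }

  treatments <- unique(panel$treatment)
  comparisons <- NULL
  if (length(treatments) > 1L) {
    pairs <- utils::combn(treatments, 2L)
    comparisons <- do.call(rbind, lapply(seq_len(ncol(pairs)), function(i) {
      x <- panel$delta_a_percent[panel$treatment == pairs[1L, i]]
      y <- panel$delta_a_percent[panel$treatment == pairs[2L, i]]
      if (length(x) < 2L || length(y) < 2L || (stats::sd(x) == 0 &&
                                               stats::sd(y) == 0)) {
        return(data.frame(treatment_1 = pairs[1L, i],
                          treatment_2 = pairs[2L, i],
                          statistic = NA_real_, p_value = NA_real_))
      }
      tt <- stats::t.test(x, y)
      data.frame(treatment_1 = pairs[1L, i], treatment_2 = pairs[2L, i],
                 statistic = unname(tt$statistic), p_value = tt$p.value)
    }))
    rownames(comparisons) <- NULL
  }

  structure(list(samples = samples, comparisons = comparisons,
                 settings = list(b_max = calibration$b_max,
                                 k = calibration$k, n_boot = n_boot,
                                 seed = seed, conf = conf)),
            class = "quant_result")
}

#' @export
print.quant_result <- function(x, ...) {
  cat("dsRNA quantitation\n")
  cat(sprintf("  calibration: B_max %.4g %%, K %.4g M^-1\n",
              x$settings$b_max, x$settings$k))
  print(x$samples, digits = 4)
  if (!is.null(x$comparisons)) {
    cat("Pairwise Welch t-tests (percent change):\n")
    print(x$comparisons, digits = 4)
  }
  invisible(x)
}

#' Trend analysis of an induction time course
#'
#' Summarizes an ordered series of sampling days (e.g. a demethylating-agent
#' induction experiment at days 0, 1, 3, 5): per-day mean and s.e.m. of the
#' percent absorbance change, pairwise Welch tests between days, and a
#' monotonic-trend flag that is `TRUE` when later-day means are
#' non-decreasing.
#'
#' @param panel A data frame with columns `day`, `replicate`,
#'   `delta_a_percent` (as produced by [gen_decitabine_course()]).
#' @param alpha Significance level for reporting (default 0.05).
#' @return A `timecourse_trend`: list with `days` (per-day summary,
#'   including an `under_replicated` flag for days with fewer than 2
#'   replicates), `comparisons` (pairwise Welch tests with a `significant`
#'   column), and `monotonic` (logical).
#' @export
timecourse_trend <- function(panel, alpha = 0.05) {
  if (!is.data.frame(panel) ||
      !all(c("day", "delta_a_percent") %in% names(panel))) {
    stop_invalid("`panel` needs columns day and delta_a_percent")
  }
  days <- sort(unique(panel$day))
  if (length(days) < 2L) stop_invalid("need at least 2 timepoints")

  per_day <- do.call(rbind, lapply(days, function(d) {
    x <- panel$delta_a_percent[panel$day == d]
    data.frame(day = d, n = length(x), mean_delta_a = mean(x),
               sem = if (length(x) > 1) stats::sd(x) / sqrt(length(x))
                     else NA_real_,
               under_replicated = length(x) < 2L)
  }))
  if (any(per_day$under_replicated)) {
    warning("day(s) with fewer than 2 replicates", call. = FALSE)
  }

  pairs <- utils::combn(days, 2L)
  comparisons <- do.call(rbind, lapply(seq_len(ncol(pairs)), function(i) {
    x <- panel$delta_a_percent[panel$day == pairs[1L, i]]
    y <- panel$delta_a_percent[panel$day == pairs[2L, i]]
    p <- if (length(x) > 1L && length(y) > 1L &&
             (stats::sd(x) > 0 || stats::sd(y) > 0)) {
      stats::t.test(x, y)$p.value
    } else NA_real_
    data.frame(day_1 = pairs[1L, i], day_2 = pairs[2L, i], p_value = p,
               significant = !is.na(p) && p < alpha)
  }))

  structure(list(days = per_day, comparisons = comparisons,
                 monotonic = all(diff(per_day$mean_delta_a) >= 0),
                 alpha = alpha),
            class = "timecourse_trend")
}

#' @export
print.timecourse_trend <- function(x, ...) {
  cat("Induction time course\n")
  print(x$days, digits = 4)
  cat(sprintf("Monotonic (non-decreasing means): %s\n", x$monotonic))
  print(x$comparisons, digits = 4)
  invisible(x)
}
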