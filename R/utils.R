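#' dsrnadye: photochrome spectroscopy for dsRNA detection
#'
#' Equilibrium, spectral, kinetic and quantitation models for a
#' spiropyran/merocyanine-based colorimetric dsRNA assay, with seeded
#' synthetic-data generators for end-to-end validation.
#'
#' @keywords internal
"_PACKAGE"

# Internal validation helpers shared across modules.

stop_invalid <- function(...) {
  stop(sprintf(...), call. = FALSE)
}

assert_finite_scalar <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop_invalid("`%s` must be a single finite number", name)
  }
  invisible(x)
}

assert_finite_numeric <- function(x, name) {
  if (!is.numeric(x) || length(x) == 0L || any(!is.finite(x))) {
    stop_invalid("`%s` must be finite and non-empty", name)
  }
  invisible(x)
}

#' Evaluate an expression with a temporary RNG seed
#'
#' Runs `expr` under `set.seed(seed)` and restores the caller's RNG state
#' afterwards, so seeded generators never perturb the global random stream.
#'
#' @param seed Integer seed, or `NULL` to use the current stream.
#' @param expr Expression to evaluate.
#' @return The value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  assert_finite_scalar(seed, "seed")
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(as.integer(seed))
  expr
}

# Index of the grid point nearest a nominal wavelength (no interpolation;
# deterministic tie-break toward the shorter wavelength).
nearest_index <- function(grid, wavelength) {
  which.min(abs(grid - wavelength))[1L]
}
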