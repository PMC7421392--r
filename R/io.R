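# CSV readers and writers shared by all modules. Numeric columns are
# written with sprintf("%.17g") so that write-then-read round trips are
# lossless; readers validate the schema and report the offending row and
# column on malformed input.

write_csv_precise <- function(df, path) {
  out <- df
  for (nm in names(out)) {
    if (is.numeric(out[[nm]])) out[[nm]] <- sprintf("%.17g", out[[nm]])
  }
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

read_csv_schema <- function(path, numeric_cols, character_cols = character()) {
  if (!file.exists(path)) stop_invalid("file not found: %s", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character")
  required <- c(numeric_cols, character_cols)
  missing <- setdiff(required, names(df))
  if (length(missing)) {
    stop_invalid("%s: missing column(s): %s", path,
                 paste(missing, collapse = ", "))
  }
  for (nm in numeric_cols) {
    vals <- suppressWarnings(as.numeric(df[[nm]]))
    bad <- which(is.na(vals) & nzchar(trimws(df[[nm]])) |
                   !nzchar(trimws(df[[nm]])))
    if (length(bad)) {
      stop_invalid("%s: non-numeric value in column '%s', row %d",
                   path, nm, bad[1L])
    }
    df[[nm]] <- vals
  }
  df
}

#' Read and write spectrum CSV files
#'
#' Schema: columns `wavelength_nm,absorbance`, one spectrum per file,
#' wavelengths strictly ascending.
#'
#' @param spectrum A [dye_spectrum()].
#' @param path File path.
#' @param pathlength Path length (cm) to attach on read (not stored in the
#'   file); default 0.1.
#' @param label Label to attach on read; defaults to the file name.
#' @return `read_spectrum_csv()` returns a `dye_spectrum`; the writer
#'   returns `path` invisibly.
#' @export
write_spectrum_csv <- function(spectrum, path) {
  stopifnot(inherits(spectrum, "dye_spectrum"))
  write_csv_precise(data.frame(wavelength_nm = spectrum$wavelength_nm,
                               absorbance = spectrum$absorbance), path)
}

#' @rdname write_spectrum_csv
#' @export
read_spectrum_csv <- function(path, pathlength = 0.1, label = basename(path)) {
  df <- read_csv_schema(path, c("wavelength_nm", "absorbance"))
  if (is.unsorted(df$wavelength_nm, strictly = TRUE)) {
    stop_invalid("%s: wavelength grid must be strictly ascending", path)
  }
  dye_spectrum(df$wavelength_nm, df$absorbance, pathlength = pathlength,
               label = label)
}

#' Read and write titration CSV files
#'
#' Schema: columns `conc_molar,delta_a_percent,replicate,condition`.
#'
#' @param series A [titration_series()].
#' @param path File path.
#' @return `read_titration_csv()` returns a `titration_series`; the writer
#'   returns `path` invisibly.
#' @export
write_titration_csv <- function(series, path) {
  stopifnot(is.data.frame(series))
  write_csv_precise(series[c("conc_molar", "delta_a_percent", "replicate",
                             "condition")], path)
}

#' @rdname write_titration_csv
#' @export
read_titration_csv <- function(path) {
  df <- read_csv_schema(path, c("conc_molar", "delta_a_percent"),
                        c("replicate", "condition"))
  titration_series(df$conc_molar, df$delta_a_percent,
                   replicate = df$replicate, condition = df$condition)
}

#' Read and write kinetic trace CSV files
#'
#' Schema: columns `time_h,absorbance,wavelength_nm,replicate`, times
#' strictly increasing.
#'
#' @param trace A [kinetic_trace()].
#' @param path File path.
#' @return `read_trace_csv()` returns a `kinetic_trace`; the writer returns
#'   `path` invisibly.
#' @export
write_trace_csv <- function(trace, path) {
  stopifnot(is.data.frame(trace))
  write_csv_precise(trace[c("time_h", "absorbance", "wavelength_nm",
                            "replicate")], path)
}

#' @rdname write_trace_csv
#' @export
read_trace_csv <- function(path) {
  df <- read_csv_schema(path, c("time_h", "absorbance", "wavelength_nm"),
                        "replicate")
  if (is.unsorted(df$time_h, strictly = TRUE)) {
    stop_invalid("%s: time grid must be strictly increasing", path)
  }
  kinetic_trace(df$time_h, df$absorbance, wavelength = df$wavelength_nm,
                replicate = df$replicate)
}

#' Read and write sample panel CSV files
#'
#' Schema: columns `sample,treatment,replicate,delta_a_percent`, with an
#' optional `day` column for time courses.
#'
#' @param panel A [sample_panel()].
#' @param path File path.
#' @return `read_panel_csv()` returns a `sample_panel`; the writer returns
#'   `path` invisibly.
#' @export
write_panel_csv <- function(panel, path) {
  stopifnot(is.data.frame(panel))
  cols <- c("sample", "treatment", "replicate", "delta_a_percent")
  if ("day" %in% names(panel)) cols <- c(cols, "day")
  write_csv_precise(panel[cols], path)
}

#' @rdname write_panel_csv
#' @export
read_panel_csv <- function(path) {
  df <- read_csv_schema(path, c("replicate", "delta_a_percent"),
                        c("sample", "treatment"))
  out <- sample_panel(df$sample, df$treatment, df$replicate,
                      df$delta_a_percent)
  if ("day" %in% names(df)) {
    out$day <- suppressWarnings(as.numeric(df$day))
  }
  out
}

#' Write a fit report as JSON
#'
#' Serializes a `binding_fit` or `relaxation_fit` (estimates, standard
#' errors, residual sum of squares, convergence flag) to a flat JSON file.
#'
#' @param fit A `binding_fit` or `relaxation_fit`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fit_report <- function(fit, path) {
  stopifnot(inherits(fit, "binding_fit") || inherits(fit, "relaxation_fit"))
  jsonlite::write_json(unclass(fit), path, auto_unbox = TRUE, digits = NA,
                       null = "null", na = "null")
  invisible(path)
}
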