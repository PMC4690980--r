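# Spectrum container and CSV I/O.

fu_stop <- function(msg, class, call. = FALSE) {
  stop(errorCondition(msg, class = c(class, "forelule_error")))
}

#' Construct a sampled spectrum
#'
#' A `fu_spectrum` holds a sampled wavelength/value curve: remote-sensing
#' reflectance \eqn{R_{RS}(\lambda)} in sr\eqn{^{-1}} (`kind = "reflectance"`)
#' or an absorption coefficient \eqn{a(\lambda)} in m\eqn{^{-1}}
#' (`kind = "absorption"`). Wavelengths must be strictly increasing and all
#' values finite; input rows are sorted by wavelength.
#'
#' @param wavelength Numeric vector of wavelengths in nm.
#' @param value Numeric vector of the same length.
#' @param kind Either `"reflectance"` or `"absorption"`.
#' @return A data frame of class `fu_spectrum` with columns `wavelength_nm`
#'   and `value` and an attribute `kind`.
#' @examples
#' s <- fu_spectrum(c(400, 500, 600), c(0.002, 0.004, 0.001))
#' spectrum_kind(s)
#' @export
fu_spectrum <- function(wavelength, value, kind = c("reflectance", "absorption")) {
  kind <- match.arg(kind)
  if (length(wavelength) != length(value))
    fu_stop("wavelength and value must have equal length", "forelule_length_mismatch")
  if (length(wavelength) < 2)
    fu_stop("a spectrum needs at least 2 samples", "forelule_too_few_rows")
  if (!is.numeric(wavelength) || !is.numeric(value) ||
      anyNA(wavelength) || anyNA(value) ||
      any(!is.finite(wavelength)) || any(!is.finite(value)))
    fu_stop("wavelengths and values must be finite numbers", "forelule_nonfinite")
  o <- order(wavelength)
  wavelength <- as.numeric(wavelength[o])
  value <- as.numeric(value[o])
  if (any(diff(wavelength) == 0))
    fu_stop("duplicate wavelengths in spectrum", "forelule_duplicate_wavelength")
  structure(
    data.frame(wavelength_nm = wavelength, value = value),
    kind = kind,
    class = c("fu_spectrum", "data.frame")
  )
}

#' @rdname fu_spectrum
#' @param s A `fu_spectrum`.
#' @export
spectrum_kind <- function(s) {
  stopifnot(inherits(s, "fu_spectrum"))
  attr(s, "kind")
}

#' @export
print.fu_spectrum <- function(x, ...) {
  cat(sprintf("<fu_spectrum: %s, %d samples, %.1f-%.1f nm>\n",
              attr(x, "kind"), nrow(x),
              min(x$wavelength_nm), max(x$wavelength_nm)))
  invisible(x)
}

#' Read a spectrum from a two-column CSV file
#'
#' Expects a one-line header and two numeric columns, wavelength (nm) then
#' value. Rows may be in any order; the returned spectrum is sorted.
#'
#' @param path Path to the CSV file.
#' @param kind Spectrum kind, `"reflectance"` (default) or `"absorption"`.
#' @return A validated [fu_spectrum].
#' @export
read_spectrum_csv <- function(path, kind = c("reflectance", "absorption")) {
  kind <- match.arg(kind)
  if (!file.exists(path))
    fu_stop(sprintf("spectrum file not found: %s", path), "forelule_missing_file")
  raw <- utils::read.csv(path, header = TRUE, colClasses = "character",
                         strip.white = TRUE)
  if (ncol(raw) < 2)
    fu_stop("spectrum CSV must have two columns", "forelule_bad_columns")
  wl <- suppressWarnings(as.numeric(raw[[1]]))
  va <- suppressWarnings(as.numeric(raw[[2]]))
  if (anyNA(wl) || anyNA(va))
    fu_stop(sprintf("non-numeric cell in %s", path), "forelule_non_numeric")
  if (length(wl) < 2)
    fu_stop("spectrum CSV needs at least 2 data rows", "forelule_too_few_rows")
  if (anyDuplicated(wl))
    fu_stop(sprintf("duplicate wavelength(s) in %s: %s", path,
                    paste(unique(wl[duplicated(wl)]), collapse = ", ")),
            "forelule_duplicate_wavelength")
  fu_spectrum(wl, va, kind)
}

#' Write a spectrum to CSV
#'
#' Inverse of [read_spectrum_csv()]; values round-trip at full double
#' precision.
#'
#' @param s A `fu_spectrum`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_spectrum_csv <- function(s, path) {
  stopifnot(inherits(s, "fu_spectrum"))
  df <- data.frame(wavelength_nm = format(s$wavelength_nm, digits = 17, trim = TRUE),
                   value = format(s$value, digits = 17, trim = TRUE))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Resample a spectrum onto a wavelength grid
#'
#' Linear interpolation onto `grid`. The grid must lie inside the measured
#' wavelength range: no extrapolation is ever performed.
#'
#' @param s A `fu_spectrum`.
#' @param grid Strictly increasing numeric vector of target wavelengths (nm).
#' @return A `fu_spectrum` on `grid`, same kind as `s`.
#' @export
resample_to_grid <- function(s, grid) {
  stopifnot(inherits(s, "fu_spectrum"))
  if (length(grid) < 1 || any(diff(grid) <= 0))
    fu_stop("grid must be non-empty and strictly increasing", "forelule_bad_grid")
  rng <- range(s$wavelength_nm)
  if (min(grid) < rng[1] || max(grid) > rng[2])
    fu_stop(sprintf("grid [%g, %g] extends outside measured range [%g, %g]",
                    min(grid), max(grid), rng[1], rng[2]),
            "forelule_out_of_range")
  v <- stats::approx(s$wavelength_nm, s$value, xout = grid, method = "linear")$y
  if (length(grid) == 1) {
    # degenerate one-point grid: bypass the >= 2 sample rule of the constructor
    return(structure(data.frame(wavelength_nm = as.numeric(grid), value = v),
                     kind = attr(s, "kind"),
                     class = c("fu_spectrum", "data.frame")))
  }
  fu_spectrum(grid, v, attr(s, "kind"))
}
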