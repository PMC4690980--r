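# Spectrum -> tristimulus -> chromaticity -> hue angle -> Forel-Ule index.
#
# The visible integration domain is the intersection of the spectrum's range
# with 380-720 nm; spectra are resampled onto the colour-matching-function
# grid (never the other way round) and integrated by the trapezoidal rule.

VIS_MIN <- 380
VIS_MAX <- 720

#' Tristimulus values of a reflectance spectrum
#'
#' Computes \eqn{X = \int R_{RS}(\lambda)\bar{x}(\lambda) d\lambda} (and
#' likewise Y with \eqn{\bar{y}}, Z with \eqn{\bar{z}}) by the trapezoidal
#' rule on the colour-matching-function grid restricted to 380-720 nm. The
#' operation is linear in the spectrum.
#'
#' @param s A reflectance [fu_spectrum] covering at least 380-720 nm.
#' @param cmf A colour-matching-function table from [load_cmf_table()].
#' @return An object of class `fu_tristimulus`: named numeric `c(X, Y, Z)`.
#' @export
tristimulus <- function(s, cmf = load_cmf_table()) {
  stopifnot(inherits(s, "fu_spectrum"))
  if (spectrum_kind(s) != "reflectance")
    fu_stop("tristimulus is defined for reflectance spectra", "forelule_wrong_kind")
  if (min(s$wavelength_nm) > VIS_MIN || max(s$wavelength_nm) < VIS_MAX)
    fu_stop(sprintf(
      "spectrum [%g, %g] nm does not cover the visible domain [%d, %d] nm",
      min(s$wavelength_nm), max(s$wavelength_nm), VIS_MIN, VIS_MAX),
      "forelule_coverage")
  grid <- cmf$wavelength_nm[cmf$wavelength_nm >= VIS_MIN & cmf$wavelength_nm <= VIS_MAX]
  rs <- resample_to_grid(s, grid)
  sub <- cmf[cmf$wavelength_nm %in% grid, ]
  out <- c(X = trapz(grid, rs$value * sub$xbar),
           Y = trapz(grid, rs$value * sub$ybar),
           Z = trapz(grid, rs$value * sub$zbar))
  structure(out, class = "fu_tristimulus")
}

#' Chromaticity coordinates of a tristimulus triple
#'
#' `x = X / (X + Y + Z)`, `y = Y / (X + Y + Z)`. The intensity of the
#' stimulus is normalised away; only the colour remains.
#'
#' @param t Tristimulus values: `fu_tristimulus` or a numeric `c(X, Y, Z)`,
#'   all non-negative and not all zero.
#' @return Named numeric `c(x, y)` of class `fu_chromaticity`.
#' @export
chromaticity <- function(t) {
  t <- unclass(t)
  stopifnot(length(t) == 3)
  if (any(t < 0)) fu_stop("tristimulus values must be non-negative", "forelule_domain")
  tot <- sum(t)
  if (tot <= 0)
    fu_stop("all-zero tristimulus has no colour", "forelule_degenerate_colour")
  structure(c(x = unname(t[1]) / tot, y = unname(t[2]) / tot),
            class = "fu_chromaticity")
}

#' Hue angle about the white point
#'
#' The angle of the vector from the equal-energy white point (1/3, 1/3) to
#' the chromaticity point, measured counter-clockwise from the positive
#' x-axis, in degrees in [0, 360). Blue waters sit near 230 degrees, brown
#' waters near 20 degrees.
#'
#' @param c A `fu_chromaticity` or numeric `c(x, y)`.
#' @return Hue angle in degrees.
#' @export
hue_angle <- function(c) {
  c <- unclass(c)
  stopifnot(length(c) == 2)
  dx <- unname(c[1]) - 1 / 3
  dy <- unname(c[2]) - 1 / 3
  if (dx == 0 && dy == 0)
    fu_stop("chromaticity at the white point has undefined hue", "forelule_undefined_hue")
  (atan2(dy, dx) * 180 / pi) %% 360
}

# piecewise-linear FU index as a function of hue angle, unrounded.
# Reference angles decrease with index; clamp beyond both scale ends.
fui_interp <- function(angle, scale) {
  if (any(angle < 0 | angle >= 360)) fu_stop("hue angle must lie in [0, 360)", "forelule_domain")
  ang <- scale$hue_angle_deg
  idx <- scale$index
  out <- stats::approx(rev(ang), rev(idx), xout = angle, method = "linear",
                       yleft = max(idx), yright = min(idx))$y
  pmin(pmax(out, 1), 21)
}

#' Discrete Forel-Ule class of a hue angle
#'
#' Assigns the class whose reference hue angle is nearest, with class
#' boundaries at the midpoints between successive reference angles. An angle
#' exactly on a boundary goes to the lower (bluer) class; angles beyond the
#' blue end of the scale clamp to 1 and beyond the brown end to 21.
#'
#' @param angle Hue angle(s) in degrees, in [0, 360).
#' @param scale A Forel-Ule scale table from [load_fu_scale()].
#' @return Integer class(es) in 1..21.
#' @export
classify_fui <- function(angle, scale = load_fu_scale()) {
  check_scale(scale)
  cont <- fui_interp(angle, scale)
  # half-down rounding with a tiny tolerance so an angle exactly on a class
  # boundary (index k + 0.5 up to floating-point error) goes to the bluer class
  as.integer(pmin(pmax(ceiling(cont - 0.5 - 1e-9), 1), 21))
}

#' Continuous Forel-Ule index of a hue angle
#'
#' Piecewise-linear interpolation of the class index against the reference
#' hue angles, clamped to [1, 21] and rounded to one decimal place. The
#' continuous index removes the clustering artefacts that the 21 discrete
#' classes impose on correlations with continuous water-quality variables.
#'
#' @inheritParams classify_fui
#' @return Numeric index in [1.0, 21.0], one-decimal precision.
#' @export
continuous_fui <- function(angle, scale = load_fu_scale()) {
  check_scale(scale)
  round(fui_interp(angle, scale), 1)
}

check_scale <- function(scale) {
  if (!is.data.frame(scale) || nrow(scale) != 21 ||
      !all(c("index", "hue_angle_deg") %in% names(scale)) ||
      any(diff(scale$hue_angle_deg) >= 0))
    fu_stop("malformed Forel-Ule scale table", "forelule_table_integrity")
  invisible(scale)
}

#' Derive the Forel-Ule index from a remote-sensing reflectance spectrum
#'
#' The full colour pipeline: optional glint offset, convolution with the CIE
#' 1931 colour-matching functions to tristimulus values, chromaticity, hue
#' angle, and discrete plus continuous FUI. When `glint_nir_null = TRUE` the
#' mean reflectance over 700-720 nm is subtracted from the whole spectrum (a
#' simple residual-glint null in the near infrared, where clear-water
#' reflectance is negligible); negative values after subtraction are floored
#' at zero with a warning.
#'
#' @param s A reflectance [fu_spectrum] covering at least 380-720 nm.
#' @param glint_nir_null Apply the constant NIR-null offset first?
#' @param cmf,scale Reference tables; defaults load the packaged ones.
#' @return A list of class `fu_result` with elements `hue_angle_deg`,
#'   `fui_discrete` (integer 1-21), `fui_continuous` (one decimal),
#'   `chromaticity`.
#' @examples
#' tabs <- load_reference_tables()
#' s <- generate_rrs(cpa_record("st1", cdom_a440 = 0.2, chl = 1, spm = 2))
#' derive_fui_from_rrs(s, cmf = tabs$cmf, scale = tabs$fu_scale)
#' @export
derive_fui_from_rrs <- function(s, glint_nir_null = FALSE,
                                cmf = load_cmf_table(), scale = load_fu_scale()) {
  stopifnot(inherits(s, "fu_spectrum"))
  if (glint_nir_null) {
    nir <- s$value[s$wavelength_nm >= 700 & s$wavelength_nm <= 720]
    if (length(nir) == 0)
      fu_stop("no samples in 700-720 nm for the NIR glint null", "forelule_coverage")
    off <- mean(nir)
    v <- s$value - off
    if (any(v < 0)) {
      warning(sprintf("%d reflectance value(s) negative after NIR offset; floored at 0",
                      sum(v < 0)))
      v <- pmax(v, 0)
    }
    s <- fu_spectrum(s$wavelength_nm, v, "reflectance")
  }
  tri <- tristimulus(s, cmf)
  if (sum(unclass(tri)) <= 0)
    fu_stop("spectrum is zero over the visible domain; no colour to classify",
            "forelule_degenerate_colour")
  xy <- chromaticity(tri)
  ang <- hue_angle(xy)
  structure(list(hue_angle_deg = ang,
                 fui_discrete = classify_fui(ang, scale),
                 fui_continuous = continuous_fui(ang, scale),
                 chromaticity = xy),
            class = "fu_result")
}

#' @export
print.fu_result <- function(x, ...) {
  cat(sprintf("Forel-Ule result: hue angle %.2f deg, FUI %d (continuous %.1f)\n",
              x$hue_angle_deg, x$fui_discrete, x$fui_continuous))
  invisible(x)
}
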