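# Packaged reference tables: CIE 1931 colour-matching functions, the 21-class
# Forel-Ule hue-angle scale, and coarse pure-water optical constants. All
# classification code treats these as data, never as hard-coded constants, so
# a revised scale can be dropped in without touching the algorithm.

ref_path <- function(file) {
  p <- system.file("extdata", file, package = "forelule")
  if (identical(p, "") || !file.exists(p))
    fu_stop(sprintf("packaged table missing: %s", file), "forelule_table_integrity")
  p
}

#' Load the CIE 1931 2-degree colour-matching functions
#'
#' The standard-observer weights \eqn{\bar{x}, \bar{y}, \bar{z}} tabulated at
#' 5 nm from 380 to 780 nm. In the equal-energy normalisation of the 1931
#' system the three curves integrate to the same area; this is verified
#' numerically (within 1\%) every time the table is loaded.
#'
#' @return A data frame of class `fu_cmf` with columns `wavelength_nm`,
#'   `xbar`, `ybar`, `zbar`.
#' @export
load_cmf_table <- function() {
  d <- utils::read.csv(ref_path("cmf_1931_2deg.csv"))
  need <- c("wavelength_nm", "xbar", "ybar", "zbar")
  if (!all(need %in% names(d)) || anyNA(d) ||
      any(diff(d$wavelength_nm) <= 0) ||
      any(d$xbar < 0 | d$ybar < 0 | d$zbar < 0) ||
      min(d$wavelength_nm) > 380 || max(d$wavelength_nm) < 720)
    fu_stop("colour-matching function table is corrupted", "forelule_table_integrity")
  ints <- vapply(c("xbar", "ybar", "zbar"),
                 function(k) trapz(d$wavelength_nm, d[[k]]), numeric(1))
  if (max(ints) / min(ints) - 1 > 0.01)
    fu_stop("colour-matching functions violate equal-energy normalisation",
            "forelule_table_integrity")
  structure(d, class = c("fu_cmf", "data.frame"))
}

#' Load the Forel-Ule reference hue angles
#'
#' One reference hue angle per FU class, 1 (indigo-blue) through 21 (cola
#' brown). Hue angles are measured counter-clockwise from the positive x-axis
#' about the white point (1/3, 1/3) of the CIE 1931 chromaticity diagram and
#' decrease strictly from the blue to the brown end of the scale. The shipped
#' values follow the published chromaticity characterisations of the Forel-Ule
#' standard solutions (Wernand & van der Woerd 2010; Novoa et al. 2013).
#'
#' @return A data frame of class `fu_scale` with columns `index` (1-21) and
#'   `hue_angle_deg`.
#' @export
load_fu_scale <- function() {
  d <- utils::read.csv(ref_path("fu_scale_hue_angles.csv"))
  if (!all(c("index", "hue_angle_deg") %in% names(d)) ||
      nrow(d) != 21 || !identical(as.integer(d$index), 1:21) ||
      anyNA(d$hue_angle_deg) || any(diff(d$hue_angle_deg) >= 0))
    fu_stop("Forel-Ule scale table is corrupted", "forelule_table_integrity")
  structure(d, class = c("fu_scale", "data.frame"))
}

#' Load pure-water absorption and backscattering
#'
#' A coarse visible-range table of the absorption coefficient of pure water
#' (after Pope & Fry 1997, approximate) and the backscattering coefficient of
#' pure seawater (power-law in wavelength, after Morel 1974), both in
#' m\eqn{^{-1}}. Used by the bio-optical forward model in
#' [generate_rrs()]; coarse tabulation is adequate there because the model is
#' schematic by design.
#'
#' @return A data frame with columns `wavelength_nm`, `absorption_m1`,
#'   `backscatter_m1`.
#' @export
load_water_iops <- function() {
  d <- utils::read.csv(ref_path("pure_water_iops.csv"))
  if (!all(c("wavelength_nm", "absorption_m1", "backscatter_m1") %in% names(d)) ||
      anyNA(d) || any(diff(d$wavelength_nm) <= 0) ||
      any(d$absorption_m1 <= 0 | d$backscatter_m1 <= 0))
    fu_stop("pure-water optical table is corrupted", "forelule_table_integrity")
  d
}

#' Load all packaged reference tables
#'
#' @return A list with elements `cmf` ([load_cmf_table()]), `fu_scale`
#'   ([load_fu_scale()]) and `water_iops` ([load_water_iops()]).
#' @examples
#' tabs <- load_reference_tables()
#' nrow(tabs$fu_scale)  # 21 colour classes
#' @export
load_reference_tables <- function() {
  list(cmf = load_cmf_table(),
       fu_scale = load_fu_scale(),
       water_iops = load_water_iops())
}

# trapezoidal integral on an irregular grid
trapz <- function(x, y) {
  n <- length(x)
  sum((x[-1] - x[-n]) * (y[-1] + y[-n])) / 2
}
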