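# Independent oracles and small fixture builders used across the suite.

# Fine-grid (1 nm) numeric tristimulus integration, written independently of
# the package's trapezoidal path: midpoint-free rectangle-free plain
# trapezoid on a dense grid with linearly interpolated CMF weights.
oracle_tristimulus <- function(spec_fun, cmf, lo = 380, hi = 720) {
  wl <- seq(lo, hi, by = 1)
  xb <- approx(cmf$wavelength_nm, cmf$xbar, xout = wl)$y
  yb <- approx(cmf$wavelength_nm, cmf$ybar, xout = wl)$y
  zb <- approx(cmf$wavelength_nm, cmf$zbar, xout = wl)$y
  v <- spec_fun(wl)
  tz <- function(f) {
    n <- length(wl)
    sum((wl[-1] - wl[-n]) * (f[-1] + f[-n]) / 2)
  }
  c(X = tz(v * xb), Y = tz(v * yb), Z = tz(v * zb))
}

# smooth synthetic reflectance shapes for oracle comparisons
smooth_spectrum_funs <- list(
  blue_peak = function(wl) 0.002 + 0.01 * exp(-0.5 * ((wl - 440) / 40)^2),
  green_peak = function(wl) 0.001 + 0.008 * exp(-0.5 * ((wl - 555) / 60)^2),
  sloped = function(wl) 0.012 * exp(-(wl - 380) / 300),
  broad = function(wl) 0.004 + 0.003 * sin((wl - 380) / 80)^2
)

write_tmp_csv <- function(lines) {
  f <- tempfile(fileext = ".csv")
  writeLines(lines, f)
  f
}
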