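# Synthetic bio-optical data: a deliberately simple reflectance forward
# model, a noisy handheld observer, whole campaigns, and tidal time series.
# The forward model is a schematic bb/(a+bb) closure -- adequate for ordering
# water colours from blue to brown, not for radiometric accuracy.

# run code under a fixed seed without disturbing the caller's RNG stream
with_seed <- function(seed, code) {
  if (is.null(seed)) return(code)
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  code
}

#' One station's colour-producing-agent record
#'
#' @param station Station identifier.
#' @param cdom_a440 CDOM absorption at 440 nm, m^-1, >= 0.
#' @param chl Chlorophyll-a, ug/L, >= 0.
#' @param spm Inorganic suspended particulate material, mg/L, >= 0.
#' @param turbidity Optional turbidity, NTU, >= 0.
#' @param sdd Optional Secchi-disk depth, m, > 0.
#' @param fui Optional FUI value in [1, 21].
#' @return A one-row data frame of class `fu_cpa_record`.
#' @export
cpa_record <- function(station, cdom_a440, chl, spm,
                       turbidity = NA_real_, sdd = NA_real_, fui = NA_real_) {
  if (cdom_a440 < 0 || chl < 0 || spm < 0 || (!is.na(turbidity) && turbidity < 0))
    fu_stop("concentrations must be non-negative", "forelule_domain")
  if (!is.na(sdd) && sdd <= 0)
    fu_stop("Secchi-disk depth must be positive", "forelule_domain")
  if (!is.na(fui) && (fui < 1 || fui > 21))
    fu_stop("FUI must lie in [1, 21]", "forelule_domain")
  structure(data.frame(station = as.character(station),
                       cdom_a440_m1 = cdom_a440, chl_ugL = chl, spm_mgL = spm,
                       turbidity_ntu = turbidity, sdd_m = sdd, fui = fui),
            class = c("fu_cpa_record", "data.frame"))
}

#' Forward-model parameters
#'
#' Bio-optical constants of the schematic reflectance model used by
#' [generate_rrs()]:
#' \itemize{
#'   \item `cdom_slope` (nm^-1): exponential slope of CDOM absorption,
#'     referenced to 440 nm; default 0.018, a typical coastal value.
#'   \item `nap_a440` (m^2/g) and `nap_slope` (nm^-1): mass-specific
#'     absorption of non-algal particles at 440 nm and its exponential slope.
#'   \item `chl_specific_absorption`: function of wavelength (nm) returning
#'     the chlorophyll-specific absorption in m^2/mg; the default is a
#'     schematic two-Gaussian curve peaking at 440 nm (0.0378) and 675 nm
#'     (0.0207).
#'   \item `bbp_550` (m^2/g) and `bbp_exponent`: mass-specific particulate
#'     backscattering at 550 nm and its power-law wavelength exponent.
#'   \item `reflectance_factor` (sr^-1): the proportionality in
#'     \eqn{R_{RS} = f \, b_b / (a + b_b)}.
#' }
#'
#' @return A list of class `fu_forward_params`.
#' @export
forward_model_params <- function(cdom_slope = 0.018,
                                 nap_a440 = 0.031,
                                 nap_slope = 0.011,
                                 chl_specific_absorption = default_chl_absorption,
                                 bbp_550 = 0.01,
                                 bbp_exponent = 1.0,
                                 reflectance_factor = 0.095) {
  vals <- c(cdom_slope, nap_a440, nap_slope, bbp_550, bbp_exponent,
            reflectance_factor)
  if (any(!is.finite(vals)) || any(vals <= 0))
    fu_stop("all forward-model slopes and coefficients must be positive",
            "forelule_domain")
  stopifnot(is.function(chl_specific_absorption))
  structure(list(cdom_slope = cdom_slope, nap_a440 = nap_a440,
                 nap_slope = nap_slope,
                 chl_specific_absorption = chl_specific_absorption,
                 bbp_550 = bbp_550, bbp_exponent = bbp_exponent,
                 reflectance_factor = reflectance_factor),
            class = "fu_forward_params")
}

#' @rdname forward_model_params
#' @param wavelength_nm Wavelengths in nm.
#' @export
default_chl_absorption <- function(wavelength_nm) {
  0.0378 * exp(-0.5 * ((wavelength_nm - 440) / 34)^2) +
    0.0207 * exp(-0.5 * ((wavelength_nm - 675) / 12)^2)
}

#' Forward-model a remote-sensing reflectance spectrum
#'
#' Builds \eqn{R_{RS}(\lambda) = f \, b_b(\lambda) / (a(\lambda) +
#' b_b(\lambda))} with total absorption
#' \eqn{a = a_w + a_{CDOM} + a_{chl} + a_{NAP}} (pure water; CDOM exponential
#' anchored at 440 nm; chlorophyll-specific curve; non-algal particles) and
#' total backscattering \eqn{b_b = b_{b,w} + b_{b,p}} (pure seawater plus an
#' SPM-driven power law). Deterministic given its inputs.
#'
#' @param cpa A [cpa_record()] (or data frame row with `cdom_a440_m1`,
#'   `chl_ugL`, `spm_mgL`).
#' @param grid Wavelength grid in nm, within 380-720.
#' @param params A [forward_model_params()].
#' @param water_iops Pure-water table; defaults to the packaged one.
#' @return A reflectance [fu_spectrum] on `grid` (values in sr^-1, all
#'   finite and >= 0).
#' @export
generate_rrs <- function(cpa, grid = seq(380, 720, by = 5),
                         params = forward_model_params(),
                         water_iops = load_water_iops()) {
  if (min(grid) < 380 || max(grid) > 720 || any(diff(grid) <= 0))
    fu_stop("grid must be strictly increasing within 380-720 nm", "forelule_bad_grid")
  cdom <- cpa$cdom_a440_m1; chl <- cpa$chl_ugL; spm <- cpa$spm_mgL
  if (anyNA(c(cdom, chl, spm)) || cdom < 0 || chl < 0 || spm < 0)
    fu_stop("CPA concentrations must be non-negative", "forelule_domain")
  aw <- stats::approx(water_iops$wavelength_nm, water_iops$absorption_m1,
                      xout = grid)$y
  bbw <- stats::approx(water_iops$wavelength_nm, water_iops$backscatter_m1,
                       xout = grid)$y
  a <- aw +
    cdom * exp(-params$cdom_slope * (grid - 440)) +
    chl * params$chl_specific_absorption(grid) +
    spm * params$nap_a440 * exp(-params$nap_slope * (grid - 440))
  bb <- bbw + spm * params$bbp_550 * (550 / grid)^params$bbp_exponent
  rrs <- params$reflectance_factor * bb / (a + bb)
  fu_spectrum(grid, rrs, "reflectance")
}

#' Observer model for handheld scale readings
#'
#' Colour perception with the handheld comparator scale is subjective; the
#' observer model shifts a reading by one class (up or down with equal
#' chance) with probability `misclass_prob`. The default of 0.2 is a free
#' assumption, not a validated error rate.
#'
#' @param misclass_prob Probability in [0, 1] of a +/-1 class error.
#' @param seed Optional integer seed making the observer reproducible.
#' @return A list of class `fu_observer`.
#' @export
observer_model <- function(misclass_prob = 0.2, seed = NULL) {
  if (misclass_prob < 0 || misclass_prob > 1)
    fu_stop("misclass_prob must lie in [0, 1]", "forelule_domain")
  structure(list(misclass_prob = misclass_prob, seed = seed),
            class = "fu_observer")
}

#' Simulate a handheld Forel-Ule observation
#'
#' Rounds the true continuous FUI to the nearest class (ties to the lower,
#' bluer class) and applies the observer's misclassification model, clamping
#' to the 1-21 scale.
#'
#' @param true_fui True FUI value(s) in [1, 21].
#' @param obs An [observer_model()].
#' @return Integer class(es) in 1..21.
#' @export
simulate_handheld <- function(true_fui, obs = observer_model()) {
  if (any(is.na(true_fui)) || any(true_fui < 1 | true_fui > 21))
    fu_stop("true_fui must lie in [1, 21]", "forelule_domain")
  with_seed(obs$seed, {
    base <- pmin(pmax(ceiling(true_fui - 0.5), 1), 21)
    n <- length(base)
    err <- stats::runif(n) < obs$misclass_prob
    shift <- ifelse(stats::runif(n) < 0.5, -1L, 1L)
    as.integer(pmin(pmax(base + ifelse(err, shift, 0L), 1), 21))
  })
}

#' Generate a synthetic field campaign
#'
#' Draws station CPA concentrations uniformly within `cpa_ranges`, forward
#' models each station's reflectance spectrum, derives discrete and
#' continuous FUI from it, simulates a handheld reading of the derived
#' discrete class, and generates the clarity indicators: Secchi-disk depth as
#' \eqn{c_{SDD} / \langle a + b_b \rangle} (visible-band mean attenuation)
#' and turbidity proportional to particulate backscatter at 550 nm, each with
#' lognormal noise.
#'
#' @param n_stations Number of stations, >= 1.
#' @param cpa_ranges Named list of `c(min, max)` ranges for `cdom` (m^-1),
#'   `chl` (ug/L) and `spm` (mg/L). Defaults span clear shelf water to a
#'   turbid estuary.
#' @param params A [forward_model_params()].
#' @param obs An [observer_model()]; its own seed, if any, is ignored here --
#'   the campaign seed drives everything.
#' @param seed Integer seed; the whole campaign is bit-for-bit reproducible.
#' @param grid Wavelength grid for the spectra.
#' @param sdd_coeff Numerator of the Secchi-disk law, m * m^-1.
#' @param turb_coeff Turbidity per unit particulate backscatter, NTU/m^-1.
#' @param clarity_noise_sd Standard deviation of the lognormal noise on SDD
#'   and turbidity (log scale).
#' @return A list of class `fu_campaign`: `stations` (data frame with
#'   station, CPA, turbidity, SDD, hue angle, continuous `fui`, discrete
#'   `fui_discrete`, handheld `fui_handheld`), `spectra` (named list of
#'   [fu_spectrum]), and `metadata` recording every generator setting
#'   including the seed.
#' @export
generate_campaign <- function(n_stations = 34,
                              cpa_ranges = list(cdom = c(0.02, 1.2),
                                                chl = c(0.1, 10),
                                                spm = c(0.5, 50)),
                              params = forward_model_params(),
                              obs = observer_model(),
                              seed = NULL,
                              grid = seq(380, 720, by = 5),
                              sdd_coeff = 2.5,
                              turb_coeff = 100,
                              clarity_noise_sd = 0.15) {
  if (n_stations < 1) fu_stop("n_stations must be >= 1", "forelule_domain")
  for (k in c("cdom", "chl", "spm")) {
    r <- cpa_ranges[[k]]
    if (is.null(r) || length(r) != 2 || r[1] < 0 || r[2] < r[1])
      fu_stop(sprintf("invalid range for %s", k), "forelule_domain")
  }
  tabs <- load_reference_tables()
  with_seed(seed, {
    cdom <- stats::runif(n_stations, cpa_ranges$cdom[1], cpa_ranges$cdom[2])
    chl <- stats::runif(n_stations, cpa_ranges$chl[1], cpa_ranges$chl[2])
    spm <- stats::runif(n_stations, cpa_ranges$spm[1], cpa_ranges$spm[2])
    noise_sdd <- stats::rnorm(n_stations, 0, clarity_noise_sd)
    noise_turb <- stats::rnorm(n_stations, 0, clarity_noise_sd)
    station <- sprintf("st%03d", seq_len(n_stations))
    spectra <- vector("list", n_stations)
    names(spectra) <- station
    hue <- fui_cont <- fui_disc <- sdd <- turb <- numeric(n_stations)
    for (i in seq_len(n_stations)) {
      rec <- data.frame(cdom_a440_m1 = cdom[i], chl_ugL = chl[i], spm_mgL = spm[i])
      sp <- generate_rrs(rec, grid, params, tabs$water_iops)
      res <- derive_fui_from_rrs(sp, cmf = tabs$cmf, scale = tabs$fu_scale)
      spectra[[i]] <- sp
      hue[i] <- res$hue_angle_deg
      fui_cont[i] <- res$fui_continuous
      fui_disc[i] <- res$fui_discrete
      atten <- total_attenuation(rec, grid, params, tabs$water_iops)
      sdd[i] <- sdd_coeff / atten * exp(noise_sdd[i])
      bbp550 <- spm[i] * params$bbp_550
      turb[i] <- turb_coeff * bbp550 * exp(noise_turb[i])
    }
    handheld <- simulate_handheld(fui_disc, observer_model(obs$misclass_prob))
    stations <- data.frame(station = station,
                           cdom_a440_m1 = cdom, chl_ugL = chl, spm_mgL = spm,
                           turbidity_ntu = turb, sdd_m = sdd,
                           hue_angle_deg = hue, fui = fui_cont,
                           fui_discrete = fui_disc, fui_handheld = handheld)
    structure(list(stations = stations, spectra = spectra,
                   metadata = list(seed = seed, n_stations = n_stations,
                                   cpa_ranges = cpa_ranges, params = params,
                                   obs = obs, grid = grid,
                                   sdd_coeff = sdd_coeff,
                                   turb_coeff = turb_coeff,
                                   clarity_noise_sd = clarity_noise_sd)),
              class = "fu_campaign")
  })
}

# visible-band mean of a + bb for the clarity law
total_attenuation <- function(cpa, grid, params, water_iops) {
  aw <- stats::approx(water_iops$wavelength_nm, water_iops$absorption_m1,
                      xout = grid)$y
  bbw <- stats::approx(water_iops$wavelength_nm, water_iops$backscatter_m1,
                       xout = grid)$y
  a <- aw +
    cpa$cdom_a440_m1 * exp(-params$cdom_slope * (grid - 440)) +
    cpa$chl_ugL * params$chl_specific_absorption(grid) +
    cpa$spm_mgL * params$nap_a440 * exp(-params$nap_slope * (grid - 440))
  bb <- bbw + cpa$spm_mgL * params$bbp_550 * (550 / grid)^params$bbp_exponent
  mean(a + bb)
}

#' @export
print.fu_campaign <- function(x, ...) {
  cat(sprintf("<fu_campaign: %d stations, seed %s, FUI %.1f-%.1f>\n",
              nrow(x$stations),
              if (is.null(x$metadata$seed)) "none" else x$metadata$seed,
              min(x$stations$fui), max(x$stations$fui)))
  invisible(x)
}

#' Generate a synthetic tidal time series
#'
#' Minute-resolution water level (sinusoid with the M2 period of 12.42 h)
#' and FUI at a fixed platform. FUI follows a sediment-resuspension term that
#' peaks at low water (resuspended particles darken the water toward the
#' brown end of the scale) plus Gaussian noise, clamped to [1, 21]. With
#' `noise_sd = 0` the series is exactly periodic with the tidal period.
#'
#' @param days Number of days, >= 1.
#' @param amplitude_m Tidal amplitude in metres.
#' @param fui_base FUI at high water.
#' @param resuspension_gain FUI increase from high to low water.
#' @param noise_sd Standard deviation of the FUI noise.
#' @param seed Optional integer seed.
#' @param start Start instant (UTC).
#' @return A data frame of class `fu_timeseries` with columns `timestamp`
#'   (POSIXct, UTC, strictly increasing), `water_level_m` and `fui`.
#' @export
generate_tidal_series <- function(days = 6, amplitude_m = 1.5, fui_base = 9,
                                  resuspension_gain = 6, noise_sd = 0.5,
                                  seed = NULL,
                                  start = as.POSIXct("2013-08-15 00:00:00",
                                                     tz = "UTC")) {
  if (days < 1) fu_stop("days must be >= 1", "forelule_domain")
  n <- days * 1440L
  t_min <- seq_len(n) - 1L
  period_min <- 12.42 * 60
  level <- amplitude_m * sin(2 * pi * t_min / period_min)
  resus <- resuspension_gain * (amplitude_m - level) / (2 * amplitude_m)
  with_seed(seed, {
    fui <- fui_base + resus +
      if (noise_sd > 0) stats::rnorm(n, 0, noise_sd) else 0
    structure(data.frame(timestamp = start + 60 * t_min,
                         water_level_m = level,
                         fui = pmin(pmax(fui, 1), 21)),
              class = c("fu_timeseries", "data.frame"))
  })
}
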