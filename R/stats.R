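# Validation and regression statistics: percent-difference uncertainty
# metrics, Spearman rank association, handheld-vs-derived linear correction,
# CDOM spectral-slope fitting, and the multivariate CPA -> FUI regressions.

#' Percent-difference uncertainty statistics
#'
#' `mapd()` is the mean absolute percent difference,
#' \deqn{\psi_{mapd} = 100 \frac{1}{N} \sum_{i=1}^{N}
#'   \frac{|X_{predicted} - X_{insitu}|}{X_{insitu}},}
#' a measure of scatter; `mpd()` drops the absolute value,
#' \deqn{\psi_{mpd} = 100 \frac{1}{N} \sum_{i=1}^{N}
#'   \frac{X_{predicted} - X_{insitu}}{X_{insitu}},}
#' and indicates bias. Both report the standard deviation of the per-point
#' percent differences alongside the mean, the form in which field validation
#' results are usually quoted (e.g. "6\% +/- 5.5\%"). `|mpd| <= mapd` always.
#'
#' @param predicted,insitu Equal-length numeric vectors; `insitu` must be
#'   nonzero everywhere.
#' @return For `uncertainty_stats()`: a list of class `fu_uncertainty` with
#'   `mapd`, `mapd_sd`, `mpd`, `mpd_sd` (percent) and `n`. `mapd()` and
#'   `mpd()` return the single mean value.
#' @examples
#' mapd(c(11, 9), c(10, 10))  # 10
#' mpd(c(11, 9), c(10, 10))   # 0
#' @export
uncertainty_stats <- function(predicted, insitu) {
  pd <- percent_diffs(predicted, insitu)
  structure(list(mapd = mean(abs(pd)),
                 mapd_sd = if (length(pd) > 1) stats::sd(abs(pd)) else 0,
                 mpd = mean(pd),
                 mpd_sd = if (length(pd) > 1) stats::sd(pd) else 0,
                 n = length(pd)),
            class = "fu_uncertainty")
}

percent_diffs <- function(predicted, insitu) {
  if (length(predicted) != length(insitu) || length(insitu) < 1)
    fu_stop("predicted and in-situ vectors must have equal length >= 1",
            "forelule_length_mismatch")
  zero <- which(insitu == 0)
  if (length(zero))
    fu_stop(sprintf("in-situ value is zero at index %s: percent difference undefined",
                    paste(zero, collapse = ", ")),
            "forelule_division_by_zero")
  100 * (predicted - insitu) / insitu
}

#' @rdname uncertainty_stats
#' @export
mapd <- function(predicted, insitu) uncertainty_stats(predicted, insitu)$mapd

#' @rdname uncertainty_stats
#' @export
mpd <- function(predicted, insitu) uncertainty_stats(predicted, insitu)$mpd

#' @export
print.fu_uncertainty <- function(x, ...) {
  cat(sprintf("psi_mapd = %.1f%% +/- %.1f%%, psi_mpd = %.1f%% +/- %.1f%% (n = %d)\n",
              x$mapd, x$mapd_sd, x$mpd, x$mpd_sd, x$n))
  invisible(x)
}

#' Spearman rank association
#'
#' Rank correlation with mid-ranks for ties. The p-value is exact
#' (permutation distribution) for n <= 9 without ties and uses the
#' t-approximation otherwise, as in [stats::cor.test()]. Monotone transforms
#' of either variable (e.g. taking logs of positive concentrations) leave the
#' result unchanged.
#'
#' @param x,y Equal-length numeric vectors, n >= 3.
#' @return A list of class `fu_correlation` with `rho`, `p`, `n`.
#' @export
spearman_assoc <- function(x, y) {
  if (length(x) != length(y) || length(x) < 3)
    fu_stop("Spearman association needs equal-length vectors with n >= 3",
            "forelule_insufficient_data")
  ok <- stats::complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3)
    fu_stop("fewer than 3 complete pairs", "forelule_insufficient_data")
  if (stats::var(x) == 0 || stats::var(y) == 0)
    fu_stop("correlation undefined for a constant variable",
            "forelule_undefined_correlation")
  ct <- suppressWarnings(
    stats::cor.test(x, y, method = "spearman", exact = length(x) <= 9))
  structure(list(rho = unname(ct$estimate), p = ct$p.value, n = length(x)),
            class = "fu_correlation")
}

#' @export
print.fu_correlation <- function(x, ...) {
  cat(sprintf("Spearman rho = %.3f (N = %d, p = %.3g)\n", x$rho, x$n, x$p))
  invisible(x)
}

#' Fit a linear correction from derived to reference FUI
#'
#' Ocean-colour-derived FUI is validated against handheld-scale readings (the
#' reference measurement) and a least-squares line `reference ~ derived` is
#' fitted so that derived values can be corrected and mapped at stations
#' where no handheld observation exists.
#'
#' @param derived Numeric FUI values derived from reflectance (discrete or
#'   continuous; which one was used is recorded on the model).
#' @param reference Matched handheld FUI readings.
#' @return A list of class `fu_correction` with `slope`, `intercept`, `n`,
#'   `fui_type`, and `stats_before` / `stats_after`
#'   ([uncertainty_stats()] of derived resp. corrected values against the
#'   reference).
#' @export
fit_linear_correction <- function(derived, reference) {
  if (length(derived) != length(reference) || length(derived) < 3)
    fu_stop("correction fit needs at least 3 matched pairs",
            "forelule_insufficient_data")
  if (stats::var(derived) == 0)
    fu_stop("derived FUI has zero variance; correction line is degenerate",
            "forelule_degenerate_fit")
  fit <- stats::lm(reference ~ derived)
  m <- structure(list(slope = unname(stats::coef(fit)[2]),
                      intercept = unname(stats::coef(fit)[1]),
                      n = length(derived),
                      fui_type = if (all(derived == round(derived)))
                        "discrete" else "continuous",
                      stats_before = uncertainty_stats(derived, reference)),
                 class = "fu_correction")
  m$stats_after <- uncertainty_stats(apply_correction(m, derived), reference)
  m
}

#' Apply a fitted FUI correction
#'
#' @param m A `fu_correction` from [fit_linear_correction()].
#' @param derived Numeric derived FUI values.
#' @param round_decimal Round the corrected values to one decimal?
#' @return Corrected FUI values, clamped to [1, 21].
#' @export
apply_correction <- function(m, derived, round_decimal = FALSE) {
  stopifnot(inherits(m, "fu_correction"))
  out <- pmin(pmax(m$slope * derived + m$intercept, 1), 21)
  if (round_decimal) out <- round(out, 1)
  out
}

#' @export
print.fu_correction <- function(x, ...) {
  cat(sprintf("FUI correction: reference = %.3f x derived + %.3f (n = %d, %s FUI)\n",
              x$slope, x$intercept, x$n, x$fui_type))
  cat("  before: "); print(x$stats_before)
  cat("  after:  "); print(x$stats_after)
  invisible(x)
}

#' Fit the CDOM exponential absorption model
#'
#' Nonlinear least squares of \eqn{a(\lambda) = a_{275} e^{-S (\lambda - 275)}}
#' over the 275-295 nm window only (the range in which the spectral slope of
#' coloured dissolved organic matter is determined); the absorption
#' coefficient at 440 nm is then obtained by extrapolating the fitted curve:
#' \eqn{a_{440} = a_{275} e^{-165 S}}.
#'
#' @param s An absorption [fu_spectrum] covering 275-295 nm with positive
#'   values.
#' @return A list of class `fu_cdom_fit` with `a275` (m^-1), `slope_s`
#'   (nm^-1), `a440` (m^-1) and `rss`.
#' @export
fit_cdom_a440 <- function(s) {
  stopifnot(inherits(s, "fu_spectrum"))
  if (spectrum_kind(s) != "absorption")
    fu_stop("CDOM fit needs an absorption spectrum", "forelule_wrong_kind")
  if (min(s$wavelength_nm) > 275 || max(s$wavelength_nm) < 295)
    fu_stop("absorption spectrum must cover 275-295 nm", "forelule_coverage")
  sub <- s[s$wavelength_nm >= 275 & s$wavelength_nm <= 295, , drop = FALSE]
  if (nrow(sub) < 3)
    fu_stop("need at least 3 samples inside 275-295 nm", "forelule_insufficient_data")
  if (any(sub$value <= 0))
    fu_stop("absorption must be positive for the exponential fit", "forelule_domain")
  # log-linear start values, then full nonlinear refinement
  lf <- stats::lm(log(value) ~ I(wavelength_nm - 275), data = sub)
  start <- list(a275 = exp(unname(stats::coef(lf)[1])),
                S = max(-unname(stats::coef(lf)[2]), 1e-6))
  fit <- tryCatch(
    stats::nls(value ~ a275 * exp(-S * (wavelength_nm - 275)),
               data = sub, start = start,
               control = stats::nls.control(maxiter = 200, warnOnly = FALSE,
                                            scaleOffset = 1)),
    error = function(e)
      fu_stop(sprintf("CDOM exponential fit did not converge: %s",
                      conditionMessage(e)), "forelule_convergence"))
  co <- stats::coef(fit)
  structure(list(a275 = unname(co["a275"]),
                 slope_s = unname(co["S"]),
                 a440 = unname(co["a275"]) * exp(-unname(co["S"]) * (440 - 275)),
                 rss = sum(stats::residuals(fit)^2)),
            class = "fu_cdom_fit")
}

#' @export
print.fu_cdom_fit <- function(x, ...) {
  cat(sprintf("CDOM fit: a(275) = %.4f m^-1, S = %.5f nm^-1, a(440) = %.5f m^-1\n",
              x$a275, x$slope_s, x$a440))
  invisible(x)
}

#' Multivariate regression of FUI on colour-producing agents
#'
#' Ordinary least squares of FUI on CDOM absorption at 440 nm (m^-1),
#' chlorophyll-a (ug/L) and inorganic suspended particulate material (mg/L):
#' `FUI ~ intercept + CDOM + chl + SPM`. Reports R-squared, the overall
#' F-test p-value, and the psi_mapd / psi_mpd of fitted versus observed FUI.
#'
#' @param records A data frame with columns `fui`, `cdom_a440_m1`, `chl_ugL`,
#'   `spm_mgL` (a campaign table from [generate_campaign()] works directly),
#'   at least 5 complete rows.
#' @param fui_type Label recorded on the model: was `fui` discrete or
#'   continuous?
#' @return A list of class `fu_regression` with `intercept`, `coef_cdom`,
#'   `coef_chl`, `coef_spm`, `r2`, `p`, `n`, `stats`
#'   ([uncertainty_stats()] of fitted vs observed), `fui_type` and the
#'   underlying `lm` fit.
#' @export
fit_cpa_regression <- function(records, fui_type = c("continuous", "discrete")) {
  fui_type <- match.arg(fui_type)
  need <- c("fui", "cdom_a440_m1", "chl_ugL", "spm_mgL")
  if (!is.data.frame(records) || !all(need %in% names(records)))
    fu_stop(sprintf("records must contain columns %s", paste(need, collapse = ", ")),
            "forelule_bad_columns")
  d <- records[stats::complete.cases(records[need]), need]
  if (nrow(d) < 5)
    fu_stop("CPA regression needs at least 5 complete records",
            "forelule_insufficient_data")
  X <- as.matrix(cbind(1, d$cdom_a440_m1, d$chl_ugL, d$spm_mgL))
  if (kappa(X, exact = TRUE) > 1e8)
    warning("predictors are nearly collinear; coefficients are unstable")
  fit <- stats::lm(fui ~ cdom_a440_m1 + chl_ugL + spm_mgL, data = d)
  sm <- summary(fit)
  p_overall <- if (is.null(sm$fstatistic)) NA_real_ else
    unname(stats::pf(sm$fstatistic[1], sm$fstatistic[2], sm$fstatistic[3],
                     lower.tail = FALSE))
  co <- stats::coef(fit)
  structure(list(intercept = unname(co[1]),
                 coef_cdom = unname(co["cdom_a440_m1"]),
                 coef_chl = unname(co["chl_ugL"]),
                 coef_spm = unname(co["spm_mgL"]),
                 r2 = sm$r.squared,
                 p = p_overall,
                 n = nrow(d),
                 stats = uncertainty_stats(stats::fitted(fit), d$fui),
                 fui_type = fui_type,
                 fit = fit),
            class = "fu_regression")
}

#' @export
print.fu_regression <- function(x, ...) {
  cat(sprintf("FUI = %.2f %+.2f x CDOM %+.2f x chl-a %+.2f x SPM  (N = %d, R2 = %.2f, p = %.3g)\n",
              x$intercept, x$coef_cdom, x$coef_chl, x$coef_spm, x$n, x$r2, x$p))
  print(x$stats)
  invisible(x)
}

#' Published regional FUI regression presets
#'
#' The two published multivariate models linking FUI to the three primary
#' colour-producing agents, with CDOM as a(440) in m^-1, chl-a in ug/L and
#' SPM in mg/L:
#' \itemize{
#'   \item `"nw_european_seas"`: FUI = 4.4 + 19.4 CDOM - 0.1 chl-a + 0.06 SPM
#'     (N = 47, R2 = 0.25, p < 0.01)
#'   \item `"west_greenland_iceland"`: FUI = 4.6 + 9.5 CDOM + 0.3 chl-a -
#'     0.05 SPM (N = 24, R2 = 0.32, p < 0.05)
#' }
#'
#' @param name Preset name.
#' @return A list of class `fu_regression` (without a stored `lm` fit).
#' @export
fui_preset_model <- function(name = c("nw_european_seas", "west_greenland_iceland")) {
  name <- match.arg(name)
  presets <- list(
    nw_european_seas = list(intercept = 4.4, coef_cdom = 19.4,
                            coef_chl = -0.1, coef_spm = 0.06,
                            r2 = 0.25, p = 0.01, n = 47),
    west_greenland_iceland = list(intercept = 4.6, coef_cdom = 9.5,
                                  coef_chl = 0.3, coef_spm = -0.05,
                                  r2 = 0.32, p = 0.05, n = 24))
  m <- presets[[name]]
  m$stats <- NULL
  m$fui_type <- "discrete"
  m$region <- name
  class(m) <- "fu_regression"
  m
}

#' Predict FUI from colour-producing agent concentrations
#'
#' Evaluates a CPA regression model (fitted with [fit_cpa_regression()] or a
#' preset from [fui_preset_model()]) and clamps the prediction to the
#' physical scale range [1, 21].
#'
#' @param m A `fu_regression`.
#' @param cdom CDOM absorption at 440 nm, m^-1, >= 0.
#' @param chl Chlorophyll-a, ug/L, >= 0.
#' @param spm Suspended particulate material, mg/L, >= 0.
#' @return Predicted FUI value(s) in [1, 21].
#' @examples
#' predict_fui_from_cpa(fui_preset_model("nw_european_seas"), 0.1, 0, 0)  # 6.34
#' @export
predict_fui_from_cpa <- function(m, cdom, chl, spm) {
  stopifnot(inherits(m, "fu_regression"))
  if (any(cdom < 0) || any(chl < 0) || any(spm < 0))
    fu_stop("CPA concentrations must be non-negative", "forelule_domain")
  pmin(pmax(m$intercept + m$coef_cdom * cdom + m$coef_chl * chl +
              m$coef_spm * spm, 1), 21)
}
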