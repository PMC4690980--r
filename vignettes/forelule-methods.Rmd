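---
title: "Deriving and validating the Forel-Ule colour index"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Deriving and validating the Forel-Ule colour index}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(forelule)
```

## The Forel-Ule colour system

The Forel-Ule index (FUI) classifies the apparent colour of natural waters on
a 21-class scale running from indigo-blue (class 1, oligotrophic ocean) to
cola brown (class 21, humic or sediment-laden water). The colour of a water
mass is set by its colour-producing agents (CPAs): coloured dissolved organic
matter (CDOM), phytoplankton chlorophyll-a, and inorganic suspended
particulate material (SPM). Because the index can be read with a cheap
handheld comparator scale, derived from remote-sensing reflectance
$R_{RS}(\lambda)$, or estimated with a smartphone app, it serves as a
low-cost, long-running proxy for optical water quality.

This package implements the full desk-side workflow: spectrum to FUI
(colorimetry), FUI against handheld readings (validation and bias
correction), FUI against water-quality variables (association and
regression), fixed-platform time series, and a synthetic-data generator that
stands in for field campaigns.

## From spectrum to index

The colorimetric chain is:

1. **Tristimulus.** $X = \int R_{RS}(\lambda)\,\bar{x}(\lambda)\,d\lambda$
   (and likewise $Y$, $Z$) with the CIE 1931 2° standard-observer
   colour-matching functions, integrated by the trapezoidal rule over
   380–720 nm. Spectra are resampled onto the 5 nm CMF grid by linear
   interpolation, never the other way round, and never extrapolated. The 5 nm
   trapezoid agrees with a 1 nm fine-grid integration to well within 0.5% on
   smooth water spectra (this is tested).
2. **Chromaticity.** $x = X/(X+Y+Z)$, $y = Y/(X+Y+Z)$; intensity cancels, so
   FUI is invariant under any positive scaling of the spectrum — a useful
   property because absolute radiometric calibration is hard and
   colour-relevant information survives it.
3. **Hue angle.** The angle of $(x - 1/3,\, y - 1/3)$ counter-clockwise from
   the positive x-axis, in $[0, 360)$. The convention is not universal in the
   colour literature; this one puts blue waters near 230° and brown waters
   near 20°, decreasing monotonically along the FU scale.
4. **Classification.** The 21 reference hue angles ship as an editable data
   file (`fu_scale_hue_angles.csv`). The discrete class is the nearest
   reference angle, with class boundaries at midpoints between successive
   references; a boundary tie goes to the lower (bluer) class, and angles
   beyond either end of the scale clamp to 1 or 21. The continuous index
   interpolates the class index piecewise-linearly in hue angle and is
   rounded to one decimal; it removes the clustering that 21 discrete levels
   impose on correlations with continuous variables. Whether the nearest
   class should instead be defined by boundary intervals in a different
   metric is genuinely open; nearest-reference-angle was chosen and is
   documented, and because classification reads the table as data, any
   revision of the scale values is a drop-in replacement.

The shipped reference angles are class-centre values consistent with
published chromaticity characterisations of the Forel-Ule standard solutions;
they are configuration, not algorithm.

A simple glint option subtracts the mean reflectance over 700–720 nm (where
clear-water reflectance is negligible) from the whole spectrum before
colorimetry; small negative values that result are floored at zero with a
warning. Full directional glint correction is out of scope.

```{r}
tabs <- load_reference_tables()
s <- generate_rrs(cpa_record("demo", cdom_a440 = 0.3, chl = 2, spm = 5))
derive_fui_from_rrs(s, cmf = tabs$cmf, scale = tabs$fu_scale)
```

## Validation statistics

Predicted values are compared with in-situ reference values through the mean
absolute percent difference (scatter) and mean percent difference (bias):

$$\psi_{mapd} = 100\,\frac{1}{N}\sum_{i=1}^{N}
  \frac{|X_{pred,i} - X_{insitu,i}|}{X_{insitu,i}}, \qquad
  \psi_{mpd} = 100\,\frac{1}{N}\sum_{i=1}^{N}
  \frac{X_{pred,i} - X_{insitu,i}}{X_{insitu,i}}.$$

Both are reported with the standard deviation of the per-point percent
differences, the "bias ± scatter" form in which field validations are usually
quoted. $|\psi_{mpd}| \le \psi_{mapd}$ always, and both are invariant under a
common positive rescaling of the two series.

Monotonic association uses the Spearman rank test (mid-ranks for ties; exact
p for $n \le 9$ without ties, t-approximation otherwise). Rank correlation is
invariant under strictly increasing transforms, which is why log-transforming
skewed concentration variables before testing changes nothing — a property
the test suite checks.

Handheld-scale readings act as the reference measurement for
reflectance-derived FUI: `fit_linear_correction()` fits
`reference ~ derived` by least squares and reports the percent-difference
statistics before and after correction, so corrected FUI can be mapped at
stations that lack a handheld observation. The correction can be fitted on
discrete or continuous derived values; the model records which it was given.

## CDOM and the CPA regressions

CDOM absorption is summarised by $a(440)$, obtained from a nonlinear
least-squares fit of $a(\lambda) = a_{275}e^{-S(\lambda-275)}$ over
275–295 nm only (the window in which the spectral slope is defined), then
extrapolated: $a_{440} = a_{275}e^{-165S}$. The fit is seeded by a log-linear
regression, so convergence on clean exponentials is immediate; a noise-free
exponential is recovered to better than 0.1%.

`fit_cpa_regression()` is ordinary least squares of FUI on CDOM (m^-1),
chl-a (µg/L) and SPM (mg/L), reporting R², the overall F-test p-value, a
collinearity warning when the design matrix condition number exceeds 1e8,
and $\psi_{mapd}/\psi_{mpd}$ of fitted versus observed FUI. Two published
regional models ship as presets:

```{r}
fui_preset_model("nw_european_seas")[c("intercept", "coef_cdom", "coef_chl", "coef_spm")]
predict_fui_from_cpa(fui_preset_model("nw_european_seas"), cdom = 0.1, chl = 0, spm = 0)
```

Predictions are clamped to the physical scale range [1, 21].

## The synthetic generator: what it emulates and what it does not

No field data ship with the package; a schematic bio-optical forward model
generates everything the other modules consume:

$$R_{RS}(\lambda) = f\,\frac{b_b(\lambda)}{a(\lambda) + b_b(\lambda)},$$

with total absorption $a = a_w + a_{CDOM} + a_{chl} + a_{NAP}$ (pure water
from a coarse packaged table; CDOM exponential with slope 0.018 nm^-1
anchored at 440 nm; a two-Gaussian chlorophyll-specific curve peaking at
440 and 675 nm; non-algal particle absorption at 0.031 m²/g with slope
0.011 nm^-1) and backscattering $b_b = b_{b,w} + b_{b,p}$ (pure seawater
power law plus SPM-driven particulate backscatter, 0.01 m²/g at 550 nm,
wavelength exponent 1). $f = 0.095$ sr^-1. These defaults are typical
coastal-water values. The model orders colours correctly — FUI is
non-decreasing in each CPA, pure water is the bluest case — and that ordering
is what the tests rely on. It is **not** radiometrically accurate: no
radiative transfer, no inelastic scattering, no bidirectional effects, no
sensor noise. Passing tests therefore demonstrate correctness of the
algorithms and the qualitative physics, not retrieval accuracy on real
spectra.

Campaign generation draws CPA concentrations uniformly within ranges spanning
clear shelf water to a turbid estuary (CDOM 0.02–1.2 m^-1, chl 0.1–10 µg/L,
SPM 0.5–50 mg/L), forward-models each station's spectrum, derives FUI, and
simulates the clarity indicators as monotone functions of the optical state:
Secchi-disk depth as $2.5/\langle a+b_b\rangle$ m and turbidity proportional
to particulate backscatter (100 NTU per m^-1), each with lognormal noise
(sd 0.15 on the log scale). These functional forms are package choices — the
field literature treats SDD and turbidity as correlated indicators without
giving closed forms — and they reproduce the expected sign structure:
FUI rises with turbidity and falls with Secchi depth.

The handheld observer shifts a reading by ±1 class with probability
`misclass_prob` (default 0.2). That default is a free assumption standing in
for subjective human colour perception, not a validated error rate. The
campaign feeds the derived *discrete* class to the observer, so with
`misclass_prob = 0` handheld and derived classes agree exactly at every
station.

The tidal series is a 12.42 h (M2) sinusoidal water level at minute
resolution with FUI driven by a resuspension term peaking at low water plus
Gaussian noise — enough structure to exercise the daylight-window hourly
averaging and level/FUI pairing, nothing more. All generators are
bit-for-bit reproducible under a seed, and every setting is recorded in the
output metadata.

## Time series and maps

`hourly_average()` restricts samples to clock hours within a daylight window
(default 08:00–16:00 UTC, inclusive of the 16:00 bin start — the "between
8:00 and 16:00" reading; configurable), bins them half-open by start hour,
and averages the *continuous* FUI — averaging discrete classes first would
discard information; rounding for display happens afterwards. Window hours
with no data are emitted as missing, and hours with fewer than half the
expected samples are flagged `low_coverage` but still reported.
`pair_with_water_level()` aligns FUI with water level on shared hours and
reports their Spearman association.

`export_station_map()` writes RFC 7946 GeoJSON point features (longitude,
latitude order) with `station`, one-decimal `fui` and a `source` label, plus
a sidecar CSV; invalid coordinates are reported per record and skipped
without aborting the export.

## Numerical choices and limitations

* Integration domain: intersection of the spectrum's range with 380–720 nm;
  spectra narrower than that raise a coverage error rather than silently
  extrapolating.
* Midpoint class ties go to the bluer class, implemented with a 1e-9
  index-space tolerance so ties computed in floating point land
  deterministically.
* The continuous index is rounded to one decimal *after* interpolation; in a
  hairline band (width 0.05 in index units) around a class boundary the
  rounded value can sit on the boundary itself while the unrounded value does
  not — consistency between discrete and continuous values is defined on the
  unrounded index.
* Problem sizes in the shipped tests (34–150 station campaigns, n = 200
  regression recovery, minute-resolution 2–6 day tidal series) were chosen so
  the whole suite runs in seconds while leaving the statistical checks
  well-powered.
* Published field results that depend on unpublished campaign data (regional
  bias percentages, observed correlation coefficients) are out of reach by
  construction; the package validates itself on generated data with known
  truth instead, and no empirical claim beyond what its own tests compute is
  made here.
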