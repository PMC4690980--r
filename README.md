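# forelule

Tools for the Forel-Ule colour index (FUI) of natural waters — the 21-class
scale running from indigo-blue (1) to cola brown (21) that has been used to
record the apparent colour of seas and lakes since the 1890s, and that today
can be derived from remote-sensing reflectance as well as read off a handheld
comparator scale.

The package is aimed at aquatic-optics and water-quality researchers who
want to:

* convert hyperspectral remote-sensing reflectance $R_{RS}(\lambda)$
  (sr⁻¹) into discrete and continuous FUI via CIE 1931 colorimetry:
  $X = \int R_{RS}\bar{x}\,d\lambda$ (likewise $Y$, $Z$), chromaticity
  $x = X/(X{+}Y{+}Z)$, the hue angle about the white point $(1/3, 1/3)$, and
  nearest-class matching against the 21 reference hue angles of the FU
  scale;
* validate derived FUI against handheld observations with the standard
  uncertainty metrics
  $\psi_{mapd} = 100\frac{1}{N}\sum|X_{pred}-X_{insitu}|/X_{insitu}$
  (scatter) and its signed counterpart $\psi_{mpd}$ (bias), and fit a linear
  bias correction;
* relate FUI to water-quality variables: Spearman rank association with
  turbidity, Secchi-disk depth and colour-producing agents (CPAs), CDOM
  $a(440)$ from the 275–295 nm spectral slope
  ($a(\lambda)=a_{275}e^{-S(\lambda-275)}$), and multivariate regressions
  FUI ~ CDOM + chl-a + SPM, including two published regional presets;
* reduce fixed-platform time series (daylight-window hourly averaging,
  FUI/water-level pairing) and export station colour maps as GeoJSON;
* generate synthetic campaigns from a simple bio-optical forward model
  $R_{RS} = f\,b_b/(a+b_b)$, so the entire pipeline is testable with no
  field data.

## Worked example

```r
library(forelule)
tabs <- load_reference_tables()

# forward-model a coastal water: CDOM a(440) = 0.3 m^-1, 2 ug/L chl, 5 mg/L SPM
s <- generate_rrs(cpa_record("demo", cdom_a440 = 0.3, chl = 2, spm = 5))
derive_fui_from_rrs(s, cmf = tabs$cmf, scale = tabs$fu_scale)
#> Forel-Ule result: hue angle 90.96 deg, FUI 9 (continuous 9.3)
```

A hue angle of 91° sits in the greenish middle of the scale; class 9 with a
continuous index of 9.3 is a typical productive coastal water.

```r
# a 34-station synthetic campaign, then validate derived FUI against the
# simulated handheld readings and fit the bias correction
camp <- generate_campaign(n_stations = 34, seed = 42)
fit_linear_correction(camp$stations$fui, camp$stations$fui_handheld)
#> FUI correction: reference = 0.987 x derived + 0.188 (n = 34, continuous FUI)
#>   before: psi_mapd = 3.6% +/- 2.8%, psi_mpd = 0.1% +/- 4.6% (n = 34)
#>   after:  psi_mapd = 3.6% +/- 2.8%, psi_mpd = 0.2% +/- 4.6% (n = 34)

spearman_assoc(camp$stations$fui, camp$stations$turbidity_ntu)
#> Spearman rho = 0.852 (N = 34, p = 1.62e-10)
spearman_assoc(camp$stations$fui, camp$stations$sdd_m)
#> Spearman rho = -0.928 (N = 34, p = 2.81e-15)
```

Colour darkens with turbidity (positive rho) and brightens with water
clarity (negative rho against Secchi-disk depth) — the sign structure seen
in field campaigns.

```r
# CDOM spectral slope on a clean exponential, extrapolated to 440 nm
wl <- seq(260, 500, 1)
fit_cdom_a440(fu_spectrum(wl, 0.5 * exp(-0.018 * (wl - 275)), kind = "absorption"))
#> CDOM fit: a(275) = 0.5000 m^-1, S = 0.01800 nm^-1, a(440) = 0.02565 m^-1

# regional preset regression: predicted FUI for CDOM-only water
predict_fui_from_cpa(fui_preset_model("nw_european_seas"), cdom = 0.1, chl = 0, spm = 0)
#> [1] 6.34
```

See `vignettes/forelule-methods.Rmd` for the model assumptions, parameter
defaults and known limitations.

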