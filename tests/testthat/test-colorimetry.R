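tabs <- load_reference_tables()
cmf <- tabs$cmf
scale <- tabs$fu_scale
vis_grid <- seq(380, 720, 5)

test_that("tristimulus integration is zero on zero, linear, and hits white on flat input", {
  zero <- fu_spectrum(vis_grid, rep(0, length(vis_grid)))
  expect_equal(unclass(tristimulus(zero, cmf)), c(X = 0, Y = 0, Z = 0))

  s <- fu_spectrum(vis_grid, 0.001 + 0.01 * exp(-((vis_grid - 490) / 50)^2))
  t1 <- unclass(tristimulus(s, cmf))
  s2 <- fu_spectrum(vis_grid, 2 * s$value)
  expect_equal(unclass(tristimulus(s2, cmf)), 2 * t1)

  # spectrally flat input must land at the equal-energy white point
  flat <- fu_spectrum(vis_grid, rep(0.01, length(vis_grid)))
  xy <- chromaticity(tristimulus(flat, cmf))
  expect_lt(max(abs(unclass(xy) - 1 / 3)), 0.005)

  narrow <- fu_spectrum(seq(400, 700, 5), rep(0.01, 61))
  expect_error(tristimulus(narrow, cmf), class = "forelule_coverage")
})

test_that("trapezoidal tristimulus agrees with a 1 nm fine-grid oracle within 0.5%", {
  for (nm in names(smooth_spectrum_funs)) {
    f <- smooth_spectrum_funs[[nm]]
    s <- fu_spectrum(vis_grid, f(vis_grid))
    got <- unclass(tristimulus(s, cmf))
    want <- oracle_tristimulus(f, cmf)
    expect_lt(max(abs(got - want) / want), 0.005, label = nm)
  }
})

test_that("chromaticity normalises intensity away", {
  expect_equal(unclass(chromaticity(c(1, 1, 1))), c(x = 1 / 3, y = 1 / 3))
  expect_equal(unclass(chromaticity(c(2, 1, 1))), c(x = 0.5, y = 0.25))
  expect_error(chromaticity(c(0, 0, 0)), class = "forelule_degenerate_colour")
})

test_that("hue angle follows the counter-clockwise convention about the white point", {
  expect_equal(hue_angle(c(1 / 3 + 0.1, 1 / 3)), 0)
  expect_equal(hue_angle(c(1 / 3, 1 / 3 + 0.1)), 90)
  expect_equal(hue_angle(c(1 / 3 - 0.1, 1 / 3)), 180)
  expect_equal(hue_angle(c(1 / 3, 1 / 3 - 0.1)), 270)
  expect_error(hue_angle(c(1 / 3, 1 / 3)), class = "forelule_undefined_hue")
})

test_that("discrete classification uses nearest reference angle with midpoint boundaries", {
  # at every reference angle the class is its own index
  expect_identical(classify_fui(scale$hue_angle_deg, scale), as.integer(scale$index))
  # exactly midway between k and k+1 ties to the lower (bluer) class k
  mids <- (scale$hue_angle_deg[-21] + scale$hue_angle_deg[-1]) / 2
  expect_identical(classify_fui(mids, scale), as.integer(1:20))
  # beyond both scale ends: clamp
  expect_identical(classify_fui(scale$hue_angle_deg[1] + 5, scale), 1L)
  expect_identical(classify_fui(350, scale), 1L)
  expect_identical(classify_fui(scale$hue_angle_deg[21] - 5, scale), 21L)
})

test_that("continuous FUI interpolates the scale and stays consistent with the discrete class", {
  expect_equal(continuous_fui(scale$hue_angle_deg, scale), as.numeric(scale$index))
  mids <- (scale$hue_angle_deg[-21] + scale$hue_angle_deg[-1]) / 2
  expect_equal(continuous_fui(mids, scale), 1:20 + 0.5)
  # clamped and one-decimal everywhere; nearest class matches classify_fui
  set.seed(101)
  angs <- runif(500, 0, 359.99)
  cont <- continuous_fui(angs, scale)
  disc <- classify_fui(angs, scale)
  expect_true(all(cont >= 1 & cont <= 21))
  expect_equal(cont, round(cont, 1))
  expect_true(all(abs(cont - disc) <= 0.5 + 1e-9))
  expect_true(all(abs(round(cont) - disc) <= 1))
  # monotone: decreasing hue angle never decreases the continuous index
  o <- order(angs, decreasing = TRUE)
  expect_true(all(diff(cont[o]) >= 0))
})

test_that("derived FUI is invariant under positive scaling of the spectrum", {
  s <- generate_rrs(data.frame(cdom_a440_m1 = 0.3, chl_ugL = 2, spm_mgL = 5))
  r1 <- derive_fui_from_rrs(s, cmf = cmf, scale = scale)
  for (c0 in c(0.01, 3, 1000)) {
    s2 <- fu_spectrum(s$wavelength_nm, c0 * s$value)
    r2 <- derive_fui_from_rrs(s2, cmf = cmf, scale = scale)
    expect_equal(r2$hue_angle_deg, r1$hue_angle_deg)
    expect_identical(r2$fui_discrete, r1$fui_discrete)
    expect_identical(r2$fui_continuous, r1$fui_continuous)
  }
})

test_that("the NIR glint null removes a constant offset", {
  s <- generate_rrs(data.frame(cdom_a440_m1 = 0.2, chl_ugL = 1, spm_mgL = 3))
  shifted <- fu_spectrum(s$wavelength_nm, s$value + 0.004)
  r0 <- suppressWarnings(derive_fui_from_rrs(s, glint_nir_null = TRUE,
                                             cmf = cmf, scale = scale))
  r1 <- suppressWarnings(derive_fui_from_rrs(shifted, glint_nir_null = TRUE,
                                             cmf = cmf, scale = scale))
  expect_equal(r1$hue_angle_deg, r0$hue_angle_deg)
  expect_identical(r1$fui_continuous, r0$fui_continuous)

  # spectrum that is all offset collapses to zero after the null
  const <- fu_spectrum(vis_grid, rep(0.004, length(vis_grid)))
  expect_error(derive_fui_from_rrs(const, glint_nir_null = TRUE,
                                   cmf = cmf, scale = scale),
               class = "forelule_degenerate_colour")
})
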