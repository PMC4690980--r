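test_that("percent-difference statistics follow their defining formulas", {
  # hand-worked: (+10% and -10%) -> mapd 10, mpd 0
  expect_equal(mapd(c(11, 9), c(10, 10)), 10)
  expect_equal(mpd(c(11, 9), c(10, 10)), 0)
  expect_equal(mapd(c(5, 7, 2), c(5, 7, 2)), 0)
  expect_equal(mpd(1.1 * c(3, 8, 40), c(3, 8, 40)), 10)

  st <- uncertainty_stats(c(11, 9), c(10, 10))
  expect_equal(st$n, 2)
  expect_equal(st$mapd_sd, 0)        # both absolute diffs are 10%
  expect_equal(st$mpd_sd, sd(c(10, -10)))

  expect_error(mapd(c(1, 2), c(1, 0)), class = "forelule_division_by_zero")
  expect_error(mapd(c(1, 2), c(1, 0)), "index 2")
  expect_error(mapd(1:3, 1:2), class = "forelule_length_mismatch")
})

test_that("mapd bounds |mpd| and both are scale invariant", {
  set.seed(11)
  for (i in 1:200) {
    n <- sample(2:30, 1)
    obs <- runif(n, 0.5, 20)
    pred <- obs * exp(rnorm(n, 0, 0.4))
    st <- uncertainty_stats(pred, obs)
    expect_gte(st$mapd, abs(st$mpd))
    expect_gte(st$mapd, 0)
    c0 <- runif(1, 0.1, 50)
    st2 <- uncertainty_stats(c0 * pred, c0 * obs)
    expect_equal(st2$mapd, st$mapd)
    expect_equal(st2$mpd, st$mpd)
  }
})

test_that("Spearman association captures monotone relationships and their sign", {
  expect_equal(spearman_assoc(c(1, 2, 3), c(2, 4, 9))$rho, 1)
  expect_equal(spearman_assoc(c(1, 2, 3), c(3, 2, 1))$rho, -1)

  # rank invariance under strictly increasing transforms (log-transform usage)
  set.seed(21)
  x <- rlnorm(40); y <- x^0.7 * exp(rnorm(40, 0, 0.3))
  a <- spearman_assoc(x, y)
  b <- spearman_assoc(log(x), y)
  expect_equal(a$rho, b$rho)
  expect_equal(a$p, b$p)

  expect_error(spearman_assoc(rep(1, 5), 1:5),
               class = "forelule_undefined_correlation")
  expect_error(spearman_assoc(1:2, 1:2), class = "forelule_insufficient_data")
})

test_that("linear FUI correction recovers exact affine relations", {
  d <- c(4, 7, 11, 15)
  m0 <- fit_linear_correction(d, d)
  expect_equal(m0$slope, 1)
  expect_equal(m0$intercept, 0)
  expect_equal(apply_correction(m0, d), d)

  m2 <- fit_linear_correction(d, d + 2)
  expect_equal(m2$slope, 1)
  expect_equal(m2$intercept, 2)

  expect_error(fit_linear_correction(c(1, 2), c(1, 2)),
               class = "forelule_insufficient_data")
  expect_error(fit_linear_correction(rep(3, 5), 1:5),
               class = "forelule_degenerate_fit")

  # corrected values are clamped to the scale
  big <- fit_linear_correction(c(10, 15, 20), c(12, 17, 22))
  expect_equal(apply_correction(big, 20), 21)
})

test_that("fitting a correction on biased synthetic pairs reduces the scatter metric", {
  set.seed(31)
  ref <- runif(30, 3, 18)
  derived <- 1.25 * ref - 1.5 + rnorm(30, 0, 0.4)
  m <- fit_linear_correction(derived, ref)
  expect_lte(m$stats_after$mapd, m$stats_before$mapd)
  expect_lt(abs(m$stats_after$mpd), abs(m$stats_before$mpd))
})

test_that("CDOM exponential fit recovers a noise-free spectrum and extrapolates a440", {
  wl <- seq(250, 500, 1)
  s <- fu_spectrum(wl, 0.5 * exp(-0.018 * (wl - 275)), kind = "absorption")
  fit <- fit_cdom_a440(s)
  expect_equal(fit$a275, 0.5, tolerance = 1e-6)
  expect_equal(fit$slope_s, 0.018, tolerance = 1e-6)
  a440_closed_form <- 0.5 * exp(-0.018 * 165)
  expect_lt(abs(fit$a440 - a440_closed_form) / a440_closed_form, 0.001)
  # internal consistency of the fitted parameters
  expect_equal(fit$a440, fit$a275 * exp(-fit$slope_s * 165))

  # recovery still close under mild noise
  set.seed(41)
  sn <- fu_spectrum(wl, 0.5 * exp(-0.018 * (wl - 275)) * exp(rnorm(length(wl), 0, 0.01)),
                    kind = "absorption")
  fn <- fit_cdom_a440(sn)
  expect_equal(fn$slope_s, 0.018, tolerance = 0.05)

  short <- fu_spectrum(seq(300, 500, 5), exp(-0.01 * seq(300, 500, 5)),
                       kind = "absorption")
  expect_error(fit_cdom_a440(short), class = "forelule_coverage")
  neg <- fu_spectrum(seq(270, 300, 1), seq(-0.1, 0.4, length.out = 31),
                     kind = "absorption")
  expect_error(fit_cdom_a440(neg), class = "forelule_domain")
  refl <- fu_spectrum(wl, 0.5 * exp(-0.018 * (wl - 275)))
  expect_error(fit_cdom_a440(refl), class = "forelule_wrong_kind")
})

test_that("CPA regression recovers generating coefficients", {
  set.seed(51)
  n <- 60
  d <- data.frame(cdom_a440_m1 = runif(n, 0, 1), chl_ugL = runif(n, 0, 10),
                  spm_mgL = runif(n, 0, 50))
  d$fui <- 4.4 + 19.4 * d$cdom_a440_m1 - 0.1 * d$chl_ugL + 0.06 * d$spm_mgL
  # lm warns that the fit is essentially perfect -- here that is the point
  m <- suppressWarnings(fit_cpa_regression(d))
  expect_equal(m$intercept, 4.4, tolerance = 1e-9)
  expect_equal(m$coef_cdom, 19.4, tolerance = 1e-9)
  expect_equal(m$coef_chl, -0.1, tolerance = 1e-9)
  expect_equal(m$coef_spm, 0.06, tolerance = 1e-9)
  expect_equal(m$r2, 1, tolerance = 1e-12)
  expect_equal(m$stats$mapd, 0, tolerance = 1e-9)

  expect_error(fit_cpa_regression(d[1:4, ]), class = "forelule_insufficient_data")
  dd <- d; dd$spm_mgL <- 2 * dd$cdom_a440_m1  # exactly collinear pair
  expect_warning(fit_cpa_regression(dd), "collinear")
})

test_that("regression coefficient estimates converge to truth as n grows", {
  truth <- c(4.4, 19.4, -0.1, 0.06)
  err <- sapply(c(50, 200, 1000), function(n) {
    set.seed(n)
    d <- data.frame(cdom_a440_m1 = runif(n, 0, 1), chl_ugL = runif(n, 0, 10),
                    spm_mgL = runif(n, 0, 50))
    d$fui <- truth[1] + truth[2] * d$cdom_a440_m1 + truth[3] * d$chl_ugL +
      truth[4] * d$spm_mgL + rnorm(n, 0, 1)
    m <- fit_cpa_regression(d)
    sqrt(sum((c(m$intercept, m$coef_cdom, m$coef_chl, m$coef_spm) - truth)^2))
  })
  expect_true(all(diff(err) < 0))
})

test_that("preset regional models evaluate and clamp correctly", {
  nw <- fui_preset_model("nw_european_seas")
  wg <- fui_preset_model("west_greenland_iceland")
  expect_identical(predict_fui_from_cpa(nw, 0, 0, 0), 4.4)
  expect_identical(predict_fui_from_cpa(wg, 0, 0, 0), 4.6)
  expect_equal(predict_fui_from_cpa(nw, 0.1, 0, 0), 6.34)
  # high-CDOM water clamps at the brown end of the scale
  expect_equal(predict_fui_from_cpa(nw, 2, 0, 0), 21)
  expect_error(predict_fui_from_cpa(nw, -0.1, 0, 0), class = "forelule_domain")
})
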