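# Spectrum estimation, normalization and the QUS parameter estimators.

test_that("periodogram peaks at the tone frequency and handles edge cases", {
  g <- fix_geom()
  n <- n_axial_samples(g)
  t <- (0:(n - 1)) / g$sampling_rate
  fr <- structure(list(samples = matrix(sin(2 * pi * 8e6 * t), n, 8),
                       geometry = g, truth = NULL), class = "rf_frame")
  sp <- compute_power_spectrum(fr, list(axial = c(0.4, 1.0),
                                        lateral = c(0, 0.05)))
  expect_equal(sp$freq[which.max(sp$power)], 8, tolerance = 0.1)
  # all-zero window -> all-zero spectrum
  fr$samples[] <- 0
  sp0 <- compute_power_spectrum(fr, list(axial = c(0.4, 1.0),
                                         lateral = c(0, 0.05)))
  expect_true(all(sp0$power == 0))
  # window below the 16-sample floor
  expect_error(compute_power_spectrum(fr, list(axial = c(0.4, 0.4005),
                                               lateral = c(0, 0.05))),
               "window too small")
})

test_that("averaging periodograms over L lines shrinks variance like 1/L", {
  g <- fix_geom()
  set.seed(11)
  n <- n_axial_samples(g)
  fr <- structure(list(samples = matrix(rnorm(n * g$n_lines), n, g$n_lines),
                       geometry = g, truth = NULL), class = "rf_frame")
  var_of <- function(lat_hi) {
    sp <- compute_power_spectrum(fr, list(axial = c(0.3, 1.9),
                                          lateral = c(0, lat_hi)))
    k <- sp$freq > 2 & sp$freq < 18
    stats::var(sp$power[k]) / mean(sp$power[k])^2
  }
  v2 <- var_of(0.07)    # 2-3 lines
  v48 <- var_of(1.44)   # all 48 lines
  expect_gt(v2 / v48, 8) # ~16x expected; well above 8 with sampling noise
})

test_that("normalization is exact dB arithmetic and validates grids", {
  f <- seq(4, 12, by = 0.1)
  mk <- function(p) structure(list(freq = f, power = p, db = FALSE,
                                   n_lines = 10, center = c(1, 1)),
                              class = "power_spectrum")
  s <- mk(rep(2, length(f)))
  expect_true(all(normalize_spectrum(s, s)$power == 0))
  expect_equal(normalize_spectrum(mk(rep(20, length(f))), s)$power,
               rep(10, length(f)))
  # constructed dB-linear tilt recovered exactly by least squares
  b <- 0.7
  tilted <- mk(2 * 10^(b * f / 10))
  nps <- normalize_spectrum(tilted, s)
  fit <- stats::lm(nps$power ~ nps$freq)
  expect_equal(unname(stats::coef(fit)[2]), b, tolerance = 1e-10)
  # grid mismatch and zero reference bins
  s2 <- mk(rep(2, length(f))); s2$freq <- f + 0.01
  expect_error(normalize_spectrum(s, s2), "grid mismatch")
  z <- mk(c(0, rep(2, length(f) - 1)))
  expect_error(normalize_spectrum(s, z), "zero reference")
})

test_that("linear spectral fit is exact on exact lines and MBF = SI + SS*fc", {
  f <- seq(4, 12, length.out = 65)
  nps <- structure(list(freq = f, power = 2 + 0.5 * f, db = TRUE,
                        n_lines = 10, center = c(1, 1)),
                   class = "power_spectrum")
  fit <- fit_linear_spectral_params(nps, c(4, 12))
  expect_equal(fit$SI, 2); expect_equal(fit$SS, 0.5); expect_equal(fit$MBF, 6)
  # flat zero spectrum
  nps$power <- rep(0, length(f))
  fit0 <- fit_linear_spectral_params(nps, c(4, 12))
  expect_equal(unlist(fit0[c("MBF", "SS", "SI")]), c(MBF = 0, SS = 0, SI = 0))
  # noisy line matches the closed-form normal-equations oracle
  set.seed(3)
  nps$power <- 1.5 - 0.3 * f + rnorm(length(f), 0, 0.5)
  fit <- fit_linear_spectral_params(nps, c(4, 12))
  X <- cbind(1, f)
  beta <- solve(t(X) %*% X, t(X) %*% nps$power)
  expect_equal(fit$SI, beta[1], tolerance = 1e-12)
  expect_equal(fit$SS, beta[2], tolerance = 1e-12)
  expect_equal(fit$MBF, fit$SI + fit$SS * 8, tolerance = 1e-12)
  expect_error(fit_linear_spectral_params(nps, c(4, 4.05)), "degenerate band")
})

test_that("attenuation compensation is exact arithmetic with identity cases", {
  f <- seq(4, 12, by = 0.25)
  nps <- structure(list(freq = f, power = rnorm(length(f)), db = TRUE,
                        n_lines = 5, center = c(2, 1)),
                   class = "power_spectrum")
  expect_equal(compensate_attenuation(nps, 0.576, 0.576, 2)$power, nps$power)
  expect_equal(compensate_attenuation(nps, 1.0, 0.576, 0)$power, nps$power)
  out <- compensate_attenuation(nps, 1.0, 0.576, 2)
  expect_equal(out$power, nps$power + 2 * (1 - 0.576) * f * 2)
})

test_that("ACE recovers planted attenuation and round-trips to zero slope", {
  g <- fix_geom()
  ref <- fix_ref()
  roi <- roi_rect(c(0.45, 1.85), c(0.15, 1.3))
  ws <- window_spec(2, 2, 0.5)
  fld <- make_scatterer_field("random", density = 1000, diameter = 0,
                              geometry = g, seed = 51)
  planted <- c(0.576, 1.0, 0.05)
  for (a in planted) {
    fr <- simulate_rf_frame(fld, g, attenuation = a, seed = 52)
    ace <- estimate_ace(fr, ref, roi, ws)
    expect_equal(as.numeric(ace), a, tolerance = max(0.15 * a, 0.06))
  }
  # single-depth ROI rejected
  expect_error(estimate_ace(simulate_rf_frame(fld, g, seed = 1), ref,
                            roi_rect(c(0.9, 1.12), c(0.15, 1.3)), ws),
               "insufficient depth span|fit")
})

test_that("BSC estimation applies the reference law exactly", {
  f <- seq(4, 12, by = 0.25)
  mk_nps <- function(p) structure(list(freq = f, power = p, db = TRUE,
                                       n_lines = 5, center = c(2, 1)),
                                  class = "power_spectrum")
  flat <- reference_phantom(backscatter_law = "flat")
  b0 <- estimate_bsc(mk_nps(rep(0, length(f))), flat)
  expect_equal(b0$power, rep(1, length(f)))
  b3 <- estimate_bsc(mk_nps(rep(3, length(f))), flat)
  expect_equal(b3$power, rep(10^0.3, length(f)))
  ray <- reference_phantom()
  expect_equal(estimate_bsc(mk_nps(rep(0, length(f))), ray)$power, f^4)
})

test_that("Gaussian form-factor inversion is exact on the analytic model", {
  f <- seq(4, 12, by = 0.1)
  cs <- 1540
  k <- 2 * pi * f * 1e6 / cs
  a <- 12.5e-6
  C <- 3.7
  bsc <- structure(list(freq = f, power = C * f^4 * exp(-0.827 * k^2 * a^2),
                        db = FALSE, n_lines = 5, center = c(2, 1)),
                   class = "power_spectrum")
  fit <- fit_gaussian_form_factor(bsc, c(4, 12), cs)
  expect_equal(fit$ASD, 25, tolerance = 1e-9)
  expect_equal(fit$AAC, 10 * log10(C), tolerance = 1e-9)
  # x10 concentration: +10 dB AAC, ASD unchanged
  bsc10 <- bsc; bsc10$power <- 10 * bsc$power
  fit10 <- fit_gaussian_form_factor(bsc10, c(4, 12), cs)
  expect_equal(fit10$AAC - fit$AAC, 10, tolerance = 1e-9)
  expect_equal(fit10$ASD, fit$ASD, tolerance = 1e-9)
  # nonphysical positive slope flagged, ASD 0
  bad <- bsc; bad$power <- f^4 * exp(+0.827 * k^2 * a^2)
  expect_warning(fitb <- fit_gaussian_form_factor(bad, c(4, 12), cs),
                 "positive")
  expect_equal(fitb$ASD, 0)
  expect_true(fitb$nonphysical)
})

test_that("Burg AR spacing analysis inverts an exact cosine ripple", {
  df <- 0.05
  f <- seq(3, 13, by = df)
  ripple <- 1 + 0.5 * cos(2 * pi * f / 2.567)   # period 2.567 MHz
  sp <- structure(list(freq = f, power = ripple, db = FALSE, n_lines = 5,
                       center = c(1, 1)), class = "power_spectrum")
  sas <- estimate_sas(sp, ar_order = 10, speed_of_sound = 1540)
  expect_equal(as.numeric(sas), 1540 / (2 * 2.567e6) * 1000,
               tolerance = 0.02)
  expect_true(attr(sas, "reliable"))
  expect_error(estimate_sas(sp, ar_order = 60), "too short")
})

test_that("spacing is recovered from lattice RF but dispersed on random RF", {
  g <- fix_geom()
  ref <- fix_ref()
  roi <- fix_roi()
  ms_lat <- build_parametric_maps(fix_frame_lattice(), ref, roi,
                                  window_spec(2, 2, 0.5))
  sas_lat <- ms_lat$maps$SAS[ms_lat$roi_mask]
  expect_equal(stats::median(sas_lat, na.rm = TRUE), 0.30, tolerance = 0.10)
  # fully random field: window estimates far more dispersed than the lattice
  ms_rnd <- fix_maps_diffuse()
  sas_rnd <- ms_rnd$maps$SAS[ms_rnd$roi_mask]
  cv <- function(v) stats::sd(v, na.rm = TRUE) / mean(v, na.rm = TRUE)
  expect_gt(cv(sas_rnd), 2 * cv(sas_lat))
})

test_that("normalization cancels the transmit pulse", {
  # two pulse shapes, same tissue: normalized spectra agree within speckle
  g1 <- fix_geom()
  g2 <- g1; g2$bandwidth <- 0.45
  roi <- list(axial = c(0.6, 1.6), lateral = c(0.1, 1.3))
  tilt_of <- function(g) {
    ref <- simulate_reference_frame(reference_phantom(), g,
                                    noise_floor = Inf, seed = 61)
    fld <- make_scatterer_field("random", density = 1000, diameter = 35,
                                geometry = g, seed = 62)
    fr <- simulate_rf_frame(fld, g, attenuation = 0.576, noise_floor = Inf,
                            seed = 63)
    nps <- normalize_spectrum(compute_power_spectrum(fr, roi),
                              compute_power_spectrum(ref, roi),
                              band = c(6, 10))
    unname(stats::coef(stats::lm(nps$power ~ nps$freq))[2])
  }
  t1 <- tilt_of(g1); t2 <- tilt_of(g2)
  expect_equal(t1, t2, tolerance = 0.15)
})
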