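# The seven QUS parameter estimators.
#
# Attenuation convention used throughout: an attenuation coefficient alpha in
# dB/MHz/cm is a one-way loss, so echo POWER received from depth z (cm) at
# frequency f (MHz) is reduced by 2 * alpha * f * z dB (round trip). The
# normalized spectrum therefore decays with depth as
#   NPS(f, z) = B(f) - 2 * (alpha_sample - alpha_ref) * f * z   [dB],
# which is what estimate_ace() inverts and compensate_attenuation() adds back.

#' Estimate the attenuation coefficient (ACE) by the reference-phantom method
#'
#' Pools uncompensated normalized spectra from all in-ROI windows and fits the
#' depth decay: with a free intercept per frequency bin, the common slope of
#' `NPS(f, z)` against `f * z` equals `-2 (alpha_sample - alpha_ref)`, giving
#' a single frame-level ACE. The estimate is clamped to the physical range
#' [0, 3] dB/MHz/cm.
#'
#' @param frame,reference_frame Sample and reference `rf_frame`s (same
#'   geometry).
#' @param roi A `qus_roi`.
#' @param window A `window_spec`.
#' @param band Analysis band in MHz; default the reference -6 dB band.
#' @return ACE in dB/MHz/cm, with attributes `slope` (dB per MHz*cm) and
#'   `n_windows`.
#' @export
estimate_ace <- function(frame, reference_frame, roi,
                         window = window_spec(), band = NULL) {
  if (is.null(band)) band <- analysis_band(reference_frame)
  grid <- window_grid(frame$geometry, roi, window)
  if (nrow(grid$centers) == 0) stop("empty ROI")
  nps <- vector("list", nrow(grid$centers))
  z <- numeric(nrow(grid$centers))
  for (i in seq_len(nrow(grid$centers))) {
    reg <- grid$regions[[i]]
    s <- compute_power_spectrum(frame, reg)
    r <- compute_power_spectrum(reference_frame, reg)
    nps[[i]] <- normalize_spectrum(s, r, band)
    z[i] <- mean(reg$axial)
  }
  if (length(unique(round(z, 6))) < 2) stop("insufficient depth span")
  f <- nps[[1]]$freq
  Y <- vapply(nps, `[[`, numeric(length(f)), "power")  # bins x windows
  zc <- z - mean(z)
  num <- sum(f * ((Y - rowMeans(Y)) %*% zc))
  den <- sum(f^2) * sum(zc^2)
  slope <- num / den                      # d NPS / d (f z)
  ace <- frame_ref_attenuation(reference_frame) - slope / 2
  structure(min(3, max(0, ace)), slope = slope, n_windows = length(z))
}

frame_ref_attenuation <- function(reference_frame) {
  ph <- reference_frame$truth$phantom
  if (!is.null(ph)) ph$attenuation else reference_frame$truth$attenuation
}

#' Point attenuation compensation of a normalized spectrum
#'
#' Adds back the round-trip attenuation difference at the window-centre depth:
#' `+ 2 (ace - alpha_ref) * f * depth` dB at each frequency.
#'
#' @param nps A dB `power_spectrum` (normalized).
#' @param ace Sample attenuation estimate, dB/MHz/cm.
#' @param reference_attenuation Phantom attenuation, dB/MHz/cm.
#' @param depth Window-centre depth in cm (>= 0).
#' @return The compensated dB `power_spectrum`.
#' @export
compensate_attenuation <- function(nps, ace, reference_attenuation, depth) {
  stopifnot(isTRUE(nps$db), depth >= 0)
  nps$power <- nps$power + 2 * (ace - reference_attenuation) * nps$freq * depth
  nps
}

#' Linear-fit spectral parameters: mid-band fit, slope, intercept
#'
#' Ordinary least squares `NPS(f) = SI + SS * f` over the analysis band;
#' the mid-band fit is the fitted value at the band centre, so
#' `MBF = SI + SS * f_c` holds exactly.
#'
#' @param nps A dB `power_spectrum`.
#' @param band Length-2 band in MHz.
#' @return List with `MBF` (dB), `SS` (dB/MHz), `SI` (dB), `band`.
#' @export
fit_linear_spectral_params <- function(nps, band) {
  stopifnot(isTRUE(nps$db))
  keep <- nps$freq >= band[1] & nps$freq <= band[2]
  f <- nps$freq[keep]; y <- nps$power[keep]
  if (length(f) < 3 || diff(range(f)) == 0) stop("degenerate band")
  fm <- mean(f)
  ss <- sum((f - fm) * (y - mean(y))) / sum((f - fm)^2)
  si <- mean(y) - ss * fm
  fc <- mean(band)
  list(MBF = si + ss * fc, SS = ss, SI = si, band = band)
}

#' Backscatter coefficient from a compensated normalized spectrum
#'
#' `BSC_sample(f) = BSC_ref(f) * 10^(NPS_comp(f) / 10)`, where the reference
#' law comes from the phantom description: `"flat"` (constant), `"rayleigh"`
#' (proportional to f^4), or `"gaussian"` (f^4 times a Gaussian form factor).
#' Relative units; absolute calibration cancels in delta features.
#'
#' @param nps_compensated A dB `power_spectrum` after attenuation compensation.
#' @param phantom A `qus_phantom` carrying the backscatter law.
#' @return A `power_spectrum` with linear `power` holding the BSC.
#' @export
estimate_bsc <- function(nps_compensated, phantom) {
  stopifnot(isTRUE(nps_compensated$db))
  f <- nps_compensated$freq
  ref <- switch(phantom$backscatter_law,
                flat = rep(1, length(f)),
                rayleigh = f^4,
                gaussian = {
                  k <- 2 * pi * f * 1e6 / phantom$speed_of_sound
                  f^4 * exp(-0.827 * k^2 * (phantom$a_eff_um * 1e-6)^2)
                },
                stop("unknown reference backscatter law"))
  structure(list(freq = f, power = ref * 10^(nps_compensated$power / 10),
                 db = FALSE, n_lines = nps_compensated$n_lines,
                 center = nps_compensated$center),
            class = "power_spectrum")
}

#' Fit a spherical Gaussian form factor: scatterer diameter and concentration
#'
#' Under the Insana-Hall model `BSC(f) = C f^4 exp(-0.827 k^2 a_eff^2)`,
#' a linear fit of `ln BSC(f) - 4 ln f` against `k^2` (k = 2 pi f / c, rad/m)
#' has slope `-0.827 a_eff^2`. The average scatterer diameter is
#' `ASD = 2 a_eff` and the average acoustic concentration is reported as
#' `AAC = 10 log10(C)` dB (C from the fit intercept, with f in MHz; the
#' multiplicative Insana-Hall constant is absorbed into C and cancels in
#' delta features).
#'
#' @param bsc A linear `power_spectrum` holding the BSC.
#' @param band Length-2 band in MHz.
#' @param speed_of_sound Speed of sound in m/s.
#' @return List with `ASD` (micrometres), `AAC` (dB), and `nonphysical`
#'   (TRUE when the slope was positive and ASD is reported as 0).
#' @export
fit_gaussian_form_factor <- function(bsc, band, speed_of_sound = 1540) {
  stopifnot(!isTRUE(bsc$db))
  keep <- bsc$freq >= band[1] & bsc$freq <= band[2] & bsc$power > 0
  f <- bsc$freq[keep]
  if (length(f) < 3) stop("degenerate band")
  k2 <- (2 * pi * f * 1e6 / speed_of_sound)^2
  y <- log(bsc$power[keep]) - 4 * log(f)
  xm <- mean(k2)
  slope <- sum((k2 - xm) * (y - mean(y))) / sum((k2 - xm)^2)
  intercept <- mean(y) - slope * xm
  nonphys <- slope > 0
  a_eff <- if (nonphys) 0 else sqrt(-slope / 0.827)   # metres
  if (nonphys) warning("positive form-factor slope; ASD reported as 0")
  list(ASD = 2 * a_eff * 1e6, AAC = 10 * intercept / log(10),
       nonphysical = nonphys)
}

#' Mean scatterer spacing from the spectral ripple (Burg AR method)
#'
#' Quasi-regular scatterer spacing d produces a ripple of period
#' `delta_f = c / (2 d)` in the backscatter power spectrum. The mean-removed
#' spectrum, viewed as a pseudo-time series sampled every `df` MHz, is fitted
#' with an autoregressive model by Burg's recursive algorithm; the dominant AR
#' spectral peak at "quefrency" q (cycles per MHz) gives `delta_f = 1/q` and
#' `SAS = c / (2 delta_f)`.
#'
#' @param spectrum A `power_spectrum` (linear power; a dB spectrum is used
#'   as-is on its dB scale, which leaves the ripple period unchanged).
#' @param ar_order Burg model order (default 10).
#' @param speed_of_sound Speed of sound in m/s.
#' @param band Optional band (MHz) to restrict the ripple analysis to.
#' @param peak_snr Minimum ratio of the AR peak to the median AR spectrum for
#'   the estimate to be considered reliable.
#' @return SAS in mm, with attributes `delta_f` (MHz) and `reliable`.
#' @export
estimate_sas <- function(spectrum, ar_order = 10, speed_of_sound = 1540,
                         band = NULL, peak_snr = 2) {
  stopifnot(ar_order >= 2)
  f <- spectrum$freq; p <- spectrum$power
  if (!is.null(band)) {
    keep <- f >= band[1] & f <= band[2]
    f <- f[keep]; p <- p[keep]
  }
  if (length(p) < 4 * ar_order) stop("spectrum too short for the AR order")
  df <- f[2] - f[1]
  x <- stats::residuals(stats::lm(p ~ f))    # remove mean and linear trend
  fit <- stats::ar.burg(x, aic = FALSE, order.max = ar_order, demean = TRUE)
  q <- seq(1e-4, 1 / (2 * df), length.out = 2048)   # cycles per MHz
  ar_psd <- function(q) {
    E <- exp(-2i * pi * outer(q * df, seq_len(ar_order)))
    fit$var.pred / Mod(1 - as.vector(E %*% fit$ar))^2
  }
  psd <- ar_psd(q)
  # exclude periods longer than the analysed band (under one ripple cycle)
  valid <- q >= 1 / diff(range(f))
  if (!any(valid)) stop("band too narrow for spacing analysis")
  pk <- which(valid)[which.max(psd[valid])]
  delta_f <- 1 / q[pk]
  reliable <- psd[pk] / stats::median(psd) >= peak_snr
  if (!reliable) warning("no dominant AR spectral peak; SAS flagged unreliable")
  sas_mm <- speed_of_sound / (2 * delta_f * 1e6) * 1000
  structure(sas_mm, delta_f = delta_f, reliable = reliable)
}
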