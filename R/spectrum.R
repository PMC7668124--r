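# Power-spectrum estimation and reference-phantom normalization.

#' Sliding-window specification
#'
#' @param axial Axial window extent in mm (default 2).
#' @param lateral Lateral window extent in mm (default 2).
#' @param overlap Fractional overlap between adjacent windows in both axes
#'   (default 0.94, i.e. a 0.12 mm step for a 2 mm window).
#' @return An object of class `window_spec`.
#' @export
window_spec <- function(axial = 2, lateral = 2, overlap = 0.94) {
  stopifnot(axial > 0, lateral > 0, overlap >= 0, overlap < 1)
  structure(list(axial = axial, lateral = lateral, overlap = overlap),
            class = "window_spec")
}

hann_window <- function(m) {
  if (m == 1) return(1)
  0.5 - 0.5 * cos(2 * pi * (0:(m - 1)) / (m - 1))
}

# convert a window region in cm to sample-row / line-column index ranges;
# enforces the minimum usable window (16 axial samples, 2 lines)
window_indices <- function(geometry, window) {
  n <- n_axial_samples(geometry)
  fs <- geometry$sampling_rate
  c_ms <- geometry$speed_of_sound
  r0 <- floor(window$axial[1] / 100 * 2 / c_ms * fs) + 1
  r1 <- ceiling(window$axial[2] / 100 * 2 / c_ms * fs)
  r0 <- max(1L, as.integer(r0)); r1 <- min(n, as.integer(r1))
  if (r1 - r0 + 1 < 16) stop("window too small")
  pitch <- lateral_pitch(geometry)
  c0 <- max(1L, as.integer(floor(window$lateral[1] / pitch)) + 1L)
  c1 <- min(geometry$n_lines, as.integer(ceiling(window$lateral[2] / pitch)))
  if (c1 < c0) stop("window too small")
  list(rows = r0:r1, cols = c0:c1)
}

#' Mean periodogram of an RF window
#'
#' Per scan line in the window, the mean is removed, the stated taper applied,
#' and the periodogram computed on an `nfft`-point grid; line periodograms are
#' averaged. Power is in linear (arbitrary) units.
#'
#' @param frame An `rf_frame`.
#' @param window List with `axial` and `lateral` length-2 ranges in cm.
#' @param taper `"hann"` (default) or `"rect"`.
#' @param nfft FFT length; default the next power of two of the axial sample
#'   count, at least 512 (zero-padded for a fine frequency grid).
#' @return An object of class `power_spectrum` with `freq` (MHz), `power`
#'   (linear), `db = FALSE`, `n_lines`, and `center` (axial, lateral in cm).
#' @export
compute_power_spectrum <- function(frame, window, taper = c("hann", "rect"),
                                   nfft = NULL) {
  taper <- match.arg(taper)
  wi <- window_indices(frame$geometry, window)
  x <- frame$samples[wi$rows, wi$cols, drop = FALSE]
  m <- nrow(x)
  if (is.null(nfft)) nfft <- max(512L, 2^ceiling(log2(m)))
  w <- if (taper == "hann") hann_window(m) else rep(1, m)
  xw <- (x - rep(colMeans(x), each = m)) * w
  pad <- rbind(xw, matrix(0, nfft - m, ncol(xw)))
  sp <- stats::mvfft(pad)
  nf <- nfft %/% 2 + 1
  pgram <- Mod(sp[seq_len(nf), , drop = FALSE])^2 / sum(w^2)
  structure(list(freq = (seq_len(nf) - 1) * frame$geometry$sampling_rate / nfft / 1e6,
                 power = rowMeans(pgram), db = FALSE,
                 n_lines = ncol(x),
                 center = c(mean(window$axial), mean(window$lateral))),
            class = "power_spectrum")
}

#' Normalize a sample spectrum by a reference-phantom spectrum
#'
#' Forms the normalized power spectrum `NPS(f) = 10 log10(S_sample / S_ref)`
#' in dB, cancelling the system and transducer responses. Frequency grids must
#' be identical; the reference must be strictly positive on the requested band.
#'
#' @param sample,reference `power_spectrum` objects on the same grid (linear).
#' @param band Optional length-2 band (MHz) to restrict to.
#' @return A `power_spectrum` with `db = TRUE`.
#' @export
normalize_spectrum <- function(sample, reference, band = NULL) {
  if (length(sample$freq) != length(reference$freq) ||
      max(abs(sample$freq - reference$freq)) > 1e-9)
    stop("frequency grid mismatch")
  keep <- if (is.null(band)) rep(TRUE, length(sample$freq))
          else sample$freq >= band[1] & sample$freq <= band[2]
  if (!any(keep)) stop("empty band")
  if (any(reference$power[keep] <= 0)) stop("zero reference bin in band")
  structure(list(freq = sample$freq[keep],
                 power = 10 * log10(sample$power[keep] / reference$power[keep]),
                 db = TRUE, n_lines = sample$n_lines, center = sample$center),
            class = "power_spectrum")
}

#' Analysis band from a reference frame
#'
#' The usable band is taken where the mean reference-phantom spectrum is
#' within `drop_db` of its peak (default -10 dB), evaluated over a central
#' region of the frame. The -10 dB width trades a wider fitting lever arm for
#' the form-factor and attenuation fits against band-edge noise.
#'
#' @param reference_frame An `rf_frame` from [simulate_reference_frame()].
#' @param drop_db Band edge level below the spectral peak, in dB.
#' @return Length-2 numeric band in MHz.
#' @export
analysis_band <- function(reference_frame, drop_db = 10) {
  g <- reference_frame$geometry
  win <- list(axial = c(0.25, 0.75) * g$depth,
              lateral = c(0.25, 0.75) * g$lateral_width)
  sp <- compute_power_spectrum(reference_frame, win)
  pk <- which.max(sp$power)
  thr <- sp$power[pk] * 10^(-drop_db / 10)
  lo <- pk; while (lo > 1 && sp$power[lo - 1] >= thr) lo <- lo - 1
  hi <- pk; while (hi < length(sp$power) && sp$power[hi + 1] >= thr) hi <- hi + 1
  c(sp$freq[lo], sp$freq[hi])
}
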