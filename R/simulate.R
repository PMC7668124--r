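# RF frame synthesis: 1-D per-line convolutional model built in the frequency
# domain, so that frequency-dependent attenuation and the Gaussian form factor
# are applied exactly per echo.

# inverse real FFT: S is the positive-frequency half-spectrum (length
# floor(n/2)+1); returns a real signal of length n
irfft <- function(S, n) {
  nf <- length(S)
  stopifnot(nf == n %/% 2 + 1)
  X <- complex(n)
  X[seq_len(nf)] <- S
  X[1] <- complex(real = Re(S[1]))
  if (n %% 2 == 0) X[nf] <- complex(real = Re(S[nf]))
  ks <- 2:(nf - (if (n %% 2 == 0) 1 else 0))
  X[n + 2 - ks] <- Conj(X[ks])
  Re(stats::fft(X, inverse = TRUE)) / n
}

# Gaussian pulse magnitude spectrum on a frequency grid (Hz); bandwidth is the
# fractional -6 dB (half-amplitude) width around f0
pulse_spectrum <- function(f, f0, bandwidth) {
  sigma <- bandwidth * f0 / (2 * sqrt(2 * log(2)))
  exp(-(f - f0)^2 / (2 * sigma^2))
}

# Gaussian form-factor amplitude for effective radius a_eff (m); k in rad/m
form_factor_amplitude <- function(k, a_eff_m) exp(-0.827 * k^2 * a_eff_m^2 / 2)

#' Simulate a beamformed RF frame from a scatterer field
#'
#' Per scan line, each scatterer contributes a Gaussian-modulated echo delayed
#' by its round-trip travel time. Echo spectra are shaped exactly in the
#' frequency domain by (i) two-way frequency-dependent attenuation
#' `10^(-attenuation * f_MHz * 2 z_cm / 20)` (an amplitude factor, i.e. one-way
#' power loss of `attenuation` dB per MHz per cm), and (ii) the Gaussian
#' form-factor amplitude `exp(-0.827 k^2 a_eff^2 / 2)` for effective radius
#' `a_eff = diameter / 2`. Echo amplitudes scale with the square root of the
#' acoustic concentration, so mean RF power is proportional to concentration.
#' White Gaussian noise is added at `noise_floor` dB below the mean echo power.
#'
#' @param field A `scatterer_field`.
#' @param geometry A `qus_geometry`; the field must fit inside it.
#' @param attenuation Medium attenuation in dB/MHz/cm (one-way); must be >= 0.
#' @param noise_floor Noise power relative to mean signal power, in dB
#'   (positive number of dB below signal). `Inf` disables noise.
#' @param seed Integer seed for the noise draw.
#'
#' @return An object of class `rf_frame`: `samples` (axial sample x scan line
#'   matrix), `geometry`, and a `truth` list recording the field and the
#'   attenuation used.
#' @export
simulate_rf_frame <- function(field, geometry = acq_geometry(),
                              attenuation = 0.576, noise_floor = 30,
                              seed = 1) {
  if (attenuation < 0) stop("attenuation must be non-negative")
  pos <- field$positions
  if (any(pos[, 1] < 0 | pos[, 1] > geometry$depth |
          pos[, 2] < 0 | pos[, 2] > geometry$lateral_width))
    stop("scatterer field does not fit inside the geometry")

  n <- n_axial_samples(geometry)
  nf <- n %/% 2 + 1
  fs <- geometry$sampling_rate
  f <- (seq_len(nf) - 1) * fs / n              # Hz
  fMHz <- f / 1e6
  c_ms <- geometry$speed_of_sound
  pulse <- pulse_spectrum(f, geometry$center_frequency, geometry$bandwidth)
  a_eff_m <- field$effective_diameter * 1e-6 / 2
  ff <- form_factor_amplitude(2 * pi * f / c_ms, a_eff_m)
  shape <- pulse * ff

  # per-echo factor exp(g(f) * z_cm): phase delay for round-trip 2z plus
  # two-way attenuation, both proportional to depth z
  gz <- complex(real = -log(10) * attenuation * 2 / 20 * fMHz,
                imaginary = -2 * pi * f * 2 / (100 * c_ms))

  pitch <- lateral_pitch(geometry)
  line_of <- pmin(geometry$n_lines, pmax(1L, ceiling(pos[, 2] / pitch)))
  amp <- field$amplitudes * sqrt(field$acoustic_concentration)

  rf <- matrix(0, n, geometry$n_lines)
  for (j in unique(line_of)) {
    idx <- which(line_of == j)
    z <- pos[idx, 1]
    S <- shape * as.vector(exp(outer(gz, z)) %*% amp[idx])
    rf[, j] <- irfft(S, n)
  }

  if (is.finite(noise_floor)) {
    set.seed(as.integer(seed))
    sig_pow <- mean(rf^2)
    if (sig_pow > 0) {
      sd_n <- sqrt(sig_pow * 10^(-noise_floor / 10))
      rf <- rf + matrix(stats::rnorm(length(rf), 0, sd_n), nrow(rf))
    }
  }

  structure(list(samples = rf, geometry = geometry,
                 truth = list(field = field, attenuation = attenuation,
                              noise_floor = noise_floor)),
            class = "rf_frame")
}

#' Simulate a reference-phantom RF frame
#'
#' A dense random field of point scatterers (diameter 0, unit concentration)
#' imaged with the same geometry as the patient scan, attenuated at the
#' phantom's known coefficient. Used to normalize sample spectra so that the
#' system transfer function cancels.
#'
#' @param phantom A `qus_phantom`.
#' @param geometry A `qus_geometry`.
#' @param density Scatterers per cm^2 for the phantom field.
#' @param noise_floor Noise level in dB below signal (as in
#'   [simulate_rf_frame()]).
#' @param seed Integer seed.
#' @return An `rf_frame` whose `truth$phantom` records the phantom.
#' @export
simulate_reference_frame <- function(phantom = reference_phantom(),
                                     geometry = acq_geometry(),
                                     density = 2000, noise_floor = 40,
                                     seed = 1) {
  geom_ref <- geometry
  geom_ref$speed_of_sound <- phantom$speed_of_sound
  field <- make_scatterer_field("random", density = density, diameter = 0,
                                concentration = 1, geometry = geom_ref,
                                seed = seed)
  fr <- simulate_rf_frame(field, geom_ref, attenuation = phantom$attenuation,
                          noise_floor = noise_floor,
                          seed = as.integer((as.numeric(seed) + 104729) %% 2147483646) + 1L)
  fr$truth$phantom <- phantom
  fr
}

#' @export
print.rf_frame <- function(x, ...) {
  cat(sprintf("rf_frame: %d samples x %d lines", nrow(x$samples), ncol(x$samples)))
  if (!is.null(x$truth$attenuation))
    cat(sprintf(" | attenuation %.3f dB/MHz/cm", x$truth$attenuation))
  cat("\n")
  invisible(x)
}

#' Write an RF frame to a portable text container
#'
#' The sample matrix goes to `rf.tsv` (tab-separated, one row per axial
#' sample) and the acquisition metadata (plus ground truth, if present) to
#' `meta.json` inside `dir`.
#'
#' @param frame An `rf_frame`.
#' @param dir Directory to create/write into.
#' @return `dir`, invisibly.
#' @export
write_rf_frame <- function(frame, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.table(frame$samples, file.path(dir, "rf.tsv"), sep = "\t",
                     row.names = FALSE, col.names = FALSE)
  g <- frame$geometry
  meta <- list(sampling_rate_hz = g$sampling_rate, n_lines = g$n_lines,
               lateral_width_cm = g$lateral_width, depth_cm = g$depth,
               center_frequency_hz = g$center_frequency,
               bandwidth = g$bandwidth, speed_mps = g$speed_of_sound)
  if (!is.null(frame$truth$attenuation))
    meta$truth <- list(attenuation = frame$truth$attenuation,
                       diameter_um = frame$truth$field$effective_diameter,
                       concentration = frame$truth$field$acoustic_concentration,
                       mean_spacing_mm = frame$truth$field$mean_spacing)
  jsonlite::write_json(meta, file.path(dir, "meta.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(dir)
}

#' Read an RF frame written by [write_rf_frame()]
#' @param dir Directory containing `rf.tsv` and `meta.json`.
#' @return An `rf_frame` (without ground-truth scatterer positions).
#' @export
read_rf_frame <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "meta.json"), simplifyVector = TRUE)
  g <- acq_geometry(sampling_rate = meta$sampling_rate_hz,
                    n_lines = meta$n_lines,
                    lateral_width = meta$lateral_width_cm,
                    depth = meta$depth_cm,
                    center_frequency = meta$center_frequency_hz,
                    bandwidth = meta$bandwidth,
                    speed_of_sound = meta$speed_mps)
  rf <- as.matrix(utils::read.table(file.path(dir, "rf.tsv"), sep = "\t"))
  dimnames(rf) <- NULL
  structure(list(samples = rf, geometry = g, truth = meta$truth),
            class = "rf_frame")
}
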