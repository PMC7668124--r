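#' Acquisition geometry for a beamformed RF frame
#'
#' Describes the scan geometry of a linear-array acquisition. The defaults
#' mirror a clinical neck-node protocol: 40 MHz sampling, 256 scan lines over a
#' 3.8 cm lateral field of view, 5 cm depth, and a transmit pulse centred near
#' 8 MHz.
#'
#' @param sampling_rate Sampling rate of the RF digitizer in Hz.
#' @param n_lines Number of lateral scan lines.
#' @param lateral_width Lateral field of view in cm.
#' @param depth Imaging depth in cm.
#' @param center_frequency Pulse centre frequency in Hz.
#' @param bandwidth Fractional -6 dB pulse bandwidth (dimensionless).
#' @param speed_of_sound Assumed speed of sound in m/s.
#'
#' @return An object of class `qus_geometry`.
#' @export
acq_geometry <- function(sampling_rate = 40e6, n_lines = 256,
                         lateral_width = 3.8, depth = 5,
                         center_frequency = 8e6, bandwidth = 0.6,
                         speed_of_sound = 1540) {
  stopifnot(depth > 0, lateral_width > 0, n_lines >= 2,
            bandwidth > 0, speed_of_sound > 0)
  if (sampling_rate <= 2 * center_frequency * (1 + bandwidth))
    stop("sampling_rate must exceed twice the upper pulse band edge")
  g <- list(sampling_rate = sampling_rate, n_lines = as.integer(n_lines),
            lateral_width = lateral_width, depth = depth,
            center_frequency = center_frequency, bandwidth = bandwidth,
            speed_of_sound = speed_of_sound)
  class(g) <- "qus_geometry"
  g
}

#' Number of axial samples implied by a geometry
#'
#' Round-trip travel time to the full depth times the sampling rate.
#' @param geometry A `qus_geometry`.
#' @return Integer sample count.
#' @export
n_axial_samples <- function(geometry) {
  as.integer(round(2 * (geometry$depth / 100) / geometry$speed_of_sound *
                     geometry$sampling_rate))
}

#' Lateral pitch (cm per scan line)
#' @param geometry A `qus_geometry`.
#' @return Line pitch in cm.
#' @export
lateral_pitch <- function(geometry) geometry$lateral_width / geometry$n_lines

#' Depth of an axial sample index, in cm
#' @param geometry A `qus_geometry`.
#' @param index 1-based sample index (vectorised).
#' @return Depth in cm.
#' @export
sample_depth <- function(geometry, index) {
  (index - 1) / geometry$sampling_rate * geometry$speed_of_sound / 2 * 100
}

#' @export
print.qus_geometry <- function(x, ...) {
  cat(sprintf(
    "qus_geometry: %d lines x %d samples | %.2f cm lateral, %.2f cm depth | fs %.1f MHz, f0 %.1f MHz, c %.0f m/s\n",
    x$n_lines, n_axial_samples(x), x$lateral_width, x$depth,
    x$sampling_rate / 1e6, x$center_frequency / 1e6, x$speed_of_sound))
  invisible(x)
}

#' Reference phantom description
#'
#' A tissue-mimicking calibration phantom of known attenuation, speed of sound
#' and backscatter law, used to cancel the system and transducer responses in
#' spectral normalization. The defaults describe a glass-bead-in-gelatin
#' phantom with attenuation 0.576 dB/MHz/cm and speed of sound 1540 m/s.
#'
#' @param attenuation Attenuation coefficient in dB/MHz/cm (one-way).
#' @param speed_of_sound Speed of sound in m/s.
#' @param backscatter_law One of `"rayleigh"` (backscatter coefficient
#'   proportional to f^4, appropriate for sub-resolution bead scatterers),
#'   `"flat"` (frequency-independent), or `"gaussian"` (f^4 times a Gaussian
#'   form factor with effective radius `a_eff_um`).
#' @param a_eff_um Effective scatterer radius in micrometres (only for
#'   `backscatter_law = "gaussian"`).
#'
#' @return An object of class `qus_phantom`.
#' @export
reference_phantom <- function(attenuation = 0.576, speed_of_sound = 1540,
                              backscatter_law = c("rayleigh", "flat", "gaussian"),
                              a_eff_um = NULL) {
  backscatter_law <- match.arg(backscatter_law)
  stopifnot(attenuation >= 0, speed_of_sound > 0)
  if (backscatter_law == "gaussian" && is.null(a_eff_um))
    stop("a_eff_um required for gaussian backscatter law")
  structure(list(attenuation = attenuation, speed_of_sound = speed_of_sound,
                 backscatter_law = backscatter_law, a_eff_um = a_eff_um),
            class = "qus_phantom")
}

#' Rectangular region of interest
#'
#' @param axial Length-2 numeric, axial (depth) range in cm.
#' @param lateral Length-2 numeric, lateral range in cm.
#' @return An object of class `qus_roi`.
#' @export
roi_rect <- function(axial, lateral) {
  stopifnot(length(axial) == 2, length(lateral) == 2,
            diff(axial) > 0, diff(lateral) > 0)
  structure(list(shape = "rect", axial = axial, lateral = lateral),
            class = "qus_roi")
}

#' Elliptical region of interest
#'
#' Lymph nodes are roughly oval in a scan plane; an ellipse is the natural ROI
#' model for simulated nodes.
#'
#' @param center Length-2 numeric, (axial, lateral) centre in cm.
#' @param semiaxes Length-2 numeric, (axial, lateral) semi-axes in cm.
#' @return An object of class `qus_roi`.
#' @export
roi_ellipse <- function(center, semiaxes) {
  stopifnot(length(center) == 2, length(semiaxes) == 2, all(semiaxes > 0))
  structure(list(shape = "ellipse", center = center, semiaxes = semiaxes,
                 axial = center[1] + c(-1, 1) * semiaxes[1],
                 lateral = center[2] + c(-1, 1) * semiaxes[2]),
            class = "qus_roi")
}

#' Test whether points fall inside an ROI
#' @param roi A `qus_roi`.
#' @param axial,lateral Coordinates in cm (vectorised, recycled).
#' @return Logical vector.
#' @export
roi_contains <- function(roi, axial, lateral) {
  if (roi$shape == "rect") {
    axial >= roi$axial[1] & axial <= roi$axial[2] &
      lateral >= roi$lateral[1] & lateral <= roi$lateral[2]
  } else {
    ((axial - roi$center[1]) / roi$semiaxes[1])^2 +
      ((lateral - roi$center[2]) / roi$semiaxes[2])^2 <= 1
  }
}

#' Bounding box of an ROI
#' @param roi A `qus_roi`.
#' @return List with `axial` and `lateral` ranges (cm).
#' @export
roi_bounds <- function(roi) list(axial = roi$axial, lateral = roi$lateral)

#' Area of an ROI in cm^2
#' @param roi A `qus_roi`.
#' @return Numeric area.
#' @export
roi_area <- function(roi) {
  if (roi$shape == "rect") diff(roi$axial) * diff(roi$lateral)
  else pi * prod(roi$semiaxes)
}
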