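# Sliding-window parametric maps of the seven QUS parameters.

# Grid of window centres covering the ROI bounding box: per axis the step is
# extent * (1 - overlap); windows are kept when the centroid lies inside the
# ROI. Returns centres, per-window regions (cm) and the in-ROI mask.
window_grid <- function(geometry, roi, window = window_spec()) {
  b <- roi_bounds(roi)
  if (b$axial[1] < 0 || b$axial[2] > geometry$depth ||
      b$lateral[1] < 0 || b$lateral[2] > geometry$lateral_width)
    stop("ROI extends outside the frame")
  ext_ax <- window$axial / 10      # cm
  ext_lat <- window$lateral / 10
  step_ax <- ext_ax * (1 - window$overlap)
  step_lat <- ext_lat * (1 - window$overlap)
  span_ax <- diff(b$axial); span_lat <- diff(b$lateral)
  if (span_ax < ext_ax || span_lat < ext_lat) stop("window does not fit in ROI")
  n_ax <- floor((span_ax - ext_ax) / step_ax + 1e-9) + 1
  n_lat <- floor((span_lat - ext_lat) / step_lat + 1e-9) + 1
  cz <- b$axial[1] + ext_ax / 2 + (seq_len(n_ax) - 1) * step_ax
  cx <- b$lateral[1] + ext_lat / 2 + (seq_len(n_lat) - 1) * step_lat
  centers <- cbind(axial = rep(cz, times = n_lat),
                   lateral = rep(cx, each = n_ax))
  inroi <- roi_contains(roi, centers[, 1], centers[, 2])
  keep <- which(inroi)
  regions <- lapply(keep, function(i)
    list(axial = centers[i, 1] + c(-0.5, 0.5) * ext_ax,
         lateral = centers[i, 2] + c(-0.5, 0.5) * ext_lat))
  list(centers = centers[keep, , drop = FALSE], regions = regions,
       grid_axial = cz, grid_lateral = cx,
       index = cbind(row = rep(seq_len(n_ax), times = n_lat)[keep],
                     col = rep(seq_len(n_lat), each = n_ax)[keep]),
       mask = matrix(inroi, n_ax, n_lat))
}

#' QUS parameter names
#' @return Character vector of the seven map names.
#' @export
qus_params <- function() c("MBF", "SS", "SI", "ACE", "SAS", "ASD", "AAC")

#' Build the seven sliding-window QUS parametric maps over an ROI
#'
#' Applies the full spectral pipeline per window: mean periodogram, reference
#' normalization, point attenuation compensation at the window-centre depth
#' (using a single frame-level ACE estimated from all in-ROI windows), linear
#' band fit (MBF/SS/SI), backscatter-coefficient estimation with Gaussian
#' form-factor inversion (ASD/AAC), and Burg-AR spectral-ripple analysis
#' (SAS). Windows whose centroid falls outside the ROI are excluded; window
#' estimates that are non-finite or out of physical bounds are masked.
#'
#' @param frame Sample `rf_frame`.
#' @param reference_frame Reference-phantom `rf_frame` (same geometry).
#' @param roi A `qus_roi`.
#' @param window A `window_spec`.
#' @param band Analysis band (MHz) for normalization and the linear/form-factor
#'   fits; default the reference -6 dB band.
#' @param sas_band Wider band (MHz) for the spacing analysis; default the
#'   reference -20 dB band.
#' @param ar_order Burg AR order for SAS.
#' @return An object of class `parametric_maps`: `maps` (named list of seven
#'   matrices on the window-centre grid, NA outside the ROI), grid coordinate
#'   vectors, `roi_mask`, and metadata (`ace`, `band`, window spec).
#' @export
build_parametric_maps <- function(frame, reference_frame, roi,
                                  window = window_spec(), band = NULL,
                                  sas_band = NULL, ar_order = 10) {
  geometry <- frame$geometry
  if (is.null(band)) band <- analysis_band(reference_frame)
  if (is.null(sas_band)) sas_band <- analysis_band(reference_frame, drop_db = 20)
  phantom <- reference_frame$truth$phantom
  if (is.null(phantom)) phantom <- reference_phantom()
  grid <- window_grid(geometry, roi, window)
  nw <- nrow(grid$centers)
  if (nw == 0) stop("empty ROI")

  ace <- estimate_ace(frame, reference_frame, roi, window = window, band = band)

  dims <- dim(grid$mask)
  maps <- stats::setNames(
    replicate(7, matrix(NA_real_, dims[1], dims[2]), simplify = FALSE),
    qus_params())
  c_ms <- geometry$speed_of_sound
  for (i in seq_len(nw)) {
    reg <- grid$regions[[i]]
    s <- compute_power_spectrum(frame, reg)
    r <- compute_power_spectrum(reference_frame, reg)
    depth <- grid$centers[i, 1]
    vals <- tryCatch({
      nps <- normalize_spectrum(s, r, band = sas_band)
      nps_c <- compensate_attenuation(nps, as.numeric(ace),
                                      phantom$attenuation, depth)
      lin <- fit_linear_spectral_params(nps_c, band)
      bsc <- estimate_bsc(nps_c, phantom)
      ffit <- suppressWarnings(fit_gaussian_form_factor(bsc, band, c_ms))
      sas <- suppressWarnings(estimate_sas(nps_c, ar_order = ar_order,
                                           speed_of_sound = c_ms,
                                           band = sas_band))
      c(MBF = lin$MBF, SS = lin$SS, SI = lin$SI, ACE = as.numeric(ace),
        SAS = as.numeric(sas), ASD = ffit$ASD, AAC = ffit$AAC)
    }, error = function(e) NULL)
    if (is.null(vals)) next
    rr <- grid$index[i, 1]; cc <- grid$index[i, 2]
    for (p in qus_params()) {
      v <- vals[[p]]
      if (is.finite(v)) maps[[p]][rr, cc] <- v
    }
  }
  structure(list(maps = maps, axial = grid$grid_axial,
                 lateral = grid$grid_lateral, roi_mask = grid$mask,
                 ace = as.numeric(ace), band = band, sas_band = sas_band,
                 window = window, roi = roi, n_windows = nw),
            class = "parametric_maps")
}

#' @export
print.parametric_maps <- function(x, ...) {
  cat(sprintf("parametric_maps: %d x %d grid, %d in-ROI windows, band %.2f-%.2f MHz, ACE %.3f dB/MHz/cm\n",
              length(x$axial), length(x$lateral), x$n_windows,
              x$band[1], x$band[2], x$ace))
  invisible(x)
}

#' Mean value of a parametric map over the ROI
#'
#' Arithmetic mean of the finite in-ROI pixels.
#'
#' @param map Numeric matrix (one map).
#' @param roi_mask Logical matrix of the same shape marking in-ROI pixels.
#' @return Scalar mean.
#' @export
mean_map_value <- function(map, roi_mask) {
  stopifnot(all(dim(map) == dim(roi_mask)))
  v <- map[roi_mask & is.finite(map)]
  if (length(v) == 0) stop("no valid in-ROI pixels")
  mean(v)
}
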