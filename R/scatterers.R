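#' Generate a point-scatterer field with known ground truth
#'
#' Builds the scatterer configuration an RF frame is simulated from. Two modes
#' are supported: `"random"` draws a homogeneous planar Poisson field (fully
#' diffuse scattering), while `"quasi_periodic"` places, on each lateral
#' column, an axial lattice of scatterers with mean spacing `mean_spacing` and
#' multiplicative spacing jitter, emulating the quasi-regular microstructure
#' that gives rise to a measurable mean scatterer spacing. The ground-truth
#' scatterer diameter, acoustic concentration and (for the lattice mode)
#' spacing are stored with the field so downstream estimators can be validated
#' against them.
#'
#' @param mode `"random"` or `"quasi_periodic"`.
#' @param density Scatterers per cm^2 (random mode; in quasi-periodic mode a
#'   weak diffuse background at this density is added when `density > 0`).
#' @param mean_spacing Mean axial spacing of the lattice in mm
#'   (quasi-periodic mode).
#' @param jitter Fractional standard deviation of individual lattice spacings.
#' @param diameter Effective scatterer diameter in micrometres.
#' @param concentration Relative acoustic concentration (linear scale;
#'   echo power scales proportionally).
#' @param mask Optional `qus_roi` restricting scatterer placement; default is
#'   the whole frame.
#' @param geometry A `qus_geometry` defining the frame extent.
#' @param seed Integer seed; the field is a deterministic function of it.
#'
#' @return An object of class `scatterer_field`: a list with `positions`
#'   (two-column matrix, axial and lateral in cm), `amplitudes`, and the
#'   ground-truth parameters.
#' @export
make_scatterer_field <- function(mode = c("random", "quasi_periodic"),
                                 density = 1000, mean_spacing = 0.30,
                                 jitter = 0.1, diameter = 0,
                                 concentration = 1, mask = NULL,
                                 geometry = acq_geometry(), seed = 1) {
  mode <- match.arg(mode)
  stopifnot(diameter >= 0, concentration > 0)
  if (mode == "quasi_periodic" && mean_spacing <= 0)
    stop("mean_spacing must be positive in quasi-periodic mode")
  if (!is.null(mask) && roi_area(mask) <= 0) stop("empty region")
  set.seed(as.integer(seed))

  if (is.null(mask)) {
    ax_rng <- c(0, geometry$depth)
    lat_rng <- c(0, geometry$lateral_width)
    area <- diff(ax_rng) * diff(lat_rng)
  } else {
    b <- roi_bounds(mask)
    ax_rng <- c(max(0, b$axial[1]), min(geometry$depth, b$axial[2]))
    lat_rng <- c(max(0, b$lateral[1]),
                 min(geometry$lateral_width, b$lateral[2]))
    if (diff(ax_rng) <= 0 || diff(lat_rng) <= 0) stop("empty region")
    area <- roi_area(mask)
  }

  pos <- matrix(numeric(0), ncol = 2)
  if (mode == "random") {
    if (density <= 0) stop("density must be positive")
    n <- stats::rpois(1, density * area)
    # rejection-sample into the (possibly elliptical) mask
    got <- 0
    while (got < n) {
      m <- max(16L, 2L * (n - got))
      ax <- stats::runif(m, ax_rng[1], ax_rng[2])
      lat <- stats::runif(m, lat_rng[1], lat_rng[2])
      keep <- if (is.null(mask)) rep(TRUE, m) else roi_contains(mask, ax, lat)
      take <- which(keep)[seq_len(min(sum(keep), n - got))]
      pos <- rbind(pos, cbind(ax[take], lat[take]))
      got <- nrow(pos)
    }
  } else {
    d_cm <- mean_spacing / 10
    pitch <- lateral_pitch(geometry)
    lat_centers <- (seq_len(geometry$n_lines) - 0.5) * pitch
    lat_centers <- lat_centers[lat_centers >= lat_rng[1] & lat_centers <= lat_rng[2]]
    for (lc in lat_centers) {
      z <- stats::runif(1, 0, d_cm)
      zs <- numeric(0)
      while (z <= ax_rng[2] - ax_rng[1]) {
        zs <- c(zs, z)
        step <- d_cm * (1 + if (jitter > 0) stats::rnorm(1, 0, jitter) else 0)
        z <- z + max(step, d_cm * 0.05)
      }
      zs <- zs + ax_rng[1]
      keep <- if (is.null(mask)) rep(TRUE, length(zs)) else roi_contains(mask, zs, lc)
      if (any(keep)) pos <- rbind(pos, cbind(zs[keep], lc))
    }
    if (density > 0) {
      bg <- make_scatterer_field("random", density = density, diameter = diameter,
                                 concentration = concentration, mask = mask,
                                 geometry = geometry, seed = as.integer((as.numeric(seed) + 7919) %% 2147483646) + 1L)
      pos <- rbind(pos, bg$positions)
    }
  }
  if (nrow(pos) == 0) stop("empty region")
  amps <- abs(stats::rnorm(nrow(pos), mean = 1, sd = 0.1))
  structure(list(positions = pos, amplitudes = amps, mode = mode,
                 mean_spacing = if (mode == "quasi_periodic") mean_spacing else NA_real_,
                 spacing_jitter = if (mode == "quasi_periodic") jitter else NA_real_,
                 effective_diameter = diameter, acoustic_concentration = concentration,
                 mask = mask, seed = as.integer(seed)),
            class = "scatterer_field")
}

#' @export
print.scatterer_field <- function(x, ...) {
  cat(sprintf("scatterer_field (%s): %d scatterers, diameter %.1f um, concentration %.3g",
              x$mode, nrow(x$positions), x$effective_diameter,
              x$acoustic_concentration))
  if (x$mode == "quasi_periodic")
    cat(sprintf(", spacing %.3f mm (jitter %.2f)", x$mean_spacing, x$spacing_jitter))
  cat("\n")
  invisible(x)
}
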