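# Shared fixtures, built once per test run. Frames use a scaled-down scan
# geometry (48 lines over 1.44 cm, 2.2 cm depth) so the whole suite stays
# fast while keeping the 40 MHz / 8 MHz spectral setup of the full protocol.

.fix <- new.env(parent = emptyenv())

fix_cached <- function(key, build) {
  if (is.null(.fix[[key]])) .fix[[key]] <- build()
  .fix[[key]]
}

fix_geom <- function() acq_geometry(n_lines = 48, lateral_width = 1.44,
                                    depth = 2.2)

fix_ref <- function() fix_cached("ref", function()
  simulate_reference_frame(reference_phantom(), fix_geom(), seed = 402))

fix_roi <- function() roi_rect(c(0.5, 1.7), c(0.15, 1.3))

# diffuse 30 um field at phantom-matched attenuation
fix_frame_diffuse <- function() fix_cached("fr_diffuse", function() {
  fld <- make_scatterer_field("random", density = 1000, diameter = 30,
                              geometry = fix_geom(), seed = 403)
  simulate_rf_frame(fld, fix_geom(), attenuation = 0.576, seed = 404)
})

# zero-jitter 0.30 mm lattice
fix_frame_lattice <- function() fix_cached("fr_lattice", function() {
  fld <- make_scatterer_field("quasi_periodic", density = 0,
                              mean_spacing = 0.30, jitter = 0, diameter = 0,
                              geometry = fix_geom(), seed = 405)
  simulate_rf_frame(fld, fix_geom(), attenuation = 0.576, seed = 406)
})

fix_maps_diffuse <- function() fix_cached("maps_diffuse", function()
  build_parametric_maps(fix_frame_diffuse(), fix_ref(), fix_roi(),
                        window_spec(2, 2, 0.5)))

# small cohort (shared by feature/pipeline tests)
fix_cohort <- function() fix_cached("cohort", function()
  generate_cohort(n_patients = 8, cr_fraction = 0.5, geometry = fix_geom(),
                  seed = 407))

fix_cohort_features <- function() fix_cached("cohort_features", function()
  extract_cohort_features(fix_cohort(), window = window_spec(2, 2, 0.5)))

# deterministic synthetic delta-feature table for classifier tests
fix_toy_dataset <- function(n = 24, p = 6, sep = 0, seed = 1) {
  set.seed(seed)
  labels <- factor(rep(c("CR", "PR"), c(round(n * 0.4), n - round(n * 0.4))),
                   levels = c("CR", "PR"))
  x <- matrix(rnorm(n * p), n, p,
              dimnames = list(NULL, paste0("f", seq_len(p))))
  x[labels == "CR", 1] <- x[labels == "CR", 1] + sep
  list(x = x, labels = labels)
}

# brute-force pair-counting oracle, independent of compute_glcm internals
glcm_oracle <- function(lev, valid, d, angle, G) {
  off <- switch(as.character(angle), "0" = c(0, d), "45" = c(-d, d),
                "90" = c(-d, 0), "135" = c(-d, -d))
  m <- matrix(0, G, G)
  for (r in seq_len(nrow(lev))) for (cc in seq_len(ncol(lev))) {
    r2 <- r + off[1]; c2 <- cc + off[2]
    if (r2 < 1 || r2 > nrow(lev) || c2 < 1 || c2 > ncol(lev)) next
    if (!valid[r, cc] || !valid[r2, c2]) next
    i <- lev[r, cc] + 1; j <- lev[r2, c2] + 1
    m[i, j] <- m[i, j] + 1
    m[j, i] <- m[j, i] + 1
  }
  m / sum(m)
}
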