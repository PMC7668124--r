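# Synthetic cohorts with planted response-group differences and survival.

#' Effect specification: planted CR-vs-PR tissue trajectories
#'
#' Each tissue knob of the simulator (acoustic concentration in dB, effective
#' scatterer diameter in micrometres, mean scatterer spacing in mm, and
#' attenuation in dB/MHz/cm) follows a per-group additive trajectory over the
#' four scan times (baseline, 24 h, week 1, week 4), starting at 0 at
#' baseline. On top of the group trajectory, every patient receives an
#' independent Gaussian perturbation of SD `sd` at each post-baseline time, so
#' `sd` is the between-patient standard deviation of the true delta and the
#' planted group separation at a time point is `cr[t] - pr[t]` in those units.
#'
#' The defaults emulate a radiotherapy course in which complete responders
#' show earlier and larger microstructural change (cell death increases
#' acoustic concentration and scatterer size, and makes spacing drift) than
#' partial responders.
#'
#' @param concentration_db,diameter_um,spacing_mm,attenuation Lists with
#'   numeric `cr`, `pr` (length-4 trajectories over the time points) and a
#'   scalar `sd`.
#' @return A list of class `effect_spec`.
#' @export
effect_spec <- function(
    concentration_db = list(cr = c(0, 2.0, 3.0, 3.5), pr = c(0, 0.5, 1.0, 1.5), sd = 1.0),
    diameter_um = list(cr = c(0, 3, 5, 6), pr = c(0, 1, 2, 2), sd = 2.5),
    spacing_mm = list(cr = c(0, 0.020, 0.030, 0.030), pr = c(0, 0, 0.010, 0.010), sd = 0.015),
    attenuation = list(cr = c(0, 0.08, 0.12, 0.15), pr = c(0, 0.02, 0.04, 0.05), sd = 0.05)) {
  spec <- list(concentration_db = concentration_db, diameter_um = diameter_um,
               spacing_mm = spacing_mm, attenuation = attenuation)
  for (nm in names(spec)) {
    s <- spec[[nm]]
    stopifnot(length(s$cr) == 4, length(s$pr) == 4, s$sd >= 0,
              s$cr[1] == 0, s$pr[1] == 0)
  }
  structure(spec, class = "effect_spec")
}

#' Null effect specification (no group difference)
#'
#' Both groups share the PR trajectories of the default [effect_spec()];
#' between-patient variability is retained.
#' @return An `effect_spec` with `cr == pr` for every knob.
#' @export
null_effect_spec <- function() {
  spec <- effect_spec()
  for (nm in names(spec)) spec[[nm]]$cr <- spec[[nm]]$pr
  spec
}

#' Survival specification: per-group exponential hazards with censoring
#'
#' Defaults give 3-year recurrence-free survival of 84% (CR) and 72% (PR)
#' under exponential hazards, with administrative censoring drawn uniformly
#' over a 12-57 month follow-up window.
#'
#' @param rfs3_cr,rfs3_pr Target 3-year (36-month) recurrence-free survival
#'   per group.
#' @param followup_range Censoring window in months.
#' @return A list of class `survival_spec` with per-group monthly hazard
#'   `rate`.
#' @export
survival_spec <- function(rfs3_cr = 0.84, rfs3_pr = 0.72,
                          followup_range = c(12, 57)) {
  stopifnot(rfs3_cr > 0, rfs3_cr < 1, rfs3_pr > 0, rfs3_pr < 1,
            followup_range[1] > 0, diff(followup_range) > 0)
  structure(list(rate = c(CR = -log(rfs3_cr) / 36, PR = -log(rfs3_pr) / 36),
                 followup_range = followup_range),
            class = "survival_spec")
}

# baseline tissue parameters shared by all simulated nodes
cohort_tissue_defaults <- function() {
  list(attenuation = 0.7, diameter_um = 30, concentration_db = 0,
       spacing_mm = 0.30, spacing_jitter = 0.15, density = 600)
}

#' Generate a synthetic patient cohort with known ground truth
#'
#' For each patient, a response label (CR/PR) is assigned, the four scan-time
#' tissue parameter sets are drawn from the effect specification, and an RF
#' frame is simulated per time point from a fresh quasi-periodic scatterer
#' field (so scan-rescan speckle variability is included). A single
#' reference-phantom frame is simulated for the cohort. Survival times are
#' drawn from the per-group exponential hazards with uniform censoring.
#'
#' @param n_patients Number of patients (>= 4).
#' @param cr_fraction Fraction of complete responders (0 < f < 1); the CR
#'   count is `round(n_patients * cr_fraction)` (36 patients with 14/36 give
#'   14 CR and 22 PR).
#' @param effects An [effect_spec()]; use [null_effect_spec()] for no group
#'   difference.
#' @param survival A [survival_spec()].
#' @param geometry A `qus_geometry` for all frames.
#' @param phantom A `qus_phantom` for the reference frame.
#' @param roi A `qus_roi` (the simulated node); default an ellipse in the
#'   middle of the frame.
#' @param tissue Baseline tissue parameters (see
#'   `qusdr:::cohort_tissue_defaults`).
#' @param scan_times Subset of [timepoints()] to simulate (baseline must be
#'   included); default all four. Restricting to e.g. baseline + 24 h halves
#'   the cost of targeted simulation experiments.
#' @param seed Integer seed; the cohort is a deterministic function of it.
#' @return An object of class `qus_cohort`: `patients` (each with `id`,
#'   `label`, `frames` per time point, `roi`, `followup_months`, `event`,
#'   and the ground-truth knob values), `reference_frame`, `geometry`,
#'   `phantom`, and the specs used.
#' @export
generate_cohort <- function(n_patients = 36, cr_fraction = 14 / 36,
                            effects = effect_spec(),
                            survival = survival_spec(),
                            geometry = acq_geometry(),
                            phantom = reference_phantom(),
                            roi = NULL,
                            tissue = cohort_tissue_defaults(),
                            scan_times = timepoints(),
                            seed = 1) {
  if (n_patients < 4) stop("need at least 4 patients to cross-validate")
  stopifnot(cr_fraction > 0, cr_fraction < 1,
            "baseline" %in% scan_times, all(scan_times %in% timepoints()))
  set.seed(as.integer(seed))
  n_cr <- round(n_patients * cr_fraction)
  labels <- c(rep("CR", n_cr), rep("PR", n_patients - n_cr))
  if (is.null(roi))
    roi <- roi_ellipse(center = c(geometry$depth / 2, geometry$lateral_width / 2),
                       semiaxes = c(0.22 * geometry$depth,
                                    0.33 * geometry$lateral_width))
  tps <- timepoints()[timepoints() %in% scan_times]
  tp_idx <- match(tps, timepoints())
  knobs <- names(effects)
  patients <- vector("list", n_patients)
  frame_seed <- function(p, t)
    as.integer((as.numeric(seed) * 1009 + p * 101 + t) %% 2147483646) + 1L
  for (p in seq_len(n_patients)) {
    gl <- tolower(labels[p])
    traj <- lapply(knobs, function(nm) {
      s <- effects[[nm]]
      eps <- c(0, stats::rnorm(3, 0, s$sd))
      s[[gl]] + eps
    })
    names(traj) <- knobs
    frames <- vector("list", length(tps)); names(frames) <- tps
    truth_knobs <- vector("list", length(tps)); names(truth_knobs) <- tps
    for (t in seq_along(tps)) {
      ti <- tp_idx[t]
      kv <- list(
        attenuation = max(0.05, tissue$attenuation + traj$attenuation[ti]),
        diameter_um = max(1, tissue$diameter_um + traj$diameter_um[ti]),
        concentration = 10^((tissue$concentration_db + traj$concentration_db[ti]) / 10),
        spacing_mm = max(0.05, tissue$spacing_mm + traj$spacing_mm[ti]))
      fld <- make_scatterer_field("quasi_periodic",
                                  density = tissue$density,
                                  mean_spacing = kv$spacing_mm,
                                  jitter = tissue$spacing_jitter,
                                  diameter = kv$diameter_um,
                                  concentration = kv$concentration,
                                  geometry = geometry,
                                  seed = frame_seed(p, t))
      frames[[t]] <- simulate_rf_frame(fld, geometry,
                                       attenuation = kv$attenuation,
                                       noise_floor = 30,
                                       seed = frame_seed(p, t) + 13L)
      truth_knobs[[t]] <- kv
    }
    rate <- survival$rate[[labels[p]]]
    tt <- stats::rexp(1, rate)
    cc <- stats::runif(1, survival$followup_range[1], survival$followup_range[2])
    patients[[p]] <- list(id = sprintf("P%02d", p), label = labels[p],
                          frames = frames, roi = roi,
                          followup_months = min(tt, cc),
                          event = as.integer(tt <= cc),
                          truth = truth_knobs)
  }
  ref <- simulate_reference_frame(phantom, geometry,
                                  seed = as.integer((as.numeric(seed) * 7907) %% 2147483646) + 1L)
  structure(list(patients = patients, reference_frame = ref,
                 geometry = geometry, phantom = phantom, roi = roi,
                 effects = effects, survival = survival, seed = seed),
            class = "qus_cohort")
}

#' @export
print.qus_cohort <- function(x, ...) {
  labs <- vapply(x$patients, `[[`, "", "label")
  cat(sprintf("qus_cohort: %d patients (%d CR / %d PR), 4 time points, seed %d\n",
              length(x$patients), sum(labs == "CR"), sum(labs == "PR"), x$seed))
  invisible(x)
}

#' Cohort manifest as a data frame (CSV shape)
#'
#' One row per patient with label, follow-up and event indicator.
#' @param cohort A `qus_cohort`.
#' @return Data frame: patient_id, label, followup_months, event.
#' @export
cohort_manifest <- function(cohort) {
  do.call(rbind, lapply(cohort$patients, function(p)
    data.frame(patient_id = p$id, label = p$label,
               followup_months = p$followup_months, event = p$event,
               stringsAsFactors = FALSE)))
}
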