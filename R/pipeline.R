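# End-to-end orchestration: simulate -> extract -> delta -> test -> classify.

#' Pipeline configuration
#'
#' Bundles every tunable of the end-to-end run with validated defaults: the
#' clinical acquisition geometry, the 0.576 dB/MHz/cm reference phantom, the
#' sliding-window spec, texture quantization, classifier settings and cohort
#' parameters.
#'
#' @param n_patients,cr_fraction Cohort size and CR fraction.
#' @param effects,survival Planted effect and survival specifications.
#' @param geometry,phantom,roi Acquisition geometry, reference phantom, node
#'   ROI (NULL = default ellipse).
#' @param window Sliding-window spec for feature extraction.
#' @param band,sas_band Analysis bands in MHz (NULL = derived from the
#'   reference frame at -6 and -20 dB).
#' @param n_levels Texture grey levels.
#' @param k K-NN neighbour count.
#' @param max_features Wrapper cap; NULL = the subjects/10 rule.
#' @param models Classifiers to run.
#' @param seed Integer seed for the whole run.
#' @return A validated list of class `pipeline_config`.
#' @export
pipeline_config <- function(n_patients = 36, cr_fraction = 14 / 36,
                            effects = effect_spec(),
                            survival = survival_spec(),
                            geometry = acq_geometry(),
                            phantom = reference_phantom(),
                            roi = NULL,
                            window = window_spec(2, 2, 0.5),
                            band = NULL, sas_band = NULL, n_levels = 16,
                            k = 3, max_features = NULL,
                            models = c("nb", "knn"), seed = 1) {
  if (n_patients < 4) stop("n_patients must be at least 4")
  stopifnot(inherits(geometry, "qus_geometry"), inherits(phantom, "qus_phantom"),
            inherits(window, "window_spec"), n_levels >= 2, k >= 1)
  models <- match.arg(models, c("nb", "knn"), several.ok = TRUE)
  structure(list(n_patients = n_patients, cr_fraction = cr_fraction,
                 effects = effects, survival = survival, geometry = geometry,
                 phantom = phantom, roi = roi, window = window, band = band,
                 sas_band = sas_band, n_levels = n_levels, k = k,
                 max_features = max_features, models = models,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Run the full delta-radiomics pipeline
#'
#' Generates (or accepts) a cohort, extracts the 31 features per patient and
#' time point, forms delta features at 24 h, week 1 and week 4, runs the
#' group-comparison table per time point, the Kaplan-Meier / log-rank
#' survival analysis, and the wrapper-selected K-NN and naive-Bayes
#' classifiers for 1..max_features features per time point.
#'
#' @param config A [pipeline_config()].
#' @param cohort Optionally, a pre-generated `qus_cohort` (skips simulation).
#' @param out_dir Optional directory; when given, the feature table, group
#'   tests, classifier report and manifest are written as CSV/JSON.
#' @return An object of class `qus_run_report`: `classifier_table` (one row
#'   per model x time point x subset size), `group_tests` (per time point),
#'   `survival` (KM curves, log-rank, 3-year RFS per group), `features`
#'   (long table), and `provenance`.
#' @export
run_pipeline <- function(config = pipeline_config(), cohort = NULL,
                         out_dir = NULL) {
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE))
  }
  if (is.null(cohort))
    cohort <- stage("cohort", generate_cohort(
      n_patients = config$n_patients, cr_fraction = config$cr_fraction,
      effects = config$effects, survival = config$survival,
      geometry = config$geometry, phantom = config$phantom, roi = config$roi,
      seed = config$seed))

  feats <- stage("extract", extract_cohort_features(
    cohort, window = config$window, band = config$band,
    sas_band = config$sas_band, n_levels = config$n_levels))

  manifest <- cohort_manifest(cohort)
  tps <- setdiff(timepoints(), "baseline")

  group_tests <- stage("group_tests", {
    out <- lapply(tps, function(tp) {
      dm <- delta_feature_matrix(feats, tp)
      cbind(timepoint = tp, group_test_table(dm$x, dm$labels))
    })
    do.call(rbind, out)
  })

  surv <- stage("survival", {
    km <- km_estimate(manifest$followup_months, manifest$event, manifest$label)
    lr <- logrank_test(manifest$followup_months, manifest$event, manifest$label)
    list(km = km, logrank = lr,
         rfs3 = vapply(km, km_surv_at, 1, t = 36))
  })

  max_feat <- if (is.null(config$max_features))
    default_feature_cap(config$n_patients) else config$max_features
  classifier_table <- stage("classify", {
    rows <- list()
    for (tp in tps) {
      dm <- delta_feature_matrix(feats, tp)
      for (model in config$models) {
        sel <- sequential_forward_select(dm$x, dm$labels, model = model,
                                         max_features = max_feat, k = config$k)
        for (size in seq_along(sel)) {
          s <- sel[[size]]
          rows[[length(rows) + 1L]] <- data.frame(
            model = model, timepoint = tp, n_features = size,
            Sn = s$Sn, Sp = s$Sp, Acc = s$Acc, AUC = s$AUC,
            features = paste(s$features, collapse = " + "),
            stringsAsFactors = FALSE)
        }
      }
    }
    do.call(rbind, rows)
  })

  report <- structure(
    list(classifier_table = classifier_table, group_tests = group_tests,
         survival = surv, features = feats, manifest = manifest,
         provenance = list(seed = config$seed,
                           n_patients = config$n_patients,
                           cr_fraction = config$cr_fraction,
                           package_version = as.character(utils::packageVersion("qusdr")))),
    class = "qus_run_report")

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(feats, file.path(out_dir, "features.csv"), row.names = FALSE)
    utils::write.csv(group_tests, file.path(out_dir, "group_tests.csv"),
                     row.names = FALSE)
    utils::write.csv(classifier_table, file.path(out_dir, "classifiers.csv"),
                     row.names = FALSE)
    utils::write.csv(manifest, file.path(out_dir, "manifest.csv"),
                     row.names = FALSE)
    jsonlite::write_json(
      list(logrank_p = surv$logrank$p_value, rfs3 = as.list(surv$rfs3),
           provenance = report$provenance),
      file.path(out_dir, "survival.json"), auto_unbox = TRUE, digits = NA)
  }
  report
}

#' @export
print.qus_run_report <- function(x, ...) {
  cat(sprintf("qus_run_report: %d patients, seed %d\n",
              x$provenance$n_patients, x$provenance$seed))
  cat(sprintf("log-rank p = %.3f; 3-year RFS CR %.0f%% / PR %.0f%%\n",
              x$survival$logrank$p_value, 100 * x$survival$rfs3[["CR"]],
              100 * x$survival$rfs3[["PR"]]))
  cat("top classifier rows by accuracy:\n")
  ct <- x$classifier_table
  print(utils::head(ct[order(-ct$Acc), ], 6), row.names = FALSE)
  invisible(x)
}

# envelope via the analytic signal (FFT-based Hilbert transform), per column
envelope <- function(x) {
  n <- nrow(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[c(1, n / 2 + 1)] <- 1; h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1; h[2:((n + 1) / 2)] <- 2
  }
  Mod(stats::mvfft(stats::mvfft(x) * h, inverse = TRUE) / n)
}

#' Export a B-mode image with a parametric-map overlay
#'
#' Renders the log-compressed envelope of the RF frame (50 dB dynamic range)
#' in grey, with the chosen parametric map overlaid in colour on the in-ROI
#' window grid, and writes a PNG whose pixel grid is the frame's sample/line
#' grid (axially decimated to roughly square pixels).
#'
#' @param frame An `rf_frame`.
#' @param map_set A `parametric_maps` built from the same frame geometry.
#' @param path Output PNG path.
#' @param param Which map to overlay (default `"SI"`).
#' @param dynamic_range Display dynamic range in dB.
#' @return Invisibly, the image array dimensions. Warns and writes B-mode only
#'   if the ROI has no valid map pixels.
#' @export
export_parametric_overlay <- function(frame, map_set, path, param = "SI",
                                      dynamic_range = 50) {
  g <- frame$geometry
  if (!param %in% names(map_set$maps)) stop("unknown parametric map: ", param)
  if (max(map_set$axial) > g$depth + 1e-9 ||
      max(map_set$lateral) > g$lateral_width + 1e-9)
    stop("map grid does not match the frame geometry")
  env <- envelope(frame$samples)
  # decimate axially so pixels are roughly isotropic on the cm scale
  dec <- max(1L, floor(nrow(env) / (ncol(env) * g$depth / g$lateral_width)))
  rows <- seq(1, nrow(env), by = dec)
  env <- env[rows, , drop = FALSE]
  db <- 20 * log10(env / max(env) + 1e-12)
  grey <- matrix(pmin(1, pmax(0, (db + dynamic_range) / dynamic_range)),
                 nrow(db), ncol(db))
  img <- array(rep(grey, 3), dim = c(dim(grey), 3))

  m <- map_set$maps[[param]]
  ok <- map_set$roi_mask & is.finite(m)
  if (!any(ok)) {
    warning("empty ROI overlay; writing B-mode only")
  } else {
    rng <- range(m[ok])
    depth_cm <- sample_depth(g, rows)
    pitch <- lateral_pitch(g)
    idx <- which(ok, arr.ind = TRUE)
    n_over <- 0L
    for (w in seq_len(nrow(idx))) {
      zc <- map_set$axial[idx[w, 1]]; xc <- map_set$lateral[idx[w, 2]]
      ri <- which.min(abs(depth_cm - zc))
      ci <- max(1L, min(ncol(grey), round(xc / pitch)))
      v <- if (diff(rng) > 0) (m[idx[w, 1], idx[w, 2]] - rng[1]) / diff(rng) else 0.5
      img[ri, ci, ] <- c(v, 0.2, 1 - v)   # blue -> red colour scale
      n_over <- n_over + 1L
    }
    attr(img, "n_overlay") <- n_over
  }
  png::writePNG(img, path)
  invisible(structure(dim(img), n_overlay = attr(img, "n_overlay")))
}
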