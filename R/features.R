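# Assembly of the 31-feature QUS radiomics vector and its delta form.

texture_feature_names <- function() {
  params <- setdiff(qus_params(), "ACE")    # no texture for the constant ACE map
  as.vector(t(outer(params, c("CON", "COR", "ENE", "HOM"), paste, sep = "-")))
}

#' Names of the 31 radiomic features
#'
#' Seven spectral means plus 24 texture features (four Haralick features for
#' each map except ACE, whose map is constant by construction).
#' @return Character vector of length 31.
#' @export
feature_names <- function() c(qus_params(), texture_feature_names())

#' Assemble the 31-feature vector from a parametric map set
#'
#' Spectral features are ROI means of the seven maps; texture features are
#' 16-GLCM-averaged Haralick statistics of the six non-ACE maps.
#'
#' @param map_set A `parametric_maps` object.
#' @param n_levels Grey levels for texture quantization.
#' @return Named numeric vector of length 31 (class `qus_features`).
#' @export
assemble_features <- function(map_set, n_levels = 16) {
  missing <- setdiff(qus_params(), names(map_set$maps))
  if (length(missing) > 0)
    stop("missing map(s): ", paste(missing, collapse = ", "))
  out <- stats::setNames(numeric(31), feature_names())
  for (p in qus_params())
    out[p] <- mean_map_value(map_set$maps[[p]], map_set$roi_mask)
  for (p in setdiff(qus_params(), "ACE")) {
    tx <- texture_summary(map_set$maps[[p]], map_set$roi_mask,
                          n_levels = n_levels)
    out[paste(p, names(tx), sep = "-")] <- tx
  }
  class(out) <- c("qus_features", "numeric")
  out
}

#' Delta features: change from the pre-treatment baseline
#'
#' Elementwise subtraction `x(timepoint) - x(baseline)`; names are prefixed
#' with `d` (e.g. `dSI-ENE`).
#'
#' @param current,baseline `qus_features` vectors with identical names.
#' @return Named numeric vector of 31 delta features.
#' @export
delta_features <- function(current, baseline) {
  if (!identical(names(current), names(baseline)))
    stop("feature name mismatch")
  stats::setNames(as.numeric(current) - as.numeric(baseline),
                  paste0("d", names(current)))
}

#' Time points of the scan protocol
#' @return Character vector: baseline, 24h, week1, week4.
#' @export
timepoints <- function() c("baseline", "24h", "week1", "week4")

#' Extract features for every patient and time point of a cohort
#'
#' Runs [build_parametric_maps()] and [assemble_features()] on each frame.
#'
#' @param cohort A `qus_cohort` from [generate_cohort()].
#' @param window A `window_spec`.
#' @param band,sas_band Analysis bands (MHz); defaults from the cohort's
#'   reference frame.
#' @param n_levels Texture grey levels.
#' @return Long data frame with columns `patient_id`, `label`, `timepoint`,
#'   `feature`, `value`.
#' @export
extract_cohort_features <- function(cohort, window = window_spec(2, 2, 0.5),
                                    band = NULL, sas_band = NULL,
                                    n_levels = 16) {
  ref <- cohort$reference_frame
  if (is.null(band)) band <- analysis_band(ref)
  if (is.null(sas_band)) sas_band <- analysis_band(ref, drop_db = 20)
  rows <- list()
  for (p in cohort$patients) {
    for (tp in names(p$frames)) {
      ms <- build_parametric_maps(p$frames[[tp]], ref, p$roi, window = window,
                                  band = band, sas_band = sas_band)
      fv <- assemble_features(ms, n_levels = n_levels)
      rows[[length(rows) + 1L]] <-
        data.frame(patient_id = p$id, label = p$label, timepoint = tp,
                   feature = names(fv), value = as.numeric(fv),
                   stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Delta-feature matrix for one time point
#'
#' Pivots the long feature table into a patients x 31 matrix of changes from
#' baseline at `timepoint`.
#'
#' @param feature_table Long data frame from [extract_cohort_features()].
#' @param timepoint One of `"24h"`, `"week1"`, `"week4"`.
#' @return List with `x` (matrix, rownames = patient ids, colnames = delta
#'   feature names) and `labels` (factor CR/PR aligned with rows).
#' @export
delta_feature_matrix <- function(feature_table, timepoint) {
  stopifnot(timepoint %in% setdiff(timepoints(), "baseline"))
  ids <- unique(feature_table$patient_id)
  fn <- feature_names()
  x <- matrix(NA_real_, length(ids), length(fn),
              dimnames = list(ids, paste0("d", fn)))
  labels <- character(length(ids))
  for (k in seq_along(ids)) {
    sub <- feature_table[feature_table$patient_id == ids[k], ]
    base <- sub[sub$timepoint == "baseline", ]
    cur <- sub[sub$timepoint == timepoint, ]
    if (nrow(base) == 0) stop("patient ", ids[k], " has no baseline scan")
    x[k, ] <- cur$value[match(fn, cur$feature)] -
      base$value[match(fn, base$feature)]
    labels[k] <- sub$label[1]
  }
  list(x = x, labels = factor(labels, levels = c("CR", "PR")))
}
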