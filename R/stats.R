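# Group-comparison and survival statistics for delta features.

#' Compare a delta feature between response groups
#'
#' Normality is assessed with the Shapiro-Wilk test in each group at
#' alpha = 0.05; when neither group rejects, a two-sided Welch t-test is used,
#' otherwise a two-sided Mann-Whitney U-test. A zero-variance group on the
#' t-test route falls back to Mann-Whitney with a warning. Group summaries
#' are mean +/- SEM (SD / sqrt(n)).
#'
#' @param values Numeric vector, one delta-feature value per patient.
#' @param labels Factor or character, CR/PR per patient.
#' @param alpha Shapiro-Wilk routing level.
#' @return List: `test_used` ("t" or "mann_whitney"), `p_value`, and
#'   per-group `mean` and `sem` (named by group).
#' @export
compare_groups <- function(values, labels, alpha = 0.05) {
  labels <- factor(labels)
  stopifnot(nlevels(labels) == 2, length(values) == length(labels))
  g <- split(values, labels)
  if (any(vapply(g, length, 1L) < 3)) stop("need at least 3 patients per group")
  zero_var <- vapply(g, stats::sd, 1) == 0
  normal <- vapply(seq_along(g), function(i) {
    if (zero_var[i]) return(TRUE)   # degenerate; handled below
    tryCatch(stats::shapiro.test(g[[i]])$p.value > alpha,
             error = function(e) FALSE)
  }, logical(1))
  use_t <- all(normal) && !any(zero_var)
  if (all(normal) && any(zero_var))
    warning("zero within-group variance; falling back to Mann-Whitney")
  if (identical(g[[1]], g[[2]])) {
    # identical groups: define the degenerate comparison exactly
    p <- 1; test <- if (use_t) "t" else "mann_whitney"
  } else if (use_t) {
    p <- stats::t.test(g[[1]], g[[2]], var.equal = FALSE)$p.value
    test <- "t"
  } else {
    p <- suppressWarnings(
      stats::wilcox.test(g[[1]], g[[2]], exact = FALSE)$p.value)
    test <- "mann_whitney"
  }
  list(test_used = test, p_value = p,
       mean = vapply(g, mean, 1),
       sem = vapply(g, function(v) stats::sd(v) / sqrt(length(v)), 1))
}

#' Group-comparison table over all delta features (Table-2 shape)
#'
#' @param x Patients x features delta matrix (e.g. from
#'   [delta_feature_matrix()]).
#' @param labels CR/PR labels aligned with rows.
#' @return Data frame: feature, test, p_value, and per-group mean/SEM, sorted
#'   by p-value.
#' @export
group_test_table <- function(x, labels) {
  res <- lapply(colnames(x), function(f) {
    r <- compare_groups(x[, f], labels)
    data.frame(feature = f, test = r$test_used, p_value = r$p_value,
               cr_mean = r$mean[["CR"]], cr_sem = r$sem[["CR"]],
               pr_mean = r$mean[["PR"]], pr_sem = r$sem[["PR"]],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out[order(out$p_value), ]
}

#' Kaplan-Meier product-limit curves per response group
#'
#' @param times Follow-up times in months (> 0).
#' @param events Event indicators (1 = recurrence/death, 0 = censored).
#' @param groups Group labels (e.g. CR/PR).
#' @return List of per-group data frames with `time` and `surv`
#'   (right-continuous product-limit estimate), plus the underlying
#'   `survival::survfit` object as attribute `fit`.
#' @export
km_estimate <- function(times, events, groups) {
  stopifnot(all(times > 0))
  if (!is.factor(groups)) groups <- factor(groups)
  if (any(table(groups) == 0)) stop("empty group")
  fit <- survival::survfit(survival::Surv(times, events) ~ groups)
  sm <- summary(fit, censored = TRUE)
  strata <- if (is.null(sm$strata)) rep(levels(groups)[1], length(sm$time))
            else sub("^groups=", "", as.character(sm$strata))
  curves <- lapply(levels(groups), function(gl) {
    k <- strata == gl
    data.frame(time = sm$time[k], surv = sm$surv[k])
  })
  names(curves) <- levels(groups)
  structure(curves, fit = fit)
}

#' Two-group log-rank test
#'
#' @inheritParams km_estimate
#' @return List with `statistic` (chi-square, 1 df) and `p_value`.
#' @export
logrank_test <- function(times, events, groups) {
  if (!is.factor(groups)) groups <- factor(groups)
  stopifnot(nlevels(groups) == 2)
  if (any(table(groups) == 0)) stop("empty group")
  sd <- survival::survdiff(survival::Surv(times, events) ~ groups)
  list(statistic = sd$chisq,
       p_value = stats::pchisq(sd$chisq, df = 1, lower.tail = FALSE))
}

#' Survival probability at a landmark time from a KM curve
#'
#' @param curve Data frame with `time` and `surv` (from [km_estimate()]).
#' @param t Landmark time (same units as `time`).
#' @return Survival probability at `t` (right-continuous step function).
#' @export
km_surv_at <- function(curve, t) {
  s <- c(1, curve$surv)[findInterval(t, curve$time) + 1]
  s
}
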