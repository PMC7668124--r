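# K-NN and Gaussian naive-Bayes response classifiers with sequential forward
# selection in a leave-one-out wrapper.

# z-score columns by training-set statistics; zero-SD columns are left at
# their centred value
standardize_train <- function(train, test) {
  mu <- colMeans(train)
  sd <- apply(train, 2, stats::sd)
  sd[sd == 0] <- 1
  list(train = sweep(sweep(train, 2, mu), 2, sd, "/"),
       test = sweep(sweep(test, 2, mu), 2, sd, "/"))
}

#' k-nearest-neighbour classification of one point
#'
#' Majority vote among the `k` Euclidean-nearest training points. A vote tie
#' is resolved by the class of the single nearest neighbour. The score is the
#' fraction of neighbours voting for the positive class, which is the ROC
#' ordering variable.
#'
#' @param train_x Training matrix (rows = patients; features should already be
#'   standardized with training statistics).
#' @param train_y Training labels (factor or character).
#' @param test_x Numeric vector (one point) or single-row matrix.
#' @param k Number of neighbours (default 3); must be <= nrow(train_x).
#' @param positive Positive class label (default `"CR"`).
#' @return List with `label` and `score`.
#' @export
knn_classify <- function(train_x, train_y, test_x, k = 3, positive = "CR") {
  train_x <- as.matrix(train_x)
  stopifnot(k >= 1, k <= nrow(train_x))
  test_x <- as.numeric(test_x)
  d2 <- rowSums(sweep(train_x, 2, test_x)^2)
  ord <- order(d2)
  nb <- as.character(train_y)[ord[seq_len(k)]]
  tab <- table(nb)
  top <- names(tab)[tab == max(tab)]
  label <- if (length(top) == 1) top else nb[1]
  list(label = label, score = mean(nb == positive))
}

#' Gaussian naive-Bayes classification of one point
#'
#' Per-feature Gaussian class-conditional likelihoods with empirical class
#' priors; computed in the log domain. Class variances are floored at
#' 1e-9 times the pooled feature variance (plus a tiny absolute floor) to
#' keep degenerate features finite.
#'
#' @inheritParams knn_classify
#' @return List with `label` and `posterior` (named probabilities summing
#'   to 1) and `score` (posterior of the positive class).
#' @export
naive_bayes_classify <- function(train_x, train_y, test_x, positive = "CR") {
  train_x <- as.matrix(train_x)
  y <- factor(train_y)
  if (any(table(y) < 2)) stop("need at least 2 training points per class")
  test_x <- as.numeric(test_x)
  pooled <- apply(train_x, 2, stats::var)
  floor_v <- pmax(1e-9 * pooled, 1e-12)
  logp <- vapply(levels(y), function(cl) {
    xs <- train_x[y == cl, , drop = FALSE]
    mu <- colMeans(xs)
    v <- pmax(apply(xs, 2, stats::var), floor_v)
    sum(stats::dnorm(test_x, mu, sqrt(v), log = TRUE)) +
      log(mean(y == cl))
  }, numeric(1))
  post <- exp(logp - max(logp))
  post <- post / sum(post)
  list(label = names(post)[which.max(post)], posterior = post,
       score = if (positive %in% names(post)) post[[positive]] else NA_real_)
}

#' Leave-one-out cross-validation of a classifier
#'
#' Each patient is predicted from a model trained on the remaining n-1, with
#' feature standardization refit on each training fold only. Deterministic:
#' neither classifier involves randomness.
#'
#' @param x Patients x features matrix.
#' @param y Labels.
#' @param model `"nb"` (Gaussian naive Bayes) or `"knn"`.
#' @param features Character vector of feature (column) names to use;
#'   default all.
#' @param k Neighbours for K-NN.
#' @param positive Positive class label.
#' @return Data frame with per-patient `pred` and `score`.
#' @export
loo_cv <- function(x, y, model = c("nb", "knn"), features = colnames(x),
                   k = 3, positive = "CR") {
  model <- match.arg(model)
  x <- as.matrix(x)
  n <- nrow(x)
  if (n < 4) stop("need at least 4 patients for cross-validation")
  bad <- setdiff(features, colnames(x))
  if (length(bad) > 0) stop("unknown feature(s): ", paste(bad, collapse = ", "))
  xs <- x[, features, drop = FALSE]
  pred <- character(n); score <- numeric(n)
  for (i in seq_len(n)) {
    st <- standardize_train(xs[-i, , drop = FALSE], xs[i, , drop = FALSE])
    r <- if (model == "knn")
      knn_classify(st$train, y[-i], st$test, k = k, positive = positive)
    else
      naive_bayes_classify(st$train, y[-i], st$test, positive = positive)
    pred[i] <- r$label; score[i] <- r$score
  }
  data.frame(pred = pred, score = score, stringsAsFactors = FALSE)
}

#' Classifier performance: sensitivity, specificity, accuracy, AUC
#'
#' The positive class defaults to CR (complete responder). Sensitivity is
#' TP / (TP + FN) x 100, specificity TN / (TN + FP) x 100, accuracy
#' (TP + TN) / n x 100. The ROC is swept over score thresholds and the AUC
#' computed by the trapezoid rule (rank form, tie-aware).
#'
#' @param pred Predicted labels.
#' @param scores Held-out scores (higher = more positive).
#' @param labels True labels.
#' @param positive Positive class label.
#' @return List: `Sn`, `Sp`, `Acc` (percent), `AUC`.
#' @export
evaluate_classifier <- function(pred, scores, labels, positive = "CR") {
  labels <- as.character(labels); pred <- as.character(pred)
  stopifnot(length(pred) == length(labels), length(scores) == length(labels))
  pos <- labels == positive
  if (all(pos) || !any(pos)) stop("labels contain a single class; AUC undefined")
  tp <- sum(pred == positive & pos); fn <- sum(pred != positive & pos)
  tn <- sum(pred != positive & !pos); fp <- sum(pred == positive & !pos)
  r <- rank(scores)
  auc <- (sum(r[pos]) - sum(pos) * (sum(pos) + 1) / 2) / (sum(pos) * sum(!pos))
  list(Sn = 100 * tp / (tp + fn), Sp = 100 * tn / (tn + fp),
       Acc = 100 * (tp + tn) / length(labels), AUC = auc)
}

#' Default wrapper feature cap: the n/10 rule of thumb
#' @param n Number of subjects.
#' @return `floor(n / 10)`, at least 1.
#' @export
default_feature_cap <- function(n) max(1L, as.integer(floor(n / 10)))

#' Sequential forward selection in a leave-one-out wrapper
#'
#' Greedy forward search: at each step the feature whose addition maximizes
#' leave-one-out accuracy is added (accuracy ties broken by earlier column
#' order, so the search is deterministic). The best subset of each size from
#' 1 to `max_features` is recorded with its LOO metrics.
#'
#' @param x Patients x features matrix.
#' @param y Labels.
#' @param model `"nb"` or `"knn"`.
#' @param max_features Subset-size cap; default `floor(n/10)` (the
#'   subjects/10 rule of thumb).
#' @param k Neighbours for K-NN.
#' @param positive Positive class label.
#' @return List of per-size results: each has `features`, `Sn`, `Sp`, `Acc`,
#'   `AUC`, and the per-patient `loo` predictions.
#' @export
sequential_forward_select <- function(x, y, model = c("nb", "knn"),
                                      max_features = NULL, k = 3,
                                      positive = "CR") {
  model <- match.arg(model)
  x <- as.matrix(x)
  if (is.null(max_features)) max_features <- default_feature_cap(nrow(x))
  if (max_features < 1) stop("max_features must be at least 1")
  max_features <- min(max_features, ncol(x))
  selected <- character(0)
  out <- vector("list", max_features)
  for (size in seq_len(max_features)) {
    cand <- setdiff(colnames(x), selected)
    accs <- vapply(cand, function(f) {
      cv <- loo_cv(x, y, model, features = c(selected, f), k = k,
                   positive = positive)
      mean(cv$pred == as.character(y))
    }, numeric(1))
    best <- cand[which.max(accs)]        # which.max keeps the earliest tie
    selected <- c(selected, best)
    cv <- loo_cv(x, y, model, features = selected, k = k, positive = positive)
    met <- evaluate_classifier(cv$pred, cv$score, y, positive = positive)
    out[[size]] <- c(list(features = selected, loo = cv), met)
  }
  out
}
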