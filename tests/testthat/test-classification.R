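# K-NN, naive Bayes, LOO wrapper, forward selection, and metrics.

test_that("1-NN returns the label of a coincident training point", {
  x <- matrix(c(0, 0, 5, 5, 9, 1), 3, 2, byrow = TRUE)
  y <- c("CR", "PR", "PR")
  r <- knn_classify(x, y, c(5, 5), k = 1)
  expect_equal(r$label, "PR")
  expect_equal(r$score, 0)
})

test_that("K-NN neighbour set matches an exhaustive distance-sort oracle", {
  set.seed(41)
  x <- matrix(rnorm(40), 20, 2)
  y <- rep(c("CR", "PR"), 10)
  for (i in 1:10) {
    test_pt <- rnorm(2)
    d <- sqrt(colSums((t(x) - test_pt)^2))
    nb_oracle <- y[order(d)][1:5]
    r <- knn_classify(x, y, test_pt, k = 5)
    expect_equal(r$score, mean(nb_oracle == "CR"))
    tab <- table(nb_oracle)
    if (length(tab) == 1 || diff(range(tab)) != 0)
      expect_equal(r$label, names(which.max(tab)))
    else
      expect_equal(r$label, y[order(d)][1])   # tie: nearest neighbour
  }
})

test_that("K-NN separates well-separated clusters perfectly under LOO", {
  set.seed(42)
  n <- 20
  x <- rbind(matrix(rnorm(n, 0, 0.3), n / 2, 2),
             matrix(rnorm(n, 8, 0.3), n / 2, 2))
  colnames(x) <- c("a", "b")
  y <- factor(rep(c("CR", "PR"), each = n / 2))
  cv <- loo_cv(x, y, "knn", k = 3)
  expect_equal(mean(cv$pred == as.character(y)), 1)
})

test_that("naive Bayes posterior is symmetric at the class-mean midpoint", {
  x <- matrix(c(-1, -1.5, -0.5, 1, 1.5, 0.5), ncol = 1,
              dimnames = list(NULL, "f"))
  y <- c("CR", "CR", "CR", "PR", "PR", "PR")
  r <- naive_bayes_classify(x, y, 0)
  expect_equal(unname(r$posterior), c(0.5, 0.5), tolerance = 1e-12)
  expect_equal(sum(r$posterior), 1)
})

test_that("naive Bayes agrees with a log-domain brute-force oracle", {
  set.seed(43)
  for (rep in 1:10) {
    x <- matrix(rnorm(36), 12, 3, dimnames = list(NULL, c("a", "b", "c")))
    y <- rep(c("CR", "PR"), c(5, 7))
    pt <- rnorm(3)
    r <- naive_bayes_classify(x, y, pt)
    lp <- vapply(c("CR", "PR"), function(cl) {
      xs <- x[y == cl, , drop = FALSE]
      sum(dnorm(pt, colMeans(xs), apply(xs, 2, sd), log = TRUE)) +
        log(mean(y == cl))
    }, numeric(1))
    post <- exp(lp - max(lp)); post <- post / sum(post)
    expect_equal(unname(r$posterior), unname(post), tolerance = 1e-9)
    expect_equal(sum(r$posterior), 1)
  }
})

test_that("LOO produces one deterministic prediction per patient", {
  ds <- fix_toy_dataset(n = 16, sep = 1)
  cv1 <- loo_cv(ds$x, ds$labels, "nb")
  cv2 <- loo_cv(ds$x, ds$labels, "nb")
  expect_equal(nrow(cv1), 16)
  expect_identical(cv1, cv2)
  expect_error(loo_cv(ds$x, ds$labels, "nb", features = "nope"),
               "unknown feature")
  expect_error(loo_cv(ds$x[1:3, ], ds$labels[1:3], "nb"), "at least 4")
})

test_that("label permutation drives LOO accuracy to the majority rate", {
  accs <- vapply(1:30, function(s) {
    ds <- fix_toy_dataset(n = 20, sep = 3, seed = 100)
    set.seed(s)
    yp <- sample(ds$labels)
    cv <- loo_cv(ds$x, yp, "nb", features = "f1")
    mean(cv$pred == as.character(yp))
  }, numeric(1))
  maj <- 12 / 20
  expect_lt(abs(mean(accs) - maj), 0.12)
})

test_that("the feature cap follows the subjects/10 rule", {
  expect_equal(default_feature_cap(36), 3L)
  expect_equal(default_feature_cap(20), 2L)
  expect_equal(default_feature_cap(9), 1L)
  ds <- fix_toy_dataset(n = 36, p = 8, sep = 2)
  sel <- sequential_forward_select(ds$x, ds$labels, "nb")
  expect_length(sel, 3)
  expect_length(sel[[3]]$features, 3)
  expect_error(sequential_forward_select(ds$x, ds$labels, "nb",
                                         max_features = 0),
               "at least 1")
})

test_that("forward selection finds the informative feature first", {
  ds <- fix_toy_dataset(n = 24, p = 4, sep = 3, seed = 7)
  sel <- sequential_forward_select(ds$x, ds$labels, "nb", max_features = 2)
  expect_equal(sel[[1]]$features, "f1")
  expect_gt(sel[[1]]$Acc, 75)
})

test_that("greedy selection agrees with exhaustive search on a clean case", {
  # constructed so the greedy path is unambiguous: f1 informative alone,
  # f2 adds independent signal, f3/f4 noise
  set.seed(8)
  n <- 24
  y <- factor(rep(c("CR", "PR"), each = n / 2))
  x <- cbind(f1 = rnorm(n) + 3 * (y == "CR"),
             f2 = rnorm(n) + 2 * (y == "CR"),
             f3 = rnorm(n), f4 = rnorm(n))
  acc_of <- function(fs) {
    cv <- loo_cv(x, y, "nb", features = fs)
    mean(cv$pred == as.character(y))
  }
  sel <- sequential_forward_select(x, y, "nb", max_features = 2)
  # exhaustive over all subsets of size <= 2
  singles <- vapply(colnames(x), function(f) acc_of(f), numeric(1))
  expect_equal(sel[[1]]$features, names(which.max(singles)))
  pairs <- utils::combn(colnames(x), 2, simplify = FALSE)
  pair_acc <- vapply(pairs, acc_of, numeric(1))
  best_pair <- pairs[[which.max(pair_acc)]]
  expect_setequal(sel[[2]]$features, best_pair)
})

test_that("metrics match the hand confusion table and ROC conventions", {
  # TP=5 FN=2 TN=8 FP=1 with CR positive
  labels <- rep(c("CR", "PR"), c(7, 9))
  pred <- c(rep("CR", 5), rep("PR", 2), rep("PR", 8), "CR")
  set.seed(9)
  scores <- (pred == "CR") + rnorm(16, 0, 0.01)
  m <- evaluate_classifier(pred, scores, labels)
  expect_equal(m$Sn, 500 / 7, tolerance = 1e-9)
  expect_equal(m$Sp, 800 / 9, tolerance = 1e-9)
  expect_equal(m$Acc, 81.25)
  # perfect prediction
  mp <- evaluate_classifier(labels, as.numeric(labels == "CR"), labels)
  expect_equal(c(mp$Sn, mp$Sp, mp$Acc, mp$AUC), c(100, 100, 100, 1))
  # all predicted PR: Sn 0, Sp 100
  ma <- evaluate_classifier(rep("PR", 16), rep(0.2, 16), labels)
  expect_equal(c(ma$Sn, ma$Sp), c(0, 100))
  expect_error(evaluate_classifier(rep("CR", 3), 1:3, rep("CR", 3)),
               "single class")
})

test_that("AUC is invariant to monotone score transforms and matches pROC", {
  skip_if_not_installed("pROC")
  set.seed(10)
  labels <- rep(c("CR", "PR"), c(8, 12))
  scores <- rnorm(20) + (labels == "CR")
  pred <- ifelse(scores > 0.5, "CR", "PR")
  a1 <- evaluate_classifier(pred, scores, labels)$AUC
  a2 <- evaluate_classifier(pred, exp(3 * scores), labels)$AUC
  expect_equal(a1, a2)
  proc <- pROC::auc(pROC::roc(response = labels, predictor = scores,
                              levels = c("PR", "CR"), direction = "<",
                              quiet = TRUE))
  expect_equal(a1, as.numeric(proc))
})

test_that("2-SD planted shifts on two features yield >= 80% NB accuracy", {
  accs <- vapply(1:15, function(s) {
    set.seed(s)
    n <- 36
    y <- factor(rep(c("CR", "PR"), c(14, 22)))
    x <- matrix(rnorm(n * 6), n, 6,
                dimnames = list(NULL, paste0("f", 1:6)))
    x[y == "CR", 1] <- x[y == "CR", 1] + 2   # 2 pooled SD
    x[y == "CR", 2] <- x[y == "CR", 2] + 2
    sel <- sequential_forward_select(x, y, "nb", max_features = 1)
    sel[[1]]$Acc
  }, numeric(1))
  expect_gte(stats::median(accs), 80)
})
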