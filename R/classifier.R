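# t-filtered, min-max scaled RBF-SVM under leave-one-out
# cross-validation, with ROC/AUC and permutation significance.

# Logical keep-mask from a two-sample t filter computed on (training)
# data only. Guarantees at least one feature (top |t|) with a warning.
.tFilterMask <- function(X, labels, alpha) {
  z <- labels == levels(labels)[1L]
  t <- .colTStats(X, z)
  p <- 2 * stats::pt(-abs(t), nrow(X) - 2L)
  keep <- !is.na(p) & p < alpha
  if (!any(keep)) {
    warning("t filter retained no features; keeping top-1 by |t|")
    tt <- abs(t); tt[is.na(tt)] <- -Inf
    keep[which.max(tt)] <- TRUE
  }
  keep
}

#' Two-sample t-test feature filter
#'
#' Keeps features whose pooled two-sample t-test p-value is below
#' \code{alpha}.  When used inside cross-validation the filter must be
#' recomputed per training fold (as \code{\link{loocvSvm}} does) to avoid
#' selection leakage.
#'
#' @param X subjects x features numeric matrix.
#' @param labels two-level factor (or coercible).
#' @param alpha retention threshold (1 keeps everything).
#' @return list: X (reduced matrix), keep (logical mask).
#' @export
tFilterFeatures <- function(X, labels, alpha = 0.05) {
  X <- as.matrix(X)
  labels <- factor(labels)
  stopifnot(nlevels(labels) == 2L, alpha > 0, alpha <= 1)
  keep <- if (alpha >= 1) rep(TRUE, ncol(X)) else
    .tFilterMask(X, labels, alpha)
  list(X = X[, keep, drop = FALSE], keep = keep)
}

#' Min-max feature scaling
#'
#' Per-feature (x - min)/(max - min) with min/max taken from the training
#' data; test rows are scaled with the training statistics and clipped to
#' [0, 1].  Constant features map to 0 (with a warning).
#'
#' @param train training subjects x features matrix.
#' @param test optional test matrix scaled with the training statistics.
#' @return list: train, test (NULL if absent), min, range.
#' @export
minMaxScale <- function(train, test = NULL) {
  train <- as.matrix(train)
  lo <- apply(train, 2L, min)
  hi <- apply(train, 2L, max)
  rg <- hi - lo
  const <- rg == 0
  if (any(const)) {
    warning(sum(const), " constant feature(s) mapped to 0")
    rg[const] <- 1
  }
  sc <- function(M) {
    M <- sweep(sweep(M, 2L, lo), 2L, rg, "/")
    M[, const] <- 0
    pmin(pmax(M, 0), 1)
  }
  list(train = sc(train),
       test = if (is.null(test)) NULL else
         sc(matrix(test, ncol = ncol(train))),
       min = lo, range = rg)
}

#' ROC curve from continuous decision scores
#'
#' @param scores decision values, larger favoring the positive class.
#' @param labels logical (TRUE = positive) or two-level factor.
#' @param positive positive level when \code{labels} is a factor.
#' @return data.frame of (FPR, TPR) points, monotone nondecreasing.
#' @export
rocCurve <- function(scores, labels, positive = NULL) {
  if (!is.logical(labels)) {
    labels <- factor(labels)
    if (is.null(positive)) positive <- levels(labels)[2L]
    labels <- labels == positive
  }
  thr <- c(Inf, sort(unique(scores), decreasing = TRUE))
  P <- sum(labels); N <- sum(!labels)
  tpr <- vapply(thr, function(t) sum(scores >= t & labels) / P, numeric(1))
  fpr <- vapply(thr, function(t) sum(scores >= t & !labels) / N, numeric(1))
  data.frame(FPR = fpr, TPR = tpr)
}

#' Area under the ROC curve
#'
#' Rank-based (Mann-Whitney) estimator, equal to the trapezoidal area of
#' the ROC curve with ties split evenly; invariant under strictly
#' monotone transforms of the scores.
#'
#' @inheritParams rocCurve
#' @return AUC in [0, 1].
#' @export
aucScore <- function(scores, labels, positive = NULL) {
  if (!is.logical(labels)) {
    labels <- factor(labels)
    if (is.null(positive)) positive <- levels(labels)[2L]
    labels <- labels == positive
  }
  P <- sum(labels); N <- sum(!labels)
  if (P == 0L || N == 0L) stop("both classes required")
  r <- rank(scores)
  (sum(r[labels]) - P * (P + 1) / 2) / (P * N)
}

# Decision value oriented toward `positive` from an e1071 svm fit.
.decisionFor <- function(fit, newX, positive) {
  pr <- stats::predict(fit, newX, decision.values = TRUE)
  dv <- attr(pr, "decision.values")
  cls <- strsplit(colnames(dv)[1L], "/", fixed = TRUE)[[1L]]
  d <- dv[, 1L]
  if (cls[1L] != positive) d <- -d
  list(class = as.character(pr), decision = d)
}

# Train an RBF SVM on one fold and score the held-out row.  Leave-one-out
# training folds are imbalanced against the held-out subject's class,
# which shifts the SVM intercept toward the fold majority and biases
# pooled decision values; the offset is recalibrated to the midpoint of
# the two training-class mean decision values (training data only, so
# nothing about the held-out subject leaks in).
.foldSvm <- function(Xtr, ytr, Xte, cost, gamma, positive) {
  fit <- e1071::svm(Xtr, ytr, kernel = "radial", cost = cost,
                    gamma = gamma, scale = FALSE)
  dtr <- .decisionFor(fit, Xtr, positive)$decision
  offset <- (mean(dtr[ytr == positive]) + mean(dtr[ytr != positive])) / 2
  if (!is.finite(offset)) offset <- 0
  d <- .decisionFor(fit, Xte, positive)$decision - offset
  lv <- levels(ytr)
  list(class = if (d > 0) positive else setdiff(lv, positive),
       decision = d)
}

#' Leave-one-out cross-validated RBF-SVM classification
#'
#' For each subject: the t filter and min-max scaling statistics are
#' computed on the remaining n-1 subjects, an RBF-kernel SVM is trained
#' on them, and the held-out subject is predicted.  Aggregates accuracy,
#' sensitivity and specificity of the hard predictions, and the ROC/AUC
#' of the continuous decision values.  \code{leaky = TRUE} reproduces the
#' whole-sample filter/scale variant (selection leakage) for comparison
#' only, clearly labeled in the returned config.
#'
#' @param X subjects x features numeric matrix.
#' @param labels two-level grouping (>= 2 subjects per class).
#' @param cost,gamma RBF-SVM hyperparameters; \code{gamma} defaults to
#'   1 / n(retained features) per fold.
#' @param filterAlpha t-filter level (NULL disables filtering).
#' @param positive label treated as positive (default: second level).
#' @param leaky compute filter/scaling once on all subjects (diagnostic).
#' @return list of class \code{ClassificationReport}: accuracy,
#'   sensitivity, specificity, auc, roc_points, decision_values,
#'   predictions, config.
#' @export
loocvSvm <- function(X, labels, cost = 1, gamma = NULL,
                     filterAlpha = 0.05, positive = NULL, leaky = FALSE) {
  X <- as.matrix(X)
  labels <- factor(labels)
  stopifnot(nlevels(labels) == 2L, nrow(X) == length(labels))
  if (any(table(labels) < 2L)) stop("need >= 2 subjects per class")
  if (is.null(positive)) positive <- levels(labels)[2L]
  n <- nrow(X)

  keepAll <- NULL
  if (leaky) {
    keepAll <- if (is.null(filterAlpha)) rep(TRUE, ncol(X)) else
      .tFilterMask(X, labels, filterAlpha)
    scAll <- suppressWarnings(minMaxScale(X[, keepAll, drop = FALSE]))
  }

  preds <- character(n); dec <- numeric(n)
  for (i in seq_len(n)) {
    ytr <- labels[-i]
    if (leaky) {
      Xtr <- scAll$train[-i, , drop = FALSE]
      Xte <- scAll$train[i, , drop = FALSE]
    } else {
      keep <- if (is.null(filterAlpha)) rep(TRUE, ncol(X)) else
        suppressWarnings(.tFilterMask(X[-i, , drop = FALSE], ytr,
                                      filterAlpha))
      sc <- suppressWarnings(
        minMaxScale(X[-i, keep, drop = FALSE], X[i, keep]))
      Xtr <- sc$train; Xte <- sc$test
    }
    g <- if (is.null(gamma)) 1 / ncol(Xtr) else gamma
    out <- .foldSvm(Xtr, ytr, Xte, cost, g, positive)
    preds[i] <- out$class
    dec[i] <- out$decision
  }

  isPos <- labels == positive
  acc <- mean(preds == as.character(labels))
  sens <- sum(preds == positive & isPos) / sum(isPos)
  spec <- sum(preds != positive & !isPos) / sum(!isPos)
  structure(list(
    accuracy = acc, sensitivity = sens, specificity = spec,
    auc = aucScore(dec, isPos), roc_points = rocCurve(dec, isPos),
    decision_values = dec, predictions = preds,
    config = list(kernel = "radial", cost = cost, gamma = gamma,
                  filter_alpha = filterAlpha, positive = positive,
                  leaky = leaky)),
    class = "ClassificationReport")
}

#' @export
print.ClassificationReport <- function(x, ...) {
  cat(sprintf(
    "LOOCV %s-SVM: accuracy %.3f, sensitivity %.3f, specificity %.3f, AUC %.3f\n",
    x$config$kernel, x$accuracy, x$sensitivity, x$specificity, x$auc))
  if (isTRUE(x$config$leaky))
    cat("  [leaky whole-sample filter/scaling: diagnostic mode]\n")
  invisible(x)
}

#' Permutation significance of the classification accuracy
#'
#' Repeats the LOOCV pipeline on label-permuted data;
#' p = (1 + #\{permuted accuracy >= observed\}) / (1 + nPerm).
#'
#' @inheritParams loocvSvm
#' @param nPerm number of label permutations (>= 1; >= 100 recommended).
#' @param seed RNG seed.
#' @param ... forwarded to \code{\link{loocvSvm}}.
#' @return list: p_perm, observed_accuracy, null_accuracies.
#' @export
permutationSignificance <- function(X, labels, nPerm = 100, seed = NULL,
                                    ...) {
  if (nPerm < 1) stop("nPerm must be >= 1")
  obs <- loocvSvm(X, labels, ...)$accuracy
  null <- withSeed(seed, vapply(seq_len(nPerm), function(p) {
    loocvSvm(X, sample(labels), ...)$accuracy
  }, numeric(1)))
  list(p_perm = (1 + sum(null >= obs)) / (1 + nPerm),
       observed_accuracy = obs, null_accuracies = null)
}

#' Leakage canary audit for the LOOCV pipeline
#'
#' Appends a canary feature that equals the (numeric) class label for
#' every training subject but whose held-out entry is replaced with a
#' draw from the label marginal, independent of the subject.  The canary
#' is therefore perfectly informative inside every training fold (the t
#' filter will always retain it and the SVM will lean on it) yet carries
#' no information about the held-out subject, so a pipeline that
#' computes filtering and scaling strictly within folds must stay at
#' chance AUC on otherwise uninformative data.  Any whole-sample
#' shortcut that lets the held-out canary value through yields AUC near
#' 1.
#'
#' The audit uses a much stricter filter level than the analysis
#' default so that the canary is essentially the only retained feature:
#' at looser levels, stray noise features selected within folds deflate
#' the null AUC below chance (ordinary selection pessimism), which
#' would blur the inflation signal the canary is meant to expose.
#'
#' @inheritParams loocvSvm
#' @param filterAlpha t-filter level for the audit (default 0.001).
#' @param seed RNG seed for the per-fold canary masking.
#' @return The null-data \code{ClassificationReport} with the canary
#'   inserted.
#' @export
leakageCanary <- function(X, labels, cost = 1, gamma = NULL,
                          filterAlpha = 0.001, positive = NULL,
                          seed = NULL) {
  X <- as.matrix(X)
  labels <- factor(labels)
  stopifnot(nlevels(labels) == 2L)
  if (is.null(positive)) positive <- levels(labels)[2L]
  yNum <- as.numeric(labels == positive)
  n <- nrow(X)
  masks <- withSeed(seed, sample(yNum, n, replace = TRUE))
  preds <- character(n); dec <- numeric(n)
  for (i in seq_len(n)) {
    canary <- yNum
    canary[i] <- masks[i]   # held-out entry carries no label signal
    Xi <- cbind(X, canary = canary)
    ytr <- labels[-i]
    keep <- if (is.null(filterAlpha)) rep(TRUE, ncol(Xi)) else
      suppressWarnings(.tFilterMask(Xi[-i, , drop = FALSE], ytr,
                                    filterAlpha))
    sc <- suppressWarnings(
      minMaxScale(Xi[-i, keep, drop = FALSE], Xi[i, keep]))
    g <- if (is.null(gamma)) 1 / ncol(sc$train) else gamma
    out <- .foldSvm(sc$train, ytr, sc$test, cost, g, positive)
    preds[i] <- out$class
    dec[i] <- out$decision
  }
  isPos <- labels == positive
  structure(list(
    accuracy = mean(preds == as.character(labels)),
    sensitivity = sum(preds == positive & isPos) / sum(isPos),
    specificity = sum(preds != positive & !isPos) / sum(!isPos),
    auc = aucScore(dec, isPos), roc_points = rocCurve(dec, isPos),
    decision_values = dec, predictions = preds,
    config = list(kernel = "radial", cost = cost, gamma = gamma,
                  filter_alpha = filterAlpha, positive = positive,
                  canary = TRUE)),
    class = "ClassificationReport")
}

#' Nodal-metric feature matrix for classification
#'
#' One feature per node: the chosen nodal metric at the given sparsity,
#' computed per subject.
#'
#' @param cohort a \linkS4class{CohortDataset}.
#' @param sparsity binarization sparsity.
#' @param metric "Ne", "Dc" or "Bc".
#' @param nodes optional node-id subset (e.g. hubs or non-hubs).
#' @return subjects x nodes numeric matrix with dimnames.
#' @export
nodalFeatureMatrix <- function(cohort, sparsity = 0.2,
                               metric = c("Ne", "Dc", "Bc"),
                               nodes = NULL) {
  metric <- match.arg(metric)
  if (is.null(nodes)) nodes <- cohort@nodeIds
  feats <- t(vapply(cohort@subjects, function(s) {
    nm <- nodalMetrics(sparsityBinarize(s, sparsity))
    nm[[metric]][match(nodes, nm$node_id)]
  }, numeric(length(nodes))))
  dimnames(feats) <- list(cohort@subjectIds, nodes)
  feats
}

#' Edge-class feature matrix for classification
#'
#' One feature per node pair of the requested class (given the hub set):
#' the subject's connection weight restricted to edges surviving the
#' sparsity threshold (0 when absent).
#'
#' @param cohort a \linkS4class{CohortDataset}.
#' @param hubs hub node ids defining the rich/feeder/local partition.
#' @param class "rich", "feeder" or "local".
#' @param sparsity binarization sparsity.
#' @return subjects x pairs numeric matrix.
#' @export
edgeFeatureMatrix <- function(cohort, hubs,
                              class = c("feeder", "rich", "local"),
                              sparsity = 0.2) {
  class <- match.arg(class)
  ids <- cohort@nodeIds
  n <- length(ids)
  ut <- .upperTri(n)
  ih <- ids[ut[, "i"]] %in% hubs
  jh <- ids[ut[, "j"]] %in% hubs
  want <- switch(class, rich = ih & jh, feeder = xor(ih, jh),
                 local = !ih & !jh)
  sel <- ut[want, , drop = FALSE]
  feats <- t(vapply(cohort@subjects, function(s) {
    A <- adjacencyMatrix(sparsityBinarize(s, sparsity))
    (s@weights * A)[sel]
  }, numeric(nrow(sel))))
  dimnames(feats) <- list(cohort@subjectIds,
                          paste(ids[sel[, "i"]], ids[sel[, "j"]],
                                sep = "--"))
  feats
}
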