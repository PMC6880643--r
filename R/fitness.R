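#' Classification accuracy from confusion counts
#'
#' `AC = (TP + TN) / (TP + FN + TN + FP)`.
#'
#' @param counts Named numeric vector or list with elements `TP`, `TN`,
#'   `FP`, `FN`.
#' @return Accuracy in `[0, 1]`.
#' @examples
#' classification_accuracy(c(TP = 9, TN = 7, FP = 1, FN = 3)) # 0.8
#' @export
classification_accuracy <- function(counts) {
  counts <- as.list(counts)
  total <- counts$TP + counts$TN + counts$FP + counts$FN
  if (is.null(total) || total <= 0) {
    stop("confusion counts must sum to a positive total", call. = FALSE)
  }
  (counts$TP + counts$TN) / total
}

#' Combined fitness of a candidate subset
#'
#' `f = (1 - r) * AC + r * (t - s) / t`: cross-validated accuracy blended
#' with a reward for selecting few attributes out of the current terminal
#' set of size `t`. With `r = 0` fitness is the accuracy alone; `r` is
#' restricted to `[0, 0.5)` so accuracy always dominates.
#'
#' @param AC Accuracy in `[0, 1]`.
#' @param s Number of selected attributes (`1 <= s <= t`).
#' @param t Current terminal-set size.
#' @param r Size-penalty weight in `[0, 0.5)`.
#' @return Fitness in `[0, 1]`.
#' @examples
#' fitness_score(0.8, s = 2, t = 10, r = 0.25) # 0.8
#' @export
fitness_score <- function(AC, s, t, r) {
  if (r < 0 || r >= 0.5) stop("r must lie in [0, 0.5)", call. = FALSE)
  if (s < 1 || s > t) stop("s must lie in [1, t]", call. = FALSE)
  if (AC < 0 || AC > 1) stop("AC must lie in [0, 1]", call. = FALSE)
  (1 - r) * AC + r * (t - s) / t
}

default_classifier <- function() {
  list(kernel = "linear", cost = 1, scale = FALSE)
}

svm_fit_predict <- function(x_train, y_train, x_test, classifier) {
  fit <- e1071::svm(x = x_train, y = y_train,
                    kernel = classifier$kernel, cost = classifier$cost,
                    scale = classifier$scale, fitted = FALSE)
  stats::predict(fit, x_test)
}

# Minimal marshaling straight to e1071's compiled libsvm trainer for the
# binary / linear-kernel / unscaled case that dominates the evolutionary
# loop. Identical model to e1071::svm (same routine, same parameters);
# only the R-level wrapping is skipped. Predictions come from the primal
# weight vector w = t(coefs) %*% SV with libsvm's sign convention
# (positive decision value -> first internal label).
lean_linear_svm_predict <- function(x_train, y_int, x_test, cost = 1) {
  nr <- nrow(x_train)
  nc <- ncol(x_train)
  err <- paste(rep(" ", 255), collapse = "")
  cret <- .C(e1071:::R_svmtrain,
             as.double(t(x_train)), as.integer(nr), as.integer(nc),
             as.double(y_int), as.integer(0), as.integer(0),
             as.integer(0),            # type: C-classification
             as.integer(0),            # kernel: linear
             as.integer(3), as.double(1 / nc), as.double(0),
             as.double(cost), as.double(0.5),
             as.integer(0), as.double(0), as.integer(0),
             as.double(40), as.double(0.001), as.double(0.1),
             as.integer(1), as.integer(0), as.integer(0), as.integer(0),
             nclasses = integer(1), nr = integer(1), index = integer(nr),
             labels = integer(2), nSV = integer(2), rho = double(1),
             coefs = double(nr), sigma = double(1), probA = double(1),
             probB = double(1), cresults = double(0), ctotal1 = double(1),
             ctotal2 = double(1), error = err)
  if (cret$error != err) stop(trimws(cret$error), call. = FALSE)
  sv_idx <- cret$index[seq_len(cret$nr)]
  sv <- x_train[sv_idx, , drop = FALSE]
  w <- as.vector(crossprod(cret$coefs[seq_len(cret$nr)], sv))
  d <- as.vector(x_test %*% w) - cret$rho[1]
  ifelse(d > 0, cret$labels[1], cret$labels[2])
}

# Stratified fold assignment from the current RNG stream: within each
# class, samples are shuffled and dealt round-robin into folds.
stratified_folds <- function(labels, folds) {
  fold_id <- integer(length(labels))
  for (cl in levels(labels)) {
    idx <- which(labels == cl)
    idx <- idx[sample.int(length(idx))]
    fold_id[idx] <- rep_len(seq_len(folds), length(idx))
  }
  fold_id
}

# Cross-validated accuracy for a feature matrix given a fixed fold
# assignment. Returns mean per-fold accuracy plus pooled confusion counts
# (positive class = second factor level; for >2 classes, counts collapse
# to correct/incorrect).
cv_accuracy <- function(x, labels, fold_id, classifier = default_classifier()) {
  folds <- sort(unique(fold_id))
  acc <- numeric(length(folds))
  counts <- c(TP = 0, TN = 0, FP = 0, FN = 0)
  binary <- nlevels(labels) == 2
  pos <- levels(labels)[2]
  lean <- binary && identical(classifier$kernel, "linear") &&
    !isTRUE(classifier$scale)
  y_int <- as.integer(labels)
  for (j in seq_along(folds)) {
    test <- fold_id == folds[j]
    if (lean) {
      pred_int <- lean_linear_svm_predict(x[!test, , drop = FALSE],
                                          y_int[!test],
                                          x[test, , drop = FALSE],
                                          classifier$cost)
      pred <- factor(levels(labels)[pred_int], levels = levels(labels))
    } else {
      pred <- svm_fit_predict(x[!test, , drop = FALSE], labels[!test],
                              x[test, , drop = FALSE], classifier)
    }
    truth <- labels[test]
    acc[j] <- mean(pred == truth)
    if (binary) {
      counts["TP"] <- counts["TP"] + sum(pred == pos & truth == pos)
      counts["TN"] <- counts["TN"] + sum(pred != pos & truth != pos)
      counts["FP"] <- counts["FP"] + sum(pred == pos & truth != pos)
      counts["FN"] <- counts["FN"] + sum(pred != pos & truth == pos)
    } else {
      counts["TP"] <- counts["TP"] + sum(pred == truth)
      counts["FN"] <- counts["FN"] + sum(pred != truth)
    }
  }
  list(AC = mean(acc), counts = counts)
}

#' Cross-validated accuracy of an attribute subset
#'
#' Estimates how well a candidate subset separates the classes: a linear
#' support-vector machine (C = 1) under stratified k-fold
#' cross-validation, reporting the mean held-out accuracy and the pooled
#' confusion counts. Folds are built from a seeded shuffle, so the same
#' seed always yields the same folds and the same accuracy regardless of
#' sample order. If the smallest class has fewer samples than `cv_folds`,
#' the fold count is reduced to that class size (with a message).
#'
#' @param data Data frame or matrix restricted to the candidate
#'   attributes (samples in rows).
#' @param labels Class labels, one per sample (>= 2 classes).
#' @param cv_folds Number of folds (default 5).
#' @param classifier List with `kernel`, `cost`, `scale` passed to the
#'   support-vector machine.
#' @param seed Integer seed for the fold shuffle.
#' @return List with `AC` (mean fold accuracy) and `counts` (pooled
#'   `TP`/`TN`/`FP`/`FN`).
#' @export
estimate_accuracy <- function(data, labels, cv_folds = 5L,
                              classifier = default_classifier(), seed = 1L) {
  x <- as.matrix(as.data.frame(data))
  if (ncol(x) == 0) stop("attribute subset must be non-empty", call. = FALSE)
  storage.mode(x) <- "double"
  labels <- droplevels(as.factor(labels))
  if (nlevels(labels) < 2) stop("need at least 2 classes", call. = FALSE)
  min_class <- min(table(labels))
  if (min_class < cv_folds) {
    message("reducing cv folds from ", cv_folds, " to ", min_class,
            " (smallest class size)")
    cv_folds <- min_class
  }
  if (cv_folds < 2) stop("need at least 2 samples per class", call. = FALSE)
  fold_id <- withr::with_seed(seed, stratified_folds(labels, cv_folds))
  cv_accuracy(x, labels, fold_id, classifier)
}
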