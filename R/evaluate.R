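#' Random train/validation split
#'
#' Partitions sample indices into a training set of size
#' \code{round(n * train_fraction)} and its complement, reproducibly for a
#' given seed. Stratified mode samples within each class so that per-class
#' proportions are preserved to within one sample; a class with a single
#' member cannot be split and is assigned to the training set with a
#' warning.
#'
#' @param n Number of samples (>= 2).
#' @param train_fraction Fraction for training, strictly in (0, 1).
#'   Default 0.8 — the usual 80/20 split.
#' @param seed Integer RNG seed.
#' @param stratify_by Optional vector of class labels of length \code{n}.
#' @return List with sorted integer vectors \code{train} and \code{test}
#'   (disjoint, exhaustive).
#' @export
train_test_split <- function(n, train_fraction = 0.8, seed = 1L,
                             stratify_by = NULL) {
  if (n < 2L) stop("need at least 2 samples to split", call. = FALSE)
  if (train_fraction <= 0 || train_fraction >= 1) {
    stop("train_fraction must be in (0, 1)", call. = FALSE)
  }
  set.seed(seed)
  if (is.null(stratify_by)) {
    n_train <- round(n * train_fraction)
    train <- sort(sample.int(n, n_train))
  } else {
    if (length(stratify_by) != n) {
      stop("stratify_by must have length n", call. = FALSE)
    }
    train <- integer(0)
    for (cl in unique(stratify_by)) {
      idx <- which(stratify_by == cl)
      if (length(idx) == 1L) {
        warning("class '", cl, "' has a single member; assigned to train",
                call. = FALSE)
        train <- c(train, idx)
        next
      }
      k <- round(length(idx) * train_fraction)
      k <- max(1L, min(k, length(idx) - 1L))
      train <- c(train, sample(idx, k))
    }
    train <- sort(train)
  }
  list(train = train, test = setdiff(seq_len(n), train))
}

#' Confusion matrix
#'
#' @param y_true,y_pred Integer labels in 0..K-1 (factors are converted
#'   using their level codes).
#' @param K Number of classes.
#' @return K x K matrix of counts; rows are true classes, columns
#'   predicted.
#' @export
confusion_matrix <- function(y_true, y_pred, K) {
  to_int <- function(y) if (is.factor(y)) as.integer(y) - 1L else as.integer(y)
  yt <- to_int(y_true); yp <- to_int(y_pred)
  if (length(yt) != length(yp)) stop("length mismatch", call. = FALSE)
  if (any(yt < 0 | yt >= K) || any(yp < 0 | yp >= K)) {
    stop("labels out of range 0..K-1", call. = FALSE)
  }
  m <- matrix(0L, K, K, dimnames = list(true = 0:(K - 1),
                                        predicted = 0:(K - 1)))
  for (i in seq_along(yt)) m[yt[i] + 1L, yp[i] + 1L] <-
      m[yt[i] + 1L, yp[i] + 1L] + 1L
  m
}

#' Precision, recall and F1 for one class
#'
#' One-vs-rest counts from the confusion matrix:
#' precision = TP/(TP+FP), recall = TP/(TP+FN),
#' F1 = 2 P R / (P + R). A zero denominator yields 0 (with a message) —
#' the convention that matters when a small validation set leaves a class
#' unpredicted.
#'
#' @param confusion K x K confusion matrix (rows true, columns predicted).
#' @param k Class index in 0..K-1.
#' @return Named numeric vector \code{c(precision, recall, f1)}.
#' @export
precision_recall_f1 <- function(confusion, k) {
  kk <- k + 1L
  tp <- confusion[kk, kk]
  fp <- sum(confusion[, kk]) - tp
  fn <- sum(confusion[kk, ]) - tp
  safe_div <- function(num, den, what) {
    if (den == 0) {
      message(sprintf("class %d: %s undefined (0/0), reported as 0", k, what))
      return(0)
    }
    num / den
  }
  precision <- safe_div(tp, tp + fp, "precision")
  recall <- safe_div(tp, tp + fn, "recall")
  f1 <- if (precision + recall == 0) 0 else
    2 * precision * recall / (precision + recall)
  c(precision = precision, recall = recall, f1 = f1)
}

#' Rank-based (Mann-Whitney) AUC
#'
#' \deqn{AUC = \frac{\sum_{i \in pos} rank_i - n_1(n_1+1)/2}{n_1 n_2}}
#' with ranks ascending in score and average ranks for ties, which makes
#' the statistic equal the fraction of positive-negative pairs ordered
#' correctly, ties counting one half.
#'
#' @param scores Numeric prediction scores.
#' @param labels Binary labels (1 = positive, 0 = negative; logicals
#'   accepted).
#' @return AUC in [0, 1]; \code{NA} with a warning when only one class is
#'   present.
#' @export
rank_auc <- function(scores, labels) {
  labels <- as.integer(as.logical(labels))
  n1 <- sum(labels == 1L)
  n2 <- sum(labels == 0L)
  if (n1 == 0L || n2 == 0L) {
    warning("rank_auc: only one class present; AUC undefined", call. = FALSE)
    return(NA_real_)
  }
  ranks <- rank(scores)          # average ranks for ties
  (sum(ranks[labels == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n2)
}

#' One-vs-rest AUC for each class
#'
#' Class k's AUC is \code{rank_auc} of the predicted probability of class
#' k against the indicator of membership in class k. The average is the
#' unweighted mean over classes with a defined value; a class absent from
#' \code{y_true} gets \code{NA} and a warning and is excluded.
#'
#' @param proba Samples x K matrix of class probabilities (rows sum to 1).
#' @param y_true Integer labels 0..K-1 or a factor.
#' @return List with \code{per_class} (length-K named vector) and
#'   \code{average}.
#' @export
one_vs_rest_auc <- function(proba, y_true) {
  proba <- as.matrix(proba)
  K <- ncol(proba)
  yt <- if (is.factor(y_true)) as.integer(y_true) - 1L else as.integer(y_true)
  per <- setNames(rep(NA_real_, K),
                  colnames(proba) %||% as.character(0:(K - 1)))
  for (k in seq_len(K)) {
    pos <- yt == (k - 1L)
    if (!any(pos) || all(pos)) {
      warning("class ", k - 1L,
              " absent from y_true (or fills it); AUC undefined",
              call. = FALSE)
      next
    }
    per[k] <- rank_auc(proba[, k], pos)
  }
  list(per_class = per, average = mean(per, na.rm = TRUE))
}

#' ROC curve points
#'
#' Sweeps a threshold over every distinct score, descending, emitting
#' (false positive rate, true positive rate) pairs. The curve starts at
#' (0, 0), ends at (1, 1), and is monotone non-decreasing in both
#' coordinates; its trapezoidal area equals \code{\link{rank_auc}}.
#'
#' @inheritParams rank_auc
#' @return Data frame with columns \code{threshold}, \code{fpr},
#'   \code{tpr}.
#' @export
roc_curve <- function(scores, labels) {
  labels <- as.integer(as.logical(labels))
  n1 <- sum(labels == 1L); n2 <- sum(labels == 0L)
  if (n1 == 0L || n2 == 0L) {
    warning("roc_curve: only one class present", call. = FALSE)
    return(data.frame(threshold = numeric(0), fpr = numeric(0),
                      tpr = numeric(0)))
  }
  thr <- sort(unique(scores), decreasing = TRUE)
  tpr <- vapply(thr, function(t) sum(labels == 1L & scores >= t) / n1,
                numeric(1))
  fpr <- vapply(thr, function(t) sum(labels == 0L & scores >= t) / n2,
                numeric(1))
  data.frame(threshold = c(Inf, thr), fpr = c(0, fpr), tpr = c(0, tpr))
}

#' Evaluate a fitted tree on held-out data
#'
#' Assembles the confusion matrix, per-class and macro (unweighted mean)
#' precision/recall/F1, and per-class one-vs-rest AUC from leaf-frequency
#' probability scores.
#'
#' @param model A fitted \code{fh_tree}.
#' @param X_test Held-out feature matrix or data frame (non-empty).
#' @param y_test True labels (factor on the model's classes, or integers
#'   0..K-1).
#' @param split_seed,train_fraction Optional bookkeeping recorded in the
#'   report.
#' @return An \code{eval_report}.
#' @export
evaluation_report <- function(model, X_test, y_test, split_seed = NA,
                              train_fraction = NA) {
  if (NROW(X_test) == 0L) stop("empty test set", call. = FALSE)
  K <- length(model$classes)
  yt <- if (is.factor(y_test)) as.integer(y_test) - 1L else as.integer(y_test)
  pred <- predict(model, X_test, type = "class")
  proba <- predict(model, X_test, type = "prob")
  conf <- confusion_matrix(yt, as.integer(pred) - 1L, K)
  per <- t(vapply(0:(K - 1), function(k) precision_recall_f1(conf, k),
                  numeric(3)))
  per_class <- data.frame(class = model$classes,
                          precision = per[, "precision"],
                          recall = per[, "recall"],
                          f1 = per[, "f1"],
                          row.names = NULL)
  auc <- one_vs_rest_auc(proba, yt)
  rep <- list(
    confusion = conf,
    per_class = per_class,
    macro = c(precision = mean(per_class$precision),
              recall = mean(per_class$recall),
              f1 = mean(per_class$f1)),
    auc_per_class = auc$per_class,
    auc_average = auc$average,
    n_test = NROW(X_test),
    split_seed = split_seed,
    train_fraction = train_fraction
  )
  class(rep) <- "eval_report"
  rep
}

#' @export
print.eval_report <- function(x, digits = 4, ...) {
  cat("Evaluation on", x$n_test, "held-out plots\n")
  print(x$confusion)
  print(transform(x$per_class,
                  precision = round(precision, digits),
                  recall = round(recall, digits),
                  f1 = round(f1, digits)))
  cat("macro:", paste(names(x$macro), round(x$macro, digits),
                      sep = "=", collapse = "  "), "\n")
  cat("average one-vs-rest AUC:", round(x$auc_average, digits), "\n")
  invisible(x)
}
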