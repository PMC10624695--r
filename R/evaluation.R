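#' Stratified hold-out split
#'
#' Splits sample indices into train/test sets, stratified by class: each
#' class contributes `round(train_fraction * n_k)` training samples
#' (clamped so both sides keep at least one sample). Deterministic for a
#' given seed.
#'
#' @param labels class labels.
#' @param train_fraction fraction of each class used for training,
#'   in (0, 1); default 0.8.
#' @param seed integer seed.
#' @return List with integer index vectors `train` and `test`, plus the
#'   `seed` used.
#' @export
split_holdout <- function(labels, train_fraction = 0.8, seed = 1L) {
  if (train_fraction <= 0 || train_fraction >= 1)
    stop("'train_fraction' must be in (0, 1)")
  labels <- as.character(labels)
  counts <- table(labels)
  if (any(counts < 2))
    stop(sprintf("class '%s' has fewer than 2 samples; cannot split",
                 names(counts)[which(counts < 2)[1]]))
  with_seed(seed, {
    train <- integer(0)
    for (cls in sort(names(counts))) {
      idx <- which(labels == cls)
      n_tr <- min(max(round(train_fraction * length(idx)), 1L),
                  length(idx) - 1L)
      train <- c(train, sort(sample(idx, n_tr)))
    }
    train <- sort(train)
    list(train = train, test = setdiff(seq_along(labels), train), seed = seed)
  })
}

#' Stratified k-fold partitions
#'
#' Assigns each sample to exactly one of `k` test folds, stratified by
#' class when every class has at least `k` samples (otherwise falls back to
#' a plain shuffled partition with a warning).
#'
#' @param labels class labels.
#' @param k number of folds (>= 2).
#' @param seed integer seed.
#' @return List of `k` elements, each with `train` and `test` index
#'   vectors; the test sets partition `seq_along(labels)`.
#' @export
kfold <- function(labels, k = 10L, seed = 1L) {
  labels <- as.character(labels)
  n <- length(labels)
  if (k < 2) stop("'k' must be >= 2")
  if (k > n) stop("'k' exceeds the number of samples")
  with_seed(seed, {
    fold <- integer(n)
    counts <- table(labels)
    if (any(counts < k)) {
      warning("some class has fewer than ", k,
              " samples; using a non-stratified partition")
      fold <- sample(rep_len(seq_len(k), n))
    } else {
      for (cls in sort(names(counts))) {
        idx <- sample(which(labels == cls))
        fold[idx] <- rep_len(seq_len(k), length(idx))
      }
    }
    lapply(seq_len(k), function(f)
      list(train = which(fold != f), test = which(fold == f)))
  })
}

# One-vs-rest ranking AUC with midrank tie handling.
auc_binary <- function(scores, positive) {
  n1 <- sum(positive)
  n0 <- sum(!positive)
  if (n1 == 0 || n0 == 0) return(NA_real_)
  rk <- rank(scores)
  (sum(rk[positive]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Evaluate predictions against truth
#'
#' Builds the K x K confusion matrix (rows = true class, columns =
#' predicted), accuracy, per-class precision/recall/F1, and the macro
#' (unweighted) mean of one-vs-rest ranking AUCs computed from each class's
#' score column with midrank tie handling.
#'
#' @param truth true class labels.
#' @param predicted predicted labels; every value must be a known class.
#' @param scores optional `n x K` score matrix (larger = more class-like,
#'   e.g. negated residuals), columns aligned to `classes`.
#' @param classes class order; defaults to `colnames(scores)` or the sorted
#'   union of labels.
#' @return An object of class `"wst_eval_report"`: list with `confusion`,
#'   `accuracy`, `per_class` (data frame), `auc_macro`, `class_order`, `n`.
#' @export
evaluate_predictions <- function(truth, predicted, scores = NULL,
                                 classes = NULL) {
  truth <- as.character(truth)
  predicted <- as.character(predicted)
  if (length(truth) != length(predicted))
    stop("'truth' and 'predicted' must have equal length")
  if (is.null(classes))
    classes <- if (!is.null(scores) && !is.null(colnames(scores)))
      colnames(scores) else sort(unique(c(truth, predicted)))
  if (!all(predicted %in% classes))
    stop("prediction contains a label outside the stated class order")
  if (!all(truth %in% classes))
    stop("truth contains a label outside the stated class order")
  confusion <- table(true = factor(truth, classes),
                     predicted = factor(predicted, classes))
  confusion <- unclass(confusion)
  acc <- sum(diag(confusion)) / sum(confusion)
  tp <- diag(confusion)
  prec <- tp / pmax(colSums(confusion), 1)
  prec[colSums(confusion) == 0] <- NA_real_
  rec <- tp / pmax(rowSums(confusion), 1)
  rec[rowSums(confusion) == 0] <- NA_real_
  f1 <- ifelse(is.na(prec) | is.na(rec) | (prec + rec) == 0, NA_real_,
               2 * prec * rec / (prec + rec))
  per_class <- data.frame(class = classes, n = as.integer(rowSums(confusion)),
                          precision = as.numeric(prec),
                          recall = as.numeric(rec), f1 = as.numeric(f1))
  auc_macro <- NA_real_
  if (!is.null(scores)) {
    scores <- as.matrix(scores)
    if (nrow(scores) != length(truth) || ncol(scores) != length(classes))
      stop("'scores' must be n x K, aligned to the class order")
    aucs <- vapply(seq_along(classes), function(k)
      auc_binary(scores[, k], truth == classes[k]), numeric(1))
    auc_macro <- mean(aucs, na.rm = TRUE)
  }
  structure(
    list(confusion = confusion, accuracy = acc, per_class = per_class,
         auc_macro = auc_macro, class_order = classes, n = length(truth)),
    class = "wst_eval_report"
  )
}

#' @export
print.wst_eval_report <- function(x, ...) {
  cat(sprintf("Evaluation on %d samples: accuracy %.4f", x$n, x$accuracy))
  if (!is.na(x$auc_macro)) cat(sprintf(", macro OvR AUC %.4f", x$auc_macro))
  cat("\nConfusion matrix (rows = true):\n")
  print(x$confusion)
  invisible(x)
}

#' Write an evaluation report to disk
#'
#' Writes `<stem>.json` (full report, class order recorded explicitly) and
#' `<stem>_confusion.csv`.
#'
#' @param report a `"wst_eval_report"`.
#' @param stem output path stem (no extension).
#' @export
write_report <- function(report, stem) {
  out <- list(
    class_order = report$class_order,
    accuracy = report$accuracy,
    auc_macro = report$auc_macro,
    confusion = unname(apply(report$confusion, 1, as.integer, simplify = FALSE)),
    per_class = report$per_class,
    n = report$n
  )
  jsonlite::write_json(out, paste0(stem, ".json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  utils::write.csv(as.data.frame.matrix(report$confusion),
                   paste0(stem, "_confusion.csv"))
  invisible(stem)
}
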