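# Performance evaluation: confusion-matrix metrics (SN, SP, ACC, MCC,
# Precision, F1) and stratified k-fold cross-validation with configurable
# SMOTE placement.

#' Confusion matrix for binary predictions
#'
#' Label 1 is the positive class.
#'
#' @param truth,predicted equal-length 0/1 vectors.
#' @return object of class `confusion_matrix`: list with TP, FP, TN, FN.
#' @export
confusion_matrix <- function(truth, predicted) {
  if (length(truth) != length(predicted)) {
    stop("truth and predicted must have equal length")
  }
  truth <- as.integer(truth)
  predicted <- as.integer(predicted)
  if (!all(c(truth, predicted) %in% c(0L, 1L))) {
    stop("labels must be binary 0/1")
  }
  cm <- list(TP = sum(truth == 1L & predicted == 1L),
             FP = sum(truth == 0L & predicted == 1L),
             TN = sum(truth == 0L & predicted == 0L),
             FN = sum(truth == 1L & predicted == 0L))
  class(cm) <- "confusion_matrix"
  cm
}

#' Metrics of a binary confusion matrix
#'
#' Computes sensitivity (SN = Recall), specificity (SP), accuracy (ACC),
#' Matthews correlation coefficient (MCC), Precision and F1-measure:
#' \deqn{MCC = (TP \cdot TN - FP \cdot FN) / \sqrt{(TN+FN)(TN+FP)(TP+FN)(TP+FP)}}
#' Zero-denominator conventions: MCC = 0 when any factor under the root is
#' 0; Precision = 0 when TP + FP = 0; SN/SP = 0 when their denominators are
#' 0; F1 = 0 when Precision + Recall = 0.
#'
#' @param cm a [confusion_matrix()].
#' @return named numeric vector (class `metrics_report`) with elements
#'   SN, SP, ACC, MCC, Precision, F1.
#' @export
compute_metrics <- function(cm) {
  stopifnot(inherits(cm, "confusion_matrix"))
  tp <- as.numeric(cm$TP); fp <- as.numeric(cm$FP)
  tn <- as.numeric(cm$TN); fn <- as.numeric(cm$FN)
  if (tp + fp + tn + fn < 1) stop("empty confusion matrix")
  sn <- if (tp + fn > 0) tp / (tp + fn) else 0
  sp <- if (tn + fp > 0) tn / (tn + fp) else 0
  acc <- (tp + tn) / (tp + fp + tn + fn)
  denom <- (tn + fn) * (tn + fp) * (tp + fn) * (tp + fp)
  mcc <- if (denom > 0) (tp * tn - fp * fn) / sqrt(denom) else 0
  precision <- if (tp + fp > 0) tp / (tp + fp) else 0
  f1 <- if (precision + sn > 0) 2 * precision * sn / (precision + sn) else 0
  structure(c(SN = sn, SP = sp, ACC = acc, MCC = mcc,
              Precision = precision, F1 = f1),
            class = c("metrics_report", "numeric"))
}

#' @export
print.metrics_report <- function(x, ...) {
  print(round(unclass(x), 4))
  invisible(x)
}

#' Stratified k-fold assignment
#'
#' Shuffles each class independently and deals samples round-robin into
#' folds, so fold sizes are near-equal and every fold keeps the class
#' proportions as closely as integer counts allow.
#'
#' @param labels binary 0/1 vector.
#' @param k number of folds (default 10).
#' @param seed integer seed.
#' @return integer vector of fold indices in 1..k, one per sample.
#' @export
stratified_folds <- function(labels, k = 10, seed = 1L) {
  labels <- as.integer(labels)
  if (k < 2) stop("k must be >= 2")
  counts <- table(labels)
  if (any(counts < k)) {
    stop("every class needs at least k members (smallest has ",
         min(counts), "); lower k")
  }
  set.seed(seed)
  fold <- integer(length(labels))
  for (cls in unique(labels)) {
    idx <- which(labels == cls)
    fold[idx[sample.int(length(idx))]] <- rep_len(seq_len(k), length(idx))
  }
  fold
}

#' Cross-validated evaluation of a CART classifier
#'
#' Stratified k-fold cross-validation on the given feature subset, with
#' three SMOTE placements:
#' \describe{
#'   \item{`train_only`}{(default) balance each training fold only and test
#'     on the untouched held-out fold; no synthetic sample ever reaches a
#'     test fold. Pooled held-out predictions over the original samples.}
#'   \item{`global`}{balance the full dataset first, then fold the
#'     augmented data; pooled predictions cover all augmented samples.
#'     Closest to the study's description, but synthetic points derived
#'     from test samples can leak into training.}
#'   \item{`off`}{no balancing.}
#' }
#' Metrics are computed once on the pooled held-out predictions.
#'
#' @param x numeric feature matrix.
#' @param labels binary 0/1 vector.
#' @param features character vector of column names (or integer indices)
#'   defining the feature subset (default: all columns).
#' @param config a [tree_config()].
#' @param smote_mode one of `"train_only"`, `"global"`, `"off"`.
#' @param k number of folds.
#' @param fold_seed seed for fold assignment.
#' @param smote_config a [smote_config()]; its seed is offset by the fold
#'   index in `train_only` mode so each fold balances independently.
#' @return a `metrics_report` with attribute `details`: list with pooled
#'   `predictions`, `truth`, `folds` and `synthetic` flags.
#' @export
cross_validate <- function(x, labels, features = colnames(x),
                           config = tree_config(),
                           smote_mode = c("train_only", "global", "off"),
                           k = 10, fold_seed = 1L,
                           smote_config = lncrules::smote_config()) {
  smote_mode <- match.arg(smote_mode)
  x <- as.matrix(x)
  labels <- as.integer(labels)
  stopifnot(nrow(x) == length(labels))
  if (!is.null(features)) x <- x[, features, drop = FALSE]

  synthetic <- rep(FALSE, nrow(x))
  if (smote_mode == "global") {
    bal <- balance_dataset(x, labels, smote_config)
    x <- bal$x
    labels <- bal$labels
    synthetic <- bal$synthetic
  }
  fold <- stratified_folds(labels, k, fold_seed)
  pred <- integer(length(labels))
  for (f in seq_len(k)) {
    tr <- fold != f
    xtr <- x[tr, , drop = FALSE]
    ytr <- labels[tr]
    if (smote_mode == "train_only") {
      cfg_f <- smote_config
      cfg_f$seed <- smote_config$seed + f
      bal <- balance_dataset(xtr, ytr, cfg_f)
      xtr <- bal$x
      ytr <- bal$labels
    }
    model <- grow_tree(xtr, ytr, config)
    pred[fold == f] <- predict_label(model, x[fold == f, , drop = FALSE])
  }
  metrics <- compute_metrics(confusion_matrix(labels, pred))
  attr(metrics, "details") <- list(predictions = pred, truth = labels,
                                   folds = fold, synthetic = synthetic)
  metrics
}
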