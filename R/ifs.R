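# Incremental feature selection (IFS): evaluate nested prefixes of the mRMR
# feature list with a cross-validated CART classifier, pick the MCC-optimal
# prefix and a smaller trade-off prefix, and train the final rule model.

#' Subset sizes for incremental feature selection
#'
#' Sizes `step, 2*step, ...` up to `n_features`, with `n_features` appended
#' when it is not a multiple of `step` so the curve always ends at the full
#' feature set. `step = 1` recovers the canonical one-feature-at-a-time IFS.
#'
#' @param n_features total number of features (>= 1).
#' @param step increment between consecutive subset sizes.
#' @return increasing integer vector of subset sizes.
#' @export
build_subset_sizes <- function(n_features, step = 10) {
  stopifnot(n_features >= 1, step >= 1)
  sizes <- if (step > n_features) integer(0) else
    seq.int(step, n_features, by = step)
  if (length(sizes) == 0L || sizes[length(sizes)] != n_features) {
    sizes <- c(sizes, n_features)
  }
  as.integer(sizes)
}

#' Run incremental feature selection
#'
#' For each subset size, cross-validates a CART tree on the top-`s` features
#' of the mRMR list (prefixes are nested by construction) and records the
#' pooled metrics. The optimum is the smallest size attaining the maximal
#' MCC; the trade-off point is the smallest size within `tradeoff_delta` of
#' that maximum.
#'
#' @param x numeric feature matrix (columns named by term ids).
#' @param labels binary 0/1 vector.
#' @param ranked ranked feature list from [mrmr_rank()] (or
#'   [read_ranked_list()]); must cover the columns of `x`.
#' @param step subset-size increment (default 10, the study's setting).
#' @param k folds for cross-validation.
#' @param config a [tree_config()].
#' @param smote_mode SMOTE placement, see [cross_validate()].
#' @param fold_seed,smote_seed stage seeds.
#' @param tradeoff_delta MCC tolerance for the trade-off point.
#' @return object of class `ifs_curve`: list with `curve` (data frame:
#'   n_features, SN, SP, ACC, MCC, Precision, F1), `optimum_size`,
#'   `optimum_mcc`, `tradeoff_size` and the evaluation settings.
#' @export
run_ifs <- function(x, labels, ranked, step = 10, k = 10,
                    config = tree_config(),
                    smote_mode = c("train_only", "global", "off"),
                    fold_seed = 1L, smote_seed = 1L,
                    tradeoff_delta = 0.025) {
  smote_mode <- match.arg(smote_mode)
  x <- as.matrix(x)
  if (!all(ranked$feature_id %in% colnames(x))) {
    stop("ranked list contains features absent from the matrix")
  }
  sizes <- build_subset_sizes(nrow(ranked), step)
  rows <- lapply(sizes, function(s) {
    m <- cross_validate(x, labels, features = ranked$feature_id[seq_len(s)],
                        config = config, smote_mode = smote_mode, k = k,
                        fold_seed = fold_seed,
                        smote_config = smote_config(seed = smote_seed))
    c(n_features = s, unclass(m)[c("SN", "SP", "ACC", "MCC", "Precision",
                                   "F1")])
  })
  curve <- as.data.frame(do.call(rbind, rows))
  curve$n_features <- as.integer(curve$n_features)
  opt_idx <- which.max(curve$MCC)  # ties -> smallest size (sizes ascend)
  out <- list(curve = curve,
              optimum_size = curve$n_features[opt_idx],
              optimum_mcc = curve$MCC[opt_idx],
              tradeoff_size = select_tradeoff(curve, tradeoff_delta),
              step = step, k = k, smote_mode = smote_mode,
              fold_seed = fold_seed, smote_seed = smote_seed,
              tradeoff_delta = tradeoff_delta)
  class(out) <- "ifs_curve"
  out
}

#' @export
print.ifs_curve <- function(x, ...) {
  cat("ifs_curve:", nrow(x$curve), "subset sizes; optimum MCC",
      round(x$optimum_mcc, 4), "at", x$optimum_size,
      "features; trade-off at", x$tradeoff_size, "\n")
  invisible(x)
}

#' Trade-off subset size on an IFS curve
#'
#' The smallest subset size whose MCC is within `delta` of the curve's
#' maximal MCC — a compact classifier at near-optimal performance.
#'
#' @param curve data frame with columns `n_features` and `MCC` (an
#'   `ifs_curve` object is also accepted).
#' @param delta non-negative MCC tolerance.
#' @return integer subset size.
#' @export
select_tradeoff <- function(curve, delta = 0.025) {
  if (inherits(curve, "ifs_curve")) curve <- curve$curve
  stopifnot(nrow(curve) >= 1, delta >= 0)
  ok <- curve$MCC >= max(curve$MCC) - delta
  as.integer(min(curve$n_features[ok]))
}

#' Train the final rule model on all samples
#'
#' Restricts to the top-`size` mRMR features, optionally balances the whole
#' dataset with SMOTE, grows a CART tree on all samples, and extracts and
#' summarizes its decision rules. Leaf supports (and the rule report) refer
#' to the training data the tree saw, i.e. including synthetic samples when
#' `smote = TRUE`.
#'
#' @param x numeric feature matrix.
#' @param labels binary 0/1 vector.
#' @param ranked ranked feature list from [mrmr_rank()].
#' @param size number of top-ranked features to keep.
#' @param smote balance the training data first? (default TRUE)
#' @param config a [tree_config()].
#' @param smote_config a [smote_config()].
#' @param term_metadata optional named term descriptions for the report.
#' @return list with `model`, `ruleset`, `report`, `features` and
#'   `training_metrics` (training-set metrics on the original samples).
#' @export
train_final_rule_model <- function(x, labels, ranked, size, smote = TRUE,
                                   config = tree_config(),
                                   smote_config = lncrules::smote_config(),
                                   term_metadata = NULL) {
  x <- as.matrix(x)
  stopifnot(size >= 1, size <= nrow(ranked))
  feats <- ranked$feature_id[seq_len(size)]
  xs <- x[, feats, drop = FALSE]
  labels <- as.integer(labels)
  xtr <- xs
  ytr <- labels
  if (smote) {
    bal <- balance_dataset(xs, labels, smote_config)
    xtr <- bal$x
    ytr <- bal$labels
  }
  model <- grow_tree(xtr, ytr, config)
  ruleset <- extract_rules(model)
  pred <- predict_label(model, xs)
  list(model = model, ruleset = ruleset,
       report = summarize_rules(ruleset, term_metadata),
       features = feats,
       training_metrics = compute_metrics(confusion_matrix(labels, pred)))
}
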