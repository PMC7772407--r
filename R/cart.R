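# CART decision tree: R-side interface over the compiled induction core.

#' CART tree configuration
#'
#' Defaults mirror unconstrained CART (grow to purity): no depth limit,
#' `min_samples_split = 2`, `min_samples_leaf = 1`.
#'
#' @param max_depth maximum tree depth (`Inf` = unlimited; depth 0 is the
#'   root).
#' @param min_samples_split minimum node size eligible for splitting.
#' @param min_samples_leaf minimum samples in each child of a split.
#' @return an object of class `tree_config`.
#' @export
tree_config <- function(max_depth = Inf, min_samples_split = 2,
                        min_samples_leaf = 1) {
  if (min_samples_split < 2) stop("min_samples_split must be >= 2")
  if (min_samples_leaf < 1) stop("min_samples_leaf must be >= 1")
  structure(list(max_depth = max_depth,
                 min_samples_split = as.integer(min_samples_split),
                 min_samples_leaf = as.integer(min_samples_leaf)),
            class = "tree_config")
}

#' Gini impurity of a binary class-count pair
#'
#' \eqn{1 - \sum_c (n_c / n)^2}; 0 for a pure node, 0.5 for a balanced one.
#'
#' @param class_counts non-negative counts (one per class), total >= 1.
#' @return impurity in [0, 0.5] for two classes.
#' @export
gini_impurity <- function(class_counts) {
  total <- sum(class_counts)
  if (total < 1) stop("total count must be >= 1")
  1 - sum((class_counts / total)^2)
}

#' Best Gini split of a set of samples
#'
#' Exhaustive search over all features and all candidate thresholds
#' (midpoints of consecutive distinct sorted values), maximizing the
#' weighted Gini impurity decrease subject to `min_samples_leaf`. Ties go to
#' the lowest feature index, then the smallest threshold. Returns `NULL`
#' when no admissible split improves impurity.
#'
#' @param x numeric feature matrix.
#' @param y integer 0/1 labels.
#' @param config a [tree_config()].
#' @param idx row indices defining the node (default: all rows).
#' @return list with `feature` (column index), `feature_id`, `threshold`
#'   and `gain` (weighted impurity decrease), or `NULL`.
#' @export
find_best_split <- function(x, y, config = tree_config(),
                            idx = seq_len(nrow(x))) {
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  res <- cpp_best_split(x, as.integer(y), as.integer(idx),
                        config$min_samples_leaf)
  if (!res$found) return(NULL)
  list(feature = res$feature,
       feature_id = if (!is.null(colnames(x))) colnames(x)[res$feature]
                    else res$feature,
       threshold = res$threshold, gain = res$gain)
}

#' Grow a binary CART decision tree
#'
#' Top-down induction with exhaustive best-split search per node (no
#' randomization). Growth stops at purity, at the depth/size limits of
#' `config`, or when no split strictly decreases impurity. Leaves predict
#' the majority class; ties predict 0 (conservative for the rare-positive
#' setting). Routing convention: `value <= threshold` goes left.
#'
#' @param x numeric feature matrix with column names.
#' @param y integer 0/1 labels, one per row.
#' @param config a [tree_config()].
#' @return an object of class `cart_model`: list with `nodes` (flat node
#'   data frame), `feature_ids` and `class_totals`.
#' @export
grow_tree <- function(x, y, config = tree_config()) {
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  y <- as.integer(y)
  stopifnot(nrow(x) == length(y), nrow(x) >= 1, all(y %in% c(0L, 1L)))
  if (!all(is.finite(x))) stop("feature matrix must be finite")
  if (is.null(colnames(x))) colnames(x) <- paste0("f", seq_len(ncol(x)))
  md <- if (is.finite(config$max_depth)) as.integer(config$max_depth) else -1L
  raw <- cpp_grow_tree(x, y, md, config$min_samples_split,
                       config$min_samples_leaf)
  nodes <- data.frame(is_leaf = as.logical(raw$is_leaf),
                      feature = raw$feature, threshold = raw$threshold,
                      left = raw$left, right = raw$right,
                      n0 = raw$n0, n1 = raw$n1, pred = raw$pred)
  model <- list(nodes = nodes, feature_ids = colnames(x),
                class_totals = c(n0 = sum(y == 0L), n1 = sum(y == 1L)))
  class(model) <- "cart_model"
  model
}

#' @export
print.cart_model <- function(x, ...) {
  cat("cart_model:", sum(x$nodes$is_leaf), "leaves,",
      sum(!x$nodes$is_leaf), "internal nodes,",
      length(x$feature_ids), "features\n")
  invisible(x)
}

#' Predict class labels with a CART model
#'
#' Routes each sample from the root to a leaf (`value <= threshold` goes
#' left) and returns the leaf's label.
#'
#' @param model a [grow_tree()] model.
#' @param newdata numeric matrix (or single vector) with the model's
#'   feature dimensionality.
#' @return integer vector of 0/1 predictions.
#' @export
predict_label <- function(model, newdata) {
  stopifnot(inherits(model, "cart_model"))
  if (is.null(dim(newdata))) newdata <- matrix(newdata, nrow = 1)
  newdata <- as.matrix(newdata)
  if (ncol(newdata) != length(model$feature_ids)) {
    stop("newdata has ", ncol(newdata), " features; model expects ",
         length(model$feature_ids))
  }
  nd <- model$nodes
  vapply(seq_len(nrow(newdata)), function(i) {
    node <- 1L
    while (!nd$is_leaf[node]) {
      node <- if (newdata[i, nd$feature[node]] <= nd$threshold[node]) {
        nd$left[node]
      } else {
        nd$right[node]
      }
    }
    nd$pred[node]
  }, integer(1))
}

#' Serialize / deserialize a CART model as JSON
#'
#' @param model a `cart_model`.
#' @param path file path.
#' @return `read_cart_json` returns the `cart_model`; `write_cart_json`
#'   returns `path` invisibly.
#' @export
write_cart_json <- function(model, path) {
  stopifnot(inherits(model, "cart_model"))
  payload <- list(feature_ids = model$feature_ids,
                  class_totals = as.list(model$class_totals),
                  nodes = model$nodes)
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       na = "null", pretty = TRUE)
  invisible(path)
}

#' @rdname write_cart_json
#' @export
read_cart_json <- function(path) {
  payload <- jsonlite::read_json(path, simplifyVector = TRUE)
  nodes <- as.data.frame(payload$nodes)
  nodes$feature <- as.integer(nodes$feature)
  model <- list(nodes = nodes,
                feature_ids = as.character(payload$feature_ids),
                class_totals = unlist(payload$class_totals))
  class(model) <- "cart_model"
  model
}
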