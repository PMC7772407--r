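# SMOTE oversampling: grow the minority class to parity with the majority
# by interpolating between real minority samples and their nearest minority
# neighbors in (raw, unscaled) Euclidean feature space.

#' SMOTE configuration
#'
#' @param k_neighbors number of nearest minority neighbors to interpolate
#'   towards (default 5, the study's setting).
#' @param seed integer seed controlling base ordering, neighbor choice and
#'   interpolation draws.
#' @return an object of class `smote_config`.
#' @export
smote_config <- function(k_neighbors = 5, seed = 1L) {
  if (k_neighbors < 1) stop("k_neighbors must be >= 1")
  structure(list(k_neighbors = as.integer(k_neighbors),
                 seed = as.integer(seed)),
            class = "smote_config")
}

#' k nearest minority neighbors of one minority sample
#'
#' Brute-force Euclidean neighbors within the minority class, excluding the
#' query sample itself. Distance ties are broken by the lower row index. If
#' fewer than `k` other samples exist, all of them are returned.
#'
#' @param samples numeric matrix of minority-class feature vectors (rows).
#' @param index row index of the query sample.
#' @param k number of neighbors requested.
#' @return integer vector of neighbor row indices.
#' @export
k_nearest_minority_neighbors <- function(samples, index, k) {
  samples <- as.matrix(samples)
  n <- nrow(samples)
  if (n < 2L) stop("need at least 2 minority samples to find neighbors")
  stopifnot(index >= 1L, index <= n, k >= 1L)
  d2 <- colSums((t(samples) - samples[index, ])^2)
  others <- setdiff(seq_len(n), index)
  ord <- others[order(d2[others], others)]
  ord[seq_len(min(k, length(ord)))]
}

#' Interpolate a synthetic sample between a base and a neighbor
#'
#' Returns `base + u * (neighbor - base)` component-wise; for u in [0, 1]
#' the result lies on the closed segment between the two points.
#'
#' @param base,neighbor equal-length numeric feature vectors.
#' @param u interpolation coefficient in [0, 1].
#' @return numeric feature vector.
#' @export
synthesize_sample <- function(base, neighbor, u) {
  if (length(base) != length(neighbor)) {
    stop("base and neighbor must have the same dimensionality")
  }
  base + u * (neighbor - base)
}

#' Balance a dataset by SMOTE oversampling of the minority class
#'
#' Pads the minority class with synthetic samples until both classes have
#' the same count. Base samples are cycled in a random order (fresh
#' neighbor/interpolation draws on every pass, so heavy imbalance like the
#' study's ~1:260 reuses each base many times). Each synthetic sample is a
#' convex combination of a real minority sample and one of its
#' `k_neighbors` nearest minority neighbors. Original rows are retained
#' unmodified, in their original order, ahead of all synthetic rows.
#'
#' @param x numeric feature matrix.
#' @param labels binary 0/1 vector, one per row.
#' @param config a [smote_config()].
#' @return list with `x` (augmented matrix), `labels` and `synthetic`
#'   (logical provenance flags, `FALSE` for every original row). Returned
#'   unchanged (all-`FALSE` flags) when the classes are already balanced.
#' @export
balance_dataset <- function(x, labels, config = smote_config()) {
  x <- as.matrix(x)
  labels <- as.integer(labels)
  stopifnot(inherits(config, "smote_config"), nrow(x) == length(labels))
  tab <- table(factor(labels, levels = c(0L, 1L)))
  if (tab[1] == 0L || tab[2] == 0L) stop("both classes must be present")
  if (tab[1] == tab[2]) {
    return(list(x = x, labels = labels, synthetic = rep(FALSE, nrow(x))))
  }
  min_label <- if (tab[["1"]] < tab[["0"]]) 1L else 0L
  min_idx <- which(labels == min_label)
  need <- as.integer(abs(tab[1] - tab[2]))
  if (length(min_idx) < 2L) {
    stop("SMOTE needs at least 2 minority samples to interpolate")
  }
  k <- config$k_neighbors
  if (k > length(min_idx) - 1L) {
    warning("k_neighbors capped at minority size - 1 (",
            length(min_idx) - 1L, ")")
    k <- length(min_idx) - 1L
  }
  minority <- x[min_idx, , drop = FALSE]
  nbrs <- lapply(seq_len(nrow(minority)), function(i) {
    k_nearest_minority_neighbors(minority, i, k)
  })

  set.seed(config$seed)
  bases <- rep(sample(nrow(minority)), length.out = need)
  synth <- matrix(0, need, ncol(x))
  for (j in seq_len(need)) {
    b <- bases[j]
    nb <- nbrs[[b]]
    pick <- nb[sample.int(length(nb), 1L)]
    u <- runif(1)
    synth[j, ] <- synthesize_sample(minority[b, ], minority[pick, ], u)
  }
  colnames(synth) <- colnames(x)
  aug <- rbind(x, synth)
  if (!is.null(rownames(x))) {
    rownames(aug) <- c(rownames(x), sprintf("synthetic%05d", seq_len(need)))
  }
  list(x = aug,
       labels = c(labels, rep(min_label, need)),
       synthetic = c(rep(FALSE, nrow(x)), rep(TRUE, need)))
}
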