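# mRMR feature ranking: three-level discretization of enrichment scores,
# discrete mutual information in bits, and the greedy MID (difference)
# criterion: maximize I(f; label) - mean I(f; selected).

#' Discretize a continuous feature into three codes
#'
#' Values above `mean + t * sd` map to +1, below `mean - t * sd` to -1, and
#' the rest to 0, where `sd` is the population standard deviation (divisor
#' n). A constant feature (sd = 0) maps entirely to 0. This mirrors the
#' classical mRMR program's default handling of continuous data.
#'
#' @param values finite numeric vector.
#' @param t positive threshold multiplier (default 1).
#' @return integer vector of codes in \{-1, 0, +1\}.
#' @export
discretize_feature <- function(values, t = 1) {
  if (length(values) == 0L) stop("cannot discretize an empty vector")
  if (!all(is.finite(values))) stop("values must be finite")
  if (t <= 0) stop("threshold multiplier t must be > 0")
  mu <- mean(values)
  sdev <- sqrt(mean((values - mu)^2))  # population sd
  if (sdev == 0) return(integer(length(values)))
  codes <- integer(length(values))
  codes[values > mu + t * sdev] <- 1L
  codes[values < mu - t * sdev] <- -1L
  codes
}

#' Mutual information between two discrete vectors, in bits
#'
#' Empirical MI: \eqn{\sum_{x,y} p(x,y) \log_2[p(x,y) / (p(x) p(y))]} over
#' cells with non-zero joint frequency. Non-negative and symmetric;
#' `mutual_information(x, x)` equals the entropy of `x`.
#'
#' @param x_codes,y_codes equal-length vectors of discrete values.
#' @return MI in bits (single numeric).
#' @export
mutual_information <- function(x_codes, y_codes) {
  if (length(x_codes) != length(y_codes)) {
    stop("x_codes and y_codes must have equal length")
  }
  if (length(x_codes) == 0L) stop("need at least one sample")
  xi <- match(x_codes, sort(unique(x_codes)))
  yi <- match(y_codes, sort(unique(y_codes)))
  .mi_indexed(xi, max(xi), yi, max(yi), length(xi))
}

# MI for pre-indexed codes (1..kx, 1..ky); hot path for mrmr_rank.
.mi_indexed <- function(xi, kx, yi, ky, n) {
  joint <- tabulate((xi - 1L) * ky + yi, kx * ky) / n
  px <- rowSums(matrix(joint, kx, ky, byrow = TRUE))
  py <- colSums(matrix(joint, kx, ky, byrow = TRUE))
  nz <- joint > 0
  pxy <- joint[nz]
  ex <- (rep(px, each = ky) * rep.int(py, kx))[nz]
  sum(pxy * log2(pxy / ex))
}

#' Rank features by minimum redundancy, maximum relevance (mRMR)
#'
#' Discretizes every feature column with [discretize_feature()], then ranks
#' features greedily: the first pick maximizes relevance I(f; label); every
#' later pick maximizes the MID criterion
#' \eqn{I(f; label) - \frac{1}{|S|}\sum_{s \in S} I(f; s)} against the
#' already-selected set S, until all features are listed. Criterion ties are
#' broken by the smaller original column index, so the ranking is fully
#' deterministic and invariant to sample order. Run this on the original
#' (imbalanced) data: class balancing belongs downstream, in classifier
#' evaluation, never before feature ranking.
#'
#' @param x numeric feature matrix (entities x terms, column names = ids).
#' @param labels binary 0/1 vector, one per row of `x`.
#' @param t discretization threshold multiplier (default 1).
#' @return data frame with columns `rank`, `feature_id`, `relevance`,
#'   `redundancy` (mean MI to previously selected features) and `score`
#'   (relevance - redundancy at selection time).
#' @export
mrmr_rank <- function(x, labels, t = 1) {
  x <- as.matrix(x)
  if (is.null(colnames(x))) colnames(x) <- paste0("f", seq_len(ncol(x)))
  if (nrow(x) != length(labels)) stop("labels must match rows of x")
  labels <- as.integer(labels)
  if (length(unique(labels)) < 2L) {
    stop("labels contain a single class; relevance is undefined")
  }
  n <- nrow(x)
  F <- ncol(x)
  codes <- matrix(0L, n, F)
  for (j in seq_len(F)) codes[, j] <- discretize_feature(x[, j], t) + 2L
  yi <- match(labels, sort(unique(labels)))
  ky <- max(yi)

  relevance <- vapply(seq_len(F), function(j) {
    .mi_indexed(codes[, j], 3L, yi, ky, n)
  }, numeric(1))

  rank_id <- integer(F)
  red_out <- numeric(F)
  score_out <- numeric(F)
  remaining <- rep(TRUE, F)
  redsum <- numeric(F)

  for (step in seq_len(F)) {
    if (step == 1L) {
      crit <- relevance
      red <- numeric(F)
    } else {
      red <- redsum / (step - 1L)
      crit <- relevance - red
    }
    crit[!remaining] <- -Inf
    pick <- which.max(crit)  # ties -> smallest column index
    rank_id[step] <- pick
    red_out[step] <- red[pick]
    score_out[step] <- crit[pick]
    remaining[pick] <- FALSE
    if (step < F) {
      idx <- which(remaining)
      picked <- codes[, pick]
      redsum[idx] <- redsum[idx] + vapply(idx, function(j) {
        .mi_indexed(codes[, j], 3L, picked, 3L, n)
      }, numeric(1))
    }
  }
  data.frame(rank = seq_len(F), feature_id = colnames(x)[rank_id],
             relevance = relevance[rank_id], redundancy = red_out,
             score = score_out, stringsAsFactors = FALSE)
}
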