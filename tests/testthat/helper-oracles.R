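# Independent oracles used across the suite. Each is deliberately naive
# (enumeration / brute force / a different library routine) and never shares
# code with the implementation it checks.

# Upper-tail hypergeometric by direct rational enumeration (exact doubles
# for small N, since choose() is exact there).
oracle_hg_tail_log10 <- function(N, M, n, m) {
  if (m == 0) return(0)
  l <- m:min(n, M)
  tail <- sum(choose(M, l) * choose(N - M, n - l)) / choose(N, n)
  -log10(tail)
}

# MI via an explicit double loop over a contingency table.
oracle_mi_bits <- function(x, y) {
  tab <- table(x, y)
  n <- sum(tab)
  px <- rowSums(tab) / n
  py <- colSums(tab) / n
  mi <- 0
  for (i in seq_len(nrow(tab))) {
    for (j in seq_len(ncol(tab))) {
      p <- tab[i, j] / n
      if (p > 0) mi <- mi + p * log2(p / (px[i] * py[j]))
    }
  }
  unname(mi)
}

# Naive mRMR (MID): recompute every pairwise MI from scratch each round.
oracle_mrmr <- function(x, labels, t = 1) {
  disc <- function(v) {
    mu <- mean(v)
    s <- sqrt(mean((v - mu)^2))
    if (s == 0) return(rep(0L, length(v)))
    ifelse(v > mu + t * s, 1L, ifelse(v < mu - t * s, -1L, 0L))
  }
  codes <- apply(x, 2, disc)
  F <- ncol(x)
  rel <- sapply(seq_len(F), function(j) oracle_mi_bits(codes[, j], labels))
  selected <- integer(0)
  for (step in seq_len(F)) {
    cand <- setdiff(seq_len(F), selected)
    crit <- sapply(cand, function(j) {
      red <- if (length(selected) == 0) 0 else {
        mean(sapply(selected, function(s) {
          oracle_mi_bits(codes[, j], codes[, s])
        }))
      }
      rel[j] - red
    })
    selected <- c(selected, cand[which.max(crit)])
  }
  selected
}

# Brute-force best Gini split: enumerate every feature / midpoint.
oracle_best_split <- function(x, y, min_leaf = 1) {
  n <- nrow(x)
  c0 <- sum(y == 0); c1 <- sum(y == 1)
  parent <- n - (c0^2 + c1^2) / n
  best <- NULL
  best_score <- parent
  for (j in seq_len(ncol(x))) {
    vals <- sort(unique(x[, j]))
    if (length(vals) < 2) next
    for (i in seq_len(length(vals) - 1)) {
      thr <- (vals[i] + vals[i + 1]) / 2
      left <- x[, j] <= thr
      nL <- sum(left); nR <- n - nL
      if (nL < min_leaf || nR < min_leaf) next
      l0 <- sum(y[left] == 0); l1 <- nL - l0
      r0 <- c0 - l0; r1 <- c1 - l1
      score <- nL - (l0^2 + l1^2) / nL + nR - (r0^2 + r1^2) / nR
      if (score < best_score) {
        best_score <- score
        best <- list(feature = j, threshold = thr,
                     gain = (parent - score) / n)
      }
    }
  }
  best
}

# Brute-force k nearest neighbors by full distance sort.
oracle_knn <- function(samples, index, k) {
  d <- sqrt(rowSums(sweep(samples, 2, samples[index, ])^2))
  ord <- order(d, seq_len(nrow(samples)))
  ord <- ord[ord != index]
  ord[seq_len(min(k, length(ord)))]
}

# MCC as the Pearson correlation of the underlying binary vectors.
oracle_mcc_cor <- function(tp, fp, tn, fn) {
  truth <- c(rep(1, tp), rep(1, fn), rep(0, tn), rep(0, fp))
  pred <- c(rep(1, tp), rep(0, fn), rep(0, tn), rep(1, fp))
  if (length(unique(truth)) < 2 || length(unique(pred)) < 2) return(0)
  unname(stats::cor(truth, pred))
}

# Tiny hand-built fixture: 10 genes, 4 terms, 3 entities.
tiny_fixture <- function() {
  genes <- paste0("g", 1:10)
  db <- annotation_db(
    list(T1 = genes[1:4], T2 = genes[3:8], T3 = genes[9:10],
         K1 = genes[c(1, 5, 9)]),
    c(T1 = "GO", T2 = "GO", T3 = "GO", K1 = "KEGG"))
  profiles <- list(e1 = genes[1:3], e2 = genes[c(4, 9, 10)],
                   e3 = genes[5:7])
  labels <- c(e1 = 1L, e2 = 0L, e3 = 0L)
  list(universe = genes, db = db, profiles = profiles, labels = labels)
}

# Small separable dataset for classifier tests.
separable_data <- function(n = 40, seed = 1) {
  set.seed(seed)
  y <- rep(0:1, each = n / 2)
  x <- cbind(a = rnorm(n) + 3 * y, b = rnorm(n))
  list(x = x, y = y)
}
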