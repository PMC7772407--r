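# Enrichment-score encoding: each entity becomes a vector of -log10
# hypergeometric upper-tail probabilities, one per annotation term. This is
# the feature representation everything downstream consumes.

#' Upper-tail hypergeometric probability, -log10, in log space
#'
#' Computes \deqn{-\log_{10} \sum_{l=m}^{\min(n,M)}
#'   \binom{M}{l}\binom{N-M}{n-l} / \binom{N}{n}}
#' the probability of observing at least `m` annotated genes when drawing
#' `n` genes from a universe of `N` containing `M` annotated ones. The sum
#' is evaluated with log-gamma binomials and log-sum-exp, so it neither
#' underflows nor overflows at genome scale (N in the tens of thousands).
#' Vectorized over its arguments (recycled to a common length).
#'
#' @param N universe size (total genes).
#' @param M genes annotated to the term.
#' @param n genes in the entity's co-expressed set.
#' @param m overlap between the co-expressed set and the term.
#' @return non-negative numeric score(s); 0 when `m = 0` (the tail is 1).
#' @export
hypergeometric_tail_log10 <- function(N, M, n, m) {
  len <- max(length(N), length(M), length(n), length(m))
  N <- rep_len(as.numeric(N), len)
  M <- rep_len(as.numeric(M), len)
  n <- rep_len(as.numeric(n), len)
  m <- rep_len(as.numeric(m), len)
  bad <- !is.finite(N) | !is.finite(M) | !is.finite(n) | !is.finite(m) |
    N < 1 | M < 0 | n < 0 | m < 0 | M > N | n > N | m > pmin(M, n)
  if (any(bad)) {
    i <- which(bad)[1]
    stop(sprintf(
      "invalid enrichment query at position %d: N=%g, M=%g, n=%g, m=%g (need 0 <= m <= min(M, n), M <= N, n <= N)",
      i, N[i], M[i], n[i], m[i]))
  }
  vapply(seq_len(len), function(i) {
    .hg_tail_one(N[i], M[i], n[i], m[i])
  }, numeric(1))
}

.hg_tail_one <- function(N, M, n, m) {
  if (m == 0) return(0)  # tail over the full support sums to 1 exactly
  l <- m:min(n, M)
  logterms <- lchoose(M, l) + lchoose(N - M, n - l) - lchoose(N, n)
  mx <- max(logterms)
  log_tail <- mx + log(sum(exp(logterms - mx)))
  max(-log_tail / log(10), 0)
}

#' Enrichment score of one entity against one term
#'
#' Restricts both gene sets to the universe, builds the hypergeometric
#' query (N = universe size, M = in-universe term size, n = in-universe
#' profile size, m = overlap) and delegates to
#' [hypergeometric_tail_log10()]. An entity with no in-universe genes
#' scores 0 against every term (the tail over an empty draw is 1), with a
#' warning.
#'
#' @param universe character vector of universe gene ids.
#' @param term_genes character vector, the term's gene set.
#' @param profile_genes character vector, the entity's co-expressed genes.
#' @return a single non-negative score.
#' @export
enrichment_score <- function(universe, term_genes, profile_genes) {
  universe <- unique(as.character(universe))
  term_genes <- intersect(term_genes, universe)
  profile_genes <- intersect(profile_genes, universe)
  if (length(profile_genes) == 0L) {
    warning("profile has no genes in the universe; score is 0 by convention")
    return(0)
  }
  hypergeometric_tail_log10(
    N = length(universe), M = length(term_genes),
    n = length(profile_genes),
    m = length(intersect(profile_genes, term_genes)))
}

#' Encode co-expression profiles as an enrichment feature matrix
#'
#' Builds the entities-by-terms matrix of enrichment scores: cell (i, j) is
#' the [enrichment_score()] of entity i against term j, with columns in the
#' database's fixed order (GO terms first, then KEGG). Genes absent from
#' the universe are ignored in all counts; with `universe = NULL` the
#' universe is inferred as the union of all genes seen in the database and
#' the profiles. Overlap counts are accumulated sparsely and scores are
#' computed once per distinct (M, n, m) triple, so genome-scale encodings
#' stay fast.
#'
#' @param db an [annotation_db].
#' @param profiles named list of character vectors (entity -> genes);
#'   entity ids must be unique.
#' @param universe character vector of gene ids, or `NULL` to infer.
#' @return numeric matrix, rows = entities, columns = term ids.
#' @export
encode_profiles <- function(db, profiles, universe = NULL) {
  stopifnot(inherits(db, "annotation_db"))
  if (length(profiles) == 0L || length(db$term_ids) == 0L) {
    stop("need at least one profile and one term")
  }
  if (is.null(names(profiles)) || anyDuplicated(names(profiles)) > 0) {
    stop("profiles must be a named list with unique entity ids")
  }
  if (is.null(universe)) {
    universe <- union(unlist(db$gene_sets, use.names = FALSE),
                      unlist(profiles, use.names = FALSE))
  }
  universe <- unique(as.character(universe))
  N <- length(universe)

  term_in <- lapply(db$gene_sets, function(g) {
    idx <- match(g, universe)
    idx[!is.na(idx)]
  })
  prof_in <- lapply(profiles, function(g) {
    idx <- match(unique(as.character(g)), universe)
    idx[!is.na(idx)]
  })
  if (any(lengths(prof_in) == 0L)) {
    warning(sum(lengths(prof_in) == 0L),
            " profile(s) have no genes in the universe; their scores are 0")
  }

  n_ent <- length(prof_in)
  n_term <- length(term_in)
  A <- Matrix::sparseMatrix(
    i = unlist(prof_in, use.names = FALSE),
    j = rep.int(seq_len(n_ent), lengths(prof_in)),
    x = 1, dims = c(N, n_ent))
  B <- Matrix::sparseMatrix(
    i = unlist(term_in, use.names = FALSE),
    j = rep.int(seq_len(n_term), lengths(term_in)),
    x = 1, dims = c(N, n_term))
  m_mat <- as.matrix(Matrix::crossprod(A, B))  # entities x terms overlaps

  Mv <- lengths(term_in)
  nv <- lengths(prof_in)
  scores <- matrix(0, n_ent, n_term,
                   dimnames = list(names(profiles), db$term_ids))
  nz <- which(m_mat > 0)
  if (length(nz)) {
    ri <- (nz - 1L) %% n_ent + 1L
    ci <- (nz - 1L) %/% n_ent + 1L
    key <- paste(Mv[ci], nv[ri], m_mat[nz])
    uk <- !duplicated(key)
    uval <- hypergeometric_tail_log10(N, Mv[ci][uk], nv[ri][uk],
                                      m_mat[nz][uk])
    scores[nz] <- uval[match(key, key[uk])]
  }
  scores
}
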