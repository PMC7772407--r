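# Synthetic-data generator. Emulates the structure of the real study data:
# a GO/KEGG-like annotation database, per-lncRNA co-expressed gene sets, and
# a rare positive class whose co-expression profiles are enriched in a small
# set of planted "cancer" terms. All randomness flows through one stream
# seeded from the config, consumed in a documented order (terms, then truth,
# then entities), so a (config, seed) pair pins every downstream artifact.

#' Configuration for the synthetic dataset generator
#'
#' Defaults mirror the study setting at desk scale: 57 positives against a
#' large negative background (1,000 by default; set `n_negative = 14829` for
#' the full ~1:260 imbalance), 288 GO-like + 12 KEGG-like terms, and 10
#' planted discriminative terms from which positives draw a fraction
#' `signal_fraction` of their co-expressed genes.
#'
#' @param n_genes size of the gene universe.
#' @param n_go_terms,n_kegg_terms number of GO-like / KEGG-like terms.
#' @param term_size_range inclusive integer range of term gene-set sizes.
#' @param n_positive,n_negative class sizes (label 1 / label 0).
#' @param n_discriminative_terms number of planted discriminative terms.
#' @param signal_fraction fraction of each positive's co-expressed genes
#'   drawn from the union of planted-term gene sets (0 = pure null).
#' @param coexpr_size_range inclusive integer range of co-expressed gene-set
#'   sizes per entity.
#' @param seed integer seed for the shared random stream.
#' @return an object of class `synthetic_config`.
#' @export
synthetic_config <- function(n_genes = 2000, n_go_terms = 288,
                             n_kegg_terms = 12,
                             term_size_range = c(10, 300),
                             n_positive = 57, n_negative = 1000,
                             n_discriminative_terms = 10,
                             signal_fraction = 0.3,
                             coexpr_size_range = c(20, 200), seed = 1L) {
  cfg <- list(
    n_genes = as.integer(n_genes), n_go_terms = as.integer(n_go_terms),
    n_kegg_terms = as.integer(n_kegg_terms),
    term_size_range = as.integer(term_size_range),
    n_positive = as.integer(n_positive),
    n_negative = as.integer(n_negative),
    n_discriminative_terms = as.integer(n_discriminative_terms),
    signal_fraction = as.numeric(signal_fraction),
    coexpr_size_range = as.integer(coexpr_size_range),
    seed = as.integer(seed)
  )
  counts <- c(cfg$n_genes, cfg$n_go_terms + cfg$n_kegg_terms, cfg$n_positive,
              cfg$n_negative)
  if (any(counts < 1L)) stop("all counts must be positive")
  for (r in list(cfg$term_size_range, cfg$coexpr_size_range)) {
    if (length(r) != 2L || r[1] > r[2] || r[1] < 1L) {
      stop("size ranges must be non-empty inclusive integer intervals")
    }
  }
  if (cfg$term_size_range[2] > cfg$n_genes) {
    stop("term_size_range exceeds the gene universe size")
  }
  if (cfg$coexpr_size_range[2] > cfg$n_genes) {
    stop("coexpr_size_range exceeds the gene universe size")
  }
  if (cfg$n_discriminative_terms > cfg$n_go_terms + cfg$n_kegg_terms ||
      cfg$n_discriminative_terms < 0L) {
    stop("n_discriminative_terms must be in [0, total terms]")
  }
  if (cfg$signal_fraction < 0 || cfg$signal_fraction > 1) {
    stop("signal_fraction must be in [0, 1]")
  }
  class(cfg) <- "synthetic_config"
  cfg
}

.syn_genes <- function(config) sprintf("g%05d", seq_len(config$n_genes))

#' Generate a synthetic annotation database
#'
#' Each term is an independent uniform random gene subset with size drawn
#' uniformly from `term_size_range`; term gene sets may therefore overlap,
#' loosely mirroring GO's nested structure without an ontology DAG. GO terms
#' come first, then KEGG terms.
#'
#' @param config a [synthetic_config()].
#' @param seed optional seed; if `NULL` the current RNG stream is consumed
#'   (as done by [synthesize_dataset()], which seeds once).
#' @return an [annotation_db].
#' @export
generate_annotation_db <- function(config, seed = config$seed) {
  stopifnot(inherits(config, "synthetic_config"))
  if (!is.null(seed)) set.seed(seed)
  genes <- .syn_genes(config)
  n_terms <- config$n_go_terms + config$n_kegg_terms
  ids <- c(sprintf("GO:S%04d", seq_len(config$n_go_terms)),
           sprintf("KEGG:S%03d", seq_len(config$n_kegg_terms)))
  ns <- rep(c("GO", "KEGG"), c(config$n_go_terms, config$n_kegg_terms))
  lo <- config$term_size_range[1]
  hi <- config$term_size_range[2]
  sizes <- sample(seq.int(lo, hi), n_terms, replace = TRUE)
  sets <- lapply(sizes, function(s) sample(genes, s))
  names(sets) <- ids
  annotation_db(sets, stats::setNames(ns, ids))
}

#' Plant the discriminative ground truth
#'
#' Samples `n_discriminative_terms` term ids uniformly from the database;
#' the union of their gene sets is the signal pool positives draw from.
#'
#' @inheritParams generate_annotation_db
#' @param db the [annotation_db] to plant terms in.
#' @return an object of class `synthetic_truth` with
#'   `discriminative_term_ids` and `signal_pool` (the gene union).
#' @export
generate_truth <- function(config, db, seed = NULL) {
  stopifnot(inherits(config, "synthetic_config"), inherits(db, "annotation_db"))
  if (!is.null(seed)) set.seed(seed)
  ids <- sample(db$term_ids, config$n_discriminative_terms)
  pool <- unique(unlist(db$gene_sets[ids], use.names = FALSE))
  if (config$signal_fraction > 0 && length(pool) == 0L &&
      config$n_discriminative_terms > 0L) {
    stop("empty discriminative gene union with signal_fraction > 0")
  }
  truth <- list(discriminative_term_ids = ids, signal_pool = pool)
  class(truth) <- "synthetic_truth"
  truth
}

#' Generate co-expression profiles with planted class signal
#'
#' Each entity receives a co-expressed gene set whose size is uniform in
#' `coexpr_size_range`. Negatives sample genes uniformly from the universe.
#' Positives draw `round(signal_fraction * size)` genes from the planted
#' signal pool (with replacement, de-duplicated, then topped up from the
#' pool so the signal portion keeps its intended size whenever the pool
#' allows) and the remainder uniformly from the rest of the universe, so
#' every profile is an exact-size gene set. Positives are generated first,
#' then negatives.
#'
#' @inheritParams generate_truth
#' @param truth a `synthetic_truth` planted in `db`.
#' @return list with `profiles` (named list entity -> genes) and `labels`
#'   (named integer vector, 1 = positive).
#' @export
generate_coexpression_profiles <- function(config, db, truth, seed = NULL) {
  stopifnot(inherits(config, "synthetic_config"),
            inherits(truth, "synthetic_truth"))
  if (!all(truth$discriminative_term_ids %in% db$term_ids)) {
    stop("truth refers to terms absent from the annotation database")
  }
  if (!is.null(seed)) set.seed(seed)
  genes <- .syn_genes(config)
  pool <- truth$signal_pool
  if (config$signal_fraction > 0 && length(pool) == 0L) {
    stop("empty discriminative gene union with signal_fraction > 0")
  }
  lo <- config$coexpr_size_range[1]
  hi <- config$coexpr_size_range[2]
  ids <- c(sprintf("lncP%04d", seq_len(config$n_positive)),
           sprintf("lncN%05d", seq_len(config$n_negative)))
  labels <- stats::setNames(
    rep(c(1L, 0L), c(config$n_positive, config$n_negative)), ids)

  make_one <- function(positive) {
    size <- sample(seq.int(lo, hi), 1L)
    if (!positive || config$signal_fraction == 0) {
      return(sample(genes, size))
    }
    n_sig <- round(config$signal_fraction * size)
    sig <- unique(sample(pool, n_sig, replace = TRUE))
    deficit <- n_sig - length(sig)
    if (deficit > 0L) {
      extra <- setdiff(pool, sig)
      sig <- c(sig, sample(extra, min(deficit, length(extra))))
    }
    rest <- sample(setdiff(genes, sig), size - length(sig))
    c(sig, rest)
  }
  profiles <- c(lapply(seq_len(config$n_positive), function(i) make_one(TRUE)),
                lapply(seq_len(config$n_negative), function(i) make_one(FALSE)))
  names(profiles) <- ids
  list(profiles = profiles, labels = labels)
}

#' Generate a complete synthetic dataset
#'
#' Seeds the random stream once from `config$seed` and generates, in order:
#' the annotation database, the planted truth, and the co-expression
#' profiles with labels. Identical configs give identical datasets.
#'
#' @param config a [synthetic_config()].
#' @return list of class `synthetic_dataset` with `db`, `truth`, `profiles`,
#'   `labels`, `universe` and the `config` echo.
#' @export
synthesize_dataset <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  set.seed(config$seed)
  db <- generate_annotation_db(config, seed = NULL)
  truth <- generate_truth(config, db, seed = NULL)
  pr <- generate_coexpression_profiles(config, db, truth, seed = NULL)
  out <- list(db = db, truth = truth, profiles = pr$profiles,
              labels = pr$labels, universe = .syn_genes(config),
              config = config)
  class(out) <- "synthetic_dataset"
  out
}

#' Write a synthetic dataset fixture to disk
#'
#' Writes `annotation.gmt`, `coexpression.tsv`, `labels.tsv` and
#' `universe.txt` (one gene id per line) into `outdir`. The files round-trip
#' losslessly through [read_gmt()], [read_coexpression_pairs()] and
#' [read_labels()].
#'
#' @param outdir output directory (created if missing).
#' @param db an [annotation_db].
#' @param profiles named list entity -> gene ids.
#' @param labels named integer 0/1 vector.
#' @param universe optional character vector of universe gene ids.
#' @return named character vector of the written paths, invisibly.
#' @export
write_fixture <- function(outdir, db, profiles, labels, universe = NULL) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(gmt = file.path(outdir, "annotation.gmt"),
             pairs = file.path(outdir, "coexpression.tsv"),
             labels = file.path(outdir, "labels.tsv"))
  write_gmt(db, paths[["gmt"]])
  write_coexpression_pairs(profiles, paths[["pairs"]])
  write_labels(labels, paths[["labels"]])
  if (!is.null(universe)) {
    paths[["universe"]] <- file.path(outdir, "universe.txt")
    writeLines(universe, paths[["universe"]])
  }
  invisible(paths)
}
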