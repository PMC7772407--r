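# Readers and writers for the plain-text interchange formats: GMT term ->
# gene-set files, entity/gene co-expression pair tables, label tables,
# feature matrices and ranked feature lists. All TSV, all round-trip safe.

#' Construct an annotation database
#'
#' An annotation database is an ordered collection of named gene sets
#' ("terms", e.g. GO terms or KEGG pathways). Feature order is fixed: all GO
#' terms first (in the order given), then all KEGG terms, so that encoded
#' feature matrices have a stable column order across runs.
#'
#' @param gene_sets named list of character vectors (term id -> gene ids).
#' @param namespace character vector, one of `"GO"`/`"KEGG"` per term;
#'   either named by term id or parallel to `gene_sets`.
#' @return an object of class `annotation_db` with elements `term_ids`,
#'   `namespace` (named) and `gene_sets` (named list).
#' @export
annotation_db <- function(gene_sets, namespace) {
  if (is.null(names(gene_sets)) || anyDuplicated(names(gene_sets)) > 0) {
    stop("gene_sets must be a named list with unique term ids")
  }
  if (is.null(names(namespace))) names(namespace) <- names(gene_sets)
  namespace <- namespace[names(gene_sets)]
  if (anyNA(namespace) || !all(namespace %in% c("GO", "KEGG"))) {
    stop("namespace must be 'GO' or 'KEGG' for every term")
  }
  ord <- c(which(namespace == "GO"), which(namespace == "KEGG"))
  db <- list(
    term_ids = names(gene_sets)[ord],
    namespace = namespace[ord],
    gene_sets = lapply(gene_sets[ord], function(g) unique(as.character(g)))
  )
  class(db) <- "annotation_db"
  db
}

#' @export
print.annotation_db <- function(x, ...) {
  cat("annotation_db:", length(x$term_ids), "terms (",
      sum(x$namespace == "GO"), "GO,", sum(x$namespace == "KEGG"), "KEGG ),",
      length(unique(unlist(x$gene_sets, use.names = FALSE))),
      "distinct genes\n")
  invisible(x)
}

#' Read / write GMT gene-set files
#'
#' One term per line: term id, description (used here to carry the
#' GO/KEGG namespace), then tab-separated gene ids.
#'
#' @param path file path.
#' @return `read_gmt` returns an [annotation_db]; `write_gmt` returns
#'   `path` invisibly.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- lengths(parts) < 3L
  if (any(bad)) stop("malformed GMT line(s): ", which(bad)[1])
  ids <- vapply(parts, `[[`, character(1), 1L)
  ns <- vapply(parts, `[[`, character(1), 2L)
  sets <- lapply(parts, function(p) p[-(1:2)])
  names(sets) <- ids
  annotation_db(sets, ns)
}

#' @param db an [annotation_db].
#' @rdname read_gmt
#' @export
write_gmt <- function(db, path) {
  stopifnot(inherits(db, "annotation_db"))
  lines <- vapply(db$term_ids, function(id) {
    paste(c(id, db$namespace[[id]], db$gene_sets[[id]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read / write co-expression pair tables
#'
#' TSV with header `entity_id<TAB>gene_id`, one co-expressed gene per row.
#' Entities keep their order of first appearance.
#'
#' @param path file path.
#' @return `read_coexpression_pairs` returns a named list of character
#'   vectors (entity id -> co-expressed gene ids).
#' @export
read_coexpression_pairs <- function(path) {
  df <- read.table(path, header = TRUE, sep = "\t",
                   colClasses = "character", quote = "")
  if (!identical(names(df)[1:2], c("entity_id", "gene_id"))) {
    stop("expected header 'entity_id\\tgene_id' in ", path)
  }
  ids <- unique(df$entity_id)
  out <- split(df$gene_id, factor(df$entity_id, levels = ids))
  lapply(out, unique)
}

#' @param profiles named list of character vectors (entity -> genes).
#' @rdname read_coexpression_pairs
#' @export
write_coexpression_pairs <- function(profiles, path) {
  df <- data.frame(
    entity_id = rep(names(profiles), lengths(profiles)),
    gene_id = unlist(profiles, use.names = FALSE),
    stringsAsFactors = FALSE
  )
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write binary label tables
#'
#' TSV with header `entity_id<TAB>label`, label 1 = positive class.
#'
#' @param path file path.
#' @return `read_labels` returns a named integer vector of 0/1.
#' @export
read_labels <- function(path) {
  header <- strsplit(readLines(path, n = 1L), "\t", fixed = TRUE)[[1]]
  if (!identical(header[1:2], c("entity_id", "label"))) {
    stop("expected header 'entity_id\\tlabel' in ", path)
  }
  df <- read.table(path, header = TRUE, sep = "\t",
                   colClasses = c("character", "integer"), quote = "")
  stats::setNames(df$label, df$entity_id)
}

#' @param labels named integer vector of 0/1 labels.
#' @rdname read_labels
#' @export
write_labels <- function(labels, path) {
  df <- data.frame(entity_id = names(labels), label = as.integer(labels),
                   stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write feature matrices
#'
#' Entities in rows (first column `entity_id`), term ids as remaining column
#' headers, enrichment scores as values.
#'
#' @param path file path.
#' @return `read_feature_matrix` returns a numeric matrix with entity row
#'   names and term column names.
#' @export
read_feature_matrix <- function(path) {
  df <- read.table(path, header = TRUE, sep = "\t", quote = "",
                   check.names = FALSE)
  if (names(df)[1] != "entity_id") stop("expected first column 'entity_id'")
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- as.character(df$entity_id)
  storage.mode(m) <- "double"
  m
}

#' @param mat numeric matrix with entity row names and term column names.
#' @rdname read_feature_matrix
#' @export
write_feature_matrix <- function(mat, path) {
  df <- data.frame(entity_id = rownames(mat), mat, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write a ranked feature list
#'
#' TSV with columns rank, feature_id, relevance, redundancy, score — the
#' on-disk form of the mRMR output of [mrmr_rank()].
#'
#' @param path file path.
#' @return `read_ranked_list` returns the ranked-list data frame.
#' @export
read_ranked_list <- function(path) {
  df <- read.table(path, header = TRUE, sep = "\t", quote = "",
                   colClasses = c("integer", "character", "numeric",
                                  "numeric", "numeric"))
  stopifnot(identical(names(df),
                      c("rank", "feature_id", "relevance", "redundancy",
                        "score")))
  df
}

#' @param ranked data frame as returned by [mrmr_rank()].
#' @rdname read_ranked_list
#' @export
write_ranked_list <- function(ranked, path) {
  write.table(ranked, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
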