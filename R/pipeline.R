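# End-to-end pipeline: encode -> rank -> IFS -> select -> final rules, with
# all artifacts (TSV/JSON/plot/manifest) written to an output directory.

#' Pipeline configuration
#'
#' Input data come either from files (`gmt`, `pairs`, `labels_path`,
#' optionally `universe_path`) or from a [synthetic_config()] passed as
#' `synthetic`. Seeds are split per stochastic stage (folding, SMOTE) and
#' echoed in the run manifest.
#'
#' @param gmt,pairs,labels_path,universe_path input file paths (`NULL` when
#'   `synthetic` is given; `universe_path` may be `NULL` to infer the
#'   universe from the data).
#' @param synthetic optional [synthetic_config()] generating the inputs
#'   in-memory.
#' @param outdir output directory for artifacts.
#' @param step IFS subset-size increment.
#' @param k cross-validation folds.
#' @param smote_mode SMOTE placement during evaluation
#'   (see [cross_validate()]).
#' @param smote_final balance the data before the final rule tree?
#' @param final_size `"tradeoff"` or `"optimum"`: which IFS point the final
#'   rule model uses.
#' @param tradeoff_delta MCC tolerance for the trade-off point.
#' @param discretization_t mRMR discretization threshold multiplier.
#' @param tree a [tree_config()].
#' @param smote_k SMOTE neighbor count.
#' @param fold_seed,smote_seed stage seeds.
#' @return an object of class `pipeline_config`.
#' @export
pipeline_config <- function(gmt = NULL, pairs = NULL, labels_path = NULL,
                            universe_path = NULL, synthetic = NULL,
                            outdir = tempfile("lncrules_run"), step = 10,
                            k = 10,
                            smote_mode = c("train_only", "global", "off"),
                            smote_final = TRUE,
                            final_size = c("tradeoff", "optimum"),
                            tradeoff_delta = 0.025, discretization_t = 1,
                            tree = tree_config(), smote_k = 5,
                            fold_seed = 1L, smote_seed = 1L) {
  smote_mode <- match.arg(smote_mode)
  final_size <- match.arg(final_size)
  if (is.null(synthetic) && (is.null(gmt) || is.null(pairs) ||
                             is.null(labels_path))) {
    stop("provide either a synthetic config or gmt/pairs/labels paths")
  }
  structure(list(gmt = gmt, pairs = pairs, labels_path = labels_path,
                 universe_path = universe_path, synthetic = synthetic,
                 outdir = outdir, step = step, k = k,
                 smote_mode = smote_mode, smote_final = smote_final,
                 final_size = final_size, tradeoff_delta = tradeoff_delta,
                 discretization_t = discretization_t, tree = tree,
                 smote_k = as.integer(smote_k),
                 fold_seed = as.integer(fold_seed),
                 smote_seed = as.integer(smote_seed)),
            class = "pipeline_config")
}

#' Plot an IFS curve
#'
#' MCC against subset size, with the optimum and trade-off points marked.
#'
#' @param ifs an `ifs_curve` from [run_ifs()].
#' @param path optional PDF path; `NULL` plots to the active device.
#' @return `path` (or `NULL`), invisibly.
#' @export
plot_ifs_curve <- function(ifs, path = NULL) {
  stopifnot(inherits(ifs, "ifs_curve"))
  if (!is.null(path)) pdf(path, width = 7, height = 5)
  on.exit(if (!is.null(path)) dev.off(), add = TRUE)
  plot(ifs$curve$n_features, ifs$curve$MCC, type = "l",
       xlab = "Number of top mRMR features", ylab = "MCC (pooled 10-fold CV)",
       main = "Incremental feature selection")
  points(ifs$optimum_size, ifs$optimum_mcc, pch = 8, col = "red", cex = 1.4)
  to_mcc <- ifs$curve$MCC[ifs$curve$n_features == ifs$tradeoff_size]
  points(ifs$tradeoff_size, to_mcc, pch = 1, col = "blue", cex = 1.6)
  abline(h = ifs$optimum_mcc - ifs$tradeoff_delta, lty = 3, col = "grey40")
  legend("bottomright", bty = "n", pch = c(8, 1), col = c("red", "blue"),
         legend = c(sprintf("optimum: MCC %.3f @ %d", ifs$optimum_mcc,
                            ifs$optimum_size),
                    sprintf("trade-off @ %d", ifs$tradeoff_size)))
  invisible(path)
}

#' Run the full pipeline
#'
#' Executes encode -> mRMR rank -> IFS -> subset selection -> final rule
#' model and writes the artifact bundle into `config$outdir`:
#' `features.tsv`, `ranked.tsv`, `ifs_curve.tsv`, `ifs_curve.pdf`,
#' `metrics.json`, `rules.txt`, `rules.json`, `model.json` and
#' `manifest.json` (config echo, seeds, versions). Deterministic given the
#' config: rerunning writes byte-identical TSV/JSON artifacts.
#'
#' @param config a [pipeline_config()].
#' @return list (invisibly) with `scores`, `labels`, `ranked`, `ifs`,
#'   `final` and the written `paths`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }

  inputs <- stage("load", {
    if (!is.null(config$synthetic)) {
      ds <- synthesize_dataset(config$synthetic)
      list(db = ds$db, profiles = ds$profiles, labels = ds$labels,
           universe = ds$universe)
    } else {
      list(db = read_gmt(config$gmt),
           profiles = read_coexpression_pairs(config$pairs),
           labels = read_labels(config$labels_path),
           universe = if (!is.null(config$universe_path)) {
             readLines(config$universe_path)
           })
    }
  })
  labels <- inputs$labels[names(inputs$profiles)]
  if (anyNA(labels)) stop("labels missing for some entities in the pairs file")

  scores <- stage("encode", {
    encode_profiles(inputs$db, inputs$profiles, inputs$universe)
  })
  ranked <- stage("rank", {
    mrmr_rank(scores, labels, t = config$discretization_t)
  })
  ifs <- stage("ifs", {
    run_ifs(scores, labels, ranked, step = config$step, k = config$k,
            config = config$tree, smote_mode = config$smote_mode,
            fold_seed = config$fold_seed, smote_seed = config$smote_seed,
            tradeoff_delta = config$tradeoff_delta)
  })
  chosen <- if (config$final_size == "optimum") ifs$optimum_size else
    ifs$tradeoff_size
  final <- stage("rules", {
    train_final_rule_model(
      scores, labels, ranked, chosen, smote = config$smote_final,
      config = config$tree,
      smote_config = smote_config(k_neighbors = config$smote_k,
                                  seed = config$smote_seed),
      term_metadata = stats::setNames(inputs$db$namespace,
                                      inputs$db$term_ids))
  })

  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(features = "features.tsv", ranked = "ranked.tsv",
             curve = "ifs_curve.tsv", plot = "ifs_curve.pdf",
             metrics = "metrics.json", rules_txt = "rules.txt",
             rules_json = "rules.json", model = "model.json",
             manifest = "manifest.json")
  paths <- stats::setNames(file.path(config$outdir, paths), names(paths))

  stage("write", {
    write_feature_matrix(scores, paths[["features"]])
    write_ranked_list(ranked, paths[["ranked"]])
    write.table(ifs$curve, paths[["curve"]], sep = "\t", quote = FALSE,
                row.names = FALSE)
    plot_ifs_curve(ifs, paths[["plot"]])
    opt_row <- ifs$curve[ifs$curve$n_features == ifs$optimum_size, ]
    to_row <- ifs$curve[ifs$curve$n_features == ifs$tradeoff_size, ]
    jsonlite::write_json(
      list(optimum = as.list(opt_row), tradeoff = as.list(to_row),
           chosen_size = chosen,
           training = as.list(unclass(final$training_metrics))),
      paths[["metrics"]], auto_unbox = TRUE, digits = NA, pretty = TRUE)
    writeLines(final$report, paths[["rules_txt"]])
    write_rules_json(final$ruleset, paths[["rules_json"]])
    write_cart_json(final$model, paths[["model"]])
    cfg_echo <- config
    cfg_echo$tree <- unclass(config$tree)
    cfg_echo$synthetic <- if (!is.null(config$synthetic)) {
      unclass(config$synthetic)
    }
    jsonlite::write_json(
      list(config = unclass(cfg_echo),
           seeds = list(fold = config$fold_seed, smote = config$smote_seed,
                        generator = if (!is.null(config$synthetic))
                          config$synthetic$seed),
           versions = list(lncrules = as.character(packageVersion("lncrules")),
                           R = paste(R.version$major, R.version$minor,
                                     sep = "."))),
      paths[["manifest"]], auto_unbox = TRUE, digits = NA, pretty = TRUE)
  })

  invisible(list(scores = scores, labels = labels, ranked = ranked,
                 ifs = ifs, final = final, paths = paths))
}
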