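# Incremental feature selection and the end-to-end pipeline.

test_that("subset sizes follow the step rule and always end at F", {
  expect_equal(build_subset_sizes(25, 10), c(10L, 20L, 25L))
  expect_equal(build_subset_sizes(3, 1), 1:3)
  expect_equal(build_subset_sizes(30, 10), c(10L, 20L, 30L))
  expect_equal(build_subset_sizes(5, 10), 5L)
  expect_length(build_subset_sizes(19090, 10), 1909L)
})

test_that("trade-off selection picks the smallest near-optimal size", {
  curve <- data.frame(n_features = c(10L, 20L, 30L),
                      MCC = c(0.30, 0.393, 0.415))
  # the study's own pair: 0.415 - 0.393 = 0.022 <= 0.025
  expect_equal(select_tradeoff(curve, 0.025), 20L)
  expect_equal(select_tradeoff(curve, 0), 30L)
  expect_equal(select_tradeoff(curve, 1), 10L)
  tie <- data.frame(n_features = c(10L, 20L, 30L), MCC = c(0.2, 0.5, 0.5))
  expect_equal(select_tradeoff(tie, 0), 20L)  # tie -> fewer features
})

test_that("run_ifs evaluates nested prefixes and locates the optimum", {
  set.seed(53)
  n <- 90
  y <- rep(c(1L, 0L), c(30, 60))
  x <- matrix(rnorm(n * 12), n, 12,
              dimnames = list(NULL, paste0("f", 1:12)))
  x[, 3] <- x[, 3] + 2.5 * y
  x[, 7] <- x[, 7] + 1.5 * y
  ranked <- mrmr_rank(x, y)
  ifs <- run_ifs(x, y, ranked, step = 5, k = 5, fold_seed = 2,
                 smote_seed = 2)
  expect_equal(ifs$curve$n_features, c(5L, 10L, 12L))
  expect_named(ifs$curve, c("n_features", "SN", "SP", "ACC", "MCC",
                            "Precision", "F1"))
  expect_equal(ifs$optimum_mcc, max(ifs$curve$MCC))
  expect_equal(ifs$optimum_size,
               min(ifs$curve$n_features[ifs$curve$MCC == ifs$optimum_mcc]))
  expect_lte(ifs$tradeoff_size, ifs$optimum_size)
  # single subset is trivially the optimum
  one <- run_ifs(x[, 1:3], y, ranked[ranked$feature_id %in%
                                       paste0("f", 1:3), ],
                 step = 99, k = 5)
  expect_equal(nrow(one$curve), 1L)
  expect_equal(one$optimum_size, 3L)
  # determinism given seeds
  ifs2 <- run_ifs(x, y, ranked, step = 5, k = 5, fold_seed = 2,
                  smote_seed = 2)
  expect_identical(ifs2$curve, ifs$curve)
  expect_error(run_ifs(x[, 1:4], y, ranked), "absent")
})

test_that("final rule model is perfect on separable data", {
  set.seed(59)
  y <- rep(c(1L, 0L), c(15, 45))
  x <- cbind(sig = rnorm(60) + 8 * y,
             noise1 = rnorm(60), noise2 = rnorm(60))
  ranked <- mrmr_rank(x, y)
  for (sm in c(TRUE, FALSE)) {
    final <- train_final_rule_model(x, y, ranked, size = 2, smote = sm)
    expect_equal(final$training_metrics[["ACC"]], 1)
    expect_identical(final$features, ranked$feature_id[1:2])
    # rule-tree equivalence holds regardless of balancing
    probe <- matrix(rnorm(100 * 2), 100, 2)
    tree_pred <- predict_label(final$model, probe)
    rule_pred <- vapply(seq_len(100), function(i) {
      apply_rules(final$ruleset, probe[i, ])$label
    }, integer(1))
    expect_identical(rule_pred, tree_pred)
  }
})

test_that("run_pipeline writes a deterministic artifact bundle", {
  syn <- synthetic_config(n_genes = 300, n_go_terms = 25, n_kegg_terms = 5,
                          term_size_range = c(5, 40), n_positive = 20,
                          n_negative = 60, n_discriminative_terms = 4,
                          signal_fraction = 0.6,
                          coexpr_size_range = c(10, 40), seed = 4)
  out1 <- file.path(tempdir(), "run1")
  out2 <- file.path(tempdir(), "run2")
  cfg1 <- pipeline_config(synthetic = syn, outdir = out1, step = 10, k = 5)
  res <- run_pipeline(cfg1)
  expect_true(all(file.exists(res$paths)))
  # curve TSV mirrors the in-memory curve
  curve <- read.table(res$paths[["curve"]], header = TRUE, sep = "\t")
  expect_equal(nrow(curve), nrow(res$ifs$curve))
  # rerun with an identical config: byte-identical text artifacts
  run_pipeline(pipeline_config(synthetic = syn, outdir = out2, step = 10,
                               k = 5))
  for (a in c("features", "ranked", "curve", "metrics", "rules_txt",
              "rules_json", "model")) {
    expect_identical(readLines(file.path(out1, basename(res$paths[[a]]))),
                     readLines(file.path(out2, basename(res$paths[[a]]))),
                     label = a)
  }
  # manifest echoes the seeds
  manifest <- jsonlite::read_json(res$paths[["manifest"]])
  expect_equal(manifest$seeds$generator, 4L)
})

test_that("pipeline failures name the failing stage", {
  bad <- pipeline_config(gmt = "no-such.gmt", pairs = "x", labels_path = "y",
                         outdir = tempfile())
  expect_error(suppressWarnings(run_pipeline(bad)), "stage 'load'")
})
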