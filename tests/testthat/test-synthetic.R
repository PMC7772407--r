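# Synthetic-data generator: structure, determinism, planted-signal behavior.

test_that("generator produces the configured structure", {
  cfg <- synthetic_config(n_negative = 200, seed = 7)
  ds <- synthesize_dataset(cfg)

  expect_length(ds$db$term_ids, 288 + 12)
  expect_equal(as.integer(table(ds$db$namespace)[c("GO", "KEGG")]),
               c(288L, 12L))
  sizes <- lengths(ds$db$gene_sets)
  expect_true(all(sizes >= 10 & sizes <= 300))
  expect_true(all(unlist(ds$db$gene_sets) %in% ds$universe))

  expect_length(ds$profiles, 57 + 200)
  expect_equal(sum(ds$labels == 1L), 57L)
  expect_equal(sum(ds$labels == 0L), 200L)
  csize <- lengths(ds$profiles)
  expect_true(all(csize >= 20 & csize <= 200))
  expect_false(any(vapply(ds$profiles, anyDuplicated, integer(1)) > 0))
  expect_true(all(ds$truth$discriminative_term_ids %in% ds$db$term_ids))
})

test_that("invalid configs are rejected", {
  expect_error(synthetic_config(term_size_range = c(300, 10)), "non-empty")
  expect_error(synthetic_config(n_genes = 100, term_size_range = c(10, 300)),
               "exceeds")
  expect_error(synthetic_config(n_discriminative_terms = 1000),
               "n_discriminative_terms")
  expect_error(synthetic_config(signal_fraction = 1.5), "signal_fraction")
  expect_error(synthetic_config(n_positive = 0), "positive")
})

test_that("same seed gives byte-identical GMT output", {
  cfg <- synthetic_config(n_negative = 50, seed = 11)
  f1 <- file.path(tempdir(), "a.gmt")
  f2 <- file.path(tempdir(), "b.gmt")
  write_gmt(synthesize_dataset(cfg)$db, f1)
  write_gmt(synthesize_dataset(cfg)$db, f2)
  expect_identical(readLines(f1), readLines(f2))

  ds1 <- synthesize_dataset(cfg)
  ds2 <- synthesize_dataset(cfg)
  expect_identical(ds1$profiles, ds2$profiles)
  expect_identical(ds1$truth, ds2$truth)
})

test_that("positives overlap the discriminative union more than negatives", {
  ds <- synthesize_dataset(synthetic_config(seed = 1))
  pool <- ds$truth$signal_pool
  frac <- vapply(ds$profiles, function(g) mean(g %in% pool), numeric(1))
  expect_gt(mean(frac[ds$labels == 1]), mean(frac[ds$labels == 0]))
})

test_that("signal_fraction boundaries behave as stated", {
  # sf = 1 with one discriminative term whose gene set is large enough:
  # every positive profile is a subset of that term's genes
  cfg <- synthetic_config(n_positive = 10, n_negative = 10,
                          n_discriminative_terms = 1,
                          term_size_range = c(250, 300),
                          coexpr_size_range = c(20, 100),
                          signal_fraction = 1, seed = 3)
  ds <- synthesize_dataset(cfg)
  pool <- ds$truth$signal_pool
  pos <- names(ds$labels)[ds$labels == 1]
  expect_true(all(vapply(ds$profiles[pos], function(g) all(g %in% pool),
                         logical(1))))

  # sf = 0: overlap with the union is exchangeable between classes; the
  # label-permutation test must be non-significant in >= 18 of 20 seeds
  significant <- vapply(1:20, function(s) {
    ds0 <- synthesize_dataset(synthetic_config(
      n_negative = 200, signal_fraction = 0, seed = s))
    frac <- vapply(ds0$profiles,
                   function(g) mean(g %in% ds0$truth$signal_pool),
                   numeric(1))
    obs <- mean(frac[ds0$labels == 1]) - mean(frac[ds0$labels == 0])
    set.seed(1000 + s)
    null <- replicate(200, {
      sh <- sample(ds0$labels)
      mean(frac[sh == 1]) - mean(frac[sh == 0])
    })
    mean(abs(null) >= abs(obs)) < 0.05
  }, logical(1))
  expect_lte(sum(significant), 2)
})

test_that("mean planted-term enrichment is monotone in signal_fraction", {
  means <- vapply(c(0, 0.3, 0.6, 1.0), function(sf) {
    ds <- synthesize_dataset(synthetic_config(
      n_negative = 50, signal_fraction = sf, seed = 9))
    scores <- encode_profiles(ds$db, ds$profiles, ds$universe)
    mean(scores[ds$labels == 1, ds$truth$discriminative_term_ids])
  }, numeric(1))
  expect_true(all(diff(means) >= 0))
})

test_that("fixtures round-trip losslessly through the readers", {
  ds <- synthesize_dataset(synthetic_config(n_negative = 30, seed = 2))
  outdir <- file.path(tempdir(), "fix")
  paths <- write_fixture(outdir, ds$db, ds$profiles, ds$labels, ds$universe)

  db2 <- read_gmt(paths[["gmt"]])
  expect_identical(db2$term_ids, ds$db$term_ids)
  expect_identical(db2$gene_sets, ds$db$gene_sets)
  expect_identical(db2$namespace, ds$db$namespace)
  expect_identical(read_coexpression_pairs(paths[["pairs"]]), ds$profiles)
  expect_identical(read_labels(paths[["labels"]]), ds$labels)
  expect_identical(readLines(paths[["universe"]]), ds$universe)
})
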