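# Evaluation: confusion matrices, the six metrics, stratified folds,
# cross-validation with the three SMOTE placements.

test_that("confusion matrices count the four cells", {
  truth <- c(1, 1, 0, 0, 1, 0, 0, 1, 0, 0)
  pred <- c(1, 0, 0, 1, 1, 0, 0, 0, 1, 0)
  cm <- confusion_matrix(truth, pred)
  expect_equal(unlist(cm[c("TP", "FP", "TN", "FN")]),
               c(TP = 2L, FP = 2L, TN = 4L, FN = 2L))
  perfect <- confusion_matrix(truth, truth)
  expect_equal(perfect$FP + perfect$FN, 0L)
  inverted <- confusion_matrix(truth, 1 - truth)
  expect_equal(inverted$TP + inverted$TN, 0L)
  expect_error(confusion_matrix(1:3, 1:2), "equal length")
  expect_error(confusion_matrix(c(0, 2), c(0, 1)), "binary")
})

test_that("metrics match the defining formulas and conventions", {
  m <- compute_metrics(confusion_matrix(rep(c(1, 0), 5), rep(c(1, 0), 5)))
  expect_equal(unclass(m),
               c(SN = 1, SP = 1, ACC = 1, MCC = 1, Precision = 1, F1 = 1))
  flat <- compute_metrics(
    confusion_matrix(c(1, 0, 1, 0), c(1, 1, 0, 0)))
  expect_equal(flat[["MCC"]], 0)
  # TP=2, TN=3, FP=1, FN=0 -> MCC = 6/sqrt(72)
  cm <- confusion_matrix(c(1, 1, 0, 0, 0, 0), c(1, 1, 1, 0, 0, 0))
  expect_equal(compute_metrics(cm)[["MCC"]], 6 / sqrt(72),
               tolerance = 1e-12)
  # degenerate denominators fall back to 0
  none_pos <- compute_metrics(confusion_matrix(c(1, 0), c(0, 0)))
  expect_equal(none_pos[["Precision"]], 0)
  expect_equal(none_pos[["F1"]], 0)
  expect_equal(none_pos[["MCC"]], 0)
})

test_that("MCC flips sign under label inversion; SN and SP swap", {
  cm <- confusion_matrix(c(1, 1, 1, 0, 0, 0, 0, 0),
                         c(1, 1, 0, 1, 0, 0, 0, 1))
  m <- compute_metrics(cm)
  swapped <- confusion_matrix(1 - c(1, 1, 1, 0, 0, 0, 0, 0),
                              1 - c(1, 1, 0, 1, 0, 0, 0, 1))
  ms <- compute_metrics(swapped)
  expect_equal(ms[["MCC"]], m[["MCC"]], tolerance = 1e-12)
  expect_equal(ms[["SN"]], m[["SP"]], tolerance = 1e-12)
  expect_equal(ms[["SP"]], m[["SN"]], tolerance = 1e-12)
  # inverting predictions only flips the MCC sign
  inv <- compute_metrics(confusion_matrix(c(1, 1, 1, 0, 0, 0, 0, 0),
                                          1 - c(1, 1, 0, 1, 0, 0, 0, 1)))
  expect_equal(inv[["MCC"]], -m[["MCC"]], tolerance = 1e-12)
})

test_that("stratified folds are balanced, deterministic and validated", {
  y <- rep(c(1L, 0L), each = 10)
  f <- stratified_folds(y, k = 10, seed = 3)
  expect_true(all(table(f) == 2))
  expect_true(all(table(f[y == 1]) == 1))  # one positive per fold
  expect_identical(stratified_folds(y, 10, seed = 3), f)
  expect_false(identical(stratified_folds(y, 10, seed = 4), f))
  # 57 positives / 1000 negatives, k = 10: 5-6 positives per fold
  y2 <- rep(c(1L, 0L), c(57, 1000))
  f2 <- stratified_folds(y2, 10, seed = 1)
  expect_true(all(table(f2[y2 == 1]) %in% c(5L, 6L)))
  expect_true(all(table(f2[y2 == 0]) == 100L))
  expect_error(stratified_folds(y, k = 1), "k must be")
  expect_error(stratified_folds(rep(c(1L, 0L), c(3, 20)), k = 5),
               "at least k members")
})

test_that("cross-validation is perfect on separable data in every mode", {
  set.seed(41)
  y <- rep(c(1L, 0L), c(20, 60))
  x <- cbind(a = rnorm(80) + 10 * y, b = rnorm(80))
  for (mode in c("train_only", "global", "off")) {
    m <- cross_validate(x, y, config = tree_config(), smote_mode = mode,
                        k = 5, fold_seed = 1)
    expect_equal(m[["MCC"]], 1)
  }
})

test_that("pooled predictions cover each sample once; no synthetic in test", {
  set.seed(43)
  y <- rep(c(1L, 0L), c(12, 48))
  x <- matrix(rnorm(60 * 4), 60, 4)
  m <- cross_validate(x, y, smote_mode = "train_only", k = 6, fold_seed = 2)
  det <- attr(m, "details")
  expect_length(det$predictions, 60)
  expect_identical(det$truth, y)          # metrics on original samples only
  expect_false(any(det$synthetic))        # no synthetic rows in the pool
  expect_true(all(table(det$folds) == 10))
  # global mode pools over the augmented samples instead
  mg <- cross_validate(x, y, smote_mode = "global", k = 6, fold_seed = 2)
  detg <- attr(mg, "details")
  expect_length(detg$predictions, 96)     # 48 + 48 after balancing
  expect_equal(sum(detg$synthetic), 36)
})

test_that("label-shuffled data scores near-zero MCC (train_only)", {
  set.seed(47)
  mccs <- vapply(1:10, function(s) {
    set.seed(s)
    y <- rep(c(1L, 0L), c(15, 85))
    x <- matrix(rnorm(100 * 5), 100, 5)
    x[, 1] <- x[, 1] + 1.5 * y         # signal, then break it by shuffling
    ysh <- sample(y)
    cross_validate(x, ysh, smote_mode = "train_only", k = 5,
                   fold_seed = s)[["MCC"]]
  }, numeric(1))
  expect_lt(median(abs(mccs)), 0.15)
})

test_that("invalid smote mode is rejected", {
  x <- matrix(rnorm(40), 20, 2)
  y <- rep(0:1, each = 10)
  expect_error(cross_validate(x, y, smote_mode = "bogus"), "arg")
})
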