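# CART: impurity, best-split search, induction, prediction.

test_that("gini impurity matches hand values", {
  expect_equal(gini_impurity(c(5, 5)), 0.5)
  expect_equal(gini_impurity(c(10, 0)), 0)
  expect_equal(gini_impurity(c(3, 1)), 0.375)
  expect_error(gini_impurity(c(0, 0)), "total")
})

test_that("best split finds separating midpoints and rejects constants", {
  x <- cbind(a = c(1, 2, 3, 10, 11, 12), b = rep(1, 6))
  y <- rep(0:1, each = 3)
  sp <- find_best_split(x, y)
  expect_equal(sp$feature, 1)
  expect_equal(sp$threshold, 6.5)
  expect_identical(sp$feature_id, "a")
  expect_null(find_best_split(cbind(rep(2, 4)), c(0, 1, 0, 1)))
})

test_that("best split agrees with exhaustive enumeration", {
  set.seed(21)
  for (rep in 1:10) {
    x <- matrix(round(rnorm(30 * 4), 1), 30, 4)  # rounding induces ties
    y <- sample(0:1, 30, replace = TRUE)
    got <- find_best_split(x, y)
    want <- oracle_best_split(x, y)
    if (is.null(want)) {
      expect_null(got)
    } else {
      expect_equal(got$feature, want$feature)
      expect_equal(got$threshold, want$threshold)
      expect_equal(got$gain, want$gain, tolerance = 1e-12)
    }
  }
})

test_that("min_samples_leaf constrains admissible splits", {
  x <- cbind(c(1, 2, 3, 4, 5, 6))
  y <- c(0, 1, 1, 1, 1, 1)
  sp <- find_best_split(x, y, tree_config(min_samples_leaf = 2))
  want <- oracle_best_split(x, y, min_leaf = 2)
  expect_equal(sp$threshold, want$threshold)
  expect_gte(min(sum(x <= sp$threshold), sum(x > sp$threshold)), 2)
})

test_that("tree growth reaches purity on separable and distinct data", {
  sep <- separable_data()
  model <- grow_tree(sep$x, sep$y)
  expect_equal(predict_label(model, sep$x), sep$y)
  # all one class: a single leaf
  m1 <- grow_tree(matrix(rnorm(20), 10, 2), rep(0L, 10))
  expect_equal(nrow(m1$nodes), 1L)
  expect_true(m1$nodes$is_leaf[1])
  # unlimited depth + all-distinct rows -> zero training error
  set.seed(31)
  for (rep in 1:20) {
    n <- sample(10:60, 1)
    x <- matrix(rnorm(n * 3), n, 3)
    y <- sample(0:1, n, replace = TRUE)
    m <- grow_tree(x, y)
    expect_equal(predict_label(m, x), y)
  }
})

test_that("every accepted split strictly decreases impurity", {
  set.seed(17)
  x <- matrix(sample(1:4, 200, TRUE), 50, 4)  # heavy ties
  y <- sample(0:1, 50, replace = TRUE)
  m <- grow_tree(x, y)
  nd <- m$nodes
  for (i in which(!nd$is_leaf)) {
    l <- nd$left[i]; r <- nd$right[i]
    nl <- nd$n0[l] + nd$n1[l]; nr <- nd$n0[r] + nd$n1[r]
    parent_imp <- gini_impurity(c(nd$n0[i], nd$n1[i]))
    child_imp <- (nl * gini_impurity(c(nd$n0[l], nd$n1[l])) +
                    nr * gini_impurity(c(nd$n0[r], nd$n1[r]))) / (nl + nr)
    expect_lt(child_imp, parent_imp)
    expect_equal(nd$n0[i], nd$n0[l] + nd$n0[r])
    expect_equal(nd$n1[i], nd$n1[l] + nd$n1[r])
  }
})

test_that("predictions are invariant to training sample order", {
  set.seed(13)
  x <- matrix(round(rnorm(40 * 3), 1), 40, 3)
  y <- sample(0:1, 40, replace = TRUE)
  grid <- matrix(rnorm(200 * 3), 200, 3)
  base <- predict_label(grow_tree(x, y), grid)
  for (rep in 1:5) {
    perm <- sample(40)
    expect_identical(predict_label(grow_tree(x[perm, ], y[perm]), grid),
                     base)
  }
})

test_that("depth and size limits are honored; boundary routes left", {
  sep <- separable_data()
  stump <- grow_tree(sep$x, sep$y, tree_config(max_depth = 1))
  expect_equal(nrow(stump$nodes), 3L)
  thr <- stump$nodes$threshold[1]
  f <- stump$nodes$feature[1]
  at_thr <- c(thr, 0)[order(c(f, setdiff(1:2, f)))]
  expect_equal(predict_label(stump, at_thr),
               stump$nodes$pred[stump$nodes$left[1]])
  expect_error(predict_label(stump, matrix(1, 1, 5)), "features")
  expect_error(tree_config(min_samples_split = 1), "min_samples_split")
})

test_that("leaf ties predict the negative class", {
  x <- cbind(c(1, 1, 1, 1))
  y <- c(0L, 0L, 1L, 1L)
  m <- grow_tree(x, y)  # unsplittable: constant feature
  expect_equal(nrow(m$nodes), 1L)
  expect_equal(m$nodes$pred[1], 0L)
})

test_that("models round-trip through JSON", {
  sep <- separable_data(seed = 5)
  m <- grow_tree(sep$x, sep$y)
  path <- file.path(tempdir(), "model.json")
  write_cart_json(m, path)
  m2 <- read_cart_json(path)
  expect_equal(m2$nodes, m$nodes)
  expect_identical(m2$feature_ids, m$feature_ids)
  grid <- matrix(rnorm(100 * 2), 100, 2)
  expect_identical(predict_label(m2, grid), predict_label(m, grid))
})
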