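test_that("impurity primitives match hand-evaluated values", {
  expect_equal(class_entropy(c(4, 0)), 0)
  expect_equal(class_entropy(c(2, 2)), 1.0)
  expect_equal(class_entropy(c(1, 1, 1, 1)), 2.0)
  expect_error(class_entropy(c(0, 0)), "empty")

  expect_equal(conditional_entropy(list(c(2, 2))), 1.0)     # identity
  expect_equal(conditional_entropy(list(c(2, 0), c(0, 2))), 0)
  expect_equal(conditional_entropy(list(c(2, 0), c(1, 1))), 0.5)

  expect_equal(information_gain(c(2, 2), list(c(2, 0), c(0, 2))), 1.0)
  expect_equal(information_gain(c(2, 2), list(c(2, 2))), 0)
  g <- information_gain(c(3, 1), list(c(2, 1), c(1, 0)))
  expect_equal(g, class_entropy(c(3, 1)) - 0.75 * class_entropy(c(2, 1)),
               tolerance = 1e-12)
  expect_equal(round(g, 4), 0.1226)
  expect_error(information_gain(c(3, 1), list(c(1, 1), c(1, 0))),
               "sum to parent")

  expect_equal(gain_ratio(c(2, 2), list(c(2, 0), c(0, 2))), 1.0)
  expect_equal(gain_ratio(c(3, 1), list(c(2, 1), c(1, 0))),
               g / class_entropy(c(3, 1)), tolerance = 1e-12)
  expect_equal(round(gain_ratio(c(3, 1), list(c(2, 1), c(1, 0))), 4), 0.1511)
  expect_error(gain_ratio(c(4, 0), list(c(4, 0))), "pure")

  expect_equal(gini_impurity(c(4, 0)), 0)
  expect_equal(gini_impurity(c(2, 2)), 0.5)
  expect_equal(gini_impurity(c(1, 1, 1, 1)), 0.75)

  expect_equal(gini_split(c(2, 0), c(0, 2)), 0)
  expect_equal(gini_split(c(2, 0), c(1, 1)), 0.25)
  expect_equal(gini_split(c(1, 1), c(2, 0)), 0.25)   # symmetric
  expect_error(gini_split(c(0, 0), c(1, 1)), "empty")
})

test_that("best_split finds the midpoint separating a 1-D two-class set", {
  X <- cbind(x = c(1, 2, 10, 11))
  y <- c(0L, 0L, 1L, 1L)
  s <- best_split(X, y)
  expect_equal(s$feature, 1L)
  expect_equal(s$threshold, 6.0)
  expect_equal(s$score, 0)

  expect_null(best_split(X, c(0L, 0L, 0L, 0L)))    # pure node

  # a perfectly separating feature beats a noisy one
  X2 <- cbind(noise = c(5, 1, 4, 2), sep = c(0, 0, 9, 9))
  s2 <- best_split(X2, y)
  expect_equal(s2$feature, 2L)
})

test_that("best_split equals exhaustive midpoint search on random data", {
  set.seed(17)
  for (i in 1:30) {
    n <- sample(5:40, 1)
    p <- sample(1:5, 1)
    K <- sample(2:4, 1)
    X <- matrix(sample(1:12, n * p, replace = TRUE) + 0, n, p)
    y <- sample(0:(K - 1), n, replace = TRUE)
    got <- best_split(X, y, K = K)
    want <- oracle_root_split(X, y, K)
    if (is.null(got)) {
      # no impurity-reducing split: oracle's best must not beat the parent
      parent <- gini_impurity(tabulate(y + 1L, K))
      if (!is.null(want)) expect_gte(want$score, parent - 1e-9)
    } else {
      expect_equal(got$feature, want$feature)
      expect_equal(got$threshold, want$threshold)
      expect_equal(got$score, want$score, tolerance = 1e-12)
    }
  }
})

test_that("grow_tree honors stopping rules and fits separable data exactly", {
  X <- cbind(x = c(1, 2, 10, 11))
  y <- factor(c("lo", "lo", "hi", "hi"), levels = c("lo", "hi"))
  fit <- grow_tree(X, y)
  expect_equal(tree_node_count(fit), 3L)          # 1 split + 2 leaves
  expect_identical(as.character(predict(fit, X)), as.character(y))
  expect_equal(fit$root$impurity, 0.5)

  stump <- grow_tree(X, c(0, 0, 1, 1), tree_params(max_depth = 0))
  expect_equal(tree_node_count(stump), 1L)
  expect_equal(as.character(predict(stump, X)),
               rep("0", 4))                        # majority, tie -> class 0

  # value exactly at the threshold goes left
  expect_equal(as.character(predict(fit, cbind(x = 6.0))), "lo")

  # unknown feature names rejected
  expect_error(predict(fit, cbind(z = 1)), "lacks feature")
})

test_that("structural invariants hold on a larger labeled simulation", {
  sim <- suppressMessages(
    simulate_labeled_dataset(simulation_config(n_primary = 120,
                                               n_secondary = 80, seed = 9)))
  X <- indicator_matrix(sim$table)
  fit <- grow_tree(X, sim$classes, tree_params(max_depth = 3))
  expect_lte(tree_node_count(fit), 15L)

  check <- function(node) {
    expect_equal(node$n_samples, sum(node$class_counts))
    if (node$kind == "split") {
      expect_equal(node$n_samples,
                   node$left$n_samples + node$right$n_samples)
      expect_gte(node$left$n_samples, 1L)
      expect_gte(node$right$n_samples, 1L)
      child <- (node$left$n_samples * node$left$impurity +
                  node$right$n_samples * node$right$impurity) / node$n_samples
      expect_lte(child, node$impurity + 1e-12)   # impurity monotonicity
      check(node$left); check(node$right)
    }
  }
  check(fit$root)

  # determinism: identical inputs give structurally identical trees
  fit2 <- grow_tree(X, sim$classes, tree_params(max_depth = 3))
  expect_identical(tree_to_list(fit2), tree_to_list(fit))

  # full-depth training accuracy is 1 (labels are a function of features)
  full <- grow_tree(X, sim$classes)
  expect_equal(mean(predict(full, X) == sim$classes), 1.0)

  # probabilities: rows sum to 1
  proba <- predict(fit, X, type = "prob")
  expect_equal(unname(rowSums(proba)), rep(1, nrow(X)))
})

test_that("feature importances sum to one and find the label-driving feature", {
  X <- cbind(x = c(1, 2, 10, 11))
  fit <- grow_tree(X, c(0L, 0L, 1L, 1L))
  expect_equal(unname(feature_importances(fit)), 1.0)

  set.seed(23)
  n <- 300
  Xr <- matrix(rnorm(n * 5), n, 5,
               dimnames = list(NULL, paste0("f", 1:5)))
  y <- as.integer(Xr[, "f3"] > 0.3)
  fit3 <- grow_tree(Xr, y, tree_params(max_depth = 3))
  imp <- feature_importances(fit3)
  expect_equal(sum(imp), 1.0, tolerance = 1e-12)
  expect_gte(imp[["f3"]], 0.9)

  stump <- grow_tree(X, c(0L, 0L, 1L, 1L), tree_params(max_depth = 0))
  expect_warning(z <- feature_importances(stump), "no splits")
  expect_equal(unname(z), 0)
})

test_that("tree exports render text and DOT views with depth truncation", {
  X <- cbind(x = c(1, 2, 10, 11))
  fit <- grow_tree(X, c(0L, 0L, 1L, 1L))
  txt <- export_tree(fit, "text")
  expect_length(strsplit(txt, "\n")[[1]], 3L)
  expect_match(txt, "x <= 6")

  dot <- export_tree(fit, "dot")
  expect_match(dot, "^digraph")
  expect_equal(sum(grepl("shape=", strsplit(dot, "\n")[[1]])),
               tree_node_count(fit))

  set.seed(4)
  Xd <- matrix(rnorm(400), 100, 4, dimnames = list(NULL, paste0("f", 1:4)))
  yd <- sample(0:3, 100, replace = TRUE)
  deep <- grow_tree(Xd, yd)
  shown <- export_tree(deep, "text", display_depth = 3)
  expect_lte(length(strsplit(shown, "\n")[[1]]), 15L)
  expect_lte(tree_node_count(deep, display_depth = 3), 15L)
  expect_error(export_tree(fit, "png"), "arg")
})

test_that("predictions agree with rpart on a cleanly separable dataset", {
  skip_if_not_installed("rpart")
  set.seed(12)
  n <- 120
  X <- data.frame(a = c(rnorm(n / 2, -3), rnorm(n / 2, 3)),
                  b = rnorm(n))
  y <- factor(rep(c("lo", "hi"), each = n / 2), levels = c("lo", "hi"))
  ours <- grow_tree(as.matrix(X), y)
  ref <- rpart::rpart(y ~ ., data = cbind(X, y), method = "class",
                      control = rpart::rpart.control(minsplit = 2, cp = 0,
                                                     xval = 0))
  expect_identical(as.character(predict(ours, as.matrix(X))),
                   as.character(predict(ref, X, type = "class")))
})
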