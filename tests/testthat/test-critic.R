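test_that("min-max normalization handles polarity and attains endpoints", {
  m <- cbind(a = c(2, 4, 6))
  expect_equal(minmax_normalize(m, "benefit")[, 1], c(0, 0.5, 1),
               ignore_attr = TRUE)
  expect_equal(minmax_normalize(m, "cost")[, 1], c(1, 0.5, 0),
               ignore_attr = TRUE)
  expect_error(minmax_normalize(cbind(a = c(3, 3, 3), b = 1:3)), "a")

  set.seed(2)
  m2 <- matrix(rnorm(40), 10, 4)
  norm <- minmax_normalize(m2)
  expect_true(all(norm >= 0 & norm <= 1))
  expect_equal(unname(apply(norm, 2, min)), rep(0, 4))
  expect_equal(unname(apply(norm, 2, max)), rep(1, 4))
})

test_that("contrast and conflict match hand-evaluated cases", {
  expect_equal(contrast_intensity(cbind(c(0, 1)))[1], 1 / sqrt(2),
               ignore_attr = TRUE, tolerance = 1e-12)
  expect_equal(contrast_intensity(cbind(c(0, 0.5, 1)))[1], 0.5,
               ignore_attr = TRUE)
  expect_error(contrast_intensity(matrix(1, 1, 2)), "at least 2")

  # perfectly correlated pair: zero conflict
  m <- cbind(a = c(0, 0.5, 1), b = c(0, 0.5, 1))
  expect_equal(unname(critic_conflict(m)), c(0, 0), tolerance = 1e-12,
               ignore_attr = TRUE)

  # orthogonal pair: conflict 1 each
  m2 <- cbind(a = c(1, -1, 1, -1), b = c(1, 1, -1, -1))
  expect_equal(unname(critic_conflict(m2)), c(1, 1), tolerance = 1e-12,
               ignore_attr = TRUE)

  # three columns with pairwise r = (0.5, -0.5, 0): R1 = 2
  v1 <- c(1, -1, 1, -1, 1, -1, 1, -1)
  v2 <- c(1, 1, -1, -1, 1, 1, -1, -1)
  v3 <- c(1, 1, 1, 1, -1, -1, -1, -1)
  v4 <- c(1, -1, -1, 1, 1, -1, -1, 1)
  m3 <- cbind(a = v1 + v2, b = v2 + v3, c = v4 - v1)
  r <- cor(m3)
  expect_equal(r[1, 2], 0.5); expect_equal(r[1, 3], -0.5)
  expect_equal(r[2, 3], 0)
  expect_equal(unname(critic_conflict(m3))[1], 2.0, tolerance = 1e-12,
               ignore_attr = TRUE)
})

test_that("CRITIC weights agree with an independent transcription", {
  # symmetric two-indicator case
  m <- cbind(a = c(1, -1, 1, -1), b = c(1, 1, -1, -1))
  expect_equal(unname(critic_weights(m)$weights), c(0.5, 0.5),
               tolerance = 1e-12)

  # identical columns carry no information
  expect_error(critic_weights(cbind(a = 1:4, b = 1:4)), "degenerate")

  # 4 plots x 3 indicators fixed fixture vs spreadsheet-style oracle
  fx <- cbind(IL = c(0.2, 0.6, 0.4, 0.9),
              DBH = c(12, 30, 18, 25),
              TH = c(6, 14, 9, 11))
  pol <- c("cost", "benefit", "benefit")
  got <- critic_weights(fx, polarity = pol)
  expect_equal(unname(got$weights), oracle_critic_weights(fx, pol),
               tolerance = 1e-9)

  # random small matrices
  set.seed(31)
  for (i in 1:20) {
    n <- sample(4:10, 1); p <- sample(2:6, 1)
    M <- matrix(rnorm(n * p), n, p)
    pol <- sample(c("benefit", "cost"), p, replace = TRUE)
    expect_equal(unname(critic_weights(M, pol)$weights),
                 oracle_critic_weights(M, pol), tolerance = 1e-9)
  }
})

test_that("weights are invariant to affine rescaling and equivariant to permutation", {
  set.seed(5)
  M <- matrix(rnorm(60), 12, 5)
  base <- critic_weights(M)
  aff <- M
  aff[, 2] <- 3.7 * M[, 2] + 11
  aff[, 4] <- 0.01 * M[, 4] - 2
  scaled <- critic_weights(aff)
  expect_equal(scaled$weights, base$weights, tolerance = 1e-9)
  expect_equal(forest_health_score(scaled$normalized, scaled$weights),
               forest_health_score(base$normalized, base$weights),
               tolerance = 1e-9)

  perm <- c(3, 1, 5, 2, 4)
  expect_equal(unname(critic_weights(M[, perm])$weights),
               unname(base$weights[perm]), tolerance = 1e-12)
})

test_that("a dominant-contrast, low-correlation indicator gets the top weight", {
  set.seed(8)
  n <- 200
  shared <- rnorm(n)
  M <- cbind(a = shared + rnorm(n, sd = 0.1),
             b = shared + rnorm(n, sd = 0.1),
             c = shared + rnorm(n, sd = 0.1),
             # bimodal (high normalized SD), independent of the block
             d = sample(c(-2, 2), n, replace = TRUE) + rnorm(n, sd = 0.2))
  w <- critic_weights(M)$weights
  expect_identical(names(which.max(w)), "d")
})

test_that("forest-health score is a convex combination with monotone response", {
  norm <- rbind(rep(1, 3), rep(0, 3), c(0.2, 0.8, 0.5))
  w <- c(0.5, 0.3, 0.2)
  fh <- forest_health_score(norm, w)
  expect_equal(fh[1], 1)
  expect_equal(fh[2], 0)
  expect_equal(forest_health_score(rbind(c(0.2, 0.8)), c(0.5, 0.5))[1], 0.5)
  bumped <- norm; bumped[3, 1] <- 0.4
  expect_gt(forest_health_score(bumped, w)[3], fh[3])
  expect_error(forest_health_score(norm, c(0.5, 0.5)), "mismatch")
  expect_error(forest_health_score(norm, c(0.5, 0.3, 0.1)), "sum to 1")
})

test_that("health classes bin scores as specified", {
  cls <- assign_health_classes(c(0.1, 0.3, 0.6, 0.8), scheme = "fixed",
                               thresholds = c(0.25, 0.5, 0.75))
  expect_equal(as.character(cls), c("UHF", "SHF", "HF", "VHF"))
  # score exactly at a threshold joins the upper class
  at <- assign_health_classes(0.5, "fixed", c(0.25, 0.5, 0.75))
  expect_equal(as.character(at), "HF")
  expect_error(assign_health_classes(0.5, "fixed", c(0.5, 0.5, 0.7)),
               "increasing")

  # quartile scheme: 8 distinct values -> 2 per class
  q <- assign_health_classes(c(10, 20, 30, 40, 50, 60, 70, 80) / 100)
  expect_equal(unname(table(q)), rep(2L, 4), ignore_attr = TRUE)
  expect_true(is.ordered(q))
  expect_equal(as.integer(q[1]) - 1L, 0L)   # UHF codes to 0
})

test_that("correlation analysis flags significance correctly", {
  set.seed(3)
  x <- rnorm(30)
  m <- cbind(a = x, b = x, c = rnorm(30))
  rep <- correlation_analysis(m)
  expect_equal(rep$r[1, 2], 1, tolerance = 1e-12)
  expect_true(rep$significant[1, 2])
  expect_equal(diag(rep$r), c(a = 1, b = 1, c = 1))
  expect_true(all(rep$r >= -1 & rep$r <= 1))
  expect_equal(rep$r, t(rep$r))

  # orthogonal length-4 pair: r = 0, p = 1, not significant
  m2 <- cbind(a = c(1, -1, 1, -1), b = c(1, 1, -1, -1))
  rep2 <- correlation_analysis(m2)
  expect_equal(rep2$r[1, 2], 0, tolerance = 1e-12)
  expect_false(rep2$significant[1, 2])

  # copula sample targeting r = 0.95 is recovered and significant
  n <- 100
  R <- matrix(c(1, 0.95, 0.95, 1), 2)
  set.seed(41)
  Z <- matrix(rnorm(2 * n), n, 2) %*% chol(R)
  rep3 <- correlation_analysis(Z)
  expect_lt(abs(rep3$r[1, 2] - 0.95), 0.03)
  expect_true(rep3$significant[1, 2])
})
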