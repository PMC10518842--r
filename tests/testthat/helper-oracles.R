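# Independent oracles coded as direct transcriptions (loops, no reuse of
# the package's code paths), used to cross-check the implementations.

# CRITIC weights: spreadsheet-style evaluation of normalize -> contrast ->
# conflict -> information -> weight
oracle_critic_weights <- function(M, polarity = rep("benefit", ncol(M))) {
  n <- nrow(M); p <- ncol(M)
  X <- matrix(NA_real_, n, p)
  for (j in seq_len(p)) {
    xmin <- min(M[, j]); xmax <- max(M[, j])
    for (i in seq_len(n)) {
      X[i, j] <- if (polarity[j] == "cost") {
        (xmax - M[i, j]) / (xmax - xmin)
      } else {
        (M[i, j] - xmin) / (xmax - xmin)
      }
    }
  }
  S <- numeric(p)
  for (j in seq_len(p)) {
    xbar <- sum(X[, j]) / n
    S[j] <- sqrt(sum((X[, j] - xbar)^2) / (n - 1))
  }
  r <- matrix(NA_real_, p, p)
  for (a in seq_len(p)) {
    for (b in seq_len(p)) {
      xa <- X[, a] - sum(X[, a]) / n
      xb <- X[, b] - sum(X[, b]) / n
      r[a, b] <- sum(xa * xb) / sqrt(sum(xa^2) * sum(xb^2))
    }
  }
  R <- numeric(p)
  for (j in seq_len(p)) R[j] <- sum(1 - r[, j])
  C <- S * R
  C / sum(C)
}

# exhaustive search over every feature/midpoint pair, gini criterion
oracle_root_split <- function(X, y, K = max(y) + 1L) {
  gini_of <- function(lab) {
    p <- tabulate(lab + 1L, nbins = K) / length(lab)
    1 - sum(p^2)
  }
  best <- NULL
  n <- length(y)
  for (j in seq_len(ncol(X))) {
    v <- sort(unique(X[, j]))
    if (length(v) < 2L) next
    for (t in (v[-length(v)] + v[-1]) / 2) {
      li <- y[X[, j] <= t]
      ri <- y[X[, j] > t]
      score <- length(li) / n * gini_of(li) + length(ri) / n * gini_of(ri)
      if (is.null(best) || score < best$score - 1e-12) {
        best <- list(feature = j, threshold = t, score = score)
      }
    }
  }
  best
}

# fraction of positive-negative pairs ordered correctly, ties count 1/2
oracle_pairwise_auc <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  total <- 0
  for (a in pos) {
    for (b in neg) total <- total + (a > b) + 0.5 * (a == b)
  }
  total / (length(pos) * length(neg))
}

# small indicator-table data frame with the canonical columns
make_indicator_df <- function(n = 6, seed = 1) {
  set.seed(seed)
  df <- data.frame(plot_id = sprintf("P%02d", seq_len(n)),
                   stratum = rep(c("primary", "secondary"), length.out = n))
  for (col in fh_indicators()) df[[col]] <- round(runif(n, 0.1, 0.9), 3)
  df
}

write_csv_fixture <- function(df, name) {
  path <- file.path(tempdir(), name)
  utils::write.csv(df, path, row.names = FALSE)
  path
}
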