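# Classification tree built from first principles: greedy binary recursive
# partitioning over numeric features, gini (default) or entropy impurity,
# "value <= threshold goes left" with thresholds at midpoints between
# consecutive distinct sorted values. Deterministic: ties between
# equal-quality splits resolve to the lowest feature index, then the lowest
# threshold.

#' Shannon entropy of class counts (bits)
#'
#' \eqn{H(D) = -\sum_k (C_k/|D|) \log_2 (C_k/|D|)}.
#'
#' @param class_counts Non-negative per-class counts, total >= 1.
#' @return Entropy in bits; 0 for a pure node, at most \eqn{\log_2 K}.
#' @export
class_entropy <- function(class_counts) {
  total <- sum(class_counts)
  if (total <= 0) stop("class_entropy: empty node", call. = FALSE)
  p <- class_counts[class_counts > 0] / total
  -sum(p * log2(p))
}

#' Conditional entropy of a partition
#'
#' \eqn{H(D|A) = \sum_i (|D_i|/|D|) H(D_i)}: the size-weighted mean entropy
#' of the parts \eqn{D_i} induced by splitting on a feature.
#'
#' @param partition List of per-class count vectors, one per part.
#' @return Weighted entropy in bits.
#' @export
conditional_entropy <- function(partition) {
  sizes <- vapply(partition, sum, numeric(1))
  keep <- sizes > 0
  if (!any(keep)) stop("conditional_entropy: empty partition", call. = FALSE)
  total <- sum(sizes)
  sum(vapply(partition[keep], class_entropy, numeric(1)) *
        sizes[keep] / total)
}

#' Information gain of a partition
#'
#' \eqn{g(D, A) = H(D) - H(D|A)}; equals \eqn{H(D)} when every part is
#' class-pure and 0 when the partition is uninformative.
#'
#' @param parent_counts Per-class counts of the parent node.
#' @param partition List of per-class count vectors summing to the parent.
#' @return Gain in bits, >= 0.
#' @export
information_gain <- function(parent_counts, partition) {
  part_sum <- Reduce(`+`, partition)
  if (!isTRUE(all.equal(as.numeric(part_sum),
                        as.numeric(parent_counts)))) {
    stop("information_gain: partition does not sum to parent counts",
         call. = FALSE)
  }
  max(0, class_entropy(parent_counts) - conditional_entropy(partition))
}

#' Gain ratio (parent-entropy variant)
#'
#' Information gain divided by the parent entropy \eqn{H(D)}, giving a
#' value in [0, 1]. Note this normalizes by the parent's class entropy, not
#' by the split information of the standard C4.5 gain ratio; the variant is
#' kept as such deliberately and documented here.
#'
#' @inheritParams information_gain
#' @return \eqn{g(D, A) / H(D) \in [0, 1]}.
#' @export
gain_ratio <- function(parent_counts, partition) {
  H <- class_entropy(parent_counts)
  if (H <= 0) stop("gain_ratio: parent node is pure (H = 0)", call. = FALSE)
  information_gain(parent_counts, partition) / H
}

#' Gini impurity of class counts
#'
#' \eqn{gini(D) = 1 - \sum_k (C_k/|D|)^2}: the probability that two
#' independent draws from the node differ in class.
#'
#' @param class_counts Non-negative per-class counts, total >= 1.
#' @return Impurity in \eqn{[0, 1 - 1/K]}.
#' @export
gini_impurity <- function(class_counts) {
  total <- sum(class_counts)
  if (total <= 0) stop("gini_impurity: empty node", call. = FALSE)
  1 - sum((class_counts / total)^2)
}

#' Weighted gini of a binary split
#'
#' \eqn{gini(D, A) = (|D_1|/|D|) gini(D_1) + (|D_2|/|D|) gini(D_2)}.
#'
#' @param left_counts,right_counts Per-class counts of the two children,
#'   each non-empty.
#' @return Weighted child impurity.
#' @export
gini_split <- function(left_counts, right_counts) {
  nl <- sum(left_counts); nr <- sum(right_counts)
  if (nl <= 0 || nr <= 0) stop("gini_split: empty child", call. = FALSE)
  (nl * gini_impurity(left_counts) + nr * gini_impurity(right_counts)) /
    (nl + nr)
}

.node_impurity <- function(counts, criterion) {
  if (criterion == "gini") gini_impurity(counts) else class_entropy(counts)
}

#' Best binary split of a node
#'
#' Scans every feature and every midpoint between consecutive distinct
#' sorted values, scoring each candidate by the weighted child impurity
#' (gini or entropy). Returns \code{NULL} for a pure node or when no split
#' strictly reduces impurity.
#'
#' @param X Numeric matrix, samples x features.
#' @param y Integer class labels in 0..K-1.
#' @param criterion \code{"gini"} (default) or \code{"entropy"}.
#' @param K Number of classes (defaults to \code{max(y) + 1}).
#' @return List with \code{feature} (column index), \code{threshold},
#'   \code{score} (weighted child impurity) and \code{decrease}
#'   (parent impurity minus score), or \code{NULL}.
#' @export
best_split <- function(X, y, criterion = c("gini", "entropy"), K = NULL) {
  criterion <- match.arg(criterion)
  X <- as.matrix(X)
  n <- nrow(X)
  if (n < 2L) return(NULL)
  K <- K %||% (max(y) + 1L)
  parent_counts <- tabulate(y + 1L, nbins = K)
  parent_imp <- .node_impurity(parent_counts, criterion)
  if (parent_imp <= 0) return(NULL)

  best <- NULL
  for (j in seq_len(ncol(X))) {
    ord <- order(X[, j])
    xs <- X[ord, j]
    ys <- y[ord]
    # cumulative class counts after each prefix
    onehot <- matrix(0L, n, K)
    onehot[cbind(seq_len(n), ys + 1L)] <- 1L
    cum <- apply(onehot, 2, cumsum)
    for (i in seq_len(n - 1L)) {
      if (xs[i] == xs[i + 1L]) next
      left <- cum[i, ]
      right <- parent_counts - left
      score <- if (criterion == "gini") {
        gini_split(left, right)
      } else {
        conditional_entropy(list(left, right))
      }
      if (is.null(best) || score < best$score - 1e-12) {
        best <- list(feature = j,
                     threshold = (xs[i] + xs[i + 1L]) / 2,
                     score = score,
                     decrease = parent_imp - score)
      }
    }
  }
  if (!is.null(best) && best$decrease <= 1e-12) best <- NULL
  best
}

#' Tree hyperparameters
#'
#' Defaults reproduce classic CART growth: gini criterion, unlimited
#' depth, splitting any node with at least two samples, growing until the
#' leaves are pure or too small to split. \code{min_impurity_decrease}
#' offers a light pre-pruning control.
#'
#' @param criterion \code{"gini"} or \code{"entropy"}.
#' @param max_depth Maximum depth (root = 0); \code{Inf} for unlimited.
#' @param min_samples_split Smallest node that may be split (>= 2).
#' @param min_impurity_decrease Minimum impurity decrease a split must
#'   achieve.
#' @return A \code{tree_params} list.
#' @export
tree_params <- function(criterion = c("gini", "entropy"), max_depth = Inf,
                        min_samples_split = 2L, min_impurity_decrease = 0) {
  criterion <- match.arg(criterion)
  if (min_samples_split < 2L) {
    stop("min_samples_split must be >= 2", call. = FALSE)
  }
  if (max_depth < 0) stop("max_depth must be >= 0", call. = FALSE)
  structure(list(criterion = criterion, max_depth = max_depth,
                 min_samples_split = as.integer(min_samples_split),
                 min_impurity_decrease = min_impurity_decrease),
            class = "tree_params")
}

#' Grow a classification tree
#'
#' Depth-first recursive partitioning: each node takes the best split
#' returned by \code{\link{best_split}} until it is pure, smaller than
#' \code{min_samples_split}, at \code{max_depth}, or no split reduces
#' impurity. Contradictory duplicates (identical feature vectors with
#' different labels) terminate in an impure leaf. Growth is fully
#' deterministic.
#'
#' @param X Numeric matrix or data frame, samples x features (named
#'   columns recommended).
#' @param y Class labels: a factor, or integers in 0..K-1.
#' @param params A \code{\link{tree_params}} list.
#' @return An \code{fh_tree} model.
#' @export
#' @examples
#' X <- cbind(x = c(1, 2, 10, 11))
#' fit <- grow_tree(X, c(0, 0, 1, 1))
#' predict(fit, X)
grow_tree <- function(X, y, params = tree_params()) {
  X <- as.matrix(X)
  if (is.null(colnames(X))) {
    colnames(X) <- paste0("X", seq_len(ncol(X)))
  }
  ordered_y <- is.ordered(y)
  if (is.factor(y)) {
    classes <- levels(y)
    yi <- as.integer(y) - 1L
  } else {
    yi <- as.integer(y)
    if (any(yi < 0)) stop("labels must be in 0..K-1", call. = FALSE)
    classes <- as.character(seq_len(max(yi) + 1L) - 1L)
  }
  if (nrow(X) < 1L) stop("grow_tree: no samples", call. = FALSE)
  if (nrow(X) != length(yi)) stop("X/y length mismatch", call. = FALSE)
  K <- length(classes)

  build <- function(idx, depth) {
    counts <- tabulate(yi[idx] + 1L, nbins = K)
    imp <- .node_impurity(counts, params$criterion)
    node <- list(kind = "leaf",
                 impurity = imp,
                 n_samples = length(idx),
                 class_counts = counts,
                 predicted_class = which.max(counts) - 1L,
                 depth = depth)
    if (imp <= 0 || length(idx) < params$min_samples_split ||
        depth >= params$max_depth) {
      return(node)
    }
    s <- best_split(X[idx, , drop = FALSE], yi[idx],
                    criterion = params$criterion, K = K)
    if (is.null(s) || s$decrease < params$min_impurity_decrease) {
      return(node)
    }
    go_left <- X[idx, s$feature] <= s$threshold
    node$kind <- "split"
    node$feature <- s$feature
    node$threshold <- s$threshold
    node$left <- build(idx[go_left], depth + 1L)
    node$right <- build(idx[!go_left], depth + 1L)
    node$predicted_class <- NULL
    node
  }

  structure(list(root = build(seq_len(nrow(X)), 0L),
                 feature_names = colnames(X),
                 classes = classes,
                 ordered = ordered_y,
                 params = params,
                 n = nrow(X)),
            class = "fh_tree")
}

.route <- function(node, xrow) {
  while (node$kind == "split") {
    node <- if (xrow[node$feature] <= node$threshold) node$left else node$right
  }
  node
}

.model_matrix <- function(model, newdata) {
  newdata <- as.matrix(newdata)
  if (!is.null(colnames(newdata))) {
    missing <- setdiff(model$feature_names, colnames(newdata))
    if (length(missing)) {
      stop("newdata lacks feature(s): ", paste(missing, collapse = ", "),
           call. = FALSE)
    }
    newdata <- newdata[, model$feature_names, drop = FALSE]
  } else if (ncol(newdata) != length(model$feature_names)) {
    stop("newdata has ", ncol(newdata), " columns; model expects ",
         length(model$feature_names), call. = FALSE)
  }
  newdata
}

#' Predict classes or class probabilities
#'
#' Routes each row down the tree by its threshold tests (a value exactly
#' at a threshold goes left). Class predictions are the leaf majority
#' (ties to the lowest class index); probabilities are the leaf's class
#' frequencies — the only probability source a bare CART has, and the
#' scores used for ROC/AUC evaluation.
#'
#' @param object A fitted \code{fh_tree}.
#' @param newdata Matrix or data frame containing the training features.
#' @param type \code{"class"} (default) or \code{"prob"}.
#' @param ... Unused.
#' @return Factor of class labels, or a samples x K probability matrix
#'   whose rows sum to 1.
#' @export
predict.fh_tree <- function(object, newdata, type = c("class", "prob"), ...) {
  type <- match.arg(type)
  m <- .model_matrix(object, newdata)
  K <- length(object$classes)
  if (type == "class") {
    lab <- vapply(seq_len(nrow(m)), function(i) {
      leaf <- .route(object$root, m[i, ])
      which.max(leaf$class_counts) - 1L
    }, integer(1))
    factor(object$classes[lab + 1L], levels = object$classes,
           ordered = isTRUE(object$ordered))
  } else {
    out <- t(vapply(seq_len(nrow(m)), function(i) {
      leaf <- .route(object$root, m[i, ])
      leaf$class_counts / leaf$n_samples
    }, numeric(K)))
    colnames(out) <- object$classes
    out
  }
}

#' Impurity-based feature importances
#'
#' For each feature, sums over the split nodes using it the quantity
#' \eqn{(n_{node}/n_{total}) (imp_{node} - imp_{children})}, i.e. the
#' sample-weighted impurity decrease, then normalizes the vector to sum 1.
#' Features never used in a split score 0.
#'
#' @param model A fitted \code{fh_tree}.
#' @return Named numeric vector over the model's features.
#' @export
feature_importances <- function(model) {
  imp <- setNames(numeric(length(model$feature_names)),
                  model$feature_names)
  walk <- function(node) {
    if (node$kind != "split") return(invisible())
    child_imp <- (node$left$n_samples * node$left$impurity +
                    node$right$n_samples * node$right$impurity) /
      node$n_samples
    f <- model$feature_names[node$feature]
    imp[f] <<- imp[f] + node$n_samples / model$n *
      (node$impurity - child_imp)
    walk(node$left)
    walk(node$right)
  }
  walk(model$root)
  total <- sum(imp)
  if (total <= 0) {
    warning("tree has no splits; importances are all zero", call. = FALSE)
    return(imp)
  }
  imp / total
}

#' Export a tree as text or DOT
#'
#' The text form lists one node per line, indented by depth, with the
#' split test, impurity, sample count, class counts and majority class —
#' the standard explainable-tree rendering. The DOT form is a Graphviz
#' digraph. \code{display_depth} truncates the rendering (nodes at that
#' depth are shown as leaves with their class counts) without touching the
#' fitted model, so a deep tree can be displayed at depth 3 for
#' readability.
#'
#' @param model A fitted \code{fh_tree}.
#' @param format \code{"text"} or \code{"dot"}.
#' @param display_depth Depth at which to truncate the display
#'   (default \code{Inf}).
#' @return A single character string.
#' @export
export_tree <- function(model, format = c("text", "dot"),
                        display_depth = Inf) {
  format <- match.arg(format)
  crit <- model$params$criterion
  describe <- function(node) {
    sprintf("%s=%.4f, samples=%d, value=[%s], class=%s",
            crit, node$impurity, node$n_samples,
            paste(node$class_counts, collapse = ", "),
            model$classes[which.max(node$class_counts)])
  }
  if (format == "text") {
    lines <- character(0)
    walk <- function(node, depth, prefix) {
      pad <- strrep("  ", depth)
      truncated <- node$kind == "split" && depth >= display_depth
      if (node$kind == "leaf" || truncated) {
        lines <<- c(lines, paste0(pad, prefix, "leaf: ", describe(node)))
        return(invisible())
      }
      lines <<- c(lines, sprintf("%s%s%s <= %.4f [%s]", pad, prefix,
                                 model$feature_names[node$feature],
                                 node$threshold, describe(node)))
      walk(node$left, depth + 1L, "yes: ")
      walk(node$right, depth + 1L, "no:  ")
    }
    walk(model$root, 0L, "")
    paste(lines, collapse = "\n")
  } else {
    nodes <- character(0); edges <- character(0); counter <- 0L
    walk <- function(node, depth) {
      counter <<- counter + 1L
      id <- counter
      truncated <- node$kind == "split" && depth >= display_depth
      label <- if (node$kind == "split" && !truncated) {
        sprintf("%s <= %.4f\\n%s",
                model$feature_names[node$feature], node$threshold,
                describe(node))
      } else {
        describe(node)
      }
      shape <- if (node$kind == "split" && !truncated) "box" else "ellipse"
      nodes <<- c(nodes, sprintf("  n%d [label=\"%s\", shape=%s];",
                                 id, label, shape))
      if (node$kind == "split" && !truncated) {
        lid <- walk(node$left, depth + 1L)
        rid <- walk(node$right, depth + 1L)
        edges <<- c(edges,
                    sprintf("  n%d -> n%d [label=\"yes\"];", id, lid),
                    sprintf("  n%d -> n%d [label=\"no\"];", id, rid))
      }
      id
    }
    walk(model$root, 0L)
    paste(c("digraph fh_tree {", nodes, edges, "}"), collapse = "\n")
  }
}

#' Count nodes in a fitted tree
#'
#' @param model A fitted \code{fh_tree}.
#' @param display_depth Count as if rendered truncated at this depth.
#' @return Integer node count.
#' @export
tree_node_count <- function(model, display_depth = Inf) {
  walk <- function(node, depth) {
    if (node$kind == "leaf" || depth >= display_depth) return(1L)
    1L + walk(node$left, depth + 1L) + walk(node$right, depth + 1L)
  }
  walk(model$root, 0L)
}

#' @export
print.fh_tree <- function(x, ...) {
  cat(sprintf("Classification tree (%s): %d samples, %d features, %d classes, %d nodes\n",
              x$params$criterion, x$n, length(x$feature_names),
              length(x$classes), tree_node_count(x)))
  cat(export_tree(x, "text", display_depth = 3), "\n")
  invisible(x)
}

# --- serialization ---------------------------------------------------------

#' Convert a fitted tree to a plain list (for JSON)
#'
#' @param model A fitted \code{fh_tree}.
#' @return Nested list mirroring the tree structure.
#' @export
tree_to_list <- function(model) {
  strip <- function(node) {
    base <- list(kind = node$kind, impurity = node$impurity,
                 n_samples = node$n_samples,
                 class_counts = as.integer(node$class_counts),
                 depth = node$depth)
    if (node$kind == "split") {
      base$feature <- model$feature_names[node$feature]
      base$threshold <- node$threshold
      base$left <- strip(node$left)
      base$right <- strip(node$right)
    } else {
      base$predicted_class <- model$classes[node$predicted_class + 1L]
    }
    base
  }
  params <- unclass(model$params)
  if (!is.finite(params$max_depth)) params$max_depth <- "unlimited"
  list(model = "fh_tree",
       feature_names = model$feature_names,
       classes = model$classes,
       ordered = isTRUE(model$ordered),
       params = params,
       n = model$n,
       root = strip(model$root))
}

#' Read a tree model from JSON
#'
#' Inverse of \code{\link{write_results}} on an \code{fh_tree}; the
#' reloaded model yields identical predictions.
#'
#' @param path Path to a model JSON file.
#' @return An \code{fh_tree}.
#' @export
read_tree_model <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE,
                             simplifyDataFrame = FALSE)
  feats <- unlist(raw$feature_names)
  classes <- unlist(raw$classes)
  rebuild <- function(nd) {
    node <- list(kind = nd$kind, impurity = nd$impurity,
                 n_samples = as.integer(nd$n_samples),
                 class_counts = as.integer(unlist(nd$class_counts)),
                 depth = as.integer(nd$depth))
    if (nd$kind == "split") {
      node$feature <- match(nd$feature, feats)
      node$threshold <- nd$threshold
      node$left <- rebuild(nd$left)
      node$right <- rebuild(nd$right)
    } else {
      node$predicted_class <- match(nd$predicted_class, classes) - 1L
    }
    node
  }
  p <- raw$params
  if (is.character(p$max_depth)) p$max_depth <- Inf
  params <- tree_params(criterion = p$criterion,
                        max_depth = p$max_depth %||% Inf,
                        min_samples_split = p$min_samples_split,
                        min_impurity_decrease = p$min_impurity_decrease)
  structure(list(root = rebuild(raw$root), feature_names = feats,
                 classes = classes, ordered = isTRUE(raw$ordered),
                 params = params, n = as.integer(raw$n)),
            class = "fh_tree")
}
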