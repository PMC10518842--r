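#' Default indicator polarity map
#'
#' Direction in which each indicator acts on forest health. Disturbance
#' level (IL), slope severity (SDS), soil impact (SNI) and fire risk (FRI)
#' are treated as cost indicators (higher is worse); the structural and
#' diversity indicators and elevation as benefit indicators. The polarity
#' map is an explicit, logged analysis choice: pass your own to any CRITIC
#' entry point to override.
#'
#' @return Named character vector over \code{\link{fh_indicators}} with
#'   values \code{"benefit"} or \code{"cost"}.
#' @export
fh_default_polarity <- function() {
  pol <- setNames(rep("benefit", 12L), fh_indicators())
  pol[c("IL", "SDS", "SNI", "FRI")] <- "cost"
  pol
}

#' Min-max normalization with polarity
#'
#' Rescales each indicator column to [0, 1]. Benefit columns map
#' \eqn{(x - x_{min}) / (x_{max} - x_{min})}; cost columns are reversed,
#' \eqn{(x_{max} - x) / (x_{max} - x_{min})}, so that 1 always means
#' "better for forest health". Both endpoints are attained in every column.
#'
#' @param values Numeric matrix, plots x indicators (column names kept).
#' @param polarity Character vector (\code{"benefit"}/\code{"cost"}), one
#'   per column, or a named vector matched by column name. Default: all
#'   benefit.
#' @return Normalized matrix of the same shape.
#' @export
minmax_normalize <- function(values, polarity = NULL) {
  values <- as.matrix(values)
  p <- ncol(values)
  polarity <- .resolve_polarity(polarity, colnames(values), p)
  lo <- apply(values, 2, min)
  hi <- apply(values, 2, max)
  rng <- hi - lo
  if (any(rng == 0)) {
    bad <- colnames(values)[rng == 0] %||% which(rng == 0)
    stop("degenerate (constant) indicator column: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  out <- sweep(sweep(values, 2, lo, "-"), 2, rng, "/")
  flip <- polarity == "cost"
  out[, flip] <- 1 - out[, flip, drop = FALSE]
  out
}

.resolve_polarity <- function(polarity, cn, p) {
  if (is.null(polarity)) return(rep("benefit", p))
  if (!is.null(names(polarity)) && !is.null(cn)) {
    missing <- setdiff(cn, names(polarity))
    if (length(missing)) {
      stop("polarity map lacks entries for: ",
           paste(missing, collapse = ", "), call. = FALSE)
    }
    polarity <- polarity[cn]
  }
  if (length(polarity) != p) {
    stop("polarity must have one entry per indicator column", call. = FALSE)
  }
  if (!all(polarity %in% c("benefit", "cost"))) {
    stop("polarity values must be 'benefit' or 'cost'", call. = FALSE)
  }
  unname(polarity)
}

#' Contrast intensity of normalized indicators
#'
#' The sample standard deviation (n - 1 denominator) of each normalized
#' column. A high-contrast indicator discriminates strongly between plots.
#'
#' @param normalized Matrix from \code{\link{minmax_normalize}}; >= 2 rows.
#' @return Numeric vector of per-indicator standard deviations.
#' @export
contrast_intensity <- function(normalized) {
  normalized <- as.matrix(normalized)
  if (nrow(normalized) < 2L) {
    stop("contrast_intensity: need at least 2 plots", call. = FALSE)
  }
  apply(normalized, 2, sd)
}

#' Conflict of each indicator with the rest
#'
#' \eqn{R_j = \sum_i (1 - r_{ij})} over all indicators i (the i = j term
#' contributes 0). Indicators weakly correlated with the others carry more
#' unique information and thus more conflict. The signed form is the
#' default; \code{use_abs = TRUE} substitutes \eqn{|r_{ij}|}, the variant
#' common in the multi-criteria literature.
#'
#' @param normalized Normalized indicator matrix; >= 3 rows.
#' @param corr_kind \code{"pearson"} (default) or \code{"spearman"}.
#' @param use_abs Use absolute correlations in \eqn{1 - r}.
#' @return Numeric vector \eqn{R_j}, with the correlation matrix attached
#'   as attribute \code{"r"}.
#' @export
critic_conflict <- function(normalized, corr_kind = c("pearson", "spearman"),
                            use_abs = FALSE) {
  corr_kind <- match.arg(corr_kind)
  normalized <- as.matrix(normalized)
  if (nrow(normalized) < 3L) {
    stop("critic_conflict: need at least 3 plots", call. = FALSE)
  }
  r <- cor(normalized, method = corr_kind)
  if (anyNA(r)) stop("undefined correlation (zero-variance column)",
                     call. = FALSE)
  ru <- if (use_abs) abs(r) else r
  R <- colSums(1 - ru)
  attr(R, "r") <- r
  R
}

#' CRITIC objective weights
#'
#' Combines contrast intensity and conflict into the information content
#' \eqn{C_j = S_j R_j} and normalizes to weights
#' \eqn{W_j = C_j / \sum_j C_j}. Contrast is computed on the normalized
#' matrix, after the dimensionless rescaling that removes magnitude
#' differences between indicators.
#'
#' @param values Raw plots x indicators matrix (>= 2 columns, >= 3 rows,
#'   no constant columns).
#' @param polarity See \code{\link{minmax_normalize}}.
#' @param corr_kind,use_abs See \code{\link{critic_conflict}}.
#' @return A \code{critic_result} with the normalized matrix and the
#'   per-indicator \code{sd} (contrast), \code{conflict},
#'   \code{information} and \code{weights} (summing to 1).
#' @export
#' @examples
#' m <- cbind(a = c(1, 2, 3, 4), b = c(2, 1, 4, 3))
#' critic_weights(m)$weights
critic_weights <- function(values, polarity = NULL,
                           corr_kind = c("pearson", "spearman"),
                           use_abs = FALSE) {
  corr_kind <- match.arg(corr_kind)
  values <- as.matrix(values)
  if (ncol(values) < 2L) {
    stop("critic_weights: need at least 2 indicators", call. = FALSE)
  }
  polarity <- .resolve_polarity(polarity, colnames(values), ncol(values))
  normalized <- minmax_normalize(values, polarity)
  S <- contrast_intensity(normalized)
  R <- critic_conflict(normalized, corr_kind, use_abs)
  r <- attr(R, "r")
  attr(R, "r") <- NULL
  C <- S * R
  if (all(abs(C) < 1e-12)) {
    stop("degenerate weighting: all indicators carry zero information ",
         "(mutually perfectly correlated)", call. = FALSE)
  }
  W <- C / sum(C)
  structure(
    list(normalized = normalized, sd = S, conflict = R, information = C,
         weights = W, correlation = r, polarity = setNames(
           polarity, colnames(values)),
         corr_kind = corr_kind, use_abs = use_abs,
         fh = NULL, health_class = NULL),
    class = "critic_result"
  )
}

#' Composite forest-health score
#'
#' The weighted sum \eqn{FH_i = \sum_j W_j x'_{ij}} of normalized
#' indicator values — a convex combination, so \eqn{FH \in [0, 1]} with 1
#' attained only by a plot at the favourable extreme of every indicator.
#'
#' @param normalized Normalized matrix (values in [0, 1]).
#' @param weights Non-negative weights summing to 1, one per column.
#' @return Numeric vector of per-plot scores.
#' @export
forest_health_score <- function(normalized, weights) {
  normalized <- as.matrix(normalized)
  if (length(weights) != ncol(normalized)) {
    stop("forest_health_score: weights/indicator dimension mismatch",
         call. = FALSE)
  }
  if (abs(sum(weights) - 1) > 1e-6) {
    stop("forest_health_score: weights must sum to 1", call. = FALSE)
  }
  as.numeric(normalized %*% weights)
}

#' Assign the four health classes
#'
#' Maps forest-health scores to the ordered classes UHF (0) < SHF (1) <
#' HF (2) < VHF (3). The default \code{"quartile"} scheme cuts at the
#' sample's own FH quartiles; the \code{"fixed"} scheme uses three supplied
#' thresholds with half-open bins \eqn{[0, t_1), [t_1, t_2), [t_2, t_3),
#' [t_3, 1]} — a score exactly at a threshold joins the upper class.
#'
#' @param fh Numeric vector of forest-health scores.
#' @param scheme \code{"quartile"} (default) or \code{"fixed"}.
#' @param thresholds For \code{"fixed"}: three strictly increasing values
#'   in (0, 1).
#' @return Ordered factor with levels \code{UHF < SHF < HF < VHF}; integer
#'   codes 0-3 are \code{as.integer(x) - 1L}.
#' @export
assign_health_classes <- function(fh, scheme = c("quartile", "fixed"),
                                  thresholds = NULL) {
  scheme <- match.arg(scheme)
  if (scheme == "quartile") {
    thresholds <- unname(quantile(fh, c(0.25, 0.5, 0.75)))
  } else {
    if (is.null(thresholds) || length(thresholds) != 3L) {
      stop("fixed scheme needs exactly 3 thresholds", call. = FALSE)
    }
    if (any(diff(thresholds) <= 0) ||
        any(thresholds <= 0) || any(thresholds >= 1)) {
      stop("thresholds must be strictly increasing and inside (0, 1)",
           call. = FALSE)
    }
  }
  code <- findInterval(fh, thresholds)   # [t_k, t_{k+1}) -> k
  factor(fh_classes()[code + 1L], levels = fh_classes(), ordered = TRUE)
}

#' Pairwise correlation analysis with significance mask
#'
#' Pearson correlations between all indicator pairs with two-sided
#' p-values from the t transform \eqn{t = r\sqrt{(n-2)/(1-r^2)}}, and a
#' boolean mask of pairs significant at level \code{alpha}. Mirrors the
#' correlation screen customarily shown before CRITIC weighting, where
#' non-significant cells are blanked.
#'
#' @param values Plots x indicators matrix, >= 3 rows.
#' @param alpha Significance level (default 0.05).
#' @return A \code{correlation_report}: list with \code{r},
#'   \code{p_values}, \code{significant}, \code{n}, \code{alpha}.
#' @export
correlation_analysis <- function(values, alpha = 0.05) {
  values <- as.matrix(values)
  n <- nrow(values)
  if (n < 3L) stop("correlation_analysis: need at least 3 plots",
                   call. = FALSE)
  r <- cor(values)
  if (anyNA(r)) stop("undefined correlation (zero-variance column)",
                     call. = FALSE)
  r2 <- pmin(r^2, 1 - 1e-15)
  tstat <- r * sqrt((n - 2) / (1 - r2))
  p <- 2 * pt(abs(tstat), df = n - 2, lower.tail = FALSE)
  diag(p) <- 0
  structure(list(r = r, p_values = p, significant = p <= alpha,
                 n = n, alpha = alpha),
            class = "correlation_report")
}

#' Full CRITIC assessment of an indicator table
#'
#' Convenience wrapper: normalizes, weights, scores and classifies in one
#' call.
#'
#' @param table An \code{indicator_table} (or raw matrix).
#' @param polarity Polarity map; defaults to
#'   \code{\link{fh_default_polarity}} when the columns are the canonical
#'   twelve, otherwise all-benefit.
#' @param scheme,thresholds See \code{\link{assign_health_classes}}.
#' @param corr_kind,use_abs See \code{\link{critic_conflict}}.
#' @return A \code{critic_result} with \code{fh} and \code{health_class}
#'   filled in.
#' @export
critic_assess <- function(table, polarity = NULL,
                          scheme = c("quartile", "fixed"), thresholds = NULL,
                          corr_kind = "pearson", use_abs = FALSE) {
  scheme <- match.arg(scheme)
  values <- if (inherits(table, "indicator_table")) {
    indicator_matrix(table)
  } else {
    as.matrix(table)
  }
  if (is.null(polarity) && !is.null(colnames(values)) &&
      setequal(colnames(values), fh_indicators())) {
    polarity <- fh_default_polarity()
  }
  res <- critic_weights(values, polarity, corr_kind, use_abs)
  res$fh <- forest_health_score(res$normalized, res$weights)
  names(res$fh) <- rownames(values)
  res$health_class <- assign_health_classes(res$fh, scheme, thresholds)
  res$scheme <- scheme
  res$thresholds <- thresholds
  res
}

#' @export
as.data.frame.critic_result <- function(x, ...) {
  data.frame(indicator = names(x$weights) %||%
               paste0("V", seq_along(x$weights)),
             polarity = unname(x$polarity),
             sd = unname(x$sd),
             conflict = unname(x$conflict),
             information = unname(x$information),
             weight = unname(x$weights),
             row.names = NULL)
}

#' @export
print.critic_result <- function(x, digits = 4, ...) {
  cat("CRITIC weighting of", length(x$weights), "indicators over",
      nrow(x$normalized), "plots\n")
  print(round(sort(x$weights, decreasing = TRUE), digits))
  if (!is.null(x$fh)) {
    cat("FH score range:",
        paste(round(range(x$fh), digits), collapse = " - "), "\n")
    print(table(x$health_class))
  }
  invisible(x)
}
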