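#' Gleason diversity index
#'
#' Richness per unit log-area, \eqn{D = S / \ln N}, where \eqn{S} is the
#' number of species recorded and \eqn{N} the surveyed area in square
#' metres. An empty plot (\eqn{S = 0}) scores 0.
#'
#' @param S Number of species (non-negative integer).
#' @param N Surveyed area in m2; must exceed 1 so that \eqn{\ln N > 0}.
#'   Defaults to the 400 m2 (20 m x 20 m) plot of a standard inventory grid.
#' @return Numeric index value.
#' @export
#' @examples
#' gleason_index(10, 400)
gleason_index <- function(S, N = 400) {
  if (any(N <= 1)) stop("gleason_index: area N must be > 1 m2", call. = FALSE)
  if (any(S < 0)) stop("gleason_index: S must be >= 0", call. = FALSE)
  S / log(N)
}

#' Menhinick richness index
#'
#' Richness per square-root of abundance, \eqn{M = S / \sqrt{n}}, with
#' \eqn{n} the total number of individuals. A literal ratio variant
#' \eqn{S / n} is available for compatibility with data sheets that use it.
#'
#' @param S Number of species.
#' @param n Total number of individuals.
#' @param variant \code{"sqrt"} (standard, default) or \code{"ratio"}.
#' @return Numeric index value; 0 when the plot is empty.
#' @export
menhinick_index <- function(S, n, variant = c("sqrt", "ratio")) {
  variant <- match.arg(variant)
  if (any(S >= 1 & n == 0)) {
    stop("menhinick_index: S >= 1 requires n >= 1", call. = FALSE)
  }
  out <- ifelse(S == 0, 0,
                if (variant == "sqrt") S / sqrt(n) else S / n)
  as.numeric(out)
}

#' Shannon-Wiener diversity index (bits)
#'
#' \eqn{H = -\sum_i P_i \log_2 P_i} over species proportions \eqn{P_i}.
#'
#' @param counts Named or unnamed vector of per-species individual counts,
#'   each >= 1.
#' @return Entropy in bits; 0 for a single-species plot, at most
#'   \eqn{\log_2 S}.
#' @export
#' @examples
#' shannon_index(c(A = 3, B = 1))
shannon_index <- function(counts) {
  counts <- counts[!is.na(counts)]
  if (length(counts) == 0L) {
    stop("shannon_index: empty abundance vector", call. = FALSE)
  }
  if (any(counts < 1)) {
    stop("shannon_index: every species count must be >= 1", call. = FALSE)
  }
  p <- counts / sum(counts)
  -sum(p * log2(p))
}

#' Pielou evenness
#'
#' Shannon entropy scaled by its maximum: \eqn{E = H / \log_2 S}. Both the
#' numerator and denominator use base-2 logarithms, so \eqn{E \in (0, 1]}
#' and \eqn{E = 1} exactly when all species are equally abundant. For a
#' plot with fewer than two species the index is undefined (0/0) and
#' \code{NA} is returned rather than an error, so that single-species plots
#' propagate visibly through downstream tables.
#'
#' @param counts Vector of per-species individual counts, each >= 1.
#' @return Evenness in (0, 1], or \code{NA_real_} when S < 2.
#' @export
pielou_evenness <- function(counts) {
  counts <- counts[!is.na(counts)]
  S <- length(counts)
  if (S <= 1L) return(NA_real_)
  shannon_index(counts) / log2(S)
}

#' Per-plot diversity indices from tree records
#'
#' Groups stem records by plot, builds each plot's species abundance
#' vector, and evaluates the four diversity quantities. Output order
#' follows first appearance of each plot; within-plot record order is
#' irrelevant.
#'
#' @param records Data frame of tree records as returned by
#'   \code{\link{read_tree_records}} (columns \code{plot_id},
#'   \code{species}; \code{stratum} is carried through when present).
#' @param plot_area Plot area in m2 used for the Gleason index
#'   (default 400).
#' @param menhinick_variant Passed to \code{\link{menhinick_index}}.
#' @return Data frame with one row per plot: \code{plot_id},
#'   (\code{stratum},) \code{S}, \code{n}, \code{Gleason},
#'   \code{Menhinick}, \code{Shannon}, \code{Pielou}.
#' @export
plot_indices <- function(records, plot_area = 400,
                         menhinick_variant = "sqrt") {
  if (nrow(records) == 0L) {
    stop("plot_indices: no records", call. = FALSE)
  }
  plots <- unique(records$plot_id)
  has_stratum <- "stratum" %in% names(records)
  rows <- lapply(plots, function(p) {
    sub <- records[records$plot_id == p, , drop = FALSE]
    ab <- table(sub$species)
    ab <- ab[ab > 0]
    S <- length(ab)
    n <- sum(ab)
    data.frame(
      plot_id = p,
      stratum = if (has_stratum) sub$stratum[1] else NA_character_,
      S = S, n = as.integer(n),
      Gleason = gleason_index(S, plot_area),
      Menhinick = menhinick_index(S, n, menhinick_variant),
      Shannon = if (S >= 1) shannon_index(as.numeric(ab)) else 0,
      Pielou = pielou_evenness(as.numeric(ab)),
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  if (!has_stratum) out$stratum <- NULL
  rownames(out) <- NULL
  out
}
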