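#' Symmetric uncertainty between a feature and the class labels
#'
#' `s = 2 I(x; y) / (H(x) + H(y))`, the mutual information between the
#' discretized feature and the labels normalized by the sum of marginal
#' entropies — 0 for empirically independent pairs, 1 for perfectly
#' correlated ones. The continuous feature is discretized into `n_bins`
#' equal-frequency bins; tied values always share a bin (so an already
#' discrete feature keeps its own levels when it has at most `n_bins` of
#' them). Entropies are computed in bits; the ratio is base-invariant.
#' Conventions: `s = 0` when `H(x) = 0` (constant feature).
#'
#' @param x numeric feature vector.
#' @param y labels in {-1, +1} with both classes present.
#' @param n_bins number of equal-frequency bins, `2 <= n_bins <= length(x)`.
#' @return symmetric uncertainty in [0, 1].
#' @export
symmetric_uncertainty <- function(x, y, n_bins = 2L) {
  n <- length(x)
  if (length(y) != n) stop("x and y must have equal length")
  if (length(unique(y)) < 2L) stop("y is single-class (constant labels)")
  if (n_bins < 2L || n_bins > n) stop("need n >= n_bins >= 2")
  bx <- equal_freq_bins(x, n_bins)
  hx <- entropy_bits(tabulate(bx))
  hy <- entropy_bits(table(y))
  if (hx + hy <= 0 || hx == 0) return(0)
  joint <- table(bx, y)
  mi <- hx + hy - entropy_bits(joint)
  s <- 2 * mi / (hx + hy)
  min(max(s, 0), 1)
}

# Equal-frequency binning that keeps ties together: average ranks mapped to
# ceiling(rank * n_bins / n). All equal values share an average rank, hence
# a bin, and a group's bin follows its rank midpoint (so two-valued features
# always occupy two bins regardless of imbalance).
equal_freq_bins <- function(x, n_bins) {
  r <- rank(x, ties.method = "average")
  as.integer(ceiling(r * n_bins / length(x)))
}

entropy_bits <- function(counts) {
  p <- as.numeric(counts)
  p <- p[p > 0]
  p <- p / sum(p)
  -sum(p * log2(p))
}

#' Per-feature symmetric uncertainty for a feature table
#'
#' Column-wise [symmetric_uncertainty()] against the table's labels. The
#' default bin count is `max(2, floor(sqrt(n)))`, a standard histogram rule
#' for n in the tens-to-hundreds range of motor-imagery trial counts.
#'
#' @param ft a `feature_table` from [csp_features()].
#' @param n_bins bin count; `NULL` (default) uses the sqrt rule.
#' @return an object of class `relevance_vector`: list with `s` (p-vector in
#'   [0,1]), `bins`, `entropy_base = 2`.
#' @export
relevance_vector <- function(ft, n_bins = NULL) {
  stopifnot(inherits(ft, "feature_table"))
  n <- nrow(ft$X)
  if (is.null(n_bins)) n_bins <- max(2L, floor(sqrt(n)))
  s <- vapply(seq_len(ncol(ft$X)), function(j) {
    tryCatch(symmetric_uncertainty(ft$X[, j], ft$labels, n_bins),
             error = function(e)
               stop(sprintf("feature column %d: %s", j, conditionMessage(e))))
  }, 0)
  structure(list(s = s, bins = as.integer(n_bins), entropy_base = 2L),
            class = "relevance_vector")
}
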