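#' Common spatial patterns for one frequency band
#'
#' Standard two-class CSP: per-trial covariances are trace-normalized and
#' averaged within class; the composite covariance C1 + C2 is whitened and
#' the whitened class "+1" covariance eigendecomposed. Because the whitened
#' class covariances sum to the identity, the eigenvalue spectrum lies in
#' [0, 1] and the class "-1" eigenvalue of the same filter is its complement.
#' Eigenvalues far from 0.5 indicate discriminative filters.
#'
#' @param band_epochs an [epoch_set()] already band-pass filtered.
#' @param n_filters_per_band number of spatial filters to retain (default 2).
#' @param mode `"largest"` keeps the filters with the largest eigenvalues
#'   (the default); `"paired"` keeps the classical largest+smallest pairs.
#' @param shrinkage_eps diagonal shrinkage added to each class covariance,
#'   as a fraction of trace/n_channels (default 1e-6), guaranteeing an
#'   invertible composite.
#' @return an object of class `csp_model` with fields `filters` (rows are
#'   spatial filters, sorted by descending eigenvalue), `eigenvalues`,
#'   `selected` (indices of retained filters), `band` and `channel_names`.
#' @export
fit_csp <- function(band_epochs, n_filters_per_band = 2L,
                    mode = c("largest", "paired"), shrinkage_eps = 1e-6) {
  stopifnot(inherits(band_epochs, "epoch_set"))
  mode <- match.arg(mode)
  y <- band_epochs$labels
  check_two_classes(y)
  nch <- n_channels(band_epochs)
  if (nch < n_filters_per_band)
    stop("n_filters_per_band cannot exceed the channel count")
  C1 <- class_covariance(band_epochs$data, y == 1, shrinkage_eps)
  C2 <- class_covariance(band_epochs$data, y == -1, shrinkage_eps)
  m <- csp_from_covariances(C1, C2, n_filters_per_band, mode)
  m$band <- attr(band_epochs, "band")
  m$channel_names <- band_epochs$channel_names
  m
}

# Average trace-normalized trial covariance for one class, with diagonal
# shrinkage eps * trace/n_channels.
class_covariance <- function(data, idx, eps) {
  nch <- dim(data)[2]
  C <- matrix(0, nch, nch)
  for (tr in which(idx)) {
    X <- data[tr, , , drop = TRUE]
    if (is.null(dim(X))) X <- matrix(X, nrow = 1L)
    Ct <- tcrossprod(X)
    trc <- sum(diag(Ct))
    if (trc <= 0) stop(sprintf("degenerate (zero-variance) trial %d", tr))
    C <- C + Ct / trc
  }
  C <- C / sum(idx)
  C + eps * (sum(diag(C)) / nch) * diag(nch)
}

#' CSP from class covariance matrices
#'
#' Core decomposition used by [fit_csp()], exposed so that exact covariance
#' inputs can be analysed: whitens `C1 + C2`, eigendecomposes the whitened
#' `C1`, and composes the eigenvector basis with the whitener into spatial
#' filter rows.
#'
#' @param C1,C2 symmetric positive semi-definite class covariances.
#' @param n_filters_per_band,mode see [fit_csp()].
#' @return a `csp_model` (without band/channel metadata).
#' @export
csp_from_covariances <- function(C1, C2, n_filters_per_band = 2L,
                                 mode = c("largest", "paired")) {
  mode <- match.arg(mode)
  nch <- nrow(C1)
  Cc <- (C1 + C2)
  Cc <- (Cc + t(Cc)) / 2
  ec <- eigen(Cc, symmetric = TRUE)
  if (min(ec$values) <= .Machine$double.eps * max(ec$values) * nch)
    stop("singular composite covariance; increase shrinkage_eps")
  P <- diag(1 / sqrt(ec$values), nch) %*% t(ec$vectors)
  S1 <- P %*% C1 %*% t(P)
  S1 <- (S1 + t(S1)) / 2
  e1 <- eigen(S1, symmetric = TRUE)        # eigenvalues descending
  W <- t(e1$vectors) %*% P                 # rows are spatial filters
  # deterministic sign: largest-magnitude entry of each filter positive
  for (k in seq_len(nch)) {
    j <- which.max(abs(W[k, ]))
    if (W[k, j] < 0) W[k, ] <- -W[k, ]
  }
  lam <- pmin(pmax(e1$values, 0), 1)
  selected <- if (mode == "largest") seq_len(n_filters_per_band)
  else {
    k1 <- ceiling(n_filters_per_band / 2)
    k2 <- n_filters_per_band - k1
    c(seq_len(k1), if (k2 > 0) seq.int(nch - k2 + 1L, nch))
  }
  structure(list(filters = W, eigenvalues = lam,
                 selected = as.integer(selected),
                 band = NULL, channel_names = NULL),
            class = "csp_model")
}

#' @export
print.csp_model <- function(x, ...) {
  cat(sprintf("csp_model%s: %d channels, %d retained filters\n",
              if (!is.null(x$band)) sprintf(" [%g-%g Hz]", x$band[1], x$band[2]) else "",
              nrow(x$filters), length(x$selected)))
  cat("  eigenvalues:", paste(sprintf("%.3f", x$eigenvalues), collapse = " "), "\n")
  invisible(x)
}

#' Fit one CSP model per filter-bank band
#'
#' @param bank_epochs output of [apply_bank()].
#' @param ... passed to [fit_csp()].
#' @return named list of `csp_model`s, one per band.
#' @export
fit_csp_bank <- function(bank_epochs, ...) {
  out <- lapply(bank_epochs, function(be) {
    attr(be$epochs, "band") <- be$band
    fit_csp(be$epochs, ...)
  })
  names(out) <- names(bank_epochs)
  out
}

#' Log-variance CSP features across bands
#'
#' For each trial, band and retained filter k the feature is
#' `log(var_k / sum(var_j, j in retained))` where `var_k` is the variance of
#' the trial projected on filter k. The within-band normalization makes the
#' features invariant to trial-wide amplitude scaling. Columns are ordered
#' band-major and carry provenance metadata (band edges, filter index,
#' eigenvalue).
#'
#' @param models list of `csp_model`s from [fit_csp_bank()].
#' @param bank_epochs output of [apply_bank()] on the epochs to featurize
#'   (same bands, same channel count as the fitted models).
#' @return an object of class `feature_table`: list with `X` (n x p matrix),
#'   `labels`, and `meta` (data.frame with band_low, band_high, band,
#'   filter, eigenvalue per column).
#' @export
csp_features <- function(models, bank_epochs) {
  stopifnot(length(models) == length(bank_epochs))
  n <- n_trials(bank_epochs[[1]]$epochs)
  cols <- list(); meta <- list()
  for (bi in seq_along(models)) {
    m <- models[[bi]]
    e <- bank_epochs[[bi]]$epochs
    W <- m$filters[m$selected, , drop = FALSE]
    V <- matrix(0, n, nrow(W))
    for (tr in seq_len(n)) {
      Z <- W %*% e$data[tr, , , drop = TRUE]
      v <- apply(Z, 1, stats::var)
      if (any(v <= 0))
        stop(sprintf("zero variance after projection (trial %d, band %s)",
                     tr, names(bank_epochs)[bi]))
      V[tr, ] <- log(v / sum(v))
    }
    cols[[bi]] <- V
    b <- bank_epochs[[bi]]$band
    meta[[bi]] <- data.frame(
      band_low = b[1], band_high = b[2],
      band = sprintf("%g-%g", b[1], b[2]),
      filter = m$selected,
      eigenvalue = m$eigenvalues[m$selected])
  }
  X <- do.call(cbind, cols)
  meta <- do.call(rbind, meta)
  rownames(meta) <- NULL
  colnames(X) <- paste0(meta$band, "/f", meta$filter)
  if (any(!is.finite(X))) stop("non-finite feature values")
  structure(list(X = X, labels = bank_epochs[[1]]$epochs$labels, meta = meta),
            class = "feature_table")
}

#' @export
print.feature_table <- function(x, ...) {
  cat(sprintf("feature_table: %d trials x %d features (%d bands)\n",
              nrow(x$X), ncol(x$X), length(unique(x$meta$band))))
  invisible(x)
}

#' Eigenvalue-based spatial information per feature
#'
#' For feature i extracted with a filter whose whitened-covariance eigenvalue
#' is lambda_i, the spatial information is `e_i = |lambda_i - mean(spectrum)|`
#' where the mean is over the full eigenvalue spectrum of that feature's band.
#' A flat spectrum (no class difference) gives e_i = 0; values are bounded by
#' [0, 1]. Order matches [csp_features()] columns.
#'
#' @param models list of `csp_model`s from [fit_csp_bank()].
#' @return numeric vector of length p.
#' @export
spatial_info <- function(models) {
  unlist(lapply(models, function(m) {
    abs(m$eigenvalues[m$selected] - mean(m$eigenvalues))
  }), use.names = FALSE)
}
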