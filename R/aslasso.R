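#' AS-LASSO penalty weights
#'
#' The adaptive structural LASSO penalizes feature i with weight
#' `w_i = exp(-mu * s_i * e_i)` where `s_i` is the symmetric uncertainty
#' between feature and labels, `e_i` the eigenvalue-based spatial
#' information, and `mu >= 0` an adjustment parameter. Weights are inversely
#' related to feature importance: a relevant, spatially significant feature
#' receives a small penalty. `mu = 0` gives unit weights, i.e. plain LASSO.
#' Weights are floored at 1e-8 so the rescaling step of the solver stays
#' well-conditioned. The alternative reading `exp(-mu * s_i) * e_i` is
#' available as `form = "mixed"` for comparison (clipped into (0, 1]).
#'
#' @param s symmetric uncertainty vector, entries in [0, 1].
#' @param e spatial information vector, entries >= 0, same length.
#' @param mu adjustment parameter >= 0 (default 1).
#' @param form `"exponent"` (default) or `"mixed"`.
#' @return weight vector in (0, 1].
#' @export
penalty_weights <- function(s, e, mu = 1, form = c("exponent", "mixed")) {
  form <- match.arg(form)
  if (length(s) != length(e)) stop("s and e must have equal length")
  if (any(s < 0 | s > 1)) stop("s entries must lie in [0, 1]")
  if (any(e < 0)) stop("e entries must be non-negative")
  if (mu < 0) stop("mu must be non-negative")
  w <- switch(form,
              exponent = exp(-mu * s * e),
              mixed = pmin(exp(-mu * s) * e, 1))
  pmax(w, 1e-8)
}

#' Coordinate-descent LASSO solver
#'
#' Cyclic coordinate descent for `min_beta ||y - X beta||_2^2 +
#' lambda ||beta||_1` (unscaled residual sum of squares). The coordinate
#' update is the exact soft-threshold minimizer; convergence is declared when
#' the largest absolute coefficient change in a sweep drops below `tol`.
#'
#' @param X n x p design (caller standardizes; no intercept).
#' @param y centered response.
#' @param lambda penalty >= 0 on the unscaled objective.
#' @param tol convergence tolerance on the max coefficient change (1e-8).
#' @param max_iter maximum sweeps (10000).
#' @param beta0 optional warm start.
#' @return list with `beta`, `iter`, `converged`.
#' @export
cd_lasso <- function(X, y, lambda, tol = 1e-8, max_iter = 10000L,
                     beta0 = NULL) {
  if (lambda < 0) stop("lambda must be non-negative")
  X <- as.matrix(X)
  cd_lasso_gram(crossprod(X), as.numeric(crossprod(X, y)), lambda,
                tol = tol, max_iter = max_iter, beta0 = beta0)
}

# Gram-matrix entry point: reuses G = X'X and q = X'y across a lambda path.
cd_lasso_gram <- function(G, q, lambda, tol = 1e-8, max_iter = 10000L,
                          beta0 = NULL, warn = TRUE) {
  if (is.null(beta0)) beta0 <- numeric(length(q))
  sol <- cd_lasso_cov_cpp(G, q, lambda, tol, as.integer(max_iter),
                          as.numeric(beta0))
  if (warn && !sol$converged)
    warning(sprintf("coordinate descent did not converge in %d sweeps", max_iter))
  list(beta = as.numeric(sol$beta), iter = sol$iter, converged = sol$converged)
}

# lambda at and above which every coefficient is zero for the weighted
# problem (on the rescaled design).
lambda_max_weighted <- function(Xs, yc, w)
  max(abs(2 * crossprod(sweep(Xs, 2, w, "/"), yc)))

#' Fit AS-LASSO by the weight-rescaling reduction
#'
#' Solves `min_beta ||y - X beta||^2 + lambda * sum_i w_i |beta_i|` by the
#' standard reduction: rescale each column `x_j** = x_j / w_j`, solve the
#' plain LASSO on the rescaled design by coordinate descent, and map back
#' `beta_j = beta_j** / w_j`. Columns are standardized to zero mean / unit
#' variance on the supplied data and the response (the -1/+1 labels) is
#' centered; coefficients are reported on the standardized scale.
#'
#' @param ft a `feature_table`, or a plain numeric matrix (then `y` must be
#'   given).
#' @param w penalty weights in (0, 1] (length p). Unit weights give plain
#'   LASSO.
#' @param lambda penalty parameter >= 0 (unscaled-objective scale).
#' @param y labels, only when `ft` is a matrix.
#' @param s,e optional relevance / spatial-information vectors, stored for
#'   fallback ranking in [select_features()].
#' @param mu the adjustment parameter used to build `w` (stored).
#' @param tol,max_iter solver controls, see [cd_lasso()].
#' @return an object of class `aslasso_fit`: `w`, `beta`, `mu`, `lambda`,
#'   `selected` (logical mask, `beta != 0`), `objective` (value of the
#'   weighted objective at the solution), `solver` diagnostics, and the
#'   standardization parameters (`center`, `scale`, `y_mean`).
#' @export
fit_aslasso <- function(ft, w, lambda, y = NULL, s = NULL, e = NULL,
                        mu = NA_real_, tol = 1e-8, max_iter = 10000L) {
  X <- if (inherits(ft, "feature_table")) ft$X else as.matrix(ft)
  if (is.null(y)) {
    if (!inherits(ft, "feature_table")) stop("supply y with a plain matrix")
    y <- ft$labels
  }
  p <- ncol(X)
  if (length(w) != p) stop("length(w) must equal the feature count")
  if (any(w <= 0) || any(w > 1 + 1e-12)) stop("weights must lie in (0, 1]")
  if (lambda < 0) stop("lambda must be non-negative")
  std <- standardize_columns(X)
  y_mean <- mean(y)
  yc <- y - y_mean
  Xw <- sweep(std$X, 2, w, "/")
  sol <- cd_lasso(Xw, yc, lambda, tol = tol, max_iter = max_iter)
  beta <- sol$beta / w
  resid <- yc - as.numeric(std$X %*% beta)
  structure(list(w = w, beta = beta, mu = mu, lambda = lambda,
                 selected = beta != 0,
                 objective = sum(resid^2) + lambda * sum(w * abs(beta)),
                 solver = list(tol = tol, iter = sol$iter,
                               converged = sol$converged),
                 s = s, e = e,
                 center = std$center, scale = std$scale, y_mean = y_mean),
            class = "aslasso_fit")
}

standardize_columns <- function(X) {
  ctr <- colMeans(X)
  scl <- apply(X, 2, stats::sd)
  scl[scl <= 0] <- 1          # constant columns stay (centered) zero
  list(X = sweep(sweep(X, 2, ctr), 2, scl, "/"), center = ctr, scale = scl)
}

#' @export
print.aslasso_fit <- function(x, ...) {
  cat(sprintf("aslasso_fit: lambda = %.4g, %d/%d features selected%s\n",
              x$lambda, sum(x$selected), length(x$beta),
              if (!x$solver$converged) " (NOT converged)" else ""))
  invisible(x)
}

#' Karush-Kuhn-Tucker residual of a weighted LASSO solution
#'
#' Maximum violation of the stationarity/subgradient conditions of the
#' weighted objective: for `beta_j = 0`, `|2 x_j'(y - X beta)| <= lambda w_j`;
#' for `beta_j != 0`, `2 x_j'(y - X beta) = lambda w_j sign(beta_j)`. Used by
#' the test-suite to certify solver correctness; exported because it is also
#' a useful runtime diagnostic.
#'
#' @param Xs standardized design, `yc` centered response, `beta` solution,
#'   `w` weights, `lambda` penalty.
#' @param yc,beta,w,lambda see above.
#' @return maximum KKT violation (0 for an exact solution).
#' @export
kkt_violation <- function(Xs, yc, beta, w, lambda) {
  g <- as.numeric(2 * crossprod(Xs, yc - as.numeric(Xs %*% beta)))
  viol <- ifelse(beta == 0,
                 pmax(abs(g) - lambda * w, 0),
                 abs(g - lambda * w * sign(beta)))
  max(viol)
}

#' Inner cross-validated lambda selection
#'
#' Warm-started solution path over `n_lambda` log-spaced points from
#' `lambda_max` (smallest lambda with an all-zero solution) down
#' `lambda_min_ratio` (default 3 decades), scored by stratified k-fold CV on
#' the training data. The default criterion refits the downstream classifier
#' on the features selected at each candidate and scores validation
#' misclassification; `criterion = "mse"` uses the cheaper regression error
#' of the linear predictor. Ties are broken toward the larger (sparser)
#' lambda. Fold assignment draws from the current RNG stream; seed upstream.
#'
#' @param X feature matrix, `y` labels in {-1, +1}.
#' @param y labels.
#' @param w penalty weights.
#' @param n_folds inner folds (default 5).
#' @param n_lambda path length (default 50).
#' @param lambda_min_ratio path depth (default 1e-3).
#' @param criterion `"class"` (default) or `"mse"`.
#' @param classifier downstream classifier name for `"class"` (see
#'   [fit_classifier()]).
#' @param rule `"1se"` (default) picks the sparsest lambda whose CV error is
#'   within one standard error of the minimum; `"min"` picks the error
#'   minimizer (largest such lambda on ties).
#' @return list with `lambda` (chosen), `lambda_path`, `cv_error`.
#' @export
cv_lambda <- function(X, y, w, n_folds = 5L, n_lambda = 50L,
                      lambda_min_ratio = 1e-3,
                      criterion = c("class", "mse"), classifier = "svm",
                      rule = c("1se", "min")) {
  criterion <- match.arg(criterion)
  rule <- match.arg(rule)
  folds <- stratified_folds(y, n_folds)
  err <- matrix(NA_real_, n_folds, n_lambda)
  lambda_path <- NULL
  for (f in seq_len(n_folds)) {
    tr <- folds != f
    std <- standardize_columns(X[tr, , drop = FALSE])
    yc <- y[tr] - mean(y[tr])
    Xw <- sweep(std$X, 2, w, "/")
    if (is.null(lambda_path)) {
      lmax <- max(abs(2 * crossprod(Xw, yc)))
      lambda_path <- exp(seq(log(lmax), log(lmax * lambda_min_ratio),
                             length.out = n_lambda))
    }
    Xva <- sweep(sweep(X[!tr, , drop = FALSE], 2, std$center), 2, std$scale, "/")
    G <- crossprod(Xw)
    q <- as.numeric(crossprod(Xw, yc))
    beta_ws <- numeric(ncol(X))
    err_by_mask <- new.env(parent = emptyenv())  # classifier error cache
    for (li in seq_along(lambda_path)) {
      sol <- cd_lasso_gram(G, q, lambda_path[li], tol = 1e-6,
                           beta0 = beta_ws, warn = FALSE)
      beta_ws <- sol$beta
      beta <- sol$beta / w
      sel <- beta != 0
      if (criterion == "mse") {
        pred <- as.numeric(Xva %*% beta) + mean(y[tr])
        err[f, li] <- mean((y[!tr] - pred)^2)
      } else {
        # the classifier only sees which features are selected, so candidates
        # with identical supports share one refit
        key <- paste0("m", paste(which(sel), collapse = ","))
        if (!is.null(err_by_mask[[key]])) {
          err[f, li] <- err_by_mask[[key]]
        } else {
          err[f, li] <- if (!any(sel)) {
            maj <- if (sum(y[tr] == 1) >= sum(y[tr] == -1)) 1 else -1
            mean(y[!tr] != maj)
          } else {
            mdl <- fit_classifier(std$X[, sel, drop = FALSE], y[tr],
                                  name = classifier)
            pr <- predict_classifier(mdl, Xva[, sel, drop = FALSE])
            mean(pr != y[!tr])
          }
          err_by_mask[[key]] <- err[f, li]
        }
      }
    }
  }
  cv_err <- colMeans(err)
  # path descends, so the first qualifying index is the largest (sparsest)
  # lambda; the one-standard-error rule takes the sparsest model whose CV
  # error is within one SE of the minimum
  band <- if (rule == "1se") {
    i0 <- which.min(cv_err)
    min(cv_err) + stats::sd(err[, i0]) / sqrt(n_folds)
  } else min(cv_err) + 1e-12
  best <- which(cv_err <= band)[1]
  list(lambda = lambda_path[best], lambda_path = lambda_path, cv_error = cv_err)
}

#' Reduce a feature table to the AS-LASSO-selected columns
#'
#' Keeps the columns with non-zero coefficients. If the fit is entirely
#' sparse (all-zero beta), falls back to the `fallback_k` columns with the
#' largest importance `s_i * e_i` (or smallest penalty weight when s/e are
#' not stored) and flags the fallback.
#'
#' @param fit an `aslasso_fit`.
#' @param ft the `feature_table` the fit was computed on.
#' @param fallback_k number of columns to keep if nothing was selected.
#' @return list with `ft` (reduced feature_table, meta preserved), `mask`
#'   (logical p-vector) and `fallback` flag.
#' @export
select_features <- function(fit, ft, fallback_k = 4L) {
  stopifnot(inherits(fit, "aslasso_fit"), inherits(ft, "feature_table"))
  p <- ncol(ft$X)
  mask <- fit$selected
  fallback <- FALSE
  if (!any(mask)) {
    fallback <- TRUE
    score <- if (!is.null(fit$s) && !is.null(fit$e)) fit$s * fit$e else -fit$w
    keep <- order(score, decreasing = TRUE)[seq_len(min(fallback_k, p))]
    mask <- logical(p)
    mask[keep] <- TRUE
    message(sprintf("all-zero AS-LASSO solution: falling back to top %d features by s*e",
                    sum(mask)))
  }
  red <- structure(list(X = ft$X[, mask, drop = FALSE], labels = ft$labels,
                        meta = ft$meta[mask, , drop = FALSE]),
                   class = "feature_table")
  list(ft = red, mask = mask, fallback = fallback)
}
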