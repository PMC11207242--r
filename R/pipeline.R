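#' Pipeline configuration
#'
#' Aggregates every tunable of the model in one validated object.
#'
#' Selection variants (`selection`):
#' \describe{
#'   \item{`"aslasso"`}{weights `exp(-mu * s_i * e_i)` — the full model.}
#'   \item{`"su"`}{symmetric-uncertainty-only weights `exp(-mu * s_i)`.}
#'   \item{`"spatial"`}{spatial-information-only weights `exp(-mu * e_i)`.}
#'   \item{`"lasso"`}{unit weights (plain LASSO).}
#'   \item{`"alasso"`}{classical adaptive LASSO, `w = 1/|beta_ols|^gamma`
#'     normalized into (0, 1].}
#'   \item{`"none"`}{no selection; all features go to the classifier.}
#' }
#'
#' @param bank `"default"`, `"fbcsp"`, `"single"`, a list of band pairs or a
#'   [filter_bank()].
#' @param n_filters_per_band CSP filters kept per band (default 2, the two
#'   largest-eigenvalue filters).
#' @param csp_mode `"largest"` or `"paired"` (see [fit_csp()]).
#' @param shrinkage_eps CSP covariance shrinkage (default 1e-6).
#' @param n_bins symmetric-uncertainty bins; `NULL` = sqrt rule.
#' @param mu penalty-weight adjustment parameter (default 1).
#' @param weight_form `"exponent"` or `"mixed"` (see [penalty_weights()]).
#' @param selection one of the variants above.
#' @param lambda fixed penalty, or `NULL` (default) for inner-CV selection.
#' @param lambda_criterion `"class"` or `"mse"` (see [cv_lambda()]).
#' @param n_lambda,lambda_min_ratio,inner_folds inner-CV path controls.
#' @param alasso_gamma exponent of the adaptive-LASSO weights (default 1).
#' @param fallback_k columns kept when the solution is all-zero (default 4).
#' @param classifier `"svm"`, `"knn"`, `"lda"`, `"rf"`, `"dt"`.
#' @param classifier_settings named list forwarded to [fit_classifier()].
#' @param cv_folds outer folds for [crossval()] (default 5).
#' @param target_sfreq,window optional preprocessing applied before the bank.
#' @return object of class `fsff_config`.
#' @export
fsff_config <- function(bank = "default", n_filters_per_band = 2L,
                        csp_mode = "paired", shrinkage_eps = 1e-6,
                        n_bins = NULL, mu = 1, weight_form = "exponent",
                        selection = "aslasso", lambda = NULL,
                        lambda_criterion = "class", n_lambda = 50L,
                        lambda_min_ratio = 1e-3, inner_folds = 5L,
                        alasso_gamma = 1, fallback_k = 4L,
                        classifier = "svm", classifier_settings = list(),
                        cv_folds = 5L, target_sfreq = NULL, window = NULL) {
  cfg <- structure(as.list(environment()), class = "fsff_config")
  validate_config(cfg)
}

validate_config <- function(cfg) {
  stopifnot(inherits(cfg, "fsff_config"))
  bad <- character()
  if (!(is.character(cfg$bank) || is.list(cfg$bank) ||
        inherits(cfg$bank, "filter_bank"))) bad <- c(bad, "bank")
  if (!cfg$csp_mode %in% c("largest", "paired")) bad <- c(bad, "csp_mode")
  if (!cfg$selection %in% c("aslasso", "su", "spatial", "lasso", "alasso", "none"))
    bad <- c(bad, "selection")
  if (!cfg$weight_form %in% c("exponent", "mixed")) bad <- c(bad, "weight_form")
  if (!cfg$lambda_criterion %in% c("class", "mse")) bad <- c(bad, "lambda_criterion")
  if (!cfg$classifier %in% c("svm", "knn", "lda", "rf", "dt"))
    bad <- c(bad, "classifier")
  if (cfg$mu < 0) bad <- c(bad, "mu")
  if (cfg$cv_folds < 2) bad <- c(bad, "cv_folds")
  if (length(bad))
    stop(sprintf("invalid config key(s): %s", paste(bad, collapse = ", ")))
  cfg$bank <- resolve_bank(cfg$bank)
  cfg
}

# Selection-variant penalty weights on the training features.
selection_weights <- function(cfg, ft, s, e) {
  switch(cfg$selection,
    aslasso = penalty_weights(s, e, mu = cfg$mu, form = cfg$weight_form),
    su = pmax(exp(-cfg$mu * s), 1e-8),
    spatial = pmax(exp(-cfg$mu * e), 1e-8),
    lasso = rep(1, ncol(ft$X)),
    alasso = {
      std <- standardize_columns(ft$X)
      yc <- ft$labels - mean(ft$labels)
      # ridge-stabilized least squares initial estimator
      XtX <- crossprod(std$X) + 1e-8 * diag(ncol(std$X))
      b_ols <- solve(XtX, crossprod(std$X, yc))
      w <- 1 / pmax(abs(b_ols), 1e-4)^cfg$alasso_gamma
      pmax(w / max(w), 1e-8)    # normalized into (0, 1]
    },
    stop("selection variant has no weights"))
}

# Fit the full feature-extraction + selection + classification stack on
# band-filtered training epochs. Everything fitted here is training-only.
fit_fsff <- function(bank_epochs, config) {
  y <- bank_epochs[[1]]$epochs$labels
  check_two_classes(y)
  models <- fit_csp_bank(bank_epochs,
                         n_filters_per_band = config$n_filters_per_band,
                         mode = config$csp_mode,
                         shrinkage_eps = config$shrinkage_eps)
  ft <- csp_features(models, bank_epochs)
  p <- ncol(ft$X)
  fit <- NULL; lambda <- NULL
  if (config$selection == "none") {
    mask <- rep(TRUE, p)
    sel_ft <- ft
    fallback <- FALSE
  } else {
    s <- relevance_vector(ft, n_bins = config$n_bins)$s
    e <- spatial_info(models)
    w <- selection_weights(config, ft, s, e)
    lambda <- config$lambda
    if (is.null(lambda))
      lambda <- cv_lambda(ft$X, y, w, n_folds = config$inner_folds,
                          n_lambda = config$n_lambda,
                          lambda_min_ratio = config$lambda_min_ratio,
                          criterion = config$lambda_criterion,
                          classifier = config$classifier)$lambda
    fit <- fit_aslasso(ft, w, lambda, s = s, e = e, mu = config$mu)
    sel <- select_features(fit, ft, fallback_k = config$fallback_k)
    mask <- sel$mask; sel_ft <- sel$ft; fallback <- sel$fallback
  }
  std <- standardize_columns(sel_ft$X)
  clf <- fit_classifier(std$X, y, name = config$classifier,
                        settings = config$classifier_settings)
  structure(list(csp = models, mask = mask, lambda = lambda,
                 aslasso = fit, fallback = fallback,
                 feature_meta = ft$meta,
                 scaler = list(center = std$center, scale = std$scale),
                 classifier = clf, config = config),
            class = "fsff_model")
}

predict_fsff <- function(model, bank_epochs) {
  ft <- csp_features(model$csp, bank_epochs)
  X <- ft$X[, model$mask, drop = FALSE]
  X <- sweep(sweep(X, 2, model$scaler$center), 2, model$scaler$scale, "/")
  predict_classifier(model$classifier, X)
}

#' Fit the FSFF model on a full epoch set
#'
#' Preprocesses (if the config asks for it), applies the filter bank, fits
#' per-band CSP, computes relevance and spatial information, selects features
#' with AS-LASSO (or a configured variant) and trains the classifier.
#'
#' @param e an [epoch_set()].
#' @param config an [fsff_config()].
#' @param seed seed for the inner-CV fold split and any stochastic
#'   classifier.
#' @return an `fsff_model`.
#' @export
fit_pipeline <- function(e, config = fsff_config(), seed = 1L) {
  stopifnot(inherits(e, "epoch_set"))
  config <- validate_config(config)
  set.seed(seed)
  if (!is.null(config$target_sfreq) || !is.null(config$window))
    e <- preprocess_epochs(e, config$target_sfreq, config$window)
  fit_fsff(apply_bank(e, config$bank), config)
}

#' Predict labels for new epochs with a fitted model
#'
#' @param model an `fsff_model` from [fit_pipeline()].
#' @param e an [epoch_set()] with the same channel count (labels, if present,
#'   are ignored).
#' @return numeric labels in {-1, +1}, one per trial.
#' @export
predict_pipeline <- function(model, e) {
  stopifnot(inherits(model, "fsff_model"), inherits(e, "epoch_set"))
  cfg <- model$config
  if (!is.null(cfg$target_sfreq) || !is.null(cfg$window))
    e <- preprocess_epochs(e, cfg$target_sfreq, cfg$window)
  predict_fsff(model, apply_bank(e, cfg$bank))
}

#' @export
print.fsff_model <- function(x, ...) {
  cat(sprintf("fsff_model: %d bands, %d/%d features selected, classifier %s\n",
              length(x$csp), sum(x$mask), length(x$mask),
              x$config$classifier))
  invisible(x)
}

#' Ablation grid: bank strategies x selection variants
#'
#' Runs [crossval()] for every combination of the requested bank presets and
#' selection variants, mirroring the classic ablation layout (single-band
#' CSP, non-overlapping FBCSP bank, overlapping multi-scale bank, each with
#' no selection / LASSO / adaptive LASSO / SU-only / spatial-only /
#' AS-LASSO).
#'
#' @param e an [epoch_set()].
#' @param config base [fsff_config()]; `bank` and `selection` are overridden
#'   by the grid.
#' @param seed seed forwarded to every [crossval()] run.
#' @param banks character vector of bank presets.
#' @param selections character vector of selection variants.
#' @return data.frame with one row per combination (mean/sd of each metric)
#'   and the full `cv_report`s in `attr(, "reports")`.
#' @export
ablate <- function(e, config = fsff_config(), seed = 1L,
                   banks = c("single", "fbcsp", "default"),
                   selections = c("none", "lasso", "alasso", "su", "spatial",
                                  "aslasso")) {
  rows <- list(); reports <- list()
  for (b in banks) for (sel in selections) {
    cfg <- config
    cfg$bank <- b
    cfg$selection <- sel
    rep <- crossval(e, cfg, seed = seed)
    key <- paste(b, sel, sep = "/")
    reports[[key]] <- rep
    rows[[key]] <- data.frame(bank = b, selection = sel,
                              accuracy = rep$mean["accuracy"],
                              f1 = rep$mean["f1"],
                              precision = rep$mean["precision"],
                              accuracy_sd = rep$sd["accuracy"])
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "reports") <- reports
  out
}

# Deterministic content hash of any R object (serialized stream, md5).
hash_object <- function(x) {
  f <- tempfile()
  on.exit(unlink(f))
  writeBin(serialize(x, NULL, version = 2), f)
  unname(tools::md5sum(f))
}

config_snapshot <- function(config, e) {
  cfg <- unclass(config)
  cfg$bank <- lapply(cfg$bank$bands, as.numeric)
  cfg$classifier_settings <- NULL
  cfg$input_hash <- hash_object(list(e$data, e$labels, e$sfreq))
  cfg
}
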