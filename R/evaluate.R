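#' Confusion counts for two-class predictions
#'
#' Class +1 is the positive class.
#'
#' @param truth,pred label vectors in {-1, +1}.
#' @return object of class `confusion_counts` with fields tp, tn, fp, fn.
#' @export
confusion_counts <- function(truth, pred) {
  stopifnot(length(truth) == length(pred))
  structure(list(tp = sum(truth == 1 & pred == 1),
                 tn = sum(truth == -1 & pred == -1),
                 fp = sum(truth == -1 & pred == 1),
                 fn = sum(truth == 1 & pred == -1)),
            class = "confusion_counts")
}

#' Accuracy, F1-score and precision from confusion counts
#'
#' `accuracy = (TP + TN) / (TP + TN + FP + FN)`,
#' `F1 = 2 TP / (2 TP + FP + FN)`, `precision = TP / (TP + FP)`.
#' When `TP + FP = 0` precision is reported as 0 with a warning (and F1 is 0
#' whenever TP = 0 with positives present).
#'
#' @param cc a `confusion_counts`.
#' @return named numeric vector `c(accuracy, f1, precision)` in [0, 1].
#' @export
classification_metrics <- function(cc) {
  stopifnot(inherits(cc, "confusion_counts"))
  total <- cc$tp + cc$tn + cc$fp + cc$fn
  if (total == 0) stop("empty confusion counts")
  acc <- (cc$tp + cc$tn) / total
  f1 <- if (2 * cc$tp + cc$fp + cc$fn == 0) {
    warning("no positives in truth or prediction; F1 reported as 0")
    0
  } else 2 * cc$tp / (2 * cc$tp + cc$fp + cc$fn)
  prec <- if (cc$tp + cc$fp == 0) {
    warning("no positive predictions; precision reported as 0")
    0
  } else cc$tp / (cc$tp + cc$fp)
  c(accuracy = acc, f1 = f1, precision = prec)
}

# Stratified fold assignment: within each class, shuffle and deal folds
# round-robin. Draws from the current RNG stream.
stratified_folds <- function(y, k) {
  fold <- integer(length(y))
  for (cl in unique(y)) {
    idx <- which(y == cl)
    if (length(idx) < k)
      stop(sprintf("class %s has %d trials; need at least %d for %d folds",
                   cl, length(idx), k, k))
    fold[sample(idx)] <- rep_len(seq_len(k), length(idx))
  }
  fold
}

#' Five-fold cross-validated evaluation of the full pipeline
#'
#' Stratified random k-fold split (seeded). Band-pass filtering is a
#' per-trial operation, so the bank is applied once to all trials; every
#' cross-trial fitted quantity (CSP filters, symmetric-uncertainty bins,
#' penalty weights, lambda, feature scaling, the classifier) is derived from
#' the four training subsets only and then applied to the held-out subset.
#'
#' @param e an [epoch_set()].
#' @param config an [fsff_config()].
#' @param seed integer seed controlling the fold split and any stochastic
#'   classifier.
#' @return object of class `cv_report`: per-fold metrics, mean and sd,
#'   per-fold selection masks and lambdas, feature metadata, seed and config
#'   snapshot with input content hash.
#' @export
crossval <- function(e, config = fsff_config(), seed = 1L) {
  stopifnot(inherits(e, "epoch_set"))
  config <- validate_config(config)
  set.seed(seed)
  if (!is.null(config$target_sfreq) || !is.null(config$window))
    e <- preprocess_epochs(e, config$target_sfreq, config$window)
  bank <- resolve_bank(config$bank)
  bank_epochs <- apply_bank(e, bank)
  y <- e$labels
  folds <- stratified_folds(y, config$cv_folds)
  per_fold <- vector("list", config$cv_folds)
  masks <- list(); lambdas <- numeric(config$cv_folds); meta <- NULL
  for (f in seq_len(config$cv_folds)) {
    tr <- folds != f
    if (length(unique(y[!tr])) < 2L || length(unique(y[tr])) < 2L)
      stop(sprintf("fold %d lost a class during stratification", f))
    be_tr <- subset_bank(bank_epochs, tr)
    be_te <- subset_bank(bank_epochs, !tr)
    model <- fit_fsff(be_tr, config)
    pred <- predict_fsff(model, be_te)
    cc <- confusion_counts(y[!tr], pred)
    per_fold[[f]] <- classification_metrics(cc)
    masks[[f]] <- model$mask
    lambdas[f] <- model$lambda %||% NA_real_
    meta <- model$feature_meta
  }
  pf <- do.call(rbind, per_fold)
  structure(list(
    per_fold = data.frame(fold = seq_len(config$cv_folds), pf),
    mean = colMeans(pf), sd = apply(pf, 2, stats::sd),
    masks = do.call(rbind, masks), lambdas = lambdas,
    feature_meta = meta, seed = seed,
    config = config_snapshot(config, e)),
    class = "cv_report")
}

subset_bank <- function(bank_epochs, idx) {
  lapply(bank_epochs, function(be) {
    ep <- be$epochs
    ep$data <- ep$data[idx, , , drop = FALSE]
    ep$labels <- ep$labels[idx]
    list(band = be$band, epochs = ep)
  })
}

#' @export
print.cv_report <- function(x, ...) {
  cat(sprintf("cv_report (%d folds, seed %d)\n", nrow(x$per_fold), x$seed))
  for (m in c("accuracy", "f1", "precision"))
    cat(sprintf("  %-9s %.2f%% +/- %.2f%%\n", m, 100 * x$mean[m], 100 * x$sd[m]))
  invisible(x)
}

#' Per-band selected-feature counts from a cv_report
#'
#' Summarizes how often each frequency band contributed selected features
#' across folds — the selection-visualization companion to [crossval()].
#'
#' @param report a `cv_report`.
#' @return data.frame with band, band_low, band_high, n_selected (summed over
#'   folds).
#' @export
selection_by_band <- function(report) {
  stopifnot(inherits(report, "cv_report"))
  counts <- colSums(report$masks)
  agg <- stats::aggregate(counts,
                          by = list(band = report$feature_meta$band,
                                    band_low = report$feature_meta$band_low,
                                    band_high = report$feature_meta$band_high),
                          FUN = sum)
  names(agg)[4] <- "n_selected"
  agg[order(agg$band_low, agg$band_high), ]
}

#' Write a cv_report as stable JSON plus CSV companions
#'
#' `report.json` (byte-stable for identical config + seed), `folds.csv`
#' (per-fold metrics) and `selection_by_band.csv`.
#'
#' @param report a `cv_report`.
#' @param dir output directory (created).
#' @return `dir`, invisibly.
#' @export
write_cv_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  out <- list(seed = report$seed,
              mean = as.list(report$mean), sd = as.list(report$sd),
              per_fold = report$per_fold,
              lambdas = report$lambdas,
              config = report$config)
  jsonlite::write_json(out, file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  utils::write.csv(report$per_fold, file.path(dir, "folds.csv"),
                   row.names = FALSE)
  utils::write.csv(selection_by_band(report),
                   file.path(dir, "selection_by_band.csv"), row.names = FALSE)
  invisible(dir)
}
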