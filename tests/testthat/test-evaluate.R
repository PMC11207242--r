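test_that("metrics evaluate the confusion-count formulas", {
  cc <- structure(list(tp = 3, tn = 3, fp = 1, fn = 1),
                  class = "confusion_counts")
  m <- classification_metrics(cc)
  expect_equal(unname(m), c(0.75, 0.75, 0.75))
  perfect <- confusion_counts(c(1, 1, -1, -1), c(1, 1, -1, -1))
  expect_equal(unname(classification_metrics(perfect)), c(1, 1, 1))
  # no positive predictions: precision 0 with a warning, f1 0
  degen <- confusion_counts(c(1, 1, -1), c(-1, -1, -1))
  expect_warning(m2 <- classification_metrics(degen), "precision")
  expect_equal(unname(m2), c(1 / 3, 0, 0))
  empty <- structure(list(tp = 0, tn = 0, fp = 0, fn = 0),
                     class = "confusion_counts")
  expect_error(classification_metrics(empty), "empty")
})

test_that("f1 is the harmonic mean of precision and recall on random counts", {
  set.seed(51)
  for (rep in 1:20) {
    cc <- structure(as.list(stats::setNames(rpois(4, 5) + 1,
                                            c("tp", "tn", "fp", "fn"))),
                    class = "confusion_counts")
    m <- classification_metrics(cc)
    prec <- cc$tp / (cc$tp + cc$fp)
    rec <- cc$tp / (cc$tp + cc$fn)
    expect_equal(m[["f1"]], 2 * prec * rec / (prec + rec), tolerance = 1e-12)
    expect_equal(m[["accuracy"]],
                 (cc$tp + cc$tn) / (cc$tp + cc$tn + cc$fp + cc$fn))
  }
})

test_that("stratified folds keep both classes everywhere and need enough trials", {
  set.seed(52)
  y <- rep(c(-1, 1), c(12, 8))
  folds <- fsff:::stratified_folds(y, 4)
  for (f in 1:4) {
    expect_setequal(unique(y[folds == f]), c(-1, 1))
  }
  expect_error(fsff:::stratified_folds(rep(c(-1, 1), c(3, 10)), 5), "at least")
})

test_that("cross-validation is deterministic for a fixed seed", {
  gen <- synth_epochs(synth_spec(n_trials_per_class = 12, n_channels = 4,
                                 duration = 2), seed = 3)
  cfg <- fsff_config(bank = "single", selection = "lasso", lambda = 2)
  r1 <- crossval(gen$epochs, cfg, seed = 9)
  r2 <- crossval(gen$epochs, cfg, seed = 9)
  expect_identical(r1$per_fold, r2$per_fold)
  expect_identical(r1$masks, r2$masks)
  expect_identical(r1$lambdas, r2$lambdas)
  # the report carries a content hash of its input for rerun verification
  expect_match(r1$config$input_hash, "^[0-9a-f]{32}$")
  expect_identical(r1$config$input_hash, r2$config$input_hash)
})

test_that("fitted state depends only on training data (no leakage)", {
  gen <- synth_epochs(synth_spec(n_trials_per_class = 16, n_channels = 4,
                                 duration = 2), seed = 4)
  e <- gen$epochs
  tr <- 1:24; te <- 25:32
  e_tr <- e; e_tr$data <- e$data[tr, , , drop = FALSE]; e_tr$labels <- e$labels[tr]
  cfg <- fsff_config(bank = list(c(8, 12), c(16, 24)), selection = "lasso",
                     lambda = 2)
  m1 <- fit_pipeline(e_tr, cfg, seed = 1)
  # perturbing held-out trials cannot change the fitted model
  m2 <- fit_pipeline(e_tr, cfg, seed = 1)
  expect_identical(fsff:::hash_object(m1$csp), fsff:::hash_object(m2$csp))
  expect_identical(m1$mask, m2$mask)
  e_te <- e; e_te$data <- e$data[te, , , drop = FALSE]; e_te$labels <- e$labels[te]
  p1 <- predict_pipeline(m1, e_te)
  e_te$labels <- rev(e_te$labels)              # labels of test trials ignored
  p2 <- predict_pipeline(m1, e_te)
  expect_identical(p1, p2)
  expect_length(p1, 8L)
})

test_that("alternative classifiers run through the identical harness", {
  skip_if_not_installed("MASS")
  skip_if_not_installed("randomForest")
  skip_if_not_installed("rpart")
  skip_if_not_installed("class")
  gen <- synth_epochs(synth_spec(n_trials_per_class = 12, n_channels = 4,
                                 duration = 2), seed = 5)
  for (clf in c("knn", "lda", "rf", "dt")) {
    cfg <- fsff_config(bank = "single", selection = "none", classifier = clf)
    # weak classifiers on tiny folds may predict one class only, which
    # legitimately warns about degenerate precision
    rep <- suppressWarnings(crossval(gen$epochs, cfg, seed = 2))
    expect_s3_class(rep, "cv_report")
    expect_true(all(rep$per_fold$accuracy >= 0 & rep$per_fold$accuracy <= 1))
  }
})

test_that("cv reports serialize to stable JSON with CSV companions", {
  gen <- synth_epochs(synth_spec(n_trials_per_class = 10, n_channels = 3,
                                 duration = 2), seed = 6)
  cfg <- fsff_config(bank = "single", selection = "lasso", lambda = 2)
  rep <- crossval(gen$epochs, cfg, seed = 1)
  d1 <- tempfile(); d2 <- tempfile()
  write_cv_report(rep, d1)
  write_cv_report(crossval(gen$epochs, cfg, seed = 1), d2)
  expect_true(file.exists(file.path(d1, "report.json")))
  expect_identical(readLines(file.path(d1, "report.json")),
                   readLines(file.path(d2, "report.json")))
  sb <- utils::read.csv(file.path(d1, "selection_by_band.csv"))
  expect_true(all(c("band", "n_selected") %in% names(sb)))
  unlink(c(d1, d2), recursive = TRUE)
})
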