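#' Fit a two-class classifier on selected features
#'
#' Thin dispatch over the field's standard classifiers. The default is an
#' RBF-kernel SVM with C = 1 and kernel bandwidth `gamma = 1 / (p * var(X))`
#' (the inverse of feature count times overall feature variance); a linear
#' kernel is available via `settings$kernel`. Alternates: `knn` (k = 5),
#' `lda`, `rf` (random forest, 200 trees), `dt` (CART decision tree).
#'
#' @param X n x p numeric feature matrix (already scaled by the caller).
#' @param y labels in {-1, +1}.
#' @param name one of `"svm"`, `"knn"`, `"lda"`, `"rf"`, `"dt"`.
#' @param settings named list of overrides (e.g. `kernel`, `cost`, `k`,
#'   `ntree`).
#' @return a `fsff_classifier` object for [predict_classifier()].
#' @export
fit_classifier <- function(X, y, name = "svm", settings = list()) {
  X <- as.matrix(X)
  yf <- factor(y, levels = c(-1, 1))
  fit <- switch(name,
    svm = {
      v <- stats::var(as.vector(X))
      gamma <- if (is.finite(v) && v > 0) 1 / (ncol(X) * v) else 1 / ncol(X)
      e1071::svm(x = X, y = yf,
                 kernel = settings$kernel %||% "radial",
                 cost = settings$cost %||% 1,
                 gamma = settings$gamma %||% gamma,
                 scale = FALSE)
    },
    knn = list(X = X, y = yf, k = settings$k %||% 5L),
    lda = {
      requireNamespace("MASS")
      MASS::lda(X, grouping = yf)
    },
    rf = {
      requireNamespace("randomForest")
      randomForest::randomForest(X, yf, ntree = settings$ntree %||% 200L)
    },
    dt = {
      requireNamespace("rpart")
      df <- data.frame(.y = yf, X)
      rpart::rpart(.y ~ ., data = df, method = "class")
    },
    stop(sprintf("unknown classifier '%s'", name)))
  structure(list(name = name, fit = fit, p = ncol(X)), class = "fsff_classifier")
}

#' Predict labels from a fitted classifier
#' @param model a `fsff_classifier`.
#' @param X feature matrix with the same columns the model was fitted on.
#' @return numeric labels in {-1, +1}.
#' @export
predict_classifier <- function(model, X) {
  X <- as.matrix(X)
  if (ncol(X) != model$p)
    stop(sprintf("expected %d feature columns, got %d", model$p, ncol(X)))
  pred <- switch(model$name,
    svm = stats::predict(model$fit, X),
    knn = {
      requireNamespace("class")
      class::knn(model$fit$X, X, model$fit$y, k = model$fit$k)
    },
    lda = stats::predict(model$fit, X)$class,
    rf = stats::predict(model$fit, X),
    dt = stats::predict(model$fit, data.frame(X, check.names = TRUE),
                        type = "class"))
  as.numeric(as.character(pred))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
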