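test_that("penalty weights follow the exponential fusion form", {
  expect_equal(penalty_weights(c(0, 0.5, 1), c(0.3, 0.2, 0.1), mu = 0),
               rep(1, 3))                       # mu = 0 -> plain LASSO
  expect_equal(penalty_weights(1, 0.5, mu = 2), exp(-1))
  expect_equal(penalty_weights(0, 0.9, mu = 50), 1)  # irrelevant feature
  # strictly decreasing in s * e
  s <- seq(0, 1, by = 0.1)
  w <- penalty_weights(s, rep(0.4, 11), mu = 2)
  expect_true(all(diff(w) < 0))
  # numerical floor
  expect_equal(penalty_weights(1, 50, mu = 10), 1e-8)
  expect_error(penalty_weights(c(-0.1), c(0.1), 1), "\\[0, 1\\]")
  expect_error(penalty_weights(c(0.5), c(-0.1), 1), "non-negative")
  expect_error(penalty_weights(0.5, 0.5, -1), "non-negative")
})

test_that("lambda at or above lambda_max kills every coefficient", {
  set.seed(41)
  inst <- rand_lasso_instance(41)
  Xs <- scale(inst$X); Xs <- matrix(as.numeric(Xs), nrow(inst$X))
  yc <- inst$y - mean(inst$y)
  lmax <- max(abs(2 * crossprod(sweep(Xs, 2, inst$w, "/"), yc)))
  fit <- fit_aslasso(Xs, inst$w, lmax * 1.0001, y = inst$y)
  expect_true(all(fit$beta == 0))
  expect_false(any(fit$selected))
})

test_that("orthonormal designs reproduce the soft-threshold closed form", {
  # X'X = I and unit weights: beta_j = sign(ols_j) max(0, |ols_j| - lambda/2)
  set.seed(42)
  X <- qr.Q(qr(matrix(rnorm(30 * 2), 30, 2)))
  ols <- c(3, 1)
  y <- as.numeric(X %*% ols)                    # exact OLS solution (3, 1)
  sol <- cd_lasso(X, y, lambda = 2)             # threshold = 1
  expect_equal(sol$beta, c(2, 0), tolerance = 1e-10)
})

test_that("the rescaling reduction matches an independent solver and its KKT conditions", {
  skip_if_not_installed("glmnet")
  for (seed in 1:8) {
    inst <- rand_lasso_instance(seed)
    Xw <- sweep(inst$X, 2, inst$w, "/")
    beta <- cd_lasso(Xw, inst$y, inst$lambda)$beta / inst$w
    expect_lte(kkt_violation(inst$X, inst$y, beta, inst$w, inst$lambda), 1e-6)
    expect_equal(beta, glmnet_ref(inst$X, inst$y, inst$w, inst$lambda),
                 tolerance = 1e-6)
  }
})

test_that("the weighted objective at beta* equals the rescaled LASSO objective at beta**", {
  set.seed(44)
  inst <- rand_lasso_instance(44)
  Xs <- matrix(as.numeric(scale(inst$X)), nrow(inst$X))
  yc <- inst$y - mean(inst$y)
  fit <- fit_aslasso(Xs, inst$w, inst$lambda, y = inst$y)
  Xw <- sweep(Xs, 2, inst$w, "/")
  bstar2 <- fit$beta * inst$w
  obj_rescaled <- sum((yc - Xw %*% bstar2)^2) + inst$lambda * sum(abs(bstar2))
  expect_equal(fit$objective, obj_rescaled, tolerance = 1e-8)
})

test_that("sparsity is non-increasing along a descending lambda path", {
  set.seed(45)
  g <- synth_feature_table(n = 60, p = 20, seed = 45)
  Xs <- matrix(as.numeric(scale(g$ft$X)), 60)
  yc <- g$ft$labels - mean(g$ft$labels)
  w <- penalty_weights(g$s, g$e, mu = 1)
  Xw <- sweep(Xs, 2, w, "/")
  lmax <- max(abs(2 * crossprod(Xw, yc)))
  path <- exp(seq(log(lmax), log(lmax * 1e-3), length.out = 30))
  n_active <- sapply(path, function(l) sum(cd_lasso(Xw, yc, l)$beta != 0))
  # monotone up to solver-level ties: allow no decrease when lambda shrinks
  expect_true(all(diff(n_active) >= 0))
})

test_that("feature masks and the all-zero fallback behave per contract", {
  g <- synth_feature_table(n = 40, p = 6, n_informative = 2, seed = 46)
  w <- penalty_weights(g$s, g$e, mu = 1)
  fit <- fit_aslasso(g$ft, w, lambda = 1, s = g$s, e = g$e)
  fit$beta <- c(0, 1.2, 0, -0.3, 0, 0)
  fit$selected <- fit$beta != 0
  sel <- select_features(fit, g$ft)
  expect_identical(which(sel$mask), c(2L, 4L))
  expect_false(sel$fallback)
  expect_equal(nrow(sel$ft$meta), 2L)
  # all-zero solution falls back to the top-k features by s * e
  big <- fit_aslasso(g$ft, w, lambda = 1e6, s = g$s, e = g$e)
  expect_false(any(big$selected))
  sel2 <- suppressMessages(select_features(big, g$ft, fallback_k = 4))
  expect_true(sel2$fallback)
  expect_equal(sum(sel2$mask), 4L)
  expect_length(sel2$mask, 6L)
})

test_that("inner-CV lambda selection returns a path value and is seeded", {
  g <- synth_feature_table(n = 60, p = 12, seed = 47)
  w <- penalty_weights(g$s, g$e, mu = 1)
  set.seed(1); cv1 <- cv_lambda(g$ft$X, g$ft$labels, w, n_lambda = 20)
  set.seed(1); cv2 <- cv_lambda(g$ft$X, g$ft$labels, w, n_lambda = 20)
  expect_identical(cv1$lambda, cv2$lambda)
  expect_true(cv1$lambda %in% cv1$lambda_path)
  expect_length(cv1$cv_error, 20)
  # the 1se rule never picks a denser model than the error minimizer
  set.seed(1)
  cvm <- cv_lambda(g$ft$X, g$ft$labels, w, n_lambda = 20, rule = "min")
  expect_gte(cv1$lambda, cvm$lambda)
})

test_that("degenerate penalty and weight inputs are rejected", {
  g <- synth_feature_table(n = 30, p = 4, seed = 48)
  expect_error(fit_aslasso(g$ft, rep(1, 4), -0.5), "non-negative")
  expect_error(fit_aslasso(g$ft, rep(2, 4), 1), "\\(0, 1\\]")
  expect_error(fit_aslasso(g$ft, rep(1, 3), 1), "feature count")
})
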