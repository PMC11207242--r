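# two-channel closed-form family: trace-normalized class covariances
toy_covs <- function(r) list(C1 = diag(c(r, 1)) / (r + 1),
                             C2 = diag(c(1, r)) / (r + 1))

test_that("the diag(4,1)/diag(1,4) toy has the closed-form spectrum", {
  tc <- toy_covs(4)
  m <- csp_from_covariances(tc$C1, tc$C2)
  expect_equal(m$eigenvalues, c(0.8, 0.2), tolerance = 1e-12)
  # spatial information: |lambda - mean(spectrum)| with mean 0.5
  expect_equal(spatial_info(list(m)), c(0.3, 0.3), tolerance = 1e-12)
})

test_that("paired class eigenvalues sum to one", {
  set.seed(5)
  for (rep in 1:10) {
    p <- sample(3:7, 1)
    C1 <- rand_spd(p); C2 <- rand_spd(p)
    m1 <- csp_from_covariances(C1, C2, n_filters_per_band = 2)
    m2 <- csp_from_covariances(C2, C1, n_filters_per_band = 2)
    # the k-th largest eigenvalue of whitened C1 pairs with the k-th
    # smallest of whitened C2
    expect_equal(m1$eigenvalues + rev(m2$eigenvalues), rep(1, p),
                 tolerance = 1e-9)
  }
})

test_that("filters jointly diagonalize the composite covariance to identity", {
  set.seed(6)
  C1 <- rand_spd(5); C2 <- rand_spd(5)
  m <- csp_from_covariances(C1, C2)
  expect_equal(m$filters %*% (C1 + C2) %*% t(m$filters), diag(5),
               tolerance = 1e-6, ignore_attr = TRUE)
})

test_that("eigenvalues match a generalized-eigenproblem oracle on random SPD pairs", {
  set.seed(7)
  for (rep in 1:20) {
    p <- sample(2:8, 1)
    C1 <- rand_spd(p); C2 <- rand_spd(p)
    m <- csp_from_covariances(C1, C2)
    # oracle: eigenvalues of solve(C1 + C2, C1)
    lam_ref <- sort(Re(eigen(solve(C1 + C2, C1))$values), decreasing = TRUE)
    expect_equal(m$eigenvalues, lam_ref, tolerance = 1e-8)
    # filters solve the generalized eigenproblem C1 w = lambda (C1+C2) w
    for (k in seq_len(p)) {
      w <- m$filters[k, ]
      resid <- C1 %*% w - m$eigenvalues[k] * (C1 + C2) %*% w
      expect_lt(max(abs(resid)) / max(abs(w)), 1e-8)
    }
  }
})

test_that("a larger class variance ratio raises the top eigenvalue", {
  tops <- sapply(c(1, 2, 4, 8, 16), function(r) {
    tc <- toy_covs(r)
    csp_from_covariances(tc$C1, tc$C2)$eigenvalues[1]
  })
  expect_equal(tops, c(1, 2, 4, 8, 16) / (c(1, 2, 4, 8, 16) + 1),
               tolerance = 1e-12)
  expect_true(all(diff(tops) > 0))
})

test_that("classes with identical covariance structure give a flat spectrum", {
  set.seed(8)
  e <- noise_epochs(n_trials = 200, n_channels = 3, ns = 400)
  m <- fit_csp(e)
  expect_true(all(abs(m$eigenvalues - 0.5) < 0.08))
  # flat-spectrum spatial information is near zero
  expect_true(all(spatial_info(list(m)) < 0.08))
})

test_that("fit_csp honors selection modes and rejects degenerate input", {
  set.seed(9)
  e <- noise_epochs(n_trials = 20, n_channels = 4, ns = 200)
  expect_identical(fit_csp(e, 2, mode = "largest")$selected, 1:2)
  expect_identical(fit_csp(e, 2, mode = "paired")$selected, c(1L, 4L))
  one_class <- e; one_class$labels <- rep(1, 20)
  expect_error(fit_csp(one_class), "both classes")
  expect_error(fit_csp(e, n_filters_per_band = 9), "channel count")
})

test_that("log-variance features evaluate exactly on projected variances 9:1", {
  set.seed(10)
  z <- rnorm(300)
  arr <- array(0, c(2, 2, 300))
  arr[1, 1, ] <- 3 * z; arr[1, 2, ] <- z       # projected variances 9v, v
  arr[2, 1, ] <- 3 * z; arr[2, 2, ] <- z
  e <- epoch_set(arr, c(-1, 1), 100)
  m <- structure(list(filters = diag(2), eigenvalues = c(0.9, 0.1),
                      selected = 1:2, band = c(8, 12), channel_names = NULL),
                 class = "csp_model")
  ft <- csp_features(list(m), list(list(band = c(8, 12), epochs = e)))
  expect_equal(ft$X[1, ], c(log(0.9), log(0.1)), tolerance = 1e-12,
               ignore_attr = TRUE)
})

test_that("features are invariant to trial-wide amplitude scaling", {
  set.seed(12)
  e <- noise_epochs(n_trials = 6, n_channels = 4, ns = 300)
  be <- apply_bank(e, filter_bank(list(c(8, 12), c(16, 24))))
  models <- fit_csp_bank(be, mode = "paired")
  ft1 <- csp_features(models, be)
  scaled <- e; scaled$data[3, , ] <- 7.5 * scaled$data[3, , ]
  be2 <- apply_bank(scaled, filter_bank(list(c(8, 12), c(16, 24))))
  ft2 <- csp_features(models, be2)
  expect_equal(ft2$X[3, ], ft1$X[3, ], tolerance = 1e-9)
})

test_that("the default bank with two filters per band yields 38 features", {
  set.seed(13)
  e <- noise_epochs(n_trials = 12, n_channels = 4, ns = 300, sfreq = 100)
  be <- apply_bank(e, default_bank())
  models <- fit_csp_bank(be, n_filters_per_band = 2, mode = "paired")
  ft <- csp_features(models, be)
  expect_equal(ncol(ft$X), 38L)
  expect_equal(nrow(ft$meta), 38L)
  expect_length(spatial_info(models), 38L)
  expect_true(all(spatial_info(models) >= 0 & spatial_info(models) <= 1))
})
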