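# Shared fixtures, all generated in code.

# single-channel sinusoid epochs (one trial per frequency)
sine_epochs <- function(freqs, sfreq = 100, duration = 4) {
  tt <- seq(0, duration - 1 / sfreq, by = 1 / sfreq)
  arr <- array(0, c(length(freqs), 1L, length(tt)))
  for (i in seq_along(freqs)) arr[i, 1, ] <- sin(2 * pi * freqs[i] * tt + 0.3 * i)
  epoch_set(arr, rep(c(-1, 1), length.out = length(freqs)), sfreq)
}

# balanced white-noise epochs
noise_epochs <- function(n_trials = 6, n_channels = 3, ns = 200, sfreq = 100,
                         seed = 1) {
  set.seed(seed)
  epoch_set(array(rnorm(n_trials * n_channels * ns),
                  c(n_trials, n_channels, ns)),
            rep(c(-1, 1), length.out = n_trials), sfreq)
}

# random symmetric positive-definite matrix
rand_spd <- function(p) {
  A <- matrix(rnorm(p * p), p)
  crossprod(A) / p + 0.1 * diag(p)
}

# joint-histogram symmetric-uncertainty oracle on already-discrete inputs
su_hist_oracle <- function(bx, y) {
  tab <- table(bx, y)
  H <- function(counts) {
    p <- counts[counts > 0] / sum(counts)
    -sum(p * log2(p))
  }
  hx <- H(rowSums(tab)); hy <- H(colSums(tab)); hxy <- H(as.vector(tab))
  if (hx + hy == 0 || hx == 0) return(0)
  2 * (hx + hy - hxy) / (hx + hy)
}

# squared Butterworth magnitude at frequency f (Hz), computed directly from
# the transfer-function polynomials — independent of the package's filtering
butter_mag2_at <- function(flt, f, sfreq) {
  z <- exp(-1i * 2 * pi * f / sfreq)
  num <- sum(flt$b * z^(seq_along(flt$b) - 1))
  den <- sum(flt$a * z^(seq_along(flt$a) - 1))
  Mod(num / den)^2
}

# random weighted-lasso instance for solver checks
rand_lasso_instance <- function(seed, n_max = 50L, p_max = 20L,
                                orthonormal = FALSE) {
  set.seed(seed)
  n <- sample(10:n_max, 1)
  p <- sample(2:min(p_max, n - 1), 1)
  X <- matrix(rnorm(n * p), n, p)
  if (orthonormal) X <- qr.Q(qr(X))
  beta_true <- rnorm(p) * rbinom(p, 1, 0.4)
  y <- as.numeric(X %*% beta_true + rnorm(n, sd = 0.5))
  w <- runif(p, 0.2, 1)
  lmax <- max(abs(2 * crossprod(sweep(X, 2, w, "/"), y)))
  list(X = X, y = y, w = w, lambda = runif(1, 0.05, 0.7) * lmax, n = n, p = p)
}

# reference weighted-lasso solve via glmnet (independent implementation);
# glmnet minimizes (1/2n)RSS + lambda * sum(pf_j |b_j|) with pf rescaled to
# sum to p, so our unscaled-objective lambda maps to lambda*mean(w)/(2n)
glmnet_ref <- function(X, y, w, lambda) {
  fit <- glmnet::glmnet(X, y, alpha = 1, standardize = FALSE,
                        intercept = FALSE, penalty.factor = w,
                        lambda = lambda * mean(w) / (2 * nrow(X)),
                        thresh = 1e-14, maxit = 1e7)
  as.numeric(stats::coef(fit))[-1]
}
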