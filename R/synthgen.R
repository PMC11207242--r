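#' Specification for synthetic two-class motor-imagery-like EEG
#'
#' The generator emulates the physical signature CSP exploits: event-related
#' desynchronization/synchronization, i.e. a band-limited variance difference
#' between classes at specific channels. Each source is band-pass-filtered
#' Gaussian noise of unit variance at its designated channels, scaled by
#' `sqrt(r)` for class +1 trials and `1/sqrt(r)` for class -1 trials (so the
#' class variance ratio at those channels inside the band is r^2). Sources
#' are spread across channels by a mixing matrix `I + N(0, crosstalk_sd^2)`
#' (making whitening non-trivial) and broadband white noise is added
#' everywhere.
#'
#' Defaults describe a small realistic recording: 50 trials per class, 8
#' channels, 100 Hz, 4 s epochs, one mu-band (8-12 Hz) source on channels
#' 1-2 with variance ratio 4, background noise sd 0.5.
#'
#' @param n_trials_per_class trials per class (default 50).
#' @param n_channels channel count (default 8).
#' @param sfreq sampling rate in Hz (default 100).
#' @param duration epoch length in seconds (default 4).
#' @param sources list of `list(band = c(lo, hi), channels = <indices>,
#'   ratio = r >= 1)`.
#' @param noise_sd broadband white-noise standard deviation (default 0.5).
#' @param crosstalk_sd sd of the off-diagonal mixing perturbation (0.1).
#' @return object of class `synth_spec`.
#' @export
synth_spec <- function(n_trials_per_class = 50L, n_channels = 8L,
                       sfreq = 100, duration = 4,
                       sources = list(list(band = c(8, 12),
                                           channels = c(1L, 2L), ratio = 4)),
                       noise_sd = 0.5, crosstalk_sd = 0.1) {
  for (src in sources) {
    if (src$band[1] <= 0 || src$band[2] >= sfreq / 2)
      stop(sprintf("source band %g-%g Hz violates (0, Nyquist = %g)",
                   src$band[1], src$band[2], sfreq / 2))
    if (src$ratio < 1) stop("class-variance ratio must be >= 1")
    if (!length(src$channels) || any(src$channels > n_channels))
      stop("each source needs at least one valid channel index")
  }
  structure(list(n_trials_per_class = as.integer(n_trials_per_class),
                 n_channels = as.integer(n_channels), sfreq = sfreq,
                 duration = duration, sources = sources,
                 noise_sd = noise_sd, crosstalk_sd = crosstalk_sd),
            class = "synth_spec")
}

#' Generate synthetic epochs with ground truth
#'
#' Deterministic for a given `(spec, seed)`.
#'
#' @param spec a [synth_spec()].
#' @param seed integer seed.
#' @return list with `epochs` (an [epoch_set()], labels balanced) and
#'   `truth` (data.frame of informative band/channel pairs and ratios).
#' @export
synth_epochs <- function(spec, seed = 1L) {
  stopifnot(inherits(spec, "synth_spec"))
  set.seed(seed)
  n <- 2L * spec$n_trials_per_class
  nch <- spec$n_channels
  ns <- as.integer(round(spec$sfreq * spec$duration))
  labels <- rep(c(-1, 1), times = spec$n_trials_per_class)
  A <- diag(nch) + matrix(stats::rnorm(nch * nch, sd = spec$crosstalk_sd),
                          nch, nch)
  filters <- lapply(spec$sources, function(src)
    signal::butter(5, src$band / (spec$sfreq / 2), type = "pass"))
  data <- array(0, c(n, nch, ns))
  for (tr in seq_len(n)) {
    S <- matrix(0, nch, ns)
    for (si in seq_along(spec$sources)) {
      src <- spec$sources[[si]]
      gain <- if (labels[tr] == 1) sqrt(src$ratio) else 1 / sqrt(src$ratio)
      for (ch in src$channels) {
        s_raw <- zerophase_filter(filters[[si]]$b, filters[[si]]$a,
                                  stats::rnorm(ns))
        S[ch, ] <- S[ch, ] + gain * s_raw / stats::sd(s_raw)
      }
    }
    data[tr, , ] <- A %*% S +
      matrix(stats::rnorm(nch * ns, sd = spec$noise_sd), nch, ns)
  }
  truth <- do.call(rbind, lapply(spec$sources, function(src)
    data.frame(band_low = src$band[1], band_high = src$band[2],
               channel = src$channels, ratio = src$ratio)))
  list(epochs = epoch_set(data, labels, spec$sfreq), truth = truth)
}

#' Synthetic feature table with known informative columns
#'
#' Emulates a CSP log-variance feature matrix for selection-recovery
#' studies: standard-normal background columns, with `n_informative` columns
#' shifted by `+/- delta/2` according to the class label (a one-standard-
#' deviation class separation at the default `delta = 1`, typical of CSP
#' features on a discriminative band). Feature metadata assigns informative
#' columns a whitened-covariance eigenvalue of 0.8 and background columns
#' 0.55, from which the spatial-information vector `e` follows as distance
#' from the 0.5 spectrum mean.
#'
#' @param n trials (default 100, balanced).
#' @param p feature count (default 38 = 19 bands x 2 filters).
#' @param n_informative leading informative columns (default 4).
#' @param delta class-mean separation in SD units (default 1).
#' @param seed integer seed.
#' @return list with `ft` (a `feature_table`), `s` (symmetric uncertainty of
#'   each column), `e` (spatial information), `informative` (column indices).
#' @export
synth_feature_table <- function(n = 100L, p = 38L, n_informative = 4L,
                                delta = 1, seed = 1L) {
  set.seed(seed)
  y <- rep(c(-1, 1), length.out = n)
  X <- matrix(stats::rnorm(n * p), n, p)
  info <- seq_len(n_informative)
  X[, info] <- X[, info] + outer(y, rep(delta / 2, n_informative))
  lam <- c(rep(0.8, n_informative), rep(0.55, p - n_informative))
  meta <- data.frame(band_low = 0, band_high = 0,
                     band = paste0("synth", seq_len(p)),
                     filter = 1L, eigenvalue = lam)
  colnames(X) <- paste0("x", seq_len(p))
  ft <- structure(list(X = X, labels = y, meta = meta),
                  class = "feature_table")
  e <- abs(lam - 0.5)
  s <- relevance_vector(ft)$s
  list(ft = ft, s = s, e = e, informative = info)
}
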