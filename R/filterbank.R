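#' Band-pass filter bank specification
#'
#' Ordered list of (f_low, f_high) band edges in Hz plus a Butterworth filter
#' order and a zero-phase flag. Applied per trial, per channel by
#' [apply_bank()].
#'
#' @param bands list of length-2 numeric vectors `c(f_low, f_high)`.
#' @param order Butterworth order (the zero-phase forward-backward pass
#'   doubles the effective order).
#' @param zero_phase apply the filter forward and backward (default TRUE).
#' @return an object of class `filter_bank`.
#' @export
filter_bank <- function(bands, order = 5L, zero_phase = TRUE) {
  if (!length(bands)) stop("band list must be non-empty")
  bands <- lapply(bands, function(b) {
    b <- as.numeric(b)
    if (length(b) != 2L || !all(is.finite(b)) || b[1] <= 0 || b[1] >= b[2])
      stop("each band must be c(f_low, f_high) with 0 < f_low < f_high")
    b
  })
  structure(list(bands = bands, order = as.integer(order),
                 zero_phase = isTRUE(zero_phase)),
            class = "filter_bank")
}

#' @export
print.filter_bank <- function(x, ...) {
  cat(sprintf("filter_bank: %d bands, Butterworth order %d%s\n",
              length(x$bands), x$order, if (x$zero_phase) ", zero-phase" else ""))
  cat(" ", paste(vapply(x$bands, function(b) sprintf("%g-%g", b[1], b[2]),
                        ""), collapse = " "), "\n")
  invisible(x)
}

band_names <- function(spec)
  vapply(spec$bands, function(b) sprintf("%g-%g", b[1], b[2]), "")

#' Default overlapping multi-scale bank (4-40 Hz)
#'
#' Nineteen bands at three scales, all within 4-40 Hz: nine narrow 4 Hz bands
#' on a 4 Hz grid (4-8, ..., 36-40), eight wide 8 Hz bands on a 4 Hz step
#' (4-12, ..., 32-40) that overlap each other and the narrow bands, and two
#' broad bands 4-32 and 12-40. Order-5 Butterworth, zero-phase.
#'
#' @return a [filter_bank()].
#' @export
default_bank <- function() {
  narrow <- lapply(seq(4, 36, by = 4), function(lo) c(lo, lo + 4))
  wide   <- lapply(seq(4, 32, by = 4), function(lo) c(lo, lo + 8))
  broad  <- list(c(4, 32), c(12, 40))
  filter_bank(c(narrow, wide, broad), order = 5L, zero_phase = TRUE)
}

#' Non-overlapping nine-band bank (FBCSP-style)
#' @return a [filter_bank()] with nine contiguous 4 Hz bands over 4-40 Hz.
#' @export
fbcsp_bank <- function()
  filter_bank(lapply(seq(4, 36, by = 4), function(lo) c(lo, lo + 4)),
              order = 5L, zero_phase = TRUE)

#' Single broadband 4-40 Hz "bank"
#' @return a [filter_bank()] with the one band c(4, 40).
#' @export
single_band_bank <- function()
  filter_bank(list(c(4, 40)), order = 5L, zero_phase = TRUE)

#' Resolve a bank preset name or pass a filter_bank through
#' @param bank `"default"`, `"fbcsp"`, `"single"`, a list of band pairs, or a
#'   `filter_bank`.
#' @return a [filter_bank()].
#' @export
resolve_bank <- function(bank) {
  if (inherits(bank, "filter_bank")) return(bank)
  if (is.character(bank) && length(bank) == 1L)
    return(switch(bank,
                  default = default_bank(),
                  fbcsp = fbcsp_bank(),
                  single = single_band_bank(),
                  stop(sprintf("unknown bank preset '%s'", bank))))
  if (is.list(bank)) return(filter_bank(bank))
  stop("`bank` must be a preset name, a list of band pairs, or a filter_bank")
}

# Squared Butterworth magnitude response |H(e^{iw})|^2 on the N-point DFT
# grid, from the transfer-function polynomials.
butter_mag2 <- function(flt, N) {
  z <- exp(-1i * 2 * pi * (0:(N - 1)) / N)
  num <- outer(z, seq_along(flt$b) - 1, "^") %*% flt$b
  den <- outer(z, seq_along(flt$a) - 1, "^") %*% flt$a
  as.numeric(Mod(num / den)^2)
}

# Zero-phase band-pass of the rows of a channels x samples matrix: the
# epoch is mirror-extended (even reflection, value-continuous periodic
# extension) and multiplied by |H|^2 on the DFT grid — the exact steady-state
# response of a forward-backward Butterworth pass, with no start-up
# transient. `h2` must come from butter_mag2(flt, 2 * n_samples).
zerophase_bandpass_mat <- function(X, h2) {
  ns <- ncol(X)
  ext <- cbind(X, X[, ns:1, drop = FALSE])       # nch x 2ns, mirrored
  E <- t(stats::mvfft(t(ext)))                   # row-wise FFT
  Y <- Re(t(stats::mvfft(t(E * rep(h2, each = nrow(X))), inverse = TRUE))) /
    (2 * ns)
  Y[, seq_len(ns), drop = FALSE]
}

# Zero-phase IIR filtering (time domain) with odd-reflection padding at both
# ends; used for the wideband anti-alias low-pass and the synthetic-source
# band-pass, where start-up transients are short.
zerophase_filter <- function(b, a, x) {
  n <- length(x)
  pad <- min(3L * (max(length(a), length(b)) - 1L) * 2L, n - 1L)
  xx <- c(2 * x[1] - x[seq(pad + 1L, 2L)], x,
          2 * x[n] - x[seq(n - 1L, n - pad)])
  y <- as.numeric(signal::filter(b, a, xx))
  y <- rev(as.numeric(signal::filter(b, a, rev(y))))
  y[(pad + 1L):(pad + n)]
}

forward_filter <- function(b, a, x) {
  n <- length(x)
  pad <- min(3L * (max(length(a), length(b)) - 1L) * 2L, n - 1L)
  xx <- c(2 * x[1] - x[seq(pad + 1L, 2L)], x)
  y <- as.numeric(signal::filter(b, a, xx))
  y[(pad + 1L):(pad + n)]
}

#' Apply a filter bank to an epoch set
#'
#' Designs one Butterworth band-pass per band and filters every trial and
#' channel, returning one filtered `epoch_set` per band (same shape and
#' labels as the input).
#'
#' @param e an [epoch_set()].
#' @param spec a [filter_bank()].
#' @return a named list, one element per band, each
#'   `list(band = c(lo, hi), epochs = <filtered epoch_set>)`.
#' @export
apply_bank <- function(e, spec) {
  stopifnot(inherits(e, "epoch_set"), inherits(spec, "filter_bank"))
  nyq <- e$sfreq / 2
  for (b in spec$bands)
    if (b[2] >= nyq)
      stop(sprintf("band %g-%g Hz violates the Nyquist limit (sfreq = %g Hz)",
                   b[1], b[2], e$sfreq))
  dm <- dim(e$data)
  out <- vector("list", length(spec$bands))
  for (bi in seq_along(spec$bands)) {
    b <- spec$bands[[bi]]
    flt <- signal::butter(spec$order, c(b[1], b[2]) / nyq, type = "pass")
    arr <- array(0, dm)
    if (spec$zero_phase) {
      h2 <- butter_mag2(flt, 2L * dm[3])
      for (tr in seq_len(dm[1]))
        arr[tr, , ] <- zerophase_bandpass_mat(
          matrix(e$data[tr, , ], dm[2], dm[3]), h2)
    } else {
      for (tr in seq_len(dm[1])) for (ch in seq_len(dm[2]))
        arr[tr, ch, ] <- forward_filter(flt$b, flt$a, e$data[tr, ch, ])
    }
    fe <- e
    fe$data <- arr
    out[[bi]] <- list(band = b, epochs = fe)
  }
  names(out) <- band_names(spec)
  out
}
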