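#' Epoched multichannel EEG container
#'
#' An `epoch_set` bundles a trials x channels x samples array with per-trial
#' class labels, channel names, the sampling rate and the epoch-relative start
#' time. It is the unit of data every stage of the pipeline consumes and
#' produces. Labels are stored as -1/+1; arbitrary two-level labels are mapped
#' so that the lexicographically smaller original label becomes -1 (the
#' mapping is kept in the `label_map` attribute and reported via `message()`).
#'
#' @param data numeric array of shape (n_trials, n_channels, n_samples),
#'   nominally in microvolts (the scale is not enforced).
#' @param labels vector of length n_trials with exactly two distinct values
#'   (or a subset of {-1, 1}).
#' @param sfreq sampling rate in Hz (> 0).
#' @param channel_names optional character vector of length n_channels.
#' @param t_start epoch-relative start time in seconds (default 0).
#' @return an object of class `epoch_set`.
#' @export
epoch_set <- function(data, labels, sfreq, channel_names = NULL, t_start = 0) {
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("`data` must be a 3-d array (trials x channels x samples)")
  dm <- dim(data)
  if (dm[3] < 2L) stop("epochs must contain at least 2 samples")
  if (length(labels) != dm[1])
    stop(sprintf("length(labels) == %d but data has %d trials",
                 length(labels), dm[1]))
  if (!is.numeric(sfreq) || length(sfreq) != 1L || !is.finite(sfreq) || sfreq <= 0)
    stop("`sfreq` must be a single positive number")
  bad <- which(!is.finite(data))
  if (length(bad)) {
    idx <- arrayInd(bad[1], dm)
    stop(sprintf("non-finite value in data at trial %d, channel %d, sample %d",
                 idx[1], idx[2], idx[3]))
  }
  mapped <- map_labels(labels)
  if (is.null(channel_names)) channel_names <- paste0("ch", seq_len(dm[2]))
  if (length(channel_names) != dm[2])
    stop("length(channel_names) must equal the number of channels")
  structure(list(data = data, labels = mapped$labels,
                 channel_names = as.character(channel_names),
                 sfreq = as.numeric(sfreq), t_start = as.numeric(t_start)),
            label_map = mapped$map, class = "epoch_set")
}

# Map two-level labels to {-1, +1}: lexicographically smaller original -> -1.
map_labels <- function(labels) {
  lv <- sort(unique(as.character(labels)))
  if (length(lv) > 2L)
    stop(sprintf("two-class model: found %d distinct labels (%s)",
                 length(lv), paste(lv, collapse = ", ")))
  if (length(lv) < 1L) stop("no labels supplied")
  if (all(lv %in% c("-1", "1"))) {
    return(list(labels = as.numeric(as.character(labels)),
                map = stats::setNames(as.numeric(lv), lv)))
  }
  map <- stats::setNames(c(-1, 1)[seq_along(lv)], lv)
  message(sprintf("label mapping: %s",
                  paste(sprintf("%s -> %+d", lv, map[lv]), collapse = ", ")))
  list(labels = unname(map[as.character(labels)]), map = map)
}

#' @export
print.epoch_set <- function(x, ...) {
  dm <- dim(x$data)
  cat(sprintf("epoch_set: %d trials x %d channels x %d samples @ %g Hz, t0 = %g s\n",
              dm[1], dm[2], dm[3], x$sfreq, x$t_start))
  cat(sprintf("  labels: %d x -1, %d x +1\n",
              sum(x$labels == -1), sum(x$labels == 1)))
  invisible(x)
}

n_trials  <- function(e) dim(e$data)[1]
n_channels <- function(e) dim(e$data)[2]
n_samples <- function(e) dim(e$data)[3]

# Both classes must be present before any class-contrast fit.
check_two_classes <- function(labels) {
  if (length(unique(labels)) < 2L)
    stop("both classes must be present for fitting")
  invisible(TRUE)
}

#' Save an epoch_set to the HDF5 epochs container
#'
#' One self-describing HDF5 file with datasets `data`, `labels`,
#' `channel_names` and scalar datasets `sfreq`, `t_start`. Round-trips
#' bit-exactly through [load_epochs()].
#'
#' @param e an `epoch_set`.
#' @param path output file path (overwritten if present).
#' @return `path`, invisibly.
#' @export
save_epochs <- function(e, path) {
  stopifnot(inherits(e, "epoch_set"))
  if (file.exists(path)) unlink(path)
  rhdf5::h5createFile(path)
  # rhdf5 writes R arrays in column-major order and restores dim on read,
  # so the 3-d array round-trips exactly.
  rhdf5::h5write(e$data, path, "data")
  rhdf5::h5write(e$labels, path, "labels")
  rhdf5::h5write(e$channel_names, path, "channel_names")
  rhdf5::h5write(e$sfreq, path, "sfreq")
  rhdf5::h5write(e$t_start, path, "t_start")
  rhdf5::h5closeAll()
  invisible(path)
}

#' Load epoched EEG
#'
#' Reads the package's HDF5 epochs container, or a plain-text adapter format.
#' The `csv` adapter expects a long table with columns `trial`, `channel`,
#' `label`, then one column per sample (`s1`, `s2`, ...); the sampling rate
#' must then be given via `sfreq`.
#'
#' @param path file to read.
#' @param format_hint `"container"` (HDF5, default) or `"csv"`.
#' @param sfreq sampling rate in Hz, required by the `csv` adapter.
#' @param t_start epoch start time for the `csv` adapter (default 0).
#' @return a validated [epoch_set()].
#' @export
load_epochs <- function(path, format_hint = "container", sfreq = NULL, t_start = 0) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  switch(format_hint,
    container = load_epochs_h5(path),
    csv = load_epochs_csv(path, sfreq = sfreq, t_start = t_start),
    stop(sprintf("no adapter registered for format '%s'", format_hint)))
}

load_epochs_h5 <- function(path) {
  contents <- tryCatch(rhdf5::h5ls(path, recursive = FALSE)$name,
                       error = function(e) stop(sprintf("unreadable container: %s", path)))
  need <- c("data", "labels", "sfreq")
  if (!all(need %in% contents))
    stop(sprintf("container %s is missing dataset(s): %s", path,
                 paste(setdiff(need, contents), collapse = ", ")))
  data <- rhdf5::h5read(path, "data")
  labels <- as.vector(rhdf5::h5read(path, "labels"))
  chn <- if ("channel_names" %in% contents)
    as.character(rhdf5::h5read(path, "channel_names")) else NULL
  sfreq <- as.numeric(rhdf5::h5read(path, "sfreq"))
  t_start <- if ("t_start" %in% contents)
    as.numeric(rhdf5::h5read(path, "t_start")) else 0
  rhdf5::h5closeAll()
  epoch_set(data, labels, sfreq, channel_names = chn, t_start = t_start)
}

load_epochs_csv <- function(path, sfreq, t_start = 0) {
  if (is.null(sfreq)) stop("the csv adapter requires `sfreq`")
  tab <- utils::read.csv(path, check.names = FALSE)
  need <- c("trial", "channel", "label")
  if (!all(need %in% names(tab)))
    stop("csv adapter expects columns trial, channel, label, s1..sN")
  scols <- grep("^s[0-9]+$", names(tab), value = TRUE)
  scols <- scols[order(as.integer(sub("^s", "", scols)))]
  trials <- sort(unique(tab$trial)); chans <- unique(tab$channel)
  arr <- array(NA_real_, c(length(trials), length(chans), length(scols)))
  labels <- rep(NA_character_, length(trials))
  for (i in seq_len(nrow(tab))) {
    ti <- match(tab$trial[i], trials); ci <- match(tab$channel[i], chans)
    arr[ti, ci, ] <- as.numeric(tab[i, scols])
    labels[ti] <- as.character(tab$label[i])
  }
  epoch_set(arr, labels, sfreq, channel_names = as.character(chans),
            t_start = t_start)
}

#' Crop and down-sample an epoch set
#'
#' Crops each epoch to `window = c(t0, t1)` (seconds, epoch-relative,
#' half-open so the output has exactly `(t1 - t0) * sfreq` samples), then
#' down-samples to `target_sfreq`. For an integer decimation factor a
#' zero-phase order-8 Butterworth low-pass anti-alias filter (cutoff 0.8 x
#' the new Nyquist) is applied before taking every k-th sample; for rational
#' factors polyphase FIR resampling (`signal::resample`) is used. Trial count
#' and labels are never changed.
#'
#' @param e an `epoch_set`.
#' @param target_sfreq new sampling rate in Hz (must be <= `e$sfreq`).
#' @param window length-2 numeric `c(t0, t1)` in seconds, or `NULL` to keep
#'   the full span.
#' @return a new `epoch_set`.
#' @export
preprocess_epochs <- function(e, target_sfreq = NULL, window = NULL) {
  stopifnot(inherits(e, "epoch_set"))
  data <- e$data
  t_start <- e$t_start
  if (!is.null(window)) {
    t0 <- window[1]; t1 <- window[2]
    if (!(t0 < t1)) stop("window must satisfy t0 < t1")
    span_end <- e$t_start + n_samples(e) / e$sfreq
    if (t0 < e$t_start - 1e-9 || t1 > span_end + 1e-9)
      stop(sprintf("window [%g, %g] outside epoch span [%g, %g]",
                   t0, t1, e$t_start, span_end))
    i0 <- round((t0 - e$t_start) * e$sfreq) + 1L
    i1 <- round((t1 - e$t_start) * e$sfreq)
    data <- data[, , i0:i1, drop = FALSE]
    t_start <- t0
  }
  sfreq <- e$sfreq
  if (!is.null(target_sfreq) && target_sfreq != sfreq) {
    if (target_sfreq > sfreq)
      stop("up-sampling is not supported (target_sfreq > sfreq)")
    data <- downsample_array(data, sfreq, target_sfreq)
    sfreq <- target_sfreq
  }
  epoch_set(data, e$labels, sfreq, channel_names = e$channel_names,
            t_start = t_start)
}

downsample_array <- function(data, sfreq, target) {
  ratio <- sfreq / target
  dm <- dim(data)
  if (abs(ratio - round(ratio)) < 1e-9) {
    k <- as.integer(round(ratio))
    bw <- signal::butter(8, 0.8 * (target / 2) / (sfreq / 2), type = "low")
    keep <- seq(1L, dm[3], by = k)
    out <- array(0, c(dm[1], dm[2], length(keep)))
    for (tr in seq_len(dm[1])) for (ch in seq_len(dm[2])) {
      y <- zerophase_filter(bw$b, bw$a, data[tr, ch, ])
      out[tr, ch, ] <- y[keep]
    }
    return(out)
  }
  # rational ratio: anti-alias, then interpolate on the new sample grid
  # (spline interpolation is accurate for signals band-limited well below
  # the original Nyquist, which the anti-alias filter guarantees)
  n_out <- floor(dm[3] * target / sfreq)
  t_old <- (seq_len(dm[3]) - 1L) / sfreq
  t_new <- (seq_len(n_out) - 1L) / target
  bw <- signal::butter(8, 0.8 * (target / 2) / (sfreq / 2), type = "low")
  out <- array(0, c(dm[1], dm[2], n_out))
  for (tr in seq_len(dm[1])) for (ch in seq_len(dm[2])) {
    y <- zerophase_filter(bw$b, bw$a, data[tr, ch, ])
    out[tr, ch, ] <- stats::spline(t_old, y, xout = t_new)$y
  }
  out
}
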