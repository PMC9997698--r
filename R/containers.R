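#' Construct an epoch set
#'
#' The package's signal-level container: a `trials x channels x samples`
#' numeric array (microvolts) plus its sampling metadata. Result-level
#' objects downstream are tibbles; epochs stay an array because per-sample
#' long format at 500 Hz is impractical.
#'
#' @param data Numeric array, trials x channels x samples.
#' @param fs Sampling rate in Hz.
#' @param t0 Time of the first sample in seconds relative to the lock event
#'   (negative = before the event).
#' @param lock One of `"cue"`, `"target"`, `"rest"`.
#' @param channel_names Character vector, length = dim 2.
#' @param montage Optional [montage_1010()]-style montage.
#' @param trial_ids Optional integer ids, length = dim 1.
#' @return An object of class `epoch_set`.
#' @export
epoch_set <- function(data, fs, t0, lock = c("cue", "target", "rest"),
                      channel_names, montage = NULL, trial_ids = NULL) {
  lock <- match.arg(lock)
  if (length(dim(data)) != 3) {
    abort("`data` must be a 3-D trials x channels x samples array.",
          class = "alphasync_bad_epochs")
  }
  if (dim(data)[2] != length(channel_names)) {
    abort("channel_names length does not match data dimension 2.",
          class = "alphasync_bad_epochs")
  }
  if (fs <= 0) abort("fs must be positive.", class = "alphasync_bad_epochs")
  trial_ids <- trial_ids %||% seq_len(dim(data)[1])
  dimnames(data) <- list(NULL, channel_names, NULL)
  structure(
    list(data = data, fs = fs, t0 = t0, lock = lock,
         channel_names = channel_names, montage = montage,
         trial_ids = as.integer(trial_ids)),
    class = "epoch_set"
  )
}

#' @export
print.epoch_set <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf(
    "<epoch_set> %d trials x %d channels x %d samples @ %g Hz, %s-locked, t = [%.3f, %.3f] s\n",
    d[1], d[2], d[3], x$fs, x$lock, x$t0, x$t0 + (d[3] - 1) / x$fs))
  invisible(x)
}

#' Time axis of an epoch set or spectral tensor (seconds)
#' @param x An `epoch_set` or `spectral_tensor`.
#' @return Numeric vector of sample times in seconds relative to the lock.
#' @export
time_axis <- function(x) {
  n <- if (inherits(x, "epoch_set")) dim(x$data)[3] else dim(x$coeffs)[4]
  x$t0 + (seq_len(n) - 1) / x$fs
}

#' Construct a spectral tensor
#'
#' Complex Morlet coefficients, trials x channels x frequencies x samples.
#'
#' @param coeffs Complex 4-D array.
#' @param freqs Frequencies (Hz), length = dim 3.
#' @param fs Sampling rate (Hz).
#' @param t0 Time of first sample (s).
#' @param channel_names Channel names, length = dim 2.
#' @param trial_ids Trial ids, length = dim 1.
#' @return Object of class `spectral_tensor`.
#' @export
spectral_tensor <- function(coeffs, freqs, fs, t0, channel_names,
                            trial_ids = NULL) {
  if (length(dim(coeffs)) != 4) {
    abort("`coeffs` must be 4-D (trials x channels x freqs x samples).",
          class = "alphasync_bad_tensor")
  }
  trial_ids <- trial_ids %||% seq_len(dim(coeffs)[1])
  dimnames(coeffs) <- list(NULL, channel_names, NULL, NULL)
  structure(
    list(coeffs = coeffs, freqs = freqs, fs = fs, t0 = t0,
         channel_names = channel_names, trial_ids = as.integer(trial_ids)),
    class = "spectral_tensor"
  )
}

#' @export
print.spectral_tensor <- function(x, ...) {
  d <- dim(x$coeffs)
  cat(sprintf(
    "<spectral_tensor> %d trials x %d channels x %d freqs x %d samples @ %g Hz\n",
    d[1], d[2], d[3], d[4], x$fs))
  cat("freqs:", paste(signif(x$freqs, 4), collapse = ", "), "Hz\n")
  invisible(x)
}

#' Write / read an epoch set in the package's on-disk container
#'
#' One directory per dataset: `meta.json` (sampling rate, channels, lock,
#' t0, shape, dtype, byte order) plus `data.bin`, a flat little-endian
#' float32 dump of the epoch tensor in trials x channels x samples order
#' (trial index fastest, R column-major).
#'
#' @param epochs An `epoch_set`.
#' @param dir Directory to create/read.
#' @return `write_epochs()` returns `dir` invisibly; `read_epochs()` an
#'   `epoch_set` (montage is not persisted).
#' @export
write_epochs <- function(epochs, dir) {
  stopifnot(inherits(epochs, "epoch_set"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  d <- dim(epochs$data)
  meta <- list(
    fs = epochs$fs, t0 = epochs$t0, lock = epochs$lock,
    channels = epochs$channel_names, trial_ids = epochs$trial_ids,
    shape = d, dtype = "float32", byte_order = "little"
  )
  jsonlite::write_json(meta, file.path(dir, "meta.json"), auto_unbox = TRUE,
                       digits = NA)
  con <- file(file.path(dir, "data.bin"), "wb")
  on.exit(close(con))
  writeBin(as.vector(epochs$data), con, size = 4, endian = "little")
  invisible(dir)
}

#' @rdname write_epochs
#' @export
read_epochs <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "meta.json"), simplifyVector = TRUE)
  n <- prod(meta$shape)
  con <- file(file.path(dir, "data.bin"), "rb")
  on.exit(close(con))
  x <- readBin(con, "numeric", n = n, size = 4, endian = "little")
  epoch_set(array(x, dim = meta$shape), fs = meta$fs, t0 = meta$t0,
            lock = meta$lock, channel_names = meta$channels,
            trial_ids = meta$trial_ids)
}

#' Write / read a trial table as CSV
#'
#' Header columns: `trial_id, attended_side, target_side, valid, detected,
#' discriminated, correct, isi` (isi in ms; logical flags as TRUE/FALSE).
#'
#' @param trials Trial tibble (see [design_trials()]).
#' @param path CSV path.
#' @return `read_trials()` returns a tibble.
#' @export
write_trials <- function(trials, path) {
  write.csv(as.data.frame(trials), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_trials
#' @export
read_trials <- function(path) {
  tibble::as_tibble(read.csv(path, stringsAsFactors = FALSE))
}
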