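#' Logarithmically spaced wavelet frequency grid
#'
#' `f_j = f_min * (f_max/f_min)^(j/(n-1))`, j = 0..n-1; endpoints exact.
#' The default 16-point grid from 2.6 to 42 Hz is the one used throughout
#' the pipeline.
#'
#' @param f_min,f_max Band edges, Hz.
#' @param n Number of frequencies.
#' @return Numeric vector of length `n`.
#' @examples
#' make_frequency_grid()
#' @export
make_frequency_grid <- function(f_min = 2.6, f_max = 42, n = 16) {
  if (f_min <= 0 || f_max <= f_min || n < 2) {
    abort("Need 0 < f_min < f_max and n >= 2.", class = "alphasync_bad_grid")
  }
  f_min * (f_max / f_min)^((seq_len(n) - 1) / (n - 1))
}

#' Morlet wavelet bank
#'
#' Complex Morlet wavelets with a fixed cycle count: at center frequency f,
#' the Gaussian envelope has sd `sigma_t = n_cycles / (2 pi f)`.
#'
#' @param center_freqs Center frequencies, Hz (strictly increasing).
#' @param n_cycles Cycles per wavelet (default 5).
#' @param fs Sampling rate, Hz.
#' @return List of class `wavelet_bank`.
#' @export
morlet_bank <- function(center_freqs = make_frequency_grid(), n_cycles = 5,
                        fs = 500) {
  if (is.unsorted(center_freqs, strictly = TRUE)) {
    abort("center_freqs must be strictly increasing.",
          class = "alphasync_bad_bank")
  }
  if (any(center_freqs >= fs / 2)) {
    abort("All frequencies must be below Nyquist.",
          class = "alphasync_bad_bank")
  }
  if (n_cycles < 1) abort("n_cycles must be >= 1.",
                          class = "alphasync_bad_bank")
  structure(list(center_freqs = center_freqs, n_cycles = n_cycles, fs = fs),
            class = "wavelet_bank")
}

#' Morlet wavelet transform of an epoch set
#'
#' Convolution with complex Morlet wavelets, implemented as FFT
#' multiplication with the wavelet's Gaussian frequency response. The
#' kernel is peak-normalized in the frequency domain (analysis gain: a
#' unit-amplitude tone at a wavelet's center frequency yields an envelope
#' of 0.5); only amplitude ratios and phases are claim-bearing. Negative
#' frequencies are zeroed, so coefficients are analytic and their argument
#' is the instantaneous phase.
#'
#' With `mirror = TRUE` (default) epochs are mirror-padded before the
#' transform and trimmed back afterwards, so no epoch edge is visible to
#' the wavelet.
#'
#' @param epochs An `epoch_set`.
#' @param bank A [morlet_bank()]; its `fs` must match the epochs.
#' @param channels Optional channel subset (names) to transform.
#' @param mirror Mirror-pad and trim (set `FALSE` if `epochs` are already
#'   mirrored or edge artifacts are acceptable).
#' @return A `spectral_tensor` (trials x channels x freqs x samples) on the
#'   original time axis.
#' @export
morlet_transform <- function(epochs, bank, channels = NULL, mirror = TRUE) {
  stopifnot(inherits(epochs, "epoch_set"), inherits(bank, "wavelet_bank"))
  if (abs(bank$fs - epochs$fs) > 1e-9) {
    abort("Bank and epochs sampling rates differ.",
          class = "alphasync_bad_bank")
  }
  channels <- channels %||% epochs$channel_names
  check_channels(channels, epochs$channel_names)
  fs <- epochs$fs
  if (mirror) {
    work <- epoch_mirror(epochs)
    pad <- 0L
  } else {
    # zero-pad so the FFT convolution is linear, not circular
    L <- dim(epochs$data)[3]
    sig_t_max <- bank$n_cycles / (2 * pi * min(bank$center_freqs))
    pad <- min(L, ceiling(4 * sig_t_max * fs))
    work <- epochs
    padded <- array(0, dim = c(dim(epochs$data)[1], dim(epochs$data)[2],
                               L + 2 * pad))
    padded[, , pad + seq_len(L)] <- epochs$data
    work$data <- padded
    work$t0 <- epochs$t0 - pad / fs
  }
  n <- dim(work$data)[3]
  # longest wavelet (lowest freq): require ~3 sd of Gaussian support
  sig_t_max <- bank$n_cycles / (2 * pi * min(bank$center_freqs))
  if (6 * sig_t_max * fs > n) {
    abort("Wavelet support exceeds the (mirrored) epoch length.",
          class = "alphasync_epoch_too_short")
  }
  fbins <- (seq_len(n) - 1) * fs / n
  pos <- fbins <= fs / 2 & fbins > 0
  W <- matrix(0, length(bank$center_freqs), n)
  for (j in seq_along(bank$center_freqs)) {
    f0 <- bank$center_freqs[j]
    sig_t <- bank$n_cycles / (2 * pi * f0)
    W[j, pos] <- exp(-2 * pi^2 * sig_t^2 * (fbins[pos] - f0)^2)
  }
  ci <- match(channels, epochs$channel_names)
  n_tr <- dim(work$data)[1]
  out <- array(complex(real = 0), dim = c(n_tr, length(ci),
                                          length(bank$center_freqs), n))
  for (k in seq_len(n_tr)) {
    for (c2 in seq_along(ci)) {
      X <- fft(work$data[k, ci[c2], ])
      for (j in seq_len(nrow(W))) {
        out[k, c2, j, ] <- fft(X * W[j, ], inverse = TRUE) / n
      }
    }
  }
  tens <- spectral_tensor(out, freqs = bank$center_freqs, fs = fs,
                          t0 = work$t0, channel_names = channels,
                          trial_ids = epochs$trial_ids)
  if (mirror) {
    attr(tens, "mirror_span") <- attr(work, "mirror_span")
    tens <- epoch_trim(tens)
  } else if (pad > 0) {
    L <- dim(epochs$data)[3]
    tens$coeffs <- tens$coeffs[, , , pad + seq_len(L), drop = FALSE]
    tens$t0 <- epochs$t0
  }
  tens
}

#' Upper-alpha subset of a frequency grid
#'
#' Grid frequencies falling inside the upper-alpha band (default
#' 9.54-14.31 Hz) with a small tolerance at the edges.
#'
#' @param grid Frequency grid (Hz).
#' @param band Band edges (Hz).
#' @param eps Edge tolerance (Hz).
#' @return Increasing numeric vector (errors if empty).
#' @export
upper_alpha_subset <- function(grid, band = c(9.54, 14.31), eps = 0.05) {
  out <- grid[grid >= band[1] - eps & grid <= band[2] + eps]
  if (length(out) == 0) {
    abort("No grid frequencies inside the band.",
          class = "alphasync_empty_band")
  }
  out
}

#' Welch power spectral density
#'
#' Overlapping Hann-tapered segments averaged into a PSD on a fixed
#' frequency resolution (zero-padded as needed). Defaults: 1000 ms
#' segments, overlap equal to 10% of the segment, 0.25 Hz resolution.
#'
#' @param rest A single-trial `epoch_set` (e.g. [simulate_rest()]) or a
#'   channels x samples matrix.
#' @param fs Sampling rate (taken from `rest` if it is an `epoch_set`).
#' @param segment Segment length, ms.
#' @param overlap Fractional overlap of consecutive segments.
#' @param resolution Frequency resolution of the PSD grid, Hz.
#' @return Tibble with `channel`, `freq` (Hz), `psd` (uV^2/Hz, one-sided).
#' @export
welch_psd <- function(rest, fs = NULL, segment = 1000, overlap = 0.1,
                      resolution = 0.25) {
  if (inherits(rest, "epoch_set")) {
    fs <- rest$fs
    x <- rest$data[1, , , drop = FALSE]
    dim(x) <- dim(x)[-1]
    rownames(x) <- rest$channel_names
  } else {
    x <- rest
    if (is.null(fs)) abort("fs required for matrix input.",
                           class = "alphasync_bad_psd")
  }
  ns <- round(segment / 1000 * fs)
  if (ncol(x) < ns) {
    abort("Recording shorter than one segment.",
          class = "alphasync_too_short")
  }
  step <- max(1L, round(ns * (1 - overlap)))
  starts <- seq(1, ncol(x) - ns + 1, by = step)
  w <- 0.5 - 0.5 * cos(2 * pi * (seq_len(ns) - 1) / (ns - 1)) # Hann
  nfft <- max(ns, round(fs / resolution))
  nf <- floor(nfft / 2) + 1
  freqs <- (seq_len(nf) - 1) * fs / nfft
  scale <- 1 / (fs * sum(w^2))
  chans <- rownames(x) %||% paste0("ch", seq_len(nrow(x)))
  res <- lapply(seq_len(nrow(x)), function(ci) {
    acc <- numeric(nf)
    for (s0 in starts) {
      seg <- x[ci, s0:(s0 + ns - 1)]
      seg <- (seg - mean(seg)) * w
      sp <- abs(fft(c(seg, numeric(nfft - ns))))^2 * scale
      half <- sp[seq_len(nf)]
      half[2:(nf - 1)] <- 2 * half[2:(nf - 1)] # one-sided
      acc <- acc + half
    }
    tibble::tibble(channel = chans[ci], freq = freqs,
                   psd = acc / length(starts))
  })
  dplyr::bind_rows(res)
}

#' Estimate the individual alpha frequency from a resting PSD
#'
#' The PSD is averaged across the supplied parieto-occipital channels,
#' normalized by its mean power from 1 to 40 Hz, and searched for local
#' maxima inside `search_band`; the largest local maximum is the IAF. A
#' spectrum with no interior peak (e.g. pure 1/f) raises a
#' `alphasync_no_peak` error so the participant can be flagged rather
#' than silently defaulted.
#'
#' @param psd Tibble from [welch_psd()] (already restricted to the
#'   channels of interest, or use `channels`).
#' @param channels Optional channel subset to average.
#' @param search_band Peak search band, Hz.
#' @param norm_band Normalization band, Hz.
#' @return List of class `iaf_estimate`: `iaf` (Hz), `psd` (tibble of
#'   `freq`, `power`, normalized), `search_band`.
#' @export
estimate_iaf <- function(psd, channels = NULL, search_band = c(5, 15),
                         norm_band = c(1, 40)) {
  if (!is.null(channels)) psd <- dplyr::filter(psd, .data$channel %in% channels)
  avg <- psd |>
    dplyr::group_by(.data$freq) |>
    dplyr::summarise(power = mean(.data$psd), .groups = "drop") |>
    dplyr::arrange(.data$freq)
  norm <- mean(avg$power[avg$freq >= norm_band[1] & avg$freq <= norm_band[2]])
  if (!is.finite(norm) || norm <= 0) {
    abort("PSD does not cover the normalization band.",
          class = "alphasync_bad_psd")
  }
  avg$power <- avg$power / norm
  inb <- which(avg$freq >= search_band[1] & avg$freq <= search_band[2])
  if (length(inb) < 3) abort("Search band too narrow for the PSD grid.",
                             class = "alphasync_bad_psd")
  p <- avg$power
  is_peak <- vapply(inb, function(i) {
    i > 1 && i < nrow(avg) && p[i] > p[i - 1] && p[i] >= p[i + 1]
  }, logical(1))
  peaks <- inb[is_peak]
  if (length(peaks) == 0) {
    abort("No local maximum in the IAF search band.",
          class = "alphasync_no_peak")
  }
  best <- peaks[which.max(p[peaks])]
  structure(list(iaf = avg$freq[best], psd = avg, search_band = search_band),
            class = "iaf_estimate")
}

#' @export
print.iaf_estimate <- function(x, ...) {
  cat(sprintf("<iaf_estimate> IAF = %.2f Hz (search band %g-%g Hz)\n",
              x$iaf, x$search_band[1], x$search_band[2]))
  invisible(x)
}
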