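#' Filter specification for signal conditioning
#'
#' Zero-phase (two-pass) IIR chain: 50 Hz notch, then 5th-order high-pass
#' at 0.16 Hz, then 16th-order low-pass at 45 Hz. Orders are the designed
#' one-pass orders; forward-backward application doubles the effective
#' attenuation and cancels phase lag.
#'
#' @param hp_order,lp_order Butterworth orders.
#' @param hp_cut,lp_cut Cutoffs, Hz.
#' @param notch_freq Line frequency, Hz.
#' @param notch_q Notch quality factor.
#' @param two_pass Apply each filter forward and backward.
#' @return List of class `filter_spec`.
#' @export
filter_spec <- function(hp_order = 5, lp_order = 16, hp_cut = 0.16,
                        lp_cut = 45, notch_freq = 50, notch_q = 35,
                        two_pass = TRUE) {
  if (hp_order < 1 || lp_order < 1) {
    abort("Filter orders must be >= 1.", class = "alphasync_bad_filter")
  }
  if (hp_cut <= 0 || lp_cut <= 0) {
    abort("Cutoffs must be positive.", class = "alphasync_bad_filter")
  }
  structure(list(hp_order = hp_order, lp_order = lp_order, hp_cut = hp_cut,
                 lp_cut = lp_cut, notch_freq = notch_freq, notch_q = notch_q,
                 two_pass = two_pass), class = "filter_spec")
}

# Butterworth design as cascaded second-order sections (bilinear transform
# of the analog prototype). A flat transfer function is numerically
# unusable at order 16 with fc << fs/2; the SOS cascade is exact and
# stable. Returns a list of list(b, a) sections.
butter_sos <- function(order, fc, fs, type = c("low", "high")) {
  type <- match.arg(type)
  if (fc <= 0 || fc >= fs / 2) {
    abort("Cutoff must lie inside (0, fs/2).", class = "alphasync_bad_filter")
  }
  wc <- 2 * fs * tan(pi * fc / fs) # prewarped analog cutoff
  k <- seq_len(order)
  proto <- exp(1i * pi * (2 * k + order - 1) / (2 * order)) # unit Butterworth poles
  if (type == "low") {
    p <- wc * proto
    z_zero <- -1
  } else {
    p <- wc / proto
    z_zero <- 1
  }
  zp <- (2 * fs + p) / (2 * fs - p) # bilinear poles
  # group into conjugate-pair biquads (odd order: one real pole)
  used <- rep(FALSE, order)
  sections <- list()
  for (i in seq_len(order)) {
    if (used[i]) next
    if (abs(Im(zp[i])) < 1e-12) {
      a <- c(1, -Re(zp[i]))
      b <- c(1, -z_zero)
      used[i] <- TRUE
    } else {
      j <- which(!used & abs(zp - Conj(zp[i])) < 1e-9)[1]
      a <- c(1, -2 * Re(zp[i]), Mod(zp[i])^2)
      b <- c(1, -2 * z_zero, 1)
      used[c(i, j)] <- TRUE
    }
    sections[[length(sections) + 1]] <- list(b = b, a = a)
  }
  # normalize so gain is 1 at DC (low) / Nyquist (high)
  zref <- if (type == "low") 1 else -1
  for (s in seq_along(sections)) {
    sec <- sections[[s]]
    zr <- zref^(0:(length(sec$b) - 1))
    g <- sum(sec$b * zr) / sum(sec$a * zr)
    sections[[s]]$b <- sec$b / g
  }
  sections
}

# Second-order IIR notch (RBJ biquad).
notch_sos <- function(f0, fs, q) {
  w0 <- 2 * pi * f0 / fs
  alpha <- sin(w0) / (2 * q)
  a0 <- 1 + alpha
  list(list(b = c(1, -2 * cos(w0), 1) / a0,
            a = c(1, -2 * cos(w0), 1 - alpha) / a0))
}

apply_sos <- function(x, sections) {
  for (sec in sections) x <- as.numeric(signal::filter(sec$b, sec$a, x))
  x
}

# Forward(-backward) cascade application.
apply_filter <- function(x, sections, two_pass = TRUE) {
  y <- apply_sos(x, sections)
  if (two_pass) y <- rev(apply_sos(rev(y), sections))
  y
}

#' Demean, notch and band-limit an epoch set (zero-phase)
#'
#' Per trial and channel: remove the mean, notch at `notch_freq`, then
#' high-pass and low-pass Butterworth, each applied forward and backward so
#' the net phase shift is zero.
#'
#' @param epochs An `epoch_set`.
#' @param spec A [filter_spec()].
#' @return A filtered `epoch_set`.
#' @export
condition_signal <- function(epochs, spec = filter_spec()) {
  stopifnot(inherits(epochs, "epoch_set"))
  if (epochs$fs <= 2 * spec$lp_cut) {
    abort("Sampling rate must exceed twice the low-pass cutoff.",
          class = "alphasync_bad_filter")
  }
  if (!all(is.finite(epochs$data))) {
    abort("Non-finite samples in input.", class = "alphasync_bad_data")
  }
  nt <- notch_sos(spec$notch_freq, epochs$fs, spec$notch_q)
  hp <- butter_sos(spec$hp_order, spec$hp_cut, epochs$fs, "high")
  lp <- butter_sos(spec$lp_order, spec$lp_cut, epochs$fs, "low")
  d <- epochs$data
  for (k in seq_len(dim(d)[1])) {
    for (ch in seq_len(dim(d)[2])) {
      x <- d[k, ch, ]
      x <- x - mean(x)
      x <- apply_filter(x, nt, spec$two_pass)
      x <- apply_filter(x, hp, spec$two_pass)
      x <- apply_filter(x, lp, spec$two_pass)
      d[k, ch, ] <- x
    }
  }
  epochs$data <- d
  epochs
}

#' Reject trials with large EOG deflections
#'
#' A trial is excluded when the peak absolute amplitude of any demeaned EOG
#' channel strictly exceeds `threshold` (a deflection of exactly the
#' threshold is kept).
#'
#' @param epochs An `epoch_set`.
#' @param eog_channels Channel names treated as EOG.
#' @param threshold Microvolts (default 50).
#' @return Logical keep-mask of length n_trials; the data are untouched.
#' @export
reject_eog_trials <- function(epochs, eog_channels, threshold = 50) {
  check_channels(eog_channels, epochs$channel_names)
  idx <- match(eog_channels, epochs$channel_names)
  n_tr <- dim(epochs$data)[1]
  keep <- vapply(seq_len(n_tr), function(k) {
    pk <- max(vapply(idx, function(ch) {
      x <- epochs$data[k, ch, ]
      max(abs(x - mean(x)))
    }, numeric(1)))
    pk <= threshold
  }, logical(1))
  keep
}

#' Repair bad channels by inverse-distance neighbor averaging
#'
#' Each bad channel is replaced by the inverse-distance-weighted mean of
#' its good montage neighbors; good channels are unchanged.
#'
#' @param epochs An `epoch_set`.
#' @param bad_channels Channel names to repair.
#' @param montage Montage (defaults to the one attached to `epochs`).
#' @return A repaired `epoch_set`.
#' @export
repair_channels <- function(epochs, bad_channels, montage = NULL) {
  montage <- montage %||% epochs$montage
  if (is.null(montage)) abort("No montage available.",
                              class = "alphasync_no_montage")
  check_channels(bad_channels, epochs$channel_names)
  pos <- montage$positions
  out <- epochs$data
  for (bad in bad_channels) {
    nb <- setdiff(montage$neighbors[[bad]], bad_channels)
    nb <- intersect(nb, epochs$channel_names)
    if (length(nb) == 0) {
      abort(paste0("Channel ", bad, " has no good neighbors; unrepairable."),
            class = "alphasync_unrepairable")
    }
    p0 <- pos[pos$channel == bad, c("x", "y")]
    d <- vapply(nb, function(ch) {
      p <- pos[pos$channel == ch, c("x", "y")]
      sqrt((p$x - p0$x)^2 + (p$y - p0$y)^2)
    }, numeric(1))
    w <- (1 / d) / sum(1 / d)
    bi <- match(bad, epochs$channel_names)
    ni <- match(nb, epochs$channel_names)
    for (k in seq_len(dim(out)[1])) {
      out[k, bi, ] <- drop(w %*% epochs$data[k, ni, , drop = TRUE])
    }
  }
  epochs$data <- out
  epochs
}

#' Mirror-pad epochs against edge artifacts, and trim back
#'
#' `epoch_mirror()` extends every epoch with a full time-reversed copy at
#' both edges (length L becomes 3L); `epoch_trim()` removes the reflected
#' edges (or crops to a `window` in ms), restoring exactly the original
#' time axis. Mirror followed by trim is the identity on the data; a
#' wavelet transform applied in between sees no epoch edges.
#'
#' @param epochs An `epoch_set`.
#' @return `epoch_mirror()`: a mirrored `epoch_set` carrying the original
#'   span as an attribute.
#' @export
epoch_mirror <- function(epochs) {
  stopifnot(inherits(epochs, "epoch_set"))
  d <- epochs$data
  L <- dim(d)[3]
  rev_idx <- rev(seq_len(L))
  out <- array(0, dim = c(dim(d)[1], dim(d)[2], 3 * L))
  out[, , seq_len(L)] <- d[, , rev_idx, drop = FALSE]
  out[, , L + seq_len(L)] <- d
  out[, , 2 * L + seq_len(L)] <- d[, , rev_idx, drop = FALSE]
  dimnames(out) <- list(NULL, epochs$channel_names, NULL)
  res <- epochs
  res$data <- out
  res$t0 <- epochs$t0 - L / epochs$fs
  attr(res, "mirror_span") <- c(epochs$t0, epochs$t0 + (L - 1) / epochs$fs)
  attr(res, "mirror_len") <- L
  res
}

#' @rdname epoch_mirror
#' @param x A mirrored `epoch_set` or a `spectral_tensor` computed from
#'   one.
#' @param window Optional `c(start, end)` ms window to crop to instead of
#'   the full original axis (half-open, `[start, end)`).
#' @export
epoch_trim <- function(x, window = NULL) {
  span <- attr(x, "mirror_span")
  tv <- time_axis(x)
  if (!is.null(window)) {
    idx <- window_samples(tv, window)
  } else if (!is.null(span)) {
    idx <- which(tv >= span[1] - 1e-9 & tv <= span[2] + 1e-9)
  } else {
    abort("Not a mirrored object and no window given.",
          class = "alphasync_bad_trim")
  }
  if (length(idx) == 0) abort("Trim window outside data.",
                              class = "alphasync_bad_trim")
  if (inherits(x, "epoch_set")) {
    x$data <- x$data[, , idx, drop = FALSE]
  } else {
    x$coeffs <- x$coeffs[, , , idx, drop = FALSE]
  }
  x$t0 <- tv[idx[1]]
  attr(x, "mirror_span") <- NULL
  attr(x, "mirror_len") <- NULL
  x
}

#' Hjorth surface-Laplacian reference
#'
#' Each channel is replaced by itself minus the mean of its montage
#' neighbors, a local spatial filter that mitigates volume conduction.
#'
#' @param epochs An `epoch_set`.
#' @param montage Montage (defaults to the one attached to `epochs`).
#' @return A re-referenced `epoch_set`.
#' @export
hjorth_laplacian <- function(epochs, montage = NULL) {
  montage <- montage %||% epochs$montage
  if (is.null(montage)) abort("No montage available.",
                              class = "alphasync_no_montage")
  chans <- epochs$channel_names
  nb_idx <- lapply(chans, function(ch) {
    nb <- intersect(montage$neighbors[[ch]] %||% character(), chans)
    if (length(nb) == 0) {
      abort(paste0("Channel ", ch, " has no montage neighbors."),
            class = "alphasync_no_neighbors")
    }
    match(nb, chans)
  })
  d <- epochs$data
  out <- d
  for (ci in seq_along(chans)) {
    idx <- nb_idx[[ci]]
    nbm <- apply(d[, idx, , drop = FALSE], c(1, 3), mean)
    out[, ci, ] <- d[, ci, ] - nbm
  }
  epochs$data <- out
  epochs
}

#' Select trials for analysis
#'
#' The default rule keeps validly cued trials answered correctly — the
#' trial set all phase-coupling analyses run on.
#'
#' @param trials A trial tibble with `valid` and `correct` columns.
#' @param rule `"valid-correct"` (default), `"valid"`, `"correct"`,
#'   `"all"`, or a predicate function of the trial tibble returning a
#'   logical vector.
#' @return Logical keep-mask over trials.
#' @export
select_trials <- function(trials, rule = "valid-correct") {
  mask <- if (is.function(rule)) {
    rule(trials)
  } else {
    switch(rule,
      "valid-correct" = trials$valid & trials$correct,
      "valid" = trials$valid,
      "correct" = trials$correct,
      "all" = rep(TRUE, nrow(trials)),
      abort("Unknown selection rule.", class = "alphasync_bad_rule")
    )
  }
  if (!any(mask)) {
    abort("Selection rule keeps no trials.", class = "alphasync_empty_selection")
  }
  mask
}
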