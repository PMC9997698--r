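# Unit-length phase vectors of one channel: coeffs / |coeffs|.
phase_units <- function(tensor, channel) {
  ci <- match(channel, tensor$channel_names)
  if (is.na(ci)) {
    abort(paste0("Channel ", channel, " not in tensor."),
          class = "alphasync_unknown_channel")
  }
  x <- tensor$coeffs[, ci, , , drop = FALSE]
  dim(x) <- dim(x)[-2]
  x / Mod(x)
}

# Unit phase-difference array for a channel pair: trials x freqs x samples.
pair_units <- function(tensor, pair) {
  phase_units(tensor, pair[1]) * Conj(phase_units(tensor, pair[2]))
}

resolve_trials <- function(tensor, trials) {
  n <- dim(tensor$coeffs)[1]
  if (is.null(trials)) return(seq_len(n))
  if (is.logical(trials)) {
    stopifnot(length(trials) == n)
    return(which(trials))
  }
  idx <- match(trials, tensor$trial_ids)
  if (anyNA(idx)) abort("Unknown trial ids.", class = "alphasync_bad_trials")
  idx
}

#' Cross-trial phase-locking value for one electrode pair
#'
#' The modulus of the mean complex unit-length phase difference across
#' trials, per frequency and time sample:
#' `PLV(x, y) = | (1/n) sum_k exp(i (phi_x(k) - phi_y(k))) |`.
#' PLV is 1 for a constant phase difference and tends to 0 for random
#' phases; its positive small-sample bias depends on `n`, which is
#' reported alongside.
#'
#' @param tensor A `spectral_tensor`.
#' @param pair Length-2 channel name vector.
#' @param trials Optional trial subset: logical mask over tensor rows or
#'   trial ids. At least 2 trials.
#' @return Tibble with `frequency`, `time_ms`, `plv`, `n_trials`.
#' @export
plv_cross_trial <- function(tensor, pair, trials = NULL) {
  idx <- resolve_trials(tensor, trials)
  if (length(idx) < 2) {
    abort("PLV undefined for fewer than 2 trials.",
          class = "alphasync_too_few_trials")
  }
  U <- pair_units(tensor, pair)[idx, , , drop = FALSE]
  m <- colMeans(U) # freqs x samples complex
  tv <- time_axis(tensor) * 1000
  tibble::tibble(
    frequency = rep(tensor$freqs, times = length(tv)),
    time_ms = rep(tv, each = length(tensor$freqs)),
    plv = as.vector(Mod(m)),
    n_trials = length(idx)
  )
}

#' Network PLV time courses per attention condition
#'
#' Cross-trial PLV for every individual electrode pair of the FM-PL and
#' FM-PR frontoparietal networks (3 x 3 pairs each), then averaged over
#' the 9 pairs — the modulus is taken per pair *before* averaging.
#'
#' @param tensor A `spectral_tensor` containing all EOI channels.
#' @param trials Trial tibble with `trial_id` and `attended_side`, aligned
#'   with the tensor via trial ids.
#' @param scheme An [eoi_scheme()].
#' @param freqs Optional frequency subset (Hz values present in the
#'   tensor).
#' @return Tibble: `network` (`FM-PL`/`FM-PR`), `condition`
#'   (`attend-left`/`attend-right`), `frequency`, `time_ms`, `plv`,
#'   `n_trials`.
#' @export
network_plv <- function(tensor, trials, scheme = eoi_scheme(), freqs = NULL) {
  check_channels(c(scheme$fm, scheme$pl, scheme$pr), tensor$channel_names,
                 "EOI channel")
  fidx <- if (is.null(freqs)) seq_along(tensor$freqs) else {
    m <- match(round(freqs, 6), round(tensor$freqs, 6))
    if (anyNA(m)) abort("Requested freqs not in tensor.",
                        class = "alphasync_bad_freqs")
    m
  }
  tv <- time_axis(tensor) * 1000
  nets <- list(`FM-PL` = scheme$pl, `FM-PR` = scheme$pr)
  conds <- list(`attend-left` = "left", `attend-right` = "right")
  out <- list()
  cond_idx <- lapply(conds, function(side) {
    ids <- trials$trial_id[trials$attended_side == side]
    idx <- resolve_trials(tensor, ids)
    if (length(idx) < 2) {
      abort(paste0("Condition attend-", side, " has < 2 trials."),
            class = "alphasync_too_few_trials")
    }
    idx
  })
  for (nn in names(nets)) {
    pairs <- expand.grid(f = scheme$fm, p = nets[[nn]],
                         stringsAsFactors = FALSE)
    acc <- lapply(conds, function(...) 0)
    for (pi2 in seq_len(nrow(pairs))) {
      U <- pair_units(tensor, c(pairs$f[pi2], pairs$p[pi2]))
      for (cn in names(conds)) {
        idx <- cond_idx[[cn]]
        acc[[cn]] <- acc[[cn]] +
          Mod(colMeans(U[idx, fidx, , drop = FALSE]))
      }
    }
    for (cn in names(conds)) {
      plv <- acc[[cn]] / nrow(pairs)
      out[[paste(nn, cn)]] <- tibble::tibble(
        network = nn, condition = cn,
        frequency = rep(tensor$freqs[fidx], times = length(tv)),
        time_ms = rep(tv, each = length(fidx)),
        plv = as.vector(plv), n_trials = length(cond_idx[[cn]])
      )
    }
  }
  dplyr::bind_rows(out)
}

#' Collapse network-by-condition PLV into contralateral / ipsilateral
#'
#' Contralateral = mean of (FM-PR | attend-left) and (FM-PL |
#' attend-right); ipsilateral = mean of (FM-PL | attend-left) and (FM-PR |
#' attend-right).
#'
#' @param series Output of [network_plv()]; both networks and both
#'   conditions must be present.
#' @return Tibble: `laterality` (`contra`/`ipsi`), `frequency`, `time_ms`,
#'   `plv`.
#' @export
collapse_contra_ipsi <- function(series) {
  need <- expand.grid(network = c("FM-PL", "FM-PR"),
                      condition = c("attend-left", "attend-right"))
  have <- unique(series[, c("network", "condition")])
  if (nrow(dplyr::inner_join(need, have,
                             by = c("network", "condition"))) < 4) {
    abort("Series must contain both networks x both conditions.",
          class = "alphasync_incomplete_series")
  }
  series |>
    dplyr::mutate(laterality = dplyr::case_when(
      (.data$network == "FM-PR" & .data$condition == "attend-left") |
        (.data$network == "FM-PL" & .data$condition == "attend-right") ~ "contra",
      TRUE ~ "ipsi"
    )) |>
    dplyr::group_by(.data$laterality, .data$frequency, .data$time_ms) |>
    dplyr::summarise(plv = mean(.data$plv), .groups = "drop")
}

#' Average a time-resolved series over analysis windows
#'
#' Windows are half-open `[start, end)` in ms; samples are assigned by
#' their timestamps. The value is additionally averaged over frequency
#' when several frequencies are present (the two means commute).
#'
#' @param df Tibble with a `time_ms` column and a value column, e.g.
#'   [collapse_contra_ipsi()] output.
#' @param windows List of `c(start, end)` ms pairs; names become window
#'   labels (defaults to `"start-end"`).
#' @param value Name of the value column (default `"plv"`).
#' @param freq_average Average over the `frequency` column if present.
#' @return Tibble with a `window` column replacing `time_ms` (and
#'   `frequency` if averaged).
#' @export
window_average <- function(df, windows, value = "plv", freq_average = TRUE) {
  if (!is.list(windows)) windows <- list(windows)
  if (is.null(names(windows)) || any(names(windows) == "")) {
    names(windows) <- vapply(windows, function(w)
      paste0(w[1], "-", w[2]), character(1))
  }
  out <- lapply(names(windows), function(wn) {
    w <- windows[[wn]]
    sub <- dplyr::filter(df, .data$time_ms >= w[1] - 1e-9,
                         .data$time_ms < w[2] - 1e-9)
    if (nrow(sub) == 0) {
      abort(paste0("Window ", wn, " contains no samples."),
            class = "alphasync_empty_window")
    }
    grp <- setdiff(names(sub), c("time_ms", value,
                                 if (freq_average) "frequency"))
    sub |>
      dplyr::group_by(dplyr::across(dplyr::all_of(grp))) |>
      dplyr::summarise(!!value := mean(.data[[value]]), .groups = "drop") |>
      dplyr::mutate(window = wn, .before = 1)
  })
  dplyr::bind_rows(out)
}

#' Five consecutive 200-ms cue-to-target windows
#'
#' The cue-locked analysis interval 500-1500 ms after cue onset, split
#' into nonoverlapping 200-ms bins.
#' @return Named list of `c(start, end)` ms pairs.
#' @export
cue_windows <- function() {
  starts <- seq(500, 1300, by = 200)
  out <- lapply(starts, function(s) c(s, s + 200))
  names(out) <- vapply(out, function(w) paste0(w[1], "-", w[2]), character(1))
  out
}

#' Pretarget and post-target windows
#' @return Named list: `pretarget` = `[-200, 0)` ms, `posttarget` =
#'   `[200, 400)` ms.
#' @export
target_windows <- function() {
  list(pretarget = c(-200, 0), posttarget = c(200, 400))
}

#' Cross-time phase clustering (ISPC) per trial
#'
#' The PLV statistic with the average running over time samples within a
#' window instead of over trials, giving one connectivity scalar per trial
#' — the single-trial feature the decoder consumes. Values are averaged
#' over the supplied frequencies.
#'
#' @param tensor A `spectral_tensor`.
#' @param pair Length-2 channel name vector.
#' @param window `c(start, end)` ms (half-open), at least 2 samples.
#' @param freqs Optional frequency subset (Hz).
#' @param freq_average Average over frequencies (default) or return one
#'   row per frequency.
#' @return Tibble with `trial_id` and `ispc` (plus `frequency` when not
#'   averaged).
#' @export
plv_cross_time <- function(tensor, pair, window, freqs = NULL,
                           freq_average = TRUE) {
  tv <- time_axis(tensor)
  sidx <- window_samples(tv, window)
  if (length(sidx) < 2) {
    abort("Window contains fewer than 2 samples.",
          class = "alphasync_window_too_short")
  }
  fidx <- if (is.null(freqs)) seq_along(tensor$freqs) else {
    m <- match(round(freqs, 6), round(tensor$freqs, 6))
    if (anyNA(m)) abort("Requested freqs not in tensor.",
                        class = "alphasync_bad_freqs")
    m
  }
  U <- pair_units(tensor, pair)[, fidx, sidx, drop = FALSE]
  # mean over samples (dim 3) -> trials x freqs
  m <- Mod(apply(U, c(1, 2), mean))
  if (freq_average) {
    tibble::tibble(trial_id = tensor$trial_ids, ispc = rowMeans(m))
  } else {
    tibble::tibble(
      trial_id = rep(tensor$trial_ids, times = length(fidx)),
      frequency = rep(tensor$freqs[fidx], each = length(tensor$trial_ids)),
      ispc = as.vector(m)
    )
  }
}

#' @rdname plv_cross_time
#' @export
ispc <- plv_cross_time

#' Phase linearity measurement (PLM) per trial
#'
#' The fraction of the interferometric signal's spectral power within a
#' narrow band around 0 Hz: with `z(t) = exp(i dphi(t))` the phase
#' difference between the pair, `PLM = sum_{|f| <= B} S_z(f) / sum_f
#' S_z(f)`. High when the phase difference evolves slowly (near-linear
#' phase), in [0, 1].
#'
#' @param tensor A `spectral_tensor`.
#' @param pair Length-2 channel name vector.
#' @param freq Analysis frequency (Hz; the nearest tensor frequency is
#'   used).
#' @param bandwidth Half-bandwidth B around 0 Hz, Hz (default 1).
#' @return Tibble with `trial_id`, `plm`.
#' @export
plm <- function(tensor, pair, freq = NULL, bandwidth = 1) {
  fidx <- if (is.null(freq)) 1L else which.min(abs(tensor$freqs - freq))
  U <- pair_units(tensor, pair)[, fidx, , drop = FALSE]
  n <- dim(U)[3]
  if (n < 8) abort("Too few samples for spectral estimation.",
                   class = "alphasync_too_short")
  fax <- (seq_len(n) - 1) * tensor$fs / n
  fax[fax > tensor$fs / 2] <- fax[fax > tensor$fs / 2] - tensor$fs
  inband <- abs(fax) <= bandwidth
  vals <- vapply(seq_len(dim(U)[1]), function(k) {
    z <- U[k, 1, ]
    if (all(!is.finite(z))) {
      abort("Degenerate input to PLM.", class = "alphasync_bad_data")
    }
    S <- Mod(fft(z))^2
    sum(S[inband]) / sum(S)
  }, numeric(1))
  tibble::tibble(trial_id = tensor$trial_ids, plm = vals)
}
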