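#' Parieto-occipital alpha power around the individual alpha frequency
#'
#' Morlet power (5 cycles) at `{IAF-1, IAF, IAF+1}` Hz, averaged over the
#' three frequencies and over each side's power-EOI channels.
#'
#' @param epochs An `epoch_set` (cue-locked, ideally spanning -1.5 to 3 s).
#' @param iaf An [estimate_iaf()] result or a numeric IAF in Hz.
#' @param eois A [power_eois()] electrode set.
#' @param n_cycles Wavelet cycles.
#' @return Tibble: `trial_id`, `side` (`pl`/`pr`), `time_ms`, `power`
#'   (uV^2, wavelet analysis gain included; only ratios are
#'   claim-bearing).
#' @export
alpha_power <- function(epochs, iaf, eois = power_eois(), n_cycles = 5) {
  f0 <- if (inherits(iaf, "iaf_estimate")) iaf$iaf else iaf
  if (f0 - 1 <= 0) abort("IAF - 1 Hz must be positive.",
                         class = "alphasync_bad_iaf")
  chans <- c(eois$pl, eois$pr)
  check_channels(chans, epochs$channel_names, "power EOI channel")
  bank <- morlet_bank(c(f0 - 1, f0, f0 + 1), n_cycles = n_cycles,
                      fs = epochs$fs)
  tens <- morlet_transform(epochs, bank, channels = chans)
  pw <- Mod(tens$coeffs)^2
  tv <- time_axis(tens) * 1000
  out <- lapply(c(pl = "pl", pr = "pr"), function(side) {
    ci <- match(eois[[side]], tens$channel_names)
    # mean over channels (dim 2) and freqs (dim 3): trials x samples
    m <- apply(pw[, ci, , , drop = FALSE], c(1, 4), mean)
    tibble::tibble(
      trial_id = rep(tens$trial_ids, times = length(tv)),
      side = side,
      time_ms = rep(tv, each = length(tens$trial_ids)),
      power = as.vector(m)
    )
  })
  dplyr::bind_rows(out)
}

#' Interhemispheric alpha-power lateralization index
#'
#' `LI = (a_PR - a_PL) / mean(a_PL, a_PR)`: negative when alpha is more
#' prominent over the left hemisphere, positive for the opposite pattern,
#' bounded in [-2, 2]. Attention to the right hemifield should yield
#' larger LI than attention to the left (contralateral alpha
#' suppression).
#'
#' @param power_pl,power_pr Alpha power over the left / right EOI sets
#'   (numeric vectors of equal length; any shape, applied elementwise).
#' @return Numeric LI of the same length.
#' @examples
#' lateralization_index(1, 3) # 1.0
#' @export
lateralization_index <- function(power_pl, power_pr) {
  tot <- (power_pl + power_pr) / 2
  if (any(tot <= 0)) {
    abort("Zero or negative total power; LI undefined.",
          class = "alphasync_zero_power")
  }
  (power_pr - power_pl) / tot
}

#' Trial-by-time lateralization-index series
#'
#' Applies [lateralization_index()] to the per-trial, per-sample power of
#' the two hemispheres.
#'
#' @param power Output of [alpha_power()].
#' @return Tibble: `trial_id`, `time_ms`, `li`.
#' @export
li_series <- function(power) {
  wide <- tidyr::pivot_wider(power, names_from = "side",
                             values_from = "power")
  tibble::tibble(
    trial_id = wide$trial_id, time_ms = wide$time_ms,
    li = lateralization_index(wide$pl, wide$pr)
  )
}

#' Condition-wise lateralization-index summary
#'
#' Per-condition mean and SEM of LI over trials, time-resolved, plus the
#' mean over an analysis window (default the 500-1500 ms cue-to-target
#' interval). With planted contralateral alpha suppression,
#' `LI(attend-right) > LI(attend-left)`.
#'
#' @param li Tibble from [li_series()].
#' @param trials Trial tibble with `trial_id`, `attended_side`.
#' @param window `c(start, end)` ms for the window summary.
#' @return List of class `li_summary`: `timecourse` (condition x time
#'   tibble with `mean`, `sem`, `n`), `window` (per-condition window
#'   means), `delta` (window mean LI right minus left).
#' @export
li_by_condition <- function(li, trials, window = c(500, 1500)) {
  df <- dplyr::inner_join(li, trials[, c("trial_id", "attended_side")],
                          by = "trial_id")
  counts <- table(factor(df$attended_side, levels = c("left", "right")))
  if (any(counts == 0)) {
    abort("A condition has zero trials.", class = "alphasync_empty_condition")
  }
  tc <- df |>
    dplyr::group_by(.data$attended_side, .data$time_ms) |>
    dplyr::summarise(mean = mean(.data$li),
                     sem = sd(.data$li) / sqrt(dplyr::n()),
                     n = dplyr::n(), .groups = "drop")
  per_trial <- df |>
    dplyr::filter(.data$time_ms >= window[1] - 1e-9,
                  .data$time_ms < window[2] - 1e-9) |>
    dplyr::group_by(.data$attended_side, .data$trial_id) |>
    dplyr::summarise(li = mean(.data$li), .groups = "drop")
  win <- per_trial |>
    dplyr::group_by(.data$attended_side) |>
    dplyr::summarise(mean = mean(.data$li),
                     sem = sd(.data$li) / sqrt(dplyr::n()),
                     n = dplyr::n(), .groups = "drop")
  delta <- win$mean[win$attended_side == "right"] -
    win$mean[win$attended_side == "left"]
  structure(list(timecourse = tc, window = win, delta = delta,
                 window_ms = window),
            class = "li_summary")
}

#' @export
print.li_summary <- function(x, ...) {
  cat(sprintf(
    "<li_summary> window %g-%g ms: LI(right) - LI(left) = %.4f\n",
    x$window_ms[1], x$window_ms[2], x$delta))
  print(x$window)
  invisible(x)
}
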