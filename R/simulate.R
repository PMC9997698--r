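#' Simulation configuration for synthetic covert-attention EEG
#'
#' Bundles every tunable of the generator: trial design (cue validity,
#' jittered cue-to-target interval), behavior (hit rates for attended and
#' unattended targets), and the EEG model (individual alpha frequency,
#' von Mises frontoparietal phase coupling, parieto-occipital power
#' lateralization on a 1/f background).
#'
#' The EEG model: every trial carries 1/f background noise on all channels;
#' parieto-occipital channels additionally carry an alpha oscillation at
#' `iaf` whose amplitude is `alpha_amp_attend` on the hemisphere
#' *contralateral* to the attended side and `alpha_amp_unattend`
#' ipsilateral (the classic contralateral suppression when
#' `alpha_amp_attend < alpha_amp_unattend`). Fronto-medial channels carry an
#' alpha component that serves as the phase reference; each parietal
#' cluster's phase lag to it is drawn per trial from a von Mises
#' distribution with concentration `kappa_contra` (cluster contralateral to
#' attention) or `kappa_ipsi` (ipsilateral), so the cross-trial PLV of each
#' frontoparietal network converges to the Bessel ratio I1(k)/I0(k).
#' `sample_jitter_kappa` optionally adds i.i.d. per-sample von Mises jitter
#' to the parietal phases for cross-time (ISPC) coupling control; it
#' defaults to `Inf` (off) because wavelet temporal smoothing attenuates
#' such jitter.
#'
#' @param n_trials Trials per simulated participant (default 290).
#' @param fs Sampling rate, Hz.
#' @param cue_validity Probability that the target appears at the cued side.
#' @param isi_center,isi_halfrange Cue-to-target interval: uniform on
#'   `isi_center +/- isi_halfrange` (ms).
#' @param iaf Individual alpha frequency, Hz.
#' @param kappa_contra,kappa_ipsi Von Mises concentrations of the
#'   frontal-parietal phase lag for the contralateral / ipsilateral network.
#' @param alpha_amp_attend,alpha_amp_unattend Parieto-occipital alpha
#'   amplitude (uV) contralateral / ipsilateral to the attended side.
#' @param alpha_amp_frontal Fronto-medial alpha amplitude (uV).
#' @param noise_exponent 1/f slope of the background (power ~ f^-exponent).
#' @param noise_amp Background RMS amplitude, uV.
#' @param hit_rate_attended,hit_rate_unattended P(correct) on valid /
#'   invalid trials.
#' @param sample_jitter_kappa Per-sample phase-jitter concentration
#'   (`Inf` = no jitter).
#' @param coupling_window Optional `c(start, end)` ms window outside which
#'   the parietal clusters decohere from the frontal reference (used to
#'   plant time-limited coupling, e.g. post-target only). `NULL` couples the
#'   whole epoch.
#' @param epoch_start,epoch_end Epoch span in seconds around the lock.
#' @param seed Integer seed; identical seed + config gives bit-identical
#'   output.
#' @param montage Montage (defaults to [montage_1010()]).
#' @return A list of class `sim_config`.
#' @examples
#' cfg <- sim_config(n_trials = 20, seed = 1)
#' trials <- design_trials(cfg)
#' @export
sim_config <- function(n_trials = 290, fs = 500, cue_validity = 0.75,
                       isi_center = 2000, isi_halfrange = 500,
                       iaf = 10, kappa_contra = 2, kappa_ipsi = 0.5,
                       alpha_amp_attend = 7, alpha_amp_unattend = 10,
                       alpha_amp_frontal = 5,
                       noise_exponent = 1, noise_amp = 5,
                       hit_rate_attended = 0.68, hit_rate_unattended = 0.46,
                       sample_jitter_kappa = Inf,
                       coupling_window = NULL,
                       epoch_start = -1.5, epoch_end = 3,
                       seed = NULL, montage = NULL) {
  if (cue_validity < 0 || cue_validity > 1) {
    abort("cue_validity must be in [0, 1].", class = "alphasync_bad_config")
  }
  if (kappa_contra < 0 || kappa_ipsi < 0) {
    abort("kappa_* must be >= 0.", class = "alphasync_bad_config")
  }
  if (fs <= 0) abort("fs must be positive.", class = "alphasync_bad_config")
  if (isi_halfrange >= isi_center) {
    abort("isi_halfrange must be smaller than isi_center.",
          class = "alphasync_bad_config")
  }
  rates <- c(hit_rate_attended, hit_rate_unattended)
  if (any(rates < 0 | rates > 1)) {
    abort("hit rates must be probabilities.", class = "alphasync_bad_config")
  }
  structure(as.list(environment()), class = "sim_config")
}

#' Generate the trial design of a cueing session
#'
#' Attended sides are balanced to within one trial and randomly ordered;
#' the target appears at the cued side with probability `cue_validity`; the
#' cue-to-target interval is drawn uniformly on
#' `isi_center +/- isi_halfrange`.
#'
#' @param config A [sim_config()].
#' @return A tibble with `trial_id`, `attended_side`, `target_side`,
#'   `valid`, `isi` (ms). Response columns are added by
#'   [simulate_behavior()].
#' @export
design_trials <- function(config) {
  n <- config$n_trials
  if (n < 2) abort("Need at least 2 trials.", class = "alphasync_bad_design")
  with_seed(child_seed(config$seed, 1L), {
    sides <- sample(rep(c("left", "right"), length.out = n))
    same <- runif(n) < config$cue_validity
    target <- ifelse(same, sides, ifelse(sides == "left", "right", "left"))
    isi <- runif(n, config$isi_center - config$isi_halfrange,
                 config$isi_center + config$isi_halfrange)
    tibble::tibble(
      trial_id = seq_len(n),
      attended_side = sides,
      target_side = target,
      valid = sides == target,
      isi = isi
    )
  })
}

#' Simulate detection/discrimination responses
#'
#' Detection and discrimination are conditionally independent given the
#' attention condition, each with probability `sqrt(rate)` so that their
#' conjunction (a correct trial) occurs at the configured rate:
#' `hit_rate_attended` on valid trials, `hit_rate_unattended` on invalid
#' ones. `correct` is recomputed as `detected & discriminated`.
#'
#' @param trials Output of [design_trials()].
#' @param config A [sim_config()].
#' @return `trials` with `detected`, `discriminated`, `correct` columns.
#' @export
simulate_behavior <- function(trials, config) {
  rates <- c(config$hit_rate_attended, config$hit_rate_unattended)
  if (any(rates < 0 | rates > 1)) {
    abort("hit rates must be in [0, 1].", class = "alphasync_bad_config")
  }
  with_seed(child_seed(config$seed, 2L), {
    rate <- ifelse(trials$valid, config$hit_rate_attended,
                   config$hit_rate_unattended)
    p_each <- sqrt(rate)
    detected <- runif(nrow(trials)) < p_each
    discriminated <- runif(nrow(trials)) < p_each
    dplyr::mutate(trials,
      detected = detected,
      discriminated = discriminated,
      correct = detected & discriminated
    )
  })
}

# 1/f noise: channels x samples matrix, RMS = amp, power ~ f^-exponent.
onef_noise <- function(n_chan, n_samp, fs, exponent, amp) {
  f <- seq(0, fs, length.out = n_samp + 1)[seq_len(n_samp)]
  f[f > fs / 2] <- fs - f[f > fs / 2] # two-sided axis
  gain <- c(0, abs(f[-1])^(-exponent / 2))
  out <- matrix(0, n_chan, n_samp)
  for (ch in seq_len(n_chan)) {
    spec <- (rnorm(n_samp) + 1i * rnorm(n_samp)) * gain
    x <- Re(fft(spec, inverse = TRUE)) / n_samp
    out[ch, ] <- x / sd(x) * amp
  }
  out
}

# Smooth 0->1->0 gate over a half-open [start, end) ms window with `ramp` ms
# cosine flanks, evaluated on a time axis in seconds.
coupling_gate <- function(time_s, window_ms, ramp = 100) {
  t <- time_s * 1000
  up <- pmin(pmax((t - (window_ms[1] - ramp)) / ramp, 0), 1)
  dn <- pmin(pmax(((window_ms[2]) - t) / ramp, 0), 1)
  g <- pmin(up, dn)
  0.5 - 0.5 * cos(pi * g) # cosine-shaped flank
}

#' Simulate multichannel EEG epochs for a designed session
#'
#' See [sim_config()] for the generative model. Epochs span
#' `config$epoch_start` to `config$epoch_end` seconds around the lock
#' event.
#'
#' @param trials Trial table from [design_trials()] (behavior columns not
#'   required).
#' @param config A [sim_config()].
#' @param lock `"cue"` or `"target"`; the generative model is identical,
#'   only the container's lock label differs (coupling windows are given
#'   relative to the lock).
#' @return An `epoch_set` with the montage attached.
#' @export
simulate_epochs <- function(trials, config, lock = c("cue", "target")) {
  lock <- match.arg(lock)
  montage <- config$montage %||% montage_1010()
  chans <- montage$positions$channel
  fs <- config$fs
  n_samp <- round((config$epoch_end - config$epoch_start) * fs)
  if (n_samp < fs) {
    abort("Epoch span shorter than one second of data.",
          class = "alphasync_bad_config")
  }
  tvec <- config$epoch_start + (seq_len(n_samp) - 1) / fs
  n_tr <- nrow(trials)
  scheme <- eoi_scheme()
  pos <- montage$positions
  post <- pos$y <= -1.7 # parieto-occipital rows (P, PO, O)
  left_set <- pos$channel[post & pos$x < 0]
  right_set <- pos$channel[post & pos$x > 0]
  fm_set <- scheme$fm
  omega <- 2 * pi * config$iaf
  gate <- if (is.null(config$coupling_window)) {
    rep(1, n_samp)
  } else {
    coupling_gate(tvec, config$coupling_window)
  }

  with_seed(child_seed(config$seed, 3L), {
    arr <- array(0, dim = c(n_tr, length(chans), n_samp))
    for (k in seq_len(n_tr)) {
      sig <- onef_noise(length(chans), n_samp, fs, config$noise_exponent,
                        config$noise_amp)
      rownames(sig) <- chans
      attended <- trials$attended_side[k]
      contra_hemi <- if (attended == "left") "right" else "left"
      theta_f <- runif(1, -pi, pi)
      # per-trial frontoparietal lags
      lag <- list(
        left = rvonmises(1, 0, if (contra_hemi == "left")
          config$kappa_contra else config$kappa_ipsi),
        right = rvonmises(1, 0, if (contra_hemi == "right")
          config$kappa_contra else config$kappa_ipsi)
      )
      amp <- list(
        left = if (contra_hemi == "left") config$alpha_amp_attend
               else config$alpha_amp_unattend,
        right = if (contra_hemi == "right") config$alpha_amp_attend
                else config$alpha_amp_unattend
      )
      base_phase <- omega * tvec + theta_f
      sig[fm_set, ] <- sig[fm_set, , drop = FALSE] +
        rep(config$alpha_amp_frontal * cos(base_phase), each = length(fm_set))
      for (side in c("left", "right")) {
        chs <- if (side == "left") left_set else right_set
        jit <- if (is.finite(config$sample_jitter_kappa)) {
          rvonmises(n_samp, 0, config$sample_jitter_kappa)
        } else 0
        coupled <- base_phase + lag[[side]] + jit
        free <- omega * tvec + runif(1, -pi, pi)
        wave <- amp[[side]] *
          (gate * cos(coupled) + (1 - gate) * cos(free))
        sig[chs, ] <- sig[chs, , drop = FALSE] +
          rep(wave, each = length(chs))
      }
      arr[k, , ] <- sig
    }
    epoch_set(arr, fs = fs, t0 = config$epoch_start, lock = lock,
              channel_names = chans, montage = montage,
              trial_ids = trials$trial_id)
  })
}

#' Simulate a resting (eyes-closed) recording for IAF estimation
#'
#' 1/f background on all channels plus an alpha oscillation at `config$iaf`
#' over the parieto-occipital channels (both hemispheres, amplitude
#' `alpha_amp_unattend`) with slowly drifting phase, emulating the resting
#' alpha peak that the Welch/IAF pipeline has to recover.
#'
#' @param config A [sim_config()].
#' @param duration Recording length in seconds (default 300, a 5-minute
#'   rest).
#' @return A single-trial `epoch_set` with `lock = "rest"`.
#' @export
simulate_rest <- function(config, duration = 300) {
  montage <- config$montage %||% montage_1010()
  chans <- montage$positions$channel
  fs <- config$fs
  n_samp <- round(duration * fs)
  tvec <- (seq_len(n_samp) - 1) / fs
  post <- montage$positions$y <= -1.7
  alpha_chs <- montage$positions$channel[post]
  with_seed(child_seed(config$seed, 4L), {
    sig <- onef_noise(length(chans), n_samp, fs, config$noise_exponent,
                      config$noise_amp)
    rownames(sig) <- chans
    # random-walk phase drift: realistic non-stationary alpha
    drift <- cumsum(rnorm(n_samp, 0, 0.3 / sqrt(fs)))
    wave <- config$alpha_amp_unattend * cos(2 * pi * config$iaf * tvec + drift)
    sig[alpha_chs, ] <- sig[alpha_chs, , drop = FALSE] +
      rep(wave, each = length(alpha_chs))
    arr <- array(0, dim = c(1, length(chans), n_samp))
    arr[1, , ] <- sig
    epoch_set(arr, fs = fs, t0 = 0, lock = "rest", channel_names = chans,
              montage = montage)
  })
}

#' Simulate a complete participant (design, behavior, epochs)
#'
#' @param config A [sim_config()].
#' @param lock Lock event for the epochs.
#' @return List with `trials`, `epochs`, `config`.
#' @export
simulate_participant <- function(config, lock = "cue") {
  trials <- simulate_behavior(design_trials(config), config)
  list(trials = trials,
       epochs = simulate_epochs(trials, config, lock = lock),
       config = config)
}
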