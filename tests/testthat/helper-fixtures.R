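# Shared fixtures, all built in code.

FS <- 500

# Reduced montage covering every channel the pipeline touches, to keep
# simulation costs down in tests.
small_montage <- function() {
  m <- montage_1010()
  keep <- c("Fz", "FC1", "FC2", "F1", "F2", "FCz", "Cz",
            "P3", "PO3", "PO1", "P4", "PO4", "PO2",
            "P5", "P7", "O1", "P6", "P8", "O2",
            "P1", "P2", "Pz", "POz", "Oz")
  m$positions <- m$positions[m$positions$channel %in% keep, ]
  m$neighbors <- alphasync:::compute_neighbors(m$positions, m$radius)
  m
}

small_sim <- function(...) {
  args <- utils::modifyList(
    list(montage = small_montage(), epoch_start = -0.5, epoch_end = 1.5),
    list(...))
  do.call(sim_config, args)
}

# Single-channel epoch set from a vector (or trials x samples matrix).
vec_epochs <- function(x, fs = FS, t0 = 0, ch = "A", lock = "rest") {
  if (is.null(dim(x))) x <- matrix(x, nrow = 1)
  arr <- array(0, dim = c(nrow(x), 1, ncol(x)))
  arr[, 1, ] <- x
  epoch_set(arr, fs, t0, lock, ch)
}

# Multichannel single-trial epoch set from a channels x samples matrix.
mat_epochs <- function(m, fs = FS, t0 = 0, lock = "rest",
                       montage = NULL) {
  arr <- array(0, dim = c(1, nrow(m), ncol(m)))
  arr[1, , ] <- m
  epoch_set(arr, fs, t0, lock, rownames(m), montage = montage)
}

# Spectral tensor with prescribed phases (unit amplitude):
# phases: named list channel -> trials x samples matrix (one frequency).
phase_tensor <- function(phases, freqs = 10, fs = FS, t0 = 0) {
  chans <- names(phases)
  n_tr <- nrow(phases[[1]])
  ns <- ncol(phases[[1]])
  co <- array(complex(real = 0), dim = c(n_tr, length(chans), length(freqs), ns))
  for (ci in seq_along(chans)) {
    for (fi in seq_along(freqs)) {
      co[, ci, fi, ] <- exp(1i * phases[[chans[ci]]])
    }
  }
  spectral_tensor(co, freqs, fs, t0, chans)
}

# Phase-level tensor for a 1-channel-per-cluster EOI scheme with planted
# von Mises coupling: FM channel has uniform phase per trial(+sample),
# parietal lags drawn with the given concentrations.
coupled_phase_tensor <- function(n_trials, n_samples, kappa_l, kappa_r,
                                 scheme = eoi_scheme("Fz", "P3", "P4")) {
  base <- matrix(runif(n_trials, -pi, pi), n_trials, n_samples)
  lag_l <- matrix(alphasync:::rvonmises(n_trials, 0, kappa_l),
                  n_trials, n_samples)
  lag_r <- matrix(alphasync:::rvonmises(n_trials, 0, kappa_r),
                  n_trials, n_samples)
  phase_tensor(stats::setNames(
    list(base, base + lag_l, base + lag_r),
    c(scheme$fm[1], scheme$pl[1], scheme$pr[1])))
}

balanced_trials <- function(n) {
  tibble::tibble(trial_id = seq_len(n),
                 attended_side = rep(c("left", "right"), length.out = n))
}
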