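#' Subset an epoch set by trials or channels
#'
#' @param epochs An `epoch_set`.
#' @param trials Logical mask or trial ids.
#' @param channels Channel names to keep.
#' @return An `epoch_set`.
#' @export
subset_epochs <- function(epochs, trials = NULL, channels = NULL) {
  if (!is.null(trials)) {
    idx <- if (is.logical(trials)) which(trials)
           else match(trials, epochs$trial_ids)
    if (anyNA(idx)) abort("Unknown trial ids.",
                          class = "alphasync_bad_trials")
    epochs$data <- epochs$data[idx, , , drop = FALSE]
    epochs$trial_ids <- epochs$trial_ids[idx]
  }
  if (!is.null(channels)) {
    check_channels(channels, epochs$channel_names)
    ci <- match(channels, epochs$channel_names)
    epochs$data <- epochs$data[, ci, , drop = FALSE]
    epochs$channel_names <- channels
    dimnames(epochs$data)[[2]] <- channels
  }
  epochs
}

#' Full analysis configuration
#'
#' Bundles every tunable of the two analysis pipelines (target-locked
#' replication and cue-locked exploration): the simulated cohort, the
#' frequency grid and upper-alpha band, EOI schemes, analysis windows,
#' permutation counts and the decoding plan. Per-participant simulation
#' seeds and individual alpha frequencies are derived deterministically
#' from `seed`.
#'
#' @param n_participants Simulated cohort size.
#' @param sim Template [sim_config()]; per-participant copies get derived
#'   seeds and jittered IAFs (normal, sd `iaf_sd`, truncated to 8-12 Hz).
#' @param iaf_sd Between-participant IAF spread, Hz.
#' @param grid Wavelet frequency grid.
#' @param band Upper-alpha band edges, Hz.
#' @param n_cycles Wavelet cycles.
#' @param scheme Connectivity [eoi_scheme()].
#' @param eois Power [power_eois()].
#' @param preprocess Run [condition_signal()] before the transform.
#' @param hjorth Apply the [hjorth_laplacian()] control re-reference.
#' @param select_rule Trial selection rule (see [select_trials()]).
#' @param n_iter PLV permutation iterations.
#' @param n_rand Cluster-test randomizations.
#' @param plan Decoding [split_plan()].
#' @param svm_grid Decoding [grid_spec()].
#' @param seed Master seed.
#' @return List of class `analysis_config`.
#' @export
analysis_config <- function(n_participants = 10, sim = sim_config(),
                            iaf_sd = 0.8, grid = make_frequency_grid(),
                            band = c(9.54, 14.31), n_cycles = 5,
                            scheme = eoi_scheme(), eois = power_eois(),
                            preprocess = TRUE, hjorth = FALSE,
                            select_rule = "valid-correct",
                            n_iter = 10000, n_rand = 100000,
                            plan = split_plan(), svm_grid = grid_spec(),
                            seed = 1) {
  structure(as.list(environment()), class = "analysis_config")
}

# Per-participant simulation configs with derived seeds and IAFs.
participant_configs <- function(config) {
  with_seed(child_seed(config$seed, 21L), {
    iafs <- pmin(12, pmax(8, rnorm(config$n_participants, config$sim$iaf,
                                   config$iaf_sd)))
    lapply(seq_len(config$n_participants), function(i) {
      cfg <- config$sim
      cfg$iaf <- iafs[i]
      cfg$seed <- child_seed(config$seed, 100L + i)
      cfg
    })
  })
}

# Channels any branch of the pipeline needs.
pipeline_channels <- function(config) {
  unique(c(config$scheme$fm, config$scheme$pl, config$scheme$pr,
           config$eois$pl, config$eois$pr))
}

# One participant's PLV branch: preprocess, select, transform, test.
# full_grid keeps all grid frequencies in the tensor (needed for the
# exploratory map); otherwise only the analysis band is transformed.
participant_plv <- function(trials, epochs, config, windows,
                            freqs, seed, full_grid = FALSE) {
  mask <- select_trials(trials, config$select_rule)
  keep_ch <- intersect(pipeline_channels(config), epochs$channel_names)
  ep <- subset_epochs(epochs, trials = mask, channels = keep_ch)
  if (config$preprocess) ep <- condition_signal(ep)
  if (config$hjorth) {
    # Hjorth needs the full montage context; re-subset afterwards
    ep_full <- subset_epochs(epochs, trials = mask)
    if (config$preprocess) ep_full <- condition_signal(ep_full)
    ep <- subset_epochs(hjorth_laplacian(ep_full), channels = keep_ch)
  }
  sel_trials <- trials[mask, ]
  eoi_ch <- unique(c(config$scheme$fm, config$scheme$pl, config$scheme$pr))
  bank_freqs <- if (full_grid) config$grid else freqs
  bank <- morlet_bank(bank_freqs, config$n_cycles, ep$fs)
  tens <- morlet_transform(ep, bank, channels = eoi_ch)
  series <- network_plv(tens, sel_trials, config$scheme, freqs = freqs)
  collapsed <- collapse_contra_ipsi(series)
  win <- window_average(collapsed, windows)
  perm <- plv_permutation_test(tens, sel_trials, config$scheme, windows,
                               freqs = freqs, n_iter = config$n_iter,
                               seed = seed)
  list(series = series, collapsed = collapsed, windows = win,
       perm = perm, tensor = tens, trials = sel_trials)
}

#' Target-locked analysis: contra vs ipsi upper-alpha PLV
#'
#' For each (simulated) participant: preprocessing, valid-correct trial
#' selection, mirror-padded Morlet transform restricted to the
#' upper-alpha grid frequencies, network PLV, contra/ipsi collapsing,
#' averaging over the pretarget (-200-0 ms) and post-target (200-400 ms)
#' windows, and the individual Monte-Carlo permutation test; then the
#' group test by surrogate averaging.
#'
#' @param config An [analysis_config()].
#' @param cohort Optional list of `list(trials=, epochs=)` per
#'   participant (target-locked); simulated from `config` when `NULL`.
#' @return List of class `alphasync_report` with `participants` (each:
#'   window tibble + permutation test), `group` (group-level
#'   `plv_perm_test`), `windows`, `band_freqs`, `lock`.
#' @export
run_target_locked <- function(config, cohort = NULL) {
  freqs <- upper_alpha_subset(config$grid, config$band)
  windows <- target_windows()
  run_lock(config, cohort, windows, freqs, lock = "target")
}

run_lock <- function(config, cohort, windows, freqs, lock) {
  cfgs <- participant_configs(config)
  if (is.null(cohort)) {
    cohort <- lapply(cfgs, function(cfg) {
      tr <- simulate_behavior(design_trials(cfg), cfg)
      list(trials = tr, epochs = simulate_epochs(tr, cfg, lock = lock),
           config = cfg)
    })
  }
  parts <- vector("list", length(cohort))
  for (i in seq_along(cohort)) {
    res <- participant_plv(cohort[[i]]$trials, cohort[[i]]$epochs, config,
                           windows, freqs,
                           seed = child_seed(config$seed, 300L + i))
    res$tensor <- NULL # drop the heavy tensor from the report
    parts[[i]] <- res
  }
  group <- group_permutation_test(lapply(parts, function(p) p$perm))
  structure(list(participants = parts, group = group, windows = windows,
                 band_freqs = freqs, lock = lock, config_hash =
                   rlang::hash(config)),
            class = "alphasync_report")
}

#' Cue-locked analysis: orienting-interval PLV, LI reality check, decoding
#'
#' The same PLV pipeline as [run_target_locked()] over the five 200-ms
#' cue-to-target windows (500-1500 ms), plus optional branches:
#' `"map"` — exploratory z-scored group contra-ipsi difference across the
#' full frequency grid; `"li"` — IAF estimation from a simulated rest
#' recording, alpha-power lateralization index, group paired cluster
#' test; `"decoding"` — single-trial SVM decoding on one participant.
#'
#' @param config An [analysis_config()].
#' @param cohort Optional cohort (cue-locked epochs).
#' @param branches Character subset of `c("map", "li", "decoding")`.
#' @param decode_participant Index of the participant to decode.
#' @return An `alphasync_report` with additional elements per branch.
#' @export
run_cue_locked <- function(config, cohort = NULL,
                           branches = c("map", "li", "decoding"),
                           decode_participant = 1) {
  freqs <- upper_alpha_subset(config$grid, config$band)
  windows <- cue_windows()
  cfgs <- participant_configs(config)
  if (is.null(cohort)) {
    cohort <- lapply(cfgs, function(cfg) {
      tr <- simulate_behavior(design_trials(cfg), cfg)
      list(trials = tr, epochs = simulate_epochs(tr, cfg, lock = "cue"),
           config = cfg)
    })
  }
  parts <- vector("list", length(cohort))
  maps <- list()
  li_rows <- list()
  for (i in seq_along(cohort)) {
    res <- participant_plv(cohort[[i]]$trials, cohort[[i]]$epochs, config,
                           windows, freqs,
                           seed = child_seed(config$seed, 300L + i),
                           full_grid = "map" %in% branches)
    if ("map" %in% branches) {
      full <- network_plv(res$tensor, res$trials, config$scheme)
      coll <- collapse_contra_ipsi(full)
      maps[[i]] <- coll |>
        tidyr::pivot_wider(names_from = "laterality",
                           values_from = "plv") |>
        dplyr::mutate(diff = .data$contra - .data$ipsi,
                      participant = i)
    }
    if ("li" %in% branches) {
      cfg <- cohort[[i]]$config %||% cfgs[[i]]
      rest <- simulate_rest(cfg, duration = 60)
      psd <- welch_psd(subset_epochs(
        rest, channels = intersect(iaf_channels(),
                                   rest$channel_names)))
      iaf <- estimate_iaf(psd)
      pw <- alpha_power(subset_epochs(cohort[[i]]$epochs,
                                      channels = c(config$eois$pl,
                                                   config$eois$pr)),
                        iaf, config$eois)
      li <- li_series(pw)
      lic <- li_by_condition(li, cohort[[i]]$trials)
      li_rows[[i]] <- list(iaf = iaf$iaf, summary = lic)
    }
    res$tensor <- NULL
    parts[[i]] <- res
  }
  group <- group_permutation_test(lapply(parts, function(p) p$perm))
  out <- list(participants = parts, group = group, windows = windows,
              band_freqs = freqs, lock = "cue",
              config_hash = rlang::hash(config))
  if ("map" %in% branches) {
    gm <- dplyr::bind_rows(maps) |>
      dplyr::group_by(.data$frequency, .data$time_ms) |>
      dplyr::summarise(diff = mean(.data$diff), .groups = "drop")
    gm$z <- as.vector(scale(gm$diff)) # z-scored over time x frequency cells
    out$map <- gm
  }
  if ("li" %in% branches) {
    out$li <- li_rows
    # group paired cluster test on per-participant LI difference courses
    dmat <- do.call(rbind, lapply(li_rows, function(l) {
      tc <- l$summary$timecourse
      r <- tc$mean[tc$attended_side == "right"]
      lft <- tc$mean[tc$attended_side == "left"]
      r - lft
    }))
    tvals <- li_rows[[1]]$summary$timecourse
    tms <- sort(unique(tvals$time_ms))
    out$li_cluster <- cluster_permutation_li(
      dmat, time_ms = tms, n_rand = min(config$n_rand, 10000),
      paired = TRUE, seed = child_seed(config$seed, 400L))
  }
  if ("decoding" %in% branches) {
    i <- decode_participant
    cfg <- cohort[[i]]$config %||% cfgs[[i]]
    mask <- select_trials(cohort[[i]]$trials, config$select_rule)
    eoi_ch <- unique(c(config$scheme$fm, config$scheme$pl,
                       config$scheme$pr))
    ep <- subset_epochs(cohort[[i]]$epochs, trials = mask,
                        channels = eoi_ch)
    if (config$preprocess) ep <- condition_signal(ep)
    bank <- morlet_bank(config$grid, config$n_cycles, ep$fs)
    tens <- morlet_transform(ep, bank, channels = eoi_ch)
    feats <- build_features(tens, cohort[[i]]$trials[mask, ],
                            config$scheme, windows, freqs = freqs)
    out$decoding <- crossval_evaluate(feats, config$plan, config$svm_grid)
  }
  class(out) <- "alphasync_report"
  out
}

#' @export
print.alphasync_report <- function(x, ...) {
  cat(sprintf("<alphasync_report> %s-locked, %d participants\n", x$lock,
              length(x$participants)))
  cat("group permutation test:\n")
  print(x$group$result)
  if (!is.null(x$decoding)) {
    cat(sprintf("decoding accuracy: %.3f\n", x$decoding$accuracy))
  }
  invisible(x)
}

#' Serialize an analysis report to JSON plus a text summary
#'
#' @param report An `alphasync_report`.
#' @param path Optional JSON output path.
#' @return Invisibly, the report as a plain list (what was serialized).
#' @export
make_report <- function(report, path = NULL) {
  out <- list(
    lock = report$lock,
    config_hash = report$config_hash,
    band_freqs = report$band_freqs,
    windows = report$windows,
    group = as.list(report$group$result),
    participants = lapply(report$participants, function(p) {
      list(windows = as.list(p$windows), perm = as.list(p$perm$result))
    })
  )
  if (!is.null(report$decoding)) {
    out$decoding <- list(accuracy = report$decoding$accuracy,
                         confusion = as.list(report$decoding$confusion))
  }
  if (!is.null(path)) {
    jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  }
  invisible(out)
}
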