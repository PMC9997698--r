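# Build the unit phase-difference matrix for the permutation engine:
# rows = (network, pair, frequency, window, sample), cols = trials.
# Returns list(re, im, meta) with meta rows aligned to the matrix rows.
unit_phase_rows <- function(tensor, scheme, windows, freqs = NULL) {
  fidx <- if (is.null(freqs)) seq_along(tensor$freqs) else {
    m <- match(round(freqs, 6), round(tensor$freqs, 6))
    if (anyNA(m)) abort("Requested freqs not in tensor.",
                        class = "alphasync_bad_freqs")
    m
  }
  tv <- time_axis(tensor)
  if (!is.list(windows)) windows <- list(windows)
  if (is.null(names(windows)) || any(names(windows) == "")) {
    names(windows) <- vapply(windows, function(w)
      paste0(w[1], "-", w[2]), character(1))
  }
  widx <- lapply(windows, function(w) {
    s <- window_samples(tv, w)
    if (length(s) == 0) abort("Empty analysis window.",
                              class = "alphasync_empty_window")
    s
  })
  nets <- list(`FM-PL` = scheme$pl, `FM-PR` = scheme$pr)
  n_tr <- dim(tensor$coeffs)[1]
  blocks <- list(); metas <- list()
  for (nn in names(nets)) {
    pairs <- expand.grid(f = scheme$fm, p = nets[[nn]],
                         stringsAsFactors = FALSE)
    for (pi2 in seq_len(nrow(pairs))) {
      U <- pair_units(tensor, c(pairs$f[pi2], pairs$p[pi2]))
      for (wn in names(widx)) {
        sub <- U[, fidx, widx[[wn]], drop = FALSE]
        nr <- length(fidx) * length(widx[[wn]])
        m <- matrix(aperm(sub, c(2, 3, 1)), nrow = nr, ncol = n_tr)
        blocks[[length(blocks) + 1]] <- m
        metas[[length(metas) + 1]] <- tibble::tibble(
          network = nn, window = wn, n_rows = nr
        )
      }
    }
  }
  M <- do.call(rbind, blocks)
  meta <- dplyr::bind_rows(metas)
  meta_rows <- tibble::tibble(
    network = rep(meta$network, meta$n_rows),
    window = rep(meta$window, meta$n_rows)
  )
  list(re = Re(M), im = Im(M), meta = meta_rows,
       windows = names(widx))
}

# Contra-ipsi window statistic from per-condition PLV values (rows x 2).
# weights: list of per-window row-weight vectors for each network.
contra_ipsi_stat <- function(plv_left, plv_right, meta, windows) {
  vapply(windows, function(wn) {
    pr <- meta$window == wn & meta$network == "FM-PR"
    pl <- meta$window == wn & meta$network == "FM-PL"
    contra <- (mean(plv_left[pr]) + mean(plv_right[pl])) / 2
    ipsi <- (mean(plv_left[pl]) + mean(plv_right[pr])) / 2
    contra - ipsi
  }, numeric(1), USE.NAMES = FALSE)
}

#' Monte-Carlo permutation test of the contra-ipsi PLV difference
#'
#' The observed statistic per analysis window is the contralateral minus
#' ipsilateral window-averaged network PLV. Under the null, attended-side
#' labels are randomly reassigned to trials (preserving the original
#' condition counts), the full pipeline — pairwise PLV, 9-pair network
#' average, contra/ipsi collapse, window average — is recomputed, and the
#' difference recorded. The one-tailed p-value is the proportion of
#' surrogate iterations with a difference strictly larger than the
#' observed one; with the strict rule the smallest reportable p is 0 and
#' `1/n_iter` is reported as `p_min`. `smooth = TRUE` uses the add-one
#' rule `p = (1 + #{surrogate >= obs}) / (1 + n_iter)` instead.
#'
#' @param tensor A `spectral_tensor` restricted to the analysis trials.
#' @param trials Trial tibble (`trial_id`, `attended_side`) aligned via
#'   trial ids.
#' @param scheme An [eoi_scheme()].
#' @param windows List of `c(start, end)` ms windows.
#' @param freqs Frequency subset (Hz), e.g.
#'   `upper_alpha_subset(make_frequency_grid())`.
#' @param n_iter Permutation iterations (default 10000).
#' @param seed Integer seed.
#' @param smooth Use the add-one smoothed p-value.
#' @return Object of class `plv_perm_test`: `result` tibble (`window`,
#'   `observed`, `p`, `p_min`), `surrogates` matrix (n_iter x windows),
#'   `n_iter`, `seed`.
#' @export
plv_permutation_test <- function(tensor, trials, scheme = eoi_scheme(),
                                 windows, freqs = NULL, n_iter = 10000,
                                 seed = NULL, smooth = FALSE) {
  lab <- trials$attended_side[match(tensor$trial_ids, trials$trial_id)]
  if (anyNA(lab)) abort("Trials/tensor mismatch.",
                        class = "alphasync_bad_trials")
  n <- length(lab)
  nL <- sum(lab == "left"); nR <- n - nL
  if (nL < 2 || nR < 2) {
    abort("Need >= 2 trials per condition.",
          class = "alphasync_too_few_trials")
  }
  up <- unit_phase_rows(tensor, scheme, windows, freqs)
  obs_plv <- function(is_left) {
    sL_re <- rowMeans(up$re[, is_left, drop = FALSE])
    sL_im <- rowMeans(up$im[, is_left, drop = FALSE])
    sR_re <- rowMeans(up$re[, !is_left, drop = FALSE])
    sR_im <- rowMeans(up$im[, !is_left, drop = FALSE])
    list(left = sqrt(sL_re^2 + sL_im^2), right = sqrt(sR_re^2 + sR_im^2))
  }
  p0 <- obs_plv(lab == "left")
  observed <- contra_ipsi_stat(p0$left, p0$right, up$meta, up$windows)

  surr <- matrix(NA_real_, n_iter, length(up$windows))
  with_seed(seed, {
    chunk <- 500L
    done <- 0L
    while (done < n_iter) {
      b <- min(chunk, n_iter - done)
      WL <- matrix(0, n, b); WR <- matrix(0, n, b)
      for (j in seq_len(b)) {
        idx <- sample.int(n, nL)
        WL[idx, j] <- 1 / nL
        WR[-idx, j] <- 1 / nR
      }
      pvL <- sqrt((up$re %*% WL)^2 + (up$im %*% WL)^2)
      pvR <- sqrt((up$re %*% WR)^2 + (up$im %*% WR)^2)
      for (w in seq_along(up$windows)) {
        wn <- up$windows[w]
        pr <- up$meta$window == wn & up$meta$network == "FM-PR"
        pl <- up$meta$window == wn & up$meta$network == "FM-PL"
        contra <- (colMeans(pvL[pr, , drop = FALSE]) +
                     colMeans(pvR[pl, , drop = FALSE])) / 2
        ipsi <- (colMeans(pvL[pl, , drop = FALSE]) +
                   colMeans(pvR[pr, , drop = FALSE])) / 2
        surr[done + seq_len(b), w] <- contra - ipsi
      }
      done <- done + b
    }
  })
  p <- vapply(seq_along(up$windows), function(w) {
    if (smooth) (1 + sum(surr[, w] >= observed[w])) / (1 + n_iter)
    else mean(surr[, w] > observed[w])
  }, numeric(1))
  structure(list(
    result = tibble::tibble(window = up$windows, observed = observed,
                            p = p, p_min = 1 / n_iter),
    surrogates = surr, n_iter = n_iter, seed = seed, smooth = smooth
  ), class = "plv_perm_test")
}

#' @export
print.plv_perm_test <- function(x, ...) {
  cat(sprintf("<plv_perm_test> %d iterations\n", x$n_iter))
  print(x$result)
  invisible(x)
}

#' Group-level permutation test by surrogate averaging
#'
#' Surrogate distributions are averaged across participants iteration by
#' iteration (iteration i of each participant with iteration i of the
#' others), the observed statistics likewise, and the individual p-value
#' rule is applied to the averaged distribution.
#'
#' @param results List of `plv_perm_test` objects sharing `n_iter` and
#'   windows.
#' @param smooth Add-one smoothed p-value.
#' @return A `plv_perm_test` for the group.
#' @export
group_permutation_test <- function(results, smooth = FALSE) {
  n_iter <- unique(vapply(results, function(r) r$n_iter, numeric(1)))
  if (length(n_iter) != 1) {
    abort("All participants must share n_iter.",
          class = "alphasync_mismatched_iters")
  }
  wins <- results[[1]]$result$window
  for (r in results) {
    if (!identical(r$result$window, wins)) {
      abort("All participants must share windows.",
            class = "alphasync_mismatched_windows")
    }
  }
  surr <- Reduce(`+`, lapply(results, function(r) r$surrogates)) /
    length(results)
  observed <- Reduce(`+`, lapply(results, function(r) r$result$observed)) /
    length(results)
  p <- vapply(seq_along(wins), function(w) {
    if (smooth) (1 + sum(surr[, w] >= observed[w])) / (1 + n_iter)
    else mean(surr[, w] > observed[w])
  }, numeric(1))
  structure(list(
    result = tibble::tibble(window = wins, observed = observed, p = p,
                            p_min = 1 / n_iter),
    surrogates = surr, n_iter = n_iter, seed = NULL, smooth = smooth
  ), class = "plv_perm_test")
}

# Max cluster mass above threshold for one t-vector.
max_cluster_mass <- function(tvec, thr) {
  above <- tvec > thr
  if (!any(above)) return(0)
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  max(vapply(which(r$values), function(i)
    sum(tvec[starts[i]:ends[i]]), numeric(1)))
}

#' Cluster-based permutation test on a lateralization-index time course
#'
#' Samplewise one-tailed t statistics (independent samples at the
#' individual level; one-sample on paired differences at the group
#' level) are thresholded at the one-tailed critical value at
#' `alpha`; temporally contiguous supra-threshold samples form clusters
#' whose mass is the sum of t values. The null distribution of the
#' maximum cluster mass is built by label randomization (independent:
#' label shuffles preserving counts; paired: sign flips), and each
#' observed cluster's p is the proportion of null maxima at least as
#' large.
#'
#' @param x Observations x time matrix: per-trial LI (independent) or
#'   per-participant LI differences right minus left (paired). Use
#'   [li_matrix()] to build it from [li_series()] output.
#' @param labels For the independent test: character/factor with levels
#'   `left`/`right`; the test direction is right > left. Ignored when
#'   `paired = TRUE` (direction: difference > 0).
#' @param time_ms Optional time axis for cluster extents (defaults to
#'   column index).
#' @param n_rand Randomizations (default 100000).
#' @param alpha Cluster-forming (and reporting) alpha.
#' @param paired Group-level paired variant.
#' @param seed Integer seed.
#' @return Object of class `cluster_perm_test`: `clusters` tibble
#'   (`start_ms`, `end_ms`, `mass`, `p`, `significant`), `threshold`,
#'   `null_max` vector, settings.
#' @export
cluster_permutation_li <- function(x, labels = NULL, time_ms = NULL,
                                   n_rand = 100000, alpha = 0.05,
                                   paired = FALSE, seed = NULL) {
  x <- as.matrix(x)
  n <- nrow(x); Tn <- ncol(x)
  time_ms <- time_ms %||% seq_len(Tn)
  if (any(apply(x, 2, sd) == 0)) {
    abort("Zero-variance input.", class = "alphasync_zero_variance")
  }
  if (paired) {
    if (n < 2) abort("Need >= 2 participants.",
                     class = "alphasync_too_few_trials")
    df <- n - 1
    thr <- qt(1 - alpha, df)
    t_of_mean <- function(m, msq) {
      v <- (msq - m^2) * n / (n - 1)
      m / sqrt(v / n)
    }
    msq <- colMeans(x^2)
    t_obs <- t_of_mean(colMeans(x), msq)
    Xt <- t(x) # Tn x n
    null_max <- numeric(n_rand)
    with_seed(seed, {
      chunk <- 2000L; done <- 0L
      while (done < n_rand) {
        b <- min(chunk, n_rand - done)
        S <- matrix(sample(c(-1, 1), n * b, replace = TRUE), n, b)
        Mb <- (Xt %*% S) / n # Tn x b column means under sign flip
        for (j in seq_len(b)) {
          tb <- t_of_mean(Mb[, j], msq)
          null_max[done + j] <- max_cluster_mass(tb, thr)
        }
        done <- done + b
      }
    })
  } else {
    if (is.null(labels)) abort("labels required for the independent test.",
                               class = "alphasync_bad_labels")
    g <- as.character(labels)
    iR <- g == "right"; iL <- g == "left"
    nR <- sum(iR); nL <- sum(iL)
    if (nR < 2 || nL < 2) abort("Need >= 2 observations per condition.",
                                class = "alphasync_too_few_trials")
    df <- nR + nL - 2
    thr <- qt(1 - alpha, df)
    Xt <- t(x); X2t <- t(x^2) # Tn x n
    t_indep <- function(wR, wL) {
      mR <- Xt %*% wR / nR; mL <- Xt %*% wL / nL
      sR <- X2t %*% wR / nR; sL <- X2t %*% wL / nL
      vR <- (sR - mR^2) * nR / (nR - 1)
      vL <- (sL - mL^2) * nL / (nL - 1)
      sp <- ((nR - 1) * vR + (nL - 1) * vL) / df
      (mR - mL) / sqrt(sp * (1 / nR + 1 / nL))
    }
    t_obs <- as.vector(t_indep(as.numeric(iR), as.numeric(iL)))
    null_max <- numeric(n_rand)
    with_seed(seed, {
      chunk <- 2000L; done <- 0L
      while (done < n_rand) {
        b <- min(chunk, n_rand - done)
        WR <- matrix(0, n, b); WL <- matrix(0, n, b)
        for (j in seq_len(b)) {
          idx <- sample.int(n, nR)
          WR[idx, j] <- 1; WL[-idx, j] <- 1
        }
        mR <- (Xt %*% WR) / nR; mL <- (Xt %*% WL) / nL
        sR <- (X2t %*% WR) / nR; sL <- (X2t %*% WL) / nL
        vR <- (sR - mR^2) * nR / (nR - 1)
        vL <- (sL - mL^2) * nL / (nL - 1)
        sp <- ((nR - 1) * vR + (nL - 1) * vL) / df
        tb <- (mR - mL) / sqrt(sp * (1 / nR + 1 / nL))
        for (j in seq_len(b)) {
          null_max[done + j] <- max_cluster_mass(tb[, j], thr)
        }
        done <- done + b
      }
    })
  }
  above <- t_obs > thr
  clusters <- tibble::tibble(start_ms = numeric(), end_ms = numeric(),
                             mass = numeric(), p = numeric(),
                             significant = logical())
  if (any(above)) {
    r <- rle(above)
    ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1
    ci <- which(r$values)
    clusters <- tibble::tibble(
      start_ms = time_ms[starts[ci]],
      end_ms = time_ms[ends[ci]],
      mass = vapply(ci, function(i) sum(t_obs[starts[i]:ends[i]]),
                    numeric(1))
    )
    clusters$p <- vapply(clusters$mass, function(m) mean(null_max >= m),
                         numeric(1))
    clusters$significant <- clusters$p < alpha
  }
  structure(list(clusters = clusters, threshold = thr, t_obs = t_obs,
                 time_ms = time_ms, null_max = null_max, n_rand = n_rand,
                 alpha = alpha, paired = paired, seed = seed),
            class = "cluster_perm_test")
}

#' @export
print.cluster_perm_test <- function(x, ...) {
  cat(sprintf("<cluster_perm_test> %d randomizations, threshold t > %.3f\n",
              x$n_rand, x$threshold))
  if (nrow(x$clusters) == 0) cat("no supra-threshold clusters\n")
  else print(x$clusters)
  invisible(x)
}

#' Trials x time LI matrix for the cluster test
#'
#' @param li Tibble from [li_series()].
#' @return Matrix (trials x time) with trial ids as rownames and the time
#'   axis (ms) as an attribute.
#' @export
li_matrix <- function(li) {
  wide <- tidyr::pivot_wider(li, names_from = "time_ms",
                             values_from = "li")
  m <- as.matrix(wide[, -1])
  rownames(m) <- wide$trial_id
  attr(m, "time_ms") <- as.numeric(colnames(m))
  m
}

#' One-tailed t test of performance against chance
#'
#' One-sample t on `rates - chance`; the combined detection +
#' discrimination response has chance level 0.25 (two independent binary
#' guesses).
#'
#' @param rates Per-participant correct rates.
#' @param chance Chance level (default 0.25).
#' @param tail `"greater"` (default), `"less"`, or `"two.sided"`.
#' @return Tibble with `t`, `df`, `p`, `mean`.
#' @export
ttest_vs_chance <- function(rates, chance = 0.25, tail = "greater") {
  if (length(rates) < 2) abort("Need n >= 2.",
                               class = "alphasync_too_few_trials")
  if (sd(rates) == 0) abort("Zero variance.",
                            class = "alphasync_zero_variance")
  tt <- t.test(rates, mu = chance, alternative = tail)
  tibble::tibble(t = unname(tt$statistic), df = unname(tt$parameter),
                 p = tt$p.value, mean = mean(rates))
}

#' Pearson correlations between LI and contra-ipsi PLV with BH-FDR
#'
#' One correlation per analysis cell (e.g. window x attended side), with
#' two-sided p-values corrected across the family by the
#' Benjamini-Hochberg false discovery rate.
#'
#' @param data Tibble of paired per-participant observations.
#' @param li,plv Column names of the two variables.
#' @param by Grouping columns defining the family of tests.
#' @return Tibble per cell: grouping columns, `n`, `r`, `p`, `q`.
#' @export
correlate_li_plv <- function(data, li = "li", plv = "plv_diff",
                             by = c("window", "condition")) {
  by <- intersect(by, names(data))
  res <- data |>
    dplyr::group_by(dplyr::across(dplyr::all_of(by))) |>
    dplyr::summarise(
      n = dplyr::n(),
      r = {
        xs <- .data[[li]]; ys <- .data[[plv]]
        if (dplyr::n() < 3) abort("Need n >= 3 per cell.",
                                  class = "alphasync_too_few_trials")
        if (sd(xs) == 0 || sd(ys) == 0) {
          abort("Constant vector in correlation.",
                class = "alphasync_zero_variance")
        }
        cor(xs, ys)
      },
      p = cor.test(.data[[li]], .data[[plv]])$p.value,
      .groups = "drop"
    )
  res$q <- p.adjust(res$p, method = "BH")
  res
}
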