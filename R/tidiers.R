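#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy a PLV permutation test
#'
#' @param x A `plv_perm_test`.
#' @param ... Unused.
#' @return Tibble with one row per analysis window: `window`, `observed`,
#'   `p`, `p_min`.
#' @export
tidy.plv_perm_test <- function(x, ...) x$result

#' @rdname tidy.plv_perm_test
#' @export
glance.plv_perm_test <- function(x, ...) {
  tibble::tibble(n_iter = x$n_iter, n_windows = nrow(x$result),
                 min_p = min(x$result$p),
                 any_significant = any(x$result$p < 0.05))
}

#' Tidy a cluster-based permutation test
#'
#' @param x A `cluster_perm_test`.
#' @param ... Unused.
#' @return Tibble with one row per supra-threshold cluster.
#' @export
tidy.cluster_perm_test <- function(x, ...) x$clusters

#' @rdname tidy.cluster_perm_test
#' @export
glance.cluster_perm_test <- function(x, ...) {
  tibble::tibble(n_rand = x$n_rand, threshold = x$threshold,
                 n_clusters = nrow(x$clusters),
                 n_significant = sum(x$clusters$significant),
                 paired = x$paired)
}

#' Tidy a decoding report
#'
#' @param x A `decoding_report`.
#' @param ... Unused.
#' @return The per-fold results tibble.
#' @export
tidy.decoding_report <- function(x, ...) x$fold_results

#' @rdname tidy.decoding_report
#' @export
glance.decoding_report <- function(x, ...) {
  tibble::tibble(method = x$method, accuracy = x$accuracy,
                 n_trials = x$n_trials,
                 sd_fold = sd(x$fold_results$accuracy))
}

#' Tidy a condition-wise LI summary
#'
#' @param x A `li_summary`.
#' @param ... Unused.
#' @return The time-resolved condition tibble.
#' @export
tidy.li_summary <- function(x, ...) x$timecourse

#' @rdname tidy.li_summary
#' @export
glance.li_summary <- function(x, ...) {
  tibble::tibble(delta = x$delta, window_start = x$window_ms[1],
                 window_end = x$window_ms[2])
}
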