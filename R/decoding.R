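#' Single-trial ISPC feature matrix for attended-side decoding
#'
#' For each trial, cross-time PLV (ISPC, upper-alpha averaged) of each
#' frontoparietal network in each analysis window, averaged over the
#' network's 9 electrode pairs. With the default five 200-ms cue-to-target
#' windows this yields the 10-dimensional feature vector (five FM-PR
#' values then five FM-PL values) the classifiers consume.
#'
#' @param tensor A cue-locked `spectral_tensor` covering the windows.
#' @param trials Trial tibble with `trial_id`, `attended_side`.
#' @param scheme An [eoi_scheme()].
#' @param windows List of `c(start, end)` ms windows (default
#'   [cue_windows()]).
#' @param freqs Frequency subset (Hz; default all tensor frequencies).
#' @return Tibble: `trial_id`, `attended_side`, then one `[0, 1]` ISPC
#'   column per network x window, named `fmpr_<win>` / `fmpl_<win>`; the
#'   feature column names are attached as attribute `feature_cols`.
#' @export
build_features <- function(tensor, trials, scheme = eoi_scheme(),
                           windows = cue_windows(), freqs = NULL) {
  if (!is.list(windows)) windows <- list(windows)
  if (is.null(names(windows)) || any(names(windows) == "")) {
    names(windows) <- vapply(windows, function(w)
      paste0(w[1], "-", w[2]), character(1))
  }
  nets <- list(fmpr = scheme$pr, fmpl = scheme$pl)
  out <- tibble::tibble(
    trial_id = tensor$trial_ids,
    attended_side = trials$attended_side[match(tensor$trial_ids,
                                               trials$trial_id)]
  )
  if (anyNA(out$attended_side)) {
    abort("Trials/tensor mismatch.", class = "alphasync_bad_trials")
  }
  feat_cols <- character()
  for (nn in names(nets)) {
    pairs <- expand.grid(f = scheme$fm, p = nets[[nn]],
                         stringsAsFactors = FALSE)
    for (wn in names(windows)) {
      acc <- 0
      for (pi2 in seq_len(nrow(pairs))) {
        v <- plv_cross_time(tensor, c(pairs$f[pi2], pairs$p[pi2]),
                            windows[[wn]], freqs = freqs)
        acc <- acc + v$ispc
      }
      cn <- paste0(nn, "_", gsub("[^0-9a-zA-Z]+", "_", wn))
      out[[cn]] <- acc / nrow(pairs)
      feat_cols <- c(feat_cols, cn)
    }
  }
  attr(out, "feature_cols") <- feat_cols
  out
}

feature_cols <- function(features) {
  attr(features, "feature_cols") %||%
    setdiff(names(features), c("trial_id", "attended_side"))
}

#' Nested split / cross-validation plan
#'
#' Trials are split 80/20 into training and testing; the training set is
#' further split 80/20 into sub-training and validation for
#' hyperparameter optimization; reported accuracy comes from stratified
#' 10-fold cross-validation. Splits are keyed to trial ids (sorted before
#' assignment), so permuting feature rows does not change fold
#' membership.
#'
#' @param test_frac,val_frac Held-out fractions of the outer and inner
#'   split.
#' @param folds Cross-validation folds.
#' @param seed Integer seed.
#' @param stratified Stratify all splits by class.
#' @return List of class `split_plan`.
#' @export
split_plan <- function(test_frac = 0.2, val_frac = 0.2, folds = 10,
                       seed = 1, stratified = TRUE) {
  stopifnot(test_frac > 0, test_frac < 1, val_frac > 0, val_frac < 1,
            folds >= 2)
  structure(list(test_frac = test_frac, val_frac = val_frac, folds = folds,
                 seed = seed, stratified = stratified),
            class = "split_plan")
}

#' Logarithmic hyperparameter grid for the RBF-SVM
#'
#' Soft-margin cost and kernel gamma explored in logarithmic steps from
#' `10^-6` to `10^3` (one point per decade by default).
#'
#' @param from,to Grid range.
#' @param per_decade Points per decade.
#' @return List of class `grid_spec` with sorted `cost` and `gamma`.
#' @export
grid_spec <- function(from = 1e-6, to = 1e3, per_decade = 1) {
  g <- 10^seq(log10(from), log10(to), by = 1 / per_decade)
  structure(list(cost = g, gamma = g), class = "grid_spec")
}

# Deterministic stratified assignment of ids into `k` groups,
# proportional to `fracs` (or equal folds when fracs is NULL).
assign_groups <- function(ids, labels, k, seed, fracs = NULL,
                          stratified = TRUE) {
  ord <- order(ids)
  ids <- ids[ord]; labels <- labels[ord]
  out <- integer(length(ids))
  with_seed(seed, {
    strata <- if (stratified) split(seq_along(ids), labels)
              else list(seq_along(ids))
    for (s in strata) {
      n <- length(s)
      g <- if (is.null(fracs)) {
        rep_len(seq_len(k), n)
      } else {
        rep(seq_len(k), times = round(n * fracs / sum(fracs)))
      }
      g <- rep_len(g, n)
      out[s] <- sample(g)
    }
  })
  out[order(ord)] # back to input order
}

svm_fit_predict <- function(Xtr, ytr, Xte, cost, gamma) {
  fit <- e1071::svm(Xtr, factor(ytr, levels = c("left", "right")),
                    kernel = "radial", cost = cost, gamma = gamma,
                    scale = FALSE)
  as.character(predict(fit, Xte))
}

#' Optimize the RBF-SVM hyperparameters on a validation split
#'
#' The training trials are split into sub-training and validation sets;
#' for every (cost, gamma) grid point a soft-margin SVM with Gaussian
#' kernel `K(u, v) = exp(-gamma ||u - v||^2)` is trained on the
#' sub-training set and scored on the validation set. The smallest pair
#' attaining the maximum validation accuracy is selected (ties broken
#' toward the smallest cost, then the smallest gamma).
#'
#' @param features Feature tibble (see [build_features()]), training
#'   trials only.
#' @param plan A [split_plan()].
#' @param grid A [grid_spec()].
#' @return List: `best_cost`, `best_gamma`, `best_accuracy`, `landscape`
#'   (tibble cost x gamma x accuracy).
#' @export
optimize_rbf_svm <- function(features, plan = split_plan(),
                             grid = grid_spec()) {
  fc <- feature_cols(features)
  y <- features$attended_side
  if (length(unique(y)) < 2) {
    abort("Sub-training set has a single class.",
          class = "alphasync_single_class")
  }
  grp <- assign_groups(features$trial_id, y, 2, child_seed(plan$seed, 7L),
                       fracs = c(1 - plan$val_frac, plan$val_frac),
                       stratified = plan$stratified)
  sub <- grp == 1; val <- grp == 2
  X <- as.matrix(features[, fc])
  land <- expand.grid(cost = grid$cost, gamma = grid$gamma)
  land$accuracy <- vapply(seq_len(nrow(land)), function(i) {
    pred <- svm_fit_predict(X[sub, , drop = FALSE], y[sub],
                            X[val, , drop = FALSE],
                            land$cost[i], land$gamma[i])
    mean(pred == y[val])
  }, numeric(1))
  best_acc <- max(land$accuracy)
  cand <- land[land$accuracy >= best_acc - 1e-12, ]
  cand <- cand[order(cand$cost, cand$gamma), ]
  list(best_cost = cand$cost[1], best_gamma = cand$gamma[1],
       best_accuracy = best_acc, landscape = tibble::as_tibble(land))
}

confusion_table <- function(truth, pred) {
  lev <- c("left", "right")
  counts <- table(factor(truth, lev), factor(pred, lev))
  pct <- sweep(counts, 1, pmax(rowSums(counts), 1), "/") * 100
  tibble::tibble(
    truth = rep(lev, each = 2), predicted = rep(lev, 2),
    count = as.vector(t(counts)), percent = as.vector(t(pct))
  )
}

#' Cross-validated decoding of the attended side
#'
#' Stratified 10-fold cross-validation. Within each fold the
#' hyperparameters are re-optimized on the fold's training trials via the
#' nested validation split, the classifier is refit on the full training
#' portion, and the held-out fold is scored. The pooled confusion matrix
#' reports raw counts and row-normalized percentages (each
#' ground-truth row sums to 100).
#'
#' @param features Feature tibble from [build_features()].
#' @param plan A [split_plan()].
#' @param grid A [grid_spec()] (ignored when `params` is given).
#' @param params Optional fixed `list(cost=, gamma=)` to skip the grid.
#' @return Object of class `decoding_report`: `accuracy`, `fold_results`
#'   (per-fold accuracy and chosen params), `confusion`, `n_trials`,
#'   `method`.
#' @export
crossval_evaluate <- function(features, plan = split_plan(),
                              grid = grid_spec(), params = NULL) {
  fc <- feature_cols(features)
  y <- features$attended_side
  if (min(table(y)) < plan$folds) {
    abort("Need at least `folds` trials per class.",
          class = "alphasync_too_few_trials")
  }
  folds <- assign_groups(features$trial_id, y, plan$folds,
                         child_seed(plan$seed, 11L),
                         stratified = plan$stratified)
  X <- as.matrix(features[, fc])
  truth <- character(0); pred <- character(0)
  fold_res <- list()
  for (f in seq_len(plan$folds)) {
    te <- folds == f; tr <- !te
    if (is.null(params)) {
      opt <- optimize_rbf_svm(features[tr, ], plan, grid)
      cost <- opt$best_cost; gamma <- opt$best_gamma
    } else {
      cost <- params$cost; gamma <- params$gamma
    }
    p <- svm_fit_predict(X[tr, , drop = FALSE], y[tr],
                         X[te, , drop = FALSE], cost, gamma)
    truth <- c(truth, y[te]); pred <- c(pred, p)
    fold_res[[f]] <- tibble::tibble(fold = f, accuracy = mean(p == y[te]),
                                    cost = cost, gamma = gamma,
                                    n_test = sum(te))
  }
  structure(list(
    accuracy = mean(pred == truth),
    fold_results = dplyr::bind_rows(fold_res),
    confusion = confusion_table(truth, pred),
    n_trials = length(truth), method = "rbf-svm"
  ), class = "decoding_report")
}

#' @export
print.decoding_report <- function(x, ...) {
  cat(sprintf("<decoding_report> %s: overall accuracy %.3f on %d trials\n",
              x$method, x$accuracy, x$n_trials))
  print(x$confusion)
  invisible(x)
}

# Schafer-Strimmer analytic shrinkage of a covariance matrix toward the
# scaled identity target (trace(S)/d) * I. Returns list(sigma, lambda).
shrink_cov <- function(X) {
  n <- nrow(X); d <- ncol(X)
  Xc <- scale(X, center = TRUE, scale = FALSE)
  S <- crossprod(Xc) / (n - 1)
  target <- diag(mean(diag(S)), d)
  # var of each covariance entry estimate
  W <- array(0, dim = c(d, d))
  for (i in seq_len(d)) {
    for (j in seq_len(d)) {
      w <- Xc[, i] * Xc[, j]
      W[i, j] <- n / ((n - 1)^3) * sum((w - mean(w))^2)
    }
  }
  num <- sum(W)
  den <- sum((S - target)^2)
  lambda <- if (den > 0) min(1, max(0, num / den)) else 1
  list(sigma = (1 - lambda) * S + lambda * target, lambda = lambda)
}

slda_train <- function(X, y, lambda = NULL) {
  lev <- c("left", "right")
  mu <- lapply(lev, function(l) colMeans(X[y == l, , drop = FALSE]))
  Xc <- X
  for (l in lev) {
    Xc[y == l, ] <- sweep(X[y == l, , drop = FALSE], 2,
                          mu[[match(l, lev)]])
  }
  if (is.null(lambda)) {
    sh <- shrink_cov(Xc)
    # recenter: Xc is already centered per class; shrink pooled scatter
    S <- crossprod(Xc) / (nrow(Xc) - 2)
    target <- diag(mean(diag(S)), ncol(X))
    sigma <- (1 - sh$lambda) * S + sh$lambda * target
    lambda <- sh$lambda
  } else {
    S <- crossprod(Xc) / (nrow(Xc) - 2)
    target <- diag(mean(diag(S)), ncol(X))
    sigma <- (1 - lambda) * S + lambda * target
  }
  w <- solve(sigma, mu[[2]] - mu[[1]])
  b <- -sum(w * (mu[[1]] + mu[[2]]) / 2)
  list(w = w, b = b, lambda = lambda)
}

slda_predict <- function(model, X) {
  ifelse(as.vector(X %*% model$w) + model$b > 0, "right", "left")
}

# --- Riemannian geometry on SPD matrices ---------------------------------

spd_pow <- function(A, p) {
  e <- eigen(A, symmetric = TRUE)
  e$vectors %*% diag(e$values^p, nrow(A)) %*% t(e$vectors)
}

spd_log <- function(A) {
  e <- eigen(A, symmetric = TRUE)
  if (any(e$values <= 0)) abort("Matrix not positive definite.",
                                class = "alphasync_not_spd")
  e$vectors %*% diag(log(e$values), nrow(A)) %*% t(e$vectors)
}

#' Affine-invariant Riemannian distance between SPD matrices
#'
#' `delta(A, B) = || log(A^{-1/2} B A^{-1/2}) ||_F`.
#'
#' @param A,B Symmetric positive-definite matrices.
#' @return Nonnegative scalar; 0 iff `A == B`.
#' @export
riemann_dist <- function(A, B) {
  is <- spd_pow(A, -0.5)
  L <- spd_log(is %*% B %*% is)
  sqrt(sum(L^2))
}

# Karcher (geometric) mean of SPD matrices by fixed-point iteration.
riemann_mean <- function(mats, tol = 1e-8, max_iter = 50) {
  M <- Reduce(`+`, mats) / length(mats)
  for (it in seq_len(max_iter)) {
    Mh <- spd_pow(M, 0.5); Mih <- spd_pow(M, -0.5)
    Tm <- Reduce(`+`, lapply(mats, function(C)
      spd_log(Mih %*% C %*% Mih))) / length(mats)
    M <- Mh %*% spd_pow_exp(Tm) %*% Mh
    if (sqrt(sum(Tm^2)) < tol) break
  }
  M
}

spd_pow_exp <- function(A) {
  e <- eigen((A + t(A)) / 2, symmetric = TRUE)
  e$vectors %*% diag(exp(e$values), nrow(A)) %*% t(e$vectors)
}

#' Per-trial band-limited channel covariance matrices
#'
#' Covariance across channels of the band-limited signal reconstructed
#' from the spectral tensor (real part of the summed upper-alpha
#' coefficients), regularized by `+ eps I` with
#' `eps = 1e-10 * trace` — the SPD features the Riemannian classifier
#' consumes.
#'
#' @param tensor A `spectral_tensor` over the EOI channels.
#' @param freqs Frequency subset (Hz; default all).
#' @param window Optional `c(start, end)` ms crop.
#' @return List of SPD matrices, one per trial, named by trial id.
#' @export
trial_covariances <- function(tensor, freqs = NULL, window = NULL) {
  fidx <- if (is.null(freqs)) seq_along(tensor$freqs) else {
    m <- match(round(freqs, 6), round(tensor$freqs, 6))
    if (anyNA(m)) abort("Requested freqs not in tensor.",
                        class = "alphasync_bad_freqs")
    m
  }
  sidx <- if (is.null(window)) seq_len(dim(tensor$coeffs)[4]) else {
    window_samples(time_axis(tensor), window)
  }
  lapply(stats::setNames(seq_len(dim(tensor$coeffs)[1]), tensor$trial_ids),
         function(k) {
    # channels x samples band signal
    co <- tensor$coeffs[k, , fidx, sidx, drop = FALSE]
    sig <- apply(Re(co), c(2, 4), sum)
    C <- stats::cov(t(sig))
    C + diag(1e-10 * sum(diag(C)), nrow(C))
  })
}

#' Baseline classifiers: shrinkage LDA and Riemannian MDM
#'
#' Cross-validated with the same stratified folds as the SVM. `slda`
#' operates on the 10-D ISPC feature vector with an analytically shrunk
#' pooled covariance (shrinkage toward the scaled identity). `rmdm`
#' assigns each trial to the class whose Riemannian geometric-mean
#' covariance is nearest under the affine-invariant metric; it consumes
#' per-trial covariance matrices ([trial_covariances()]).
#'
#' @param features Feature tibble from [build_features()].
#' @param plan A [split_plan()].
#' @param method `"slda"` or `"rmdm"`.
#' @param covs For `rmdm`: list of per-trial SPD matrices aligned with
#'   `features$trial_id`.
#' @return A `decoding_report`.
#' @export
baseline_classifiers <- function(features, plan = split_plan(),
                                 method = c("slda", "rmdm"), covs = NULL) {
  method <- match.arg(method)
  y <- features$attended_side
  folds <- assign_groups(features$trial_id, y, plan$folds,
                         child_seed(plan$seed, 11L),
                         stratified = plan$stratified)
  truth <- character(0); pred <- character(0)
  fold_res <- list()
  if (method == "rmdm") {
    if (is.null(covs)) abort("rmdm requires per-trial covariances.",
                             class = "alphasync_bad_input")
    covs <- covs[as.character(features$trial_id)]
  }
  X <- as.matrix(features[, feature_cols(features)])
  for (f in seq_len(plan$folds)) {
    te <- which(folds == f); tr <- which(folds != f)
    if (method == "slda") {
      model <- slda_train(X[tr, , drop = FALSE], y[tr])
      p <- slda_predict(model, X[te, , drop = FALSE])
    } else {
      means <- lapply(c(left = "left", right = "right"), function(l) {
        riemann_mean(covs[tr[y[tr] == l]])
      })
      p <- vapply(te, function(k) {
        d <- vapply(means, function(M) riemann_dist(M, covs[[k]]),
                    numeric(1))
        names(d)[which.min(d)]
      }, character(1))
    }
    truth <- c(truth, y[te]); pred <- c(pred, p)
    fold_res[[f]] <- tibble::tibble(fold = f, accuracy = mean(p == y[te]),
                                    n_test = length(te))
  }
  structure(list(
    accuracy = mean(pred == truth),
    fold_results = dplyr::bind_rows(fold_res),
    confusion = confusion_table(truth, pred),
    n_trials = length(truth), method = method
  ), class = "decoding_report")
}
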