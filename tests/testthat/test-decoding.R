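sch1 <- eoi_scheme("Fz", "P3", "P4")

make_feature_fixture <- function(n = 60, sep = 2, seed = 1) {
  set.seed(seed)
  y <- rep(c("left", "right"), each = n / 2)
  X <- matrix(rnorm(n * 10, 0, 1), n, 10)
  X[y == "right", 1:5] <- X[y == "right", 1:5] + sep
  f <- tibble::as_tibble(as.data.frame(X))
  names(f) <- paste0("f", 1:10)
  out <- dplyr::bind_cols(tibble::tibble(trial_id = 1:n,
                                         attended_side = y), f)
  attr(out, "feature_cols") <- paste0("f", 1:10)
  out
}

test_that("feature matrix has ten columns of in-range ISPC values", {
  ns <- 600 # 1200 ms at 500 Hz starting at 400 ms
  n <- 12
  tt <- 0.4 + (seq_len(ns) - 1) / FS
  base <- matrix(rep(2 * pi * 10 * tt, n), n, byrow = TRUE)
  tens <- phase_tensor(list(Fz = base, P3 = base, P4 = base), t0 = 0.4)
  tr <- balanced_trials(n)
  f <- build_features(tens, tr, sch1)
  fc <- attr(f, "feature_cols")
  expect_length(fc, 10)
  expect_equal(fc[1:5], paste0("fmpr_", gsub("-", "_", names(cue_windows()))))
  # identical phases across the network -> all features 1
  expect_true(all(abs(as.matrix(f[, fc]) - 1) < 1e-12))
})

test_that("feature means increase monotonically with coupling strength", {
  kappas <- c(0.25, 0.5, 1, 2, 4)
  set.seed(3)
  means <- vapply(kappas, function(k) {
    n <- 30; ns <- 600
    tt <- 0.4 + (seq_len(ns) - 1) / FS
    base <- matrix(rep(2 * pi * 10 * tt, n), n, byrow = TRUE)
    jit <- matrix(alphasync:::rvonmises(n * ns, 0, k), n, ns)
    tens <- phase_tensor(list(Fz = base, P3 = base + jit,
                              P4 = base + jit), t0 = 0.4)
    f <- build_features(tens, balanced_trials(n), sch1)
    mean(as.matrix(f[, attr(f, "feature_cols")]))
  }, numeric(1))
  expect_equal(cor(means, besselI(kappas, 1) / besselI(kappas, 0),
                   method = "spearman"), 1)
})

test_that("grid optimization solves a separable toy and not shuffled labels", {
  f <- make_feature_fixture(sep = 4)
  opt <- optimize_rbf_svm(f, split_plan(seed = 2), grid_spec())
  expect_equal(opt$best_accuracy, 1)
  expect_equal(nrow(opt$landscape), 100)

  set.seed(9)
  f2 <- f
  f2$attended_side <- sample(f2$attended_side)
  opt2 <- optimize_rbf_svm(f2, split_plan(seed = 2), grid_spec())
  # validation set has 12 trials; 95% binomial band around 0.5
  expect_lt(opt2$best_accuracy, 0.5 + 1.96 * sqrt(0.25 / 12) + 1e-9)
})

test_that("cross-validation is perfect on leaked labels and reports a clean confusion", {
  f <- make_feature_fixture(sep = 6)
  rep_ <- crossval_evaluate(f, split_plan(seed = 5))
  expect_equal(rep_$accuracy, 1)
  conf <- rep_$confusion
  expect_equal(sum(conf$count), nrow(f))
  rows <- conf |>
    dplyr::group_by(truth) |>
    dplyr::summarise(pct = sum(percent))
  expect_true(all(abs(rows$pct - 100) < 0.1))
  diag_counts <- conf$count[conf$truth == conf$predicted]
  expect_equal(sum(diag_counts), nrow(f))
})

test_that("decoding respects trial-id keyed splits under row permutation", {
  f <- make_feature_fixture(sep = 1, seed = 4)
  r1 <- crossval_evaluate(f, split_plan(seed = 3))
  perm <- sample(nrow(f))
  f2 <- f[perm, ]
  attr(f2, "feature_cols") <- attr(f, "feature_cols")
  r2 <- crossval_evaluate(f2, split_plan(seed = 3))
  expect_equal(r1$accuracy, r2$accuracy)
  expect_equal(r1$fold_results$accuracy, r2$fold_results$accuracy)
})

test_that("sLDA with full shrinkage reduces to nearest class mean", {
  f <- make_feature_fixture(sep = 3, seed = 6)
  X <- as.matrix(f[, attr(f, "feature_cols")])
  y <- f$attended_side
  model <- alphasync:::slda_train(X, y, lambda = 1)
  pred <- alphasync:::slda_predict(model, X)
  mu_l <- colMeans(X[y == "left", ]); mu_r <- colMeans(X[y == "right", ])
  nearest <- ifelse(
    colSums((t(X) - mu_r)^2) < colSums((t(X) - mu_l)^2), "right", "left")
  expect_equal(pred, unname(nearest))

  rep_ <- baseline_classifiers(f, split_plan(seed = 7), "slda")
  expect_gt(rep_$accuracy, 0.9)
})

test_that("Riemannian distance is a metric at zero and RMDM separates rotated covariances", {
  A <- crossprod(matrix(rnorm(16), 4)) + diag(4)
  expect_equal(riemann_dist(A, A), 0, tolerance = 1e-8)
  B <- crossprod(matrix(rnorm(16), 4)) + diag(4)
  expect_gt(riemann_dist(A, B), 0)
  expect_equal(riemann_dist(A, B), riemann_dist(B, A), tolerance = 1e-8)

  set.seed(8)
  n <- 40
  y <- rep(c("left", "right"), each = n / 2)
  th <- pi / 3
  R <- rbind(c(cos(th), -sin(th)), c(sin(th), cos(th)))
  base <- diag(c(4, 0.5))
  covs <- lapply(seq_len(n), function(i) {
    S <- if (y[i] == "right") R %*% base %*% t(R) else base
    X <- matrix(rnorm(100 * 2), 100) %*% chol(S)
    stats::cov(X) + diag(1e-10 * sum(diag(stats::cov(X))), 2)
  })
  names(covs) <- seq_len(n)
  f <- make_feature_fixture(n = n, sep = 0, seed = 9)
  f$attended_side <- y
  rep_ <- baseline_classifiers(f, split_plan(seed = 10), "rmdm",
                               covs = covs)
  expect_gt(rep_$accuracy, 0.5 + 1.96 * sqrt(0.25 / n))

  # identical class distributions: within the chance band
  covs0 <- lapply(seq_len(n), function(i) {
    X <- matrix(rnorm(100 * 2), 100) %*% chol(base)
    stats::cov(X) + diag(1e-10, 2)
  })
  names(covs0) <- seq_len(n)
  rep0 <- baseline_classifiers(f, split_plan(seed = 11), "rmdm",
                               covs = covs0)
  expect_lt(abs(rep0$accuracy - 0.5), 2.58 * sqrt(0.25 / n))
})

test_that("trial covariances are SPD and regularized", {
  set.seed(10)
  n <- 5; ns <- 100
  ph <- lapply(c("Fz", "P3", "P4"), function(ch)
    matrix(runif(n * ns, -pi, pi), n, ns))
  names(ph) <- c("Fz", "P3", "P4")
  tens <- phase_tensor(ph)
  covs <- trial_covariances(tens)
  expect_length(covs, n)
  for (C in covs) {
    expect_true(isSymmetric(C, tol = 1e-10))
    expect_true(all(eigen(C, symmetric = TRUE, only.values = TRUE)$values > 0))
  }
})
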