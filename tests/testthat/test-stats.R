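sch1 <- eoi_scheme("Fz", "P3", "P4")

test_that("permutation test p-value follows the strict one-tailed rule", {
  set.seed(2)
  # strong planted contra effect: observed should beat every surrogate
  tens <- coupled_phase_tensor(60, 20, kappa_l = 8, kappa_r = 8)
  tr <- balanced_trials(60)
  # contra for left-attend is FM-PR; make right-parietal locked only for
  # attend-left trials by regenerating: simpler, use asymmetric kappas and
  # both conditions
  res <- plv_permutation_test(tens, tr, sch1, list(w = c(0, 50)),
                              n_iter = 200, seed = 3)
  expect_s3_class(res, "plv_perm_test")
  expect_true(all(res$result$p >= 0 & res$result$p <= 1))
  expect_equal(nrow(res$surrogates), 200)
  expect_equal(res$result$p_min, 1 / 200)

  # identical seeds reproduce exactly; different seeds agree statistically
  res2 <- plv_permutation_test(tens, tr, sch1, list(w = c(0, 50)),
                               n_iter = 200, seed = 3)
  expect_identical(res$result, res2$result)
  res3 <- plv_permutation_test(tens, tr, sch1, list(w = c(0, 50)),
                               n_iter = 200, seed = 4)
  p <- res$result$p
  expect_lt(abs(res3$result$p - p),
            3 * sqrt(max(p * (1 - p), 0.01) / 200) + 0.05)
})

test_that("smoothed p-value floor is 1/(n_iter + 1) for a dominant effect", {
  set.seed(11)
  n <- 40
  base <- matrix(runif(n, -pi, pi), n, 10)
  tr <- balanced_trials(n)
  iL <- tr$attended_side == "left"
  # plant: PR locked to FM on attend-left (contra), PL locked on
  # attend-right (contra), everything else uniform
  pr <- matrix(runif(n * 10, -pi, pi), n, 10)
  pl <- matrix(runif(n * 10, -pi, pi), n, 10)
  pr[iL, ] <- base[iL, ] + 0.2
  pl[!iL, ] <- base[!iL, ] + 0.2
  tens <- phase_tensor(list(Fz = base, P3 = pl, P4 = pr))
  res <- plv_permutation_test(tens, tr, sch1, list(w = c(0, 100)),
                              n_iter = 100, seed = 5, smooth = TRUE)
  expect_equal(res$result$p, 1 / 101)
  res0 <- plv_permutation_test(tens, tr, sch1, list(w = c(0, 100)),
                               n_iter = 100, seed = 5)
  expect_equal(res0$result$p, 0) # strict rule
})

test_that("Monte-Carlo p matches the exhaustive oracle on a 4-trial toy", {
  set.seed(21)
  n <- 4
  phases <- list(Fz = matrix(runif(n * 6, -pi, pi), n, 6),
                 P3 = matrix(runif(n * 6, -pi, pi), n, 6),
                 P4 = matrix(runif(n * 6, -pi, pi), n, 6))
  tens <- phase_tensor(phases)
  tr <- balanced_trials(4)
  win <- list(w = c(0, 100))
  res <- plv_permutation_test(tens, tr, sch1, win, n_iter = 2000, seed = 7)

  # exhaustive oracle: all C(4,2) assignments, statistic computed from
  # first principles
  stat_for <- function(left_idx) {
    plvw <- function(ch_pair, idx) {
      dphi <- phases[[ch_pair[1]]][idx, , drop = FALSE] -
        phases[[ch_pair[2]]][idx, , drop = FALSE]
      mean(Mod(colMeans(exp(1i * dphi))))
    }
    contra <- (plvw(c("Fz", "P4"), left_idx) +
                 plvw(c("Fz", "P3"), setdiff(1:4, left_idx))) / 2
    ipsi <- (plvw(c("Fz", "P3"), left_idx) +
               plvw(c("Fz", "P4"), setdiff(1:4, left_idx))) / 2
    contra - ipsi
  }
  obs <- stat_for(which(tr$attended_side == "left"))
  expect_equal(res$result$observed, obs, tolerance = 1e-10)
  perms <- utils::combn(4, 2, simplify = FALSE)
  null_stats <- vapply(perms, stat_for, numeric(1))
  p_exh <- mean(null_stats > obs)
  expect_lt(abs(res$result$p - p_exh), 0.05)
})

test_that("group test averages surrogates and reduces to the individual test", {
  set.seed(31)
  tens <- coupled_phase_tensor(30, 10, 1, 1)
  tr <- balanced_trials(30)
  ind <- plv_permutation_test(tens, tr, sch1, list(w = c(0, 50)),
                              n_iter = 300, seed = 9)
  grp1 <- group_permutation_test(list(ind))
  expect_equal(grp1$result$p, ind$result$p)
  expect_equal(grp1$surrogates, ind$surrogates)

  # planted group effect across participants: contra kappa 2, ipsi 0.5
  make_part <- function(s) {
    set.seed(s)
    n <- 40
    tr <- balanced_trials(n)
    iL <- tr$attended_side == "left"
    base <- matrix(runif(n * 10, -pi, pi), n, 10)
    pr <- base + matrix(alphasync:::rvonmises(n, 0, 2), n, 10)
    pl <- base + matrix(alphasync:::rvonmises(n, 0, 2), n, 10)
    pr[!iL, ] <- base[!iL, ] +
      matrix(alphasync:::rvonmises(sum(!iL), 0, 0.5), sum(!iL), 10)
    pl[iL, ] <- base[iL, ] +
      matrix(alphasync:::rvonmises(sum(iL), 0, 0.5), sum(iL), 10)
    tens <- phase_tensor(list(Fz = base, P3 = pl, P4 = pr))
    plv_permutation_test(tens, tr, sch1, list(w = c(0, 50)),
                         n_iter = 300, seed = 100 + s)
  }
  grp <- group_permutation_test(lapply(1:6, make_part))
  expect_lt(grp$result$p, 0.05)

  bad <- plv_permutation_test(tens, tr, sch1, list(w = c(0, 50)),
                              n_iter = 100, seed = 1)
  expect_error(group_permutation_test(list(ind, bad)),
               class = "alphasync_mismatched_iters")
})

test_that("cluster test finds nothing below threshold and recovers a planted effect", {
  set.seed(41)
  n <- 60; Tn <- 50
  half <- matrix(rnorm(n / 2 * Tn), n / 2, Tn)
  x <- rbind(half, half) # identical groups: every samplewise t is zero
  labels <- rep(c("left", "right"), each = n / 2)
  null_res <- cluster_permutation_li(x, labels, n_rand = 500, seed = 1)
  expect_equal(nrow(null_res$clusters), 0)

  # planted sustained right > left effect, d = 1, samples 20..27 (160 ms
  # at 50 Hz resolution)
  x2 <- matrix(rnorm(n * Tn), n, Tn)
  x2[labels == "right", 20:27] <- x2[labels == "right", 20:27] + 1
  tms <- seq(0, by = 20, length.out = Tn)
  res <- cluster_permutation_li(x2, labels, time_ms = tms, n_rand = 1000,
                                seed = 2)
  expect_gt(nrow(res$clusters), 0)
  sig <- res$clusters[res$clusters$significant, ]
  expect_gt(nrow(sig), 0)
  # the significant cluster overlaps the planted window
  expect_true(any(sig$start_ms <= tms[27] & sig$end_ms >= tms[20]))

  # seed reproducibility
  res2 <- cluster_permutation_li(x2, labels, time_ms = tms, n_rand = 1000,
                                 seed = 2)
  expect_identical(res$clusters, res2$clusters)
  expect_error(cluster_permutation_li(matrix(1, 10, 5), labels[1:10]),
               class = "alphasync_zero_variance")
})

test_that("paired cluster variant detects a group-level LI shift", {
  set.seed(51)
  n <- 12; Tn <- 40
  d <- matrix(rnorm(n * Tn, 0, 1), n, Tn)
  d[, 15:22] <- d[, 15:22] + 1.2
  res <- cluster_permutation_li(d, paired = TRUE, n_rand = 1000, seed = 3)
  expect_true(any(res$clusters$significant))
  null <- cluster_permutation_li(matrix(rnorm(n * Tn), n, Tn),
                                 paired = TRUE, n_rand = 500, seed = 4)
  expect_true(all(!null$clusters$significant) || nrow(null$clusters) == 0)
})

test_that("t test against chance matches the closed form", {
  r <- c(0.35, 0.45, 0.30, 0.40)
  out <- ttest_vs_chance(r, 0.25)
  t_manual <- (mean(r) - 0.25) / (sd(r) / sqrt(4))
  expect_equal(out$t, t_manual, tolerance = 1e-10)
  expect_equal(out$df, 3)
  expect_equal(out$p, pt(t_manual, 3, lower.tail = FALSE), tolerance = 1e-10)

  sym <- c(0.20, 0.30)
  out2 <- ttest_vs_chance(sym, 0.25)
  expect_equal(out2$t, 0, tolerance = 1e-12)
  expect_equal(out2$p, 0.5, tolerance = 1e-12)

  tight <- 0.40 + c(-1, 0, 1, -1, 0, 1) * 1e-4
  expect_lt(ttest_vs_chance(tight, 0.25)$p, 1e-6)
  expect_error(ttest_vs_chance(rep(0.3, 4)),
               class = "alphasync_zero_variance")
})

test_that("LI-PLV correlations apply Benjamini-Hochberg across the family", {
  x <- 1:10
  d <- tibble::tibble(window = "w", condition = "c",
                      li = x, plv_diff = 2 * x + 1)
  out <- correlate_li_plv(d)
  expect_equal(out$r, 1, tolerance = 1e-12)

  # step-up on p = .01 .02 .03 .04 with m = 4 gives q = .04 everywhere
  expect_equal(p.adjust(c(0.01, 0.02, 0.03, 0.04), "BH"), rep(0.04, 4))

  # critical |r| at alpha = .05, n = 10: about 5% of independent pairs
  set.seed(61)
  hits <- mean(replicate(1000, abs(cor(rnorm(10), rnorm(10))) > 0.632))
  expect_lt(abs(hits - 0.05), 0.02)
})
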