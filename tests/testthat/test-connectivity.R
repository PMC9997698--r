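test_that("PLV analytic cases: constant offset, antipodal pair, null scale", {
  # constant pi/4 offset on every trial -> PLV 1
  n <- 8; ns <- 10
  base <- matrix(runif(n * ns, -pi, pi), n, ns)
  tens <- phase_tensor(list(A = base, B = base - pi / 4))
  expect_equal(plv_cross_trial(tens, c("A", "B"))$plv, rep(1, ns))

  # two trials, offsets 0 and pi -> PLV 0
  b2 <- matrix(0, 2, 5)
  tens2 <- phase_tensor(list(A = b2, B = rbind(rep(0, 5), rep(pi, 5))))
  expect_equal(plv_cross_trial(tens2, c("A", "B"))$plv, rep(0, 5),
               tolerance = 1e-12)

  expect_error(plv_cross_trial(tens, c("A", "B"), trials = 1),
               class = "alphasync_too_few_trials")
})

test_that("null PLV matches the Rayleigh resultant-length expectation", {
  # mean PLV of n uniform phase differences ~ sqrt(pi / (4 n))
  set.seed(42)
  n <- 1000; reps <- 200
  vals <- replicate(reps, {
    dphi <- runif(n, -pi, pi)
    Mod(mean(exp(1i * dphi)))
  })
  expected <- sqrt(pi / (4 * n))
  se <- sd(vals) / sqrt(reps)
  expect_lt(abs(mean(vals) - expected), 3 * se)
  # and the engine agrees with the direct formula on one draw
  ns <- 4
  ph <- matrix(runif(n * ns, -pi, pi), n, ns)
  tens <- phase_tensor(list(A = ph, B = matrix(0, n, ns)))
  direct <- Mod(colMeans(exp(1i * ph)))
  expect_equal(plv_cross_trial(tens, c("A", "B"))$plv, direct,
               tolerance = 1e-12)
})

test_that("network PLV averages moduli over the 9 pairs, not complex means", {
  sch <- eoi_scheme()
  n <- 12; ns <- 6
  chans <- c(sch$fm, sch$pl, sch$pr)
  # every pair perfectly locked but at different offsets: pair PLVs all 1,
  # complex-mean-first would cancel
  offs <- seq(0, 2 * pi, length.out = length(chans) + 1)[seq_along(chans)]
  base <- matrix(runif(n * ns, -pi, pi), n, ns)
  phases <- stats::setNames(lapply(offs, function(o) base + o), chans)
  tens <- phase_tensor(phases)
  tr <- balanced_trials(n)
  np <- network_plv(tens, tr, sch)
  expect_equal(np$plv, rep(1, nrow(np)), tolerance = 1e-12)
  # the alternative order would NOT give 1 here
  cm <- Mod(mean(exp(1i * (offs[1] - offs[4:6]))))
  expect_lt(cm, 0.999)
})

test_that("contra/ipsi collapsing maps cells correctly and symmetrically", {
  grid <- expand.grid(network = c("FM-PL", "FM-PR"),
                      condition = c("attend-left", "attend-right"),
                      frequency = 10, time_ms = 0,
                      stringsAsFactors = FALSE)
  grid$n_trials <- 10
  grid$plv <- c(0.3, 0.6, 0.4, 0.3) # PL|L, PR|L, PL|R, PR|R
  cc <- collapse_contra_ipsi(tibble::as_tibble(grid))
  expect_equal(cc$plv[cc$laterality == "contra"], (0.6 + 0.4) / 2)
  expect_equal(cc$plv[cc$laterality == "ipsi"], (0.3 + 0.3) / 2)

  swapped <- grid
  swapped$condition <- ifelse(grid$condition == "attend-left",
                              "attend-right", "attend-left")
  cs <- collapse_contra_ipsi(tibble::as_tibble(swapped))
  expect_equal(cs$plv[cs$laterality == "contra"],
               cc$plv[cc$laterality == "ipsi"])
  expect_error(collapse_contra_ipsi(grid[1:2, ]),
               class = "alphasync_incomplete_series")
})

test_that("window averaging is a half-open rectangular mean", {
  df <- tibble::tibble(time_ms = seq(0, 395, by = 5),
                       plv = seq(0, 395, by = 5)) # linear ramp
  wa <- window_average(df, list(a = c(0, 200), b = c(200, 400)))
  # mean of a linear function = value at window midpoint (of sampled pts)
  expect_equal(wa$plv[wa$window == "a"], mean(seq(0, 195, by = 5)))
  expect_equal(wa$plv[wa$window == "b"], mean(seq(200, 395, by = 5)))

  const <- tibble::tibble(time_ms = 0:99, plv = 0.7)
  expect_equal(window_average(const, list(c(0, 50)))$plv, 0.7)
  expect_error(window_average(const, list(c(500, 600))),
               class = "alphasync_empty_window")
  expect_length(cue_windows(), 5)
  expect_true(all(vapply(cue_windows(), diff, numeric(1)) == 200))
})

test_that("frequency and window means commute for rectangular averaging", {
  set.seed(3)
  df <- expand.grid(frequency = c(9.5, 11.5, 13.8),
                    time_ms = seq(500, 695, by = 5))
  df$plv <- runif(nrow(df))
  df <- tibble::as_tibble(df)
  a <- window_average(df, list(w = c(500, 700)), freq_average = TRUE)$plv
  b <- df |>
    dplyr::group_by(time_ms) |>
    dplyr::summarise(plv = mean(plv)) |>
    window_average(list(w = c(500, 700)), freq_average = FALSE)
  expect_equal(a, b$plv)
})

test_that("ISPC: identical signals give 1, beating gives 0, von Mises matches Bessel", {
  ns <- 500; n <- 40
  tt <- (seq_len(ns) - 1) / FS
  base <- matrix(rep(2 * pi * 10 * tt, n), n, byrow = TRUE)
  tens <- phase_tensor(list(A = base, B = base))
  v <- plv_cross_time(tens, c("A", "B"), c(0, 1000))
  expect_equal(v$ispc, rep(1, n))

  # 5 Hz offset over an integer number of beat cycles
  off <- matrix(rep(2 * pi * 15 * tt, n), n, byrow = TRUE)
  tens2 <- phase_tensor(list(A = base, B = off))
  v2 <- plv_cross_time(tens2, c("A", "B"), c(0, 400)) # 2 beat cycles
  expect_lt(max(v2$ispc), 0.02)

  set.seed(5)
  for (k in c(0.5, 2)) {
    jit <- matrix(alphasync:::rvonmises(n * ns, 0, k), n, ns)
    tens3 <- phase_tensor(list(A = base, B = base + jit))
    v3 <- plv_cross_time(tens3, c("A", "B"), c(0, 1000))
    expect_lt(abs(mean(v3$ispc) - besselI(k, 1) / besselI(k, 0)),
              3 / sqrt(ns))
  }
  expect_error(plv_cross_time(tens, c("A", "B"), c(0, 1 / FS * 1000)),
               class = "alphasync_window_too_short")
})

test_that("PLM concentrates at 1 for locked pairs and drops for detuned ones", {
  ns <- 1000; n <- 6
  tt <- (seq_len(ns) - 1) / FS
  base <- matrix(rep(2 * pi * 10 * tt, n), n, byrow = TRUE)
  locked <- phase_tensor(list(A = base, B = base + 0.3))
  expect_equal(plm(locked, c("A", "B"))$plm, rep(1, n), tolerance = 1e-9)

  # constant 5 Hz frequency offset >> 1 Hz bandwidth
  det <- phase_tensor(list(A = base, B = base + 2 * pi * 5 *
                             matrix(rep(tt, n), n, byrow = TRUE)))
  expect_lt(max(plm(det, c("A", "B"))$plm), 0.1)

  # independent random phases: PLM ~ fraction of band in spectrum, small
  set.seed(6)
  noisy <- phase_tensor(list(A = matrix(runif(n * ns, -pi, pi), n),
                             B = matrix(runif(n * ns, -pi, pi), n)))
  expect_lt(mean(plm(noisy, c("A", "B"))$plm), 0.2)
})

test_that("phase metrics ignore common amplitude and phase shifts", {
  ns <- 200; n <- 20
  set.seed(7)
  pa <- matrix(runif(n * ns, -pi, pi), n, ns)
  pb <- pa + matrix(alphasync:::rvonmises(n, 0, 1), n, ns)
  t1 <- phase_tensor(list(A = pa, B = pb))
  # amplitude rescaling of the coefficients
  t2 <- t1
  t2$coeffs <- t1$coeffs * 7.3
  expect_equal(plv_cross_trial(t2, c("A", "B"))$plv,
               plv_cross_trial(t1, c("A", "B"))$plv, tolerance = 1e-12)
  # common phase constant
  t3 <- phase_tensor(list(A = pa + 1.1, B = pb + 1.1))
  expect_equal(plv_cross_trial(t3, c("A", "B"))$plv,
               plv_cross_trial(t1, c("A", "B"))$plv, tolerance = 1e-12)
  expect_equal(plv_cross_time(t3, c("A", "B"), c(0, 300))$ispc,
               plv_cross_time(t1, c("A", "B"), c(0, 300))$ispc,
               tolerance = 1e-12)
})

test_that("flipping one phase difference to antipodal lowers PLV", {
  ns <- 3
  ph <- matrix(alphasync:::rvonmises(30, 0, 3), 30, ns)
  t1 <- phase_tensor(list(A = ph, B = matrix(0, 30, ns)))
  ph2 <- ph; ph2[1, ] <- ph2[1, ] + pi
  t2 <- phase_tensor(list(A = ph2, B = matrix(0, 30, ns)))
  expect_true(all(plv_cross_trial(t2, c("A", "B"))$plv <
                    plv_cross_trial(t1, c("A", "B"))$plv))
})
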