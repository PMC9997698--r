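t_ax <- seq(0, 4 - 1 / FS, by = 1 / FS)

test_that("conditioning removes DC, notches 50 Hz and passes 10 Hz with zero lag", {
  dc <- vec_epochs(rep(3, length(t_ax)))
  expect_lt(max(abs(condition_signal(dc)$data)), 1e-6)

  mid <- 500:1500
  x50 <- sin(2 * pi * 50 * t_ax)
  y50 <- condition_signal(vec_epochs(x50))$data[1, 1, ]
  atten_db <- 20 * log10(sqrt(mean(y50[mid]^2)) / sqrt(mean(x50[mid]^2)))
  expect_lt(atten_db, -30)

  x10 <- sin(2 * pi * 10 * t_ax)
  y10 <- condition_signal(vec_epochs(x10))$data[1, 1, ]
  gain <- sqrt(mean(y10[mid]^2)) / sqrt(mean(x10[mid]^2))
  expect_true(gain > 0.95 && gain < 1.05)
  cc <- stats::ccf(y10[mid], x10[mid], lag.max = 5, plot = FALSE)
  expect_equal(cc$lag[which.max(cc$acf)], 0)
})

test_that("conditioning is linear and preserves a symmetric pulse peak", {
  set.seed(4)
  x <- rnorm(length(t_ax)); y <- rnorm(length(t_ax))
  f <- function(v) condition_signal(vec_epochs(v))$data[1, 1, ]
  expect_equal(f(2 * x + 3 * y), 2 * f(x) + 3 * f(y), tolerance = 1e-8)

  pulse <- exp(-((t_ax - 2)^2) / (2 * 0.05^2))
  yp <- f(pulse)
  expect_equal(which.max(yp), which.max(pulse))
})

test_that("SOS Butterworth matches signal::butter at low order", {
  sos <- alphasync:::butter_sos(4, 45, FS, "low")
  bt <- signal::butter(4, 45 / (FS / 2), "low")
  H <- function(b, a, f) {
    z <- exp(-1i * 2 * pi * f / FS)
    sum(b * z^(0:(length(b) - 1))) / sum(a * z^(0:(length(a) - 1)))
  }
  for (f in c(5, 20, 45, 60, 100)) {
    Hs <- prod(vapply(sos, function(s) H(s$b, s$a, f), complex(1)))
    expect_equal(Mod(Hs), Mod(H(bt$b, bt$a, f)), tolerance = 1e-6)
  }
})

test_that("EOG rejection uses a strict 50 uV rule", {
  n <- 200
  arr <- array(0, dim = c(3, 2, n))
  arr[2, 1, 100] <- 60   # spike on EOG channel, trial 2
  arr[3, 1, 50] <- 50    # exactly at threshold, trial 3
  ep <- epoch_set(arr, FS, 0, "cue", c("EOG", "Cz"))
  keep <- reject_eog_trials(ep, "EOG", 50)
  expect_equal(keep, c(TRUE, FALSE, TRUE))
  expect_true(all(reject_eog_trials(ep, "Cz", 50)))
  expect_error(reject_eog_trials(ep, "nope", 50),
               class = "alphasync_unknown_channel")
})

test_that("channel repair is an inverse-distance neighbor average", {
  m <- montage_1010()
  nb <- m$neighbors[["Cz"]]
  chans <- c("Cz", nb)
  w <- sin(2 * pi * 7 * t_ax[1:100])
  sig <- matrix(rep(w, length(chans)), nrow = length(chans), byrow = TRUE)
  rownames(sig) <- chans
  sig[1, ] <- 99 # corrupt Cz
  ep <- mat_epochs(sig, montage = m)
  rep1 <- repair_channels(ep, "Cz")
  expect_equal(rep1$data[1, 1, ], w, tolerance = 1e-12)
  # untouched good channel
  expect_equal(rep1$data[1, 2, ], w)
  expect_error(repair_channels(ep, chans), # every neighbor bad too
               class = "alphasync_unrepairable")

  # two equidistant neighbors with values 1 and 3 average to 2
  m2 <- list(positions = tibble::tibble(channel = c("b", "l", "r"),
                                        x = c(0, -1, 1), y = 0),
             neighbors = list(b = c("l", "r"), l = "b", r = "b"),
             radius = 1)
  class(m2) <- "montage"
  sig2 <- rbind(b = rep(9, 10), l = rep(1, 10), r = rep(3, 10))
  ep2 <- mat_epochs(sig2, montage = m2)
  expect_equal(repair_channels(ep2, "b")$data[1, 1, ], rep(2, 10))
})

test_that("mirroring triples length, trims to identity, flattens edges", {
  x <- cos(2 * pi * 10 * t_ax)
  ep <- vec_epochs(x)
  mir <- epoch_mirror(ep)
  expect_equal(dim(mir$data)[3], 3 * length(x))
  back <- epoch_trim(mir)
  expect_equal(back$data, ep$data)
  expect_equal(time_axis(back), time_axis(ep))

  tm <- morlet_transform(ep, morlet_bank(10, 5, FS))
  pw <- Mod(tm$coeffs[1, 1, 1, ])^2
  centre <- pw[length(pw) / 2]
  expect_lt(abs(pw[1] / centre - 1), 0.1)
  expect_lt(abs(pw[length(pw)] / centre - 1), 0.1)
  tu <- morlet_transform(ep, morlet_bank(10, 5, FS), mirror = FALSE)
  pwu <- Mod(tu$coeffs[1, 1, 1, ])^2
  expect_lt(pwu[1] / centre, 0.5) # >50% droop unmirrored
})

test_that("Hjorth filter is the local difference and is not idempotent", {
  m <- small_montage()
  chans <- m$positions$channel
  same <- matrix(rep(sin(2 * pi * 5 * t_ax[1:200]), length(chans)),
                 nrow = length(chans), byrow = TRUE)
  rownames(same) <- chans
  expect_lt(max(abs(hjorth_laplacian(mat_epochs(same, montage = m))$data)),
            1e-10)

  solo <- matrix(0, length(chans), 50)
  rownames(solo) <- chans
  active <- "Pz"
  solo[active, ] <- 1
  hj <- hjorth_laplacian(mat_epochs(solo, montage = m))
  expect_equal(hj$data[1, match(active, chans), ], rep(1, 50))
  for (nb in intersect(m$neighbors[[active]], chans)) {
    k <- length(intersect(m$neighbors[[nb]], chans))
    expect_equal(hj$data[1, match(nb, chans), ], rep(-1 / k, 50))
  }
  twice <- hjorth_laplacian(hj)
  expect_false(isTRUE(all.equal(twice$data, hj$data)))
})

test_that("trial selection keeps valid and correct trials by default", {
  tbl <- tibble::tibble(
    trial_id = 1:4,
    valid = c(TRUE, TRUE, FALSE, FALSE),
    correct = c(TRUE, FALSE, TRUE, FALSE)
  )
  expect_equal(select_trials(tbl), c(TRUE, FALSE, FALSE, FALSE))
  expect_equal(sum(select_trials(tbl, "valid")), 2)
  expect_true(all(select_trials(tbl[tbl$valid & tbl$correct, ])))
  expect_error(select_trials(tbl[tbl$valid & !tbl$correct, ]),
               class = "alphasync_empty_selection")
})

test_that("selection rate tracks validity times hit rate", {
  cfg <- sim_config(n_trials = 10000, seed = 77)
  tr <- simulate_behavior(design_trials(cfg), cfg)
  frac <- mean(select_trials(tr))
  expect_lt(abs(frac - 0.75 * 0.68), 0.02)
})

test_that("repair and Hjorth commute with channel permutation", {
  m <- small_montage()
  chans <- m$positions$channel
  set.seed(8)
  sig <- matrix(rnorm(length(chans) * 100), length(chans), 100)
  rownames(sig) <- chans
  ep <- mat_epochs(sig, montage = m)
  perm <- sample(length(chans))
  epp <- mat_epochs(sig[perm, ], montage = m)
  hj <- hjorth_laplacian(ep)
  hjp <- hjorth_laplacian(epp)
  expect_equal(hjp$data[1, , ], hj$data[1, perm, ], tolerance = 1e-12)
  rp <- repair_channels(ep, "Pz")
  rpp <- repair_channels(epp, "Pz")
  expect_equal(rpp$data[1, , ], rp$data[1, perm, ], tolerance = 1e-12)
})
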