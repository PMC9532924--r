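test_that("analytic signal recovers the phase of pure oscillations", {
  fs <- 500
  t <- (0:(10 * fs - 1)) / fs
  x <- cos(2 * pi * 10 * t)
  z <- analytic_signal(x)
  expect_equal(Re(z), x, tolerance = 1e-9)
  phase <- instantaneous_phase(z)
  expected <- vnseeg:::wrap_phase(2 * pi * 10 * t)
  mid <- 500:4500
  expect_lt(max(abs(vnseeg:::wrap_phase(phase[mid] - expected[mid]))), 0.01)

  # quadrature identity: sin lags cos by pi/2
  y <- sin(2 * pi * 10 * t)
  py <- instantaneous_phase(analytic_signal(y))
  d <- vnseeg:::wrap_phase(phase[mid] - py[mid])
  expect_equal(mean(d), pi / 2, tolerance = 0.01)

  expect_error(analytic_signal(numeric(0)), "zero-length")
  expect_true(isTRUE(attr(analytic_signal(rep(0, 100)), "degenerate")))
})

test_that("PLV: constant difference gives 1, uniform gives ~0, antiphase mix cancels", {
  n <- 1000
  base <- stats::runif(n, -pi, pi)
  expect_equal(plv(base + pi / 4, base), 1, tolerance = 1e-12)
  set.seed(99)
  expect_lt(plv(stats::runif(1e6, 0, 2 * pi), numeric(1e6)), 5e-3)
  d <- rep(c(0, pi), each = 500)
  expect_equal(plv(d, numeric(n)), 0, tolerance = 1e-12)
  expect_error(plv(1:3, 1:4), "length mismatch")
})

test_that("PLI: constant nonzero lag gives 1, self gives exactly 0, symmetric lags cancel", {
  n <- 1000
  base <- stats::runif(n, -pi, pi)
  expect_equal(pli(base + pi / 4, base), 1)
  expect_identical(pli(base, base), 0)
  d <- rep(c(pi / 6, -pi / 6), each = 500)
  expect_equal(pli(d, numeric(n)), 0)
  # a constant pi lag carries no lead/lag information either
  expect_equal(pli(vnseeg:::wrap_phase(base + pi), base), 0)
})

test_that("wPLI: quarter-cycle lag gives 1, zero lag is degenerate, bounded by 1", {
  fs <- 500
  t <- (0:(4 * fs - 1)) / fs
  za <- analytic_signal(cos(2 * pi * 10 * t))
  zb <- analytic_signal(cos(2 * pi * 10 * t - pi / 2))
  idx <- 200:1800
  expect_equal(wpli(za[idx], zb[idx]), 1, tolerance = 1e-6)

  v <- wpli(za, za)
  expect_identical(as.numeric(v), 0)
  expect_true(isTRUE(attr(v, "degenerate")))

  set.seed(7)
  for (i in 1:50) {
    w <- wpli(rand_analytic(256), rand_analytic(256))
    expect_gte(as.numeric(w), 0)
    expect_lte(as.numeric(w), 1)
  }
})

test_that("metrics match brute-force implementations and are symmetric", {
  set.seed(31)
  for (i in 1:50) {
    n <- sample(100:400, 1)
    pa <- rand_phases(n); pb <- rand_phases(n)
    za <- rand_analytic(n); zb <- rand_analytic(n)
    expect_equal(plv(pa, pb), bf_plv(pa, pb), tolerance = 1e-12)
    expect_equal(pli(pa, pb), bf_pli(pa, pb), tolerance = 1e-12)
    expect_equal(as.numeric(wpli(za, zb)), bf_wpli(za, zb),
                 tolerance = 1e-12)
    expect_identical(plv(pa, pb), plv(pb, pa))
    expect_identical(pli(pa, pb), pli(pb, pa))
    expect_identical(as.numeric(wpli(za, zb)), as.numeric(wpli(zb, za)))
  }
})

test_that("metrics stay in [0,1] on random phase pairs", {
  set.seed(17)
  for (i in 1:1000) {
    pa <- rand_phases(64); pb <- rand_phases(64)
    v <- c(plv(pa, pb), pli(pa, pb))
    expect_true(all(v >= 0 & v <= 1))
  }
})

test_that("PLV is invariant to constant offsets; PLI to sign-preserving ones", {
  set.seed(3)
  pa <- rand_phases(500); pb <- rand_phases(500)
  expect_equal(plv(pa + 1.3, pb), plv(pa, pb), tolerance = 1e-12)
  # offset that keeps all wrapped differences strictly positive
  base <- stats::runif(500, 0.2, 0.4)
  expect_identical(pli(base + 0.5, numeric(500)), pli(base, numeric(500)))
})

test_that("global metric averages pairs correctly and ignores channel order", {
  # three channels with pairwise-constant lags -> all pair PLVs are 1
  n <- 1000
  base <- stats::runif(n, -pi, pi)
  ep <- epoch_set(list(rbind(cos(base), cos(base + 1), cos(base + 2))),
                  500, n / 500, c("a", "b", "c"))
  # use phases directly through plv: check the averaging arithmetic with a
  # constructed pair matrix instead
  g <- global_metric(epoch_set(list(rbind(sin((1:n) / 10),
                                          sin((1:n) / 10 + 0.7))),
                               500, n / 500, c("x", "y")), "plv")
  expect_equal(dim(g$pairs), c(2L, 2L))
  expect_true(is.na(g$pairs[1, 1]))
  expect_equal(g$value, g$pairs[1, 2])

  rec <- generate_coupled_recording(4, 4, 250,
                                    coupling_spec("alpha", 0.6), seed = 2)
  perm <- eeg_recording(rec$data[4:1, ], 250, rec$channel_labels[4:1])
  f1 <- extract_sync_features(rec, bands = eeg_bands("alpha"),
                              montage = NULL,
                              config = list(target_fs = 250))
  f2 <- extract_sync_features(perm, bands = eeg_bands("alpha"),
                              montage = NULL,
                              config = list(target_fs = 250))
  expect_equal(unname(f1), unname(f2), tolerance = 1e-12)

  expect_error(global_metric(epoch_set(list(matrix(rnorm(100), 1, 100)),
                                       50, 2, "x"), "plv"),
               "2 channels")
})

test_that("pair averaging is mean-of-epochs then mean-of-pairs", {
  # constructed fixture: metric values per pair {0.2, 0.4, 0.6} -> 0.4
  m <- matrix(NA_real_, 3, 3)
  m[1, 2] <- m[2, 1] <- 0.2
  m[1, 3] <- m[3, 1] <- 0.4
  m[2, 3] <- m[3, 2] <- 0.6
  expect_equal(mean(m[upper.tri(m)]), 0.4)
  # epoch-averaging consistency at the metric level: on rigidly locked
  # phases, per-epoch-then-average equals the whole-series computation
  phi <- cumsum(stats::runif(4000, 0.05, 0.15))
  pa <- vnseeg:::wrap_phase(phi)
  pb <- vnseeg:::wrap_phase(phi - pi / 4)
  per_epoch <- mean(sapply(split(seq_len(4000), rep(1:8, each = 500)),
                           function(idx) plv(pa[idx], pb[idx])))
  expect_equal(per_epoch, plv(pa, pb), tolerance = 1e-6)
  per_epoch_pli <- mean(sapply(split(seq_len(4000), rep(1:8, each = 500)),
                               function(idx) pli(pa[idx], pb[idx])))
  expect_equal(per_epoch_pli, pli(pa, pb), tolerance = 1e-6)
})

test_that("the sync feature vector has 18 named entries in [0,1]", {
  rec <- generate_coupled_recording(19, 4, 500,
                                    coupling_spec("high_beta", 0.6),
                                    seed = 4)
  f <- extract_sync_features(rec)
  expect_length(f, 18)
  expect_true(all(f >= 0 & f <= 1))
  expect_identical(
    names(f),
    paste(rep(c("plv", "pli", "wpli"), each = 6),
          rep(c("delta", "theta", "alpha", "beta", "low_beta",
                "high_beta"), 3), sep = "_"))
  expect_false(anyDuplicated(names(f)) > 0)
})

test_that("stronger high-beta coupling raises the extracted high-beta PLI", {
  vals <- sapply(1:20, function(s) {
    hi <- generate_coupled_recording(
      2, 8, 200, coupling_spec("high_beta", 0.8, mixing_coefficient = 0.1),
      seed = s)
    lo <- generate_coupled_recording(
      2, 8, 200, coupling_spec("high_beta", 0.4, mixing_coefficient = 0.1),
      seed = s + 1000)
    cfg <- list(target_fs = 200)
    c(extract_sync_features(hi, eeg_bands("high_beta"), NULL,
                            cfg)[["pli_high_beta"]],
      extract_sync_features(lo, eeg_bands("high_beta"), NULL,
                            cfg)[["pli_high_beta"]])
  })
  expect_gt(mean(vals[1, ]), mean(vals[2, ]))
})
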