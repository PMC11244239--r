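# Hilbert phase, PLI, correlation weights, cwPLI.

test_that("instantaneous phase matches the analytic-signal construction", {
  fs <- 256
  t <- seq_len(fs) / fs
  x <- cos(2 * pi * 8 * t)
  ph <- instantaneous_phase(x)
  # mid-epoch unwrapped slope ~ 2*pi*8 rad/s within 1%
  mid <- 64:192
  slope <- mean(diff(ph[mid]) %% (2 * pi)) * fs
  expect_lt(abs(slope - 2 * pi * 8) / (2 * pi * 8), 0.01)
  # quadrature identity: sin lags cos by pi/2
  y <- sin(2 * pi * 8 * t)
  dmid <- (instantaneous_phase(x) - instantaneous_phase(y))[mid]
  dmid <- Arg(exp(1i * dmid))
  expect_true(all(abs(dmid - pi / 2) < 0.05))
  # negation shifts phase by pi (mod 2pi)
  dneg <- Arg(exp(1i * (instantaneous_phase(-x) - ph)))[mid]
  expect_true(all(abs(abs(dneg) - pi) < 1e-6))
  # agreement with the independent oracle
  set.seed(41)
  z <- rnorm(256)
  expect_equal(instantaneous_phase(z), oracle_phase(z), tolerance = 1e-12)
  expect_warning(instantaneous_phase(rep(3, 64)), "constant")
})

test_that("pli reproduces the defining formula on constructed cases", {
  fs <- 256
  t <- seq_len(fs) / fs
  x <- cos(2 * pi * 10 * t)
  # constant nonzero lag -> 1; identical signals -> exactly 0
  expect_equal(pli(x, cos(2 * pi * 10 * t - pi / 4)), 1.0)
  expect_identical(pli(x, x), 0)
  expect_error(pli(x, x[-1]), "equal length")
})

test_that("pli agrees with the brute-force oracle on random epoch pairs", {
  set.seed(77)
  worst <- 0
  for (i in 1:1000) {
    x <- rnorm(64); y <- rnorm(64)
    got <- pli(x, y)
    want <- oracle_pli_from_phases(oracle_phase(x), oracle_phase(y))
    worst <- max(worst, abs(got - want))
  }
  expect_lt(worst, 1e-12)
})

test_that("independent white-noise epochs have low mean PLI", {
  set.seed(5)
  vals <- replicate(100, pli(rnorm(256), rnorm(256)))
  expect_lt(mean(vals), 0.15)
})

test_that("pli_matrix is symmetric, zero-diagonal, and reduces to pli()", {
  set.seed(9)
  dat <- matrix(rnorm(3 * 256), 3, 256)
  ep <- segment(eeg_recording(dat, fs = 256), 1)
  pm <- pli_matrix(ep)[, , 1]
  expect_identical(pm, t(pm))
  expect_identical(diag(pm), rep(0, 3))
  expect_equal(pm[1, 2], pli(dat[1, ], dat[2, ]))
  # two-channel case: single off-diagonal value
  ep2 <- segment(eeg_recording(dat[1:2, ], fs = 256), 1)
  pm2 <- pli_matrix(ep2)[, , 1]
  expect_equal(pm2[1, 2], pli(dat[1, ], dat[2, ]))
})

test_that("fully coupled synthetic cohort yields near-unit PLI everywhere", {
  sc <- synth_config(duration_s = 4, n_subjects_per_class = 1,
                     coupling_strength = c(control = 1, stroke = 1),
                     noise_sd = 0,
                     complexity_scale = c(control = 1e-8, stroke = 1e-8),
                     band_freqs = c(alpha = 10), band_amps = c(alpha = 1),
                     seed = 3)
  p <- subject_pli(segment(generate_subject(sc, 0L, 1L), 1))
  off <- p[row(p) != col(p)]
  expect_true(all(off >= 0.9))
})

test_that("correlation weights implement the cross-group comparison count", {
  mk <- function(v) matrix(c(0, v, v, 0), 2, 2)
  # all four stroke < control comparisons -> |0 - 4| / 4 = 1
  w <- correlation_weights(list(mk(0.1), mk(0.2)), list(mk(0.5), mk(0.6)))
  expect_equal(w[1, 2], 1.0)
  # perfect balance -> 0
  w0 <- correlation_weights(list(mk(0.1), mk(0.6)), list(mk(0.3), mk(0.3)))
  expect_equal(w0[1, 2], 0.0)
  # P = 20, M = 19 -> 380 comparisons per entry
  expect_identical(20L * 19L, 380L)
  # random matrices: symmetry, range, and equality with a direct loop
  set.seed(13)
  sp <- lapply(1:5, function(i) { m <- matrix(runif(16), 4, 4); (m + t(m)) / 2 })
  cp <- lapply(1:4, function(i) { m <- matrix(runif(16), 4, 4); (m + t(m)) / 2 })
  w <- correlation_weights(sp, cp)
  expect_equal(unclass(w), t(unclass(w)), ignore_attr = TRUE)
  expect_true(all(w >= 0 & w <= 1))
  for (i in 1:3) for (j in (i + 1):4) {
    nl <- 0L; ns <- 0L
    for (a in sp) for (b in cp) {
      if (a[i, j] > b[i, j]) nl <- nl + 1L
      if (a[i, j] < b[i, j]) ns <- ns + 1L
    }
    expect_equal(w[i, j], abs(nl - ns) / 20)
  }
  expect_error(correlation_weights(list(), cp), "non-empty")
})

test_that("apply_weights is the elementwise product and shrinks PLI", {
  set.seed(21)
  p <- matrix(runif(25), 5, 5); p <- (p + t(p)) / 2; diag(p) <- 0
  w <- matrix(runif(25), 5, 5); w <- (w + t(w)) / 2
  class(w) <- c("correlation_weights", class(w))
  cw <- apply_weights(p, w)
  for (i in 1:5) for (j in 1:5)
    expect_identical(cw[i, j], p[i, j] * unclass(w)[i, j])
  expect_true(all(cw <= p + 1e-15))
  expect_equal(apply_weights(p, structure(matrix(1, 5, 5),
               class = c("correlation_weights", "matrix"))), p)
  expect_true(all(apply_weights(p, structure(matrix(0, 5, 5),
               class = c("correlation_weights", "matrix"))) == 0))
  expect_error(apply_weights(p, structure(matrix(1, 4, 4),
               class = c("correlation_weights", "matrix"))), "match")
})

test_that("weighting does not narrow the standardized group gap", {
  gaps <- sapply(1:4, function(s) {
    ft <- tiny_cohort_features(400 + s, n_per_class = 4, duration_s = 10)
    lab <- vapply(ft, function(f) f$label, 0L)
    spl <- lapply(ft, function(f) f$spli)
    w <- correlation_weights(spl[lab == 1L], spl[lab == 0L])
    std_gap <- function(vals) {
      a <- vals[lab == 1L]; b <- vals[lab == 0L]
      abs(mean(a) - mean(b)) / sqrt((var(a) + var(b)) / 2)
    }
    raw <- std_gap(vapply(spl, mean_connectivity, 0))
    wtd <- std_gap(vapply(spl, function(m) mean_connectivity(
      apply_weights(m, w)), 0))
    wtd - raw
  })
  expect_true(all(gaps > -1e-8))
})
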