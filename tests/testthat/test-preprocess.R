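# Filtering, bad-channel interpolation, segmentation, artifact rejection.

make_rec <- function(dat, fs = 256, ch = NULL)
  eeg_recording(dat, fs = fs, channel_names = ch)

test_that("bandpass removes 50 Hz mains and preserves 10 Hz", {
  fs <- 256
  t <- seq_len(10 * fs) / fs
  mid <- (3 * fs):(7 * fs)
  rms <- function(x) sqrt(mean(x^2))
  r50 <- make_rec(matrix(sin(2 * pi * 50 * t), 1))
  out50 <- bandpass_filter(r50)$data[1, ]
  expect_lt(rms(out50[mid]), 0.01 * rms(r50$data[1, mid]))
  r10 <- make_rec(matrix(sin(2 * pi * 10 * t), 1))
  out10 <- bandpass_filter(r10)$data[1, ]
  expect_lt(abs(rms(out10[mid]) - rms(r10$data[1, mid])) / rms(r10$data[1, mid]),
            0.12)
  # zero in, zero out
  z <- bandpass_filter(make_rec(matrix(0, 2, fs)))
  expect_true(all(z$data == 0))
  expect_error(bandpass_filter(make_rec(matrix(0, 1, fs)), 1, 200),
               "fs/2")
})

test_that("filtering is idempotent on band-limited content", {
  set.seed(2)
  # band-limit first; re-filtering in-band content must be a near no-op
  rec <- bandpass_filter(make_rec(matrix(rnorm(4 * 2560), 4, 2560)))
  twice <- bandpass_filter(rec)
  mid <- 500:2000
  r1 <- sqrt(mean(rec$data[, mid]^2))
  r2 <- sqrt(mean(twice$data[, mid]^2))
  expect_lt(abs(r1 - r2) / r1, 0.02)
})

test_that("bad-channel interpolation repairs from scalp neighbours", {
  # smooth spatial field over the montage: nearby electrodes see similar
  # mixtures of two temporal sources, plus small sensor noise
  set.seed(6)
  xyz <- montage_coords()
  n <- 1024
  s1 <- sin(2 * pi * 9 * seq_len(n) / 256)
  s2 <- sin(2 * pi * 5 * seq_len(n) / 256 + 1)
  dat <- t(sapply(seq_len(19), function(ch)
    (1 + 0.4 * xyz[ch, "y"]) * s1 + 0.6 * xyz[ch, "z"] * s2 +
      rnorm(n, 0, 0.05)))
  rec <- make_rec(dat, ch = montage_channels())
  expect_identical(interpolate_bad_channels(rec, character(0)), rec)
  truth <- rec$data["C3", ]
  rec$data["C3", ] <- rnorm(n) * 1000   # corrupt, then repair
  fixed <- interpolate_bad_channels(rec, "C3")
  expect_gt(cor(fixed$data["C3", ], truth), 0.9)
  expect_identical(fixed$data["Fp1", ], rec$data["Fp1", ])
  # constant cohort: any convex combination returns the common value
  const <- make_rec(matrix(5, 19, 64), ch = montage_channels())
  expect_true(all(abs(interpolate_bad_channels(const, "Cz")$data["Cz", ] - 5)
                  < 1e-12))
  expect_error(interpolate_bad_channels(rec, "nope"), "unknown")
  expect_error(interpolate_bad_channels(rec, montage_channels()[1:17]),
               "unrecoverable")
})

test_that("segmentation partitions the recording into 1-s epochs", {
  fs <- 256
  rec <- make_rec(matrix(seq_len(2 * fs * 300), 2), fs = fs)
  ep <- segment(rec, 1)
  expect_identical(n_epochs(ep), 300L)
  expect_identical(dim(ep$epochs)[2], as.integer(fs))
  # trailing remainder dropped
  rec2 <- make_rec(matrix(rnorm(2 * (fs * 256 + 128)), 2), fs = fs)
  expect_identical(n_epochs(segment(rec2, 1)), 256L)
  # partition property: concatenation reproduces the input exactly
  flat <- matrix(ep$epochs, nrow = 2)
  expect_identical(flat, unname(rec$data[, 1:(300 * fs)]))
  expect_warning(segment(make_rec(matrix(1, 2, 100), fs = fs), 1), "shorter")
})

test_that("artifact rejection drops exactly the epochs above threshold", {
  set.seed(3)
  dat <- matrix(rnorm(3 * 256 * 20), 3)
  ep <- segment(make_rec(dat), 1)
  expect_identical(reject_artifact_epochs(ep, Inf)$epochs, ep$epochs)
  spiked <- ep
  spiked$epochs[2, 100, 7] <- 1000
  kept <- reject_artifact_epochs(spiked, 100)
  expect_identical(n_epochs(kept), 19L)
  expect_identical(kept$epochs[, , 7], ep$epochs[, , 8])
  # survivor count equals a brute-force scan of the maxima
  thr <- 3.2
  want <- sum(apply(abs(ep$epochs), 3, max) <= thr)
  got <- suppressWarnings(n_epochs(reject_artifact_epochs(ep, thr)))
  expect_identical(got, as.integer(want))
  ep$epochs[] <- 1e6
  expect_warning(reject_artifact_epochs(ep, 1), "all epochs")
})
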