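test_that("resample_and_filter: rate halving, passband flatness, DC removal", {
  set.seed(2)
  fs <- 500
  n <- fs * 30
  t <- (0:(n - 1)) / fs
  mont <- montage_1020(8)
  X <- matrix(stats::rnorm(8 * n, 0, 5), 8, n)
  X[1, ] <- X[1, ] + 10 * sin(2 * pi * 10 * t) + 25      # tone + DC offset
  rec <- eeg_recording(X, fs, mont)
  out <- resample_and_filter(rec, preproc_params())
  expect_equal(out$srate, 250)
  expect_equal(ncol(out$data), n / 2)
  amp <- function(x, f, fs) {
    m <- length(x)
    2 * max(Mod(stats::fft(x))[abs((0:(m - 1)) * fs / m - f) < 0.3]) / m
  }
  expect_lt(abs(amp(out$data[1, ], 10, 250) - 10) / 10, 0.01)
  expect_lt(abs(mean(out$data[1, ])), 0.25)              # DC < 1% of 25 uV
  expect_error(
    resample_and_filter(eeg_recording(X[, 1:1000], 100, mont),
                        preproc_params()), "Nyquist")
})

test_that("find_bad_channels flags flatline, decorrelated and liney channels", {
  fx <- fixture_clean_walk()
  rec <- resample_and_filter(fx$eeg$rec, preproc_params())
  expect_length(find_bad_channels(rec, preproc_params()), 0)
  n <- ncol(rec$data)
  fs <- rec$srate
  bad <- rec
  bad$data[3, 1000:(1000 + 6 * fs)] <- bad$data[3, 1000]       # flat 6 s
  bad$data[7, ] <- stats::rnorm(n, 0, stats::sd(bad$data[7, ]))  # decorrelated
  bad$data[11, ] <- bad$data[11, ] +
    10 * stats::mad(bad$data[11, ]) * sin(2 * pi * 50 * (0:(n - 1)) / fs)
  flags <- find_bad_channels(bad, preproc_params())
  reasons <- attr(flags, "reasons")
  expect_true(rec$montage$label[3] %in%
                reasons$label[reasons$flatline])
  expect_true(rec$montage$label[7] %in%
                reasons$label[reasons$correlation])
  expect_true(rec$montage$label[11] %in%
                reasons$label[reasons$line_noise])
})

test_that("spherical-spline interpolation reconstructs smooth fields", {
  mont <- montage_1020(32)
  n <- 500
  # constant field: interpolation reproduces it exactly
  recc <- eeg_recording(matrix(rep(sin(1:n), each = 32), 32, n), 250, mont)
  recc$bads <- "C3"
  outc <- interpolate_bads(recc)
  i <- match("C3", mont$label)
  expect_lt(max(abs(outc$data[i, ] - sin(1:n))) / max(abs(sin(1:n))), 1e-6)
  # smooth dipolar-ish field: leave-one-out correlation > 0.95
  set.seed(3)
  src <- matrix(stats::rnorm(3 * n), 3, n)
  W <- cbind(exp(-((mont$x - 0.3)^2 + (mont$y - 0.5)^2 + (mont$z - 0.8)^2)),
             exp(-((mont$x + 0.5)^2 + mont$y^2 + (mont$z - 0.6)^2)),
             mont$z)
  rec <- eeg_recording(W %*% src, 250, mont)
  for (lab in c("Cz", "C3", "Pz")) {
    r <- rec
    r$bads <- lab
    out <- interpolate_bads(r)
    j <- match(lab, mont$label)
    expect_gt(stats::cor(out$data[j, ], rec$data[j, ]), 0.95)
  }
  # zero variance in, zero variance out
  rec0 <- eeg_recording(matrix(0, 32, 10), 250, mont)
  rec0$bads <- "Cz"
  expect_equal(stats::var(interpolate_bads(rec0)$data[1, ]), 0)
  # too few good channels
  recf <- eeg_recording(matrix(0, 8, 10), 250, montage_1020(8))
  recf$bads <- montage_1020(8)$label[1:6]
  expect_error(interpolate_bads(recf), "fewer than 4")
})

test_that("full-rank CAR: zero mean, reference reconstruction, idempotence", {
  set.seed(4)
  mont <- montage_1020(16)
  rec <- eeg_recording(matrix(stats::rnorm(16 * 1000), 16, 1000), 250, mont,
                       ref = "FCz")
  out <- rereference_car(rec)
  expect_equal(nrow(out$data), 17)                 # FCz reconstructed
  expect_true("FCz" %in% out$montage$label)
  expect_lt(max(abs(colMeans(out$data))), 1e-9)
  out2 <- rereference_car(out)
  expect_equal(out2$data, out$data, tolerance = 1e-12)  # idempotent
  one <- eeg_recording(matrix(1, 1, 10), 250, montage_1020(2)[1, ])
  expect_error(rereference_car(one), "one channel")
})

test_that("line-noise removal is narrow-band and scale-proof", {
  set.seed(5)
  fs <- 250
  n <- fs * 30
  t <- (0:(n - 1)) / fs
  mont <- montage_1020(8)
  base <- matrix(stats::rnorm(8 * n, 0, 5), 8, n)
  mk <- function(amp) {
    X <- base
    X[2, ] <- X[2, ] + 8 * sin(2 * pi * 10 * t)
    X <- X + amp %o% sin(2 * pi * 50 * t + 0.3)
    eeg_recording(X, fs, mont)
  }
  rec <- mk(rep(10, 8))
  out <- remove_line_noise(rec, preproc_params())
  red <- 10 * log10(band_power(rec$data[2, ], fs, 49, 51) /
                      band_power(out$data[2, ], fs, 49, 51))
  expect_gt(red, 15)
  # 10 Hz amplitude preserved within 2%
  amp10 <- function(x) sqrt(band_power(x, fs, 9.5, 10.5))
  expect_lt(abs(amp10(out$data[2, ]) - amp10(rec$data[2, ])) /
              amp10(rec$data[2, ]), 0.02)
  # out-of-band power changed < 1 dB
  for (bb in list(c(2, 45), c(55, 80))) {
    ratio <- band_power(out$data[2, ], fs, bb[1], bb[2]) /
      band_power(rec$data[2, ], fs, bb[1], bb[2])
    expect_lt(abs(10 * log10(ratio)), 1)
  }
  # halved line amplitude still meets the contract
  rec2 <- mk(rep(5, 8))
  out2 <- remove_line_noise(rec2, preproc_params())
  expect_gt(10 * log10(band_power(rec2$data[2, ], fs, 49, 51) /
                         band_power(out2$data[2, ], fs, 49, 51)), 15)
  # no line component: near no-op
  rec0 <- eeg_recording(base, fs, mont)
  out0 <- remove_line_noise(rec0, preproc_params())
  expect_lt(abs(10 * log10(band_power(out0$data[1, ], fs, 1, 100) /
                             band_power(rec0$data[1, ], fs, 1, 100))), 0.5)
})

test_that("epoch rejection: amplitude gate, joint probability, empty input", {
  set.seed(6)
  mont <- montage_1020(8)
  fs <- 250
  rec <- eeg_recording(matrix(stats::rnorm(8 * fs * 120, 0, 10), 8), fs, mont)
  mask <- reject_artifact_epochs(rec, 1, preproc_params())
  expect_length(mask, 120)
  expect_gte(mean(mask), 0.95)                     # Gaussian data mostly kept
  rec$data[4, 30 * fs + 17] <- 400
  mask2 <- reject_artifact_epochs(rec, 1, preproc_params())
  expect_false(mask2[31])                          # 400 uV spike epoch out
  expect_gte(attr(mask2, "n_amplitude"), 1)
  empty <- eeg_recording(matrix(numeric(0), 8, 0), fs, mont)
  expect_length(reject_artifact_epochs(empty, 1, preproc_params()), 0)
})
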