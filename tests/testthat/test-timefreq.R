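test_that("Morlet power: frequency selectivity, quadratic scaling, edges", {
  fs <- 250
  n <- fs * 20
  t <- (0:(n - 1)) / fs
  mont <- montage_1020(2)
  mk <- function(a) eeg_recording(rbind(a * sin(2 * pi * 20 * t), 0), fs, mont)
  tfp <- tf_params()
  tf1 <- morlet_power(mk(1), tfp)
  mid <- (fs * 5):(fs * 15)
  p20 <- mean(tf1$power[tf_row(tf1, 1, match(20, tfp$freqs)), mid])
  p10 <- mean(tf1$power[tf_row(tf1, 1, match(10, tfp$freqs)), mid])
  expect_gt(p20 / p10, 10)
  tf2 <- morlet_power(mk(2), tfp)
  p20b <- mean(tf2$power[tf_row(tf2, 1, match(20, tfp$freqs)), mid])
  expect_equal(p20b / p20, 4, tolerance = 1e-6)    # amplitude x2 -> power x4
  expect_lt(max(tf1$power[tf_row(tf1, 2, seq_along(tfp$freqs)), ]), 1e-12)
  expect_error(morlet_power(mk(1), tf_params(freqs = c(100, 140))),
               "Nyquist")
  short <- eeg_recording(matrix(0, 2, 50), fs, mont)
  expect_error(morlet_power(short, tfp), "shorter")
})

test_that("standing baseline equals long-run spectral power and guards zeros", {
  set.seed(8)
  fs <- 250
  n <- fs * 80
  mont <- montage_1020(2)
  x <- as.numeric(stats::filter(stats::rnorm(n), 0.6, method = "recursive"))
  rec <- eeg_recording(rbind(x, stats::rnorm(n)), fs, mont)
  tfp <- tf_params()
  tf <- morlet_power(rec, tfp)
  bl <- standing_baseline_power(tf, cbind(0, 80), tfp)
  # duration-weighted pooling over disjoint sub-intervals = single interval
  bl2 <- standing_baseline_power(tf, rbind(c(0, 40), c(40, 80)), tfp)
  expect_equal(bl, bl2, tolerance = 1e-10)
  # agrees with the long-run mean wavelet power away from edges within 5%
  rows <- tf_row(tf, 1, seq_along(tfp$freqs))
  longrun <- rowMeans(tf$power[rows, (2 * fs):(n - 2 * fs)])
  expect_lt(max(abs(bl[1, ] - longrun) / longrun), 0.05)
  expect_error(standing_baseline_power(tf, cbind(0, 10), tfp), "too short")
  zero <- eeg_recording(matrix(0, 2, n), fs, mont)
  tz <- morlet_power(zero, tfp)
  expect_error(standing_baseline_power(tz, cbind(0, 80), tfp), "zero power")
})

test_that("cycle warping: constants, amplitude gate, duration invariance", {
  fx <- fixture_clean_tf()
  tf <- fx$tf
  rec <- fixture_clean_walk()$eeg$rec
  # constant power warps to a constant
  tfc <- tf
  tfc$power <- matrix(3.3, nrow(tf$power), ncol(tf$power))
  segs <- extract_and_warp_cycles(tfc, NULL, fx$cycles, fx$tfp)
  expect_lt(max(abs(segs - 3.3)), 1e-9)
  # a 400 uV time-domain spike drops exactly that cycle
  rec2 <- rec
  cy <- fx$cycles[fx$cycles$valid, ][3, ]
  spike_at <- round((cy$rhs + 0.3) * tf$srate)
  rec2$data[2, spike_at] <- 400
  segs2 <- extract_and_warp_cycles(tf, rec2, fx$cycles, fx$tfp)
  expect_equal(attr(segs2, "n_excluded"), 1)
  expect_equal(dim(segs2)[3], sum(fx$cycles$valid) - 1L)
  # same phase-locked profile, different durations -> same warped segment
  fs <- 250
  nb <- 100
  prof <- function(ph) 2 + sin(2 * pi * ph)
  mont <- montage_1020(2)
  durs <- c(0.8, 1.25)
  rhs <- c(1, 1 + durs[1], 1 + sum(durs))
  n <- ceiling((max(rhs) + 1) * fs)
  P <- matrix(1, 2 * 30, n)
  tt <- (0:(n - 1)) / fs
  ph <- rep(NA_real_, n)
  for (k in 1:2) {
    sel <- tt >= rhs[k] & tt < rhs[k + 1]
    ph[sel] <- (tt[sel] - rhs[k]) / durs[k]
  }
  P[1, !is.na(ph)] <- prof(ph[!is.na(ph)])
  tfx <- structure(list(power = P, labels = mont$label,
                        freqs = seq(2, 60, 2), srate = fs,
                        halfwidth = rep(2, 30)), class = "tf_power")
  cycles <- data.frame(rhs = rhs[1:2], lto = rhs[1:2] + 0.1 * durs,
                       lhs = rhs[1:2] + 0.5 * durs,
                       rto = rhs[1:2] + 0.65 * durs, rhs_next = rhs[2:3],
                       duration = durs, valid = TRUE, reason = "none")
  w <- extract_and_warp_cycles(tfx, NULL, cycles, tf_params())
  d <- abs(w[1, , 1] - w[1, , 2])
  expect_lt(max(d), 0.02 * diff(range(w[1, , 1])))
})

test_that("ERSP/GPM algebra: dB definition, zero mean, shift invariance", {
  fx <- fixture_clean_tf()
  nb <- 100
  nch <- length(fx$tf$labels)
  nf <- length(fx$tf$freqs)
  segs <- array(rep(fx$baseline, nb), c(nch * nf, nb, 1))
  # arrange rows to match (channel fastest) layout
  segs[, , 1] <- matrix(as.numeric(fx$baseline), nch * nf, nb)
  ersp0 <- average_to_ersp(segs, fx$baseline, fx$tf)
  expect_lt(max(abs(ersp0)), 1e-9)                 # power == baseline -> 0 dB
  ersp10 <- average_to_ersp(segs * 10, fx$baseline, fx$tf)
  expect_equal(max(abs(ersp10 - 10)), 0, tolerance = 1e-9)   # 10x -> 10 dB
  # averaging a segment twice equals once
  twice <- array(rep(segs, 2), c(nch * nf, nb, 2))
  expect_equal(unclass(average_to_ersp(twice, fx$baseline, fx$tf)),
               unclass(ersp0), tolerance = 1e-12, ignore_attr = TRUE)
  expect_error(average_to_ersp(segs, fx$baseline * 0, fx$tf), "positive")
  # GPM rows have zero mean; constant-phase ERSP gives identically 0
  gpm <- fx$gpm
  expect_lt(max(abs(apply(unclass(gpm), c(1, 2), mean))), 1e-9)
  expect_lt(max(abs(ersp_to_gpm(ersp10))), 1e-9)
  # adding a constant per row leaves the GPM unchanged
  shifted <- fx$ersp
  shifted[2, 5, ] <- shifted[2, 5, ] + 7
  g2 <- ersp_to_gpm(shifted)
  expect_equal(g2[2, 5, ], fx$gpm[2, 5, ], tolerance = 1e-9)
})
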