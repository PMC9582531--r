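test_that("filter_accel is zero-phase and respects its cut-offs", {
  fs <- 250
  t <- (0:(fs * 40 - 1)) / fs
  # 1.5 Hz probe: well inside both passbands (the 6 Hz interim filter has an
  # effective 4th-order roll-off, so a 2 Hz tone would already lose > 1%)
  tr <- accel_trace(sin(2 * pi * 1.5 * t), sin(2 * pi * 50 * t), fs)
  f <- filter_accel(tr)
  mid <- (fs * 5):(fs * 35)
  # compare against the detrended input: detrending a finite pure tone
  # itself shifts the extrema slightly, which is not the filter's doing
  ref <- max(detrend_linear(tr$vert)[mid])
  expect_lt(abs(max(f$main$vert[mid]) - ref) / ref, 0.01)
  expect_lt(abs(max(f$interim$vert[mid]) - ref) / ref, 0.01)
  w <- (fs * 5):(fs * 5.7)                     # single 1.5 Hz cycle
  expect_lte(abs(w[which.max(tr$vert[w])] -
                   w[which.max(f$main$vert[w])]), 1)
  # 50 Hz attenuated > 20 dB in the 30 Hz output
  expect_gt(20 * log10(1 / max(abs(f$main$ap[mid]))), 20)
  # constant input is detrended to ~0
  trc <- accel_trace(rep(0.5, fs * 5), rep(-1, fs * 5), fs)
  fc <- filter_accel(trc)
  expect_lt(max(abs(fc$main$vert)), 1e-9)
  expect_lt(max(abs(fc$main$ap)), 1e-9)
  expect_error(filter_accel(accel_trace(1:10 / 10, 1:10 / 10, fs)),
               "warm-up")
})

test_that("step markers: threshold, bout restriction, conflict resolution", {
  fx <- fixture_clean_walk()
  filt <- filter_accel(fx$accel$right)
  markers <- detect_step_markers(filt$interim)
  n_strides <- length(fx$timeline$rhs) - 1L
  expect_equal(length(markers), n_strides)
  # sub-threshold input -> empty
  quiet <- accel_trace(rep(0, 2500) + 0.1 * sin(2 * pi * 2 * (0:2499) / 250),
                       rep(0, 2500), 250)
  expect_length(detect_step_markers(filter_accel(quiet)$interim), 0)
  # two peaks 400 ms apart: only the higher survives the 500 ms rule
  x <- numeric(1250)
  x[c(399, 401)] <- 0.5; x[400] <- 0.9
  x[c(499, 501)] <- 0.4; x[500] <- 0.7
  tr <- accel_trace(x, numeric(1250), 250)
  tr_pre <- accel_trace(x, numeric(1250), 250)
  m <- detect_step_markers(tr_pre)   # already "filtered" input
  expect_equal(m, 399 / 250)
})

test_that("heel strikes: first supra-threshold peak after each marker", {
  fs <- 250
  x <- numeric(fs * 4)
  put <- function(x, i, h) { x[c(i - 1, i + 1)] <- h / 2; x[i] <- h; x }
  x <- put(x, 100, 0.9)    # marker peak itself
  x <- put(x, 160, 0.7)    # heel strike (first peak after refractory)
  x <- put(x, 200, 0.8)    # later peak must not be chosen
  tr <- accel_trace(x, numeric(length(x)), fs)
  hs <- detect_heel_strikes(tr, step_markers = 99 / fs)
  expect_equal(hs, 159 / fs)
  # marker with no qualifying peak yields no event
  hs2 <- detect_heel_strikes(tr, step_markers = c(99 / fs, 3))
  expect_equal(hs2, 159 / fs)
  # synthetic walk: one RHS per marker at the transient within 1 sample
  fx <- fixture_clean_walk()
  filt <- filter_accel(fx$accel$right)
  markers <- detect_step_markers(filt$interim)
  hs3 <- detect_heel_strikes(filt$main, markers)
  tru <- fx$accel$truth$onset[fx$accel$truth$type == "RHS"]
  err <- vapply(hs3, function(v) min(abs(tru - v)), numeric(1))
  expect_equal(length(hs3), length(markers))
  expect_lt(max(err), 1 / fs + 1e-9)
})

test_that("toe-offs: mean latency of the two highest qualifying peaks", {
  fs <- 1000
  x <- numeric(fs * 2)
  put <- function(x, i, h) { x[c(i - 1, i + 1)] <- h / 2; x[i] <- h; x }
  marker <- 1.0
  x <- put(x, 801, 0.5)    # -200 ms
  x <- put(x, 851, 0.4)    # -150 ms
  tr <- accel_trace(numeric(length(x)), x, fs)
  to <- detect_toe_offs(tr, marker)
  expect_equal(to, mean(c(0.800, 0.850)))          # -175 ms
  # one qualifying peak only -> no event
  x1 <- numeric(fs * 2); x1 <- put(x1, 801, 0.5)
  expect_length(detect_toe_offs(accel_trace(numeric(fs * 2), x1, fs),
                                marker), 0)
  # three peaks: top two by height are used
  x3 <- numeric(fs * 2)
  x3 <- put(x3, 701, 0.25); x3 <- put(x3, 801, 0.5); x3 <- put(x3, 901, 0.4)
  to3 <- detect_toe_offs(accel_trace(numeric(fs * 2), x3, fs), marker)
  expect_equal(to3, mean(c(0.800, 0.900)))
})

test_that("cycle assembly enforces order and duration plausibility", {
  mk <- function(type, onset) data.frame(type = type, onset = onset)
  left <- mk(c("LTO", "LHS"), c(0.10, 0.50))
  right <- mk(c("RHS", "RTO", "RHS"), c(0.00, 0.60, 1.00))
  cyc <- assemble_gait_cycles(left, right)
  expect_true(cyc$valid[1])
  expect_equal(cyc$duration[1], 1.00)
  # 1.6 s between RHS -> duration rejection
  right2 <- mk(c("RHS", "RTO", "RHS"), c(0.00, 0.60, 1.60))
  left2 <- mk(c("LTO", "LHS"), c(0.10, 0.50))
  cyc2 <- assemble_gait_cycles(left2, right2)
  expect_false(cyc2$valid[1])
  expect_equal(cyc2$reason[1], "duration")
  # LHS before LTO -> order rejection
  left3 <- mk(c("LHS", "LTO"), c(0.10, 0.50))
  cyc3 <- assemble_gait_cycles(left3, right)
  expect_false(cyc3$valid[1])
  expect_equal(cyc3$reason[1], "order")
  # valid cycles always within the bounds, whatever the input
  set.seed(1)
  for (i in 1:20) {
    rhs <- cumsum(runif(8, 0.3, 1.8))
    ev_r <- mk(rep(c("RHS", "RTO"), 4), as.numeric(rbind(rhs, rhs + 0.1)))
    ev_l <- mk(rep(c("LTO", "LHS"), 4),
               as.numeric(rbind(rhs + 0.03, rhs + 0.07)))
    cc <- assemble_gait_cycles(ev_l, ev_r)
    expect_true(all(cc$duration[cc$valid] >= 0.5 &
                      cc$duration[cc$valid] <= 1.5))
  }
})

test_that("stride metrics: CV definition, invariances, degenerate inputs", {
  mk_cycles <- function(durs) {
    rhs <- cumsum(c(0, durs))
    n <- length(durs)
    data.frame(rhs = rhs[-length(rhs)], lto = rhs[-length(rhs)] + 0.1,
               lhs = rhs[-length(rhs)] + 0.3, rto = rhs[-length(rhs)] + 0.5,
               rhs_next = rhs[-1], duration = durs,
               valid = durs >= 0.5 & durs <= 1.5,
               reason = "none")
  }
  sm <- stride_metrics(mk_cycles(c(0.9, 1.0, 1.1)))
  expect_equal(sm$cv_pct, 10.0)                       # sample SD = 0.1
  expect_equal(sm$mean_stride, 1.0)
  expect_equal(stride_metrics(mk_cycles(c(1, 1, 1)))$cv_pct, 0)
  # CV invariant to time rescaling (to numerical precision)
  a <- stride_metrics(mk_cycles(c(0.9, 1.0, 1.1)))$cv_pct
  b <- 100 * stats::sd(c(900, 1000, 1100)) / mean(c(900, 1000, 1100))
  expect_equal(a, b, tolerance = 1e-12)
  # CV invariant to permutation of stride order
  p <- stride_metrics(mk_cycles(c(1.1, 0.9, 1.0)))$cv_pct
  expect_equal(p, a, tolerance = 1e-12)
  # one valid cycle: mean defined, CV flagged
  one <- stride_metrics(mk_cycles(1.0))
  expect_false(one$cv_defined)
  expect_true(is.na(one$cv_pct))
  # zero valid cycles: error
  expect_error(stride_metrics(mk_cycles(c(0.3, 1.7))), "no valid")
})
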