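test_that("generate_timeline honours its moments, bounds and determinism", {
  spec <- tiny_spec(stride_mean = c(even_ST = 1.0, even_DT = 1.0,
                                    uneven_ST = 1.0, uneven_DT = 1.0),
                    stride_sd = c(even_ST = 0, even_DT = 0,
                                  uneven_ST = 0, uneven_DT = 0))
  tl <- generate_timeline(spec, "even_ST", seed = 1, walk_s = 60)
  expect_equal(length(tl$rhs) - 1L, 59)            # 59 complete 1 s strides
  expect_true(all(abs(diff(tl$rhs) - 1.0) < 1e-12))
  sm <- stride_metrics(truth_cycles(tl))
  expect_equal(sm$cv_pct, 0)                       # SD 0 -> CV 0
  tl2 <- generate_timeline(spec, "even_ST", seed = 1, walk_s = 60)
  expect_identical(tl$rhs, tl2$rhs)                # same seed, same output
  bad <- spec
  bad$stride_mean["even_ST"] <- 0.4
  expect_error(generate_timeline(bad, "even_ST", seed = 1), "plausible")
  expect_error(study_spec(stride_mean = c(even_ST = 1.6, even_DT = 1,
                                          uneven_ST = 1, uneven_DT = 1)),
               "stride_mean")
})

test_that("timeline event order invariant holds over 10^4 strides", {
  spec <- tiny_spec(stride_sd = c(even_ST = 0.1, even_DT = 0.1,
                                  uneven_ST = 0.1, uneven_DT = 0.1))
  n_strides <- 0
  for (s in 1:14) {
    tl <- generate_timeline(spec, "uneven_DT", seed = s, walk_s = 900)
    ev <- timeline_events(tl)
    rhs <- tl$rhs
    n <- length(rhs) - 1L
    n_strides <- n_strides + n
    dur <- diff(rhs)
    expect_true(all(dur > 0.5 & dur < 1.5))
    for (ty in c("LTO", "LHS", "RTO")) {
      on <- ev$onset[ev$type == ty]
      expect_true(all(on > rhs[-length(rhs)] & on < rhs[-1]))
    }
    lto <- ev$onset[ev$type == "LTO"]; lhs <- ev$onset[ev$type == "LHS"]
    rto <- ev$onset[ev$type == "RTO"]
    expect_true(all(lto < lhs & lhs < rto))
  }
  expect_gte(n_strides, 1e4)
})

test_that("noise-free accelerometry lets the detector recover the truth", {
  fx <- fixture_clean_walk()
  acc <- fx$accel
  for (foot in c("left", "right")) {
    ev <- detect_gait_events(acc[[foot]])
    types <- if (foot == "right") c("RHS", "RTO") else c("LHS", "LTO")
    for (ty in types) {
      det <- ev$onset[ev$type == ty]
      tru <- acc$truth$onset[acc$truth$type == ty]
      expect_gt(length(det), 0)
      err <- vapply(det, function(x) min(abs(tru - x)), numeric(1))
      expect_lt(max(err), 1 / 250 + 1e-9)          # within one sample
    }
  }
  # zero strides -> empty traces of the requested duration, empty truth
  spec <- tiny_spec()
  tl0 <- generate_timeline(spec, "even_ST", seed = 1, walk_s = 1)
  expect_length(tl0$rhs, 1)                        # no complete stride
  acc0 <- generate_accel(tl0, 250, 0, seed = 1)
  expect_equal(nrow(acc0$truth), 0)
  expect_equal(length(acc0$left$vert), ceiling(2 * 250))
  expect_true(all(acc0$left$vert == 0))
})

test_that("generated EEG is deterministic and validates its condition", {
  spec <- tiny_spec(walk_s = 10, standing_s = 0, n_channels = 8)
  tl <- generate_timeline(spec, "even_ST", seed = 3)
  a <- generate_eeg(tl, spec, "even_ST", seed = 5, standing_s = 0)
  b <- generate_eeg(tl, spec, "even_ST", seed = 5, standing_s = 0)
  expect_identical(a$rec$data, b$rec$data)
  expect_error(generate_eeg(tl, spec, "downhill", seed = 5), "arg")
  expect_error(generate_eeg(tl, spec, "even_ST", seed = 5,
                            montage = montage_1020(4)))
  # null modulation -> flat truth profiles
  spec0 <- tiny_spec(walk_s = 10, standing_s = 0, n_channels = 8,
                     bands = data.frame(name = "beta", freq = 24, sign = -1,
                                        even_ST = 0, even_DT = 0,
                                        uneven_ST = 0, uneven_DT = 0),
                     dip = list(band = "beta", phase = 0.075, width = 0.055,
                                depth_db = c(even_ST = 0, even_DT = 0,
                                             uneven_ST = 0, uneven_DT = 0),
                                subject_sd = 0))
  z <- generate_eeg(tl, spec0, "even_ST", seed = 5, standing_s = 0)
  expect_true(all(abs(z$truth$profiles) < 1e-12))
})

test_that("generate_study writes a complete, reloadable layout", {
  dir <- withr::local_tempdir()
  spec <- tiny_spec(n_subjects = 3, walk_s = 6, standing_s = 4,
                    n_channels = 8)
  man <- generate_study(spec, dir)
  expect_length(man$subjects, 3)
  vhdrs <- list.files(dir, pattern = "_eeg\\.vhdr$", recursive = TRUE)
  expect_length(vhdrs, 12 + 3)                 # 4 conditions + standing each
  accel <- list.files(dir, pattern = "_accel-.*\\.tsv$", recursive = TRUE)
  expect_length(accel, 24)
  # refuse to clobber
  expect_error(generate_study(spec, dir), "overwrite")
  # manifest round-trip: written truth equals in-memory truth
  man2 <- jsonlite::read_json(file.path(dir, "manifest.json"),
                              simplifyVector = TRUE)
  expect_equal(man2$subjects$`sub-01`$conditions$even_ST$rhs,
               man$subjects$`sub-01`$conditions$even_ST$rhs,
               tolerance = 1e-12)
  # BrainVision round-trip preserves data to float32 precision
  vhdr <- file.path(dir, "sub-01",
                    man$subjects$`sub-01`$conditions$even_ST$eeg)
  rec <- read_brainvision(vhdr)
  sim <- simulate_subject(spec, 1, montage_1020(8))
  orig <- sim$conditions$even_ST$eeg$rec
  expect_equal(dim(rec$data), dim(orig$data))
  expect_lt(max(abs(rec$data - orig$data)), 1e-3)
  expect_setequal(rec$events$label, orig$events$label)
})
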