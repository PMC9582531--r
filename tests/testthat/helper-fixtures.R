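# Shared fixtures, built once per test run and cached (generation is the
# expensive part of most tests).

.fixture_env <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (!exists(name, envir = .fixture_env)) {
    assign(name, build(), envir = .fixture_env)
  }
  get(name, envir = .fixture_env)
}

# small, quiet study world used across tests
tiny_spec <- function(...) {
  args <- list(n_subjects = 2, walk_s = 60, standing_s = 35,
               n_channels = 16, blink_rate_hz = 0, line_amp_uv = 0,
               artifact_gain_db = 0, seed = 7L)
  dots <- list(...)
  args[names(dots)] <- dots
  do.call(study_spec, args)
}

# 60 s clean walking recording + standing span, 16 channels, with truth
fixture_clean_walk <- function() {
  fixture("clean_walk", function() {
    spec <- tiny_spec()
    tl <- generate_timeline(spec, "even_ST", seed = 11)
    eeg <- generate_eeg(tl, spec, "even_ST", seed = 12, standing_s = 35)
    acc <- generate_accel(tl, 250, 0, seed = 13)
    list(spec = spec, timeline = tl, eeg = eeg, accel = acc)
  })
}

# truth-based gait cycles aligned to an EEG recording
truth_cycles <- function(timeline, walk_offset = 0) {
  ev <- timeline_events(timeline)
  ev$onset <- ev$onset + walk_offset
  assemble_gait_cycles(ev[ev$type %in% c("LHS", "LTO"), ],
                       ev[ev$type %in% c("RHS", "RTO"), ])
}

# tf decomposition of the clean walk fixture (expensive; cached)
fixture_clean_tf <- function() {
  fixture("clean_tf", function() {
    fx <- fixture_clean_walk()
    tfp <- tf_params()
    tf <- morlet_power(fx$eeg$rec, tfp)
    baseline <- standing_baseline_power(
      tf, event_spans(fx$eeg$rec$events, "standing"), tfp)
    cycles <- truth_cycles(fx$timeline, fx$eeg$truth$walk_offset)
    segs <- extract_and_warp_cycles(tf, fx$eeg$rec, cycles, tfp)
    ersp <- average_to_ersp(segs, baseline, tf, "even_ST")
    list(tfp = tfp, tf = tf, baseline = baseline, cycles = cycles,
         segs = segs, ersp = ersp, gpm = ersp_to_gpm(ersp))
  })
}

# artifact-laden counterpart (EMG bursts at neck/lateral channels)
fixture_artifact_tf <- function() {
  fixture("artifact_tf", function() {
    spec <- tiny_spec(artifact_gain_db = 6)
    tl <- generate_timeline(spec, "even_ST", seed = 21)
    eeg <- generate_eeg(tl, spec, "even_ST", seed = 22, standing_s = 35)
    tfp <- tf_params()
    tf <- morlet_power(eeg$rec, tfp)
    baseline <- standing_baseline_power(
      tf, event_spans(eeg$rec$events, "standing"), tfp)
    cycles <- truth_cycles(tl, eeg$truth$walk_offset)
    segs <- extract_and_warp_cycles(tf, eeg$rec, cycles, tfp)
    ersp <- average_to_ersp(segs, baseline, tf, "even_ST")
    list(spec = spec, eeg = eeg, tfp = tfp, cycles = cycles,
         baseline = baseline, ersp = ersp, gpm = ersp_to_gpm(ersp))
  })
}

# synthetic GPM condition maps at one channel for the stats module:
# freq x phase Gaussian noise plus optional per-condition offsets
synth_condition_maps <- function(n_subjects, nf = 10, np = 20, sd = 1,
                                 effect = NULL, seed = 1) {
  set.seed(seed)
  lapply(seq_len(n_subjects), function(s) {
    out <- lapply(condition_grid(), function(cond) {
      m <- matrix(stats::rnorm(nf * np, 0, sd), nf, np)
      if (!is.null(effect)) m <- m + effect(cond, s)
      m
    })
    names(out) <- condition_grid()
    out
  })
}
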