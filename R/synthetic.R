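#' Specification of a synthetic 2x2 walking study
#'
#' Describes the world that [generate_study()] simulates: a cohort walking
#' under a 2x2 terrain (even, uneven) by task (single-task ST, dual-task DT)
#' design, with per-condition stride timing, gait-phase locked band power
#' modulations, double-support EMG-like artifact bursts at neck/lateral
#' channels, mains interference, blinks, and a quiet-standing baseline.
#'
#' Default stride times and modulation depths encode the qualitative pattern
#' of slower, more variable gait and deeper beta modulation on uneven
#' terrain, with a task effect on stride time only; see the methods vignette
#' for the rationale behind each number.
#'
#' @param n_subjects number of subjects (>= 2).
#' @param stride_mean named numeric, mean stride time (s) per condition;
#'   names `even_ST`, `even_DT`, `uneven_ST`, `uneven_DT`; all in (0.5, 1.5).
#' @param stride_sd named numeric, within-subject stride-time SD (s).
#' @param subject_stride_sd between-subject SD of the stride-time intercept (s).
#' @param bands data.frame with columns `name`, `freq` (Hz), `sign` (+1 power
#'   rises during double support, -1 falls) and one depth column per
#'   condition (dB peak-to-trough of the gait-phase power profile).
#' @param subject_depth_sd between-subject/condition SD of modulation depth (dB).
#' @param dip a localized extra modulation (the condition effect): list with
#'   `band` (band name), `phase` (centre, fraction of cycle), `width`
#'   (Gaussian SD, fraction of cycle), `depth_db` (named per condition,
#'   extra peak depth in dB, applied in the band's modulation direction) and
#'   `subject_sd` (between-subject/condition SD of the extra depth, dB).
#'   The default places a 1 dB deeper beta decrease just after right heel
#'   strike (2-15% of the cycle) on uneven terrain only.
#' @param artifact_gain_db amplitude gain (dB) of the double-support EMG
#'   burst relative to its baseline level at the artifact channels.
#' @param line_amp_uv 50 Hz mains amplitude (microvolts).
#' @param blink_rate_hz mean blink rate (Hz).
#' @param standing_s duration of the quiet-standing baseline (s).
#' @param walk_s duration of each walking bout (s).
#' @param eeg_srate EEG sampling rate of the generated data (Hz).
#' @param accel_fs accelerometer sampling rate (Hz).
#' @param accel_noise_sd additive accelerometer noise SD (g).
#' @param n_channels EEG montage size (passed to [montage_1020()]).
#' @param seed integer master seed; fixed seed reproduces output
#'   bit-identically.
#' @return object of class `study_spec` (a validated list).
#' @export
study_spec <- function(n_subjects = 19,
                       stride_mean = c(even_ST = 1.05, even_DT = 1.10,
                                       uneven_ST = 1.15, uneven_DT = 1.20),
                       stride_sd = c(even_ST = 0.025, even_DT = 0.025,
                                     uneven_ST = 0.045, uneven_DT = 0.045),
                       subject_stride_sd = 0.05,
                       bands = default_bands(),
                       subject_depth_sd = 0.8,
                       dip = list(band = "beta", phase = 0.075,
                                  width = 0.055,
                                  depth_db = c(even_ST = 0, even_DT = 0,
                                               uneven_ST = 1, uneven_DT = 1),
                                  subject_sd = 0.8),
                       artifact_gain_db = 6,
                       line_amp_uv = 2,
                       blink_rate_hz = 0.2,
                       standing_s = 120,
                       walk_s = 180,
                       eeg_srate = 250,
                       accel_fs = 250,
                       accel_noise_sd = 0.05,
                       n_channels = 32,
                       seed = 1L) {
  conds <- condition_grid()
  stopifnot(n_subjects >= 2,
            all(conds %in% names(stride_mean)),
            all(conds %in% names(stride_sd)),
            all(stride_sd >= 0), subject_stride_sd >= 0,
            all(c("name", "freq", "sign", conds) %in% names(bands)),
            is.list(dip), all(conds %in% names(dip$depth_db)),
            dip$width > 0, dip$subject_sd >= 0,
            artifact_gain_db >= 0, line_amp_uv >= 0, blink_rate_hz >= 0,
            standing_s >= 0, walk_s > 0, eeg_srate > 0, accel_fs >= 100,
            accel_noise_sd >= 0, n_channels >= 8)
  if (any(stride_mean <= 0.5 | stride_mean >= 1.5)) {
    stop("stride_mean must lie strictly inside (0.5, 1.5) s; the plausibility ",
         "filter would otherwise reject the typical stride")
  }
  structure(list(
    n_subjects = n_subjects, stride_mean = stride_mean, stride_sd = stride_sd,
    subject_stride_sd = subject_stride_sd, bands = bands,
    subject_depth_sd = subject_depth_sd, dip = dip,
    artifact_gain_db = artifact_gain_db,
    line_amp_uv = line_amp_uv, blink_rate_hz = blink_rate_hz,
    standing_s = standing_s, walk_s = walk_s, eeg_srate = eeg_srate,
    accel_fs = accel_fs, accel_noise_sd = accel_noise_sd,
    n_channels = n_channels, seed = as.integer(seed)
  ), class = "study_spec")
}

#' Default gait-phase modulated frequency bands
#'
#' Theta and alpha/mu power rise during double support, beta power falls.
#' The base (whole-cycle) depths are identical across conditions; the
#' condition effect lives in the localized `dip` of [study_spec()].
#'
#' @return data.frame usable as the `bands` argument of [study_spec()].
#' @export
default_bands <- function() {
  data.frame(
    name = c("theta", "alpha", "beta"),
    freq = c(7, 12, 25),
    sign = c(1, 1, -1),
    even_ST = c(1.5, 1.5, 2), even_DT = c(1.5, 1.5, 2),
    uneven_ST = c(1.5, 1.5, 2), uneven_DT = c(1.5, 1.5, 2)
  )
}

#' The four condition labels of the 2x2 design
#' @return character vector `even_ST`, `even_DT`, `uneven_ST`, `uneven_DT`.
#' @export
condition_grid <- function() c("even_ST", "even_DT", "uneven_ST", "uneven_DT")

# deterministic sub-seed derivation (kept below 2^31)
sub_seed <- function(seed, ...) {
  ix <- c(...)
  s <- as.double(seed) %% 2147483647
  for (k in seq_along(ix)) {
    s <- (s * 7919 + as.double(ix[k]) * 104729 + k * 1299709) %% 2147483647
  }
  as.integer(s)
}

# ---- gait timeline --------------------------------------------------------

#' Generate a ground-truth gait timeline for one walking bout
#'
#' Stride durations are drawn from a normal distribution truncated to
#' (0.5, 1.5) s (the plausibility window of the gait detector). Within each
#' stride the canonical event order RHS < LTO < LHS < RTO < next RHS is laid
#' out with double-support intervals near 0-15% and 50-65% of the cycle.
#'
#' @param spec [study_spec()] (only the stride fields are used).
#' @param condition one of [condition_grid()].
#' @param seed integer seed.
#' @param subject_shift additive shift of the stride-time mean (s), used for
#'   between-subject variation.
#' @param walk_s bout duration (s); defaults to `spec$walk_s`.
#' @return object of class `gait_timeline`: RHS latencies (s, relative to
#'   bout start at 0), within-stride fractional offsets of LTO/LHS/RTO, bout
#'   boundaries and the generating moments.
#' @export
generate_timeline <- function(spec, condition, seed,
                              subject_shift = 0, walk_s = spec$walk_s) {
  condition <- match.arg(condition, condition_grid())
  m <- unname(spec$stride_mean[condition]) + subject_shift
  s <- unname(spec$stride_sd[condition])
  if (m <= 0.5 || m >= 1.5) {
    stop("stride-time mean ", signif(m, 3),
         " s lies outside the plausible range (0.5, 1.5) s")
  }
  set.seed(seed)
  n_max <- ceiling(walk_s / 0.5) + 1L
  dur <- if (s == 0) rep(m, n_max) else {
    d <- stats::rnorm(n_max, m, s)
    while (any(bad <- d <= 0.5 | d >= 1.5)) {
      d[bad] <- stats::rnorm(sum(bad), m, s)
    }
    d
  }
  rhs <- cumsum(c(0.5, dur))       # first RHS 0.5 s into the bout
  rhs <- rhs[rhs <= walk_s - 0.25]
  structure(list(
    rhs = rhs,
    lto_frac = 0.15, lhs_frac = 0.50, rto_frac = 0.65,
    stride_mean = m, stride_sd = s,
    bout = c(start = 0, end = walk_s),
    condition = condition
  ), class = "gait_timeline")
}

#' @export
print.gait_timeline <- function(x, ...) {
  cat(sprintf("<gait_timeline> %s: %d RHS over %.1f s (mean stride %.3f s)\n",
              x$condition, length(x$rhs), unname(x$bout["end"]),
              x$stride_mean))
  invisible(x)
}

#' All ground-truth gait events of a timeline
#'
#' @param timeline [generate_timeline()] output.
#' @return data.frame with `type` (RHS/LTO/LHS/RTO) and `onset` (s).
#' @export
timeline_events <- function(timeline) {
  rhs <- timeline$rhs
  n <- length(rhs)
  if (n < 2L) {
    return(data.frame(type = character(0), onset = numeric(0)))
  }
  dur <- diff(rhs)
  start <- rhs[-n]
  ev <- rbind(
    data.frame(type = "RHS", onset = rhs),
    data.frame(type = "LTO", onset = start + timeline$lto_frac * dur),
    data.frame(type = "LHS", onset = start + timeline$lhs_frac * dur),
    data.frame(type = "RTO", onset = start + timeline$rto_frac * dur)
  )
  ev[order(ev$onset), ]
}

# gait phase in [0,1) at arbitrary times; NA outside strides
timeline_phase <- function(timeline, t) {
  rhs <- timeline$rhs
  ph <- rep(NA_real_, length(t))
  if (length(rhs) < 2L) return(ph)
  i <- findInterval(t, rhs)
  ok <- i >= 1L & i < length(rhs)
  ph[ok] <- (t[ok] - rhs[i[ok]]) / (rhs[i[ok] + 1L] - rhs[i[ok]])
  ph
}

# ---- accelerometer traces -------------------------------------------------

#' Per-foot accelerometer trace
#'
#' @param vert,ap vertical and anterior-posterior acceleration (g).
#' @param fs sampling rate (Hz).
#' @param foot `"left"` or `"right"`.
#' @param bouts matrix of walking-bout start/end times (s).
#' @return object of class `accel_trace`.
#' @export
accel_trace <- function(vert, ap, fs, foot = c("right", "left"),
                        bouts = NULL) {
  foot <- match.arg(foot)
  stopifnot(length(vert) == length(ap), fs > 0)
  if (is.null(bouts)) bouts <- cbind(start = 0, end = length(vert) / fs)
  structure(list(vert = vert, ap = ap, fs = fs, foot = foot, bouts = bouts),
            class = "accel_trace")
}

#' @export
print.accel_trace <- function(x, ...) {
  cat(sprintf("<accel_trace> %s foot, %d samples @ %g Hz\n",
              x$foot, length(x$vert), x$fs))
  invisible(x)
}

add_bump <- function(x, fs, center, amp, width) {
  n <- length(x)
  for (k in seq_along(center)) {
    i0 <- max(1L, floor((center[k] - 4 * width) * fs) + 1L)
    i1 <- min(n, ceiling((center[k] + 4 * width) * fs) + 1L)
    if (i0 > n || i1 < 1L) next
    t <- (seq(i0, i1) - 1) / fs
    x[i0:i1] <- x[i0:i1] + amp * exp(-0.5 * ((t - center[k]) / width)^2)
  }
  x
}

#' Generate two-foot accelerometer traces with ground truth
#'
#' The waveform is designed so the detection rules of the gait-events module
#' recover the timeline exactly on noise-free input: per stride, the vertical
#' axis carries a broad mid-swing bump (> 0.6 g, survives the 6 Hz interim
#' filter) followed by a sharp heel-strike transient (> 0.6 g in the 30 Hz
#' data, strongly attenuated at 6 Hz); the anterior-posterior axis carries
#' two bumps (> 0.2 g) placed symmetrically around the true toe-off so that
#' the mean of the two peak latencies equals the toe-off time.
#'
#' @param timeline [generate_timeline()] output.
#' @param fs sampling rate (Hz, >= 100).
#' @param noise_sd additive Gaussian noise SD (g).
#' @param seed integer seed.
#' @return list with elements `left`, `right` ([accel_trace()]) and `truth`
#'   (data.frame of true event types and onsets).
#' @export
generate_accel <- function(timeline, fs = 250, noise_sd = 0.05, seed = 1L) {
  stopifnot(fs >= 100)
  set.seed(seed)
  dur_total <- unname(timeline$bout["end"]) + 1
  n <- ceiling(dur_total * fs)
  truth <- timeline_events(timeline)
  mk <- function() list(vert = numeric(n), ap = numeric(n))
  right <- mk(); left <- mk()
  rhs <- timeline$rhs
  if (length(rhs) >= 2L) {
    d <- diff(rhs); s <- rhs[-length(rhs)]
    lto <- s + timeline$lto_frac * d
    lhs <- s + timeline$lhs_frac * d
    rto <- s + timeline$rto_frac * d
    nxt <- rhs[-1L]
    # right foot: swing is RTO -> next RHS
    right$vert <- add_bump(right$vert, fs, (rto + nxt) / 2, 1.2, 0.05)
    right$vert <- add_bump(right$vert, fs, nxt, 0.9, 0.012)
    right$ap   <- add_bump(right$ap, fs, rto - 0.04, 0.50, 0.015)
    right$ap   <- add_bump(right$ap, fs, rto + 0.04, 0.45, 0.015)
    # left foot: swing is LTO -> LHS
    left$vert <- add_bump(left$vert, fs, (lto + lhs) / 2, 1.2, 0.05)
    left$vert <- add_bump(left$vert, fs, lhs, 0.9, 0.012)
    left$ap   <- add_bump(left$ap, fs, lto - 0.04, 0.50, 0.015)
    left$ap   <- add_bump(left$ap, fs, lto + 0.04, 0.45, 0.015)
  }
  if (noise_sd > 0) {
    right$vert <- right$vert + stats::rnorm(n, 0, noise_sd)
    right$ap   <- right$ap + stats::rnorm(n, 0, noise_sd)
    left$vert  <- left$vert + stats::rnorm(n, 0, noise_sd)
    left$ap    <- left$ap + stats::rnorm(n, 0, noise_sd)
  }
  bouts <- rbind(timeline$bout)
  list(
    left = accel_trace(left$vert, left$ap, fs, "left", bouts),
    right = accel_trace(right$vert, right$ap, fs, "right", bouts),
    truth = truth
  )
}

# ---- EEG ------------------------------------------------------------------

# 1/f-shaped background noise via FFT spectral shaping, RMS ~= `rms` uV
pink_noise <- function(n, fs, rms = 8) {
  nf <- next_pow2(n)
  X <- stats::fft(stats::rnorm(nf))
  f <- c(1e-3, seq_len(nf - 1)) * fs / nf
  f <- pmin(f, fs - f)            # mirror for negative frequencies
  shape <- 1 / sqrt(pmax(f, 0.5))
  x <- Re(stats::fft(X * shape, inverse = TRUE)) / nf
  x <- x[seq_len(n)]
  x * rms / stats::sd(x)
}

# smooth 0/1 envelope of double-support phases, given gait phase per sample
double_support_envelope <- function(phase, fs) {
  ind <- as.numeric(!is.na(phase) &
                      ((phase >= 0 & phase < 0.15) |
                         (phase >= 0.50 & phase < 0.65)))
  k <- max(3L, round(0.05 * fs))
  kern <- stats::dnorm(seq(-3, 3, length.out = 2L * k + 1L))
  kern <- kern / sum(kern)
  as.numeric(stats::filter(c(rep(ind[1], k), ind, rep(ind[length(ind)], k)),
                           kern, sides = 2))[(k + 1L):(k + length(ind))]
}

#' Generate a multichannel EEG recording locked to a gait timeline
#'
#' The recording contains, per channel: 1/f background noise; band-limited
#' oscillations whose instantaneous power follows a two-peaked cosine profile
#' over the gait cycle (peaks/troughs at the double-support phases, depth per
#' band and condition from `spec` plus subject noise); broadband EMG-like
#' bursts during double support at the neck and lateral channel sets; a 50 Hz
#' mains sinusoid; stereotyped frontal blink transients; and, optionally, a
#' leading quiet-standing segment with stationary power. Span events
#' (`standing_start`/`_end`, `walk_start`/`_end`) and the condition label are
#' stored in the event table.
#'
#' @param timeline [generate_timeline()] output.
#' @param spec [study_spec()].
#' @param condition one of [condition_grid()].
#' @param seed integer seed.
#' @param montage montage data.frame; default `montage_1020(spec$n_channels)`.
#' @param standing_s duration of the prepended standing segment (s).
#' @param depth_offsets optional named numeric (per band name) added to the
#'   condition depth, e.g. per-subject depth noise; default 0.
#' @param dip_offset scalar added to the condition's localized dip depth
#'   (per-subject dip noise); default 0.
#' @return list with `rec` ([eeg_recording()]) and `truth` (list: per-band
#'   100-bin dB phase profiles, artifact channels and gain, blink onsets,
#'   walking-bout offset of the timeline within the recording).
#' @export
generate_eeg <- function(timeline, spec, condition, seed,
                         montage = montage_1020(spec$n_channels),
                         standing_s = spec$standing_s,
                         depth_offsets = NULL, dip_offset = 0) {
  condition <- match.arg(condition, c(condition_grid(), "standing"))
  sets <- channel_sets(montage)
  if (nrow(montage) < 8 || !length(sets$neck)) {
    stop("montage must have >= 8 channels including a neck set")
  }
  set.seed(seed)
  fs <- spec$eeg_srate
  gap <- if (standing_s > 0) 2 else 0
  walk_s <- unname(timeline$bout["end"])
  dur <- standing_s + gap + walk_s + 1
  n <- ceiling(dur * fs)
  t <- (seq_len(n) - 1) / fs
  walk_offset <- standing_s + gap
  phase <- timeline_phase(timeline, t - walk_offset)

  nchan <- nrow(montage)
  # spatially correlated 1/f background: pink sources with smooth random
  # scalp topographies (volume conduction), plus small independent sensor
  # noise so channels remain mutually predictable, as real EEG is
  data <- matrix(0, nchan, n)
  Wbg <- matrix(0, nchan, nchan)
  for (k in seq_len(nchan)) {
    az <- stats::runif(1, 0, 2 * pi)
    inc <- stats::runif(1, 0, 2 * pi / 3)
    cx <- sin(inc) * sin(az); cy <- sin(inc) * cos(az); cz <- cos(inc)
    dx <- sqrt((montage$x - cx)^2 + (montage$y - cy)^2 + (montage$z - cz)^2)
    Wbg[, k] <- exp(-0.5 * (dx / 1.1)^2)
  }
  Wbg <- Wbg / sqrt(rowSums(Wbg^2))   # uniform background power per channel
  S <- matrix(0, nchan, n)
  for (k in seq_len(nchan)) S[k, ] <- pink_noise(n, fs, rms = 1)
  data <- 8 * (Wbg %*% S)
  data <- data + matrix(stats::rnorm(nchan * n, 0, 1.5), nchan, n)

  # scalp distance-based topography helper (unit-sphere chord distance)
  topo <- function(center_label, width = 0.8) {
    ci <- match(center_label, montage$label)
    dx <- sqrt((montage$x - montage$x[ci])^2 + (montage$y - montage$y[ci])^2 +
                 (montage$z - montage$z[ci])^2)
    exp(-0.5 * (dx / width)^2)
  }
  band_centers <- c(theta = "Fz", alpha = sets$vertex, beta = sets$vertex)

  bands <- spec$bands
  profiles <- matrix(0, nrow(bands), 100,
                     dimnames = list(bands$name, NULL))
  pgrid <- (0:99) / 100
  depth_used <- numeric(nrow(bands))
  for (b in seq_len(nrow(bands))) {
    depth <- if (condition == "standing") 0 else bands[[condition]][b]
    if (!is.null(depth_offsets)) {
      depth <- depth + depth_offsets[[bands$name[b]]]
    }
    depth <- max(depth, 0)
    depth_used[b] <- depth
    sgn <- bands$sign[b]
    dip_depth <- 0
    if (condition != "standing" && identical(bands$name[b], spec$dip$band)) {
      # subject noise may flip the dip's sign: legitimate between-subject
      # variation, and keeps the condition means unbiased
      dip_depth <- unname(spec$dip$depth_db[condition]) + dip_offset
    }
    dp <- spec$dip
    prof_fun <- function(ph) {
      sgn * ((depth / 2) * cos(4 * pi * (ph - 0.075)) +
               dip_depth * exp(-0.5 * ((ph - dp$phase) / dp$width)^2))
    }
    profiles[b, ] <- prof_fun(pgrid)
    amp_db <- ifelse(is.na(phase), 0, prof_fun(phase))
    carrier <- sin(2 * pi * bands$freq[b] * t + stats::runif(1, 0, 2 * pi))
    w <- topo(band_centers[[bands$name[b]]])
    osc <- carrier * 10^(amp_db / 20)
    data <- data + (20 * w) %o% osc
  }

  art_chans <- unique(c(sets$neck, sets$lateral))
  if (spec$artifact_gain_db > 0 && condition != "standing" &&
      length(timeline$rhs) >= 2L) {
    # EMG-like bursts from a few shared neck-muscle sources (spatially
    # correlated across the artifact set, like real volume-conducted EMG)
    env <- double_support_envelope(phase, fs)
    gain <- 10^(spec$artifact_gain_db / 20)
    walk_mask <- as.numeric(!is.na(phase))
    ai <- match(art_chans, montage$label)
    n_src <- min(4L, length(ai))
    src_at <- ai[round(seq(1, length(ai), length.out = n_src))]
    Wa <- matrix(0, length(ai), n_src)
    for (k in seq_len(n_src)) {
      dx <- sqrt((montage$x[ai] - montage$x[src_at[k]])^2 +
                   (montage$y[ai] - montage$y[src_at[k]])^2 +
                   (montage$z[ai] - montage$z[src_at[k]])^2)
      Wa[, k] <- exp(-0.5 * (dx / 0.9)^2)
    }
    Wa <- Wa / sqrt(rowSums(Wa^2))            # unit gain per channel
    # 1/f-shaped EMG sources: broadband like the background so channel-level
    # spectral criteria (line-noise ratio) stay comparable across the scalp
    Sa <- matrix(0, n_src, n)
    for (k in seq_len(n_src)) Sa[k, ] <- pink_noise(n, fs, rms = 3)
    burst <- (Wa %*% Sa) *
      rep((1 + (gain - 1) * env) * walk_mask, each = length(ai))
    data[ai, ] <- data[ai, ] + burst
  }

  if (spec$line_amp_uv > 0) {
    ph50 <- stats::runif(1, 0, 2 * pi)
    line <- sin(2 * pi * 50 * t + ph50)
    data <- data + (spec$line_amp_uv * (0.8 + 0.4 * stats::runif(nchan))) %o%
      line
  }

  blink_onsets <- numeric(0)
  if (spec$blink_rate_hz > 0) {
    n_blinks <- stats::rpois(1, spec$blink_rate_hz * dur)
    if (n_blinks > 0) {
      blink_onsets <- sort(stats::runif(n_blinks, 0, dur - 0.4))
      w <- pmax(montage$y, 0)^2        # frontal topography
      tmpl_len <- round(0.3 * fs)
      tmpl <- 120 * sin(pi * seq_len(tmpl_len) / tmpl_len)^2
      for (on in blink_onsets) {
        i0 <- floor(on * fs) + 1L
        idx <- i0:(i0 + tmpl_len - 1L)
        data[, idx] <- data[, idx] + w %o% tmpl
      }
    }
  }

  ev <- data.frame(label = character(0), onset = numeric(0))
  if (standing_s > 0) {
    ev <- rbind(ev, data.frame(label = c("standing_start", "standing_end"),
                               onset = c(0, standing_s)))
  }
  if (walk_s > 0 && condition != "standing") {
    ev <- rbind(ev, data.frame(
      label = c(paste0("condition/", condition), "walk_start", "walk_end"),
      onset = c(walk_offset, walk_offset, walk_offset + walk_s)))
  }
  rec <- eeg_recording(data, fs, montage, events = ev, ref = "FCz")
  truth <- list(profiles = profiles, depths = stats::setNames(
    depth_used, bands$name),
    artifact_channels = art_chans, artifact_gain_db = spec$artifact_gain_db,
    blink_onsets = blink_onsets, walk_offset = walk_offset)
  list(rec = rec, truth = truth)
}

# ---- study on disk --------------------------------------------------------

#' Simulate one subject of a synthetic study in memory
#'
#' Draws the subject's random effects (stride-time intercept, per-condition
#' modulation-depth noise), then generates the standing-baseline recording
#' and, per condition, the gait timeline, the two-foot accelerometer traces
#' and the EEG recording. All seeds derive deterministically from
#' `spec$seed` and the subject index.
#'
#' @param spec [study_spec()].
#' @param subject subject index (1-based).
#' @param montage montage data.frame; default `montage_1020(spec$n_channels)`.
#' @return list: `standing` (list `rec`, `truth`), `subject_params`, and
#'   `conditions` (per condition: `timeline`, `accel`, `eeg`).
#' @export
simulate_subject <- function(spec, subject,
                             montage = montage_1020(spec$n_channels)) {
  sseed <- sub_seed(spec$seed, subject)
  subj <- draw_subject_params(spec, sseed)
  tl0 <- structure(list(rhs = numeric(0), lto_frac = 0.15, lhs_frac = 0.5,
                        rto_frac = 0.65, stride_mean = NA, stride_sd = NA,
                        bout = c(start = 0, end = 0),
                        condition = "standing"), class = "gait_timeline")
  standing <- generate_eeg(tl0, spec, "standing", sub_seed(sseed, 99),
                           montage = montage, standing_s = spec$standing_s)
  conds <- condition_grid()
  out <- vector("list", length(conds))
  names(out) <- conds
  for (ci in seq_along(conds)) {
    cond <- conds[ci]
    cseed <- sub_seed(sseed, ci)
    tl <- generate_timeline(spec, cond, cseed,
                            subject_shift = subj$stride_shift)
    acc <- generate_accel(tl, spec$accel_fs, spec$accel_noise_sd,
                          sub_seed(cseed, 1))
    eeg <- generate_eeg(tl, spec, cond, sub_seed(cseed, 2),
                        montage = montage, standing_s = 0,
                        depth_offsets = subj$depth_noise[[cond]],
                        dip_offset = subj$dip_noise[[cond]])
    out[[cond]] <- list(timeline = tl, accel = acc, eeg = eeg, seed = cseed)
  }
  list(standing = standing, subject_params = subj, conditions = out)
}

#' Generate a full synthetic study on disk
#'
#' Writes a BIDS-like layout: per subject, one quiet-standing recording plus
#' one recording and one accelerometer-table pair per condition (BrainVision
#' triplets for EEG, tab-separated tables for acceleration and ground-truth
#' events), and a JSON manifest holding every piece of ground truth.
#'
#' @param spec [study_spec()].
#' @param out_dir output directory.
#' @param overwrite overwrite an existing non-empty directory?
#' @return invisibly, the manifest as a list (also written to
#'   `manifest.json`).
#' @export
generate_study <- function(spec, out_dir, overwrite = FALSE) {
  if (dir.exists(out_dir) && length(dir(out_dir)) && !overwrite) {
    stop("output directory exists and is not empty: ", out_dir,
         " (use overwrite = TRUE)")
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  montage <- montage_1020(spec$n_channels)
  manifest <- list(spec = unclass(spec), subjects = list())
  conds <- condition_grid()
  for (s in seq_len(spec$n_subjects)) {
    sid <- sprintf("sub-%02d", s)
    sdir <- file.path(out_dir, sid)
    dir.create(sdir, showWarnings = FALSE)
    sim <- simulate_subject(spec, s, montage)
    write_brainvision(sim$standing$rec,
                      file.path(sdir, paste0(sid, "_standing_eeg")))
    sub_entry <- list(standing = paste0(sid, "_standing_eeg.vhdr"),
                      stride_shift = sim$subject_params$stride_shift,
                      conditions = list())
    for (ci in seq_along(conds)) {
      cond <- conds[ci]
      tl <- sim$conditions[[cond]]$timeline
      acc <- sim$conditions[[cond]]$accel
      eeg <- sim$conditions[[cond]]$eeg
      cseed <- sim$conditions[[cond]]$seed
      stem <- file.path(sdir, paste0(sid, "_task-", cond))
      write_brainvision(eeg$rec, paste0(stem, "_eeg"))
      for (foot in c("left", "right")) {
        tr <- acc[[foot]]
        utils::write.table(
          data.frame(time = (seq_along(tr$vert) - 1) / tr$fs,
                     vert = tr$vert, ap = tr$ap),
          paste0(stem, "_accel-", foot, ".tsv"),
          sep = "\t", row.names = FALSE, quote = FALSE)
      }
      utils::write.table(
        data.frame(onset = acc$truth$onset, duration = 0,
                   trial_type = acc$truth$type),
        paste0(stem, "_true-events.tsv"),
        sep = "\t", row.names = FALSE, quote = FALSE)
      sub_entry$conditions[[cond]] <- list(
        eeg = basename(paste0(stem, "_eeg.vhdr")),
        accel = stats::setNames(
          as.list(basename(paste0(stem, "_accel-", c("left", "right"),
                                  ".tsv"))), c("left", "right")),
        true_events = data.frame(type = acc$truth$type,
                                 onset = acc$truth$onset),
        rhs = tl$rhs,
        depths = as.list(eeg$truth$depths),
        artifact_channels = eeg$truth$artifact_channels,
        seed = cseed)
    }
    manifest$subjects[[sid]] <- sub_entry
  }
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}

# subject-level random effects (stride intercept, per-condition depth noise)
draw_subject_params <- function(spec, seed) {
  set.seed(seed)
  shift <- stats::rnorm(1, 0, spec$subject_stride_sd)
  # keep the subject mean inside the plausible stride window for all conditions
  lo <- 0.5 - min(spec$stride_mean) + 0.02
  hi <- 1.5 - max(spec$stride_mean) - 0.02
  shift <- min(max(shift, lo), hi)
  depth_noise <- lapply(condition_grid(), function(cond) {
    stats::setNames(stats::rnorm(nrow(spec$bands), 0, spec$subject_depth_sd),
                    spec$bands$name)
  })
  names(depth_noise) <- condition_grid()
  dip_noise <- stats::setNames(
    stats::rnorm(length(condition_grid()), 0, spec$dip$subject_sd),
    condition_grid())
  list(stride_shift = shift, depth_noise = depth_noise,
       dip_noise = dip_noise)
}

#' Read an accelerometer table written by [generate_study()]
#'
#' @param path `.tsv` file with columns `time`, `vert`, `ap`.
#' @param fs sampling rate; inferred from the time column when `NULL`.
#' @param foot foot label.
#' @return [accel_trace()].
#' @export
read_accel_tsv <- function(path, fs = NULL, foot = c("right", "left")) {
  foot <- match.arg(foot)
  d <- utils::read.delim(path)
  stopifnot(all(c("time", "vert", "ap") %in% names(d)))
  if (is.null(fs)) fs <- round(1 / stats::median(diff(d$time)))
  accel_trace(d$vert, d$ap, fs, foot)
}
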