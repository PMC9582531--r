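#' Gait-detection parameters
#'
#' Thresholds and windows for accelerometer-based gait-event detection.
#' Defaults follow the published detection rules: mid-swing step markers are
#' peaks > 0.6 g (fallback 0.24 g for low-amplitude walkers) with >= 500 ms
#' separation in the 6 Hz low-passed vertical axis; heel strikes are the
#' first peak > 0.6 g after a step marker in the 30 Hz data; toe-offs are the
#' mean latency of the two highest anterior-posterior peaks > 0.2 g in the
#' 500 ms before a step marker; plausible strides last 0.5-1.5 s.
#'
#' @param step_threshold step-marker peak threshold (g).
#' @param step_threshold_fallback fallback threshold (g) for recordings where
#'   the main threshold finds implausibly few steps.
#' @param step_min_separation minimum step-marker separation (s).
#' @param hs_threshold heel-strike peak threshold (g).
#' @param to_threshold toe-off peak threshold (g).
#' @param to_window toe-off search window before the step marker (s).
#' @param hs_refractory dead time after a step marker before the heel-strike
#'   search begins (s). Excludes the tail of the mid-swing peak itself, which
#'   also exceeds the threshold in the 30 Hz data; mid-swing and heel strike
#'   are separated by well over this for any plausible stride.
#' @param lp_main,lp_interim low-pass cut-offs (Hz) of the 30 Hz detection
#'   and 6 Hz step-counting filters.
#' @param duration_bounds plausible stride-duration bounds (s).
#' @return object of class `gait_params`.
#' @export
gait_params <- function(step_threshold = 0.6,
                        step_threshold_fallback = 0.24,
                        step_min_separation = 0.5,
                        hs_threshold = 0.6,
                        to_threshold = 0.2,
                        to_window = 0.5,
                        hs_refractory = 0.06,
                        lp_main = 30, lp_interim = 6,
                        duration_bounds = c(0.5, 1.5)) {
  stopifnot(step_threshold > 0, step_threshold_fallback > 0,
            step_min_separation > 0, hs_threshold > 0, to_threshold > 0,
            to_window > 0, hs_refractory >= 0,
            lp_main > lp_interim, lp_interim > 0,
            length(duration_bounds) == 2,
            0 < duration_bounds[1], duration_bounds[1] < duration_bounds[2])
  structure(as.list(environment()), class = "gait_params")
}

#' Detrend and low-pass filter an accelerometer trace
#'
#' Each axis is linearly detrended per walking bout, then zero-phase low-pass
#' filtered with a forward-backward 2nd-order Butterworth design (effective
#' order 4, zero phase): once at the main cut-off (default 30 Hz, used for
#' heel-strike/toe-off detection) and once at the interim cut-off (default
#' 6 Hz, used for step counting).
#'
#' @param trace [accel_trace()].
#' @param params [gait_params()].
#' @return list with elements `main` and `interim`, both [accel_trace()].
#' @export
filter_accel <- function(trace, params = gait_params()) {
  fs <- trace$fs
  if (length(trace$vert) < fs) {
    stop("trace shorter than the 1 s filter warm-up")
  }
  detrend_bouts <- function(x) {
    for (b in seq_len(nrow(trace$bouts))) {
      i0 <- max(1L, floor(trace$bouts[b, 1] * fs) + 1L)
      i1 <- min(length(x), ceiling(trace$bouts[b, 2] * fs) + 1L)
      x[i0:i1] <- detrend_linear(x[i0:i1])
    }
    x
  }
  run <- function(fc) {
    flt <- butter2_lowpass(fc, fs)
    pad <- min(length(trace$vert) - 2L, max(9L, round(3 * fs / fc)))
    accel_trace(
      filtfilt2(flt$b, flt$a, detrend_bouts(trace$vert), pad),
      filtfilt2(flt$b, flt$a, detrend_bouts(trace$ap), pad),
      fs, trace$foot, trace$bouts)
  }
  list(main = run(params$lp_main), interim = run(params$lp_interim))
}

#' Detect mid-swing step markers
#'
#' Local maxima of the 6 Hz low-passed vertical acceleration exceeding the
#' step threshold with the minimum separation enforced (higher peak wins on
#' conflict). Only samples inside walking bouts are considered. If fewer than
#' `fallback_min` markers are found, detection is retried once with the
#' fallback threshold.
#'
#' @param trace_interim 6 Hz-filtered [accel_trace()] (from [filter_accel()]).
#' @param params [gait_params()].
#' @param fallback_min minimum plausible marker count before the fallback
#'   threshold is tried (default 2).
#' @return numeric vector of marker latencies (s, 0-based from recording
#'   start), possibly empty.
#' @export
detect_step_markers <- function(trace_interim, params = gait_params(),
                                fallback_min = 2L) {
  fs <- trace_interim$fs
  x <- trace_interim$vert
  in_bout <- logical(length(x))
  for (b in seq_len(nrow(trace_interim$bouts))) {
    i0 <- max(1L, floor(trace_interim$bouts[b, 1] * fs) + 1L)
    i1 <- min(length(x), ceiling(trace_interim$bouts[b, 2] * fs) + 1L)
    in_bout[i0:i1] <- TRUE
  }
  xm <- ifelse(in_bout, x, -Inf)
  md <- round(params$step_min_separation * fs)
  idx <- find_peaks(xm, height = params$step_threshold, min_distance = md)
  if (length(idx) < fallback_min) {
    idx <- find_peaks(xm, height = params$step_threshold_fallback,
                      min_distance = md)
  }
  (idx - 1L) / fs
}

#' Detect heel strikes following step markers
#'
#' For each step marker, the earliest local maximum of the 30 Hz vertical
#' acceleration after the marker (past the refractory window), exceeding the
#' heel-strike threshold and before the next marker (or end of data).
#' Markers with no qualifying peak contribute no event.
#'
#' @param trace_main 30 Hz-filtered [accel_trace()].
#' @param step_markers sorted marker latencies (s).
#' @param params [gait_params()].
#' @return numeric vector of heel-strike latencies (s).
#' @export
detect_heel_strikes <- function(trace_main, step_markers,
                                params = gait_params()) {
  fs <- trace_main$fs
  x <- trace_main$vert
  peaks <- find_peaks(x, height = params$hs_threshold)
  ptimes <- (peaks - 1L) / fs
  out <- numeric(0)
  bounds <- c(step_markers, length(x) / fs)
  for (k in seq_along(step_markers)) {
    cand <- ptimes[ptimes > step_markers[k] + params$hs_refractory &
                     ptimes < bounds[k + 1L]]
    if (length(cand)) out <- c(out, cand[1L])
  }
  out
}

#' Detect toe-offs preceding step markers
#'
#' Per marker, qualifying peaks are local maxima of the anterior-posterior
#' 30 Hz acceleration exceeding the toe-off threshold within the search
#' window before the marker. With two or more qualifying peaks, the toe-off
#' latency is the arithmetic mean of the latencies of the two highest;
#' fewer than two yield no event.
#'
#' @param trace_main 30 Hz-filtered [accel_trace()].
#' @param step_markers sorted marker latencies (s).
#' @param params [gait_params()].
#' @return numeric vector of toe-off latencies (s).
#' @export
detect_toe_offs <- function(trace_main, step_markers,
                            params = gait_params()) {
  fs <- trace_main$fs
  x <- trace_main$ap
  peaks <- find_peaks(x, height = params$to_threshold)
  ptimes <- (peaks - 1L) / fs
  heights <- x[peaks]
  out <- numeric(0)
  for (m in step_markers) {
    sel <- ptimes >= m - params$to_window & ptimes < m
    if (sum(sel) < 2L) next
    h <- heights[sel]; tt <- ptimes[sel]
    top2 <- order(h, decreasing = TRUE)[1:2]
    out <- c(out, mean(tt[top2]))
  }
  out
}

#' Run the full per-foot detection chain
#'
#' Convenience wrapper: filters the trace, detects step markers, then heel
#' strikes and toe-offs. Event side is assigned by sensor foot.
#'
#' @param trace [accel_trace()].
#' @param params [gait_params()].
#' @return data.frame with `type` (`RHS`/`RTO` or `LHS`/`LTO`), `onset` (s)
#'   and `foot`.
#' @export
detect_gait_events <- function(trace, params = gait_params()) {
  filt <- filter_accel(trace, params)
  markers <- detect_step_markers(filt$interim, params)
  hs <- detect_heel_strikes(filt$main, markers, params)
  to <- detect_toe_offs(filt$main, markers, params)
  pre <- if (trace$foot == "right") "R" else "L"
  ev <- rbind(
    data.frame(type = paste0(pre, "HS"), onset = hs),
    data.frame(type = paste0(pre, "TO"), onset = to)
  )
  ev$foot <- trace$foot
  ev[order(ev$onset), ]
}

#' Assemble plausibility-filtered gait cycles
#'
#' One candidate cycle per consecutive pair of right heel strikes. A cycle is
#' valid when (1) exactly one LTO, LHS and RTO fall strictly between the two
#' RHS in the canonical order RHS < LTO < LHS < RTO < next RHS, and (2) the
#' duration lies within the plausibility bounds. Invalid cycles carry a
#' rejection reason (`"duration"` when out of bounds, else `"order"`).
#'
#' @param events_left,events_right per-foot event data.frames from
#'   [detect_gait_events()] (or any frames with `type` and `onset`).
#' @param params [gait_params()].
#' @return data.frame of class `gait_cycles`: columns `rhs`, `lto`, `lhs`,
#'   `rto`, `rhs_next` (s; NA when missing), `duration`, `valid`, `reason`.
#' @export
assemble_gait_cycles <- function(events_left, events_right,
                                 params = gait_params()) {
  ev <- rbind(events_left[, c("type", "onset")],
              events_right[, c("type", "onset")])
  ev <- ev[order(ev$onset), ]
  rhs <- sort(ev$onset[ev$type == "RHS"])
  n <- length(rhs) - 1L
  if (n < 1L) {
    out <- data.frame(rhs = numeric(0), lto = numeric(0), lhs = numeric(0),
                      rto = numeric(0), rhs_next = numeric(0),
                      duration = numeric(0), valid = logical(0),
                      reason = character(0))
    class(out) <- c("gait_cycles", class(out))
    return(out)
  }
  pick <- function(type, a, b) {
    v <- ev$onset[ev$type == type & ev$onset > a & ev$onset < b]
    if (length(v) == 1L) v else if (length(v) == 0L) NA_real_ else -Inf
  }
  out <- data.frame(rhs = rhs[-length(rhs)], rhs_next = rhs[-1L])
  out$lto <- mapply(pick, "LTO", out$rhs, out$rhs_next)
  out$lhs <- mapply(pick, "LHS", out$rhs, out$rhs_next)
  out$rto <- mapply(pick, "RTO", out$rhs, out$rhs_next)
  out$duration <- out$rhs_next - out$rhs
  dur_ok <- out$duration >= params$duration_bounds[1] &
    out$duration <= params$duration_bounds[2]
  order_ok <- !is.na(out$lto) & !is.na(out$lhs) & !is.na(out$rto) &
    is.finite(out$lto) & is.finite(out$lhs) & is.finite(out$rto) &
    out$lto < out$lhs & out$lhs < out$rto
  out$valid <- dur_ok & order_ok
  out$reason <- ifelse(out$valid, "none",
                       ifelse(!dur_ok, "duration", "order"))
  out$lto[!is.finite(out$lto)] <- NA_real_
  out$lhs[!is.finite(out$lhs)] <- NA_real_
  out$rto[!is.finite(out$rto)] <- NA_real_
  out <- out[, c("rhs", "lto", "lhs", "rto", "rhs_next", "duration",
                 "valid", "reason")]
  class(out) <- c("gait_cycles", class(out))
  out
}

#' Stride time and stride-time variability
#'
#' Stride times are the durations of valid cycles (RHS to next RHS, s); the
#' coefficient of variation is `100 * SD / mean` with the sample SD
#' (n - 1 denominator).
#'
#' @param cycles [assemble_gait_cycles()] output.
#' @return list of class `stride_metrics`: `stride_times`, `mean_stride`,
#'   `cv_pct` (NA with a flag when only one valid cycle), `n_valid`,
#'   `n_detected`.
#' @export
stride_metrics <- function(cycles) {
  st <- cycles$duration[cycles$valid]
  if (!length(st)) stop("no valid gait cycles: stride metrics undefined")
  cv <- if (length(st) >= 2L) 100 * stats::sd(st) / mean(st) else NA_real_
  structure(list(stride_times = st, mean_stride = mean(st), cv_pct = cv,
                 cv_defined = length(st) >= 2L,
                 n_valid = length(st), n_detected = nrow(cycles)),
            class = "stride_metrics")
}

#' @export
print.stride_metrics <- function(x, ...) {
  cat(sprintf("<stride_metrics> %d/%d valid cycles, mean %.3f s, CV %.2f%%\n",
              x$n_valid, x$n_detected, x$mean_stride, x$cv_pct))
  invisible(x)
}

#' Write detected events as a BIDS-style events table
#'
#' @param events combined event data.frame (`type`, `onset`).
#' @param path output `.tsv` path.
#' @return invisibly, `path`.
#' @export
write_events_tsv <- function(events, path) {
  utils::write.table(
    data.frame(onset = events$onset, duration = 0, trial_type = events$type),
    path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
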