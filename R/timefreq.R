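#' Time-frequency analysis parameters
#'
#' @param freqs analysis frequency grid (Hz), strictly increasing.
#' @param stats_band frequency band used by the group statistics (Hz).
#' @param phase_bins number of gait-phase bins per cycle (>= 2); bin `k`
#'   covers `[k, k+1)` percent of the cycle with bin 0 at right heel strike.
#' @param cycle_uv absolute time-domain amplitude (uV) above which a gait
#'   cycle is excluded from averaging.
#' @param n_cycles wavelet width rule: either a fixed cycle count, or a
#'   length-2 vector giving the number of Morlet cycles at the lowest and
#'   highest frequency (linearly interpolated in between).
#' @param min_standing_s minimum usable standing-baseline duration (s).
#' @return object of class `tf_params`.
#' @export
tf_params <- function(freqs = seq(2, 60, by = 2), stats_band = c(6, 40),
                      phase_bins = 100, cycle_uv = 350,
                      n_cycles = c(3, 8), min_standing_s = 30) {
  stopifnot(all(diff(freqs) > 0), length(stats_band) == 2,
            stats_band[1] < stats_band[2], phase_bins >= 2, cycle_uv > 0,
            length(n_cycles) %in% c(1, 2), all(n_cycles > 0),
            min_standing_s > 0)
  structure(as.list(environment()), class = "tf_params")
}

wavelet_cycles <- function(params) {
  f <- params$freqs
  nc <- params$n_cycles
  if (length(nc) == 1L) rep(nc, length(f))
  else nc[1] + (nc[2] - nc[1]) * (f - f[1]) / (f[length(f)] - f[1])
}

#' Morlet wavelet power of a recording
#'
#' Complex Morlet convolution implemented in the frequency domain (analytic
#' Gaussian kernels centred on each grid frequency); power is the squared
#' magnitude. Samples within one wavelet half-width (3 temporal SD) of
#' either edge are flagged per frequency and excluded from baseline
#' averaging downstream.
#'
#' @param rec [eeg_recording()].
#' @param params [tf_params()].
#' @param channels optional subset of channel labels to decompose.
#' @return object of class `tf_power`: `power` matrix of
#'   `(channel * frequency) x samples` (channel fastest), plus `labels`,
#'   `freqs`, `srate`, `halfwidth` (edge samples per frequency).
#' @export
morlet_power <- function(rec, params = tf_params(), channels = NULL) {
  if (rec$srate < 2 * max(params$freqs)) {
    stop("sampling rate below Nyquist for the highest analysis frequency")
  }
  labels <- if (is.null(channels)) rec$montage$label else channels
  ci <- match(labels, rec$montage$label)
  if (anyNA(ci)) stop("unknown channels: ",
                      paste(labels[is.na(ci)], collapse = ", "))
  n <- ncol(rec$data)
  fs <- rec$srate
  freqs <- params$freqs
  ncyc <- wavelet_cycles(params)
  sigma_t <- ncyc / (2 * pi * freqs)
  halfwidth <- ceiling(3 * sigma_t * fs)
  if (n <= 2 * max(halfwidth)) {
    stop("recording shorter than the widest wavelet")
  }
  nfft <- next_pow2(n)
  fgrid <- (seq_len(nfft) - 1) * fs / nfft
  nch <- length(ci)
  nf <- length(freqs)
  P <- matrix(0, nch * nf, n)
  for (k in seq_len(nch)) {
    X <- stats::fft(c(rec$data[ci[k], ], rep(0, nfft - n)))
    for (j in seq_len(nf)) {
      sf <- freqs[j] / ncyc[j]
      W <- exp(-((fgrid - freqs[j])^2) / (2 * sf^2))
      W[fgrid > fs / 2] <- 0                       # analytic: positive only
      y <- stats::fft(X * W, inverse = TRUE)[seq_len(n)] / nfft
      P[(j - 1L) * nch + k, ] <- 2 * Mod(y)^2      # one-sided power
    }
  }
  structure(list(power = P, labels = labels, freqs = freqs, srate = fs,
                 halfwidth = halfwidth), class = "tf_power")
}

# row index helper: (channel, frequency) -> row of tf$power
tf_row <- function(tf, ch, fr) (fr - 1L) * length(tf$labels) + ch

#' @export
print.tf_power <- function(x, ...) {
  cat(sprintf("<tf_power> %d channels x %d freqs (%g-%g Hz) x %d samples\n",
              length(x$labels), length(x$freqs), min(x$freqs), max(x$freqs),
              ncol(x$power)))
  invisible(x)
}

#' Mean standing-baseline power per channel and frequency
#'
#' Time-averaged wavelet power over one or more standing spans, excluding
#' edge-flagged samples; spans are duration-weighted through pooling of
#' their samples.
#'
#' @param tf [morlet_power()] output.
#' @param spans two-column matrix of span start/end times (s), e.g. from
#'   [event_spans()].
#' @param params [tf_params()].
#' @return matrix channels x frequencies of strictly positive power, class
#'   `baseline_power`.
#' @export
standing_baseline_power <- function(tf, spans, params = tf_params()) {
  spans <- rbind(spans)
  n <- ncol(tf$power)
  fs <- tf$srate
  nch <- length(tf$labels)
  nf <- length(tf$freqs)
  out <- matrix(NA_real_, nch, nf,
                dimnames = list(tf$labels, tf$freqs))
  total <- 0
  idx_all <- vector("list", nrow(spans))
  for (s in seq_len(nrow(spans))) {
    i0 <- max(1L, floor(spans[s, 1] * fs) + 1L)
    i1 <- min(n, ceiling(spans[s, 2] * fs))
    idx_all[[s]] <- if (i1 >= i0) i0:i1 else integer(0)
    total <- total + length(idx_all[[s]])
  }
  for (j in seq_len(nf)) {
    hw <- tf$halfwidth[j]
    idx <- unlist(lapply(idx_all, function(ii) {
      ii[ii > hw & ii <= n - hw]
    }))
    if (length(idx) < params$min_standing_s * fs) {
      stop("standing interval too short: ", round(length(idx) / fs, 1),
           " s of unflagged samples at ", tf$freqs[j], " Hz (need >= ",
           params$min_standing_s, " s)")
    }
    rows <- tf_row(tf, seq_len(nch), j)
    out[, j] <- rowMeans(tf$power[rows, idx, drop = FALSE])
  }
  if (any(out <= 0)) {
    stop("standing baseline contains zero power; dB baseline undefined")
  }
  class(out) <- c("baseline_power", class(out))
  out
}

#' Extract gait cycles from the power trajectory and warp to phase bins
#'
#' For every valid gait cycle, the power between its two right heel strikes
#' is linearly interpolated onto `phase_bins` uniformly spaced phase points
#' (bin 0 at RHS). Cycles in which any time-domain sample of any channel
#' exceeds the amplitude gate are dropped and counted.
#'
#' @param tf [morlet_power()] output.
#' @param rec the cleaned [eeg_recording()] the power was computed from
#'   (time-domain amplitude gate); pass `NULL` to skip the gate.
#' @param cycles [assemble_gait_cycles()] output (or any frame with `rhs`,
#'   `rhs_next`, `valid`).
#' @param params [tf_params()].
#' @return 3-D array `(channel * frequency) x phase_bins x kept cycles` with
#'   attributes `n_excluded` (amplitude exclusions) and `kept` (indices into
#'   the valid cycles).
#' @export
extract_and_warp_cycles <- function(tf, rec, cycles,
                                    params = tf_params()) {
  val <- which(cycles$valid)
  fs <- tf$srate
  n <- ncol(tf$power)
  nb <- params$phase_bins
  segs <- vector("list", length(val))
  kept <- logical(length(val))
  for (k in seq_along(val)) {
    cy <- cycles[val[k], ]
    i0 <- floor(cy$rhs * fs) + 1L
    i1 <- ceiling(cy$rhs_next * fs) + 1L
    if (i0 < 1L || i1 > n) next
    if (!is.null(rec) &&
        max(abs(rec$data[, i0:i1])) > params$cycle_uv) next
    # linear interpolation of every row at the 100 phase time points
    pos <- (cy$rhs + (0:(nb - 1)) / nb * (cy$rhs_next - cy$rhs)) * fs + 1
    lo <- pmin(floor(pos), n - 1L)
    w <- pos - lo
    seg <- tf$power[, lo, drop = FALSE] * rep(1 - w, each = nrow(tf$power)) +
      tf$power[, lo + 1L, drop = FALSE] * rep(w, each = nrow(tf$power))
    segs[[k]] <- seg
    kept[k] <- TRUE
  }
  segs <- segs[kept]
  out <- array(unlist(segs),
               dim = c(nrow(tf$power), nb, length(segs)))
  attr(out, "n_excluded") <- sum(!kept)
  attr(out, "kept") <- val[kept]
  out
}

#' Average warped cycles into a gait ERSP
#'
#' `ERSP = 10 log10(mean-over-cycles power / standing baseline)` per
#' channel, frequency and phase bin.
#'
#' @param segments array from [extract_and_warp_cycles()].
#' @param baseline [standing_baseline_power()] matrix.
#' @param tf the [morlet_power()] object the segments came from (provides
#'   channel/frequency labels).
#' @param condition optional condition label stored with the map.
#' @return object of class `gait_ersp`: array channels x frequencies x
#'   phase bins (dB), with attributes `freqs`, `labels`, `n_cycles`,
#'   `condition`, `kind = "ersp"`.
#' @export
average_to_ersp <- function(segments, baseline, tf, condition = NA) {
  if (!length(segments) || dim(segments)[3] < 1L) {
    stop("no gait cycles to average")
  }
  if (any(baseline <= 0)) stop("baseline must be strictly positive")
  nch <- length(tf$labels)
  nf <- length(tf$freqs)
  nb <- dim(segments)[2]
  mp <- rowMeans(segments, dims = 2)            # (ch*freq) x bins
  ersp <- array(NA_real_, c(nch, nf, nb),
                dimnames = list(tf$labels, tf$freqs, NULL))
  for (j in seq_len(nf)) {
    rows <- tf_row(tf, seq_len(nch), j)
    ersp[, j, ] <- 10 * log10(mp[rows, , drop = FALSE] / baseline[, j])
  }
  structure(ersp, freqs = tf$freqs, labels = tf$labels,
            n_cycles = dim(segments)[3], condition = condition,
            kind = "ersp", class = "gait_ersp")
}

#' Gait-phase power modulation (GPM) from a gait ERSP
#'
#' Subtracts, per channel and frequency, the mean across phase bins, leaving
#' only the within-cycle modulation; every row of the result has zero mean
#' across phase.
#'
#' @param ersp [average_to_ersp()] output.
#' @return `gait_ersp` object with `kind = "gpm"`.
#' @export
ersp_to_gpm <- function(ersp) {
  stopifnot(all(is.finite(ersp)))
  m <- apply(ersp, c(1, 2), mean)
  out <- sweep(unclass(ersp), c(1, 2), m)
  attributes(out) <- attributes(ersp)
  attr(out, "kind") <- "gpm"
  out
}

#' @export
print.gait_ersp <- function(x, ...) {
  d <- dim(x)
  cat(sprintf("<gait_ersp:%s> %d channels x %d freqs x %d phase bins (%s cycles)\n",
              attr(x, "kind"), d[1], d[2], d[3],
              as.character(attr(x, "n_cycles"))))
  invisible(x)
}

#' Average several ERSP/GPM maps (equal weight per map)
#' @param maps list of `gait_ersp` objects with identical dimensions.
#' @return `gait_ersp` of the same shape.
#' @export
average_maps <- function(maps) {
  stopifnot(length(maps) >= 1)
  out <- Reduce(`+`, lapply(maps, unclass)) / length(maps)
  attributes(out) <- attributes(maps[[1]])
  attr(out, "n_cycles") <- sum(sapply(maps, attr, "n_cycles"))
  out
}
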