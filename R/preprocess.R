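#' EEG preprocessing parameters
#'
#' Defaults follow the cleaning chain this package implements: downsample to
#' 250 Hz, zero-phase FIR band-pass 0.2-60 Hz, bad-channel rules (flatline
#' 5 s, neighbour-correlation floor 0.8, line-noise z-score 4), burst
#' correction hook (ASR-style cut-off 20, hook only), 350 uV / 3 SD epoch
#' rejection, 90% eye-probability IC rejection, 50 Hz mains.
#'
#' @param target_rate analysis sampling rate (Hz).
#' @param band band-pass edges (Hz).
#' @param flatline_s flatline duration flagging a channel (s).
#' @param corr_floor minimum correlation with the spline prediction from the
#'   remaining channels.
#' @param line_z robust z-score of the line-noise-to-signal ratio above
#'   which a channel is flagged.
#' @param asr_cutoff burst-correction cut-off in SD (hook contract only; the
#'   default pipeline substitutes epoch rejection).
#' @param epoch_uv absolute amplitude threshold for epoch rejection (uV).
#' @param jointprob_sd joint-probability z threshold (SD).
#' @param eye_prob eye-component score above which an IC is removed.
#' @param line_freq mains frequency (Hz).
#' @return object of class `preproc_params`.
#' @export
preproc_params <- function(target_rate = 250, band = c(0.2, 60),
                           flatline_s = 5, corr_floor = 0.8, line_z = 4,
                           asr_cutoff = 20, epoch_uv = 350,
                           jointprob_sd = 3, eye_prob = 0.90,
                           line_freq = 50) {
  stopifnot(target_rate > 0, length(band) == 2, band[1] > 0,
            band[1] < band[2], flatline_s > 0, corr_floor > 0, line_z > 0,
            asr_cutoff > 0, epoch_uv > 0, jointprob_sd > 0,
            eye_prob > 0, eye_prob <= 1, line_freq > 0)
  structure(as.list(environment()), class = "preproc_params")
}

#' Downsample and band-pass filter a recording
#'
#' Integer-factor downsampling (after a zero-phase anti-alias FIR low-pass)
#' followed by a zero-phase FIR band-pass implemented as a long high-pass
#' (narrow 0.2 Hz transition) plus a short low-pass, mirroring the usual
#' two-filter realisation.
#'
#' @param rec [eeg_recording()].
#' @param params [preproc_params()].
#' @return filtered [eeg_recording()] at the target rate.
#' @export
resample_and_filter <- function(rec, params = preproc_params()) {
  if (rec$srate < 2 * params$band[2]) {
    stop("native rate ", rec$srate, " Hz violates the Nyquist requirement ",
         "for the ", params$band[2], " Hz band edge")
  }
  fs <- rec$srate
  X <- rec$data
  if (fs != params$target_rate) {
    ratio <- fs / params$target_rate
    if (abs(ratio - round(ratio)) > 1e-9) {
      stop("only integer downsampling factors are supported (got ",
           signif(ratio, 4), ")")
    }
    ratio <- as.integer(round(ratio))
    h <- fir_design(16L * ratio, 0, 0.4 * params$target_rate, fs)
    keep <- seq(1L, ncol(X), by = ratio)
    X <- fir_filtfilt_mat(h, X)[, keep, drop = FALSE]
    fs <- params$target_rate  # event onsets are in seconds: unchanged
  }
  # band-pass realised as long high-pass (transition ~ passband edge)
  # convolved with a short low-pass, applied in one zero-phase pass
  hp_order <- 2L * round(3.3 / (params$band[1]) * fs / 2)
  hp <- fir_design(hp_order, params$band[1], fs / 2, fs)
  lp_order <- 2L * round(3.3 / 15 * fs / 2)
  lp <- fir_design(lp_order, 0, params$band[2], fs)
  h_band <- stats::convolve(hp, rev(lp), type = "open")
  X <- fir_filtfilt_mat(h_band, X)
  out <- rec
  out$data <- X
  rownames(out$data) <- rec$montage$label
  out$srate <- fs
  out$provenance$filtered <- params$band
  out
}

# power in [f1,f2) Hz from a one-sided periodogram
band_power <- function(x, fs, f1, f2) {
  n <- length(x)
  P <- Mod(stats::fft(x))^2 / n
  f <- (seq_len(n) - 1) * fs / n
  sum(P[f >= f1 & f < f2 & f <= fs / 2])
}

#' Flag bad channels (flatline, correlation, line noise)
#'
#' A channel is flagged when (a) it contains a near-constant run of at least
#' `flatline_s` seconds, (b) its correlation with the spherical-spline
#' prediction from all other channels falls below `corr_floor`, or (c) the
#' robust z-score (median/MAD across channels) of its line-noise-to-signal
#' power ratio exceeds `line_z`.
#'
#' @param rec [eeg_recording()] (>= 8 channels).
#' @param params [preproc_params()].
#' @return character vector of bad-channel labels with a `reasons` attribute.
#' @export
find_bad_channels <- function(rec, params = preproc_params()) {
  X <- rec$data
  nchan <- nrow(X)
  if (nchan < 8) stop("bad-channel detection needs >= 8 channels")
  fs <- rec$srate
  reasons <- list()
  # flatline: longest run with |first difference| below a tiny tolerance
  flat_len <- round(params$flatline_s * fs)
  flat <- vapply(seq_len(nchan), function(i) {
    small <- abs(diff(X[i, ])) < 1e-8 * max(1, stats::mad(X[i, ]))
    if (!any(small)) return(FALSE)
    r <- rle(small)
    any(r$lengths[r$values] >= flat_len)
  }, logical(1))
  # correlation with spline prediction from the remaining channels
  P <- as.matrix(rec$montage[, c("x", "y", "z")])
  corr <- vapply(seq_len(nchan), function(i) {
    W <- spline_operator(P[-i, , drop = FALSE], P[i, , drop = FALSE])
    est <- as.numeric(W %*% X[-i, , drop = FALSE])
    suppressWarnings(stats::cor(X[i, ], est))
  }, numeric(1))
  corr[is.na(corr)] <- 0
  low_corr <- corr < params$corr_floor
  # line-noise-to-signal ratio: line band vs its local flanking bands
  # (robust to how rhythm power is distributed over the scalp)
  lf <- params$line_freq
  ratio <- vapply(seq_len(nchan), function(i) {
    pl <- band_power(X[i, ], fs, lf - 1, lf + 1)
    ps <- band_power(X[i, ], fs, lf - 5, lf - 1) +
      band_power(X[i, ], fs, lf + 1, lf + 5)
    if (ps <= 0) Inf else pl / ps
  }, numeric(1))
  med <- stats::median(ratio[is.finite(ratio)])
  s <- stats::mad(ratio[is.finite(ratio)])
  z <- if (s > 0) (ratio - med) / s else rep(0, nchan)
  liney <- z > params$line_z
  bad <- flat | low_corr | liney
  labels <- rec$montage$label[bad]
  attr(labels, "reasons") <- data.frame(
    label = rec$montage$label[bad],
    flatline = flat[bad], correlation = low_corr[bad], line_noise = liney[bad])
  labels
}

#' Re-reference to the full-rank common average
#'
#' Reconstructs the original online reference channel (zero signal at its
#' scalp position) before subtracting the per-sample channel mean, so the
#' re-referenced data keep full rank. Applying the function twice equals
#' applying it once.
#'
#' @param rec [eeg_recording()] (bads interpolated first).
#' @return re-referenced [eeg_recording()] with `ref = "CAR"`; the
#'   reconstructed reference channel is appended as a data row.
#' @export
rereference_car <- function(rec) {
  if (nrow(rec$data) < 2) stop("common average undefined for one channel")
  if (length(rec$bads)) {
    warning("re-referencing with uninterpolated bad channels: ",
            paste(rec$bads, collapse = ", "))
  }
  if (!identical(rec$ref, "CAR")) {
    full <- montage_table()
    ri <- match(rec$ref, full$label)
    if (!is.na(ri) && !(rec$ref %in% rec$montage$label)) {
      rec$montage <- rbind(rec$montage, full[ri, ])
      rec$data <- rbind(rec$data, 0)
      rownames(rec$data) <- rec$montage$label
    }
  }
  m <- colMeans(rec$data)
  rec$data <- sweep(rec$data, 2, m)
  rec$ref <- "CAR"
  rec
}

#' Remove mains interference by sliding-window sinusoid regression
#'
#' Fits sine/cosine pairs at the line frequency (and its first harmonic when
#' below Nyquist) in overlapping 2 s windows and subtracts the fit with a
#' Hann overlap-add, tracking slow amplitude/phase drift. Narrow-band by
#' construction: only the fitted sinusoids are removed.
#'
#' @param rec [eeg_recording()].
#' @param params [preproc_params()].
#' @param window_s regression window length (s).
#' @return cleaned [eeg_recording()].
#' @export
remove_line_noise <- function(rec, params = preproc_params(),
                              window_s = 2) {
  fs <- rec$srate
  lf <- params$line_freq
  if (fs <= 2 * lf) stop("sampling rate too low for ", lf, " Hz removal")
  n <- ncol(rec$data)
  L <- round(window_s * fs)
  hop <- L %/% 2L
  starts <- seq(1L, max(1L, n - L + 1L), by = hop)
  freqs <- lf
  if (2 * lf < fs / 2) freqs <- c(lf, 2 * lf)
  tglob <- (seq_len(n) - 1) / fs
  B <- do.call(cbind, lapply(freqs, function(f) {
    cbind(sin(2 * pi * f * tglob), cos(2 * pi * f * tglob))
  }))
  win <- 0.5 - 0.5 * cos(2 * pi * (seq_len(L) - 1) / (L - 1))
  fit_acc <- matrix(0, nrow(rec$data), n)
  wsum <- numeric(n)
  for (s in starts) {
    idx <- s:min(n, s + L - 1L)
    Bi <- B[idx, , drop = FALSE]
    coefs <- qr.solve(Bi, t(rec$data[, idx, drop = FALSE]))
    fit <- t(Bi %*% coefs)
    w <- win[seq_along(idx)]
    fit_acc[, idx] <- fit_acc[, idx] + sweep(fit, 2, w, `*`)
    wsum[idx] <- wsum[idx] + w
  }
  wsum[wsum < 1e-6] <- 1
  rec$data <- rec$data - sweep(fit_acc, 2, wsum, `/`)
  rec$provenance$line_removed <- lf
  rec
}

#' Reject high-amplitude / improbable epochs
#'
#' Splits the recording into consecutive non-overlapping epochs. An epoch is
#' rejected when any sample exceeds the absolute threshold, or when its
#' per-channel joint log-probability under a kernel-density estimate of that
#' channel's amplitude distribution is improbably low (robust z below
#' `-jointprob_sd` on any channel).
#'
#' @param rec [eeg_recording()].
#' @param epoch_len epoch length (s).
#' @param params [preproc_params()].
#' @return logical keep-mask, one element per epoch, with attributes
#'   `n_amplitude` and `n_jointprob` (rejection counts).
#' @export
reject_artifact_epochs <- function(rec, epoch_len = 1,
                                   params = preproc_params()) {
  stopifnot(epoch_len > 0)
  L <- round(epoch_len * rec$srate)
  n_ep <- floor(ncol(rec$data) / L)
  if (n_ep == 0L) {
    mask <- logical(0)
    attr(mask, "n_amplitude") <- 0L
    attr(mask, "n_jointprob") <- 0L
    return(mask)
  }
  ep_idx <- function(e) ((e - 1L) * L + 1L):(e * L)
  amp_bad <- vapply(seq_len(n_ep), function(e) {
    any(abs(rec$data[, ep_idx(e)]) > params$epoch_uv)
  }, logical(1))
  # joint probability: per channel KDE over all samples, epoch log-likelihood
  jp_bad <- rep(FALSE, n_ep)
  if (n_ep >= 3L) {
    for (ch in seq_len(nrow(rec$data))) {
      x <- rec$data[ch, seq_len(n_ep * L)]
      d <- stats::density(x, n = 512)
      logp <- log(pmax(stats::approx(d$x, d$y, xout = x, rule = 2)$y,
                       1e-300))
      ll <- colSums(matrix(logp, nrow = L))
      z <- (ll - stats::median(ll)) / max(stats::mad(ll), 1e-12)
      jp_bad <- jp_bad | (z < -params$jointprob_sd)
    }
  }
  mask <- !(amp_bad | jp_bad)
  attr(mask, "n_amplitude") <- sum(amp_bad)
  attr(mask, "n_jointprob") <- sum(jp_bad & !amp_bad)
  mask
}

#' Burst-correction hook (ASR stand-in)
#'
#' Contract of an artifact-subspace-reconstruction stage: calibrated on the
#' quiet-standing span, correcting bursts beyond `asr_cutoff` SD. The
#' algorithm itself is out of scope here; the default hook is the identity
#' and the pipeline relies on epoch/cycle rejection instead. Supply your own
#' function via `hook` to plug in a real implementation.
#'
#' @param rec [eeg_recording()].
#' @param params [preproc_params()].
#' @param hook function `(rec, calibration_span, cutoff) -> rec` or `NULL`.
#' @return [eeg_recording()].
#' @export
burst_correct_hook <- function(rec, params = preproc_params(), hook = NULL) {
  if (is.null(hook)) return(rec)
  span <- tryCatch(event_spans(rec$events, "standing"),
                   error = function(e) NULL)
  hook(rec, span, params$asr_cutoff)
}
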