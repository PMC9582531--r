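#' @title Signal-processing primitives
#' @description Small, dependency-free DSP helpers used across the package:
#'   linear detrending, a 2nd-order zero-phase Butterworth low-pass,
#'   windowed-sinc FIR filtering, and peak detection with a minimum-distance
#'   rule. These are deliberately minimal re-implementations of the standard
#'   tools (Butterworth bilinear design, forward-backward filtering, Hamming
#'   FIR design) because no DSP package is assumed at run time.
#' @name dsp
#' @keywords internal
NULL

#' Remove a least-squares linear trend from a signal
#'
#' @param x numeric vector.
#' @return detrended vector of the same length.
#' @keywords internal
detrend_linear <- function(x) {
  n <- length(x)
  if (n < 2L) return(x - mean(x))
  t <- seq_len(n)
  ct <- t - mean(t)
  beta <- sum(ct * x) / sum(ct * ct)
  x - mean(x) - beta * ct
}

#' Second-order Butterworth low-pass coefficients (bilinear transform)
#'
#' @param fc cut-off frequency (Hz).
#' @param fs sampling rate (Hz).
#' @return list with numerator `b` and denominator `a` (a[1] = 1).
#' @keywords internal
butter2_lowpass <- function(fc, fs) {
  stopifnot(fc > 0, fs > 0, fc < fs / 2)
  K <- tan(pi * fc / fs)
  norm <- 1 / (1 + sqrt(2) * K + K^2)
  b0 <- K^2 * norm
  list(b = c(b0, 2 * b0, b0),
       a = c(1, 2 * (K^2 - 1) * norm, (1 - sqrt(2) * K + K^2) * norm))
}

# One-pass IIR filtering (direct form), vectorised via stats::filter.
iir_filter <- function(b, a, x) {
  n <- length(x)
  # FIR part: full convolution truncated to n with leading zeros as history
  v <- stats::filter(c(rep(0, length(b) - 1L), x), b, method = "convolution",
                     sides = 1)
  v <- as.numeric(v)[length(b):(length(b) - 1L + n)]
  if (length(a) > 1L) {
    v <- as.numeric(stats::filter(v, -a[-1L], method = "recursive"))
  }
  v
}

#' Zero-phase (forward-backward) IIR filtering with reflective padding
#'
#' Applies the filter forwards and backwards so the net phase response is
#' zero and the effective magnitude response is squared (a 2nd-order design
#' acts as an effective 4th-order filter).
#'
#' @param b,a filter coefficients.
#' @param x numeric vector.
#' @param padlen number of odd-reflection padding samples at each edge.
#' @return filtered vector, same length as `x`.
#' @keywords internal
filtfilt2 <- function(b, a, x, padlen = NULL) {
  n <- length(x)
  if (is.null(padlen)) padlen <- min(n - 1L, max(9L, 3L * 25L))
  if (n <= padlen + 1L) stop("signal too short for zero-phase filtering")
  # odd reflection: 2*x[1] - x[p+1 .. 2]
  pre  <- 2 * x[1] - x[(padlen + 1L):2L]
  post <- 2 * x[n] - x[(n - 1L):(n - padlen)]
  y <- iir_filter(b, a, c(pre, x, post))
  y <- rev(iir_filter(b, a, rev(y)))
  y[(padlen + 1L):(padlen + n)]
}

#' Windowed-sinc (Hamming) FIR design
#'
#' Linear-phase type-I FIR. `low`/`high` are the band edges in Hz; pass
#' `low = 0` for a low-pass and `high = fs/2` for a high-pass.
#'
#' @param order even filter order (length = order + 1).
#' @param low,high band edges (Hz).
#' @param fs sampling rate (Hz).
#' @return numeric coefficient vector of length `order + 1`.
#' @keywords internal
fir_design <- function(order, low, high, fs) {
  if (order %% 2L != 0L) order <- order + 1L
  m <- seq(-order / 2, order / 2)
  sinc <- function(fc) {
    h <- 2 * fc / fs * sapply(m, function(k) {
      if (k == 0) 1 else sin(2 * pi * fc * k / fs) / (2 * pi * fc * k / fs)
    })
    h
  }
  h <- if (low <= 0) {
    sinc(high)                       # low-pass
  } else if (high >= fs / 2) {       # high-pass = delta - low-pass
    d <- as.numeric(m == 0)
    d - sinc(low)
  } else {                           # band-pass
    sinc(high) - sinc(low)
  }
  w <- 0.54 + 0.46 * cos(2 * pi * m / (order + 1))  # periodic-ish Hamming
  h * w
}

#' Zero-phase FIR filtering via FFT convolution
#'
#' Convolves with a symmetric (linear-phase) kernel and compensates the group
#' delay, yielding zero net phase. Edges are odd-reflection padded.
#'
#' @param h symmetric FIR kernel (odd length).
#' @param x numeric vector.
#' @return filtered vector, same length as `x`.
#' @keywords internal
fir_filtfilt <- function(h, x) {
  L <- length(h)
  half <- (L - 1L) %/% 2L
  n <- length(x)
  pad <- min(n - 1L, half)
  pre  <- 2 * x[1] - x[(pad + 1L):2L]
  post <- 2 * x[n] - x[(n - 1L):(n - pad)]
  xx <- c(pre, x, post)
  nn <- length(xx)
  nfft <- 2^ceiling(log2(nn + L))
  X <- stats::fft(c(xx, rep(0, nfft - nn)))
  H <- stats::fft(c(h, rep(0, nfft - L)))
  y <- Re(stats::fft(X * H, inverse = TRUE)) / nfft
  # linear-phase delay of `half` samples, plus `pad` leading pad samples
  y[(half + pad + 1L):(half + pad + n)]
}

#' Find local maxima with height and minimum-distance constraints
#'
#' Candidate peaks are strict local maxima; when two candidates lie closer
#' than `min_distance` samples the higher one wins (greedy by descending
#' height), matching common peak-finder semantics.
#'
#' @param x numeric vector.
#' @param height minimum peak height (values `<= height` are discarded when
#'   `strict = TRUE` is the default comparison `>`).
#' @param min_distance minimum separation in samples (0 = no constraint).
#' @return integer vector of 1-based peak sample indices, sorted ascending.
#' @keywords internal
find_peaks <- function(x, height = -Inf, min_distance = 0L) {
  n <- length(x)
  if (n < 3L) return(integer(0))
  core <- x[2:(n - 1L)]
  idx <- which(core > x[1:(n - 2L)] & core >= x[3:n]) + 1L
  idx <- idx[x[idx] > height]
  if (length(idx) <= 1L || min_distance <= 0L) return(idx)
  ord <- idx[order(x[idx], decreasing = TRUE)]
  keep <- logical(0)
  kept <- integer(0)
  for (i in ord) {
    if (!length(kept) || all(abs(kept - i) >= min_distance)) {
      kept <- c(kept, i)
    }
  }
  sort(kept)
}

# next power of two >= n
next_pow2 <- function(n) 2^ceiling(log2(max(n, 2)))

#' Zero-phase FIR filtering of a channel matrix (shared kernel FFT)
#'
#' Row-wise [fir_filtfilt()] with the kernel transformed once; much faster
#' than filtering channels independently.
#'
#' @param h symmetric FIR kernel (odd length).
#' @param X channels x samples matrix.
#' @return filtered matrix of the same shape.
#' @keywords internal
fir_filtfilt_mat <- function(h, X) {
  L <- length(h)
  half <- (L - 1L) %/% 2L
  n <- ncol(X)
  pad <- min(n - 1L, half)
  nn <- n + 2L * pad
  nfft <- next_pow2(nn + L)
  H <- stats::fft(c(h, rep(0, nfft - L)))
  out <- X
  for (i in seq_len(nrow(X))) {
    x <- X[i, ]
    xx <- c(2 * x[1] - x[(pad + 1L):2L], x, 2 * x[n] - x[(n - 1L):(n - pad)])
    Xf <- stats::fft(c(xx, rep(0, nfft - nn)))
    y <- Re(stats::fft(Xf * H, inverse = TRUE)) / nfft
    out[i, ] <- y[(half + pad + 1L):(half + pad + n)]
  }
  out
}
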