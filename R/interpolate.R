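#' @title Spherical-spline scalp interpolation
#' @description Perrin-style spherical splines on the unit sphere, used to
#'   interpolate bad channels and to predict a channel from its neighbours in
#'   bad-channel detection.
#' @name spline-interp
#' @keywords internal
NULL

# Legendre polynomials P_1..P_nmax evaluated at x (vector), as matrix
legendre_upto <- function(x, nmax) {
  out <- matrix(0, length(x), nmax)
  pm1 <- rep(1, length(x))   # P_0
  p <- x                     # P_1
  out[, 1] <- p
  if (nmax >= 2) {
    for (n in 2:nmax) {
      pn <- ((2 * n - 1) * x * p - (n - 1) * pm1) / n
      out[, n] <- pn
      pm1 <- p
      p <- pn
    }
  }
  out
}

# spline kernel g(cos angle) with stiffness m, nmax series terms
spline_g <- function(cosang, m = 4, nmax = 20) {
  cosang <- pmin(pmax(cosang, -1), 1)
  P <- legendre_upto(cosang, nmax)
  n <- seq_len(nmax)
  coef <- (2 * n + 1) / (n * (n + 1))^m
  matrix(P %*% coef / (4 * pi), nrow = length(cosang))
}

# interpolation operator mapping signals at `from` positions (k x 3) to
# `to` positions (q x 3); returns q x k matrix (rows sum to ~1)
spline_operator <- function(from, to, m = 4, nmax = 20, lambda = 1e-7) {
  k <- nrow(from)
  G <- matrix(spline_g(tcrossprod(from, from), m, nmax), k, k)
  G <- G + diag(lambda, k)
  A <- rbind(cbind(G, 1), c(rep(1, k), 0))
  Gto <- matrix(spline_g(tcrossprod(to, from), m, nmax), nrow(to), k)
  # weights W such that interp = W %*% x: solve A^T for the mapping
  sol <- solve(A, diag(k + 1))            # (k+1) x (k+1) inverse
  cbind(Gto, 1) %*% sol[, seq_len(k), drop = FALSE]
}

#' Interpolate bad channels by spherical splines
#'
#' Replaces each channel in `rec$bads` by a spherical-spline interpolation
#' (stiffness 4) of the good channels; the bad set is cleared and recorded in
#' the returned object's `provenance`.
#'
#' @param rec [eeg_recording()] with `bads` set.
#' @param m spline stiffness (default 4).
#' @param nmax number of Legendre series terms.
#' @return [eeg_recording()] with bad channels replaced.
#' @export
interpolate_bads <- function(rec, m = 4, nmax = 20) {
  if (!length(rec$bads)) return(rec)
  good <- !(rec$montage$label %in% rec$bads)
  if (sum(good) < 4) stop("fewer than 4 good channels: cannot interpolate")
  P <- as.matrix(rec$montage[, c("x", "y", "z")])
  W <- spline_operator(P[good, , drop = FALSE], P[!good, , drop = FALSE],
                       m = m, nmax = nmax)
  rec$data[!good, ] <- W %*% rec$data[good, , drop = FALSE]
  rec$provenance$interpolated <- rec$bads
  rec$bads <- character(0)
  rec
}
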