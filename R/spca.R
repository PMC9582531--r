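#' Fit a spectral PCA artifact model on a subject's average gait ERSP
#'
#' Muscle artifacts in walking EEG share one broadband spectral shape that
#' dominates the spectral variance of gait ERSPs. The model treats every
#' (channel, phase-bin) pair of the all-condition average ERSP as an
#' observation and the frequency bins as variables, mean-centres, and
#' decomposes with PCA. The component with the greatest eigenvalue is
#' rejected: the stored projector `W` maps a centred spectrum onto the span
#' of all remaining eigenvectors.
#'
#' @param ersp subject-level `gait_ersp` averaged over all cycles and
#'   conditions (dB).
#' @return object of class `spca_model`: `eigvec` (frequency x component,
#'   decreasing eigenvalue), `eigval`, `center` (per-frequency means),
#'   `W` (symmetric idempotent projector, frequency x frequency), `freqs`.
#' @export
fit_spca <- function(ersp) {
  stopifnot(inherits(ersp, "gait_ersp"), all(is.finite(ersp)))
  freqs <- attr(ersp, "freqs")
  nf <- length(freqs)
  if (nf < 2) stop("need >= 2 frequency bins for spectral PCA")
  X <- spectra_matrix(ersp)              # (channel*phase) x frequency
  mu <- colMeans(X)
  Xc <- sweep(X, 2, mu)
  S <- crossprod(Xc) / (nrow(Xc) - 1)
  e <- eigen(S, symmetric = TRUE)
  if (sum(e$values > max(e$values) * 1e-12) < 2) {
    stop("spectral covariance is rank-deficient (< 2 nonzero eigenvalues)")
  }
  V <- e$vectors
  W <- V[, -1, drop = FALSE] %*% t(V[, -1, drop = FALSE])
  structure(list(eigvec = V, eigval = e$values, center = mu, W = W,
                 freqs = freqs), class = "spca_model")
}

# unfold a gait_ersp into observations x frequencies
spectra_matrix <- function(ersp) {
  d <- dim(ersp)   # ch x freq x phase
  m <- matrix(aperm(unclass(ersp), c(1, 3, 2)), d[1] * d[3], d[2])
  m
}

# fold back
spectra_unfold <- function(X, template) {
  d <- dim(template)
  out <- aperm(array(X, c(d[1], d[3], d[2])), c(1, 3, 2))
  attributes(out) <- attributes(template)
  out
}

#' @export
print.spca_model <- function(x, ...) {
  cat(sprintf("<spca_model> %d frequencies; first component %.1f%% of variance\n",
              length(x$freqs), 100 * x$eigval[1] / sum(x$eigval)))
  invisible(x)
}

#' Apply a fitted spectral-PCA model to an ERSP
#'
#' Centres each observation's spectrum with the model means, projects with
#' `W` (removing the first spectral component) and restores the means. The
#' same model must be applied to the all-condition average and to every
#' condition-specific ERSP of that subject so the attenuation cannot
#' introduce condition-specific variance.
#'
#' @param model [fit_spca()] output.
#' @param ersp `gait_ersp` on the same frequency grid.
#' @param n_keep `NULL` to use the model projector (drop the first
#'   component); the number of leading components to keep otherwise
#'   (`n_keep = length(freqs)` reproduces the input).
#' @return cleaned `gait_ersp` of identical shape.
#' @export
apply_spca <- function(model, ersp, n_keep = NULL) {
  stopifnot(inherits(model, "spca_model"), inherits(ersp, "gait_ersp"))
  if (!isTRUE(all.equal(attr(ersp, "freqs"), model$freqs))) {
    stop("frequency grid of the ERSP does not match the fitted model")
  }
  W <- if (is.null(n_keep)) model$W else {
    V <- model$eigvec[, seq_len(n_keep), drop = FALSE]
    V %*% t(V)
  }
  X <- spectra_matrix(ersp)
  Xc <- sweep(X, 2, model$center)
  Y <- sweep(Xc %*% W, 2, model$center, `+`)
  spectra_unfold(Y, ersp)
}
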