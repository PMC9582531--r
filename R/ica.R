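#' @title ICA-based eye-artifact attenuation
#' @description A fixed-seed symmetric FastICA (tanh nonlinearity) with
#'   PCA whitening stands in for the adaptive-mixture ICA used on real
#'   recordings, and a documented topography-times-spectrum heuristic stands
#'   in for a trained component classifier. Both are swappable: any function
#'   returning an unmixing matrix, or any scorer returning per-component
#'   eye probabilities in [0, 1], can be passed in.
#' @name ica
NULL

# symmetric FastICA with tanh contrast on whitened data Z (k x n)
fastica_core <- function(Z, seed, max_iter = 200, tol = 1e-7,
                         max_restarts = 5) {
  k <- nrow(Z)
  n <- ncol(Z)
  set.seed(seed)
  sym_decor <- function(W) {
    e <- eigen(W %*% t(W), symmetric = TRUE)
    if (any(e$values < 1e-12)) return(NULL)   # degenerate iterate
    e$vectors %*% diag(1 / sqrt(e$values), k) %*% t(e$vectors) %*% W
  }
  for (restart in seq_len(max_restarts)) {
    W <- sym_decor(matrix(stats::rnorm(k * k), k, k))
    if (is.null(W)) next
    failed <- FALSE
    for (it in seq_len(max_iter)) {
      WX <- W %*% Z
      G <- tanh(WX)
      gprime <- rowMeans(1 - G^2)
      W1 <- sym_decor(G %*% t(Z) / n - diag(gprime, k) %*% W)
      if (is.null(W1)) {
        failed <- TRUE
        break
      }
      delta <- max(abs(abs(diag(W1 %*% t(W))) - 1))
      W <- W1
      if (delta < tol) {
        return(list(W = W, iterations = it, converged = TRUE))
      }
    }
    if (!failed) return(list(W = W, iterations = max_iter, converged = FALSE))
  }
  stop("ICA failed to produce a non-degenerate decomposition after ",
       max_restarts, " restarts")
}

#' Independent component decomposition of an EEG recording
#'
#' Fits ICA on a 1 Hz high-passed copy restricted to clean 1 s epochs
#' (amplitude and joint-probability rejection), then back-projects the
#' unmixing weights to the full original data. Whitening retains the
#' numerical rank (common-average-referenced data lose one dimension).
#'
#' @param rec [eeg_recording()] (the data the weights will be applied to).
#' @param params [preproc_params()].
#' @param seed integer seed for the ICA initialisation.
#' @return list of class `ic_decomposition`: `unmixing` (k x channels),
#'   `mixing` (channels x k), `sources` (k x samples, from `rec`),
#'   `kept_epochs`, `converged`.
#' @export
ica_decompose <- function(rec, params = preproc_params(), seed = 1L) {
  fs <- rec$srate
  hp <- fir_design(2L * round(3.3 / 1 * fs / 2), 1, fs / 2, fs)
  Xh <- t(apply(rec$data, 1, function(x) fir_filtfilt(hp, x)))
  rech <- rec
  rech$data <- Xh
  mask <- reject_artifact_epochs(rech, 1, params)
  L <- round(fs)
  keep_idx <- unlist(lapply(which(mask), function(e) {
    ((e - 1L) * L + 1L):(e * L)
  }))
  if (length(keep_idx) < 10L * nrow(rec$data)) {
    stop("too little clean data to fit ICA (", length(keep_idx), " samples)")
  }
  Xf <- Xh[, keep_idx, drop = FALSE]
  Xf <- Xf - rowMeans(Xf)
  C <- tcrossprod(Xf) / ncol(Xf)
  e <- eigen(C, symmetric = TRUE)
  rank <- sum(e$values > max(e$values) * 1e-9)
  K <- diag(1 / sqrt(e$values[seq_len(rank)]), rank) %*%
    t(e$vectors[, seq_len(rank), drop = FALSE])
  fit <- fastica_core(K %*% Xf, seed = seed)
  if (!fit$converged) {
    warning("FastICA did not fully converge after ", fit$iterations,
            " iterations; using last iterate")
  }
  U <- fit$W %*% K                                     # k x nchan unmixing
  A <- e$vectors[, seq_len(rank), drop = FALSE] %*%
    diag(sqrt(e$values[seq_len(rank)]), rank) %*% t(fit$W)  # mixing
  S <- U %*% rec$data                                  # sources on full data
  structure(list(unmixing = U, mixing = A, sources = S,
                 kept_epochs = mask, converged = fit$converged),
            class = "ic_decomposition")
}

#' Heuristic eye-likeness score for independent components
#'
#' Product of a topography term and a spectral term, each calibrated to
#' [0, 1]: the topography term is the frontal concentration of the mixing
#' weights -- the share of squared weight on the frontal set divided by its
#' share under a uniform topography, rescaled by `topo_calib` and clipped at
#' 1 (ocular topographies concentrate several-fold above uniform); the
#' spectral term is the fraction of source power below `lowfreq_hz`,
#' rescaled by `calib` and clipped at 1 (ocular sources are almost entirely
#' sub-3 Hz, background EEG is not). A stereotyped blink component scores
#' near 1, oscillatory or broadband components score far below the 0.90
#' removal threshold.
#'
#' @param decomp [ica_decompose()] output.
#' @param montage montage of the decomposed recording.
#' @param srate sampling rate (Hz).
#' @param lowfreq_hz boundary of the "low frequency" band (Hz).
#' @param calib spectral calibration constant.
#' @param topo_calib frontal-concentration calibration constant.
#' @return numeric vector of scores in [0, 1], one per component.
#' @export
eye_score <- function(decomp, montage, srate, lowfreq_hz = 3, calib = 0.5,
                      topo_calib = 3) {
  sets <- channel_sets(montage)
  fr <- montage$label %in% sets$frontal
  if (!any(fr)) stop("montage has no frontal channels for eye scoring")
  vapply(seq_len(ncol(decomp$mixing)), function(j) {
    a2 <- decomp$mixing[, j]^2
    conc <- (sum(a2[fr]) / sum(a2)) / (sum(fr) / length(a2))
    topo <- min(1, conc / topo_calib)
    s <- decomp$sources[j, ]
    lf <- band_power(s, srate, 0, lowfreq_hz) /
      max(band_power(s, srate, 0, srate / 2), 1e-300)
    spec <- min(1, lf / calib)
    topo * spec
  }, numeric(1))
}

#' Remove eye components from a recording
#'
#' Fits (or reuses) an IC decomposition, scores components for eye-likeness
#' and reconstructs the recording from the retained sources only:
#' `X_clean = mixing[, keep] %*% sources[keep, ]`.
#'
#' @param rec [eeg_recording()].
#' @param params [preproc_params()] (`eye_prob` is the removal threshold).
#' @param seed ICA seed.
#' @param decomp optional precomputed [ica_decompose()] result.
#' @param scorer scoring function with the signature of [eye_score()].
#' @return list: `rec` (cleaned recording), `decomp`, `scores`,
#'   `removed` (component indices).
#' @export
ica_eye_removal <- function(rec, params = preproc_params(), seed = 1L,
                            decomp = NULL, scorer = eye_score) {
  if (is.null(decomp)) decomp <- ica_decompose(rec, params, seed)
  scores <- scorer(decomp, rec$montage, rec$srate)
  removed <- which(scores > params$eye_prob)
  out <- rec
  if (length(removed)) {
    # subtract the removed back-projections; keeps any rank-deficient
    # residual the decomposition did not span
    out$data <- rec$data - decomp$mixing[, removed, drop = FALSE] %*%
      decomp$sources[removed, , drop = FALSE]
    rownames(out$data) <- rec$montage$label
  }
  out$provenance$removed_ics <- removed
  out$provenance$n_ics_kept <- nrow(decomp$sources) - length(removed)
  list(rec = out, decomp = decomp, scores = scores, removed = removed)
}
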