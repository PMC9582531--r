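#' Gait-phase bins in double vs single support
#'
#' Derives the double-support phase bins from a recording's own average
#' event timing: initial double support spans RHS to the mean left toe-off
#' fraction, the second spans the mean left heel-strike to right toe-off
#' fraction; all remaining bins are single support.
#'
#' @param cycles [assemble_gait_cycles()] output (valid cycles used).
#' @param phase_bins number of phase bins.
#' @return list with integer bin vectors `double` and `single` (1-based).
#' @export
support_phase_bins <- function(cycles, phase_bins = 100) {
  v <- cycles[cycles$valid, ]
  if (!nrow(v)) stop("no valid cycles to derive support phases from")
  frac <- function(x) mean((x - v$rhs) / (v$rhs_next - v$rhs))
  lto <- frac(v$lto); lhs <- frac(v$lhs); rto <- frac(v$rto)
  bins <- seq_len(phase_bins)
  ph <- (bins - 1) / phase_bins
  dbl <- bins[(ph < lto) | (ph >= lhs & ph < rto)]
  list(double = dbl, single = setdiff(bins, dbl),
       fractions = c(lto = lto, lhs = lhs, rto = rto))
}

#' Five-feature gait-artifact footprint of an ERSP/GPM pair
#'
#' Quantifies residual gait-related artifact, each feature oriented so that
#' larger means more artifact:
#' \describe{
#'   \item{B}{explained-variance fraction of the first spectral principal
#'     component of the ERSP (broadband artifacts concentrate variance).}
#'   \item{C}{mean positive-dB ERSP over the lateral channel set divided by
#'     the medial set (power decreases are discarded: gait artifacts raise
#'     power above the standing baseline, neural alpha/beta lower it).}
#'   \item{D}{mean positive-dB ERSP over the neck set divided by all
#'     non-neck scalp channels.}
#'   \item{E}{mean |GPM| during double-support bins divided by
#'     single-support bins.}
#'   \item{F}{mean linear walking/standing power ratio, `mean(10^(ERSP/10))`.}
#' }
#' When the ERSP carries no positive power at all, C and D are guarded to
#' the neutral ratio 1.
#'
#' @param ersp subject `gait_ersp` (dB vs standing).
#' @param gpm matching GPM map.
#' @param support list from [support_phase_bins()].
#' @param sets channel sets from [channel_sets()].
#' @return object of class `footprint_vector`: named numeric
#'   (B, C, D, E, F) with the channel sets recorded as an attribute.
#' @export
compute_footprint <- function(ersp, gpm, support, sets) {
  labels <- attr(ersp, "labels")
  need <- c("lateral", "medial", "neck")
  for (s in need) {
    if (!length(intersect(sets[[s]], labels))) {
      stop("empty or unmatched channel set: ", s)
    }
  }
  rows <- function(set) which(labels %in% set)
  pos <- pmax(unclass(ersp), 0)
  B <- {
    m <- fit_spca(ersp)
    m$eigval[1] / sum(m$eigval)
  }
  ratio_guarded <- function(num, den) {
    if (num == 0 && den == 0) return(1)
    if (den == 0) stop("zero denominator in footprint ratio")
    num / den
  }
  C <- ratio_guarded(mean(pos[rows(sets$lateral), , ]),
                     mean(pos[rows(sets$medial), , ]))
  D <- ratio_guarded(mean(pos[rows(sets$neck), , ]),
                     mean(pos[setdiff(seq_along(labels), rows(sets$neck)), , ]))
  ag <- abs(unclass(gpm))
  E <- ratio_guarded(mean(ag[, , support$double]),
                     mean(ag[, , support$single]))
  F_ <- mean(10^(unclass(ersp) / 10))
  structure(c(B = B, C = C, D = D, E = E, F = F_),
            sets = sets, scaled = FALSE, class = "footprint_vector")
}

#' Min-max scale footprint vectors across a cohort
#'
#' Scales each feature to [0, 1] over all supplied vectors (both cleaning
#' states pooled) so the Euclidean distance weighs features comparably.
#' Constant features are mapped to 0.
#'
#' @param fps list of [compute_footprint()] vectors.
#' @return list of scaled `footprint_vector`s carrying the common scaling
#'   as an attribute.
#' @export
scale_footprints <- function(fps) {
  M <- do.call(rbind, lapply(fps, unclass))
  lo <- apply(M, 2, min)
  rg <- apply(M, 2, max) - lo
  rg[rg <= 0] <- 1
  lapply(fps, function(f) {
    structure((unclass(f) - lo) / rg, sets = attr(f, "sets"),
              scaled = TRUE, scaling = list(lo = lo, range = rg),
              class = "footprint_vector")
  })
}

#' Euclidean distance between two footprint vectors
#'
#' @param before,after `footprint_vector`s under the same scaling.
#' @return non-negative scalar.
#' @export
footprint_distance <- function(before, after) {
  if (!identical(attr(before, "scaled"), attr(after, "scaled")) ||
      !isTRUE(all.equal(attr(before, "scaling"), attr(after, "scaling")))) {
    stop("footprint vectors were scaled differently; rescale jointly")
  }
  if (!identical(names(before), names(after))) {
    stop("feature sets differ")
  }
  sqrt(sum((unclass(before) - unclass(after))^2))
}

#' @export
print.footprint_vector <- function(x, ...) {
  cat("<footprint_vector>",
      if (isTRUE(attr(x, "scaled"))) "(scaled)" else "(raw)", "\n")
  print(round(unclass(x), 4))
  invisible(x)
}
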