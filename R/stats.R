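#' Parameters for cluster-based permutation statistics
#'
#' @param n_perm number of sign-flip permutations (>= 100).
#' @param alpha cluster-forming alpha (two-tailed paired t).
#' @param seed permutation seed.
#' @param circular treat the phase axis as circular (wrap 0%/100%)?
#'   Default `FALSE`, matching standard implementations.
#' @return object of class `stats_params`.
#' @export
stats_params <- function(n_perm = 1000, alpha = 0.05, seed = 1L,
                         circular = FALSE) {
  stopifnot(n_perm >= 100, alpha > 0, alpha < 1)
  structure(list(n_perm = as.integer(n_perm), alpha = alpha,
                 seed = as.integer(seed), circular = circular),
            class = "stats_params")
}

#' Per-subject condition maps for one within-subject effect
#'
#' Reduces the four condition maps of a 2x2 design to the paired maps a
#' dependent-samples test compares: for the terrain main effect, each
#' subject's task-average on even vs uneven terrain; for the task effect,
#' the terrain-averages of ST vs DT; for the interaction, the task contrast
#' on even vs uneven terrain (so the paired difference is the difference of
#' differences).
#'
#' @param maps list (one element per subject) of named lists holding a
#'   numeric matrix (frequency x phase) per condition of
#'   [condition_grid()].
#' @param effect `"terrain"`, `"task"` or `"interaction"`.
#' @return list with 3-D arrays `a` and `b` (subject x frequency x phase).
#' @export
effect_maps <- function(maps, effect = c("terrain", "task", "interaction")) {
  effect <- match.arg(effect)
  conds <- condition_grid()
  for (s in seq_along(maps)) {
    if (!all(conds %in% names(maps[[s]]))) {
      stop("subject ", s, " is missing conditions: ",
           paste(setdiff(conds, names(maps[[s]])), collapse = ", "))
    }
  }
  d <- dim(maps[[1]][[conds[1]]])
  n <- length(maps)
  pick <- function(f) {
    out <- array(NA_real_, c(n, d[1], d[2]))
    for (s in seq_len(n)) out[s, , ] <- f(maps[[s]])
    out
  }
  switch(effect,
    terrain = list(
      a = pick(function(m) (m$even_ST + m$even_DT) / 2),
      b = pick(function(m) (m$uneven_ST + m$uneven_DT) / 2)),
    task = list(
      a = pick(function(m) (m$even_ST + m$uneven_ST) / 2),
      b = pick(function(m) (m$even_DT + m$uneven_DT) / 2)),
    interaction = list(
      a = pick(function(m) m$even_ST - m$even_DT),
      b = pick(function(m) m$uneven_ST - m$uneven_DT))
  )
}

# 4-connected components of a logical matrix, split by the sign matrix
label_components <- function(mask, sgn, circular = FALSE) {
  nr <- nrow(mask); nc <- ncol(mask)
  lab <- matrix(0L, nr, nc)
  cur <- 0L
  clusters <- list()
  for (start in which(mask)) {
    if (lab[start] > 0L) next
    cur <- cur + 1L
    queue <- start
    lab[start] <- cur
    members <- start
    while (length(queue)) {
      j <- queue[[1L]]
      queue <- queue[-1L]
      r <- (j - 1L) %% nr + 1L
      cc <- (j - 1L) %/% nr + 1L
      nb <- integer(0)
      if (r > 1L) nb <- c(nb, j - 1L)
      if (r < nr) nb <- c(nb, j + 1L)
      if (cc > 1L) nb <- c(nb, j - nr)
      if (cc < nc) nb <- c(nb, j + nr)
      if (circular) {
        if (cc == 1L) nb <- c(nb, j + nr * (nc - 1L))
        if (cc == nc) nb <- c(nb, j - nr * (nc - 1L))
      }
      nb <- nb[mask[nb] & lab[nb] == 0L & sgn[nb] == sgn[j]]
      lab[nb] <- cur
      queue <- c(queue, nb)
      members <- c(members, nb)
    }
    clusters[[cur]] <- members
  }
  clusters
}

# paired t per bin for sign-flipped differences; D is n x bins, s is length n
t_stats_flipped <- function(D, sumsq, s) {
  n <- nrow(D)
  m <- as.numeric(s %*% D) / n
  v <- (sumsq / n - m^2) * n / (n - 1)
  m / sqrt(pmax(v, 1e-300) / n)
}

#' Cluster-based dependent-samples permutation test
#'
#' Bin-wise paired t-tests over subjects; bins exceeding the two-tailed
#' t-criterion form 4-connected clusters of common sign in the
#' frequency-by-phase plane; the cluster statistic is the summed t (cluster
#' mass). The null distribution is the maximum absolute cluster mass over
#' random per-subject sign flips of the paired differences, and
#' `p = (1 + #{null >= observed}) / (n_perm + 1)`.
#'
#' @param pairs list with arrays `a`, `b` (subject x frequency x phase),
#'   e.g. from [effect_maps()].
#' @param params [stats_params()].
#' @return object of class `cluster_result`: `t_map`, `clusters` (list of
#'   bin-index vectors), `mass`, `p`, `masks` (logical freq x phase per
#'   cluster), `t_crit`, `null_max` (permutation distribution).
#' @export
cluster_permutation_test <- function(pairs, params = stats_params()) {
  stopifnot(identical(dim(pairs$a), dim(pairs$b)))
  n <- dim(pairs$a)[1]
  if (n < 6) stop("cluster permutation test needs >= 6 subjects")
  nf <- dim(pairs$a)[2]; np <- dim(pairs$a)[3]
  D <- matrix(pairs$a - pairs$b, n, nf * np)
  sumsq <- colSums(D^2)
  t_crit <- stats::qt(1 - params$alpha / 2, n - 1)
  t_obs <- t_stats_flipped(D, sumsq, rep(1, n))
  t_map <- matrix(t_obs, nf, np)
  mask <- abs(t_map) > t_crit
  sgn <- sign(t_map)
  clusters <- label_components(mask, sgn, params$circular)
  mass <- vapply(clusters, function(ix) sum(t_map[ix]), numeric(1))
  set.seed(params$seed)
  flips <- matrix(sample(c(-1, 1), params$n_perm * n, replace = TRUE),
                  params$n_perm, n)
  null_max <- vapply(seq_len(params$n_perm), function(pi) {
    tp <- t_stats_flipped(D, sumsq, flips[pi, ])
    tm <- matrix(tp, nf, np)
    mk <- abs(tm) > t_crit
    if (!any(mk)) return(0)
    cl <- label_components(mk, sign(tm), params$circular)
    max(abs(vapply(cl, function(ix) sum(tm[ix]), numeric(1))))
  }, numeric(1))
  p <- vapply(mass, function(m) {
    (1 + sum(null_max >= abs(m))) / (params$n_perm + 1)
  }, numeric(1))
  ord <- order(abs(mass), decreasing = TRUE)
  masks <- lapply(clusters, function(ix) {
    m <- matrix(FALSE, nf, np); m[ix] <- TRUE; m
  })
  structure(list(t_map = t_map, clusters = clusters[ord],
                 mass = mass[ord], p = p[ord], masks = masks[ord],
                 t_crit = t_crit, null_max = null_max, n = n),
            class = "cluster_result")
}

#' @export
print.cluster_result <- function(x, ...) {
  cat(sprintf("<cluster_result> n = %d, %d cluster(s)\n", x$n,
              length(x$clusters)))
  if (length(x$clusters)) {
    for (k in seq_along(x$clusters)) {
      cat(sprintf("  #%d: %d bins, mass %.1f, p = %.4f\n", k,
                  length(x$clusters[[k]]), x$mass[k], x$p[k]))
    }
  }
  invisible(x)
}

#' Paired Cohen's d of a cluster
#'
#' Averages the paired condition differences over the cluster bins per
#' subject, then computes the paired-samples d (mean over SD of these
#' per-subject means).
#'
#' @param pairs list with arrays `a`, `b` as in [cluster_permutation_test()].
#' @param mask logical frequency x phase cluster mask.
#' @return object of class `effect_size` (kind `"cohens_dz"`); `value` is
#'   `Inf` (flagged `degenerate`) when the per-subject means have zero SD.
#' @export
cluster_effect_size <- function(pairs, mask) {
  if (!any(mask)) stop("empty cluster mask")
  n <- dim(pairs$a)[1]
  D <- matrix(pairs$a - pairs$b, n, length(mask))
  subj_means <- rowMeans(D[, as.vector(mask), drop = FALSE])
  s <- stats::sd(subj_means)
  degenerate <- !is.finite(s) || s == 0
  val <- if (degenerate) sign(mean(subj_means)) * Inf
         else mean(subj_means) / s
  structure(list(kind = "cohens_dz", value = val, n = n,
                 degenerate = degenerate, subject_means = subj_means),
            class = "effect_size")
}

#' @export
print.effect_size <- function(x, ...) {
  cat(sprintf("<effect_size> %s = %.3f (n = %d)%s\n", x$kind, x$value, x$n,
              if (isTRUE(x$degenerate)) " [degenerate]" else ""))
  invisible(x)
}

#' 2x2 repeated-measures ANOVA via within-subject contrasts
#'
#' For a complete 2x2 within-subject design each effect is a paired t-test
#' on the corresponding contrast: `F = t^2` with df (1, n-1) and partial eta
#' squared `F / (F + n - 1)`.
#'
#' @param values numeric matrix, subjects x 4, columns named as
#'   [condition_grid()].
#' @return data.frame with rows terrain, task, interaction and columns
#'   `F`, `df1`, `df2`, `p`, `pes` (partial eta squared).
#' @export
rm_anova_2x2 <- function(values) {
  values <- as.matrix(values)
  conds <- condition_grid()
  if (!all(conds %in% colnames(values)) || anyNA(values)) {
    stop("incomplete design: need all four conditions for every subject")
  }
  n <- nrow(values)
  if (n < 3) stop("need >= 3 subjects")
  v <- values[, conds]
  contrasts <- list(
    terrain = (v[, "even_ST"] + v[, "even_DT"]) / 2 -
      (v[, "uneven_ST"] + v[, "uneven_DT"]) / 2,
    task = (v[, "even_ST"] + v[, "uneven_ST"]) / 2 -
      (v[, "even_DT"] + v[, "uneven_DT"]) / 2,
    interaction = (v[, "even_ST"] - v[, "even_DT"]) -
      (v[, "uneven_ST"] - v[, "uneven_DT"]))
  out <- do.call(rbind, lapply(names(contrasts), function(nm) {
    d <- contrasts[[nm]]
    s <- stats::sd(d)
    t <- if (s == 0) 0 else mean(d) / (s / sqrt(n))
    F <- t^2
    data.frame(effect = nm, F = F, df1 = 1, df2 = n - 1,
               p = stats::pf(F, 1, n - 1, lower.tail = FALSE),
               pes = F / (F + n - 1))
  }))
  rownames(out) <- out$effect
  out
}

#' Paired-samples Cohen's d (dz)
#'
#' `d = mean(x - y) / SD(x - y)` with the sample SD; equals the paired t
#' statistic divided by sqrt(n).
#'
#' @param x,y paired numeric vectors.
#' @return object of class `effect_size`; zero-SD differences yield a
#'   flagged infinite value.
#' @export
cohens_d_paired <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 2)
  d <- x - y
  s <- stats::sd(d)
  degenerate <- s == 0
  val <- if (degenerate) {
    if (mean(d) == 0) 0 else sign(mean(d)) * Inf
  } else mean(d) / s
  structure(list(kind = "cohens_dz", value = val, n = length(x),
                 degenerate = degenerate), class = "effect_size")
}

#' Wilcoxon signed-rank test with matched rank-biserial correlation
#'
#' Zero differences are discarded; ties receive average ranks. `T` is the
#' sum of ranks of positive differences. The p-value is exact (signed-rank
#' distribution) for n <= 25 without ties, otherwise a normal approximation
#' with tie correction. `R` is the matched rank-biserial correlation,
#' `(T+ - T-) / (T+ + T-)`.
#'
#' @param x,y paired numeric vectors.
#' @return list of class `wilcoxon_result`: `T`, `p`, `R`, `n_effective`.
#' @export
wilcoxon_signed_rank <- function(x, y) {
  stopifnot(length(x) == length(y))
  d <- x - y
  d <- d[d != 0]
  n <- length(d)
  if (n == 0) stop("all paired differences are zero")
  r <- rank(abs(d))
  Tpos <- sum(r[d > 0])
  Tneg <- sum(r[d < 0])
  Tstat <- Tpos
  R <- (Tpos - Tneg) / (Tpos + Tneg)
  has_ties <- anyDuplicated(abs(d)) > 0
  if (n <= 25 && !has_ties) {
    p_lo <- stats::psignrank(Tstat, n)
    p_hi <- stats::psignrank(Tstat - 1, n, lower.tail = FALSE)
    p <- min(1, 2 * min(p_lo, p_hi))
  } else {
    mu <- n * (n + 1) / 4
    tie_tab <- table(r)
    sigma2 <- n * (n + 1) * (2 * n + 1) / 24 -
      sum(tie_tab^3 - tie_tab) / 48
    z <- (Tstat - mu) / sqrt(sigma2)
    p <- 2 * stats::pnorm(-abs(z))
  }
  structure(list(T = Tstat, p = p, R = R, n_effective = n),
            class = "wilcoxon_result")
}

#' @export
print.wilcoxon_result <- function(x, ...) {
  cat(sprintf("<wilcoxon> T = %.1f, p = %.4g, R = %.3f (n = %d)\n",
              x$T, x$p, x$R, x$n_effective))
  invisible(x)
}

#' Bonferroni-Holm step-down correction
#'
#' @param p vector of p-values in [0, 1].
#' @return adjusted p-values in the original order (monotone, capped at 1).
#' @export
holm_correction <- function(p) {
  stopifnot(all(p >= 0 & p <= 1))
  m <- length(p)
  if (m <= 1) return(p)
  o <- order(p)
  adj <- pmin(1, (m - seq_len(m) + 1) * p[o])
  adj <- cummax(adj)
  out <- numeric(m)
  out[o] <- adj
  out
}
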