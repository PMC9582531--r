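test_that("effect_maps reduces the 2x2 design correctly", {
  nf <- 4; np <- 6
  base <- matrix(1, nf, np)
  # identical maps: all paired differences zero
  maps <- lapply(1:3, function(s) {
    out <- lapply(condition_grid(), function(cc) base)
    names(out) <- condition_grid()
    out
  })
  for (eff in c("terrain", "task", "interaction")) {
    pr <- effect_maps(maps, eff)
    expect_lt(max(abs(pr$a - pr$b)), 1e-12)
  }
  # additive construction (terrain + task, no cross term): interaction zero
  A <- matrix(2, nf, np); B <- matrix(-1, nf, np)
  maps2 <- lapply(1:3, function(s) {
    list(even_ST = base, even_DT = base + B,
         uneven_ST = base + A, uneven_DT = base + A + B)
  })
  pri <- effect_maps(maps2, "interaction")
  expect_lt(max(abs(pri$a - pri$b)), 1e-12)
  prt <- effect_maps(maps2, "terrain")
  expect_equal(as.numeric(prt$a[1, , ] - prt$b[1, , ]),
               as.numeric(-A), tolerance = 1e-12)
  # pure interaction (+c on matched cells): mains zero, interaction 2c
  cst <- 0.7
  maps3 <- lapply(1:3, function(s) {
    list(even_ST = base + cst, even_DT = base - cst,
         uneven_ST = base - cst, uneven_DT = base + cst)
  })
  for (eff in c("terrain", "task")) {
    pr <- effect_maps(maps3, eff)
    expect_lt(max(abs(pr$a - pr$b)), 1e-12)
  }
  pr3 <- effect_maps(maps3, "interaction")
  expect_equal(as.numeric(pr3$a[1, , ] - pr3$b[1, , ]),
               rep(4 * cst, nf * np), tolerance = 1e-12)
  maps_bad <- maps
  maps_bad[[2]]$uneven_DT <- NULL
  expect_error(effect_maps(maps_bad, "terrain"), "missing")
})

test_that("cluster permutation test: nulls, validity, and recovery", {
  params <- stats_params(n_perm = 300, seed = 4)
  # identical pairs: no suprathreshold bins at all
  same <- synth_condition_maps(8, nf = 5, np = 8, sd = 1, seed = 2)
  pr <- effect_maps(same, "terrain")
  pr$b <- pr$a
  res <- cluster_permutation_test(pr, params)
  expect_length(res$clusters, 0)
  expect_error(cluster_permutation_test(
    list(a = pr$a[1:3, , , drop = FALSE], b = pr$b[1:3, , , drop = FALSE]),
    params), ">= 6")
  # injected localized effect at n = 19, d ~ 1.5: recovered with overlap
  hits <- 0
  reps <- 6
  for (r in seq_len(reps)) {
    eff <- function(cond, s) {
      m <- matrix(0, 10, 20)
      if (grepl("uneven", cond)) m[4:7, 3:8] <- -1.5
      m + stats::rnorm(1, 0, 0.6)   # subject-level noise shared across bins
    }
    maps <- synth_condition_maps(19, nf = 10, np = 20, sd = 1,
                                 effect = eff, seed = 100 + r)
    pr <- effect_maps(maps, "terrain")
    res <- cluster_permutation_test(pr, stats_params(n_perm = 300,
                                                     seed = r))
    sig <- which(res$p < 0.05)
    if (length(sig)) {
      mask <- res$masks[[sig[1]]]
      inj <- matrix(FALSE, 10, 20); inj[4:7, 3:8] <- TRUE
      if (sum(mask & inj) / sum(inj) >= 0.5) hits <- hits + 1
    }
  }
  expect_gte(hits, reps - 1)
  # p-values live on the permutation grid
  expect_true(all(res$p >= 1 / (300 + 1) & res$p <= 1))
})

test_that("cluster effect size matches the t/sqrt(n) identity", {
  set.seed(5)
  n <- 12
  pr <- list(a = array(stats::rnorm(n * 4 * 5), c(n, 4, 5)),
             b = array(stats::rnorm(n * 4 * 5), c(n, 4, 5)))
  mask <- matrix(FALSE, 4, 5); mask[2:3, 2:4] <- TRUE
  es <- cluster_effect_size(pr, mask)
  D <- matrix(pr$a - pr$b, n, 20)
  sm <- rowMeans(D[, as.vector(mask)])
  tt <- t.test(sm)$statistic
  expect_equal(es$value, unname(tt) / sqrt(n), tolerance = 1e-12)
  # degenerate SD flagged; [1, -1] gives 0
  pr2 <- pr
  pr2$a <- array(1, dim(pr$a)); pr2$b <- array(0, dim(pr$b))
  es2 <- cluster_effect_size(pr2, mask)
  expect_true(es2$degenerate)
  expect_true(is.infinite(es2$value))
  pr3 <- list(a = array(c(1, -1), c(2, 4, 5)), b = array(0, c(2, 4, 5)))
  expect_equal(cluster_effect_size(pr3, mask)$value, 0)
  expect_error(cluster_effect_size(pr, matrix(FALSE, 4, 5)), "empty")
})

test_that("rm_anova_2x2 equals the brute-force within-subject ANOVA", {
  set.seed(6)
  n <- 10
  vals <- matrix(stats::rnorm(n * 4, 10, 2), n, 4,
                 dimnames = list(NULL, condition_grid()))
  out <- rm_anova_2x2(vals)
  # oracle: full aov() error-stratum decomposition
  long <- data.frame(
    y = as.numeric(vals),
    subject = factor(rep(seq_len(n), 4)),
    terrain = factor(rep(c("even", "even", "uneven", "uneven"), each = n)),
    task = factor(rep(c("ST", "DT", "ST", "DT"), each = n)))
  fit <- summary(stats::aov(y ~ terrain * task +
                              Error(subject / (terrain * task)),
                            data = long))
  oracle_F <- c(
    terrain = fit[["Error: subject:terrain"]][[1]]["terrain", "F value"],
    task = fit[["Error: subject:task"]][[1]]["task", "F value"],
    interaction = fit[["Error: subject:terrain:task"]][[1]][
      "terrain:task", "F value"])
  expect_equal(unname(out$F), unname(oracle_F), tolerance = 1e-9)
  expect_equal(out$pes, out$F / (out$F + n - 1), tolerance = 1e-12)
  # identical conditions: F = 0 everywhere
  flat <- matrix(5, n, 4, dimnames = list(NULL, condition_grid()))
  expect_true(all(rm_anova_2x2(flat)$F == 0))
  # per-subject constants cancel
  shifted <- vals + stats::rnorm(n, 0, 5)
  out2 <- rm_anova_2x2(shifted)
  expect_equal(out2$F, out$F, tolerance = 1e-9)
  expect_error(rm_anova_2x2(vals[, 1:3]), "incomplete")
})

test_that("cohens_d_paired: definition, identity with t, degenerate flag", {
  set.seed(7)
  x <- stats::rnorm(19, 1, 1); y <- stats::rnorm(19, 0, 1)
  d <- cohens_d_paired(x, y)
  tt <- t.test(x, y, paired = TRUE)$statistic
  expect_equal(d$value * sqrt(19), unname(tt), tolerance = 1e-12)
  expect_equal(cohens_d_paired(x, x)$value, 0)
  dd <- cohens_d_paired(c(2, 2, 2, 2), c(1, 1, 1, 1))
  expect_true(dd$degenerate)
  # the paper-scale check: F = 102.15 at n = 19 implies |d| ~ 2.32
  expect_equal(sqrt(102.15) / sqrt(19), 2.32, tolerance = 0.01)
})

test_that("wilcoxon signed-rank: printed cases, closed form, symmetry", {
  # n = 19, all positive: T = 190, R = 1
  x <- seq_len(19) + 0.5
  w <- wilcoxon_signed_rank(x, rep(0, 19))
  expect_equal(w$T, 190)
  expect_equal(w$R, 1)
  expect_lt(w$p, 0.001)
  # 18 positive + 1 zero: zero discarded, T = 171
  x2 <- c(0, seq_len(18) + 0.25)
  w2 <- wilcoxon_signed_rank(x2, rep(0, 19))
  expect_equal(w2$T, 171)
  expect_equal(w2$R, 1)
  expect_equal(w2$n_effective, 18)
  expect_lt(w2$p, 0.001)
  # closed form for all-positive differences, n <= 30
  for (n in c(2, 5, 13, 25, 30)) {
    wn <- wilcoxon_signed_rank(seq_len(n) * 1.1, rep(0, n))
    expect_equal(wn$T, n * (n + 1) / 2)
  }
  # mirrored differences: R = 0
  wm <- wilcoxon_signed_rank(c(1, -1, 2, -2, 3, -3), rep(0, 6))
  expect_equal(wm$R, 0)
  # exact p agrees with the reference implementation when tie-free
  set.seed(8)
  a <- stats::rnorm(12); b <- stats::rnorm(12)
  ours <- wilcoxon_signed_rank(a, b)
  ref <- stats::wilcox.test(a, b, paired = TRUE, exact = TRUE)
  expect_equal(ours$p, ref$p.value, tolerance = 1e-12)
  expect_error(wilcoxon_signed_rank(c(1, 2), c(1, 2)), "zero")
})

test_that("Holm correction: hand-stepped example and dominance bounds", {
  expect_equal(holm_correction(c(0.01, 0.04, 0.03)), c(0.03, 0.06, 0.06))
  expect_equal(holm_correction(0.2), 0.2)
  expect_equal(holm_correction(rep(1, 4)), rep(1, 4))
  set.seed(9)
  p <- stats::runif(20)
  h <- holm_correction(p)
  expect_true(all(h >= p))
  expect_true(all(h <= pmin(1, length(p) * p)))
  expect_equal(h, stats::p.adjust(p, "holm"), tolerance = 1e-12)
})
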