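# Independent brute-force oracles used across the suite. These deliberately
# avoid the package's internal kernels: correlations go through stats::cor,
# subset optima through exhaustive enumeration.

oracle_ncc <- function(a, b, lag) {
  n <- length(a); m <- length(b)
  ia <- intersect(seq_len(n), seq_len(m) + lag)
  if (length(ia) < 2) return(NA_real_)
  x <- a[ia]; y <- b[ia - lag]
  if (stats::sd(x) == 0 || stats::sd(y) == 0) return(0)
  stats::cor(x, y)
}

oracle_max_ncc <- function(a, b, max_lag) {
  lags <- -max_lag:max_lag
  scores <- vapply(lags, function(l) oracle_ncc(a, b, l), 0)
  best <- max(scores)
  cand <- lags[scores == best]
  cand <- cand[order(abs(cand), cand)]
  list(score = best, lag = cand[1])
}

# exhaustive best subset of non-overlapping windows: maximize coverage,
# then minimize ambiguity sum, then earliest-window (lexicographic starts)
oracle_consolidate <- function(start, end, amb) {
  n <- length(start)
  best <- NULL
  for (mask in 0:(2^n - 1)) {
    sel <- which(bitwAnd(mask, 2^(seq_len(n) - 1)) > 0)
    if (length(sel) > 1) {
      o <- sel[order(start[sel])]
      if (any(start[o][-1] < end[o][-length(o)])) next
    }
    cand <- list(cov = sum(end[sel] - start[sel]), amb = sum(amb[sel]),
                 sel = sort(sel))
    if (is.null(best) ||
        cand$cov > best$cov ||
        (cand$cov == best$cov && cand$amb < best$amb) ||
        (cand$cov == best$cov && cand$amb == best$amb &&
         .lex_less(cand$sel, best$sel))) {
      best <- cand
    }
  }
  best$sel
}

.lex_less <- function(a, b) {
  k <- min(length(a), length(b))
  for (i in seq_len(k)) {
    if (a[i] < b[i]) return(TRUE)
    if (a[i] > b[i]) return(FALSE)
  }
  length(a) < length(b)
}

oracle_pr_auc <- function(scores, flags) {
  thr <- sort(unique(scores), decreasing = TRUE)
  pts <- t(vapply(thr, function(th) {
    pred <- scores >= th
    c(rec = sum(pred & flags) / sum(flags),
      prec = sum(pred & flags) / sum(pred))
  }, c(rec = 0, prec = 0)))
  sum(diff(c(0, pts[, "rec"])) * pts[, "prec"])
}

# exact one-sided rank-sum p (y greater) by enumerating all assignments of
# ranks to the x-sample; valid without ties
oracle_ranksum_p_greater <- function(x, y) {
  n <- length(x); m <- length(y)
  u_obs <- sum(outer(x, y, `>`))
  pooled <- seq_len(n + m)
  combos <- utils::combn(n + m, n)
  us <- apply(combos, 2, function(ix) {
    xx <- pooled[ix]; yy <- pooled[-ix]
    sum(outer(xx, yy, `>`))
  })
  mean(us <= u_obs)
}

# reference scalar (per-sample) SOM with lambda = 0: classic Kohonen rule,
# written independently of train_som's batched code path
oracle_scalar_som <- function(mat, cfg) {
  set.seed(cfg$seed)
  n <- nrow(mat)
  k <- cfg$rows * cfg$cols
  idx <- rep(sample.int(n), length.out = k)
  W <- mat[idx, , drop = FALSE]
  nr <- (seq_len(k) - 1) %/% cfg$cols + 1
  nc <- (seq_len(k) - 1) %% cfg$cols + 1
  total <- cfg$epochs * n
  lt <- log(cfg$radius0 / cfg$radius_end)
  la <- log(cfg$alpha0 / cfg$alpha_min)
  t <- 0
  for (e in seq_len(cfg$epochs)) {
    ord <- sample.int(n)
    for (i in ord) {
      x <- mat[i, ]
      sims <- apply(W, 1, function(w) {
        if (stats::sd(x) == 0 || stats::sd(w) == 0) 0 else stats::cor(x, w)
      })
      b <- which.max(round(sims / cfg$match_resolution))
      alpha <- cfg$alpha0 * exp(-t * la / total)
      rad <- cfg$radius0 * exp(-t * lt / total)
      d <- pmax(abs(nr - nr[b]), abs(nc - nc[b]))
      inside <- d <= rad
      h <- exp(-d^2 / (2 * rad^2))
      for (j in which(inside)) {
        W[j, ] <- W[j, ] + alpha * h[j] * (x - W[j, ])
      }
      t <- t + 1
    }
  }
  W
}

# small structured test track: two promoter-like bumps and one enhancer
# pair on a background, 40 regions worth of bins
toy_signal <- function(seed = 1, n_regions = 40, bins = 80) {
  set.seed(seed)
  cfg <- fixture_config(n_regions = n_regions, seed = seed)
  simulate_genome(cfg)
}

expect_region_set_equal <- function(a, b) {
  expect_equal(a$mat, b$mat)
  expect_equal(a$chrom, b$chrom)
  expect_equal(a$start, b$start)
}
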