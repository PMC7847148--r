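fake_assignment <- function(labels, chrom = "chr1", width = 8000) {
  n <- length(labels)
  out <- data.frame(chrom = chrom, start = (seq_len(n) - 1) * width,
                    end = seq_len(n) * width, best_shape = "s",
                    best_score = 1, second_score = 0, ambiguity = 0,
                    label = labels, stringsAsFactors = FALSE)
  class(out) <- c("state_assignment", "data.frame")
  out
}

truth_annotation <- function(classes, width = 8000) {
  mnem <- c(promoter = "1_TssA", enhancer = "7_Enh", weak = "9_Quies",
            other = "5_TxWk")
  n <- length(classes)
  annotation_track(rep("chr1", n), (seq_len(n) - 1) * width,
                   seq_len(n) * width, unname(mnem[classes]))
}

test_that("confusion counts follow the region-level definitions", {
  sa <- fake_assignment(c("promoter", "promoter", "enhancer", "weak"))
  annot <- truth_annotation(c("promoter", "enhancer", "enhancer", "weak"))
  cc <- confusion(sa, annot)
  p <- cc[cc$class == "promoter", ]
  expect_equal(c(p$tp, p$fp, p$fn), c(1, 1, 0))
  e <- cc[cc$class == "enhancer", ]
  expect_equal(c(e$tp, e$fp, e$fn), c(1, 0, 1))
  # all correct: no fp/fn anywhere
  cc2 <- confusion(fake_assignment(c("weak", "enhancer")),
                   truth_annotation(c("weak", "enhancer")))
  expect_true(all(cc2$fp == 0) && all(cc2$fn == 0))
})

test_that("confusion equals a brute-force tally on random label pairs", {
  set.seed(55)
  for (trial in 1:4) {
    n <- 50
    assigned <- sample(c("promoter", "enhancer", "weak"), n, TRUE)
    truth <- sample(c("promoter", "enhancer", "weak", "other"), n, TRUE)
    cc <- confusion(fake_assignment(assigned), truth_annotation(truth))
    for (A in RE_CLASSES) {
      row <- cc[cc$class == A, ]
      expect_equal(row$tp, sum(assigned == A & truth == A))
      expect_equal(row$fp, sum(assigned == A & truth != A))
      expect_equal(row$fn, sum(assigned != A & truth == A))
      expect_equal(row$tn, sum(assigned != A & truth != A))
      expect_equal(row$tp + row$fp + row$tn + row$fn, n)
    }
  }
})

test_that("the RPKM floor and promoter exclusion filter evaluated windows", {
  sa <- fake_assignment(c("promoter", "weak", "weak"))
  annot <- truth_annotation(c("promoter", "weak", "weak"))
  raw <- binned_signal("chr1", rep(c(20, 1, 6), each = 160))
  cc <- confusion(sa, annot, eval_config(rpkm_floor = 5), raw_signal = raw)
  expect_equal(sum(cc$tp + cc$fp + cc$tn + cc$fn) / nrow(cc), 2)  # 1 dropped
  cc2 <- confusion(sa, annot, eval_config(exclude_promoters = TRUE))
  expect_equal(sum(cc2$tp + cc2$fp + cc2$tn + cc2$fn) / nrow(cc2), 2)
  expect_error(confusion(sa, annot, eval_config(rpkm_floor = 5)),
               "raw_signal")
})

test_that("precision/recall formulas and N/A sentinels", {
  cc <- data.frame(class = "promoter", tp = 3L, fp = 1L, tn = 0L, fn = 1L)
  pr <- precision_recall(cc)
  expect_equal(pr$precision, 0.75)
  expect_equal(pr$recall, 0.75)

  cc <- data.frame(class = "enhancer", tp = 0L, fp = 0L, tn = 5L, fn = 2L)
  pr <- precision_recall(cc)
  expect_true(is.na(pr$precision))
  expect_equal(pr$recall, 0)

  cc <- data.frame(class = "weak", tp = 0L, fp = 5L, tn = 0L, fn = 0L)
  pr <- precision_recall(cc)
  expect_equal(pr$precision, 0)
  expect_true(is.na(pr$recall))
})

test_that("PR-AUC matches the enumeration oracle and known endpoints", {
  expect_equal(enhancer_pr_auc(c(0.9, 0.8, 0.2, 0.1),
                               c(TRUE, TRUE, FALSE, FALSE)), 1)
  expect_equal(enhancer_pr_auc(rep(0.5, 10), rep(c(TRUE, FALSE), 5)), 0.5)
  expect_equal(enhancer_pr_auc(rep(1, 4), c(TRUE, FALSE, FALSE, FALSE)),
               0.25)
  set.seed(66)
  for (trial in 1:50) {
    n <- sample(5:25, 1)
    scores <- round(stats::runif(n), 2)     # some ties
    flags <- stats::runif(n) < 0.4
    if (!any(flags) || all(flags)) next
    expect_equal(enhancer_pr_auc(scores, flags),
                 oracle_pr_auc(scores, flags))
    # invariance to strictly monotone transforms
    expect_equal(enhancer_pr_auc(exp(3 * scores), flags),
                 enhancer_pr_auc(scores, flags))
  }
  expect_error(enhancer_pr_auc(c(1, 2), c(FALSE, FALSE)), "positive")
})

test_that("rank-sum test: exact small-sample p, ties, and the oracle", {
  r <- rank_sum_test(c(1, 2, 3), c(4, 5, 6), alternative = "greater")
  expect_equal(unname(r$statistic), 0)
  expect_equal(r$p.value, 1 / 20)

  expect_equal(rank_sum_test(c(2, 2, 2), c(2, 2, 2))$p.value, 1)

  set.seed(70)
  for (trial in 1:10) {
    n <- sample(2:4, 1); m <- sample(2:4, 1)
    x <- sample(100, n); y <- sample(100, m)   # no ties
    while (length(intersect(x, y))) y <- sample(100, m)
    r <- rank_sum_test(x, y, alternative = "greater")
    expect_equal(r$p.value, oracle_ranksum_p_greater(x, y),
                 tolerance = 1e-12)
  }
})

test_that("rank-sum p-values are calibrated under the null", {
  set.seed(80)
  p <- replicate(2000, {
    rank_sum_test(stats::rnorm(50), stats::rnorm(50))$p.value
  })
  rate <- mean(p < 0.05)
  expect_gt(rate, 0.03)
  expect_lt(rate, 0.07)
})

test_that("Davies-Bouldin matches the textbook formula and a brute force", {
  # two singleton clusters: zero scatter
  m <- rbind(c(0, 0), c(10, 0))
  expect_equal(davies_bouldin(m, c(1, 2)), 0)

  # constructed scatter 1 vs centroid distance 10: DB = 0.2
  cl <- rep(1:2, each = 2)
  m <- rbind(c(-1, 0), c(1, 0), c(9, 0), c(11, 0))
  expect_equal(davies_bouldin(m, cl), 0.2)

  set.seed(90)
  m <- matrix(stats::rnorm(30 * 5), 30)
  cl <- sample(3, 30, TRUE)
  got <- davies_bouldin(m, cl)
  cent <- apply(m, 2, tapply, factor(cl), mean)
  s <- sapply(1:3, function(i)
    mean(sqrt(rowSums(sweep(m[cl == i, , drop = FALSE], 2,
                            cent[i, ])^2))))
  want <- mean(sapply(1:3, function(i)
    max(sapply(setdiff(1:3, i), function(j)
      (s[i] + s[j]) / sqrt(sum((cent[i, ] - cent[j, ])^2))))))
  expect_equal(got, want)
  expect_error(davies_bouldin(m, rep(1, 30)), "2 non-empty")
})

test_that("cross-chromosome splits are seeded, disjoint, and diverse", {
  chroms <- paste0("chr", 1:22)
  s1 <- cross_chromosome_split(chroms, 11, n_iter = 100, seed = 4)
  s2 <- cross_chromosome_split(chroms, 11, n_iter = 100, seed = 4)
  expect_identical(s1, s2)
  expect_true(all(vapply(s1, function(sp)
    length(sp$train) == 11 && length(sp$test) == 11 &&
      !length(intersect(sp$train, sp$test)) &&
      setequal(c(sp$train, sp$test), chroms), TRUE)))
  keys <- vapply(s1, function(sp) paste(sp$train, collapse = ","), "")
  expect_equal(anyDuplicated(keys), 0)
  expect_error(cross_chromosome_split(chroms, 22), "smaller")
})
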