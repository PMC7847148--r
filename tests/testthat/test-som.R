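test_that("grid initialization samples training regions deterministically", {
  one <- matrix(stats::runif(80), 1)
  g <- initialize_grid(one, som_config(rows = 1, cols = 1, seed = 3))
  expect_equal(unname(g$weights[1, ]), one[1, ])

  set.seed(99)
  mat <- matrix(stats::runif(100 * 80), 100)
  cfg <- som_config(rows = 2, cols = 2, seed = 5)
  g1 <- initialize_grid(mat, cfg)
  g2 <- initialize_grid(mat, cfg)
  expect_identical(g1$weights, g2$weights)
  # every node is a member of the region set
  for (k in 1:4) {
    expect_true(any(apply(mat, 1, function(r)
      isTRUE(all.equal(r, unname(g1$weights[k, ]))))))
  }
})

test_that("neighborhood radius follows the variable-lambda formula", {
  cfg <- som_config(rows = 10, cols = 10, lambda = 0)
  r <- neighborhood_radius(c(0.2, 0.9), t = 0, cfg, global_max = 1)
  expect_equal(r, c(5, 5))   # lambda 0: classic radius, identical nodes

  cfg1 <- som_config(rows = 10, cols = 10, lambda = 1)
  expect_equal(neighborhood_radius(1, 0, cfg1, global_max = 1), 10)  # 2 r0

  cfg2 <- som_config(rows = 10, cols = 10, lambda = 0.7)
  r2 <- neighborhood_radius(c(0.2, 0.8), 0, cfg2, global_max = 1)
  expect_equal(r2[1] / r2[2], (1 + 0.2 * 0.7) / (1 + 0.8 * 0.7))

  expect_error(neighborhood_radius(0.5, 0, cfg1, global_max = 0),
               "global_max")
})

test_that("training is a no-op at alpha ~ 0 and a fixed point on one region", {
  set.seed(4)
  mat <- matrix(stats::runif(20 * 40) + 0.1, 20)
  cfg0 <- som_config(rows = 2, cols = 2, epochs = 3, alpha0 = 1e-9,
                     alpha_min = 1e-9, seed = 8)
  trained <- train_som(mat, cfg0)
  expect_equal(trained$weights, initialize_grid(mat, cfg0)$weights,
               tolerance = 1e-6)

  one <- matrix(exp(-(seq_len(80) - 30)^2 / 50) + 0.2, 1)
  g <- train_som(one, som_config(rows = 1, cols = 1, epochs = 50, seed = 1))
  expect_gt(max_ncc(g$weights[1, ], one[1, ], 0)$score, 0.999)
})

test_that("training is deterministic and weights stay within input bounds", {
  set.seed(10)
  mat <- matrix(stats::runif(60 * 40) + 0.05, 60)
  cfg <- som_config(rows = 3, cols = 3, epochs = 10, batch_size = 16,
                    seed = 2)
  g1 <- train_som(mat, cfg)
  g2 <- train_som(mat, cfg)
  expect_identical(g1$weights, g2$weights)
  expect_gte(min(g1$weights), min(mat))
  expect_lte(max(g1$weights), max(mat))
})

test_that("batched trainer matches an independent scalar SOM at batch_size 1", {
  set.seed(31)
  pp <- make_prototype_regions(50, seed = 31)
  mat <- pp$regions$mat
  cfg <- som_config(rows = 3, cols = 3, epochs = 5, batch_size = 1,
                    lambda = 0, match_resolution = 1e-9, seed = 17)
  g <- train_som(mat, cfg)
  W_ref <- oracle_scalar_som(mat, cfg)
  expect_equal(unname(g$weights), unname(W_ref), tolerance = 1e-8)
  # final best-match partitions agree
  part <- max.col(somvn:::.ncc0_cross(mat, g$weights), ties.method = "first")
  sims <- somvn:::.ncc0_cross(mat, W_ref)
  part_ref <- max.col(sims, ties.method = "first")
  expect_equal(part, part_ref)
})

test_that("planted prototypes are recovered by some node across seeds", {
  pr <- default_prototypes()
  for (s in c(2, 12)) {
    pp <- make_prototype_regions(300, seed = s)
    g <- train_som(pp$regions,
                   som_config(rows = 4, cols = 4, epochs = 100, seed = s))
    for (p in pr) {
      best <- max(somvn:::.ncc0_cross(g$weights, rbind(p)))
      expect_gt(best, 0.9)
    }
  }
})

test_that("shape files round-trip through write_shapes/read_shapes", {
  set.seed(6)
  mat <- matrix(stats::runif(5 * 20), 5)
  rownames(mat) <- sprintf("s%02d", 1:5)
  p <- withr::local_tempfile(fileext = ".csv")
  write_shapes(mat, p)
  back <- read_shapes(p)
  expect_identical(back$shapes, mat)

  g <- initialize_grid(mat, som_config(rows = 2, cols = 2, seed = 1))
  write_shapes(g, p, celltype = "K562", chrom = "chr7")
  lib <- read_shapes(p)
  expect_true(all(grepl("^K562_chr7_[0-9]+\\.[0-9]+$", rownames(lib$shapes))))
})
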