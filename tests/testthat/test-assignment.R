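make_lib <- function(...) {
  shapes <- list(...)
  m <- do.call(rbind, shapes)
  rownames(m) <- names(shapes)
  shape_library(m)
}

fake_assoc <- function(labels) {
  data.frame(shape = names(labels), promoter = 0, enhancer = 0, weak = 0,
             other = 0, label = unname(labels),
             support = 1L, stringsAsFactors = FALSE)
}

test_that("a single-shape library yields zero ambiguity everywhere", {
  shape <- exp(-(seq_len(80) - 40)^2 / 100)
  sig <- binned_signal("chr1", c(numeric(100), shape, numeric(140)) + 0.01)
  lib <- make_lib(s1 = shape)
  wm <- match_windows(sig, lib, fake_assoc(c(s1 = "promoter")))
  expect_true(all(wm$ambiguity == 0))
  expect_true(all(wm$label[wm$best_score > 0] == "promoter"))
  expect_true(any(wm$best_score > 0.99))
})

test_that("ambiguity is the ratio of second-best to best containment", {
  set.seed(40)
  shape_a <- exp(-(seq_len(80) - 40)^2 / 100)
  shape_b <- stats::runif(80)
  sig <- binned_signal("chr1", c(numeric(40), shape_a, numeric(200)) + 0.001)
  lib <- make_lib(sa = shape_a, sb = shape_b)
  wm <- match_windows(sig, lib, fake_assoc(c(sa = "promoter", sb = "weak")))
  w <- wm[which.max(wm$best_score), ]
  expect_equal(w$best_shape, "sa")
  expect_gt(w$best_score, 0.99)
  expect_equal(w$ambiguity, w$second_score / w$best_score)
  # unknown-labeled shapes are excluded from matching
  wm2 <- match_windows(sig, lib, fake_assoc(c(sa = "promoter",
                                              sb = "unknown")))
  pos <- wm2$best_score > 0
  expect_true(any(pos))
  expect_true(all(wm2$best_shape[pos] == "sa"))
  expect_true(all(wm2$ambiguity == 0))
})

test_that("windows recover planted shapes under 5% summit noise", {
  set.seed(51)
  protos <- default_prototypes()
  n <- 60
  picks <- sample(3, n, replace = TRUE)
  vals <- unlist(lapply(picks, function(p) {
    v <- protos[[p]] + stats::rnorm(80, 0, 0.05 * max(protos[[p]]))
    pmax(v, 0)
  }))
  sig <- binned_signal("chr1", vals)
  lib <- shape_library(do.call(rbind, protos))
  assoc <- fake_assoc(c(unimodal = "promoter", bimodal = "enhancer",
                        trimodal = "weak"))
  wm <- match_windows(sig, lib, assoc, window_size = 4000, step = 4000)
  expect_equal(nrow(wm), n)
  ok <- wm$best_shape == names(protos)[picks]
  expect_gte(mean(ok), 0.9)
})

test_that("consolidation equals the exhaustive oracle on the spec geometry", {
  wm <- data.frame(chrom = "chr1", start = c(0, 4000, 8000),
                   end = c(8000, 12000, 16000),
                   best_shape = "s", best_score = 1, second_score = 0,
                   ambiguity = c(0.2, 0.9, 0.3), label = "weak",
                   stringsAsFactors = FALSE)
  sa <- consolidate(wm)
  expect_equal(sa$start, c(0, 8000))

  wm$ambiguity <- c(0.5, 0.5, 0.5)
  expect_equal(consolidate(wm)$start, c(0, 8000))  # coverage maximality

  expect_equal(nrow(consolidate(wm[1, ])), 1)
  expect_equal(nrow(consolidate(wm[0, ])), 0)
})

test_that("consolidation matches brute force on random instances", {
  set.seed(77)
  for (trial in 1:120) {
    n_all <- sample(1:12, 1)
    pos <- sort(sample(0:13, n_all))
    wm <- data.frame(chrom = "chr1", start = pos * 4000,
                     end = pos * 4000 + 8000, best_shape = "s",
                     best_score = 1, second_score = 0,
                     ambiguity = round(stats::runif(n_all), 3),
                     label = "weak", stringsAsFactors = FALSE)
    got <- consolidate(wm)
    want <- oracle_consolidate(wm$start, wm$end, wm$ambiguity)
    expect_equal(got$start, wm$start[want])
  }
})

test_that("assignments round-trip through BED with the documented format", {
  sa <- data.frame(chrom = "chr1", start = 0, end = 8000,
                   best_shape = "s", best_score = 0.9, second_score = 0.2,
                   ambiguity = 0.25, label = "promoter",
                   stringsAsFactors = FALSE)
  class(sa) <- c("state_assignment", "data.frame")
  p <- withr::local_tempfile(fileext = ".bed")
  write_assignment(sa, p)
  expect_equal(readLines(p), "chr1\t0\t8000\tpromoter\t750\t.")
  back <- read_assignment(p)
  expect_equal(back$label, "promoter")
  expect_equal(back$start, 0)
  expect_equal(back$end, 8000)
  expect_equal(back$ambiguity, 0.25)

  write_assignment(sa[0, ], p)
  expect_equal(length(readLines(p)), 0)
  expect_equal(nrow(read_assignment(p)), 0)
})
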