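test_that("15-state mnemonics simplify to the four RE classes", {
  expect_equal(simplify_state("1_TssA"), "promoter")
  expect_equal(simplify_state("7_Enh"), "enhancer")
  expect_equal(simplify_state("9_Het"), "weak")
  expect_equal(
    simplify_state(c("TssA", "TssAFlnk", "TssBiv", "BivFlnk")),
    rep("promoter", 4))
  expect_equal(simplify_state(c("EnhG", "Enh", "EnhBiv")),
               rep("enhancer", 3))
  expect_equal(simplify_state(c("Het", "Quies", "15_Quies")),
               rep("weak", 3))
  expect_equal(
    simplify_state(c("Tx", "TxWk", "TxFlnk", "ZNF/Rpts", "ReprPC",
                     "ReprPCWk")),
    rep("other", 6))
  expect_error(simplify_state("5_Fancy"), "5_Fancy")
})

test_that("annotation BED round-trips and rejects overlaps", {
  annot <- annotation_track(c("chr1", "chr1", "chr2"), c(0, 4000, 0),
                            c(4000, 8000, 2000),
                            c("1_TssA", "9_Quies", "7_Enh"))
  p <- withr::local_tempfile(fileext = ".bed")
  write_annotations(annot, p)
  back <- read_annotations(p)
  expect_equal(back$start, annot$start)
  expect_equal(back$end, annot$end)
  expect_equal(back$mnemonic, annot$mnemonic)

  expect_error(annotation_track("chr1", c(0, 100), c(200, 300),
                                c("Enh", "Enh")), "overlapping")
  expect_error(annotation_track("chr1", 10, 10, "Enh"), "start < end")
})

test_that("a fully promoter-covered matched region gives a promoter label", {
  shape <- exp(-(seq_len(80) - 40)^2 / 100)
  lib <- shape_library(matrix(shape, 1, dimnames = list("s1", NULL)))
  regions <- region_set(matrix(shape, 1), "chr1", 0)
  annot <- annotation_track("chr1", 0, 4000, "1_TssA")
  assoc <- associate_shapes(regions, lib, annot, cutoff = 0.5)
  expect_equal(assoc$promoter, 1)
  expect_equal(assoc$label, "promoter")
  expect_equal(assoc$support, 1L)
})

test_that("argmax ties at the cutoff follow the fixed class priority", {
  shape <- exp(-(seq_len(80) - 40)^2 / 100)
  lib <- shape_library(matrix(shape, 1, dimnames = list("s1", NULL)))
  # one matched region: 50% Enh bp, 50% Quies bp
  regions <- region_set(matrix(shape, 1), "chr1", 0)
  annot <- annotation_track(c("chr1", "chr1"), c(0, 2000), c(2000, 4000),
                            c("7_Enh", "9_Quies"))
  assoc <- associate_shapes(regions, lib, annot, cutoff = 0.5)
  expect_equal(assoc$enhancer, 0.5)
  expect_equal(assoc$weak, 0.5)
  expect_equal(assoc$label, "enhancer")  # promoter > enhancer > weak
})

test_that("coverage fractions equal a brute-force bp overlap tally", {
  set.seed(20)
  g <- simulate_genome(fixture_config(n_regions = 30, seed = 20,
                                      boundary_jitter = 800))
  regions <- segment(normalize_signal(g$signal, 99.9), 4000, 4000)
  protos <- default_prototypes()
  lib <- shape_library(do.call(rbind, protos))
  assoc <- associate_shapes(regions, lib, g$annotations, cutoff = 0.5)
  m <- match_shapes(regions, lib)
  cls <- simplify_state(g$annotations$mnemonic)
  for (i in seq_len(nrow(assoc))) {
    rows <- which(m$shape == assoc$shape[i])
    expect_equal(assoc$support[i], length(rows))
    if (!length(rows)) next
    bp <- c(promoter = 0, enhancer = 0, weak = 0, other = 0)
    for (r in rows) {
      ov <- pmin(regions$end[r], g$annotations$end) -
        pmax(regions$start[r], g$annotations$start)
      keep <- ov > 0 & g$annotations$chrom == regions$chrom[r]
      for (k in which(keep)) bp[cls[k]] <- bp[cls[k]] + ov[k]
    }
    expect_equal(unlist(assoc[i, c("promoter", "enhancer", "weak",
                                   "other")]),
                 bp / sum(bp), tolerance = 1e-12,
                 ignore_attr = TRUE)
  }
  # fractions sum to one whenever a shape has matched bp
  sums <- rowSums(assoc[, c("promoter", "enhancer", "weak", "other")])
  expect_true(all(abs(sums[assoc$support > 0] - 1) < 1e-9))
})

test_that("raising the association cutoff never rescues an unknown label", {
  set.seed(8)
  g <- simulate_genome(fixture_config(n_regions = 40, seed = 8))
  regions <- segment(normalize_signal(g$signal, 99.9), 4000, 4000)
  lib <- shape_library(do.call(rbind, default_prototypes()))
  prev_unknown <- NULL
  for (cutoff in c(0.3, 0.5, 0.7, 0.9)) {
    assoc <- associate_shapes(regions, lib, g$annotations, cutoff = cutoff)
    unknown <- assoc$shape[assoc$label == "unknown"]
    if (!is.null(prev_unknown)) {
      expect_true(all(prev_unknown %in% unknown))
    }
    prev_unknown <- unknown
  }
})

test_that("magnitude association bins regions by max RPKM quantiles", {
  # identical maxima: a single occupied bin
  regions <- region_set(matrix(rep(c(1, 2, 3, 2), 5), 5, byrow = TRUE),
                        rep("chr1", 5), (0:4) * 200, bin_size = 50)
  annot <- annotation_track("chr1", 0, 1000, "9_Quies")
  assoc <- associate_magnitudes(regions, annot, n_bins = 4)
  expect_equal(nrow(assoc), 1)

  # 10 regions, 2 bins: median split
  set.seed(2)
  mx <- stats::runif(10) + 1
  mat <- matrix(0.1, 10, 4)
  mat[cbind(1:10, sample(4, 10, TRUE))] <- mx
  rs <- region_set(mat, rep("chr1", 10), (0:9) * 200, bin_size = 50)
  annot <- annotation_track("chr1", 0, 2000, "9_Quies")
  assoc <- associate_magnitudes(rs, annot, n_bins = 2)
  bin <- attr(assoc, "bin")
  expect_equal(sort(as.vector(table(bin))), c(5, 5))
  expect_true(all(mx[bin == 1] < min(mx[bin == 2])))
})

test_that("only the top magnitude bin picks up a planted promoter signal", {
  set.seed(33)
  g <- simulate_genome(fixture_config(n_regions = 200, seed = 33))
  regions <- segment(g$signal, 4000, 4000)    # raw regions
  assoc <- associate_magnitudes(regions, g$annotations, n_bins = 10,
                                cutoff = 0.5)
  prom_bins <- assoc$shape[assoc$label == "promoter"]
  weak_bins <- assoc$shape[assoc$label == "weak"]
  expect_true(all(prom_bins >= max(weak_bins)))   # lexicographic bin names
  expect_gt(length(weak_bins), 0)
})
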