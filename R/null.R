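#' Permute signal intensities (null model 1)
#'
#' Uniformly permutes the per-bin values of each chromosome (seeded),
#' before any segmentation, emulating signal with no positional pattern.
#' Genomic anchoring is unchanged; every order statistic of the values is
#' preserved. Permutation is per chromosome.
#'
#' @param sig A `binned_signal` or list of them.
#' @param seed Integer seed.
#' @return Permuted copy with the same structure.
#' @export
permute_signal <- function(sig, seed = 1) {
  set.seed(seed)
  single <- inherits(sig, "binned_signal")
  sigs <- .as_signal_list(sig)
  out <- lapply(sigs, function(s) {
    s$values <- s$values[sample.int(length(s$values))]
    s
  })
  if (single) out[[1L]] else out
}

#' Permute annotation positions (null model 2)
#'
#' Re-places each chromosome's annotation intervals by shuffling the order
#' of its interval lengths (with their mnemonics) and independently the
#' multiset of inter-interval gap lengths, then laying gap, interval, gap,
#' interval, ... from the chromosome start. Interval sizes, mnemonics,
#' per-chromosome annotated bp, and total genome coverage are all preserved
#' exactly; only positions change.
#'
#' @param annot An [annotation_track()].
#' @param chrom_lengths Named vector of chromosome lengths (bp); see
#'   [signal_lengths()].
#' @param seed Integer seed.
#' @return A permuted [annotation_track()].
#' @export
permute_annotations <- function(annot, chrom_lengths, seed = 1) {
  set.seed(seed)
  chroms <- sort(unique(annot$chrom))
  parts <- lapply(chroms, function(ch) {
    d <- annot[annot$chrom == ch, ]
    d <- d[order(d$start), ]
    L <- chrom_lengths[[ch]]
    if (is.null(L) || is.na(L)) stop("no chromosome length for ", ch)
    if (max(d$end) > L)
      stop("annotation interval exceeds chromosome length on ", ch)
    n <- nrow(d)
    len <- d$end - d$start
    gaps <- c(d$start, L) - c(0, d$end)   # n + 1 gaps, possibly zero
    pi_int <- sample.int(n)
    pi_gap <- sample.int(n + 1L)
    new_len <- len[pi_int]
    new_gap <- gaps[pi_gap]
    starts <- cumsum(new_gap[seq_len(n)]) + c(0, cumsum(new_len))[seq_len(n)]
    data.frame(chrom = ch, start = starts, end = starts + new_len,
               mnemonic = d$mnemonic[pi_int], stringsAsFactors = FALSE)
  })
  all <- do.call(rbind, parts)
  annotation_track(all$chrom, all$start, all$end, all$mnemonic)
}

#' Compare matched-shape scores between a real and a null library
#'
#' For the permuted-signal null model: every region is matched against the
#' library learned from real signal and against the library learned from
#' permuted signal, and the two matched-score samples are compared with a
#' one-sided rank-sum test (real greater). Regions are grouped by their RE
#' annotation class (the coverage-argmax of `annot` over the region); an
#' RE class with no regions is marked not comparable, and a pooled `"all"`
#' group over every region is always included. Significance is flagged at
#' the Bonferroni-adjusted level `alpha / m`, with `m` defaulting to the
#' number of comparable RE groups times `n_samples`.
#'
#' @param regions A `region_set` of evaluation regions.
#' @param annot An [annotation_track()] giving each region's RE class.
#' @param library_real Real-signal [shape_library()] (or `som_grid`).
#' @param library_null Permuted-signal library.
#' @param alpha Family-wise error rate before correction (default 0.05).
#' @param bonferroni_m Correction denominator; `NULL` for the default.
#' @param n_samples Number of samples in the wider analysis this call
#'   belongs to (enters the default `m`; default 1).
#' @return Data frame: label, group sizes, rank-sum statistic, p-value,
#'   significance flag, comparability flag.
#' @export
null_shape_validation <- function(regions, annot, library_real,
                                  library_null, alpha = 0.05,
                                  bonferroni_m = NULL, n_samples = 1) {
  if (!n_regions(regions)) stop("no regions to validate")
  m_real <- match_shapes(regions, library_real)
  m_null <- match_shapes(regions, library_null)
  ov <- .class_overlap_bp(regions$chrom, regions$start, regions$end, annot)
  truth <- .argmax_class(ov)
  groups <- c("all", RE_CLASSES)
  rows <- lapply(groups, function(g) {
    sel <- if (g == "all") !is.na(truth) else !is.na(truth) & truth == g
    x <- m_null$score[sel]
    y <- m_real$score[sel]
    comparable <- sum(sel) > 0
    if (!comparable) {
      return(data.frame(label = g, n = 0L, statistic = NA_real_,
                        p_value = NA_real_, significant = NA,
                        comparable = FALSE, stringsAsFactors = FALSE))
    }
    ts <- rank_sum_test(x, y, alternative = "greater")
    data.frame(label = g, n = sum(sel), statistic = ts$statistic,
               p_value = ts$p.value, significant = NA, comparable = TRUE,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  m <- if (is.null(bonferroni_m))
    max(1L, sum(out$comparable & out$label != "all")) * n_samples
  else bonferroni_m
  out$significant <- ifelse(out$comparable, out$p_value < alpha / m, NA)
  attr(out, "alpha_adjusted") <- alpha / m
  out
}
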