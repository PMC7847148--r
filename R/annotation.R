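#' Regulatory-element classes
#'
#' The simplified state space, in tie-break priority order. Only the first
#' three are ever assigned; `other` (transcribed / ZNF / Polycomb-repressed
#' states) participates in coverage denominators but never wins a label.
#' @export
RE_CLASSES <- c("promoter", "enhancer", "weak", "other")

.MNEMONIC_MAP <- c(
  TssA = "promoter", TssAFlnk = "promoter", TssBiv = "promoter",
  BivFlnk = "promoter",
  EnhG = "enhancer", Enh = "enhancer", EnhBiv = "enhancer",
  Het = "weak", Quies = "weak",
  Tx = "other", TxWk = "other", TxFlnk = "other",
  `ZNF/Rpts` = "other", ReprPC = "other", ReprPCWk = "other")

#' Simplify 15-state ChromHMM mnemonics to RE classes
#'
#' Active, flanking-active, bivalent (poised) and flanking-bivalent TSS
#' states map to `promoter`; genic, standard and bivalent enhancers to
#' `enhancer`; heterochromatin and quiescent states to `weak`; the remaining
#' 15-state mnemonics (transcription, ZNF/repeats, Polycomb) to `other`.
#' An optional numeric prefix such as `"1_"` is stripped.
#'
#' @param mnemonic Character vector of state mnemonics (e.g. `"1_TssA"`).
#' @return Character vector of RE classes.
#' @examples
#' simplify_state(c("1_TssA", "7_Enh", "9_Het"))
#' @export
simplify_state <- function(mnemonic) {
  bare <- sub("^[0-9]+_", "", mnemonic)
  out <- .MNEMONIC_MAP[bare]
  if (anyNA(out))
    stop("unrecognized chromatin-state mnemonic: ",
         paste(unique(mnemonic[is.na(out)]), collapse = ", "))
  unname(out)
}

#' Chromatin-state annotation track
#'
#' Labeled genomic intervals (0-based, half-open) carrying raw ChromHMM-style
#' mnemonics. Intervals must be non-overlapping within a chromosome.
#'
#' @param chrom,start,end,mnemonic Parallel vectors describing the intervals.
#' @return A data frame of class `annotation_track`, sorted by
#'   (chrom, start).
#' @export
annotation_track <- function(chrom, start, end, mnemonic) {
  df <- data.frame(chrom = as.character(chrom), start = as.numeric(start),
                   end = as.numeric(end), mnemonic = as.character(mnemonic),
                   stringsAsFactors = FALSE)
  if (any(df$start >= df$end)) stop("annotation intervals need start < end")
  df <- df[order(df$chrom, df$start), , drop = FALSE]
  rownames(df) <- NULL
  for (ch in unique(df$chrom)) {
    d <- df[df$chrom == ch, ]
    if (nrow(d) > 1L && any(d$start[-1L] < d$end[-nrow(d)]))
      stop("overlapping annotation intervals on ", ch)
  }
  class(df) <- c("annotation_track", "data.frame")
  df
}

#' Read chromatin-state annotations from BED
#'
#' Expects BED with at least 4 columns (chrom, start, end, mnemonic).
#'
#' @param path BED file path.
#' @return An [annotation_track()].
#' @export
read_annotations <- function(path) {
  if (!file.exists(path)) stop("annotation file not found: ", path)
  gr <- rtracklayer::import(path, format = "bed")
  if (is.null(gr$name)) stop("BED file lacks a name (mnemonic) column: ", path)
  annotation_track(as.character(GenomicRanges::seqnames(gr)),
                   GenomicRanges::start(gr) - 1, GenomicRanges::end(gr),
                   gr$name)
}

#' Write an annotation track as 4-column BED
#'
#' @param annot An [annotation_track()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_annotations <- function(annot, path) {
  utils::write.table(
    data.frame(annot$chrom, format(annot$start, scientific = FALSE,
                                   trim = TRUE),
               format(annot$end, scientific = FALSE, trim = TRUE),
               annot$mnemonic),
    path, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

# bp overlap of query intervals (0-based half-open) with each RE class;
# returns length(chrom) x 4 matrix
.class_overlap_bp <- function(chrom, start, end, annot) {
  cls <- simplify_state(annot$mnemonic)
  out <- matrix(0, length(chrom), length(RE_CLASSES),
                dimnames = list(NULL, RE_CLASSES))
  if (!length(chrom) || !nrow(annot)) return(out)
  q <- GenomicRanges::GRanges(chrom, IRanges::IRanges(start + 1, end))
  s <- GenomicRanges::GRanges(annot$chrom,
                              IRanges::IRanges(annot$start + 1, annot$end))
  hits <- GenomicRanges::findOverlaps(q, s)
  if (!length(hits)) return(out)
  qi <- S4Vectors::queryHits(hits)
  si <- S4Vectors::subjectHits(hits)
  w <- pmin(end[qi], annot$end[si]) - pmax(start[qi], annot$start[si])
  acc <- stats::xtabs(w ~ factor(qi, levels = seq_along(chrom)) +
                        factor(cls[si], levels = RE_CLASSES))
  out[, ] <- as.numeric(acc)
  out
}

# winning class per row of a bp-overlap matrix, ties by RE_CLASSES priority;
# NA where the row has no annotated bp
.argmax_class <- function(ov) {
  tot <- rowSums(ov)
  win <- RE_CLASSES[apply(ov, 1L, which.max)]  # which.max: first max = priority
  win[tot == 0] <- NA_character_
  win
}

#' Match regions to their best shape
#'
#' Each region is matched to the library shape with the highest normalized
#' cross-correlation (lag 0 by default; ties to the first shape).
#'
#' @param regions A `region_set` or matrix of regions.
#' @param library A [shape_library()] (or `som_grid`/matrix).
#' @param max_lag Maximum absolute lag in bins (default 0).
#' @return Data frame with columns `shape` and `score`, one row per region.
#' @export
match_shapes <- function(regions, library, max_lag = 0) {
  mat <- .as_region_matrix(regions)
  S <- .shape_matrix(library)
  if (!nrow(S)) stop("empty shape library")
  R <- if (max_lag == 0) .ncc0_cross(mat, S)
       else {
         px <- .pairwise_max_ncc(rbind(mat, S), max_lag)
         px$score[seq_len(nrow(mat)), nrow(mat) + seq_len(nrow(S)),
                  drop = FALSE]
       }
  idx <- max.col(R, ties.method = "first")
  data.frame(shape = rownames(S)[idx],
             score = R[cbind(seq_len(nrow(mat)), idx)],
             stringsAsFactors = FALSE)
}

# shared association core: keys (one per region) -> coverage distribution
.associate_keys <- function(keys, all_keys, regions, annot, cutoff) {
  ov <- .class_overlap_bp(regions$chrom, regions$start, regions$end, annot)
  res <- data.frame(shape = all_keys, promoter = 0, enhancer = 0, weak = 0,
                    other = 0, label = "unknown",
                    support = 0L, stringsAsFactors = FALSE)
  for (i in seq_along(all_keys)) {
    rows <- which(keys == all_keys[i])
    res$support[i] <- length(rows)
    if (!length(rows)) next
    bp <- colSums(ov[rows, , drop = FALSE])
    tot <- sum(bp)
    if (tot == 0) next
    frac <- bp / tot
    res[i, RE_CLASSES] <- as.list(frac)
    cand <- RE_CLASSES[RE_CLASSES != "other"]
    win <- cand[which.max(frac[cand])]
    if (frac[win] >= cutoff) res$label[i] <- win
  }
  class(res) <- c("shape_assoc", "data.frame")
  res
}

#' Associate learned shapes with RE chromatin states
#'
#' Each training region is matched to its best shape ([match_shapes()]);
#' per shape, the bp overlap between its matched regions and each simplified
#' RE class is accumulated into a coverage distribution over
#' promoter/enhancer/weak/other. The winning label is the argmax class
#' (excluding `other`; ties broken promoter > enhancer > weak) if its
#' fraction reaches `cutoff`, else `unknown`. Regions with no annotation
#' overlap contribute nothing; a shape with no matched regions is `unknown`
#' with support 0.
#'
#' @param regions A `region_set` of training regions (coordinates shared
#'   with `annot`).
#' @param library A [shape_library()].
#' @param annot An [annotation_track()].
#' @param cutoff Association cutoff on the winning coverage fraction
#'   (default 0.5).
#' @param max_lag Matching lag passed to [match_shapes()] (default 0).
#' @return A `shape_assoc` data frame: shape, class fractions, label,
#'   support.
#' @export
associate_shapes <- function(regions, library, annot, cutoff = 0.5,
                             max_lag = 0) {
  S <- .shape_matrix(library)
  m <- match_shapes(regions, library, max_lag = max_lag)
  .associate_keys(m$shape, rownames(S), regions, annot, cutoff)
}

#' Associate signal magnitudes with RE chromatin states (baseline)
#'
#' The magnitude baseline replaces shapes with equal-frequency quantile bins
#' of each region's maximum raw RPKM; association then proceeds exactly as
#' in [associate_shapes()]. Use regions segmented from the raw
#' (unnormalized) track.
#'
#' @param regions A `region_set` of raw-signal training regions.
#' @param annot An [annotation_track()].
#' @param n_bins Number of equal-frequency magnitude bins (default 10).
#' @param cutoff Association cutoff (default 0.5).
#' @return A `shape_assoc` data frame keyed by magnitude bin, with an
#'   attribute `"breaks"` (quantile break points) and `"bin"` (per-region
#'   bin index).
#' @export
associate_magnitudes <- function(regions, annot, n_bins = 10, cutoff = 0.5) {
  if (n_bins < 2) stop("n_bins must be at least 2")
  mx <- apply(.as_region_matrix(regions), 1L, max)
  breaks <- unique(stats::quantile(mx, probs = seq(0, 1, length.out = n_bins + 1),
                                   names = FALSE))
  if (length(breaks) < 2L) {
    bin <- rep(1L, length(mx))
  } else {
    bin <- cut(mx, breaks, include.lowest = TRUE, labels = FALSE)
  }
  keys <- sprintf("mag_bin_%02d", bin)
  all_keys <- sprintf("mag_bin_%02d", sort(unique(bin)))
  out <- .associate_keys(keys, all_keys, regions, annot, cutoff)
  attr(out, "breaks") <- breaks
  attr(out, "bin") <- bin
  out
}

#' Write a shape association map as TSV
#'
#' @param assoc A `shape_assoc` data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_association <- function(assoc, path) {
  out <- assoc
  names(out) <- c("shape", "promoter_frac", "enhancer_frac", "weak_frac",
                  "other_frac", "label", "support")
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a shape association map written by [write_association()]
#'
#' @param path TSV path.
#' @return A `shape_assoc` data frame.
#' @export
read_association <- function(path) {
  if (!file.exists(path)) stop("association file not found: ", path)
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  names(df) <- c("shape", "promoter", "enhancer", "weak", "other", "label",
                 "support")
  class(df) <- c("shape_assoc", "data.frame")
  df
}
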