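#' Evaluation settings
#'
#' @param rpkm_floor Only evaluate windows whose maximum raw RPKM reaches
#'   this floor (default 0 = evaluate everything; the PEAS-style protocol
#'   uses 5).
#' @param exclude_promoters Drop truth-promoter windows before counting
#'   (PEAS-style enhancer evaluation).
#' @param bonferroni_m Multiple-testing denominator carried alongside the
#'   config (default 1).
#' @return An `eval_config` list.
#' @export
eval_config <- function(rpkm_floor = 0, exclude_promoters = FALSE,
                        bonferroni_m = 1) {
  stopifnot(is.finite(rpkm_floor), rpkm_floor >= 0, bonferroni_m >= 1)
  structure(list(rpkm_floor = rpkm_floor,
                 exclude_promoters = isTRUE(exclude_promoters),
                 bonferroni_m = as.integer(bonferroni_m)),
            class = "eval_config")
}

# max raw value within [start, end) per query, from raw signal tracks
.window_max_signal <- function(raw, chrom, start, end) {
  raw <- .as_signal_list(raw)
  vapply(seq_along(chrom), function(i) {
    s <- raw[[chrom[i]]]
    if (is.null(s)) return(0)
    b0 <- floor((start[i] - s$start) / s$bin_size)
    b1 <- ceiling((end[i] - s$start) / s$bin_size)
    b0 <- max(b0, 0); b1 <- min(b1, length(s$values))
    if (b1 <= b0) return(0)
    max(s$values[(b0 + 1):b1])
  }, 0)
}

# truth label per assigned window: the RE class with maximal bp coverage,
# ties broken by RE_CLASSES priority; NA when the window has no annotated bp
.window_truth <- function(assign, annot) {
  ov <- .class_overlap_bp(assign$chrom, assign$start, assign$end, annot)
  .argmax_class(ov)
}

#' Region-level confusion counts per RE class
#'
#' Every evaluated window contributes to the counts of each class A: a true
#' positive is a window both assigned to A and whose annotation coverage is
#' maximized in A; false positives are assigned to A without maximal
#' coverage in A; false negatives have maximal coverage in A but a
#' different assignment; true negatives are the rest. Windows with zero
#' annotated bp are excluded. With `cfg$rpkm_floor > 0` only windows whose
#' maximum raw RPKM reaches the floor are evaluated (supply `raw_signal`);
#' with `cfg$exclude_promoters` truth-promoter windows are dropped first.
#'
#' @param assign A `state_assignment` (or `window_matches`).
#' @param annot An [annotation_track()].
#' @param cfg An [eval_config()].
#' @param raw_signal Raw (unnormalized) signal tracks; required when
#'   `cfg$rpkm_floor > 0`.
#' @return A `confusion_counts` data frame: class, tp, fp, tn, fn.
#' @export
confusion <- function(assign, annot, cfg = eval_config(),
                      raw_signal = NULL) {
  truth <- .window_truth(assign, annot)
  keep <- !is.na(truth)
  if (cfg$rpkm_floor > 0) {
    if (is.null(raw_signal))
      stop("raw_signal is required when rpkm_floor > 0")
    mx <- .window_max_signal(raw_signal, assign$chrom, assign$start,
                             assign$end)
    keep <- keep & mx >= cfg$rpkm_floor
  }
  if (cfg$exclude_promoters) keep <- keep & truth != "promoter"
  truth <- truth[keep]
  assigned <- assign$label[keep]
  out <- data.frame(class = RE_CLASSES, tp = 0L, fp = 0L, tn = 0L, fn = 0L,
                    stringsAsFactors = FALSE)
  for (i in seq_along(RE_CLASSES)) {
    A <- RE_CLASSES[i]
    out$tp[i] <- sum(assigned == A & truth == A)
    out$fp[i] <- sum(assigned == A & truth != A)
    out$fn[i] <- sum(assigned != A & truth == A)
    out$tn[i] <- sum(assigned != A & truth != A)
  }
  class(out) <- c("confusion_counts", "data.frame")
  out
}

#' Precision and recall from confusion counts
#'
#' `precision = tp / (tp + fp)` and `recall = tp / (tp + fn)`. A zero
#' denominator yields `NA` (reported as N/A: no shapes were learned or no
#' regions carried that truth).
#'
#' @param cc A `confusion_counts` data frame.
#' @param class Optional single RE class; default returns all classes.
#' @return Data frame with class, precision, recall (plus the counts).
#' @export
precision_recall <- function(cc, class = NULL) {
  d <- if (is.null(class)) cc else cc[cc$class %in% class, , drop = FALSE]
  prec <- ifelse(d$tp + d$fp > 0, d$tp / (d$tp + d$fp), NA_real_)
  rec <- ifelse(d$tp + d$fn > 0, d$tp / (d$tp + d$fn), NA_real_)
  data.frame(class = d$class, precision = prec, recall = rec,
             tp = d$tp, fp = d$fp, tn = d$tn, fn = d$fn,
             stringsAsFactors = FALSE)
}

#' Area under the precision-recall curve
#'
#' Step-wise PR-AUC over achieved points: thresholds sweep the distinct
#' scores in decreasing order and the area is the sum of recall increments
#' times the precision at each achieved point (no interpolation). Invariant
#' to strictly monotone transforms of the scores.
#'
#' @param scores Numeric ranking score per region (higher = more
#'   enhancer-like).
#' @param truth Logical (or 0/1) enhancer flag per region.
#' @return AUC in \[0, 1\].
#' @export
enhancer_pr_auc <- function(scores, truth) {
  truth <- as.logical(truth)
  if (length(scores) != length(truth)) stop("scores/truth length mismatch")
  if (!any(truth)) stop("PR-AUC needs at least one positive region")
  if (all(truth)) stop("PR-AUC needs at least one negative region")
  thr <- sort(unique(scores), decreasing = TRUE)
  npos <- sum(truth)
  auc <- 0
  prev_rec <- 0
  for (t in thr) {
    pred <- scores >= t
    tp <- sum(pred & truth)
    prec <- tp / sum(pred)
    rec <- tp / npos
    auc <- auc + (rec - prev_rec) * prec
    prev_rec <- rec
  }
  auc
}

#' Wilcoxon rank-sum (Mann-Whitney) test
#'
#' Thin wrapper over [stats::wilcox.test()]. The reported statistic is the
#' Mann-Whitney U of `x` (number of (x, y) pairs with x > y, counting ties
#' as 1/2). `alternative = "greater"` tests whether `y` is stochastically
#' greater than `x` (small U of `x` gives small p). The p-value is exact
#' for combined sample size <= 20 without ties, and uses the normal
#' approximation with tie correction otherwise. If every value in both
#' samples is identical the p-value is 1.
#'
#' @param x,y Numeric samples.
#' @param alternative `"two.sided"` or `"greater"` (y greater than x).
#' @return List with `statistic` (U of x), `p.value`, `alternative`.
#' @export
rank_sum_test <- function(x, y, alternative = c("two.sided", "greater")) {
  alternative <- match.arg(alternative)
  if (!length(x) || !length(y)) stop("both samples must be non-empty")
  U <- sum(outer(x, y, `>`)) + 0.5 * sum(outer(x, y, `==`))
  if (length(unique(c(x, y))) == 1L)
    return(list(statistic = U, p.value = 1, alternative = alternative))
  ties <- anyDuplicated(c(x, y)) > 0
  exact <- (length(x) + length(y) <= 20) && !ties
  alt <- if (alternative == "greater") "less" else "two.sided"
  p <- suppressWarnings(
    stats::wilcox.test(x, y, alternative = alt, exact = exact,
                       correct = !exact)$p.value)
  list(statistic = U, p.value = p, alternative = alternative)
}

#' Davies-Bouldin index of a region clustering
#'
#' Standard DB index over the clusters induced by a region-to-shape
#' assignment: the mean over clusters of the maximal
#' `(s_i + s_j) / d_ij`, where `s` is the mean Euclidean distance of a
#' cluster's regions to its centroid and `d` the distance between
#' centroids. Used as a diagnostic when choosing the region size.
#' Coincident centroids make the index infinite.
#'
#' @param regions A `region_set` or matrix of regions.
#' @param assignments Cluster (shape) id per region.
#' @return DB index (>= 0, possibly `Inf`).
#' @export
davies_bouldin <- function(regions, assignments) {
  mat <- .as_region_matrix(regions)
  f <- factor(assignments)
  if (nlevels(f) < 2L) stop("need at least 2 non-empty clusters")
  cent <- apply(mat, 2L, tapply, f, mean)
  s <- vapply(levels(f), function(l) {
    rows <- mat[f == l, , drop = FALSE]
    mean(sqrt(rowSums((rows - matrix(cent[l, ], nrow(rows), ncol(rows),
                                     byrow = TRUE))^2)))
  }, 0)
  k <- nlevels(f)
  r <- numeric(k)
  for (i in seq_len(k)) {
    ratios <- vapply(seq_len(k)[-i], function(j) {
      d <- sqrt(sum((cent[i, ] - cent[j, ])^2))
      if (d == 0) Inf else (s[i] + s[j]) / d
    }, 0)
    r[i] <- max(ratios)
  }
  mean(r)
}

#' Random train/test chromosome splits
#'
#' Seeded random splits for cross-chromosome robustness evaluation (e.g.
#' training on 11 of 22 autosomes and testing on the rest).
#'
#' @param chroms Character vector of chromosome names.
#' @param n_train Number of training chromosomes per split.
#' @param n_iter Number of splits (default 100).
#' @param seed Integer seed.
#' @return List of `n_iter` lists with elements `train` and `test`
#'   (disjoint, union = `chroms`).
#' @export
cross_chromosome_split <- function(chroms, n_train, n_iter = 100, seed = 1) {
  if (n_train >= length(chroms))
    stop("n_train must be smaller than the number of chromosomes")
  set.seed(seed)
  lapply(seq_len(n_iter), function(i) {
    tr <- sort(sample(chroms, n_train))
    list(train = tr, test = setdiff(chroms, tr))
  })
}

#' Write an evaluation report
#'
#' Writes the per-class precision/recall table as TSV and a JSON summary.
#'
#' @param pr A [precision_recall()] table.
#' @param path Output TSV path; the JSON summary goes to
#'   `sub("\\\\.tsv$", ".json", path)`.
#' @return `path`, invisibly.
#' @export
write_evaluation <- function(pr, path) {
  utils::write.table(pr, path, sep = "\t", quote = FALSE, row.names = FALSE)
  js <- sub("\\.tsv$", ".json", path)
  if (identical(js, path)) js <- paste0(path, ".json")
  summary <- lapply(seq_len(nrow(pr)), function(i)
    list(precision = pr$precision[i], recall = pr$recall[i]))
  names(summary) <- pr$class
  jsonlite::write_json(summary, js, auto_unbox = TRUE, digits = NA,
                       na = "null")
  invisible(path)
}
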