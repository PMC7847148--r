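#' Shape library
#'
#' A flat, non-redundant set of learned shapes: a numeric matrix with one
#' named shape per row, plus a provenance map from each retained shape to
#' the original node names it absorbed.
#'
#' @param shapes Numeric matrix, one shape per row, unique rownames.
#' @param provenance Named list mapping each retained shape name to its
#'   constituent node names (defaults to each shape standing for itself).
#' @return An object of class `shape_library`.
#' @export
shape_library <- function(shapes, provenance = NULL) {
  shapes <- .shape_matrix(shapes)
  nm <- rownames(shapes)
  if (anyDuplicated(nm)) stop("shape names must be unique")
  if (is.null(provenance)) {
    provenance <- as.list(nm)
    names(provenance) <- nm
  }
  structure(list(shapes = shapes, provenance = provenance),
            class = "shape_library")
}

#' @export
print.shape_library <- function(x, ...) {
  cat(sprintf("<shape_library> %d shapes of %d bins\n",
              nrow(x$shapes), ncol(x$shapes)))
  invisible(x)
}

#' @export
length.shape_library <- function(x) nrow(x$shapes)

#' Merge shift-equivalent learned shapes
#'
#' Shapes learned on a grid can be shifted versions of one another.
#' This greedy agglomeration repeatedly takes the highest-scoring pair with
#' maximum normalized cross-correlation (over lags within `max_lag`) at or
#' above `threshold`, and replaces the pair with its lag-aligned
#' element-wise mean (positions covered by only one shape keep that shape's
#' value). Ties are broken toward the lexicographically first name pair.
#' The merged shape keeps the lexicographically first constituent's name;
#' constituents are recorded in the provenance map. The result satisfies the
#' library invariant that no retained pair reaches the threshold.
#'
#' When the input is a trained `som_grid` carrying final best-match support
#' counts, nodes that win no training region (dead units) are dropped
#' before merging: their weights are frozen mid-training transients that
#' would otherwise bridge distinct shape families into spurious merges.
#'
#' @param shapes A `som_grid`, [shape_library()], or named matrix of shapes.
#' @param threshold Merge threshold in (0, 1) (default 0.75).
#' @param max_lag Maximum absolute alignment shift in bins (default 20,
#'   one quarter of an 80-bin shape).
#' @param weights Optional per-shape weights for the merge combiner (one
#'   per row of `shapes`). Merging averages the aligned pair weighted by
#'   these (a trained grid supplies its per-node region support), so the
#'   combined shape approximates the mean over member regions rather than
#'   over nodes and a dominant shape is not diluted by a faint variant.
#'   Default: equal weights.
#' @return A [shape_library()] (merged weights kept in the `"weight"`
#'   attribute).
#' @export
merge_shapes <- function(shapes, threshold = 0.75, max_lag = 20,
                         weights = NULL) {
  if (threshold <= 0 || threshold >= 1)
    stop("threshold must be in (0, 1)")
  M <- .shape_matrix(shapes)
  if (inherits(shapes, "som_grid") && !is.null(shapes$support) &&
      any(shapes$support > 0)) {
    # drop dead units: their weights are frozen mid-training transients
    # that would bridge otherwise distinct shape families
    if (is.null(weights)) weights <- shapes$support[shapes$support > 0]
    M <- M[shapes$support > 0, , drop = FALSE]
  }
  if (is.null(weights)) weights <- rep(1, nrow(M))
  stopifnot(length(weights) == nrow(M), all(weights > 0))
  wts <- as.numeric(weights)
  nm <- rownames(M)
  prov <- as.list(nm)
  names(prov) <- nm
  if (nrow(M) > 1L) {
    px <- .pairwise_max_ncc(M, max_lag)
    S <- px$score; L <- px$lag
    diag(S) <- -Inf
    repeat {
      top <- max(S)
      if (top < threshold || !is.finite(top)) break
      hit <- which(S == top, arr.ind = TRUE)
      hit <- hit[hit[, 1L] != hit[, 2L], , drop = FALSE]
      key <- paste(pmin(nm[hit[, 1L]], nm[hit[, 2L]]),
                   pmax(nm[hit[, 1L]], nm[hit[, 2L]]), sep = "\r")
      pick <- hit[order(key)[1L], ]
      i <- pick[1L]; j <- pick[2L]
      lag <- L[i, j]                       # j shifted right by lag w.r.t. i
      a <- M[i, ]; b <- M[j, ]
      wa <- wts[i]; wb <- wts[j]
      n <- length(a)
      bk <- seq_len(n) - lag
      merged <- a
      inb <- bk >= 1L & bk <= n
      merged[inb] <- (wa * a[inb] + wb * b[bk[inb]]) / (wa + wb)
      keep_name <- min(nm[i], nm[j])
      members <- sort(unique(c(prov[[nm[i]]], prov[[nm[j]]])))
      prov[[nm[i]]] <- NULL; prov[[nm[j]]] <- NULL
      prov[[keep_name]] <- members
      M[i, ] <- merged
      nm[i] <- keep_name
      wts[i] <- wa + wb
      M <- M[-j, , drop = FALSE]; nm <- nm[-j]; wts <- wts[-j]
      S <- S[-j, -j, drop = FALSE]; L <- L[-j, -j, drop = FALSE]
      if (nrow(M) == 1L) break
      ii <- if (j < i) i - 1L else i
      up <- .vec_max_ncc(M[ii, ], M, max_lag)
      S[ii, ] <- up$score; L[ii, ] <- up$lag
      S[, ii] <- up$score; L[, ii] <- -up$lag
      S[ii, ii] <- -Inf
    }
  }
  rownames(M) <- nm
  out <- shape_library(M, prov[nm])
  attr(out, "weight") <- stats::setNames(wts, nm)
  out
}
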