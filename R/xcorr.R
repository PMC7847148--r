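#' Normalized cross-correlation at a fixed lag
#'
#' Pearson-style normalized cross-correlation of the overlapping segments of
#' two vectors, with the second vector shifted right by `lag` bins (so
#' `b[i]` is aligned with `a[i + lag]`). Both segments are mean-centered and
#' variance-normalized over the overlap, so the score is invariant to
#' positive affine rescaling of either vector. If either overlap segment has
#' zero variance the vectors are defined as uncorrelated and the score is 0:
#' flat regions never spuriously match flat shapes through the correlation
#' route (magnitude handles those instead).
#'
#' @param a,b Numeric vectors.
#' @param lag Signed integer shift of `b` relative to `a`, in bins.
#' @return Correlation in \[-1, 1\].
#' @examples
#' ncc_at_lag(c(0, 0, 1, 0), c(0, 1, 0, 0), 1)  # shifted copy: 1
#' @export
ncc_at_lag <- function(a, b, lag = 0L) {
  n <- length(a); m <- length(b)
  lag <- as.integer(lag)
  lo <- max(1L, 1L + lag); hi <- min(n, m + lag)
  if (hi - lo < 1L)
    stop("overlap at this lag is shorter than 2 bins")
  ia <- lo:hi
  x <- a[ia]
  y <- b[ia - lag]
  x <- x - mean(x); y <- y - mean(y)
  sx <- sqrt(sum(x * x)); sy <- sqrt(sum(y * y))
  if (sx == 0 || sy == 0) return(0)
  sum(x * y) / (sx * sy)
}

.xcorr_result <- function(score, lag) {
  structure(list(score = score, lag = as.integer(lag)),
            class = "xcorr_result")
}

#' @export
print.xcorr_result <- function(x, ...) {
  cat(sprintf("<xcorr> score %.4f at lag %d\n", x$score, x$lag))
  invisible(x)
}

#' Maximum normalized cross-correlation over a lag window
#'
#' Maximizes [ncc_at_lag()] over lags in `[-max_lag, +max_lag]`. Ties are
#' broken toward smaller absolute lag, then toward the negative lag.
#'
#' @param a,b Numeric vectors of equal length.
#' @param max_lag Maximum absolute lag in bins (`0 <= max_lag < length`).
#' @return An `xcorr_result` with fields `score` and `lag` (offset of `b`
#'   relative to `a` at the maximizing alignment).
#' @export
max_ncc <- function(a, b, max_lag = 0L) {
  if (length(a) != length(b)) stop("vectors must have equal length")
  max_lag <- as.integer(max_lag)
  if (max_lag < 0L || max_lag >= length(a))
    stop("max_lag must satisfy 0 <= max_lag < length")
  best <- -Inf; best_lag <- 0L
  for (l in .lag_preference_order(max_lag)) {
    s <- ncc_at_lag(a, b, l)
    if (s > best) { best <- s; best_lag <- l }
  }
  .xcorr_result(best, best_lag)
}

# 0, -1, +1, -2, +2, ...: scanning in this order with strict improvement
# implements the tie-break (smaller |lag|, then negative)
.lag_preference_order <- function(max_lag) {
  if (max_lag == 0L) return(0L)
  c(0L, as.integer(rbind(-seq_len(max_lag), seq_len(max_lag))))
}

#' Containment score of a shape within a longer window
#'
#' Slides a shape along a window (length >= shape length) and returns the
#' maximum normalized cross-correlation over all start offsets, evaluating
#' containment of shape rather than exact match. Ties are broken toward the
#' smallest offset.
#'
#' @param window Numeric vector (the longer signal window).
#' @param shape Numeric vector (the shape), not longer than `window`.
#' @return An `xcorr_result`; `lag` is the best start offset (0-based bins).
#' @export
containment_score <- function(window, shape) {
  nw <- length(window); ns <- length(shape)
  if (nw < ns) stop("window must be at least as long as shape")
  best <- -Inf; best_off <- 0L
  s0 <- shape - mean(shape)
  ss <- sqrt(sum(s0 * s0))
  for (off in 0:(nw - ns)) {
    w <- window[(off + 1L):(off + ns)]
    w0 <- w - mean(w)
    sw <- sqrt(sum(w0 * w0))
    sc <- if (ss == 0 || sw == 0) 0 else sum(w0 * s0) / (ss * sw)
    if (sc > best) { best <- sc; best_off <- off }
  }
  .xcorr_result(best, best_off)
}

## ---- internal vectorized kernels ------------------------------------------

# row-center a matrix and return centered rows + row norms
.center_rows <- function(M) {
  Mc <- M - rowMeans(M)
  list(m = Mc, s = sqrt(rowSums(Mc * Mc)))
}

# lag-0 NCC between every row of X and every row of Y (zero-variance rows
# score 0); equals the Pearson correlation matrix of the rows
.ncc0_cross <- function(X, Y) {
  cx <- .center_rows(X); cy <- .center_rows(Y)
  sx <- cx$s; sy <- cy$s
  sx0 <- sx == 0; sy0 <- sy == 0
  sx[sx0] <- 1; sy[sy0] <- 1
  R <- (cx$m %*% t(cy$m)) / outer(sx, sy)
  if (any(sx0)) R[sx0, ] <- 0
  if (any(sy0)) R[, sy0] <- 0
  R
}

# max NCC over [-max_lag, max_lag] for every ordered pair of rows of M;
# score[i, j] and lag[i, j] describe row j shifted relative to row i.
# Scanned in tie-preference order with strict improvement.
.pairwise_max_ncc <- function(M, max_lag) {
  n <- ncol(M)
  S <- .ncc0_cross(M, M)
  L <- matrix(0L, nrow(M), nrow(M))
  for (l in seq_len(min(max_lag, n - 2L))) {
    # P[i, j] = ncc_at_lag(row i, row j, +l)
    P <- .ncc0_cross(M[, (1L + l):n, drop = FALSE],
                     M[, 1L:(n - l), drop = FALSE])
    Tn <- t(P)  # Tn[i, j] = ncc_at_lag(row i, row j, -l)
    upd <- Tn > S
    S[upd] <- Tn[upd]; L[upd] <- -l
    upd <- P > S
    S[upd] <- P[upd]; L[upd] <- l
  }
  list(score = S, lag = L)
}

# max NCC of vector v against each row of M over [-max_lag, max_lag];
# lag describes the row shifted relative to v (same convention as above
# with i = v)
.vec_max_ncc <- function(v, M, max_lag) {
  r <- .pairwise_max_ncc(rbind(v, M), max_lag)
  list(score = r$score[1L, -1L], lag = r$lag[1L, -1L])
}

# best containment score of every shape (rows of S, length ns) within every
# window (rows of W, length nw >= ns); returns nw x nshape score matrix
.containment_cross <- function(W, S) {
  nw <- ncol(W); ns <- ncol(S)
  best <- matrix(-Inf, nrow(W), nrow(S))
  for (off in 0:(nw - ns)) {
    R <- .ncc0_cross(W[, (off + 1L):(off + ns), drop = FALSE], S)
    best <- pmax(best, R)
  }
  best
}
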