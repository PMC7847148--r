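#' Training settings for the variable-neighborhood SOM
#'
#' @param rows,cols Grid dimensions (default 10 x 10).
#' @param epochs Number of passes over the training regions (default 100).
#' @param batch_size Mini-batch size (default 100); `batch_size = 1` is the
#'   classic per-sample update.
#' @param alpha0 Initial learning rate in (0, 1] (default 0.2).
#' @param radius0 Base neighborhood radius; defaults to `max(rows, cols)/2`.
#' @param radius_end Base radius at the end of training (default 0.1, well
#'   below one grid cell, so that late training updates each node from its
#'   own winners only and low-signal nodes are wiped clean of the blends
#'   accumulated while neighborhoods were wide).
#' @param alpha_min Learning-rate floor (default 0.1): the learning rate
#'   decays exponentially from `alpha0` to `alpha_min` over training rather
#'   than to zero, leaving the late, narrow-neighborhood phase enough gain
#'   to erase mid-training contamination.
#' @param match_resolution Best-match scores are quantized to this
#'   resolution before the argmax (default 0.01). Correlation differences
#'   below the noise level carry no information; without quantization,
#'   regions with identical content split arbitrarily across near-identical
#'   nodes instead of concentrating on one via the lowest-index tie-break.
#' @param lambda Neighborhood scaling strength (default 1). With
#'   `lambda = 0` the trainer is an ordinary mini-batch SOM; larger values
#'   widen the update neighborhood of nodes with high summits, boosting the
#'   influence of high-maximum shapes in accessibility signal that is
#'   heavily imbalanced toward flat, low-signal regions.
#' @param seed Integer seed driving initialization and epoch shuffles.
#' @return A `som_config` list.
#' @export
som_config <- function(rows = 10, cols = 10, epochs = 100, batch_size = 100,
                       alpha0 = 0.2, radius0 = max(rows, cols) / 2,
                       radius_end = 0.1, alpha_min = 0.1,
                       match_resolution = 0.01, lambda = 1, seed = 1) {
  stopifnot(rows >= 1, cols >= 1, epochs >= 1, batch_size >= 1,
            alpha0 > 0, alpha0 <= 1, radius0 > 0, radius_end > 0,
            radius_end <= radius0, alpha_min > 0, alpha_min <= alpha0,
            match_resolution > 0, lambda >= 0)
  structure(list(rows = as.integer(rows), cols = as.integer(cols),
                 epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 alpha0 = alpha0, radius0 = radius0,
                 radius_end = radius_end, alpha_min = alpha_min,
                 match_resolution = match_resolution,
                 lambda = lambda, seed = as.integer(seed)),
            class = "som_config")
}

.as_region_matrix <- function(regions) {
  if (inherits(regions, "region_set")) return(regions$mat)
  if (is.matrix(regions)) return(regions)
  if (is.list(regions)) {
    lens <- lengths(regions)
    if (length(unique(lens)) != 1L)
      stop("regions have inconsistent vector lengths")
    return(do.call(rbind, regions))
  }
  stop("cannot interpret regions")
}

.make_grid <- function(W, cfg) {
  k <- cfg$rows * cfg$cols
  node_row <- (seq_len(k) - 1L) %/% cfg$cols + 1L
  node_col <- (seq_len(k) - 1L) %% cfg$cols + 1L
  rownames(W) <- sprintf("%d.%d", node_row, node_col)
  structure(list(rows = cfg$rows, cols = cfg$cols, weights = W,
                 max_weight = W[cbind(seq_len(k), max.col(W, ties.method = "first"))],
                 node_row = node_row, node_col = node_col,
                 config = cfg),
            class = "som_grid")
}

.init_weights <- function(mat, cfg) {
  n <- nrow(mat)
  if (n < 1L) stop("no training regions")
  idx <- rep(sample.int(n), length.out = cfg$rows * cfg$cols)
  mat[idx, , drop = FALSE]
}

#' Initialize a SOM grid from training regions
#'
#' Node weights are initialized by sampling training regions without
#' replacement (cycling through a fresh permutation if the grid has more
#' nodes than there are regions), seeded by `cfg$seed`.
#'
#' @param regions A `region_set`, matrix (regions as rows), or list of
#'   equal-length vectors.
#' @param cfg A [som_config()].
#' @return A `som_grid` (nodes in row-major order).
#' @export
initialize_grid <- function(regions, cfg = som_config()) {
  mat <- .as_region_matrix(regions)
  set.seed(cfg$seed)
  .make_grid(.init_weights(mat, cfg), cfg)
}

#' @export
print.som_grid <- function(x, ...) {
  cat(sprintf("<som_grid> %d x %d nodes, %d bins per shape, summit range [%.4g, %.4g]\n",
              x$rows, x$cols, ncol(x$weights),
              min(x$max_weight), max(x$max_weight)))
  invisible(x)
}

#' Variable neighborhood radius
#'
#' The neighborhood radius of a node at training step `t` is
#' `radius0 * exp(-t / T) * (1 + lambda * max_weight / global_max)`, with
#' `T = total_steps / log(radius0 / radius_end)` so that the base radius
#' decays from `radius0` to `radius_end` over training. The scaling factor
#' multiplies the classic exponentially decaying SOM radius by a term that
#' grows with the node's maximum weight, so high-summit shapes update wider
#' neighborhoods. With `lambda = 0` this reduces to the classic radius,
#' identical for all nodes.
#'
#' @param max_weight Node maximum weight (may be a vector).
#' @param t Training step index (0-based).
#' @param cfg A [som_config()].
#' @param global_max Maximum of `max_weight` over all nodes; must be > 0.
#' @param total_steps Total number of update steps
#'   (`epochs * ceiling(n/batch_size)`); defaults to `cfg$epochs`.
#' @return Radius (same length as `max_weight`).
#' @export
neighborhood_radius <- function(max_weight, t, cfg, global_max,
                                total_steps = cfg$epochs) {
  if (global_max <= 0) stop("global_max must be positive")
  if (t < 0) stop("t must be non-negative")
  lr <- log(cfg$radius0 / cfg$radius_end)
  decay <- if (lr > 0) exp(-t * lr / total_steps) else 1
  cfg$radius0 * decay * (1 + cfg$lambda * max_weight / global_max)
}

#' Train a self-organizing map with variable neighborhoods
#'
#' Mini-batch SOM training on segmented signal regions. Each epoch the
#' regions are shuffled (seeded); within a batch every region is mapped to
#' its best-matching node by lag-0 normalized cross-correlation (ties to the
#' lowest row-major node index), and each node is then pulled toward the
#' kernel-weighted mean of the batch members whose winners' neighborhoods
#' reach it: `w <- w + alpha(t) * hbar * (xbar - w)`, with a Gaussian
#' kernel `h = exp(-d^2 / (2 r^2))` over the Chebyshev grid distance `d`
#' and the winner's [neighborhood_radius()] `r`, `xbar` the h-weighted
#' member mean and `hbar` the mean kernel weight. High-summit winners thus
#' spread their shape over a wider grid patch, countering the imbalance of
#' accessibility signal toward flat regions; with `batch_size = 1` the rule
#' is exactly the classic per-sample SOM update. Node maxima (and hence the
#' variable
#' radii) are refreshed after every batch. Since `alpha(t) * h <= 1` and
#' `xbar` is a convex combination of inputs, node weights stay within the
#' range of the training values.
#'
#' @param regions A `region_set`, matrix, or list of equal-length vectors.
#' @param cfg A [som_config()].
#' @return A trained `som_grid`.
#' @export
train_som <- function(regions, cfg = som_config()) {
  mat <- .as_region_matrix(regions)
  n <- nrow(mat)
  if (n < 1L) stop("no training regions")
  set.seed(cfg$seed)
  W <- .init_weights(mat, cfg)
  k <- cfg$rows * cfg$cols
  node_row <- (seq_len(k) - 1L) %/% cfg$cols + 1L
  node_col <- (seq_len(k) - 1L) %% cfg$cols + 1L
  D <- pmax(abs(outer(node_row, node_row, `-`)),
            abs(outer(node_col, node_col, `-`)))
  steps_per_epoch <- ceiling(n / cfg$batch_size)
  total_steps <- cfg$epochs * steps_per_epoch
  lr <- log(cfg$radius0 / cfg$radius_end)
  inv_T <- if (lr > 0) lr / total_steps else 0
  la <- log(cfg$alpha0 / cfg$alpha_min)
  inv_A <- if (la > 0) la / total_steps else 0
  mw <- W[cbind(seq_len(k), max.col(W, ties.method = "first"))]
  t <- 0
  for (e in seq_len(cfg$epochs)) {
    ord <- sample.int(n)
    for (b in seq_len(steps_per_epoch)) {
      i0 <- (b - 1L) * cfg$batch_size + 1L
      chunk <- ord[i0:min(i0 + cfg$batch_size - 1L, n)]
      if (!length(chunk)) next
      X <- mat[chunk, , drop = FALSE]
      R <- .ncc0_cross(X, W)
      # quantize scores so sub-noise differences behave as ties (-> lowest
      # node index), concentrating equivalent regions on one node
      bmu <- max.col(round(R / cfg$match_resolution),
                     ties.method = "first")
      alpha <- cfg$alpha0 * exp(-t * inv_A)
      gm <- max(mw)
      if (gm <= 0)
        stop("all node maxima are zero; cannot scale neighborhoods")
      rad <- cfg$radius0 * exp(-t * inv_T) * (1 + cfg$lambda * mw / gm)
      radm <- rad[bmu]                      # winner's (variable) radius
      Dm <- D[bmu, , drop = FALSE]          # distance winner -> every node
      # a batch member reaches every node inside its winner's neighborhood:
      # high-summit winners spread their shape over a wider grid patch,
      # countering the imbalance toward flat low-accessibility regions
      member <- Dm <= radm
      H <- exp(-Dm * Dm / (2 * radm * radm)) * member
      hsum <- colSums(H)
      counts <- colSums(member)
      upd <- which(counts > 0)
      if (length(upd)) {
        # kernel-weighted member mean; step size alpha * mean kernel weight
        # (<= alpha, so the update stays a convex combination)
        xbar <- (t(H[, upd, drop = FALSE]) %*% X) / hsum[upd]
        hbar <- hsum[upd] / counts[upd]
        W[upd, ] <- W[upd, , drop = FALSE] +
          (alpha * hbar) * (xbar - W[upd, , drop = FALSE])
        bad <- !is.finite(W[upd, , drop = FALSE])
        if (any(bad))
          stop("non-finite weight produced at node ",
               upd[which(rowSums(bad) > 0)[1L]])
        mw <- W[cbind(seq_len(k), max.col(W, ties.method = "first"))]
      }
      t <- t + 1
    }
  }
  grid <- .make_grid(W, cfg)
  # final best-match partition: nodes that win no region are dead units
  # whose weights are frozen mid-training transients
  final_bmu <- max.col(round(.ncc0_cross(mat, W) / cfg$match_resolution),
                       ties.method = "first")
  grid$support <- tabulate(final_bmu, nbins = k)
  grid
}

#' Write learned shapes to a plain-text shape file
#'
#' One line per shape: `name,w1,w2,...` with weights at full precision.
#' Grid nodes are named `<celltype>_<chrom>_<row>.<col>`.
#'
#' @param x A `som_grid` or [shape_library()].
#' @param path Output file path.
#' @param celltype,chrom Name components used for `som_grid` nodes.
#' @return `path`, invisibly.
#' @export
write_shapes <- function(x, path, celltype = "sample", chrom = "genome") {
  M <- .shape_matrix(x)
  nm <- rownames(M)
  if (inherits(x, "som_grid"))
    nm <- sprintf("%s_%s_%s", celltype, chrom, nm)
  writeLines(paste(nm, apply(M, 1L, function(w)
    paste(sprintf("%.17g", w), collapse = ",")), sep = ","), path)
  invisible(path)
}

#' Read a shape file written by [write_shapes()]
#'
#' @param path Shape file path.
#' @return A [shape_library()].
#' @export
read_shapes <- function(path) {
  if (!file.exists(path)) stop("shape file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, ",")
  nm <- vapply(parts, `[[`, "", 1L)
  M <- do.call(rbind, lapply(parts, function(p) as.numeric(p[-1L])))
  rownames(M) <- nm
  shape_library(M)
}

.shape_matrix <- function(x) {
  if (inherits(x, "som_grid")) return(x$weights)
  if (inherits(x, "shape_library")) return(x$shapes)
  if (is.matrix(x)) {
    if (is.null(rownames(x)))
      rownames(x) <- sprintf("s%03d", seq_len(nrow(x)))
    return(x)
  }
  stop("expected a som_grid, shape_library, or named matrix")
}

# build a som_config from the flat workflow configuration
.som_config_from <- function(config) {
  som_config(rows = config$rows, cols = config$cols,
             epochs = config$epochs, batch_size = config$batch_size,
             alpha0 = config$alpha0, radius0 = config$radius0,
             radius_end = config$radius_end, alpha_min = config$alpha_min,
             match_resolution = config$match_resolution,
             lambda = config$lambda, seed = config$seed)
}
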