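#' Fit a SOM-VN chromatin-state shape model
#'
#' Runs the full learning workflow on raw binned accessibility signal:
#' per-chromosome percentile normalization ([normalize_signal()]),
#' segmentation into disjoint training regions ([segment()]), training of
#' the variable-neighborhood self-organizing map ([train_som()]), merging of
#' shift-equivalent shapes ([merge_shapes()]), and association of the
#' merged shapes with regulatory-element chromatin states
#' ([associate_shapes()]).
#'
#' @param signal Raw signal: a [binned_signal()] or named list of them
#'   (one per chromosome), in RPKM per bin.
#' @param annotations An [annotation_track()] of ChromHMM-style states on
#'   the same coordinates.
#' @param config A [somvn_config()] gathering all tunables.
#' @return An object of class `somvn` with components `grid` (trained
#'   `som_grid`), `library` ([shape_library()]), `association`
#'   (`shape_assoc`), `regions` (training `region_set`, normalized),
#'   `config`, and `call`.
#' @seealso [predict.somvn()] to assign states to new signal.
#' @export
somvn <- function(signal, annotations, config = somvn_config()) {
  cl <- match.call()
  sigs <- .as_signal_list(signal)
  norm <- normalize_signal(sigs, config$normalization_percentile)
  regions <- segment(norm, region_size = config$region_size,
                     step = config$region_size)
  if (!n_regions(regions))
    stop("no training regions: every chromosome is shorter than region_size")
  grid <- train_som(regions, .som_config_from(config))
  library <- merge_shapes(grid, threshold = config$merge_threshold,
                          max_lag = config$merge_max_lag)
  association <- associate_shapes(regions, library, annotations,
                                  cutoff = config$association_cutoff)
  structure(list(grid = grid, library = library, association = association,
                 regions = regions, config = config, call = cl),
            class = "somvn")
}

#' @export
print.somvn <- function(x, ...) {
  cat("SOM-VN chromatin-state shape model\n")
  cat(sprintf("  grid: %d x %d nodes -> %d merged shapes\n",
              x$grid$rows, x$grid$cols, length(x$library)))
  cat(sprintf("  training regions: %d of %d bp on %s\n",
              n_regions(x$regions), as.integer(x$config$region_size),
              paste(unique(x$regions$chrom), collapse = ", ")))
  tab <- table(x$association$label)
  cat("  shape labels:",
      paste(sprintf("%s=%d", names(tab), tab), collapse = ", "), "\n")
  invisible(x)
}

#' @method summary somvn
#' @export
summary.somvn <- function(object, ...) {
  out <- list(association = object$association,
              n_nodes = object$grid$rows * object$grid$cols,
              n_shapes = length(object$library),
              n_regions = n_regions(object$regions),
              config = object$config)
  class(out) <- "summary.somvn"
  out
}

#' @export
print.summary.somvn <- function(x, ...) {
  cat(sprintf("SOM-VN model: %d nodes merged to %d shapes, %d training regions\n\n",
              x$n_nodes, x$n_shapes, x$n_regions))
  print.data.frame(x$association, digits = 3)
  invisible(x)
}

#' @method coef somvn
#' @export
coef.somvn <- function(object, ...) object$library$shapes

#' Plot learned shapes colored by RE association
#'
#' @param x A fitted [somvn()] model.
#' @param ... Passed to [graphics::matplot()].
#' @method plot somvn
#' @export
plot.somvn <- function(x, ...) {
  S <- t(x$library$shapes)
  lab <- x$association$label[match(colnames(S), x$association$shape)]
  cols <- c(promoter = "forestgreen", enhancer = "royalblue",
            weak = "firebrick", unknown = "grey60")[lab]
  graphics::matplot(S, type = "l", lty = 1, col = cols,
                    xlab = "bin", ylab = "normalized signal", ...)
  graphics::legend("topright", legend = unique(lab),
                   col = cols[!duplicated(lab)], lty = 1, bty = "n")
  invisible(x)
}

#' Assign chromatin states to new signal
#'
#' Normalizes the new raw signal with the model's percentile scheme,
#' matches 8 kb overlapping windows against the learned shape library by
#' containment ([match_windows()]), and consolidates overlaps by dynamic
#' programming ([consolidate()]).
#'
#' @param object A fitted [somvn()] model.
#' @param newdata Raw [binned_signal()] or named list of them.
#' @param consolidate Return the consolidated non-overlapping assignment
#'   (default) or all overlapping window matches.
#' @param ... Unused.
#' @return A `state_assignment` (or `window_matches`) data frame.
#' @export
predict.somvn <- function(object, newdata, consolidate = TRUE, ...) {
  cfg <- object$config
  norm <- normalize_signal(.as_signal_list(newdata),
                           cfg$normalization_percentile)
  wm <- match_windows(norm, object$library, object$association,
                      window_size = cfg$window_size, step = cfg$window_step)
  if (consolidate) somvn::consolidate(wm) else wm
}
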