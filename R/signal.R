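#' Binned genome-wide signal
#'
#' A `binned_signal` holds one chromosome's coverage as an ordered vector of
#' fixed-width bin values (RPKM per bin), anchored at a genomic start
#' coordinate. Coordinates are 0-based, half-open (BED convention)
#' throughout the package.
#'
#' @param chrom Chromosome name.
#' @param values Numeric vector of non-negative, finite per-bin values.
#' @param start Genomic start (bp) of the first bin; must align to `bin_size`.
#' @param bin_size Bin width in bp (default 50).
#' @return An object of class `binned_signal`.
#' @examples
#' binned_signal("chr1", c(1, 0, 3))
#' @export
binned_signal <- function(chrom, values, start = 0, bin_size = 50) {
  stopifnot(is.character(chrom), length(chrom) == 1L)
  values <- as.numeric(values)
  if (length(values) < 1L)
    stop("binned_signal needs at least one bin")
  if (any(!is.finite(values)))
    stop("signal values must be finite")
  if (any(values < 0))
    stop("signal values must be non-negative")
  if (bin_size <= 0)
    stop("bin_size must be positive")
  if (start < 0 || start %% bin_size != 0)
    stop("start must be a non-negative multiple of bin_size")
  structure(
    list(chrom = chrom, start = as.numeric(start),
         bin_size = as.numeric(bin_size), values = values),
    class = "binned_signal")
}

#' @export
print.binned_signal <- function(x, ...) {
  cat(sprintf("<binned_signal> %s:%d-%d, %d bins of %d bp, max %.4g\n",
              x$chrom, x$start, x$start + length(x$values) * x$bin_size,
              length(x$values), as.integer(x$bin_size), max(x$values)))
  invisible(x)
}

#' @export
length.binned_signal <- function(x) length(x$values)

# accept a single binned_signal or a list of them; always return a named list
.as_signal_list <- function(x) {
  if (inherits(x, "binned_signal")) x <- list(x)
  if (!length(x) || !all(vapply(x, inherits, TRUE, "binned_signal")))
    stop("expected a binned_signal or a list of binned_signal objects")
  names(x) <- vapply(x, `[[`, "", "chrom")
  x
}

#' Chromosome lengths covered by a signal set
#'
#' @param sigs A `binned_signal` or list of them.
#' @return Named numeric vector of end coordinates (bp) per chromosome.
#' @export
signal_lengths <- function(sigs) {
  sigs <- .as_signal_list(sigs)
  vapply(sigs, function(s) s$start + length(s$values) * s$bin_size, 0)
}

#' Read binned signal from bedGraph or fixed-step WIG
#'
#' Parses a bedGraph (chrom, start, end, value; whitespace-delimited) or
#' fixed-step WIG file into one [binned_signal] per chromosome. Intervals
#' wider than `bin_size` are split into constant bins; gaps between intervals
#' are filled with 0 (inaccessible chromatin sits below the signal floor).
#'
#' @param path File path.
#' @param format `"bedgraph"` or `"wig"`.
#' @param bin_size Bin width in bp (default 50).
#' @return Named list of `binned_signal`, one per chromosome.
#' @export
read_signal <- function(path, format = c("bedgraph", "wig"), bin_size = 50) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("signal file not found: ", path)
  if (format == "bedgraph") {
    lines <- readLines(path)
    lines <- lines[nzchar(trimws(lines))]
    lines <- lines[!grepl("^(track|#|browser)", lines)]
    # bedGraph is whitespace-delimited; rtracklayer's reader wants tabs
    lines <- gsub("[ \t]+", "\t", trimws(lines))
    gr <- rtracklayer::import(text = paste(lines, collapse = "\n"),
                              format = "bedGraph")
  } else {
    gr <- rtracklayer::import(path, format = "wig")
  }
  out <- list()
  for (chrom in as.character(unique(GenomicRanges::seqnames(gr)))) {
    g <- gr[as.character(GenomicRanges::seqnames(gr)) == chrom]
    s0 <- GenomicRanges::start(g) - 1   # back to 0-based half-open
    e0 <- GenomicRanges::end(g)
    val <- as.numeric(g$score)
    o <- order(s0)
    s0 <- s0[o]; e0 <- e0[o]; val <- val[o]
    if (any(val < 0))
      stop("negative signal value on ", chrom)
    if (length(s0) > 1L && any(s0[-1L] < e0[-length(e0)]))
      stop("overlapping intervals on ", chrom)
    if (any((e0 - s0) %% bin_size != 0) || any(s0 %% bin_size != 0))
      stop("interval not aligned to a multiple of bin_size on ", chrom)
    first <- s0[1L]
    n_bins <- (e0[length(e0)] - first) / bin_size
    values <- numeric(n_bins)
    bi <- (s0 - first) / bin_size
    nb <- (e0 - s0) / bin_size
    idx <- sequence(nb, from = bi + 1L)
    values[idx] <- rep.int(val, nb)
    out[[chrom]] <- binned_signal(chrom, values, start = first,
                                  bin_size = bin_size)
  }
  out
}

#' Write binned signal as bedGraph
#'
#' Runs of equal value are collapsed into one interval; zero-valued runs are
#' omitted (they are re-created as gap fill on read), so
#' `read_signal(write_signal(x))` reproduces `x` exactly.
#'
#' @param sigs A `binned_signal` or list of them.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_signal <- function(sigs, path) {
  sigs <- .as_signal_list(sigs)
  con <- file(path, "w")
  on.exit(close(con))
  for (s in sigs) {
    r <- rle(s$values)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths
    keep <- r$values != 0
    # keep the first and last runs even when zero so the genomic anchor and
    # track length survive the round-trip (interior zero runs are re-created
    # as gap fill on read)
    keep[c(1L, length(keep))] <- TRUE
    writeLines(sprintf("%s\t%.0f\t%.0f\t%.17g", s$chrom,
                       s$start + starts[keep] * s$bin_size,
                       s$start + ends[keep] * s$bin_size,
                       r$values[keep]), con)
  }
  invisible(path)
}

#' Normalize a binned signal track
#'
#' Values are clipped at the per-chromosome `percentile` value P and divided
#' by P, so output lies in \[0, 1\]. This caps outlier summits without
#' destroying shape. Keep the raw track around for RPKM-floor evaluation; the
#' clipping value is stored in the `"scale"` attribute.
#'
#' @param sig A `binned_signal` or list of them.
#' @param percentile Percentile in (0, 100] used as the clipping value
#'   (default 99.9).
#' @return Normalized copy, same shape as the input. An all-zero chromosome
#'   is returned unchanged.
#' @export
normalize_signal <- function(sig, percentile = 99.9) {
  if (!inherits(sig, "binned_signal")) {
    return(lapply(.as_signal_list(sig), normalize_signal,
                  percentile = percentile))
  }
  if (percentile <= 0 || percentile > 100)
    stop("percentile must be in (0, 100]")
  p <- stats::quantile(sig$values, percentile / 100, names = FALSE)
  if (p <= 0) p <- max(sig$values)
  if (p <= 0) return(sig)          # all-zero chromosome
  out <- sig
  out$values <- pmin(sig$values, p) / p
  attr(out, "scale") <- p
  out
}

#' Segmentation / normalization settings
#'
#' @param region_size Training region size in bp (default 4000).
#' @param bin_size Bin width in bp (default 50).
#' @param normalization_percentile Clipping percentile for
#'   [normalize_signal()] (default 99.9).
#' @return A `seg_config` list.
#' @export
seg_config <- function(region_size = 4000, bin_size = 50,
                       normalization_percentile = 99.9) {
  if (region_size %% bin_size != 0)
    stop("region_size must be a multiple of bin_size")
  structure(list(region_size = region_size, bin_size = bin_size,
                 normalization_percentile = normalization_percentile,
                 region_size_bins = region_size / bin_size),
            class = "seg_config")
}

#' Segment a signal track into fixed-size regions
#'
#' Regions tile the chromosome starting at the signal's anchor, advancing by
#' `step` bp; a trailing partial region is dropped (padding would fabricate
#' shape). Training uses `step = region_size` (disjoint 4 kb regions);
#' assignment uses 8 kb regions stepped by 4 kb.
#'
#' @param sig A `binned_signal` or list of them.
#' @param region_size Region size in bp.
#' @param step Step between region starts in bp (default `region_size`).
#' @return A `region_set`: regions as rows of a matrix with genomic anchoring.
#' @export
segment <- function(sig, region_size = 4000, step = region_size) {
  if (!inherits(sig, "binned_signal")) {
    parts <- lapply(.as_signal_list(sig), segment,
                    region_size = region_size, step = step)
    return(do.call(c, parts))
  }
  bs <- sig$bin_size
  if (region_size %% bs != 0) stop("region_size must be a multiple of bin_size")
  if (step <= 0 || step %% bs != 0)
    stop("step must be a positive multiple of bin_size")
  rb <- region_size / bs
  sb <- step / bs
  n <- length(sig$values)
  if (n < rb) {
    return(region_set(matrix(numeric(0), 0, rb), character(0), numeric(0),
                      bin_size = bs))
  }
  first_bins <- seq.int(0L, n - rb, by = sb)
  mat <- matrix(sig$values[outer(seq_len(rb), first_bins, `+`)],
                nrow = length(first_bins), ncol = rb, byrow = TRUE)
  region_set(mat, rep(sig$chrom, length(first_bins)),
             sig$start + first_bins * bs, bin_size = bs)
}

#' Construct a region set
#'
#' @param mat Numeric matrix, one region per row.
#' @param chrom Chromosome per region.
#' @param start Genomic start (bp) per region.
#' @param bin_size Bin width in bp.
#' @return An object of class `region_set`.
#' @export
region_set <- function(mat, chrom, start, bin_size = 50) {
  mat <- as.matrix(mat)
  stopifnot(nrow(mat) == length(chrom), nrow(mat) == length(start))
  structure(list(mat = mat, chrom = as.character(chrom),
                 start = as.numeric(start),
                 end = as.numeric(start) + ncol(mat) * bin_size,
                 bin_size = bin_size),
            class = "region_set")
}

#' @export
c.region_set <- function(...) {
  parts <- list(...)
  stopifnot(all(vapply(parts, inherits, TRUE, "region_set")))
  region_set(do.call(rbind, lapply(parts, `[[`, "mat")),
             unlist(lapply(parts, `[[`, "chrom")),
             unlist(lapply(parts, `[[`, "start")),
             bin_size = parts[[1L]]$bin_size)
}

#' @export
print.region_set <- function(x, ...) {
  cat(sprintf("<region_set> %d regions of %d bins (%d bp) on %s\n",
              nrow(x$mat), ncol(x$mat),
              as.integer(ncol(x$mat) * x$bin_size),
              paste(unique(x$chrom), collapse = ", ")))
  invisible(x)
}

#' Number of regions in a region set
#' @param x A `region_set`.
#' @return Integer count.
#' @export
n_regions <- function(x) nrow(x$mat)
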