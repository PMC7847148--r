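#' Settings for the synthetic accessibility genome generator
#'
#' Defaults emulate the regimes the workflow targets: a weak-dominant
#' genome (80% quiescent/heterochromatin bp), promoter regions with single
#' high summits (20 RPKM), enhancer regions with lower multimodal summits
#' (10 RPKM, 2 modes), a low accessibility background (0.5 RPKM), and
#' additive Gaussian noise at 5% of each class's summit.
#'
#' @param n_regions Number of 4 kb regions to lay end-to-end (default 500).
#' @param region_size,bin_size Region and bin sizes in bp.
#' @param class_mix Named fractions over promoter/enhancer/weak, summing
#'   to 1 (default 0.1/0.1/0.8).
#' @param promoter_summit,enhancer_summit Peak heights in RPKM.
#' @param enhancer_modes Number of enhancer peaks per region (>= 2).
#' @param noise_sigma_frac Noise s.d. as a fraction of the class summit
#'   (background level for weak regions).
#' @param background Background accessibility level in RPKM (default 0.5).
#' @param center_jitter Maximal absolute shift (bp) of each region's summit
#'   pattern from the region center (default 250), emulating the arbitrary
#'   phase of real peaks relative to the segmentation grid; the resulting
#'   structured position diversity is also what lets each summit position
#'   claim its own SOM node instead of spreading degenerately.
#' @param boundary_jitter Maximal absolute shift (bp) of annotation
#'   boundaries (default 0 = annotations exactly tile regions, making truth
#'   labels unambiguous; set up to 1000 to exercise partial-overlap paths).
#' @param chroms Chromosome names; regions are divided evenly among them.
#' @param seed Integer seed.
#' @return A `fixture_config` list.
#' @export
fixture_config <- function(n_regions = 500, region_size = 4000, bin_size = 50,
                           class_mix = c(promoter = 0.1, enhancer = 0.1,
                                         weak = 0.8),
                           promoter_summit = 20, enhancer_summit = 10,
                           enhancer_modes = 2, noise_sigma_frac = 0.05,
                           background = 0.5, center_jitter = 250,
                           boundary_jitter = 0, chroms = "chrS", seed = 1) {
  stopifnot(abs(sum(class_mix) - 1) < 1e-9, enhancer_modes >= 2,
            promoter_summit > background, enhancer_summit > background,
            region_size %% bin_size == 0, noise_sigma_frac >= 0)
  if (is.null(names(class_mix)))
    names(class_mix) <- c("promoter", "enhancer", "weak")
  structure(list(n_regions = as.integer(n_regions),
                 region_size = region_size, bin_size = bin_size,
                 class_mix = class_mix, promoter_summit = promoter_summit,
                 enhancer_summit = enhancer_summit,
                 enhancer_modes = as.integer(enhancer_modes),
                 noise_sigma_frac = noise_sigma_frac,
                 background = background, center_jitter = center_jitter,
                 boundary_jitter = boundary_jitter, chroms = chroms,
                 seed = as.integer(seed)),
            class = "fixture_config")
}

# noiseless class profile over `bins` bins, pattern centered at `center`
# (bin index); peak value is exactly the class summit
.class_profile <- function(class, bins, center, cfg) {
  i <- seq_len(bins)
  bg <- cfg$background
  if (class == "promoter") {
    sd <- bins / 10
    bump <- exp(-(i - center)^2 / (2 * sd^2))
    return(bg + (cfg$promoter_summit - bg) * bump)
  }
  if (class == "enhancer") {
    m <- cfg$enhancer_modes
    sd <- bins / 16
    offs <- round(((seq_len(m)) - (m + 1) / 2) * (bins / (m + 1)))
    bump <- do.call(pmax, lapply(offs, function(o)
      exp(-(i - (center + o))^2 / (2 * sd^2))))
    return(bg + (cfg$enhancer_summit - bg) * bump)
  }
  rep(bg, bins)
}

.class_summit <- function(class, cfg) {
  switch(class, promoter = cfg$promoter_summit,
         enhancer = cfg$enhancer_summit, cfg$background)
}

#' Simulate a synthetic accessibility genome with matching annotations
#'
#' Lays `n_regions` regions end-to-end per chromosome. Promoter regions get
#' a single Gaussian summit, enhancer regions `enhancer_modes` summits,
#' weak regions background only; summit patterns are shifted by a uniform
#' jitter of up to `center_jitter` bp (integer bins). I.i.d. Gaussian noise
#' with s.d. `noise_sigma_frac` times the class summit is added and clipped
#' at zero. Annotations use mnemonics `1_TssA` / `7_Enh` / `9_Quies`
#' aligned to the regions (optionally boundary-jittered). Fully
#' deterministic under the seed.
#'
#' @param cfg A [fixture_config()].
#' @return List with `signal` (named list of raw [binned_signal()]),
#'   `annotations` ([annotation_track()]), `truth` (data frame chrom,
#'   start, end, class), and `config`.
#' @export
simulate_genome <- function(cfg = fixture_config()) {
  set.seed(cfg$seed)
  bins <- cfg$region_size / cfg$bin_size
  jit_bins <- floor(cfg$center_jitter / cfg$bin_size)
  n_chrom <- length(cfg$chroms)
  per <- diff(round(seq(0, cfg$n_regions, length.out = n_chrom + 1)))
  mnem <- c(promoter = "1_TssA", enhancer = "7_Enh", weak = "9_Quies")
  sigs <- list(); truths <- list(); annots <- list()
  for (ci in seq_len(n_chrom)) {
    n <- per[ci]
    if (n == 0) next
    ch <- cfg$chroms[ci]
    classes <- sample(names(cfg$class_mix), n, replace = TRUE,
                      prob = cfg$class_mix)
    values <- numeric(n * bins)
    for (r in seq_len(n)) {
      center <- bins / 2 +
        (if (jit_bins > 0) sample.int(2 * jit_bins + 1, 1) - jit_bins - 1
         else 0)
      prof <- .class_profile(classes[r], bins, center, cfg)
      if (cfg$noise_sigma_frac > 0) {
        prof <- prof + stats::rnorm(bins, 0, cfg$noise_sigma_frac *
                                      .class_summit(classes[r], cfg))
      }
      values[((r - 1) * bins + 1):(r * bins)] <- pmax(prof, 0)
    }
    starts <- (seq_len(n) - 1) * cfg$region_size
    ends <- starts + cfg$region_size
    b_start <- starts; b_end <- ends
    if (cfg$boundary_jitter > 0 && n > 1) {
      shift <- stats::runif(n - 1, -cfg$boundary_jitter,
                            cfg$boundary_jitter)
      shift <- round(shift / cfg$bin_size) * cfg$bin_size
      inner <- pmin(pmax(ends[-n] + shift, starts[-n] + cfg$bin_size),
                    ends[-n] + cfg$region_size - cfg$bin_size)
      b_end[-n] <- inner
      b_start[-1] <- inner
    }
    sigs[[ch]] <- binned_signal(ch, values, start = 0,
                                bin_size = cfg$bin_size)
    truths[[ch]] <- data.frame(chrom = ch, start = starts, end = ends,
                               class = classes, stringsAsFactors = FALSE)
    annots[[ch]] <- data.frame(chrom = ch, start = b_start, end = b_end,
                               mnemonic = unname(mnem[classes]),
                               stringsAsFactors = FALSE)
  }
  ann <- do.call(rbind, annots)
  truth <- do.call(rbind, truths)
  rownames(truth) <- NULL
  list(signal = sigs,
       annotations = annotation_track(ann$chrom, ann$start, ann$end,
                                      ann$mnemonic),
       truth = truth, config = cfg)
}

#' Built-in planted prototype shapes
#'
#' Three structurally distinct region prototypes used for planted-shape
#' recovery experiments: a narrow high unimodal summit (promoter-like), a
#' bimodal pattern (enhancer-like), and a trimodal low pattern. They are
#' mutually non-mergeable (pairwise maximum NCC over +/- 20 bins well below
#' the 0.75 merge threshold).
#'
#' @param bins Shape length in bins (default 80).
#' @param background Background level (default 0.5).
#' @return Named list of numeric vectors.
#' @export
default_prototypes <- function(bins = 80, background = 0.5) {
  i <- seq_len(bins)
  g <- function(center, sd) exp(-(i - center)^2 / (2 * sd^2))
  list(
    unimodal = background + (20 - background) * g(bins / 2, bins / 13),
    bimodal = background + (10 - background) *
      pmax(g(bins * 0.3, bins / 18), g(bins * 0.7, bins / 18)),
    trimodal = background + (5 - background) *
      pmax(g(bins * 0.18, bins / 22), g(bins * 0.5, bins / 22),
           g(bins * 0.82, bins / 22)))
}

#' Regions drawn from planted prototypes
#'
#' Draws `n` regions, cycling through the prototypes in turn, adding i.i.d.
#' Gaussian noise with s.d. `noise_sigma_frac` times each prototype's
#' summit (clipped at 0).
#'
#' @param n Number of regions.
#' @param prototypes List of equal-length prototype vectors (default
#'   [default_prototypes()]).
#' @param noise_sigma_frac Noise fraction of the summit (default 0.05).
#' @param seed Integer seed.
#' @return List with `regions` (a `region_set` on a synthetic chromosome)
#'   and `prototype` (index per region).
#' @export
make_prototype_regions <- function(n, prototypes = default_prototypes(),
                                   noise_sigma_frac = 0.05, seed = 1) {
  set.seed(seed)
  bins <- length(prototypes[[1L]])
  stopifnot(all(lengths(prototypes) == bins))
  proto <- rep(seq_along(prototypes), length.out = n)
  mat <- t(vapply(proto, function(p) {
    v <- prototypes[[p]] +
      stats::rnorm(bins, 0, noise_sigma_frac * max(prototypes[[p]]))
    pmax(v, 0)
  }, numeric(bins)))
  list(regions = region_set(mat, rep("chrP", n),
                            (seq_len(n) - 1) * bins * 50, bin_size = 50),
       prototype = proto)
}

#' Zero-padded shifted copies of a shape
#'
#' @param shape Numeric vector.
#' @param shifts Integer shifts (positive = right); `|shift| < length`.
#' @return List of shifted vectors (same length, zero-padded).
#' @export
make_shifted_variants <- function(shape, shifts) {
  n <- length(shape)
  stopifnot(all(abs(shifts) < n))
  lapply(shifts, function(k) {
    if (k == 0) return(shape)
    if (k > 0) c(numeric(k), shape[seq_len(n - k)])
    else c(shape[(1 - k):n], numeric(-k))
  })
}
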