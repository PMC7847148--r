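#' Full workflow configuration
#'
#' One flat configuration gathering every tunable of the workflow, each
#' with a default. Unrecognized names are a hard error (no silent typos).
#'
#' @param ... Named overrides of the defaults: `region_size` (4000),
#'   `bin_size` (50), `normalization_percentile` (99.9), `rows`/`cols`
#'   (10), `epochs` (100), `batch_size` (100), `alpha0` (0.2), `radius0`
#'   (`max(rows, cols)/2`), `radius_end` (0.1), `alpha_min` (0.1),
#'   `match_resolution` (0.01), `lambda` (1), `merge_threshold` (0.75),
#'   `merge_max_lag` (20), `association_cutoff` (0.5),
#'   `n_bins_magnitude` (10), `window_size` (8000), `window_step` (4000),
#'   `rpkm_floor` (0), `exclude_promoters` (FALSE), `seed` (1),
#'   `log_level` (`"info"`).
#' @return A `somvn_config` list.
#' @export
somvn_config <- function(...) {
  defaults <- list(
    region_size = 4000, bin_size = 50, normalization_percentile = 99.9,
    rows = 10, cols = 10, epochs = 100, batch_size = 100, alpha0 = 0.2,
    radius0 = NULL, radius_end = 0.1, alpha_min = 0.1,
    match_resolution = 0.01, lambda = 1,
    merge_threshold = 0.75, merge_max_lag = 20,
    association_cutoff = 0.5, n_bins_magnitude = 10, window_size = 8000,
    window_step = 4000, rpkm_floor = 0, exclude_promoters = FALSE,
    seed = 1, log_level = "info")
  over <- list(...)
  if (length(over) == 1L && is.null(names(over)) && is.list(over[[1L]]))
    over <- over[[1L]]
  bad <- setdiff(names(over), names(defaults))
  if (length(bad))
    stop("unknown configuration key(s): ", paste(bad, collapse = ", "))
  cfg <- utils::modifyList(defaults, over)
  if (is.null(cfg$radius0)) cfg$radius0 <- max(cfg$rows, cfg$cols) / 2
  if (cfg$region_size %% cfg$bin_size != 0)
    stop("region_size must be a multiple of bin_size")
  if (cfg$window_size %% cfg$bin_size != 0 ||
      cfg$window_step %% cfg$bin_size != 0)
    stop("window_size and window_step must be multiples of bin_size")
  structure(cfg, class = "somvn_config")
}

#' Read a workflow configuration from YAML
#'
#' @param path YAML file of configuration keys (see [somvn_config()]).
#' @return A `somvn_config` list.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  somvn_config(yaml::read_yaml(path))
}

#' Write a workflow configuration as YAML
#'
#' @param cfg A [somvn_config()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

.log_cfg <- function(cfg, subcommand) {
  if (identical(cfg$log_level, "quiet")) return(invisible())
  keys <- vapply(names(unclass(cfg)), function(k)
    paste0(k, "=", paste(format(cfg[[k]]), collapse = "/")), "")
  message("[somvn] ", subcommand, " with ", paste(keys, collapse = " "))
}

#' Run one step of the SOM-VN workflow on files
#'
#' File-level driver behind the command-line interface. Each subcommand
#' reads and writes the package's documented plain-text formats; chaining
#' `simulate`, `train`, `merge`, `associate`, `assign`, `evaluate` runs
#' the workflow end-to-end. Inputs are never mutated; every run logs the
#' resolved configuration and seed (unless `log_level = "quiet"`).
#'
#' Subcommands and their artifacts (all under `out_dir`):
#' * `simulate`: `signal.bedGraph`, `annotations.bed`, `truth.tsv`
#' * `train`: `shapes.csv` (raw grid shapes, from `--signal`)
#' * `merge`: `shapes_merged.csv`, `provenance.tsv` (from `--shapes`)
#' * `associate`: `associations.tsv` (signal + shapes + annotations)
#' * `assign`: `assignment.bed` (signal + shapes + associations)
#' * `evaluate`: `evaluation.tsv`, `evaluation.json` (assignment +
#'   annotations, and signal when `rpkm_floor > 0`)
#' * `permute`: `signal_permuted.bedGraph` or `annotations_permuted.bed`
#'
#' @param subcommand One of simulate, train, merge, associate, assign,
#'   evaluate, permute.
#' @param config A [somvn_config()].
#' @param signal,annotations,shapes,associations,assignment Input file
#'   paths as required by the subcommand.
#' @param out_dir Output directory (created if missing).
#' @param chroms Optional chromosome subset to restrict signal to.
#' @param mode For `permute`: `"signal"` or `"annotation"`.
#' @return Named list of written file paths, invisibly.
#' @export
run_pipeline <- function(subcommand = c("simulate", "train", "merge",
                                        "associate", "assign", "evaluate",
                                        "permute"),
                         config = somvn_config(), signal = NULL,
                         annotations = NULL, shapes = NULL,
                         associations = NULL, assignment = NULL,
                         out_dir = ".", chroms = NULL,
                         mode = c("signal", "annotation")) {
  subcommand <- match.arg(subcommand)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  .log_cfg(config, subcommand)
  p <- function(f) file.path(out_dir, f)
  need <- function(path, what) {
    if (is.null(path)) stop(subcommand, " requires --", what)
    if (!file.exists(path)) stop(what, " file not found: ", path)
    path
  }
  read_sig <- function() {
    s <- read_signal(need(signal, "signal"), bin_size = config$bin_size)
    if (!is.null(chroms)) {
      s <- s[intersect(names(s), chroms)]
      if (!length(s)) stop("no requested chromosome found in ", signal)
    }
    s
  }
  out <- switch(
    subcommand,
    simulate = {
      g <- simulate_genome(fixture_config(seed = config$seed,
                                          region_size = config$region_size,
                                          bin_size = config$bin_size))
      write_signal(g$signal, p("signal.bedGraph"))
      write_annotations(g$annotations, p("annotations.bed"))
      utils::write.table(g$truth, p("truth.tsv"), sep = "\t", quote = FALSE,
                         row.names = FALSE)
      list(signal = p("signal.bedGraph"), annotations = p("annotations.bed"),
           truth = p("truth.tsv"))
    },
    train = {
      sigs <- read_sig()
      norm <- normalize_signal(sigs, config$normalization_percentile)
      regions <- segment(norm, config$region_size, config$region_size)
      grid <- train_som(regions, .som_config_from(config))
      write_shapes(grid, p("shapes.csv"))
      utils::write.table(
        data.frame(shape = sprintf("sample_genome_%s",
                                   rownames(grid$weights)),
                   support = grid$support),
        p("support.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
      list(shapes = p("shapes.csv"), support = p("support.tsv"))
    },
    merge = {
      raw_lib <- read_shapes(need(shapes, "shapes"))
      sup_path <- file.path(dirname(shapes), "support.tsv")
      wts <- NULL
      if (file.exists(sup_path)) {
        sup <- utils::read.table(sup_path, sep = "\t", header = TRUE,
                                 stringsAsFactors = FALSE)
        wts <- sup$support[match(rownames(raw_lib$shapes), sup$shape)]
        keep <- !is.na(wts) & wts > 0
        if (any(keep)) {
          raw_lib <- shape_library(raw_lib$shapes[keep, , drop = FALSE])
          wts <- wts[keep]
        } else wts <- NULL
      }
      lib <- merge_shapes(raw_lib, threshold = config$merge_threshold,
                          max_lag = config$merge_max_lag, weights = wts)
      write_shapes(lib, p("shapes_merged.csv"))
      prov <- data.frame(
        shape = rep(names(lib$provenance), lengths(lib$provenance)),
        node = unlist(lib$provenance, use.names = FALSE))
      utils::write.table(prov, p("provenance.tsv"), sep = "\t",
                         quote = FALSE, row.names = FALSE)
      list(shapes = p("shapes_merged.csv"), provenance = p("provenance.tsv"))
    },
    associate = {
      sigs <- read_sig()
      lib <- read_shapes(need(shapes, "shapes"))
      annot <- read_annotations(need(annotations, "annotations"))
      norm <- normalize_signal(sigs, config$normalization_percentile)
      regions <- segment(norm, config$region_size, config$region_size)
      assoc <- associate_shapes(regions, lib, annot,
                                cutoff = config$association_cutoff)
      write_association(assoc, p("associations.tsv"))
      list(associations = p("associations.tsv"))
    },
    assign = {
      sigs <- read_sig()
      lib <- read_shapes(need(shapes, "shapes"))
      assoc <- read_association(need(associations, "associations"))
      norm <- normalize_signal(sigs, config$normalization_percentile)
      wm <- match_windows(norm, lib, assoc,
                          window_size = config$window_size,
                          step = config$window_step)
      sa <- consolidate(wm)
      write_assignment(sa, p("assignment.bed"))
      list(assignment = p("assignment.bed"))
    },
    evaluate = {
      sa <- read_assignment(need(assignment, "assignment"))
      annot <- read_annotations(need(annotations, "annotations"))
      raw <- if (config$rpkm_floor > 0) read_sig() else NULL
      cc <- confusion(sa, annot,
                      eval_config(rpkm_floor = config$rpkm_floor,
                                  exclude_promoters =
                                    config$exclude_promoters),
                      raw_signal = raw)
      pr <- precision_recall(cc)
      write_evaluation(pr, p("evaluation.tsv"))
      list(evaluation = p("evaluation.tsv"),
           json = p("evaluation.json"))
    },
    permute = {
      mode <- match.arg(mode)
      if (mode == "signal") {
        sigs <- read_sig()
        write_signal(permute_signal(sigs, seed = config$seed),
                     p("signal_permuted.bedGraph"))
        list(signal = p("signal_permuted.bedGraph"))
      } else {
        annot <- read_annotations(need(annotations, "annotations"))
        lens <- if (!is.null(signal)) signal_lengths(read_sig())
                else tapply(annot$end, annot$chrom, max)
        write_annotations(permute_annotations(annot, lens,
                                              seed = config$seed),
                          p("annotations_permuted.bed"))
        list(annotations = p("annotations_permuted.bed"))
      }
    })
  invisible(out)
}
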