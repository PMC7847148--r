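#' Match overlapping windows against a shape library
#'
#' Segments the (normalized) test signal into windows of `window_size` bp
#' stepped by `step` bp (default 8 kb windows overlapping by 4 kb) and
#' scores the containment of every library shape in every window
#' ([containment_score()]). Shapes whose association label is `unknown` are
#' excluded from matching unless every shape is unknown. Per window the best
#' and second-best scores over distinct shapes give the ambiguity
#' `second/best` (0 with a single shape; 1 when several shapes are
#' available but the best score is not positive), and the window inherits
#' the best shape's RE label. Windows in
#' which no shape achieves a positive score (flat signal) fall back to the
#' weak-associated shape with the lowest summit when one exists, since flat
#' signal is the weak/quiescent majority; otherwise they are `unknown`.
#'
#' @param sig Normalized `binned_signal` (or list of them).
#' @param library A [shape_library()].
#' @param assoc The `shape_assoc` map for `library`.
#' @param window_size Window size in bp (default 8000).
#' @param step Step between window starts in bp (default `window_size / 2`).
#' @return A `window_matches` data frame: chrom, start, end, best_shape,
#'   best_score, second_score, ambiguity, label.
#' @export
match_windows <- function(sig, library, assoc, window_size = 8000,
                          step = window_size / 2) {
  S <- .shape_matrix(library)
  if (!nrow(S)) stop("empty shape library")
  labels <- assoc$label[match(rownames(S), assoc$shape)]
  if (anyNA(labels))
    stop("association map does not cover every library shape")
  use <- labels != "unknown"
  if (!any(use)) use <- rep(TRUE, nrow(S))
  S <- S[use, , drop = FALSE]
  labels <- labels[use]
  windows <- segment(sig, region_size = window_size, step = step)
  nw <- n_regions(windows)
  if (!nw) {
    out <- data.frame(chrom = character(0), start = numeric(0),
                      end = numeric(0), best_shape = character(0),
                      best_score = numeric(0), second_score = numeric(0),
                      ambiguity = numeric(0), label = character(0),
                      stringsAsFactors = FALSE)
    class(out) <- c("window_matches", "data.frame")
    return(out)
  }
  R <- .containment_cross(windows$mat, S)
  bi <- max.col(R, ties.method = "first")
  best <- R[cbind(seq_len(nw), bi)]
  second <- if (ncol(R) == 1L) rep(NA_real_, nw) else {
    R2 <- R
    R2[cbind(seq_len(nw), bi)] <- -Inf
    apply(R2, 1L, max)
  }
  ambiguity <- ifelse(is.na(second), 0,
                      ifelse(best > 0, pmin(pmax(second / best, 0), 1), 1))
  best_shape <- rownames(S)[bi]
  label <- labels[bi]
  flat <- best <= 0 & ncol(R) > 1L
  if (any(flat)) {
    wk <- which(labels == "weak")
    if (length(wk)) {
      summits <- apply(S[wk, , drop = FALSE], 1L, max)
      fb <- wk[which.min(summits)]
      best_shape[flat] <- rownames(S)[fb]
      label[flat] <- "weak"
    } else {
      best_shape[flat] <- NA_character_
      label[flat] <- "unknown"
    }
    ambiguity[flat] <- 1
  }
  out <- data.frame(chrom = windows$chrom, start = windows$start,
                    end = windows$end, best_shape = best_shape,
                    best_score = best, second_score = second,
                    ambiguity = ambiguity, label = label,
                    stringsAsFactors = FALSE)
  class(out) <- c("window_matches", "data.frame")
  out
}

#' Consolidate overlapping window matches by dynamic programming
#'
#' Overlapping windows are reduced to a mutually non-overlapping subset
#' that first maximizes the total covered bp (the workflow annotates whole
#' chromosomes; without this constraint the empty set would trivially
#' minimize ambiguity) and, among coverage-maximal subsets, minimizes the
#' sum of ambiguities. Solved per chromosome by weighted interval
#' scheduling with a lexicographic (coverage, -ambiguity) objective; ties
#' prefer the earlier window.
#'
#' @param matches A `window_matches` data frame.
#' @return A `state_assignment`: the selected rows, sorted, non-overlapping.
#' @export
consolidate <- function(matches) {
  sel <- lapply(split(seq_len(nrow(matches)), matches$chrom), function(idx) {
    d <- matches[idx, ]
    o <- order(d$start)
    idx <- idx[o]; d <- d[o, ]
    n <- nrow(d)
    # nxt[i]: first window starting at or after end of i (never overlaps i)
    nxt <- findInterval(d$end, d$start, left.open = TRUE) + 1L
    cov <- c(numeric(n), 0)   # best coverage over windows i..n
    amb <- c(numeric(n), 0)
    take <- logical(n)
    for (i in n:1) {
      cs <- cov[i + 1L]; as <- amb[i + 1L]
      ct <- (d$end[i] - d$start[i]) + cov[nxt[i]]
      at <- d$ambiguity[i] + amb[nxt[i]]
      if (ct > cs || (ct == cs && at <= as)) {
        cov[i] <- ct; amb[i] <- at; take[i] <- TRUE
      } else {
        cov[i] <- cs; amb[i] <- as
      }
    }
    keep <- integer(0)
    i <- 1L
    while (i <= n) {
      if (take[i]) { keep <- c(keep, idx[i]); i <- nxt[i] } else i <- i + 1L
    }
    keep
  })
  out <- matches[sort(unlist(sel, use.names = FALSE)), , drop = FALSE]
  out <- out[order(out$chrom, out$start), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("state_assignment", "window_matches", "data.frame")
  out
}

#' Write a state assignment as BED
#'
#' BED6-style lines: chrom, start, end, RE label,
#' `round(1000 * (1 - ambiguity))` as score, and `"."` for strand.
#'
#' @param sa A `state_assignment` (or `window_matches`).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_assignment <- function(sa, path) {
  con <- file(path, "w")
  on.exit(close(con))
  if (nrow(sa))
    writeLines(sprintf("%s\t%.0f\t%.0f\t%s\t%d\t.", sa$chrom, sa$start,
                       sa$end, sa$label,
                       as.integer(round(1000 * (1 - sa$ambiguity)))), con)
  invisible(path)
}

#' Read a state assignment written by [write_assignment()]
#'
#' @param path BED path.
#' @return A `state_assignment` data frame (ambiguity recovered from the
#'   BED score at 1/1000 resolution).
#' @export
read_assignment <- function(path) {
  if (!file.exists(path)) stop("assignment file not found: ", path)
  if (file.size(path) == 0) {
    df <- data.frame(chrom = character(0), start = numeric(0),
                     end = numeric(0), label = character(0),
                     ambiguity = numeric(0), stringsAsFactors = FALSE)
  } else {
    raw <- utils::read.table(path, sep = "\t", stringsAsFactors = FALSE)
    df <- data.frame(chrom = raw[[1L]], start = raw[[2L]], end = raw[[3L]],
                     label = raw[[4L]], ambiguity = 1 - raw[[5L]] / 1000,
                     stringsAsFactors = FALSE)
  }
  class(df) <- c("state_assignment", "data.frame")
  df
}
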