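#' Bin a genome into fixed-size windows
#'
#' Tiles each chromosome with successive non-overlapping windows of `W` bp
#' starting at coordinate 0. Only full windows are emitted: a chromosome of
#' length L yields `floor(L / W)` windows and the terminal partial segment is
#' discarded (a 249 Mb chromosome at 500 kb gives 498 windows).
#'
#' @param layout A [genome_layout()].
#' @param W Window size in bp (> 0).
#' @return A `window_grid` data frame with columns `chrom`, `index`
#'   (1-based ordinal within chromosome), `start`, `end`, `kept` and
#'   attribute `W`. All windows start out `kept = TRUE`.
#' @export
make_windows <- function(layout, W) {
  stopifnot(inherits(layout, "genome_layout"))
  if (!is.numeric(W) || length(W) != 1L || is.na(W) || W <= 0) {
    stop("window size W must be a positive number of base pairs")
  }
  n_per <- floor(layout$length / W)
  if (sum(n_per) == 0L) {
    warning("window size ", W, " exceeds every chromosome length; empty grid")
  }
  chrom <- rep(layout$chrom, n_per)
  idx <- unlist(lapply(n_per, function(k) seq_len(k)), use.names = FALSE)
  if (is.null(idx)) idx <- integer(0)
  start <- (idx - 1) * W
  grid <- data.frame(chrom = chrom, index = idx, start = start,
                     end = start + W, kept = rep(TRUE, length(idx)),
                     stringsAsFactors = FALSE)
  attr(grid, "W") <- W
  attr(grid, "chrom_levels") <- layout$chrom
  class(grid) <- c("window_grid", "data.frame")
  grid
}

#' Number of kept windows in a grid
#' @param grid A `window_grid`.
#' @return Integer count of windows with `kept == TRUE`.
#' @export
n_kept <- function(grid) {
  stopifnot(inherits(grid, "window_grid"))
  sum(grid$kept)
}

#' Remove gap-overlapping windows
#'
#' Marks as removed (`kept = FALSE`) every window sharing at least
#' `min_overlap` bp with any gap interval (assembly gaps, centromeres,
#' telomeres, heterochromatin). The default `min_overlap = 1` is the
#' strictest any-overlap rule. The input grid is not modified.
#'
#' @param grid A `window_grid` from [make_windows()].
#' @param gaps A [feature_track()] or an interval data frame
#'   (`chrom`, `start`, `end`) of gap regions.
#' @param min_overlap Minimum shared bp that disqualifies a window.
#' @return A new `window_grid` with updated `kept` flags.
#' @export
filter_gap_windows <- function(grid, gaps, min_overlap = 1) {
  stopifnot(inherits(grid, "window_grid"))
  iv <- if (inherits(gaps, "feature_track")) gaps$intervals else
    as.data.frame(gaps, stringsAsFactors = FALSE)
  if (is.null(iv) || nrow(iv) == 0L) return(grid)
  lev <- attr(grid, "chrom_levels")
  ov <- overlap_bp_per_window(grid, iv, lev, merge = TRUE)
  out <- grid
  out$kept <- grid$kept & (ov < min_overlap)
  out
}

# total bp of a window covered by (optionally merged) intervals
overlap_bp_per_window <- function(windows, iv, chrom_levels,
                                  merge = TRUE, weights = NULL) {
  win_gr <- gr_from_df(windows, chrom_levels)
  iv <- iv[iv$chrom %in% chrom_levels, , drop = FALSE]
  if (nrow(iv) == 0L) return(numeric(nrow(windows)))
  iv_gr <- gr_from_df(iv, chrom_levels)
  if (merge) iv_gr <- IRanges::reduce(iv_gr)
  hits <- IRanges::findOverlaps(win_gr, iv_gr)
  if (length(hits) == 0L) return(numeric(nrow(windows)))
  qh <- S4Vectors::queryHits(hits)
  sh <- S4Vectors::subjectHits(hits)
  w <- IRanges::width(IRanges::pintersect(win_gr[qh], iv_gr[sh]))
  if (!is.null(weights)) w <- w * weights[sh]
  out <- numeric(nrow(windows))
  agg <- rowsum(w, qh)
  out[as.integer(rownames(agg))] <- agg[, 1]
  out
}

# build a GRanges from a 0-based half-open interval data frame
gr_from_df <- function(df, chrom_levels = NULL) {
  chrom <- if (is.null(chrom_levels)) df$chrom else
    factor(df$chrom, levels = chrom_levels)
  GenomicRanges::GRanges(seqnames = chrom,
                         ranges = IRanges::IRanges(start = df$start + 1,
                                                   end = df$end))
}

#' Export a window grid as BED4
#'
#' Writes `chrom`, `start`, `end` and the kept flag ("kept"/"removed") for
#' external inspection.
#' @param grid A `window_grid`.
#' @param path Output path.
#' @export
write_grid_bed <- function(grid, path) {
  fmt <- function(x) format(x, scientific = FALSE, trim = TRUE)
  writeLines(paste(grid$chrom, fmt(grid$start), fmt(grid$end),
                   ifelse(grid$kept, "kept", "removed"), sep = "\t"), path)
  invisible(path)
}
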