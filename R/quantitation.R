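#' Default quantitation mode and zone group per standard feature
#'
#' The 42 standard feature mnemonics with their default quantitation mode and
#' zonal group. Scored signal-type tracks (TFBS, histone marks, open
#' chromatin, expression/RNA signals, methylation, recombination rates) are
#' quantified in intensity mode; repeat and sequence-class tracks in density
#' mode; point-like variant and breakpoint tracks (SNPs, indels, CNV
#' breakpoints, microsatellites) in count mode. All assignments are
#' user-overridable per track.
#'
#' @return Data frame with columns `feature`, `mode`, `group` where `group`
#'   is one of Genic, Proximal, Distal, Marker.
#' @export
default_feature_config <- function() {
  genic <- c("GENE", "CLV", "CNVT", "REG", "H3K4", "DNase", "FAIRE", "EXPS",
             "NAS+", "GCrich", "MeMRE", "MeBS", "CpGi", "CpGe", "Me450",
             "FLAM", "AluJ", "AluS", "AluY", "LRNA+", "LRNA-", "LINC",
             "SRNA-", "SRNA+")
  proximal <- c("L2", "MIR", "CID", "TFBS")
  distal <- c("NAS-", "L1", "ATrich")
  marker <- c("SNPM", "SDP", "CNVG", "RecH", "RecD", "MST", "SNP1K",
              "SNPdb", "SINS", "SDEL", "SID")
  feature <- c(genic, proximal, distal, marker)
  group <- c(rep("Genic", length(genic)), rep("Proximal", length(proximal)),
             rep("Distal", length(distal)), rep("Marker", length(marker)))
  intensity <- c("TFBS", "H3K4", "DNase", "FAIRE", "EXPS", "LRNA+", "LRNA-",
                 "SRNA+", "SRNA-", "MeMRE", "MeBS", "Me450", "RecH", "RecD")
  count <- c("SNPdb", "SNP1K", "SINS", "SDEL", "SID", "SNPM", "CNVG",
             "CNVT", "CLV", "MST")
  mode <- ifelse(feature %in% intensity, "intensity",
                 ifelse(feature %in% count, "count", "density"))
  data.frame(feature = feature, mode = mode, group = group,
             stringsAsFactors = FALSE)
}

# per-window levels for one track over the given window rows
quantitate_windows <- function(track, windows, W, chrom_levels) {
  iv <- track$intervals
  mode <- track$mode
  if (nrow(iv) == 0L) return(numeric(nrow(windows)))
  if (mode == "count") {
    pts <- data.frame(chrom = iv$chrom, start = iv$start,
                      end = iv$start + 1, stringsAsFactors = FALSE)
    pts <- pts[pts$chrom %in% chrom_levels, , drop = FALSE]
    if (nrow(pts) == 0L) return(numeric(nrow(windows)))
    win_gr <- gr_from_df(windows, chrom_levels)
    pt_gr <- gr_from_df(pts, chrom_levels)
    as.numeric(IRanges::countOverlaps(win_gr, pt_gr))
  } else if (mode == "density") {
    overlap_bp_per_window(windows, iv, chrom_levels, merge = TRUE) / W
  } else { # intensity
    keep <- iv$chrom %in% chrom_levels
    iv <- iv[keep, , drop = FALSE]
    if (nrow(iv) == 0L) return(numeric(nrow(windows)))
    if (anyNA(iv$score)) {
      stop("track '", track$feature_name,
           "': score required for intensity mode")
    }
    overlap_bp_per_window(windows, iv, chrom_levels, merge = FALSE,
                          weights = iv$score) / W
  }
}

#' Quantify a feature in a single window
#'
#' Per-window level of a track according to its quantitation mode:
#' count mode counts elements whose start coordinate lies in the window
#' (each element is assigned to exactly one window); density mode is the
#' fraction of window bases covered by the merged intervals, in \[0, 1\];
#' intensity mode sums covered bases times element score over the
#' (unmerged) intervals and divides by window size.
#'
#' @param track A [feature_track()].
#' @param window A single-row window (one row of a `window_grid`, or a list
#'   with `chrom`, `start`, `end`, `kept`).
#' @return The level, a single non-negative number.
#' @export
quantitate_window <- function(track, window) {
  win <- as.data.frame(as.list(window)[c("chrom", "start", "end", "kept")],
                       stringsAsFactors = FALSE)
  if (!isTRUE(win$kept)) stop("window is not kept; quantify kept windows only")
  W <- win$end - win$start
  lev <- unique(c(win$chrom, track$intervals$chrom))
  quantitate_windows(track, win, W, lev)[1]
}

#' Build the windows-by-features level matrix
#'
#' Quantifies every track in every kept window of the grid, producing the
#' central object all downstream statistics (co-localization, zonation,
#' hotspot calling) consume.
#'
#' @param grid A `window_grid` (typically after [filter_gap_windows()]).
#' @param tracks List of [feature_track()] objects with unique names.
#' @return A `feature_window_matrix`: list with `windows` (kept-window data
#'   frame), `features`, `modes`, `levels` (numeric matrix, kept windows x
#'   features) and `W`.
#' @export
build_matrix <- function(grid, tracks) {
  stopifnot(inherits(grid, "window_grid"))
  if (length(tracks) < 1L) stop("at least one track required")
  kept <- grid[grid$kept, , drop = FALSE]
  rownames(kept) <- NULL
  if (nrow(kept) == 0L) stop("no kept windows in grid")
  feats <- vapply(tracks, function(t) t$feature_name, character(1))
  if (anyDuplicated(feats)) {
    stop("duplicate feature names: ",
         paste(unique(feats[duplicated(feats)]), collapse = ", "))
  }
  lev <- attr(grid, "chrom_levels")
  for (t in tracks) {
    miss <- setdiff(unique(t$intervals$chrom), lev)
    if (length(miss)) {
      stop("track '", t$feature_name,
           "' has intervals on chromosome absent from layout: ",
           paste(miss, collapse = ", "))
    }
  }
  W <- attr(grid, "W")
  mat <- matrix(0, nrow = nrow(kept), ncol = length(tracks),
                dimnames = list(NULL, feats))
  for (j in seq_along(tracks)) {
    mat[, j] <- quantitate_windows(tracks[[j]], kept, W, lev)
  }
  if (!all(is.finite(mat))) stop("non-finite level computed")
  structure(list(windows = kept[, c("chrom", "index", "start", "end")],
                 features = feats,
                 modes = vapply(tracks, function(t) t$mode, character(1)),
                 levels = mat,
                 W = W,
                 chrom_levels = lev),
            class = "feature_window_matrix")
}

#' @export
print.feature_window_matrix <- function(x, ...) {
  cat(sprintf("feature_window_matrix: %d kept windows (W = %s bp) x %d features\n",
              nrow(x$levels), format(x$W, scientific = FALSE), length(x$features)))
  invisible(x)
}

#' Export a feature-window matrix as TSV
#'
#' First three columns are chrom, start, end of each kept window, then one
#' column per feature.
#' @param fwm A `feature_window_matrix`.
#' @param path Output path.
#' @export
write_matrix_tsv <- function(fwm, path) {
  df <- cbind(fwm$windows[, c("chrom", "start", "end")],
              as.data.frame(fwm$levels))
  write_table(df, path)
}

#' Read a feature-window matrix TSV written by [write_matrix_tsv()]
#' @param path Input path.
#' @param W Window size in bp; inferred from the first row when NULL.
#' @return A `feature_window_matrix` (modes unknown, set to NA).
#' @export
read_matrix_tsv <- function(path, W = NULL) {
  df <- read_table_tsv(path)
  stopifnot(all(c("chrom", "start", "end") %in% names(df)))
  featcols <- setdiff(names(df), c("chrom", "start", "end"))
  if (is.null(W)) W <- df$end[1] - df$start[1]
  windows <- data.frame(chrom = df$chrom,
                        index = df$start %/% W + 1,
                        start = df$start, end = df$end,
                        stringsAsFactors = FALSE)
  mat <- as.matrix(df[, featcols, drop = FALSE])
  structure(list(windows = windows, features = featcols,
                 modes = rep(NA_character_, length(featcols)),
                 levels = mat, W = W,
                 chrom_levels = unique(df$chrom)),
            class = "feature_window_matrix")
}
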