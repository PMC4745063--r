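#' Construct a genome layout
#'
#' A genome layout is the coordinate universe of an analysis: an ordered set
#' of named chromosomes with their lengths in base pairs. All interval tracks
#' and window grids are interpreted against a layout.
#'
#' @param chrom Character vector of chromosome names (unique).
#' @param length Integer-like vector of chromosome lengths in bp (all > 0).
#' @return A `genome_layout` data frame with columns `chrom` and `length`,
#'   preserving the input order.
#' @export
genome_layout <- function(chrom, length) {
  chrom <- as.character(chrom)
  length <- as.numeric(length)
  if (anyNA(chrom) || anyNA(length)) {
    stop("chromosome names and lengths must not contain NA")
  }
  if (anyDuplicated(chrom)) {
    stop("duplicate chromosome name: ",
         paste(unique(chrom[duplicated(chrom)]), collapse = ", "))
  }
  if (any(length <= 0) || any(length != floor(length))) {
    stop("non-positive length (chromosome lengths must be positive integers)")
  }
  out <- data.frame(chrom = chrom, length = length,
                    stringsAsFactors = FALSE)
  class(out) <- c("genome_layout", "data.frame")
  out
}

#' Read a chrom.sizes file
#'
#' Parses a two-column TSV of chromosome name and length (UCSC chrom.sizes
#' convention). File order is preserved.
#'
#' @param path Path to a TSV with columns name, length and no header.
#' @return A [genome_layout()].
#' @export
read_chrom_sizes <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) stop("empty chrom.sizes file: ", path)
  parts <- strsplit(lines, "\t", fixed = TRUE)
  chrom <- character(length(parts))
  len <- numeric(length(parts))
  for (i in seq_along(parts)) {
    p <- parts[[i]]
    if (length(p) < 2L || !nzchar(p[1])) {
      stop("malformed chrom.sizes line ", i, ": '", lines[i], "'")
    }
    l <- suppressWarnings(as.numeric(p[2]))
    if (is.na(l)) stop("malformed chrom.sizes line ", i,
                       ": length '", p[2], "' is not a number")
    if (l <= 0) stop("non-positive length on line ", i, ": '", lines[i], "'")
    chrom[i] <- p[1]
    len[i] <- l
  }
  genome_layout(chrom, len)
}

#' Write a genome layout as chrom.sizes
#' @param layout A [genome_layout()].
#' @param path Output path.
#' @export
write_chrom_sizes <- function(layout, path) {
  writeLines(paste(layout$chrom, format(layout$length, scientific = FALSE,
                                        trim = TRUE), sep = "\t"), path)
  invisible(path)
}

#' Read BED intervals
#'
#' Reads BED3/BED5/BED6 files with 0-based half-open coordinates into a plain
#' interval data frame. Column 4 is taken as the interval name and column 5
#' as the numeric score when present.
#'
#' @param path Path to a BED file (no header).
#' @return Data frame with columns `chrom`, `start`, `end`, `name`, `score`
#'   (`name`/`score` are NA when absent from the file).
#' @export
read_bed <- function(path) {
  df <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE,
                          comment.char = "#")
  if (ncol(df) < 3L) stop("BED file needs at least 3 columns: ", path)
  out <- data.frame(chrom = as.character(df[[1]]),
                    start = as.numeric(df[[2]]),
                    end = as.numeric(df[[3]]),
                    name = if (ncol(df) >= 4L) as.character(df[[4]]) else NA_character_,
                    score = if (ncol(df) >= 5L) suppressWarnings(as.numeric(df[[5]])) else NA_real_,
                    stringsAsFactors = FALSE)
  bad <- which(!(out$start < out$end))
  if (length(bad)) {
    stop("interval with start >= end at row ", bad[1], " of ", path)
  }
  if (any(out$start < 0)) stop("negative start coordinate in ", path)
  out
}

#' Construct a feature track
#'
#' A feature track is a named set of genomic intervals with an associated
#' quantitation mode:
#' \describe{
#'   \item{count}{point-like elements (SNP sites, CNV breakpoints,
#'     microsatellites); each element is assigned to one window by its start.}
#'   \item{density}{base-covering features; per-window level is the fraction
#'     of window bases covered by the merged intervals.}
#'   \item{intensity}{scored features; per-window level is the sum of
#'     (covered bases times element score) divided by window size.}
#' }
#'
#' @param feature_name Track name (e.g. one of the standard feature mnemonics
#'   such as "L1", "TFBS", "SNPdb").
#' @param mode One of `"count"`, `"density"`, `"intensity"`.
#' @param intervals Data frame with columns `chrom`, `start`, `end` and
#'   optionally `score`, `name`; 0-based half-open coordinates.
#' @param layout Optional [genome_layout()] used to validate coordinates.
#' @return A `feature_track` object; intervals are sorted by (chrom, start).
#' @export
feature_track <- function(feature_name, mode, intervals, layout = NULL) {
  mode <- match.arg(mode, c("count", "density", "intensity"))
  stopifnot(is.character(feature_name), length(feature_name) == 1L)
  iv <- as.data.frame(intervals, stringsAsFactors = FALSE)
  if (!all(c("chrom", "start", "end") %in% names(iv))) {
    stop("intervals need columns chrom, start, end")
  }
  if (is.null(iv$score)) iv$score <- rep(NA_real_, nrow(iv))
  if (is.null(iv$name)) iv$name <- rep(NA_character_, nrow(iv))
  iv <- iv[, c("chrom", "start", "end", "name", "score")]
  if (nrow(iv)) {
    bad <- which(!(iv$start < iv$end) | iv$start < 0)
    if (length(bad)) {
      stop("track '", feature_name, "': invalid interval at row ", bad[1])
    }
    if (mode == "intensity" && anyNA(iv$score)) {
      stop("score required for intensity mode (track '", feature_name,
           "', row ", which(is.na(iv$score))[1], ")")
    }
    if (!is.null(layout)) {
      miss <- setdiff(unique(iv$chrom), layout$chrom)
      if (length(miss)) {
        stop("track '", feature_name, "': chromosome not in layout: ",
             paste(miss, collapse = ", "))
      }
      lim <- layout$length[match(iv$chrom, layout$chrom)]
      bad <- which(iv$end > lim)
      if (length(bad)) {
        stop("track '", feature_name, "': interval beyond chromosome end at row ",
             bad[1])
      }
    }
    ord <- order(iv$chrom, iv$start, iv$end)
    iv <- iv[ord, , drop = FALSE]
    rownames(iv) <- NULL
  }
  structure(list(feature_name = feature_name, mode = mode, intervals = iv),
            class = "feature_track")
}

#' Read a BED file as a feature track
#'
#' @inheritParams feature_track
#' @param path Path to a BED3/BED5/BED6 file.
#' @return A [feature_track()]; file order need not be sorted (sorting is
#'   restored on load).
#' @export
read_feature_track <- function(path, feature_name, mode, layout = NULL) {
  iv <- read_bed(path)
  feature_track(feature_name, mode, iv, layout = layout)
}

#' Write a feature track as BED
#'
#' Emits BED3 for unscored/unnamed tracks and BED5 when names or scores are
#' present.
#' @param track A [feature_track()].
#' @param path Output path.
#' @export
write_track_bed <- function(track, path) {
  iv <- track$intervals
  fmt_coord <- function(x) format(x, scientific = FALSE, trim = TRUE)
  if (all(is.na(iv$score)) && all(is.na(iv$name))) {
    writeLines(paste(iv$chrom, fmt_coord(iv$start), fmt_coord(iv$end),
                     sep = "\t"), path)
  } else {
    nm <- ifelse(is.na(iv$name), ".", iv$name)
    sc <- ifelse(is.na(iv$score), "0",
                 formatC(iv$score, format = "g", digits = 10))
    writeLines(paste(iv$chrom, fmt_coord(iv$start), fmt_coord(iv$end),
                     nm, sc, sep = "\t"), path)
  }
  invisible(path)
}

#' Interval length statistics for a track
#'
#' Summarises the length distribution of a track's intervals (length =
#' end - start under half-open coordinates) and quantifies its deviation from
#' normality with the Jarque-Bera statistic
#' `n * (S^2/6 + K^2/24)` where S is the sample skewness and K the excess
#' kurtosis. Large values indicate a strongly non-normal length distribution.
#'
#' @param track A non-empty [feature_track()].
#' @param breaks Passed to [graphics::hist()] (default "Sturges").
#' @return A `length_stats` list: `feature_name`, `n`, `mean`, `median`,
#'   `sd`, `histogram` (`breaks`, `counts`) and `normal_deviation`.
#' @export
length_stats <- function(track, breaks = "Sturges") {
  stopifnot(inherits(track, "feature_track"))
  iv <- track$intervals
  if (nrow(iv) == 0L) stop("empty track: ", track$feature_name)
  len <- iv$end - iv$start
  n <- length(len)
  m <- mean(len)
  m2 <- mean((len - m)^2)
  if (m2 > 0) {
    S <- mean((len - m)^3) / m2^1.5
    K <- mean((len - m)^4) / m2^2 - 3
    jb <- n * (S^2 / 6 + K^2 / 24)
  } else {
    jb <- 0
  }
  h <- graphics::hist(len, breaks = breaks, plot = FALSE)
  structure(list(feature_name = track$feature_name,
                 n = n,
                 mean = m,
                 median = stats::median(len),
                 sd = stats::sd(len),
                 histogram = list(breaks = h$breaks, counts = h$counts),
                 normal_deviation = jb),
            class = "length_stats")
}

#' @export
print.length_stats <- function(x, ...) {
  cat(sprintf("Length statistics for '%s': n=%d, mean=%.1f bp, median=%.1f bp, sd=%.1f bp\n",
              x$feature_name, x$n, x$mean, x$median, x$sd))
  cat(sprintf("  deviation from normality (Jarque-Bera): %.3g\n",
              x$normal_deviation))
  invisible(x)
}

#' Write a rectangular table as TSV
#'
#' Writes a header plus rows; numeric columns are written at 6 significant
#' digits so that a write/read cycle through [read_table_tsv()] reproduces
#' values at that precision.
#'
#' @param x Data frame or matrix with column names.
#' @param path Output path.
#' @export
write_table <- function(x, path) {
  if (is.matrix(x)) x <- as.data.frame(x, stringsAsFactors = FALSE)
  if (is.list(x) && !is.data.frame(x)) {
    lens <- lengths(x)
    if (length(unique(lens)) > 1L) stop("ragged rows: row lengths differ")
    x <- as.data.frame(x, stringsAsFactors = FALSE)
  }
  if (is.null(names(x)) || any(!nzchar(names(x)))) {
    stop("header required: all columns must be named")
  }
  y <- x
  for (j in seq_along(y)) {
    if (is.numeric(y[[j]])) {
      y[[j]] <- ifelse(is.na(y[[j]]), "NA",
                       formatC(y[[j]], format = "g", digits = 6))
    }
  }
  utils::write.table(y, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a TSV written by [write_table()]
#' @param path Input path.
#' @return Data frame with the file's header as column names.
#' @export
read_table_tsv <- function(path) {
  utils::read.delim(path, header = TRUE, stringsAsFactors = FALSE,
                    check.names = FALSE)
}
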