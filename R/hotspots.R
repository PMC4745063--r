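#' Call top-quantile hotspot windows for a feature
#'
#' A hotspot is a kept window whose level for the feature ranks in the top
#' fraction `q` of all kept windows (default top-5%). Membership is by rank:
#' exactly `ceiling(q * n)` windows are selected; ties at the boundary break
#' by genomic order (chrom, start) for determinism. The reported threshold is
#' the minimum member level, so the call is invariant under positive affine
#' rescaling of the feature column.
#'
#' @param fwm A `feature_window_matrix`.
#' @param feature Feature name (non-constant).
#' @param q Tail fraction in (0, 1).
#' @return A `hotspot_set`: `feature`, `q`, `threshold`, `windows`
#'   (sorted row indices into the kept-window matrix), `n`.
#' @export
call_hotspots <- function(fwm, feature, q = 0.05) {
  stopifnot(inherits(fwm, "feature_window_matrix"))
  if (!(feature %in% fwm$features)) stop("unknown feature: ", feature)
  if (!(q > 0 && q < 1)) stop("q must lie in (0, 1)")
  lev <- fwm$levels[, feature]
  if (stats::sd(lev) == 0) {
    stop("constant feature '", feature, "': hotspots undefined")
  }
  n <- length(lev)
  k <- ceiling(q * n)
  ord <- order(-lev, seq_len(n)) # windows are stored in genomic order
  members <- sort(ord[seq_len(k)])
  structure(list(feature = feature, q = q,
                 threshold = min(lev[members]),
                 windows = members, n = n),
            class = "hotspot_set")
}

#' @export
print.hotspot_set <- function(x, ...) {
  cat(sprintf("hotspot_set '%s': top %.1f%% = %d of %d windows (threshold %.4g)\n",
              x$feature, 100 * x$q, length(x$windows), x$n, x$threshold))
  invisible(x)
}

#' Intersect hotspot sets and decompose by zone
#'
#' Computes double hotspots (windows hot for at least two of the given
#' features), triple hotspots (hot for all of them), and the full Venn
#' decomposition of the union, optionally split by zone.
#'
#' @param sets List of `hotspot_set` objects from the same kept-window grid.
#' @param assign Optional `zone_assignment` over the same windows.
#' @return A `hotspot_overlap` list: `features`, `double` and `triple`
#'   window indices, `venn` (data frame `zone`, `segment`, `count`), and the
#'   logical membership matrix.
#' @export
overlap_hotspots <- function(sets, assign = NULL) {
  stopifnot(length(sets) >= 2L,
            all(vapply(sets, inherits, logical(1), "hotspot_set")))
  ns <- vapply(sets, function(s) s$n, numeric(1))
  if (length(unique(ns)) != 1L) {
    stop("hotspot sets come from different window grids")
  }
  n <- ns[1]
  feats <- vapply(sets, function(s) s$feature, character(1))
  M <- matrix(FALSE, nrow = n, ncol = length(sets),
              dimnames = list(NULL, feats))
  for (j in seq_along(sets)) M[sets[[j]]$windows, j] <- TRUE
  deg <- rowSums(M)
  double <- which(deg >= 2L)
  triple <- which(deg == length(sets))
  in_union <- which(deg >= 1L)
  segment <- vapply(in_union, function(i) {
    paste(feats[M[i, ]], collapse = "&")
  }, character(1))
  zone <- if (is.null(assign)) rep("all", length(in_union)) else {
    if (nrow(assign) != n) stop("zone assignment covers a different grid")
    assign$zone[in_union]
  }
  venn <- as.data.frame(table(zone = zone, segment = segment),
                        stringsAsFactors = FALSE)
  names(venn)[3] <- "count"
  venn <- venn[venn$count > 0, , drop = FALSE]
  venn <- venn[order(venn$zone, venn$segment), , drop = FALSE]
  rownames(venn) <- NULL
  structure(list(features = feats, double = double, triple = triple,
                 venn = venn, membership = M),
            class = "hotspot_overlap")
}

#' Genes overlapping a set of windows
#'
#' A gene belongs to a window's content if any portion of its sequence falls
#' within the window (>= 1 bp overlap). Genes spanning several selected
#' windows are listed once.
#'
#' @param genes A [feature_track()] whose intervals all carry names.
#' @param windows Data frame of selected windows (`chrom`, `start`, `end`),
#'   e.g. kept-window rows indexed by a `hotspot_set`.
#' @return Sorted character vector of unique gene names.
#' @export
genes_in_windows <- function(genes, windows) {
  stopifnot(inherits(genes, "feature_track"))
  iv <- genes$intervals
  if (nrow(iv) == 0L) return(character(0))
  if (anyNA(iv$name) || any(!nzchar(iv$name))) {
    stop("unnamed gene interval at row ",
         which(is.na(iv$name) | !nzchar(iv$name))[1])
  }
  windows <- as.data.frame(windows, stringsAsFactors = FALSE)
  if (nrow(windows) == 0L) return(character(0))
  lev <- unique(c(windows$chrom, iv$chrom))
  win_gr <- gr_from_df(windows, lev)
  gene_gr <- gr_from_df(iv, lev)
  hits <- IRanges::findOverlaps(gene_gr, win_gr)
  sort(unique(iv$name[S4Vectors::queryHits(hits)]))
}

norm_group <- function(g, what) {
  if (is.numeric(g)) {
    if (length(g) < 2L) stop(what, ": need n >= 2 observations")
    list(mean = mean(g), sd = stats::sd(g), n = length(g))
  } else if (is.list(g) && all(c("mean", "sd", "n") %in% names(g))) {
    if (g$n < 2L) stop(what, ": need n >= 2")
    g[c("mean", "sd", "n")]
  } else {
    stop(what, ": supply a numeric vector or list(mean=, sd=, n=)")
  }
}

#' Welch's two-tailed t-test between a group and the background
#'
#' Unequal-variance (Welch) two-sample t-test with Welch-Satterthwaite
#' degrees of freedom, usable with raw value vectors or printed summary
#' statistics (mean, sd, n). Typical use: recombination rate in joint
#' SNP-CNV hotspot windows versus all kept windows.
#'
#' @param values_background,values_group Numeric vector, or
#'   `list(mean=, sd=, n=)`.
#' @return A `rate_test` list: per-group summaries, `t`, `df`, `p`
#'   (two-tailed).
#' @export
rate_test <- function(values_background, values_group) {
  bg <- norm_group(values_background, "background")
  gr <- norm_group(values_group, "group")
  if (bg$sd == 0 && gr$sd == 0) {
    if (bg$mean == gr$mean) {
      # degenerate equal groups: no evidence of difference
      return(structure(list(background = bg, group = gr,
                            t = 0, df = bg$n + gr$n - 2, p = 1),
                       class = "rate_test"))
    }
    stop("both groups have zero variance")
  }
  v1 <- gr$sd^2 / gr$n
  v2 <- bg$sd^2 / bg$n
  t <- (gr$mean - bg$mean) / sqrt(v1 + v2)
  df <- (v1 + v2)^2 / (v1^2 / (gr$n - 1) + v2^2 / (bg$n - 1))
  p <- 2 * stats::pt(abs(t), df = df, lower.tail = FALSE)
  structure(list(background = bg, group = gr, t = t, df = df, p = p),
            class = "rate_test")
}

#' @export
print.rate_test <- function(x, ...) {
  cat(sprintf("Welch two-tailed t-test: group %.3f +/- %.3f (n=%d) vs background %.3f +/- %.3f (n=%d)\n",
              x$group$mean, x$group$sd, x$group$n,
              x$background$mean, x$background$sd, x$background$n))
  cat(sprintf("  t = %.3f, df = %.1f, p = %.3g\n", x$t, x$df, x$p))
  invisible(x)
}

#' Over-representation analysis of a gene list
#'
#' One-sided hypergeometric (upper-tail) test of each gene set's overlap
#' with the gene list against the universe, with Bonferroni correction,
#' Benjamini-Hochberg step-up adjusted p, and an FDR q identical to the BH
#' value. A set is flagged significant when all three corrected values fall
#' below `alpha`. Output is ordered by ascending Bonferroni-corrected p.
#'
#' @param gene_list Character vector of selected genes (subset of universe).
#' @param universe Character vector of all candidate genes.
#' @param gene_sets Named list of character vectors (each a subset of the
#'   universe).
#' @param alpha Significance threshold applied to all three corrected values.
#' @return An `enrichment_result` data frame: `set`, `set_size`, `overlap`,
#'   `p_hyper`, `p_bonferroni`, `p_bh`, `q_fdr`, `significant`.
#' @export
ora_enrichment <- function(gene_list, universe, gene_sets, alpha = 0.05) {
  gene_list <- unique(gene_list)
  universe <- unique(universe)
  if (length(universe) == 0L) stop("empty gene universe")
  if (length(gene_list) == 0L) stop("empty gene list")
  if (length(gene_sets) == 0L || is.null(names(gene_sets))) {
    stop("gene_sets must be a non-empty named list")
  }
  out <- setdiff(gene_list, universe)
  if (length(out)) {
    stop("gene list not contained in universe: ",
         paste(utils::head(out, 3), collapse = ", "))
  }
  for (nm in names(gene_sets)) {
    out <- setdiff(gene_sets[[nm]], universe)
    if (length(out)) {
      stop("gene set '", nm, "' not contained in universe: ",
           paste(utils::head(out, 3), collapse = ", "))
    }
  }
  N <- length(universe)
  n <- length(gene_list)
  K <- vapply(gene_sets, function(s) length(unique(s)), integer(1))
  k <- vapply(gene_sets, function(s) length(intersect(unique(s), gene_list)),
              integer(1))
  p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
  m <- length(gene_sets)
  bonf <- pmin(1, m * p)
  bh <- stats::p.adjust(p, method = "BH")
  res <- data.frame(set = names(gene_sets), set_size = K, overlap = k,
                    p_hyper = p, p_bonferroni = bonf, p_bh = bh,
                    q_fdr = bh,
                    significant = bonf < alpha & bh < alpha,
                    stringsAsFactors = FALSE, row.names = NULL)
  res <- res[order(res$p_bonferroni, res$p_hyper, res$set), , drop = FALSE]
  rownames(res) <- NULL
  class(res) <- c("enrichment_result", "data.frame")
  res
}

#' Read gene-set definitions from TSV
#'
#' Expected format: one line per set, `set_name<TAB>gene1,gene2,...`.
#' @param path Input path.
#' @return Named list of character vectors.
#' @export
read_gene_sets <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(parts) < 2L)
  if (length(bad)) stop("malformed gene-set line ", bad[1])
  sets <- lapply(parts, function(p) {
    strsplit(p[2], ",", fixed = TRUE)[[1]]
  })
  names(sets) <- vapply(parts, `[`, character(1), 1)
  sets
}

#' Write gene-set definitions as TSV
#' @param gene_sets Named list of character vectors.
#' @param path Output path.
#' @export
write_gene_sets <- function(gene_sets, path) {
  writeLines(paste(names(gene_sets),
                   vapply(gene_sets, paste, character(1), collapse = ","),
                   sep = "\t"), path)
  invisible(path)
}

#' Export hotspot windows as BED4
#' @param hs A `hotspot_set`.
#' @param fwm The `feature_window_matrix` it was called on.
#' @param path Output path.
#' @export
write_hotspot_bed <- function(hs, fwm, path) {
  w <- fwm$windows[hs$windows, , drop = FALSE]
  fmt <- function(x) format(x, scientific = FALSE, trim = TRUE)
  writeLines(paste(w$chrom, fmt(w$start), fmt(w$end), hs$feature,
                   sep = "\t"), path)
  invisible(path)
}
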