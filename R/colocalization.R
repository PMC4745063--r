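# asymptotic two-tailed p for a correlation coefficient:
# t = r * sqrt((n-2) / (1-r^2)) against t(n-2)
cor_p_asym <- function(r, n) {
  p <- numeric(length(r))
  sat <- abs(r) >= 1 - 1e-15
  p[sat] <- 0
  t <- r[!sat] * sqrt((n - 2) / (1 - r[!sat]^2))
  p[!sat] <- 2 * stats::pt(abs(t), df = n - 2, lower.tail = FALSE)
  p
}

#' Co-localization of one feature pair
#'
#' Computes the Pearson product-moment coefficient r, the Spearman rank
#' coefficient rho (product-moment coefficient of mid-ranks; ties receive
#' average ranks), and the asymptotic two-tailed p-value of each via the
#' t-transform `t = r * sqrt((n-2)/(1-r^2))` with n-2 degrees of freedom.
#'
#' @param x,y Numeric vectors of per-window levels (equal length, n >= 3,
#'   neither constant).
#' @param feature_a,feature_b Names used in output and error messages.
#' @return A `coloc_pair` list: `feature_a`, `feature_b`, `r`, `rho`,
#'   `p_r`, `p_rho`, `n`.
#' @export
correlate_pair <- function(x, y, feature_a = "x", feature_b = "y") {
  if (length(x) != length(y)) stop("x and y must have equal length")
  n <- length(x)
  if (n < 3L) stop("need n >= 3 windows for an asymptotic p-value")
  if (anyNA(x) || anyNA(y)) stop("levels must not contain NA")
  if (stats::sd(x) == 0) stop("constant feature: '", feature_a,
                              "' has undefined correlation")
  if (stats::sd(y) == 0) stop("constant feature: '", feature_b,
                              "' has undefined correlation")
  r <- stats::cor(x, y)
  rho <- stats::cor(rank(x), rank(y))
  structure(list(feature_a = feature_a, feature_b = feature_b,
                 r = r, rho = rho,
                 p_r = cor_p_asym(r, n), p_rho = cor_p_asym(rho, n),
                 n = n),
            class = "coloc_pair")
}

#' All pairwise co-localization coefficients
#'
#' Computes Pearson r, Spearman rho and their asymptotic p-values for every
#' unordered feature pair of a feature-window matrix (k features give
#' k(k-1)/2 pairs; 42 features give 861). Output is a long-format table
#' ordered lexicographically by (feature_a, feature_b) with names sorted
#' within each pair.
#'
#' @param fwm A `feature_window_matrix` with at least 2 features.
#' @return A `coloc_matrix` data frame: `feature_a`, `feature_b`, `r`,
#'   `rho`, `p_r`, `p_rho`, `n`.
#' @export
build_coloc_matrix <- function(fwm) {
  stopifnot(inherits(fwm, "feature_window_matrix"))
  mat <- fwm$levels
  if (ncol(mat) < 2L) stop("need at least two features")
  n <- nrow(mat)
  if (n < 3L) stop("need n >= 3 kept windows")
  sds <- apply(mat, 2, stats::sd)
  if (any(sds == 0)) {
    stop("constant feature: '", colnames(mat)[which(sds == 0)[1]],
         "' has undefined correlation")
  }
  R <- stats::cor(mat)
  RHO <- stats::cor(apply(mat, 2, rank))
  feats <- colnames(mat)
  idx <- utils::combn(seq_along(feats), 2)
  a <- feats[idx[1, ]]
  b <- feats[idx[2, ]]
  swap <- a > b
  tmp <- a[swap]; a[swap] <- b[swap]; b[swap] <- tmp
  r <- R[cbind(idx[1, ], idx[2, ])]
  rho <- RHO[cbind(idx[1, ], idx[2, ])]
  out <- data.frame(feature_a = a, feature_b = b,
                    r = r, rho = rho,
                    p_r = cor_p_asym(r, n), p_rho = cor_p_asym(rho, n),
                    n = n, stringsAsFactors = FALSE)
  out <- out[order(out$feature_a, out$feature_b), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("coloc_matrix", "data.frame")
  out
}

#' Concordance between two coefficient vectors
#'
#' Plain Pearson correlation between two aligned vectors of co-localization
#' coefficients. With `label = "R_C"` it measures agreement between Spearman
#' and Pearson coefficients at one window size; with `label = "R_W"`,
#' agreement between Pearson coefficients computed at two window sizes.
#'
#' @param coeffs_a,coeffs_b Numeric vectors over the same pairs, same order.
#' @param label `"R_C"` or `"R_W"`.
#' @return A `concordance` list: `label`, `value`, `n_pairs`.
#' @export
concordance <- function(coeffs_a, coeffs_b, label = c("R_C", "R_W")) {
  label <- match.arg(label)
  if (length(coeffs_a) != length(coeffs_b)) {
    stop("coefficient vectors must have equal length")
  }
  structure(list(label = label,
                 value = stats::cor(coeffs_a, coeffs_b),
                 n_pairs = length(coeffs_a)),
            class = "concordance")
}

#' Census of pairwise p-values over significance bins
#'
#' Counts feature pairs per p-value bin. Given cutoffs `c1 > c2 > ... > ck`,
#' the bins are `p > c1`, `(c(i+1), c(i)]`, and `p <= ck`; the bins
#' partition the pairs, so counts always sum to the pair total.
#'
#' @param cm A `coloc_matrix`.
#' @param cutoffs Decreasingly sorted p-value thresholds
#'   (default `c(0.05, 1e-16)`, the conventional significance bound and the
#'   smallest printed precision).
#' @param which Which p-value column to bin (`"p_r"` or `"p_rho"`).
#' @return Data frame with columns `bin` and `count`.
#' @export
p_value_census <- function(cm, cutoffs = c(0.05, 1e-16), which = "p_r") {
  stopifnot(inherits(cm, "coloc_matrix"), which %in% c("p_r", "p_rho"))
  cutoffs <- sort(unique(cutoffs), decreasing = TRUE)
  p <- cm[[which]]
  labs <- c(paste0("P>", format(cutoffs[1])),
            if (length(cutoffs) > 1)
              paste0(format(cutoffs[-1]), "<P<=", format(cutoffs[-length(cutoffs)])),
            paste0("P<=", format(cutoffs[length(cutoffs)])))
  counts <- integer(length(labs))
  counts[1] <- sum(p > cutoffs[1])
  if (length(cutoffs) > 1) {
    for (i in seq_len(length(cutoffs) - 1)) {
      counts[i + 1] <- sum(p > cutoffs[i + 1] & p <= cutoffs[i])
    }
  }
  counts[length(labs)] <- sum(p <= cutoffs[length(cutoffs)])
  data.frame(bin = labs, count = counts, stringsAsFactors = FALSE)
}

#' Format p-values for reports
#'
#' P-values below 1e-16 (beneath the asymptotic approximation's useful
#' precision) print as "<1e-16".
#' @param p Numeric vector of p-values.
#' @return Character vector.
#' @export
format_p <- function(p) {
  ifelse(p < 1e-16, "<1e-16", formatC(p, format = "g", digits = 3))
}

#' Export a co-localization matrix as long-format TSV
#' @param cm A `coloc_matrix`.
#' @param path Output path.
#' @export
write_coloc_tsv <- function(cm, path) {
  write_table(as.data.frame(cm), path)
}
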