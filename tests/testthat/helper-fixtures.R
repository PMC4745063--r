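# Fixture builders and independent brute-force oracles used across tests.

toy_layout <- function(lengths = 1e6, names = paste0("chrT", seq_along(lengths))) {
  genome_layout(names, lengths)
}

toy_track <- function(starts, ends, chrom = "chrT1", mode = "density",
                      scores = NA_real_, names = NA_character_,
                      feature = "toy") {
  n <- length(starts)
  feature_track(feature, mode,
                data.frame(chrom = rep_len(chrom, n), start = starts,
                           end = rep_len(ends, n),
                           score = rep_len(scores, n),
                           name = rep_len(names, n),
                           stringsAsFactors = FALSE))
}

# minimal feature_window_matrix from a bare levels matrix (windows tile one
# toy chromosome)
fwm_from_matrix <- function(mat, W = 1000) {
  n <- nrow(mat)
  structure(list(windows = data.frame(chrom = "chrT1",
                                      index = seq_len(n),
                                      start = (seq_len(n) - 1) * W,
                                      end = seq_len(n) * W,
                                      stringsAsFactors = FALSE),
                 features = colnames(mat),
                 modes = rep(NA_character_, ncol(mat)),
                 levels = mat, W = W, chrom_levels = "chrT1"),
            class = "feature_window_matrix")
}

# per-base coverage fraction of [wstart, wend) by a set of intervals
brute_density <- function(starts, ends, wstart, wend) {
  covered <- logical(wend - wstart)
  for (i in seq_along(starts)) {
    lo <- max(starts[i], wstart)
    hi <- min(ends[i], wend)
    if (lo < hi) covered[(lo - wstart + 1):(hi - wstart)] <- TRUE
  }
  mean(covered)
}

# does interval [s, e) share >= 1 bp with [ws, we)?
brute_overlaps <- function(s, e, ws, we) {
  max(s, ws) < min(e, we)
}

# two-sided permutation p-value for a correlation coefficient; vectorized
# over B random permutations generated from the given seed
perm_cor_pvalue <- function(x, y, B = 1e5, seed = 1, spearman = FALSE) {
  if (spearman) {
    x <- rank(x)
    y <- rank(y)
  }
  n <- length(x)
  robs <- abs(stats::cor(x, y))
  set.seed(seed)
  keys <- matrix(stats::runif(n * B), nrow = n)
  o <- order(col(keys), keys) # column-wise random orderings
  rows <- (o - 1L) %% n + 1L
  xp <- matrix(x[rows], nrow = n)
  s <- colSums(xp * y)
  # |r| is monotone in |S_xy - n*mean(x)*mean(y)| since sds are permutation
  # invariant
  stat <- abs(s - n * mean(x) * mean(y))
  obs <- abs(sum(x * y) - n * mean(x) * mean(y))
  mean(stat >= obs - 1e-9)
}

# small synthetic dataset shared by several tests
small_sim <- function(seed = 2, features = c("SNPdb", "SNP1K", "CNVG",
                                             "RecH", "GENE", "L1"),
                      ...) {
  feats <- default_sim_features()
  feats <- feats[feats$feature %in% features, , drop = FALSE]
  sim_config(seed = seed, n_chrom = 2, chrom_length = 1e7, W = 5e5,
             segment_length = 1e6, gap_windows_per_chrom = 1,
             features = feats, n_genes = 60, n_gene_sets = 4,
             genes_per_set = 10, ...)
}
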