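test_that("hotspot calling selects the top ceil(q*n) windows by rank", {
  set.seed(71)
  lev <- sample(seq(1, 1000), 100) # distinct levels
  fwm <- fwm_from_matrix(cbind(f = lev))
  hs <- call_hotspots(fwm, "f", 0.05)
  expect_length(hs$windows, 5)
  expect_setequal(hs$windows, order(lev, decreasing = TRUE)[1:5])
  expect_equal(hs$threshold, sort(lev, decreasing = TRUE)[5])
  expect_true(min(lev[hs$windows]) >= max(lev[-hs$windows]))

  hs20 <- call_hotspots(fwm_from_matrix(cbind(f = lev[1:20])), "f", 0.05)
  expect_length(hs20$windows, 1) # ceil(0.05 * 20) = 1

  expect_error(call_hotspots(fwm_from_matrix(cbind(f = rep(2, 10))), "f"),
               "constant")
  expect_error(call_hotspots(fwm, "f", 0), "q must lie")
})

test_that("boundary ties break by genomic order", {
  lev <- c(5, 9, 5, 5, 1, 1, 1, 1, 1, 1)
  hs <- call_hotspots(fwm_from_matrix(cbind(f = lev)), "f", 0.2)
  expect_equal(hs$windows, c(1, 2)) # first tied window wins
})

test_that("hotspot membership is invariant under positive affine rescaling", {
  set.seed(72)
  lev <- rnorm(60)
  a <- call_hotspots(fwm_from_matrix(cbind(f = lev)), "f", 0.1)
  b <- call_hotspots(fwm_from_matrix(cbind(f = 5 * lev + 100)), "f", 0.1)
  expect_equal(a$windows, b$windows)
})

test_that("set intersections give double and triple hotspots", {
  mk <- function(w, f) {
    structure(list(feature = f, q = 0.1, threshold = 0,
                   windows = sort(w), n = 50), class = "hotspot_set")
  }
  ov <- overlap_hotspots(list(mk(c(1, 2, 3), "A"), mk(c(3, 4), "B")))
  expect_equal(ov$double, 3)

  sets3 <- list(mk(c(2, 5, 9), "A"), mk(c(2, 5, 9), "B"), mk(c(2, 5, 9), "C"))
  ov3 <- overlap_hotspots(sets3)
  expect_equal(ov3$triple, c(2, 5, 9))
  expect_equal(ov3$double, c(2, 5, 9))

  bad <- mk(1:3, "D")
  bad$n <- 40
  expect_error(overlap_hotspots(list(mk(1:3, "A"), bad)), "different window")
})

test_that("Venn segments match brute-force enumeration per zone", {
  set.seed(73)
  n <- 50
  mk <- function(f) {
    structure(list(feature = f, q = 0.2, threshold = 0,
                   windows = sort(sample(n, 10)), n = n),
              class = "hotspot_set")
  }
  sets <- list(mk("A"), mk("B"), mk("C"))
  zones <- sample(c("Genic", "Proximal", "Distal"), n, replace = TRUE)
  assign <- data.frame(zone = zones)
  attr(assign, "model") <- list(Genic = "x", Proximal = "y", Distal = "z")
  class(assign) <- c("zone_assignment", "data.frame")
  ov <- overlap_hotspots(sets, assign)
  # brute force: enumerate membership per window
  member <- function(i, s) i %in% s$windows
  for (row in seq_len(nrow(ov$venn))) {
    z <- ov$venn$zone[row]
    seg <- strsplit(ov$venn$segment[row], "&", fixed = TRUE)[[1]]
    cnt <- 0
    for (i in seq_len(n)) {
      inset <- c("A", "B", "C")[vapply(sets, member, logical(1), i = i)]
      if (zones[i] == z && length(inset) && setequal(inset, seg)) {
        cnt <- cnt + 1
      }
    }
    expect_equal(ov$venn$count[row], cnt)
  }
  # segment counts per zone sum to the union count in that zone
  union_w <- sort(unique(unlist(lapply(sets, `[[`, "windows"))))
  for (z in unique(zones)) {
    expect_equal(sum(ov$venn$count[ov$venn$zone == z]),
                 sum(zones[union_w] == z))
  }
  expect_lte(length(ov$double), min(lengths(lapply(sets, `[[`, "windows"))))
  expect_lte(length(ov$triple), length(ov$double))
})

test_that("gene content of windows uses any-overlap and deduplicates", {
  win <- data.frame(chrom = "chrT1", start = c(0, 5e5), end = c(5e5, 1e6))
  genes <- toy_track(c(100, 499999, 999999), c(200, 500050, 1000000),
                     names = c("gA", "gB", "gC"))
  expect_equal(genes_in_windows(genes, win), c("gA", "gB", "gC"))
  # gB straddles both windows but is listed once
  expect_equal(genes_in_windows(genes, win[1, ]), c("gA", "gB"))
  expect_equal(genes_in_windows(genes, win[2, ]), c("gB", "gC"))

  unnamed <- toy_track(0, 10)
  expect_error(genes_in_windows(unnamed, win), "unnamed gene interval")
})

test_that("gene-window overlap matches a per-gene brute-force scan", {
  set.seed(74)
  win <- data.frame(chrom = "chrT1",
                    start = c(0, 2000, 7000), end = c(1000, 3000, 8000))
  s <- sample(0:9000, 40)
  e <- s + sample(1:1500, 40, replace = TRUE)
  nm <- sprintf("g%02d", 1:40)
  genes <- toy_track(s, e, names = nm)
  want <- sort(unique(nm[vapply(seq_len(40), function(i) {
    any(vapply(seq_len(3), function(j) {
      brute_overlaps(s[i], e[i], win$start[j], win$end[j])
    }, logical(1)))
  }, logical(1))]))
  expect_equal(genes_in_windows(genes, win), want)
})

test_that("the rate test is Welch's t and handles summaries and vectors", {
  same <- rate_test(c(1, 2, 3, 4), c(1, 2, 3, 4))
  expect_equal(same$t, 0)
  expect_equal(same$p, 1)

  a <- c(1.2, 2.3, 1.8, 2.9, 2.1, 1.5, 2.6, 1.9)
  b <- c(2.8, 3.4, 2.9, 3.8, 3.1, 2.5)
  rt <- rate_test(a, b)
  tt <- t.test(b, a) # independent oracle: Welch is t.test's default
  expect_equal(rt$t, unname(tt$statistic), tolerance = 1e-12)
  expect_equal(rt$df, unname(tt$parameter), tolerance = 1e-12)
  expect_equal(rt$p, tt$p.value, tolerance = 1e-12)

  # identical result from summary statistics
  rt2 <- rate_test(list(mean = mean(a), sd = sd(a), n = 8),
                   list(mean = mean(b), sd = sd(b), n = 6))
  expect_equal(rt2$p, rt$p, tolerance = 1e-12)

  expect_error(rate_test(1, b), "n >= 2")
})

test_that("the rate test agrees with a permutation oracle at small n", {
  a <- c(1.2, 2.3, 1.8, 2.9, 2.1, 1.5, 2.6, 1.9)
  b <- c(2.8, 3.4, 2.9, 3.8, 3.1, 2.5)
  rt <- rate_test(a, b)
  pool <- c(a, b)
  set.seed(75)
  B <- 5e4
  stat <- replicate(B, {
    idx <- sample(14, 6)
    g <- pool[idx]
    bg <- pool[-idx]
    v1 <- var(g) / 6
    v2 <- var(bg) / 8
    abs((mean(g) - mean(bg)) / sqrt(v1 + v2))
  })
  pp <- mean(stat >= abs(rt$t) - 1e-12)
  # the asymptotic t reference is an approximation at n = 8 vs 6; agreement
  # is to the approximation's accuracy, not to Monte-Carlo error
  expect_equal(rt$p, pp, tolerance = 0.5)
})

test_that("planted recombination elevation strengthens with fold", {
  ps <- vapply(c(1.5, 3, 6), function(fold) {
    cfg <- small_sim(seed = 76,
                     hotspot = list(features = c("SNPdb", "SNP1K", "CNVG"),
                                    n_triple = 3, fold = 10,
                                    recomb_fold = fold))
    ds <- simulate_dataset(cfg)
    grid <- filter_gap_windows(make_windows(ds$layout, cfg$W), ds$gaps)
    fwm <- build_matrix(grid, ds$tracks)
    rate_test(fwm$levels[, "RecH"],
              fwm$levels[ds$truth$hotspots$triple, "RecH"])$p
  }, numeric(1))
  expect_true(all(diff(ps) < 0))
})

test_that("hypergeometric enrichment matches exact combinatorics", {
  universe <- sprintf("u%02d", 1:10)
  lst <- universe[1:5]
  res <- ora_enrichment(lst, universe,
                        list(hit = universe[1:5], miss = universe[6:10]))
  expect_equal(res$p_hyper[res$set == "hit"], 1 / choose(10, 5))
  expect_equal(res$p_hyper[res$set == "miss"], 1)
  expect_equal(res$p_bonferroni[res$set == "hit"],
               min(1, 2 / choose(10, 5)))
  # ordered by ascending Bonferroni p
  expect_equal(res$set, c("hit", "miss"))
})

test_that("the significance flag requires all corrected values below 0.05", {
  universe <- sprintf("u%03d", 1:100)
  lst <- universe[1:10]
  sets <- list(strong = universe[1:10],
               weak = universe[c(1, 11:29)],
               none = universe[51:70])
  res <- ora_enrichment(lst, universe, sets)
  expect_true(res$significant[res$set == "strong"])
  expect_false(res$significant[res$set == "none"])
  expect_equal(res$q_fdr, res$p_bh)
  expect_true(all(res$p_bonferroni >= res$p_hyper))
})

test_that("enrichment p-values are calibrated under the null", {
  set.seed(77)
  universe <- sprintf("u%03d", 1:200)
  reps <- 50
  hits <- 0
  total <- 0
  for (i in seq_len(reps)) {
    lst <- sample(universe, 30)
    sets <- lapply(1:20, function(j) sample(universe, 15))
    names(sets) <- paste0("s", 1:20)
    res <- ora_enrichment(lst, universe, sets)
    hits <- hits + sum(res$p_hyper < 0.05)
    total <- total + 20
  }
  # upper-tail hypergeometric p is discrete and conservative: the rejection
  # rate stays at or below the nominal 5% (binomial slack)
  expect_lt(hits / total, 0.05 + 2 * sqrt(0.05 * 0.95 / total))
})

test_that("enrichment rejects inputs outside the universe", {
  expect_error(ora_enrichment(c("a", "zz"), c("a", "b"), list(s = "a")),
               "not contained")
  expect_error(ora_enrichment("a", c("a", "b"), list(s = "zz")),
               "not contained")
  expect_error(ora_enrichment(character(0), c("a"), list(s = "a")), "empty")
})

test_that("gene sets round-trip through the TSV format", {
  sets <- list(alpha = c("g1", "g2", "g3"), beta = "g9")
  p <- withr::local_tempfile()
  write_gene_sets(sets, p)
  expect_equal(read_gene_sets(p), sets)
})
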