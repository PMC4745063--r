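test_that("simulation is byte-deterministic in (config, seed)", {
  cfg <- small_sim(seed = 81,
                   hotspot = list(features = c("SNPdb", "SNP1K", "CNVG"),
                                  n_triple = 2))
  d1 <- simulate_dataset(cfg)
  d2 <- simulate_dataset(cfg)
  expect_identical(d1$layout, d2$layout)
  expect_identical(d1$gaps, d2$gaps)
  expect_identical(d1$tracks, d2$tracks)
  expect_identical(d1$truth, d2$truth)
  expect_identical(d1$genes, d2$genes)

  # a different seed gives a different realisation
  d3 <- simulate_dataset(small_sim(seed = 82,
                                   hotspot = list(features = c("SNPdb",
                                                               "SNP1K",
                                                               "CNVG"),
                                                  n_triple = 2)))
  expect_false(identical(d1$tracks[["SNPdb"]], d3$tracks[["SNPdb"]]))
})

test_that("the simulator does not disturb the caller's RNG stream", {
  set.seed(99)
  before <- runif(1)
  set.seed(99)
  invisible(simulate_genome(small_sim(seed = 83)))
  after <- runif(1)
  expect_identical(before, after)
})

test_that("zone apportionment matches the plan to within one window", {
  cfg <- sim_config(seed = 84, n_chrom = 2, chrom_length = 2.5e8, W = 5e5,
                    gap_windows_per_chrom = 0, segment_length = 2.5e6,
                    features = default_sim_features()[1:2, ])
  g <- simulate_genome(cfg)
  tab <- table(g$truth$windows$zone)
  n <- nrow(g$truth$windows)
  expect_equal(n, 1000)
  for (z in names(cfg$zone_mix)) {
    expect_lte(abs(tab[[z]] - cfg$zone_mix[[z]] * n), 2)
  }
  # labels come in contiguous whole-window runs
  runs <- rle(g$truth$windows$zone)
  expect_gt(mean(runs$lengths), 2)
})

test_that("invalid configurations are rejected", {
  expect_error(sim_config(zone_mix = c(Genic = 0.5, Proximal = 0.4,
                                       Distal = 0.2)), "sum to 1")
  expect_error(sim_config(segment_length = 7.5e5, W = 5e5),
               "not a multiple of W")
  expect_error(sim_config(planted_r = data.frame(feature_a = "SNPdb",
                                                 feature_b = "SNP1K",
                                                 r = 1.2)), "< 1")
  expect_error(sim_config(planted_r = data.frame(feature_a = "SNPdb",
                                                 feature_b = "nope",
                                                 r = 0.5)), "unknown feature")
})

test_that("an infeasible correlation plan is refused", {
  feats <- default_sim_features()
  feats <- feats[feats$feature %in% c("SNPdb", "SNP1K", "CNVG"), ]
  pr <- data.frame(feature_a = c("SNPdb", "SNPdb", "SNP1K"),
                   feature_b = c("SNP1K", "CNVG", "CNVG"),
                   r = c(0.9, 0.9, -0.9))
  cfg <- sim_config(seed = 85, n_chrom = 1, chrom_length = 5e6, W = 5e5,
                    gap_windows_per_chrom = 0, features = feats,
                    planted_r = pr)
  g <- simulate_genome(cfg)
  expect_error(simulate_tracks(cfg, g$truth), "infeasible correlation plan")
})

test_that("emitted intervals stay on-chromosome and clear of gaps", {
  cfg <- small_sim(seed = 86)
  ds <- simulate_dataset(cfg)
  for (t in ds$tracks) {
    iv <- t$intervals
    expect_true(all(iv$start >= 0))
    lim <- ds$layout$length[match(iv$chrom, ds$layout$chrom)]
    expect_true(all(iv$end <= lim))
    for (j in seq_len(nrow(ds$gaps))) {
      same <- iv$chrom == ds$gaps$chrom[j]
      expect_false(any(same & iv$start < ds$gaps$end[j] &
                         iv$end > ds$gaps$start[j]))
    }
  }
})

test_that("zone-dependent means realise the planted fold", {
  feats <- default_sim_features()
  feats <- feats[feats$feature %in% c("GENE", "SNPdb"), ]
  cfg <- sim_config(seed = 87, n_chrom = 2, chrom_length = 1.25e8, W = 5e5,
                    gap_windows_per_chrom = 0, features = feats,
                    zone_fold = 4)
  g <- simulate_genome(cfg)
  fwm <- build_matrix(make_windows(g$layout, cfg$W),
                      simulate_tracks(cfg, g$truth))
  zone <- g$truth$windows$zone
  in_genic <- mean(fwm$levels[zone == "Genic", "GENE"])
  out_genic <- mean(fwm$levels[zone != "Genic", "GENE"])
  expect_equal(in_genic / out_genic, 4, tolerance = 0.1)
  # marker features are zone-uniform
  expect_equal(mean(fwm$levels[zone == "Genic", "SNPdb"]) /
                 mean(fwm$levels[zone != "Genic", "SNPdb"]),
               1, tolerance = 0.1)
})

test_that("hotspot planting elevates counts and recombination scores", {
  cfg <- small_sim(seed = 88,
                   hotspot = list(features = c("SNPdb", "SNP1K", "CNVG"),
                                  n_triple = 5, fold = 10, recomb_fold = 2))
  g <- simulate_genome(cfg)
  tracks <- simulate_tracks(cfg, g$truth)
  ph <- plant_hotspots(cfg, tracks, g$truth)
  grid <- filter_gap_windows(make_windows(g$layout, cfg$W), g$gaps)
  fwm <- build_matrix(grid, ph$tracks)
  tw <- ph$truth$hotspots$triple
  # at fold 10 the planted windows dominate the count distribution
  lev <- fwm$levels[, "SNPdb"]
  expect_setequal(order(lev, decreasing = TRUE)[seq_along(tw)], tw)
  # recombination intensity elevated in the same windows
  rec <- fwm$levels[, "RecH"]
  expect_gt(mean(rec[tw]), 1.5 * mean(rec[-tw]))
})

test_that("a fold of one leaves tracks unchanged", {
  cfg <- small_sim(seed = 89,
                   hotspot = list(features = c("SNPdb", "SNP1K", "CNVG"),
                                  n_triple = 5, fold = 1, recomb_fold = 1))
  g <- simulate_genome(cfg)
  tracks <- simulate_tracks(cfg, g$truth)
  ph <- plant_hotspots(cfg, tracks, g$truth)
  expect_identical(ph$tracks, tracks)
  expect_length(ph$truth$hotspots$triple, 5)
})

test_that("datasets write to the formats the readers consume", {
  cfg <- small_sim(seed = 90,
                   hotspot = list(features = c("SNPdb", "SNP1K", "CNVG"),
                                  n_triple = 2))
  ds <- simulate_dataset(cfg)
  dir <- withr::local_tempdir()
  write_dataset(ds, dir)
  lay <- read_chrom_sizes(file.path(dir, "chrom.sizes"))
  expect_equal(lay, ds$layout)
  man <- read_table_tsv(file.path(dir, "tracks_manifest.tsv"))
  expect_setequal(man$name, names(ds$tracks))
  back <- read_feature_track(file.path(dir, man$path[man$name == "SNPdb"]),
                             "SNPdb", "count", layout = lay)
  expect_equal(back$intervals$start, ds$tracks[["SNPdb"]]$intervals$start)
  truth <- jsonlite::read_json(file.path(dir, "truth.json"),
                               simplifyVector = TRUE)
  expect_equal(sort(truth$hotspots$triple), ds$truth$hotspots$triple)
  expect_equal(length(truth$windows$zone), nrow(ds$truth$windows))
})
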