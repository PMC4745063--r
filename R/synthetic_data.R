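# run code under a temporary RNG state so simulators are pure in (cfg, seed)
with_local_seed <- function(seed, code) {
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = genv)
    else if (exists(".Random.seed", envir = genv, inherits = FALSE))
      rm(".Random.seed", envir = genv)
  })
  set.seed(seed)
  code
}

#' Default simulated feature panel
#'
#' The 42 standard features with per-feature simulation parameters: expected
#' elements per window (`base_mean`), log-normal interval-length parameters
#' for base-covering tracks, and gamma score parameters for intensity-mode
#' tracks.
#'
#' @return Data frame extending [default_feature_config()] with columns
#'   `base_mean`, `len_meanlog`, `len_sdlog`, `score_shape`, `score_rate`.
#' @export
default_sim_features <- function() {
  cfg <- default_feature_config()
  cfg$base_mean <- ifelse(cfg$mode == "count", 200, 40)
  cfg$len_meanlog <- ifelse(cfg$mode == "count", NA, log(500))
  cfg$len_sdlog <- ifelse(cfg$mode == "count", NA, 0.8)
  cfg$score_shape <- ifelse(cfg$mode == "intensity", 2, NA)
  cfg$score_rate <- ifelse(cfg$mode == "intensity", 2, NA)
  cfg
}

#' Simulation configuration
#'
#' Describes a fully synthetic genome: chromosome layout, window size, zonal
#' segment structure, per-feature generative parameters, planted pairwise
#' correlations, and an optional hotspot plan. Given the same configuration
#' and seed the simulators are byte-deterministic.
#'
#' @param seed Integer master seed; all randomness derives from it.
#' @param n_chrom Number of chromosomes (default 22 autosome-like).
#' @param chrom_length Chromosome length in bp.
#' @param W Window size in bp (default 500 kb).
#' @param zone_mix Named fractions of kept windows per zone; must sum to 1.
#'   Default 45.1/31.1/23.8% Genic/Proximal/Distal.
#' @param segment_length Zone segment length in bp; must be a multiple of
#'   `W` (zones are laid down in whole-window runs).
#' @param gap_windows_per_chrom Windows per chromosome that receive a gap
#'   interval (and are removed from analysis).
#' @param features Data frame as [default_sim_features()].
#' @param zone_fold Mean elevation of a zone feature inside its own zone
#'   relative to outside (>= 1; default 4).
#' @param level_cv Coefficient of variation of the latent window-to-window
#'   level modulation.
#' @param planted_r Optional data frame `feature_a`, `feature_b`, `r`
#'   (|r| < 1) of target level correlations between feature pairs.
#' @param hotspot Optional plan:
#'   `list(features =, n_triple =, n_double = 0, n_single = 0, fold =,
#'   recomb_feature = "RecH", recomb_fold = 2)`.
#' @param n_genes,n_gene_sets,genes_per_set Gene-track and gene-set sizes.
#' @return A `sim_config` list.
#' @export
sim_config <- function(seed = 1,
                       n_chrom = 22,
                       chrom_length = 1.25e8,
                       W = 5e5,
                       zone_mix = c(Genic = 0.451, Proximal = 0.311,
                                    Distal = 0.238),
                       segment_length = 5 * W,
                       gap_windows_per_chrom = 1,
                       features = default_sim_features(),
                       zone_fold = 4,
                       level_cv = 0.25,
                       planted_r = NULL,
                       hotspot = NULL,
                       n_genes = 400,
                       n_gene_sets = 10,
                       genes_per_set = 25) {
  if (abs(sum(zone_mix) - 1) > 1e-8) stop("zone_mix fractions must sum to 1")
  if (is.null(names(zone_mix)) || any(!nzchar(names(zone_mix)))) {
    stop("zone_mix must be named")
  }
  if (segment_length %% W != 0) {
    stop("segment length not a multiple of W")
  }
  if (zone_fold < 1) stop("zone_fold must be >= 1")
  if (!is.null(planted_r)) {
    planted_r <- as.data.frame(planted_r, stringsAsFactors = FALSE)
    stopifnot(all(c("feature_a", "feature_b", "r") %in% names(planted_r)))
    if (any(abs(planted_r$r) >= 1)) stop("target |r| must be < 1")
    miss <- setdiff(c(planted_r$feature_a, planted_r$feature_b),
                    features$feature)
    if (length(miss)) {
      stop("planted pair names the unknown feature: ",
           paste(miss, collapse = ", "))
    }
  }
  if (!is.null(hotspot)) {
    hotspot <- utils::modifyList(list(n_double = 0, n_single = 0, fold = 10,
                                      recomb_feature = "RecH",
                                      recomb_fold = 2),
                                 hotspot)
    if (is.null(hotspot$features) || is.null(hotspot$n_triple)) {
      stop("hotspot plan needs $features and $n_triple")
    }
    if (hotspot$fold < 1 || hotspot$recomb_fold < 1) {
      stop("elevation folds must be >= 1")
    }
  }
  structure(list(seed = as.integer(seed), n_chrom = n_chrom,
                 chrom_length = chrom_length, W = W, zone_mix = zone_mix,
                 segment_length = segment_length,
                 gap_windows_per_chrom = gap_windows_per_chrom,
                 features = features, zone_fold = zone_fold,
                 level_cv = level_cv, planted_r = planted_r,
                 hotspot = hotspot, n_genes = n_genes,
                 n_gene_sets = n_gene_sets, genes_per_set = genes_per_set),
            class = "sim_config")
}

# exact largest-remainder apportionment of n items to the given fractions
apportion <- function(n, fractions) {
  raw <- n * fractions
  base <- floor(raw)
  rem <- n - sum(base)
  if (rem > 0) {
    extra <- order(raw - base, decreasing = TRUE)[seq_len(rem)]
    base[extra] <- base[extra] + 1
  }
  base
}

#' Simulate a genome layout with gaps and planted zone structure
#'
#' Emits chromosomes of the configured length, plants one gap interval in
#' randomly chosen windows (which downstream gap filtering removes), and
#' assigns every kept window a true zone. Zone labels are laid down in
#' contiguous whole-window segments whose shuffled order is random but whose
#' zone totals match `zone_mix` exactly up to one window (largest-remainder
#' apportionment).
#'
#' @param cfg A [sim_config()].
#' @return List with `layout` ([genome_layout()]), `gaps` (interval data
#'   frame), and `truth` (a `sim_truth`: kept windows with `zone`, plus the
#'   planted correlation and hotspot bookkeeping).
#' @export
simulate_genome <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  with_local_seed(cfg$seed, {
    layout <- genome_layout(paste0("chr", seq_len(cfg$n_chrom)),
                            rep(cfg$chrom_length, cfg$n_chrom))
    grid <- make_windows(layout, cfg$W)
    # plant gaps inside randomly chosen windows
    gaps <- NULL
    if (cfg$gap_windows_per_chrom > 0) {
      gap_rows <- unlist(lapply(split(seq_len(nrow(grid)), grid$chrom),
                                function(ix) {
        sample(ix, min(cfg$gap_windows_per_chrom, length(ix)))
      }), use.names = FALSE)
      gw <- grid[sort(gap_rows), , drop = FALSE]
      gaps <- data.frame(chrom = gw$chrom,
                         start = gw$start + cfg$W %/% 4,
                         end = gw$end - cfg$W %/% 4,
                         stringsAsFactors = FALSE)
      grid <- filter_gap_windows(grid, gaps)
    } else {
      gaps <- data.frame(chrom = character(0), start = numeric(0),
                         end = numeric(0), stringsAsFactors = FALSE)
    }
    kept <- grid[grid$kept, c("chrom", "index", "start", "end"), drop = FALSE]
    rownames(kept) <- NULL
    n <- nrow(kept)
    # exact per-zone window counts, arranged in shuffled whole-window runs
    counts <- apportion(n, cfg$zone_mix)
    seg_w <- cfg$segment_length / cfg$W
    seg_labels <- unlist(lapply(seq_along(counts), function(i) {
      full <- counts[i] %/% seg_w
      rem <- counts[i] %% seg_w
      c(rep(list(rep(names(counts)[i], seg_w)), full),
        if (rem > 0) list(rep(names(counts)[i], rem)))
    }), recursive = FALSE)
    seg_labels <- seg_labels[sample(length(seg_labels))]
    kept$zone <- unlist(seg_labels, use.names = FALSE)
    truth <- structure(list(seed = cfg$seed, W = cfg$W, windows = kept,
                            planted_r = cfg$planted_r,
                            hotspots = NULL),
                       class = "sim_truth")
    list(layout = layout, gaps = gaps, truth = truth)
  })
}

# expected r between two Poisson counts whose means are log-normally
# modulated by latent Gaussians with correlation rl:
#   r_obs = (exp(cv^2 rl) - 1) / sqrt(d_i d_j),  d = exp(cv^2) - 1 + 1/mu
# inverted to find the latent correlation that realizes a target r_obs
latent_r_for_target <- function(r_target, d_i, d_j, cv) {
  arg <- 1 + r_target * sqrt(d_i * d_j)
  if (arg <= 0) return(NA_real_)
  log(arg) / cv^2
}

#' Simulate feature tracks over a synthetic genome
#'
#' Per kept window, latent Gaussian factors (correlated across planted
#' feature pairs) log-normally modulate zone-dependent expected levels;
#' element counts are Poisson around those expectations, interval lengths
#' log-normal, and scores gamma. For count-mode features the latent
#' correlation is calibrated analytically so that the observed Pearson r
#' between window counts converges to the planted target; for coverage-based
#' modes the same latent structure yields approximately the target.
#'
#' @param cfg A [sim_config()].
#' @param truth The `sim_truth` from [simulate_genome()].
#' @return Named list of [feature_track()] objects, one per configured
#'   feature.
#' @export
simulate_tracks <- function(cfg, truth) {
  stopifnot(inherits(cfg, "sim_config"), inherits(truth, "sim_truth"))
  with_local_seed(cfg$seed + 1L, {
    fdf <- cfg$features
    k <- nrow(fdf)
    win <- truth$windows
    n <- nrow(win)
    W <- cfg$W
    cv <- cfg$level_cv
    # zone-dependent expected elements per window
    mu <- matrix(rep(fdf$base_mean, each = n), nrow = n, ncol = k,
                 dimnames = list(NULL, fdf$feature))
    for (j in seq_len(k)) {
      if (fdf$group[j] %in% names(cfg$zone_mix)) {
        mu[win$zone == fdf$group[j], j] <- fdf$base_mean[j] * cfg$zone_fold
      }
    }
    # latent correlation matrix calibrated to the planted targets
    C <- diag(k)
    rownames(C) <- colnames(C) <- fdf$feature
    if (!is.null(cfg$planted_r) && nrow(cfg$planted_r) > 0) {
      d <- exp(cv^2) - 1 + colMeans(1 / mu)
      for (i in seq_len(nrow(cfg$planted_r))) {
        a <- cfg$planted_r$feature_a[i]
        b <- cfg$planted_r$feature_b[i]
        rl <- latent_r_for_target(cfg$planted_r$r[i], d[a], d[b], cv)
        if (is.na(rl) || abs(rl) >= 1) {
          stop("infeasible correlation plan: target r = ",
               cfg$planted_r$r[i], " for pair ", a, "-", b,
               " needs latent correlation outside (-1, 1)")
        }
        C[a, b] <- C[b, a] <- rl
      }
      ev <- eigen(C, symmetric = TRUE, only.values = TRUE)$values
      if (min(ev) < -1e-8) {
        stop("infeasible correlation plan: implied latent covariance is ",
             "not positive semi-definite")
      }
    }
    Z <- matrix(stats::rnorm(n * k), nrow = n) %*% chol(C + diag(1e-10, k))
    lambda <- mu * exp(cv * Z - cv^2 / 2)
    counts <- matrix(stats::rpois(n * k, lambda), nrow = n)
    tracks <- vector("list", k)
    names(tracks) <- fdf$feature
    for (j in seq_len(k)) {
      cnt <- counts[, j]
      total <- sum(cnt)
      widx <- rep(seq_len(n), cnt)
      wstart <- win$start[widx]
      if (fdf$mode[j] == "count") {
        start <- wstart + floor(stats::runif(total) * W)
        end <- start + 1
        score <- rep(NA_real_, total)
      } else {
        len <- pmax(1, pmin(round(stats::rlnorm(total, fdf$len_meanlog[j],
                                                fdf$len_sdlog[j])), W))
        start <- wstart + floor(stats::runif(total) * (W - len + 1))
        end <- start + len
        score <- if (fdf$mode[j] == "intensity") {
          stats::rgamma(total, shape = fdf$score_shape[j],
                        rate = fdf$score_rate[j])
        } else rep(NA_real_, total)
      }
      tracks[[j]] <- feature_track(fdf$feature[j], fdf$mode[j],
                                   data.frame(chrom = win$chrom[widx],
                                              start = start, end = end,
                                              score = score,
                                              stringsAsFactors = FALSE))
    }
    tracks
  })
}

# row indices of track elements whose start falls in the given kept window
elements_in_window <- function(iv, w) {
  which(iv$chrom == w$chrom & iv$start >= w$start & iv$start < w$end)
}

#' Plant hotspot windows into simulated tracks
#'
#' Selects disjoint sets of kept windows as single, double and triple
#' hotspots and multiplies the element counts of the planned features there
#' by the elevation fold (single windows elevate the first planned feature
#' only, double the first two, triple all). Triple-hotspot windows
#' additionally have the recombination track's scores elevated. The truth
#' object is updated with the planted window indices.
#'
#' @param cfg A [sim_config()] with a `hotspot` plan.
#' @param tracks Track list from [simulate_tracks()].
#' @param truth The matching `sim_truth`.
#' @return List with updated `tracks` and `truth`; `truth$hotspots` holds
#'   `triple`, `double`, `single` (kept-window row indices), the planted
#'   `fold`, and per-feature window sets.
#' @export
plant_hotspots <- function(cfg, tracks, truth) {
  stopifnot(inherits(cfg, "sim_config"), inherits(truth, "sim_truth"))
  plan <- cfg$hotspot
  if (is.null(plan)) return(list(tracks = tracks, truth = truth))
  with_local_seed(cfg$seed + 2L, {
    win <- truth$windows
    n <- nrow(win)
    total_needed <- plan$n_triple + plan$n_double + plan$n_single
    if (total_needed > n) stop("hotspot plan exceeds available kept windows")
    pick <- sample(n, total_needed)
    triple <- sort(pick[seq_len(plan$n_triple)])
    dbl <- sort(pick[plan$n_triple + seq_len(plan$n_double)])
    sgl <- sort(pick[plan$n_triple + plan$n_double + seq_len(plan$n_single)])
    feats <- plan$features
    per_feature <- lapply(seq_along(feats), function(j) {
      sort(unique(c(triple,
                    if (j <= 2) dbl else integer(0),
                    if (j == 1) sgl else integer(0))))
    })
    names(per_feature) <- feats
    elevate_counts <- function(track, widx) {
      if (plan$fold == 1 || length(widx) == 0L) return(track)
      iv <- track$intervals
      add <- list()
      for (i in widx) {
        w <- win[i, ]
        rows <- elements_in_window(iv, w)
        extra <- round(plan$fold * length(rows)) - length(rows)
        if (extra > 0) {
          start <- w$start + floor(stats::runif(extra) * (w$end - w$start))
          add[[length(add) + 1L]] <-
            data.frame(chrom = w$chrom, start = start, end = start + 1,
                       name = NA_character_, score = NA_real_,
                       stringsAsFactors = FALSE)
        }
      }
      if (length(add)) {
        iv <- rbind(iv, do.call(rbind, add))
      }
      feature_track(track$feature_name, track$mode, iv)
    }
    for (f in feats) {
      if (is.null(tracks[[f]])) stop("hotspot plan names unknown track: ", f)
      tracks[[f]] <- elevate_counts(tracks[[f]], per_feature[[f]])
    }
    rf <- plan$recomb_feature
    if (!is.null(rf) && !is.null(tracks[[rf]]) && plan$recomb_fold > 1 &&
        length(triple)) {
      iv <- tracks[[rf]]$intervals
      for (i in triple) {
        rows <- elements_in_window(iv, win[i, ])
        iv$score[rows] <- iv$score[rows] * plan$recomb_fold
      }
      tracks[[rf]] <- feature_track(rf, tracks[[rf]]$mode, iv)
    }
    truth$hotspots <- list(triple = triple, double = sort(c(triple, dbl)),
                           single = sgl, fold = plan$fold,
                           recomb_fold = plan$recomb_fold,
                           per_feature = per_feature)
    list(tracks = tracks, truth = truth)
  })
}

# random gene track over kept windows plus random gene-set definitions
simulate_genes <- function(cfg, truth) {
  with_local_seed(cfg$seed + 3L, {
    win <- truth$windows
    n <- nrow(win)
    widx <- sample(n, cfg$n_genes, replace = TRUE)
    W <- cfg$W
    len <- pmax(200, pmin(round(stats::rlnorm(cfg$n_genes, log(2e4), 0.8)), W))
    start <- win$start[widx] + floor(stats::runif(cfg$n_genes) * (W - len + 1))
    nm <- sprintf("g%05d", seq_len(cfg$n_genes))
    genes <- feature_track("GENE_NAMES", "density",
                           data.frame(chrom = win$chrom[widx], start = start,
                                      end = start + len, name = nm,
                                      stringsAsFactors = FALSE))
    sets <- lapply(seq_len(cfg$n_gene_sets), function(i) {
      sort(sample(nm, min(cfg$genes_per_set, cfg$n_genes)))
    })
    names(sets) <- sprintf("set%02d", seq_len(cfg$n_gene_sets))
    list(genes = genes, gene_sets = sets)
  })
}

#' Simulate a complete synthetic dataset
#'
#' Runs [simulate_genome()], [simulate_tracks()], [plant_hotspots()] and the
#' gene/gene-set generator in sequence.
#'
#' @param cfg A [sim_config()].
#' @return List: `layout`, `gaps`, `tracks`, `genes`, `gene_sets`, `truth`.
#' @export
simulate_dataset <- function(cfg) {
  g <- simulate_genome(cfg)
  tracks <- simulate_tracks(cfg, g$truth)
  ph <- plant_hotspots(cfg, tracks, g$truth)
  gg <- simulate_genes(cfg, ph$truth)
  list(layout = g$layout, gaps = g$gaps, tracks = ph$tracks,
       genes = gg$genes, gene_sets = gg$gene_sets, truth = ph$truth)
}

safe_name <- function(x) gsub("[^A-Za-z0-9_.-]", "_", x)

#' Write a synthetic dataset to disk
#'
#' Emits exactly the file formats the readers consume: chrom.sizes, gap BED,
#' one BED per track plus a track manifest TSV (name, path, mode, group),
#' gene BED, gene-set TSV, and the ground truth as JSON.
#'
#' @param ds Dataset from [simulate_dataset()].
#' @param dir Output directory (created if absent).
#' @param features Feature config used for manifest `group` entries.
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(ds, dir, features = default_sim_features()) {
  dir.create(file.path(dir, "tracks"), recursive = TRUE, showWarnings = FALSE)
  write_chrom_sizes(ds$layout, file.path(dir, "chrom.sizes"))
  if (nrow(ds$gaps)) {
    write_track_bed(feature_track("gap", "density", ds$gaps),
                    file.path(dir, "gaps.bed"))
  } else {
    writeLines(character(0), file.path(dir, "gaps.bed"))
  }
  manifest <- data.frame(name = character(0), path = character(0),
                         mode = character(0), group = character(0),
                         stringsAsFactors = FALSE)
  for (t in ds$tracks) {
    rel <- file.path("tracks", paste0(safe_name(t$feature_name), ".bed"))
    write_track_bed(t, file.path(dir, rel))
    grp <- features$group[match(t$feature_name, features$feature)]
    manifest <- rbind(manifest,
                      data.frame(name = t$feature_name, path = rel,
                                 mode = t$mode,
                                 group = ifelse(is.na(grp), "Marker", grp),
                                 stringsAsFactors = FALSE))
  }
  write_table(manifest, file.path(dir, "tracks_manifest.tsv"))
  write_track_bed(ds$genes, file.path(dir, "genes.bed"))
  write_gene_sets(ds$gene_sets, file.path(dir, "gene_sets.tsv"))
  truth <- unclass(ds$truth)
  truth$windows <- as.list(truth$windows)
  if (!is.null(truth$planted_r)) truth$planted_r <- as.list(truth$planted_r)
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(dir)
}
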