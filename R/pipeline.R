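#' Read a run configuration
#'
#' A declarative YAML file naming the inputs and analysis settings of a full
#' run. Recognised keys: `layout`, `gaps`, `tracks_manifest`, `genes`,
#' `gene_sets` (paths, resolved relative to the config file), `outdir`,
#' `window_sizes` (bp, one grid per size), `hotspot_q`, `hotspot_features`,
#' `recomb_feature`, `seed`.
#'
#' @param path Path to the YAML config.
#' @return A `run_config` list with paths resolved.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  base <- dirname(normalizePath(path))
  for (key in c("layout", "gaps", "tracks_manifest", "genes", "gene_sets")) {
    if (!is.null(cfg[[key]]) && !grepl("^/", cfg[[key]])) {
      cfg[[key]] <- file.path(base, cfg[[key]])
    }
  }
  if (!is.null(cfg$outdir) && !grepl("^/", cfg$outdir)) {
    cfg$outdir <- file.path(base, cfg$outdir)
  }
  structure(cfg, class = "run_config")
}

default_run_settings <- function() {
  list(window_sizes = 5e5,
       hotspot_q = 0.05,
       hotspot_features = c("SNPdb", "SNP1K", "CNVG"),
       recomb_feature = "RecH",
       seed = 1L)
}

load_tracks_from_manifest <- function(manifest_path, layout) {
  man <- read_table_tsv(manifest_path)
  stopifnot(all(c("name", "path", "mode") %in% names(man)))
  base <- dirname(normalizePath(manifest_path))
  tracks <- vector("list", nrow(man))
  for (i in seq_len(nrow(man))) {
    p <- man$path[i]
    if (!grepl("^/", p)) p <- file.path(base, p)
    if (!file.exists(p)) stop("track file missing: ", p)
    tracks[[i]] <- read_feature_track(p, man$name[i], man$mode[i],
                                      layout = layout)
  }
  names(tracks) <- man$name
  attr(tracks, "manifest") <- man
  tracks
}

# zone model induced by the manifest's group column (Marker rows excluded)
zone_model_from_manifest <- function(man) {
  if (is.null(man$group)) return(NULL)
  zones <- c("Genic", "Proximal", "Distal")
  model <- lapply(zones, function(z) man$name[man$group == z])
  names(model) <- zones
  model <- model[lengths(model) > 0]
  if (length(model) < 2L) return(NULL)
  class(model) <- "zone_model"
  model
}

run_stage <- function(name, expr) {
  message("[", format(Sys.time(), "%H:%M:%S"), "] stage: ", name)
  tryCatch(expr, error = function(e) {
    stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE)
  })
}

#' Run the full co-localization analysis
#'
#' Orchestrates every stage for each configured window size: window binning
#' and gap filtering, per-window quantitation, the pairwise co-localization
#' matrix with Pearson/Spearman coefficients and asymptotic p-values, zone
#' classification with proportions and designation accuracy, hotspot calling
#' with Venn decomposition, the recombination rate test in triple-hotspot
#' windows, and (when genes and gene sets are supplied) over-representation
#' analysis of triple-hotspot gene content. Cross-size concordances
#' (R_C per size, R_W per size pair) and a run manifest with file checksums
#' are written last. All outputs are pure functions of (inputs, config,
#' seed); re-running an identical config reproduces them bit-identically.
#'
#' @param config A `run_config` (from [read_run_config()]) or an equivalent
#'   named list.
#' @return Invisibly, a list with the per-size result objects and the
#'   concordance table; artifacts are written under `config$outdir`.
#' @export
run_full_analysis <- function(config) {
  cfg <- utils::modifyList(default_run_settings(), as.list(config))
  for (key in c("layout", "gaps", "tracks_manifest", "outdir")) {
    if (is.null(cfg[[key]])) stop("run config missing required key: ", key)
  }
  for (key in c("layout", "gaps", "tracks_manifest", "genes", "gene_sets")) {
    if (!is.null(cfg[[key]]) && !file.exists(cfg[[key]])) {
      stop("input path does not exist: ", cfg[[key]])
    }
  }
  dir.create(cfg$outdir, recursive = TRUE, showWarnings = FALSE)

  layout <- run_stage("read layout", read_chrom_sizes(cfg$layout))
  gaps <- run_stage("read gaps", {
    if (file.size(cfg$gaps) > 0) read_bed(cfg$gaps) else
      data.frame(chrom = character(0), start = numeric(0), end = numeric(0))
  })
  tracks <- run_stage("read tracks",
                      load_tracks_from_manifest(cfg$tracks_manifest, layout))
  man <- attr(tracks, "manifest")
  model <- zone_model_from_manifest(man)
  genes <- if (!is.null(cfg$genes)) {
    run_stage("read genes",
              read_feature_track(cfg$genes, "genes", "density", layout))
  }
  gene_sets <- if (!is.null(cfg$gene_sets)) {
    run_stage("read gene sets", read_gene_sets(cfg$gene_sets))
  }

  per_size <- list()
  outputs <- character(0)
  emit <- function(path) outputs <<- c(outputs, path)

  for (W in sort(cfg$window_sizes)) {
    tag <- paste0("W", format(W, scientific = FALSE))
    wdir <- file.path(cfg$outdir, tag)
    dir.create(wdir, showWarnings = FALSE)
    res <- list(W = W)

    grid <- run_stage(paste0(tag, ": windows"), {
      g <- make_windows(layout, W)
      filter_gap_windows(g, gaps)
    })
    emit(write_grid_bed(grid, file.path(wdir, "windows.bed")))
    message("  windows: ", nrow(grid), " total, ", n_kept(grid), " kept")

    fwm <- run_stage(paste0(tag, ": quantitation"), build_matrix(grid, tracks))
    emit(write_matrix_tsv(fwm, file.path(wdir, "feature_window_matrix.tsv")))
    res$fwm <- fwm

    cm <- run_stage(paste0(tag, ": co-localization"), build_coloc_matrix(fwm))
    emit(write_coloc_tsv(cm, file.path(wdir, "colocalization.tsv")))
    res$coloc <- cm
    res$R_C <- concordance(cm$r, cm$rho, "R_C")$value
    emit(write_table(p_value_census(cm), file.path(wdir, "p_census.tsv")))

    if (!is.null(model)) {
      assign <- run_stage(paste0(tag, ": zonation"),
                          classify_windows(fwm, model))
      emit(write_zone_bed(assign, file.path(wdir, "zones.bed")))
      emit(write_table(zone_proportions(assign),
                       file.path(wdir, "zone_proportions.tsv")))
      fr <- zonal_feature_fractions(fwm, assign,
                                    unlist(model, use.names = FALSE))
      acc <- designation_match_accuracy(fr, model)
      emit(write_table(acc$per_feature,
                       file.path(wdir, "designation_match.tsv")))
      res$zones <- assign
      res$designation_accuracy <- acc$accuracy
    } else assign <- NULL

    hs_feats <- intersect(cfg$hotspot_features, fwm$features)
    if (length(hs_feats) >= 2L) {
      sets <- run_stage(paste0(tag, ": hotspots"), {
        lapply(hs_feats, function(f) call_hotspots(fwm, f, cfg$hotspot_q))
      })
      names(sets) <- hs_feats
      for (f in hs_feats) {
        emit(write_hotspot_bed(sets[[f]], fwm,
                               file.path(wdir, paste0("hotspots_",
                                                      safe_name(f), ".bed"))))
      }
      ov <- overlap_hotspots(sets, assign)
      emit(write_table(ov$venn, file.path(wdir, "hotspot_venn.tsv")))
      res$hotspots <- sets
      res$overlap <- ov

      rf <- cfg$recomb_feature
      if (!is.null(rf) && rf %in% fwm$features && length(ov$triple) >= 2L) {
        rt <- rate_test(fwm$levels[, rf], fwm$levels[ov$triple, rf])
        emit(write_table(data.frame(group_mean = rt$group$mean,
                                    group_sd = rt$group$sd,
                                    group_n = rt$group$n,
                                    background_mean = rt$background$mean,
                                    background_sd = rt$background$sd,
                                    background_n = rt$background$n,
                                    t = rt$t, df = rt$df, p = rt$p),
                         file.path(wdir, "rate_test.tsv")))
        res$rate_test <- rt
      }

      if (!is.null(genes) && !is.null(gene_sets) && length(ov$triple) > 0) {
        gl <- genes_in_windows(genes, fwm$windows[ov$triple, , drop = FALSE])
        universe <- genes_in_windows(genes, fwm$windows)
        sets_u <- lapply(gene_sets, intersect, universe)
        sets_u <- sets_u[lengths(sets_u) > 0]
        if (length(gl) > 0 && length(sets_u) > 0) {
          enr <- ora_enrichment(gl, universe, sets_u)
          emit(write_table(as.data.frame(enr),
                           file.path(wdir, "enrichment.tsv")))
          res$enrichment <- enr
          res$n_hotspot_genes <- length(gl)
        }
      }
    }
    per_size[[tag]] <- res
  }

  # cross-size concordances on aligned pair vectors
  conc <- data.frame(label = character(0), size_a = numeric(0),
                     size_b = numeric(0), value = numeric(0),
                     stringsAsFactors = FALSE)
  tags <- names(per_size)
  for (i in seq_along(tags)) {
    conc <- rbind(conc, data.frame(label = "R_C",
                                   size_a = per_size[[i]]$W,
                                   size_b = per_size[[i]]$W,
                                   value = per_size[[i]]$R_C))
  }
  if (length(tags) >= 2L) {
    for (i in seq_len(length(tags) - 1)) {
      for (j in seq(i + 1, length(tags))) {
        a <- per_size[[i]]$coloc
        b <- per_size[[j]]$coloc
        key_a <- paste(a$feature_a, a$feature_b)
        key_b <- paste(b$feature_a, b$feature_b)
        common <- intersect(key_a, key_b)
        rw <- concordance(a$r[match(common, key_a)],
                          b$r[match(common, key_b)], "R_W")$value
        conc <- rbind(conc, data.frame(label = "R_W",
                                       size_a = per_size[[i]]$W,
                                       size_b = per_size[[j]]$W,
                                       value = rw))
      }
    }
  }
  emit(write_table(conc, file.path(cfg$outdir, "concordance.tsv")))

  manifest <- list(seed = cfg$seed,
                   window_sizes = cfg$window_sizes,
                   hotspot_q = cfg$hotspot_q,
                   hotspot_features = cfg$hotspot_features,
                   inputs = cfg[c("layout", "gaps", "tracks_manifest")],
                   checksums = as.list(tools::md5sum(sort(unique(outputs)))))
  yaml::write_yaml(manifest, file.path(cfg$outdir, "run_manifest.yaml"))

  invisible(list(per_size = per_size, concordance = conc,
                 outputs = sort(unique(outputs))))
}
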