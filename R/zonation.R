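#' Default zone model
#'
#' The tripartite zone model: each zone is defined by the non-Marker features
#' enriched in it. Genic zones carry the 24 gene-associated features
#' (genes, regulatory and epigenetic marks, expression/RNA signals, CpG and
#' methylation features, Alu elements); Proximal zones the four
#' gene-proximal features L2, MIR, CID and TFBS; Distal zones the
#' gene-distal features NAS-, L1 and ATrich — 31 defining features in total.
#' Marker features (variants, recombination rates, microsatellites) do not
#' define zones.
#'
#' @return A `zone_model`: named list of character vectors
#'   (Genic, Proximal, Distal).
#' @export
default_zone_model <- function() {
  cfg <- default_feature_config()
  model <- list(Genic = cfg$feature[cfg$group == "Genic"],
                Proximal = cfg$feature[cfg$group == "Proximal"],
                Distal = cfg$feature[cfg$group == "Distal"])
  class(model) <- "zone_model"
  model
}

validate_zone_model <- function(model) {
  if (!is.list(model) || is.null(names(model)) || length(model) < 2L) {
    stop("zone model must be a named list of feature vectors")
  }
  feats <- unlist(model, use.names = FALSE)
  if (anyDuplicated(feats)) {
    stop("zone model features must be disjoint across zones: ",
         paste(unique(feats[duplicated(feats)]), collapse = ", "))
  }
  invisible(model)
}

#' Classify windows into zones by the feature-ratios method
#'
#' For each kept window w and zone z, the ratio score is the mean over the
#' zone's defining features of the window's level divided by the feature's
#' genome-wide mean level. The window is assigned the zone with the maximal
#' score; exact ties break deterministically by zone order in the model
#' (Genic > Proximal > Distal for the default). Scores are scale-invariant
#' per feature: multiplying a feature column by a positive constant changes
#' no label.
#'
#' @param fwm A `feature_window_matrix` containing every model feature.
#' @param model A zone model (named list zone -> feature names); defaults to
#'   [default_zone_model()] restricted to Marker-free features.
#' @return A `zone_assignment` data frame: window columns, one `score_<zone>`
#'   column per zone, and `zone`; the model is kept as an attribute.
#' @export
classify_windows <- function(fwm, model = default_zone_model()) {
  stopifnot(inherits(fwm, "feature_window_matrix"))
  validate_zone_model(model)
  feats <- unlist(model, use.names = FALSE)
  miss <- setdiff(feats, fwm$features)
  if (length(miss)) {
    stop("model features absent from matrix: ", paste(miss, collapse = ", "))
  }
  mat <- fwm$levels[, feats, drop = FALSE]
  mu <- colMeans(mat)
  zero <- names(mu)[mu == 0]
  if (length(zero)) {
    stop("zero genome-wide mean for defining feature: ",
         paste(zero, collapse = ", "))
  }
  ratio <- sweep(mat, 2, mu, "/")
  scores <- vapply(model, function(f) {
    rowMeans(ratio[, f, drop = FALSE])
  }, numeric(nrow(mat)))
  zones <- names(model)
  # which.max returns the first maximum: ties break by model zone order
  lab <- zones[apply(scores, 1, which.max)]
  out <- fwm$windows
  for (z in zones) out[[paste0("score_", z)]] <- scores[, z]
  out$zone <- lab
  attr(out, "model") <- model
  class(out) <- c("zone_assignment", "data.frame")
  out
}

#' Zone proportions
#'
#' Counts and fractions of kept windows per zone; fractions sum to 1.
#' @param assign A `zone_assignment`.
#' @return Data frame with columns `zone`, `n`, `fraction` in model order.
#' @export
zone_proportions <- function(assign) {
  stopifnot(inherits(assign, "zone_assignment"))
  zones <- names(attr(assign, "model"))
  n <- vapply(zones, function(z) sum(assign$zone == z), integer(1))
  data.frame(zone = zones, n = n, fraction = n / sum(n),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Zonal fractional distribution of features
#'
#' For each feature, the fraction of its genome-wide summed level that falls
#' in each zone's windows; each row sums to 1.
#'
#' @param fwm A `feature_window_matrix`.
#' @param assign The matching `zone_assignment`.
#' @param features Features to tabulate (default all in the matrix).
#' @return Numeric matrix, features x zones.
#' @export
zonal_feature_fractions <- function(fwm, assign, features = fwm$features) {
  stopifnot(inherits(fwm, "feature_window_matrix"),
            inherits(assign, "zone_assignment"))
  if (nrow(assign) != nrow(fwm$levels)) {
    stop("assignment and matrix cover different window sets")
  }
  miss <- setdiff(features, fwm$features)
  if (length(miss)) stop("unknown features: ", paste(miss, collapse = ", "))
  zones <- names(attr(assign, "model"))
  mat <- fwm$levels[, features, drop = FALSE]
  tot <- colSums(mat)
  zero <- features[tot == 0]
  if (length(zero)) {
    stop("all-zero feature has undefined zonal fractions: ",
         paste(zero, collapse = ", "))
  }
  frac <- vapply(zones, function(z) {
    colSums(mat[assign$zone == z, , drop = FALSE]) / tot
  }, numeric(length(features)))
  if (length(features) == 1L) {
    frac <- matrix(frac, nrow = 1, dimnames = list(features, zones))
  }
  frac
}

#' Designation-match accuracy of the zone model
#'
#' A defining feature "matches" when the zone holding its largest zonal
#' fraction equals its model-designated zone. The fraction of matching
#' features is an internal consistency check of the feature-ratios
#' classification.
#'
#' @param fractions Feature x zone matrix from [zonal_feature_fractions()].
#' @param model The zone model the features were designated under.
#' @return List with `matched`, `total`, `accuracy` and a `per_feature`
#'   data frame (`feature`, `designated`, `argmax`, `match`).
#' @export
designation_match_accuracy <- function(fractions, model) {
  validate_zone_model(model)
  feats <- unlist(model, use.names = FALSE)
  miss <- setdiff(feats, rownames(fractions))
  if (length(miss)) {
    stop("fractions missing model features: ", paste(miss, collapse = ", "))
  }
  zones <- names(model)
  designated <- rep(zones, times = lengths(model))
  names(designated) <- feats
  fr <- fractions[feats, zones, drop = FALSE]
  argmax <- zones[apply(fr, 1, which.max)]
  match <- argmax == designated
  list(matched = sum(match), total = length(feats),
       accuracy = sum(match) / length(feats),
       per_feature = data.frame(feature = feats, designated = designated,
                                argmax = argmax, match = match,
                                stringsAsFactors = FALSE, row.names = NULL))
}

#' Export a zone assignment as BED4
#' @param assign A `zone_assignment`.
#' @param path Output path.
#' @export
write_zone_bed <- function(assign, path) {
  fmt <- function(x) format(x, scientific = FALSE, trim = TRUE)
  writeLines(paste(assign$chrom, fmt(assign$start), fmt(assign$end),
                   assign$zone, sep = "\t"), path)
  invisible(path)
}
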