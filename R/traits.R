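#' Cylinder geometry of a root segment
#'
#' Roots scanned into (length, diameter) segments are treated as cylinders:
#' surface area `SA = pi * d * L` and volume `RV = pi * (d/2)^2 * L`.
#' Vectorized over segments.
#'
#' @param length_mm Segment length(s) in mm (> 0).
#' @param diameter_mm Segment diameter(s) in mm (> 0).
#' @return A data frame with `length_mm`, `surface_mm2`, `volume_mm3`.
#' @examples
#' segment_geometry(10, 1)  # SA ~ 31.4159, RV ~ 7.8540
#' @export
segment_geometry <- function(length_mm, diameter_mm) {
  if (any(length_mm <= 0) || any(diameter_mm <= 0)) {
    abort_input("segment length and diameter must be > 0")
  }
  data.frame(length_mm = length_mm,
             surface_mm2 = pi * diameter_mm * length_mm,
             volume_mm3 = pi * (diameter_mm / 2)^2 * length_mm)
}

#' Assign depths to substrate layers
#'
#' Half-open layers `[lower, upper)`; the deepest layer is closed at the top
#' edge so the maximum depth belongs to it. Depths outside `[0, max edge]`
#' are an error.
#'
#' @param depth_cm Depth(s) below the substrate surface in cm.
#' @param layer_edges_cm Strictly increasing layer edges (default 0..40 by 10).
#' @return Integer layer indices (1-based).
#' @examples
#' assign_depth_layer(c(5, 10, 40))  # 1 2 4
#' @export
assign_depth_layer <- function(depth_cm, layer_edges_cm = seq(0, 40, by = 10)) {
  if (any(diff(layer_edges_cm) <= 0)) abort_input("'layer_edges_cm' must be strictly increasing")
  lo <- layer_edges_cm[1]; hi <- layer_edges_cm[length(layer_edges_cm)]
  if (any(depth_cm < lo | depth_cm > hi)) {
    abort_input(sprintf("depth outside [%g, %g] cm", lo, hi))
  }
  findInterval(depth_cm, layer_edges_cm, rightmost.closed = TRUE)
}

#' Assign diameters to 0.5-mm classes
#'
#' Half-open classes `[lower, upper)` with the last class closed at the top
#' edge. Diameters above the top edge are not an error: they go to an
#' overflow class (index `number of classes + 1`) and are flagged with a
#' warning.
#'
#' @param diameter_mm Diameter(s) in mm (> 0).
#' @param class_edges_mm Strictly increasing class edges (default 0..4.5 by 0.5).
#' @return Integer class indices (1-based) with attribute `overflow`, a
#'   logical vector marking diameters above the top edge.
#' @examples
#' assign_diameter_class(c(0.7, 0.5))  # both class 2 (0.5-1.0 mm)
#' @export
assign_diameter_class <- function(diameter_mm, class_edges_mm = seq(0, 4.5, by = 0.5)) {
  if (any(diff(class_edges_mm) <= 0)) abort_input("'class_edges_mm' must be strictly increasing")
  if (any(diameter_mm <= 0)) abort_input("diameters must be > 0")
  hi <- class_edges_mm[length(class_edges_mm)]
  overflow <- diameter_mm > hi
  idx <- findInterval(diameter_mm, class_edges_mm, rightmost.closed = TRUE)
  idx[overflow] <- length(class_edges_mm)  # n_classes + 1
  if (any(overflow)) {
    warning(sprintf("%d segment(s) thicker than %g mm assigned to the overflow class",
                    sum(overflow), hi), call. = FALSE)
  }
  attr(idx, "overflow") <- overflow
  idx
}

# internal: class labels including the overflow class
diameter_class_labels <- function(class_edges_mm) {
  n <- length(class_edges_mm) - 1L
  c(sprintf("%.1f-%.1f", class_edges_mm[-length(class_edges_mm)], class_edges_mm[-1]),
    sprintf(">%.1f", class_edges_mm[n + 1L]))
}

# internal: layer labels
depth_layer_labels <- function(layer_edges_cm) {
  sprintf("%g-%g", layer_edges_cm[-length(layer_edges_cm)], layer_edges_cm[-1])
}

#' Aggregate root traits from a segment table
#'
#' WinRhizo-style summaries from per-segment records: total root length
#' (RL, cm), surface area (SA, cm^2), volume (RV, cm^3) and mean root
#' diameter (MRD, mm; length-weighted by default) per plant, optionally
#' resolved by depth layer, diameter class, or both. All group combinations
#' are emitted, so empty groups appear with RL = SA = RV = 0 and MRD missing.
#'
#' @param segments Data frame with columns `plant_id`, `depth_cm`,
#'   `length_mm`, `diameter_mm`.
#' @param grouping One of `"plant"`, `"layer"`, `"class"`, `"layer_class"`.
#' @param layer_edges_cm,class_edges_mm Bin edges (see
#'   [assign_depth_layer()], [assign_diameter_class()]).
#' @param mrd_weighted If `TRUE` (default) MRD is the length-weighted mean
#'   segment diameter; otherwise the unweighted per-segment mean.
#' @return A data frame keyed by `plant_id` (plus `layer` and/or `class`
#'   label columns as requested) with `rl_cm`, `sa_cm2`, `rv_cm3`, `mrd_mm`,
#'   `n_segments`.
#' @examples
#' seg <- data.frame(plant_id = "p", depth_cm = c(5, 15),
#'                   length_mm = c(10, 30), diameter_mm = c(1, 3))
#' aggregate_traits(seg)$mrd_mm  # (1*10 + 3*30) / 40 = 2.5
#' @export
aggregate_traits <- function(segments,
                             grouping = c("plant", "layer", "class", "layer_class"),
                             layer_edges_cm = seq(0, 40, by = 10),
                             class_edges_mm = seq(0, 4.5, by = 0.5),
                             mrd_weighted = TRUE) {
  grouping <- match.arg(grouping)
  req <- c("plant_id", "depth_cm", "length_mm", "diameter_mm")
  if (!is.data.frame(segments) || !all(req %in% names(segments))) {
    abort_input("'segments' must have columns plant_id, depth_cm, length_mm, diameter_mm")
  }
  if (nrow(segments) == 0 && grouping == "plant") {
    abort_input("empty segment table: whole-plant totals need at least one segment")
  }
  plants <- unique(as.character(segments$plant_id))
  use_layer <- grouping %in% c("layer", "layer_class")
  use_class <- grouping %in% c("class", "layer_class")

  geo <- if (nrow(segments) > 0) {
    segment_geometry(segments$length_mm, segments$diameter_mm)
  } else data.frame(length_mm = numeric(0), surface_mm2 = numeric(0), volume_mm3 = numeric(0))

  key <- list(plant_id = as.character(segments$plant_id))
  grid <- list(plant_id = plants)
  if (use_layer) {
    labs <- depth_layer_labels(layer_edges_cm)
    key$layer <- labs[assign_depth_layer(segments$depth_cm, layer_edges_cm)]
    grid$layer <- labs
  }
  if (use_class) {
    labs <- diameter_class_labels(class_edges_mm)
    idx <- suppressWarnings(assign_diameter_class(segments$diameter_mm, class_edges_mm))
    key$class <- labs[idx]
    grid$class <- labs
  }
  full <- expand.grid(rev(grid), stringsAsFactors = FALSE)[, names(grid), drop = FALSE]

  f <- interaction(as.data.frame(key), drop = FALSE, lex.order = TRUE)
  sum_by <- function(v) {
    s <- tapply(v, f, sum, default = 0)
    s[is.na(s)] <- 0
    s
  }
  fk <- interaction(full, drop = FALSE, lex.order = TRUE)
  out <- full
  if (nrow(segments) > 0) {
    rl <- sum_by(geo$length_mm); sa <- sum_by(geo$surface_mm2); rv <- sum_by(geo$volume_mm3)
    dl <- sum_by(segments$diameter_mm * geo$length_mm)  # for weighted MRD
    dsum <- sum_by(segments$diameter_mm)
    nseg <- sum_by(rep(1, nrow(segments)))
    m <- match(as.character(fk), names(rl))
    out$rl_cm <- unname(rl[m]) / 10
    out$sa_cm2 <- unname(sa[m]) / 100
    out$rv_cm3 <- unname(rv[m]) / 1000
    out$n_segments <- as.integer(unname(nseg[m]))
    len <- unname(rl[m])
    out$mrd_mm <- if (mrd_weighted) {
      ifelse(len > 0, unname(dl[m]) / len, NA_real_)
    } else {
      ifelse(out$n_segments > 0, unname(dsum[m]) / out$n_segments, NA_real_)
    }
  } else {
    out$rl_cm <- 0; out$sa_cm2 <- 0; out$rv_cm3 <- 0
    out$n_segments <- 0L; out$mrd_mm <- NA_real_
  }
  out[is.na(out$rl_cm), c("rl_cm", "sa_cm2", "rv_cm3")] <- 0
  out$n_segments[is.na(out$n_segments)] <- 0L
  rownames(out) <- NULL
  out <- out[, c(names(grid), "rl_cm", "sa_cm2", "rv_cm3", "mrd_mm", "n_segments")]
  out[do.call(order, out[names(grid)]), , drop = FALSE] -> out
  rownames(out) <- NULL
  out
}

#' Per-plant trait table for the inferential layer
#'
#' Joins the water-accounting results with whole-plant root traits into the
#' wide per-plant table the ANOVA, plasticity and multivariate stages consume:
#' columns `WU`, `WP`, `root_shoot`, `RDW`, `SDW`, `RL`, `SA`, `RV`, `MRD`.
#'
#' @param experiment An `rsa_experiment`.
#' @param water Optional precomputed [water_results()] table.
#' @return A data frame with one row per plant.
#' @export
plant_trait_table <- function(experiment, water = water_results(experiment)) {
  traits <- aggregate_traits(experiment$root_segments, "plant",
                             layer_edges_cm = experiment$design$layer_edges_cm,
                             class_edges_mm = experiment$design$class_edges_mm)
  out <- merge(water, traits, by = "plant_id", sort = FALSE)
  out <- merge(out, experiment$plants[, c("plant_id", "rdw_g", "sdw_g")],
               by = "plant_id", sort = FALSE)
  data.frame(
    plant_id = out$plant_id, genotype = out$genotype,
    regime = out$regime, block = out$block,
    WU = out$wu_l, WP = out$wp_kg_m3, root_shoot = out$root_shoot,
    RDW = out$rdw_g, SDW = out$sdw_g,
    RL = out$rl_cm, SA = out$sa_cm2, RV = out$rv_cm3, MRD = out$mrd_mm,
    stringsAsFactors = FALSE
  )
}
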