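#' Plant biomass gain
#'
#' Daily fresh-biomass gain over the experiment:
#' `PBG = (final fresh weight - initial fresh weight) / n_days` (g/day).
#' Negative values are allowed (plants can shrink under water deficit).
#'
#' @param initial_fresh_g,final_fresh_g Fresh weights in g (>= 0).
#' @param n_days Number of days in the experiment (> 0).
#' @return PBG in g/day.
#' @examples
#' plant_biomass_gain(50, 120, 35)  # 2
#' @export
plant_biomass_gain <- function(initial_fresh_g, final_fresh_g, n_days) {
  if (any(n_days <= 0)) abort_input("'n_days' must be > 0")
  if (any(initial_fresh_g < 0) || any(final_fresh_g < 0)) {
    abort_input("fresh weights must be >= 0")
  }
  (final_fresh_g - initial_fresh_g) / n_days
}

# internal: basic checks on a pot-weight series data frame
check_series <- function(x, what) {
  req <- c("day", "weight_kg")
  if (!is.data.frame(x) || !all(req %in% names(x))) {
    abort_input(sprintf("'%s' must be a data frame with columns day and weight_kg", what))
  }
  if (nrow(x) < 2L) abort_input(sprintf("'%s' needs at least 2 measurements", what))
  if (any(x$weight_kg <= 0)) abort_input(sprintf("'%s' has nonpositive weights", what))
  if (is.unsorted(x$day)) abort_input(sprintf("'%s' days must be nondecreasing", what))
  invisible(x)
}

#' Gravimetric water use
#'
#' Total water consumed by one plant over the run, from successive pot
#' weighings corrected by an unplanted control pot (drainage/evaporation) and
#' by the plant's fresh-biomass gain:
#'
#' `WU = sum_i [ (PW_{i-1} - PW_i) - (CPW_{i-1} - CPW_i) - PBG * dt_i ]`
#'
#' where `i` runs over successive measurements, `PW`/`CPW` are planted and
#' control pot weights (kg), and the PBG term converts g/day to kg over the
#' interval length `dt_i`. When the planted series records pre- and
#' post-irrigation weights separately (well-watered pots refilled to field
#' capacity), the zero-length refill jumps are skipped, so refill intervals
#' contribute the water actually transpired, not the water added.
#'
#' @param plant_series Data frame with `day`, `weight_kg` and optionally
#'   `post_irrigation` and `is_control` columns; not a control series.
#' @param control_series Control pot data frame with `day`, `weight_kg`
#'   (one weight per day), covering every day of `plant_series`.
#' @param pbg Plant biomass gain in g/day (see [plant_biomass_gain()]).
#' @return Water use in litres (1 kg water = 1 L).
#' @examples
#' p <- data.frame(day = c(0, 1), weight_kg = c(10, 9))
#' ctl <- data.frame(day = c(0, 1), weight_kg = c(5, 5))
#' water_use(p, ctl, pbg = 0)  # 1
#' @export
water_use <- function(plant_series, control_series, pbg = 0) {
  check_series(plant_series, "plant_series")
  check_series(control_series, "control_series")
  if (isTRUE(any(plant_series$is_control))) {
    abort_input("'plant_series' is flagged as a control pot")
  }
  if (anyDuplicated(control_series$day)) {
    abort_input("'control_series' must have a single weight per day")
  }
  # order rows by day with pre-irrigation before post-irrigation
  post <- if ("post_irrigation" %in% names(plant_series)) {
    as.logical(plant_series$post_irrigation)
  } else rep(FALSE, nrow(plant_series))
  o <- order(plant_series$day, post)
  d <- plant_series$day[o]
  w <- plant_series$weight_kg[o]
  cw <- control_series$weight_kg[match(d, control_series$day)]
  if (anyNA(cw)) {
    abort_input("control series does not cover every measurement day of the plant series")
  }
  dt <- diff(d)
  keep <- dt > 0  # refill jumps (same-day pre -> post) are skipped
  sum((-diff(w))[keep] - (-diff(cw))[keep] - pbg * dt[keep] / 1000)
}

#' Water productivity
#'
#' Total dry biomass produced per unit water consumed:
#' `WP = (RDW + SDW) / WU`, in kg m^-3 (numerically g dry matter per L).
#'
#' @param rdw_g Root dry weight (g).
#' @param sdw_g Shoot (leaves + stems) dry weight (g).
#' @param wu_l Water use in litres; must be > 0, otherwise `NA` is returned
#'   with a warning.
#' @return WP in kg m^-3.
#' @examples
#' water_productivity(3, 60, 15)  # 4.2
#' @export
water_productivity <- function(rdw_g, sdw_g, wu_l) {
  if (any(rdw_g < 0, na.rm = TRUE) || any(sdw_g < 0, na.rm = TRUE)) {
    abort_input("dry weights must be >= 0")
  }
  bad <- !is.na(wu_l) & wu_l <= 0
  if (any(bad)) {
    warning("water use <= 0; water productivity undefined, returning NA", call. = FALSE)
  }
  out <- (rdw_g + sdw_g) / wu_l
  out[bad] <- NA_real_
  out
}

#' Root:shoot ratio
#'
#' `RDW / SDW`, dimensionless. Undefined (NA with a warning) when SDW is 0.
#'
#' @inheritParams water_productivity
#' @return Root:shoot ratio.
#' @export
root_shoot_ratio <- function(rdw_g, sdw_g) {
  if (any(rdw_g < 0, na.rm = TRUE) || any(sdw_g < 0, na.rm = TRUE)) {
    abort_input("dry weights must be >= 0")
  }
  bad <- !is.na(sdw_g) & sdw_g == 0
  if (any(bad)) warning("SDW = 0; root:shoot ratio undefined, returning NA", call. = FALSE)
  out <- rdw_g / sdw_g
  out[bad] <- NA_real_
  out
}

#' Per-plant water-accounting results
#'
#' Computes PBG, WU, WP and root:shoot for every plant of an experiment,
#' using the shared unplanted control pot series for the drainage correction.
#'
#' @param experiment An `rsa_experiment` (see [generate_experiment()]) or a
#'   list with `plants`, `pot_weights` and `design` components of the same
#'   shape.
#' @return A data frame with one row per plant: identity columns plus
#'   `pbg_g_day`, `wu_l`, `wp_kg_m3`, `root_shoot`.
#' @export
water_results <- function(experiment) {
  plants <- experiment$plants
  pw <- experiment$pot_weights
  n_days <- experiment$design$duration_days
  control <- pw[pw$is_control, , drop = FALSE]
  if (nrow(control) == 0) abort_input("no control pot series in the dataset")
  if (length(unique(control$pot_id)) > 1) {
    # average the controls day-wise into one reference series
    control <- stats::aggregate(weight_kg ~ day, data = control, FUN = mean)
  }
  res <- plants[, c("plant_id", "genotype", "regime", "block")]
  res$pbg_g_day <- plant_biomass_gain(plants$initial_fresh_g, plants$final_fresh_g, n_days)
  res$wu_l <- vapply(seq_len(nrow(plants)), function(i) {
    s <- pw[pw$pot_id == plants$plant_id[i] & !pw$is_control, , drop = FALSE]
    if (nrow(s) == 0) abort_input(sprintf("no pot-weight series for plant '%s'", plants$plant_id[i]))
    water_use(s, control, pbg = res$pbg_g_day[i])
  }, numeric(1))
  res$wp_kg_m3 <- water_productivity(plants$rdw_g, plants$sdw_g, res$wu_l)
  res$root_shoot <- root_shoot_ratio(plants$rdw_g, plants$sdw_g)
  res
}
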