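#' Experimental design for a pot-based irrigation trial
#'
#' Describes a randomized complete block factorial experiment: a set of
#' genotypes crossed with two irrigation regimes (well-watered `WW`,
#' water-deficit `WD`) in a number of complete blocks, run for a fixed number
#' of days with gravimetric (pot-weighing) monitoring. The default values
#' reproduce an 8 genotype x 2 regime x 3 block bottle gourd trial in 20 L
#' pots over 35 days with three weighings per week, four 10-cm substrate
#' depth layers and nine 0.5-mm root diameter classes.
#'
#' @param genotypes Character vector of genotype labels.
#' @param regimes Character vector of irrigation regime labels; must be
#'   exactly `c("WW", "WD")`.
#' @param n_blocks Number of complete blocks (>= 2).
#' @param duration_days Length of the experiment in days (>= 1).
#' @param weighings_per_week Number of pot weighings per week (1..7).
#' @param field_capacity_kg Pot weight at field capacity (kg), the 100%
#'   reference that well-watered pots are refilled to.
#' @param pot_volume_l Pot volume in litres (used only for the biomass/volume
#'   quality-control ratio).
#' @param layer_edges_cm Strictly increasing depth-layer edges in cm
#'   (default 0, 10, 20, 30, 40).
#' @param class_edges_mm Strictly increasing diameter-class edges in mm with
#'   a uniform 0.5 mm step (default 0 to 4.5).
#' @return An object of class `experiment_design` (a list).
#' @examples
#' d <- experiment_design()
#' length(d$genotypes)  # 8
#' @export
experiment_design <- function(genotypes = c("BG-58", "BG-78", "GC", "Philippines",
                                            "South Korea", "Illapel", "Chepica", "Osorno"),
                              regimes = c("WW", "WD"),
                              n_blocks = 3,
                              duration_days = 35,
                              weighings_per_week = 3,
                              field_capacity_kg = 30,
                              pot_volume_l = 20,
                              layer_edges_cm = seq(0, 40, by = 10),
                              class_edges_mm = seq(0, 4.5, by = 0.5)) {
  if (length(genotypes) < 1 || anyDuplicated(genotypes)) {
    abort_input("'genotypes' must be a non-empty set of unique labels")
  }
  if (!identical(sort(regimes), sort(c("WW", "WD")))) {
    abort_input("'regimes' must be the two labels 'WW' and 'WD'")
  }
  if (n_blocks < 2) abort_input("'n_blocks' must be >= 2")
  if (duration_days < 1) abort_input("'duration_days' must be >= 1")
  if (weighings_per_week < 1 || weighings_per_week > 7) {
    abort_input("'weighings_per_week' must be between 1 and 7")
  }
  check_pos(field_capacity_kg, "field_capacity_kg")
  check_pos(pot_volume_l, "pot_volume_l")
  if (any(diff(layer_edges_cm) <= 0)) abort_input("'layer_edges_cm' must be strictly increasing")
  steps <- diff(class_edges_mm)
  if (any(steps <= 0)) abort_input("'class_edges_mm' must be strictly increasing")
  if (any(abs(steps - 0.5) > 1e-9)) {
    abort_input("'class_edges_mm' must use a uniform 0.5 mm step")
  }
  structure(list(
    genotypes = as.character(genotypes),
    regimes = c("WW", "WD"),
    n_blocks = as.integer(n_blocks),
    duration_days = as.integer(duration_days),
    weighings_per_week = as.integer(weighings_per_week),
    field_capacity_kg = field_capacity_kg,
    pot_volume_l = pot_volume_l,
    layer_edges_cm = as.numeric(layer_edges_cm),
    class_edges_mm = as.numeric(class_edges_mm)
  ), class = "experiment_design")
}

#' Pot-weighing schedule
#'
#' Expands a weighing frequency into the sorted set of measurement days.
#' Within each 7-day week the weighings are evenly spaced starting on the
#' first day of the week (three per week gives days 0, 2 and 4 of each week);
#' day 0 and the final day are always included.
#'
#' @param design An [experiment_design()].
#' @return Integer vector of measurement days (sorted, unique, starting at 0
#'   and ending at `duration_days`).
#' @examples
#' make_schedule(experiment_design(duration_days = 35, weighings_per_week = 3))
#' @export
make_schedule <- function(design) {
  stopifnot(inherits(design, "experiment_design"))
  w <- design$weighings_per_week
  dur <- design$duration_days
  offsets <- floor(7 * (seq_len(w) - 1) / w)
  week_starts <- seq(0L, dur, by = 7L)
  days <- as.vector(outer(offsets, week_starts, `+`))
  days <- days[days <= dur]
  sort(unique(c(0L, as.integer(days), dur)))
}

#' Effect configuration for the synthetic-data generator
#'
#' Bundles the effect sizes and noise levels that drive [generate_experiment()].
#' Per-genotype arguments accept either a scalar (recycled) or one value per
#' genotype of the design. The defaults define a neutral configuration: equal
#' genotypes, every trait family reduced by the single factor `wd_reduction`
#' under water deficit. [paper_effects()] returns the genotype-differentiated
#' configuration that the package treats as its reference study pattern.
#'
#' Water dynamics: well-watered pots lose `ww_daily_loss` kg/day (times the
#' genotype `et_mult`) and are refilled to field capacity at every weighing;
#' water-deficit pots lose `wd_init_loss * exp(-wd_decay * day)` kg/day, a
#' decline that flattens toward the end of the run as the plants die back;
#' unplanted control pots lose only `drain_rate` kg/day (drainage plus
#' residual evaporation of a covered pot).
#'
#' @param design An [experiment_design()].
#' @param rl_ww_cm Expected whole-plant root length under WW (cm), per genotype.
#' @param rl_wd_k WD reduction factor for root-length targets (0..1], per genotype.
#' @param rdw_ww_g,sdw_ww_g Expected root / shoot dry weight under WW (g), per genotype.
#' @param rdw_wd_k,sdw_wd_k WD reduction factors for root / shoot dry weight.
#' @param diam_scale Multiplier on the diameter-distribution medians, per genotype.
#' @param mrd_wd_k WD multiplier on diameter medians (intensive trait; default 1).
#' @param et_mult Multiplier on the WW evapotranspiration rate, per genotype.
#' @param layer_alloc Expected fraction of root length per depth layer
#'   (must sum to 1; length = number of layers).
#' @param seg_len_mean_mm Mean root segment length (mm).
#' @param seg_len_sdlog Log-scale SD of segment lengths (0 = deterministic).
#' @param diam_fine_med_mm,diam_fine_sdlog Median / log-SD of the fine-root
#'   diameter component (mm).
#' @param diam_thick_med_mm,diam_thick_sdlog Median / log-SD of the thick-root
#'   diameter component (mm).
#' @param thick_frac Fraction of segments drawn from the thick component.
#' @param plant_sdlog Log-scale SD of the per-plant multiplicative noise.
#' @param block_sdlog Log-scale SD of the per-block multiplicative effect.
#' @param ww_daily_loss WW pot daily water loss (kg/day).
#' @param wd_init_loss Initial WD pot daily water loss (kg/day).
#' @param wd_decay Exponential decay rate of the WD daily loss (1/day).
#' @param drain_rate Control pot daily loss (kg/day).
#' @param loss_noise_sd SD of the multiplicative noise on daily losses
#'   (applied to the loss, truncated at 0, so WD weights stay monotone).
#' @param fresh_dry_ratio Fresh:dry biomass ratio linking dry weights to the
#'   fresh weights used for plant biomass gain (default 10).
#' @param initial_fresh_g Transplant fresh weight (g).
#' @param wd_reduction Default WD reduction factor used wherever a per-family
#'   factor is not given (default 0.5).
#' @return An object of class `effect_config` (a list).
#' @export
effect_config <- function(design = experiment_design(),
                          wd_reduction = 0.5,
                          rl_ww_cm = 700,
                          rl_wd_k = wd_reduction,
                          rdw_ww_g = 3.3,
                          rdw_wd_k = wd_reduction,
                          sdw_ww_g = 95,
                          sdw_wd_k = wd_reduction,
                          diam_scale = 1,
                          mrd_wd_k = 1,
                          et_mult = 1,
                          layer_alloc = c(0.30, 0.35, 0.20, 0.15),
                          seg_len_mean_mm = 40,
                          seg_len_sdlog = 0.35,
                          diam_fine_med_mm = 0.75,
                          diam_fine_sdlog = 0.45,
                          diam_thick_med_mm = 2.8,
                          diam_thick_sdlog = 0.30,
                          thick_frac = 0.12,
                          plant_sdlog = 0.08,
                          block_sdlog = 0.05,
                          ww_daily_loss = 0.65,
                          wd_init_loss = 0.50,
                          wd_decay = 0.08,
                          drain_rate = 0.02,
                          loss_noise_sd = 0.04,
                          fresh_dry_ratio = 10,
                          initial_fresh_g = 5) {
  stopifnot(inherits(design, "experiment_design"))
  ng <- length(design$genotypes)
  nl <- length(design$layer_edges_cm) - 1L
  g <- function(x, what) {
    x <- recycle_to(x, ng, what)
    if (any(!is.finite(x)) || any(x <= 0)) abort_input(sprintf("'%s' must be positive", what))
    x
  }
  cfg <- list(
    genotypes = design$genotypes,
    wd_reduction = wd_reduction,
    rl_ww_cm = g(rl_ww_cm, "rl_ww_cm"),
    rl_wd_k = g(rl_wd_k, "rl_wd_k"),
    rdw_ww_g = g(rdw_ww_g, "rdw_ww_g"),
    rdw_wd_k = g(rdw_wd_k, "rdw_wd_k"),
    sdw_ww_g = g(sdw_ww_g, "sdw_ww_g"),
    sdw_wd_k = g(sdw_wd_k, "sdw_wd_k"),
    diam_scale = g(diam_scale, "diam_scale"),
    mrd_wd_k = g(mrd_wd_k, "mrd_wd_k"),
    et_mult = g(et_mult, "et_mult"),
    layer_alloc = as.numeric(layer_alloc),
    seg_len_mean_mm = seg_len_mean_mm,
    seg_len_sdlog = seg_len_sdlog,
    diam_fine_med_mm = diam_fine_med_mm,
    diam_fine_sdlog = diam_fine_sdlog,
    diam_thick_med_mm = diam_thick_med_mm,
    diam_thick_sdlog = diam_thick_sdlog,
    thick_frac = thick_frac,
    plant_sdlog = plant_sdlog,
    block_sdlog = block_sdlog,
    ww_daily_loss = ww_daily_loss,
    wd_init_loss = wd_init_loss,
    wd_decay = wd_decay,
    drain_rate = drain_rate,
    loss_noise_sd = loss_noise_sd,
    fresh_dry_ratio = fresh_dry_ratio,
    initial_fresh_g = initial_fresh_g
  )
  if (length(cfg$layer_alloc) != nl) {
    abort_input(sprintf("'layer_alloc' must have one weight per depth layer (%d)", nl))
  }
  if (abs(sum(cfg$layer_alloc) - 1) > 1e-8 || any(cfg$layer_alloc < 0)) {
    abort_input("'layer_alloc' weights must be nonnegative and sum to 1")
  }
  for (nm in c("seg_len_sdlog", "diam_fine_sdlog", "diam_thick_sdlog",
               "plant_sdlog", "block_sdlog", "loss_noise_sd", "drain_rate")) {
    check_pos(cfg[[nm]], nm, strict = FALSE)
  }
  for (nm in c("seg_len_mean_mm", "diam_fine_med_mm", "diam_thick_med_mm",
               "ww_daily_loss", "wd_init_loss", "wd_decay", "fresh_dry_ratio",
               "initial_fresh_g")) {
    check_pos(cfg[[nm]], nm)
  }
  if (thick_frac < 0 || thick_frac >= 1) abort_input("'thick_frac' must be in [0, 1)")
  structure(cfg, class = "effect_config")
}

#' Reference study-pattern effect configuration
#'
#' The genotype-differentiated configuration the package uses as its default
#' study pattern for an 8-genotype bottle gourd trial: South African
#' genotypes (BG-58, BG-78, GC) with high root length and shoot biomass,
#' Chilean genotypes Illapel and Chepica with thicker roots (higher mean
#' diameter, surface and volume), shoot biomass reduced to ~20% and root
#' biomass to ~63% of the well-watered values under water deficit (so the
#' root:shoot ratio rises under drought), extensive root traits reduced to
#' 40-50% of WW per layer, diameter medians reduced by 15%, and the Osorno
#' genotype given an exactly proportional root-length reduction of k = 0.5,
#' whose plasticity index has the closed form (1-k)/(1+k) = 1/3 in the
#' noise-free limit.
#'
#' @param design An [experiment_design()] with the default 8 genotypes (any
#'   design with 8 genotypes is accepted; values are positional).
#' @param ... Overrides passed on to [effect_config()].
#' @return An `effect_config`.
#' @export
paper_effects <- function(design = experiment_design(), ...) {
  if (length(design$genotypes) != 8L) {
    abort_input("paper_effects() is defined for an 8-genotype design; use effect_config() otherwise")
  }
  defaults <- list(
    design = design,
    rl_ww_cm   = c(870, 780, 900, 500, 630, 700, 660, 560),
    rl_wd_k    = c(0.42, 0.45, 0.40, 0.48, 0.44, 0.46, 0.43, 0.50),
    rdw_ww_g   = c(3.7, 3.9, 4.4, 2.4, 2.6, 3.9, 3.1, 2.2),
    rdw_wd_k   = 0.63,
    sdw_ww_g   = c(115, 104, 113, 69, 94, 78, 79, 112),
    sdw_wd_k   = 0.20,
    diam_scale = c(0.95, 1.00, 0.95, 0.95, 0.90, 1.25, 1.20, 1.00),
    mrd_wd_k   = 0.85,
    et_mult    = c(1.10, 1.05, 1.10, 0.80, 0.95, 0.90, 0.90, 1.05)
  )
  args <- utils::modifyList(defaults, list(...))
  do.call(effect_config, args)
}
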