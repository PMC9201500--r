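#' Simulate a planted pot-weight series
#'
#' Produces the gravimetric record of one pot over the experiment. Well-watered
#' (`WW`) pots are weighed before irrigation and refilled to field capacity at
#' every weighing, and both the pre- and post-irrigation weights are recorded
#' as separate rows (`post_irrigation` flag), so that the water-use sum can
#' skip the refill jumps. Water-deficit (`WD`) pots receive no water and their
#' weights decline monotonically: noise is applied to the daily loss
#' (truncated at zero), never to the weights, and the daily loss decays
#' exponentially so the curve flattens as the experiment ends.
#'
#' @param design An [experiment_design()].
#' @param regime `"WW"` or `"WD"`.
#' @param effects An [effect_config()].
#' @param pot_id Identifier written into the series.
#' @param daily_loss Optional override of the (initial) daily water loss in
#'   kg/day; defaults to `ww_daily_loss` or `wd_init_loss` from `effects`.
#' @return A data frame with columns `pot_id`, `day`, `weight_kg`,
#'   `is_control`, `post_irrigation`.
#' @export
generate_pot_series <- function(design, regime, effects = effect_config(design),
                                pot_id = "pot", daily_loss = NULL) {
  stopifnot(inherits(design, "experiment_design"), inherits(effects, "effect_config"))
  regime <- match.arg(regime, c("WW", "WD"))
  sched <- make_schedule(design)
  fc <- design$field_capacity_kg
  dur <- design$duration_days
  base_loss <- if (is.null(daily_loss)) {
    if (regime == "WW") effects$ww_daily_loss else effects$wd_init_loss
  } else daily_loss
  # per-day losses; multiplicative noise truncated at zero keeps them >= 0
  days_all <- seq_len(dur) - 1L  # loss over day t -> t+1 indexed by t
  noise <- if (effects$loss_noise_sd > 0) {
    pmax(0, 1 + stats::rnorm(dur, 0, effects$loss_noise_sd))
  } else rep(1, dur)
  loss <- if (regime == "WW") {
    base_loss * noise
  } else {
    base_loss * exp(-effects$wd_decay * days_all) * noise
  }
  if (sum(loss) >= fc) {
    abort_input("configured water loss exceeds field-capacity weight; pot weight would reach zero")
  }
  cum_loss <- c(0, cumsum(loss))  # cumulative loss at day d = cum_loss[d + 1]

  if (regime == "WD") {
    out <- data.frame(
      pot_id = pot_id, day = sched,
      weight_kg = fc - cum_loss[sched + 1L],
      is_control = FALSE, post_irrigation = FALSE,
      stringsAsFactors = FALSE
    )
  } else {
    # refill to field capacity at every weighing; record pre then post
    day <- numeric(0); w <- numeric(0); post <- logical(0)
    prev_day <- 0L
    day <- c(day, 0L); w <- c(w, fc); post <- c(post, TRUE)
    for (d in sched[-1]) {
      lost <- cum_loss[d + 1L] - cum_loss[prev_day + 1L]
      day <- c(day, d); w <- c(w, fc - lost); post <- c(post, FALSE)
      if (d < dur) {  # final weighing ends the experiment; no refill
        day <- c(day, d); w <- c(w, fc); post <- c(post, TRUE)
      }
      prev_day <- d
    }
    out <- data.frame(pot_id = pot_id, day = day, weight_kg = w,
                      is_control = FALSE, post_irrigation = post,
                      stringsAsFactors = FALSE)
  }
  if (any(out$weight_kg <= 0)) abort_input("generated pot weight fell to zero")
  out
}

#' Simulate an unplanted control pot-weight series
#'
#' Control pots carry no plant and are never irrigated; they lose only
#' drained/evaporated water at `drain_rate` kg/day (noisy, truncated at 0),
#' and share the weighing schedule of the planted pots.
#'
#' @inheritParams generate_pot_series
#' @return A data frame as in [generate_pot_series()] with `is_control = TRUE`.
#' @export
generate_control_series <- function(design, effects = effect_config(design),
                                    pot_id = "control") {
  stopifnot(inherits(design, "experiment_design"), inherits(effects, "effect_config"))
  sched <- make_schedule(design)
  dur <- design$duration_days
  noise <- if (effects$loss_noise_sd > 0) {
    pmax(0, 1 + stats::rnorm(dur, 0, effects$loss_noise_sd))
  } else rep(1, dur)
  loss <- effects$drain_rate * noise
  cum_loss <- c(0, cumsum(loss))
  w <- design$field_capacity_kg - cum_loss[sched + 1L]
  if (any(w <= 0)) abort_input("control pot weight fell to zero")
  data.frame(pot_id = pot_id, day = sched, weight_kg = w,
             is_control = TRUE, post_irrigation = FALSE,
             stringsAsFactors = FALSE)
}

#' Simulate a root-segment table for one plant
#'
#' Draws root segments (depth midpoint, length, diameter) whose expected
#' totals follow the effect configuration: the expected whole-plant root
#' length is the genotype's WW target times the WD reduction factor under
#' water deficit, allocated across depth layers by `layer_alloc`; segment
#' lengths are log-normal around the per-layer target; diameters come from a
#' two-component log-normal mixture (fine and thick roots) whose medians are
#' scaled per genotype and reduced by `mrd_wd_k` under WD. Under the default
#' configuration the modal root-length diameter class is 0.5-1.0 mm.
#'
#' With all log-SDs set to zero the realized per-layer lengths equal their
#' targets exactly, so WD totals are exactly the reduction factor times WW
#' totals.
#'
#' @inheritParams generate_pot_series
#' @param genotype A genotype label present in `design`.
#' @param target_rl_cm Optional whole-plant root-length target (cm)
#'   overriding the configured genotype x regime expectation.
#' @param plant_id Identifier written into the table.
#' @return A data frame with columns `plant_id`, `depth_cm`, `length_mm`,
#'   `diameter_mm`.
#' @export
generate_root_segments <- function(design, genotype, regime,
                                   effects = effect_config(design),
                                   target_rl_cm = NULL, plant_id = "plant") {
  stopifnot(inherits(design, "experiment_design"), inherits(effects, "effect_config"))
  regime <- match.arg(regime, c("WW", "WD"))
  gi <- match(genotype, effects$genotypes)
  if (is.na(gi)) abort_input(sprintf("unknown genotype '%s'", genotype))
  alloc <- effects$layer_alloc
  if (abs(sum(alloc) - 1) > 1e-8) abort_input("layer allocation weights must sum to 1")
  if (is.null(target_rl_cm)) {
    target_rl_cm <- effects$rl_ww_cm[gi] * if (regime == "WD") effects$rl_wd_k[gi] else 1
  }
  edges <- design$layer_edges_cm
  n_layers <- length(edges) - 1L
  med_scale <- effects$diam_scale[gi] * if (regime == "WD") effects$mrd_wd_k[gi] else 1

  depth <- numeric(0); len <- numeric(0); diam <- numeric(0)
  for (l in seq_len(n_layers)) {
    target_mm <- target_rl_cm * 10 * alloc[l]
    if (target_mm <= 0) next
    n <- max(1L, as.integer(round(target_mm / effects$seg_len_mean_mm)))
    # log-normal with E[sum of lengths] = target_mm
    mu <- log(target_mm / n) - effects$seg_len_sdlog^2 / 2
    len_l <- stats::rlnorm(n, mu, effects$seg_len_sdlog)
    thick <- stats::runif(n) < effects$thick_frac
    med <- ifelse(thick, effects$diam_thick_med_mm, effects$diam_fine_med_mm) * med_scale
    sdl <- ifelse(thick, effects$diam_thick_sdlog, effects$diam_fine_sdlog)
    diam_l <- stats::rlnorm(n, log(med), sdl)
    depth_l <- stats::runif(n, edges[l], edges[l + 1])
    depth <- c(depth, depth_l); len <- c(len, len_l); diam <- c(diam, diam_l)
  }
  data.frame(plant_id = plant_id, depth_cm = depth, length_mm = len,
             diameter_mm = diam, stringsAsFactors = FALSE)
}

#' Simulate a complete experiment
#'
#' Generates the full seeded dataset of a randomized complete block factorial
#' trial: one plant per genotype x regime x block (48 plants under the
#' default design), each with a biomass record, a pot-weight series and a
#' root-segment table, plus one shared unplanted control pot series. Given the
#' same seed and configuration the output is identical.
#'
#' @inheritParams generate_pot_series
#' @param effects An [effect_config()]; defaults to the study-pattern
#'   configuration [paper_effects()].
#' @param seed Integer seed; the generator is fully deterministic given it.
#' @param qc If `TRUE`, warn when any plant's total dry biomass per pot
#'   volume exceeds 2 g/L, a published guidance bound above which pot size
#'   restricts growth.
#' @return An object of class `rsa_experiment`: a list with data frames
#'   `plants`, `pot_weights`, `root_segments`, the `design`, the weighing
#'   `schedule` and the `seed`.
#' @examples
#' ex <- generate_experiment(seed = 1)
#' nrow(ex$plants)  # 48
#' @export
generate_experiment <- function(design = experiment_design(),
                                effects = paper_effects(design),
                                seed = 1, qc = FALSE) {
  stopifnot(inherits(design, "experiment_design"), inherits(effects, "effect_config"))
  set.seed(as.integer(seed))
  rln <- function(n, sdlog) if (sdlog > 0) stats::rlnorm(n, -sdlog^2 / 2, sdlog) else rep(1, n)
  block_mult <- rln(design$n_blocks, effects$block_sdlog)

  plants <- list(); weights <- list(); segments <- list()
  k <- 0L
  for (b in seq_len(design$n_blocks)) {
    for (regime in design$regimes) {
      for (gi in seq_along(design$genotypes)) {
        k <- k + 1L
        geno <- design$genotypes[gi]
        pid <- sprintf("%s_%s_B%d", gsub("[^A-Za-z0-9-]", "", geno), regime, b)
        wd <- regime == "WD"
        p <- rln(3L, effects$plant_sdlog)
        rdw <- effects$rdw_ww_g[gi] * (if (wd) effects$rdw_wd_k[gi] else 1) * block_mult[b] * p[1]
        sdw <- effects$sdw_ww_g[gi] * (if (wd) effects$sdw_wd_k[gi] else 1) * block_mult[b] * p[2]
        rl_target <- effects$rl_ww_cm[gi] * (if (wd) effects$rl_wd_k[gi] else 1) *
          block_mult[b] * p[3]
        final_fresh <- (rdw + sdw) * effects$fresh_dry_ratio
        plants[[k]] <- data.frame(
          plant_id = pid, genotype = geno, regime = regime, block = b,
          initial_fresh_g = effects$initial_fresh_g, final_fresh_g = final_fresh,
          rdw_g = rdw, sdw_g = sdw, stringsAsFactors = FALSE
        )
        loss <- if (wd) effects$wd_init_loss else effects$ww_daily_loss * effects$et_mult[gi]
        weights[[k]] <- generate_pot_series(design, regime, effects,
                                            pot_id = pid, daily_loss = loss)
        segments[[k]] <- generate_root_segments(design, geno, regime, effects,
                                                target_rl_cm = rl_target, plant_id = pid)
      }
    }
  }
  control <- generate_control_series(design, effects, pot_id = "CONTROL")
  plants <- do.call(rbind, plants)
  plants$biomass_per_volume_g_l <- (plants$rdw_g + plants$sdw_g) / design$pot_volume_l
  if (qc && any(plants$biomass_per_volume_g_l > 2)) {
    warning(sprintf("%d plant(s) exceed 2 g dry biomass per L pot volume; pot size may restrict growth",
                    sum(plants$biomass_per_volume_g_l > 2)), call. = FALSE)
  }
  structure(list(
    plants = plants,
    pot_weights = rbind(do.call(rbind, weights), control),
    root_segments = do.call(rbind, segments),
    design = design,
    schedule = make_schedule(design),
    seed = as.integer(seed)
  ), class = "rsa_experiment")
}

#' @export
print.rsa_experiment <- function(x, ...) {
  cat(sprintf("rsa_experiment: %d plants (%d genotypes x %d regimes x %d blocks), %d days\n",
              nrow(x$plants), length(x$design$genotypes), length(x$design$regimes),
              x$design$n_blocks, x$design$duration_days))
  cat(sprintf("  pot-weight rows: %d; root segments: %d; seed: %d\n",
              nrow(x$pot_weights), nrow(x$root_segments), x$seed))
  invisible(x)
}
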