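# Column contracts for the three exchange tables (comma-separated, UTF-8,
# '.' decimal, header row mandatory; empty cells are missing, never zero).
TABLE_SCHEMAS <- list(
  plants = c("plant_id", "genotype", "regime", "block",
             "initial_fresh_g", "final_fresh_g", "rdw_g", "sdw_g"),
  pot_weights = c("pot_id", "day", "weight_kg", "is_control", "post_irrigation"),
  root_segments = c("plant_id", "depth_cm", "length_mm", "diameter_mm")
)

#' Write an experiment dataset to CSV
#'
#' Writes `plants.csv`, `pot_weights.csv` and `root_segments.csv` into a
#' directory, in the documented column layout that [read_tables()] accepts
#' back losslessly.
#'
#' @param experiment An `rsa_experiment` (or list with the three tables).
#' @param dir Output directory (created if absent).
#' @return Invisibly, the vector of files written.
#' @export
write_dataset <- function(experiment, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  files <- character(0)
  for (nm in names(TABLE_SCHEMAS)) {
    tab <- experiment[[nm]]
    if (is.null(tab)) abort_input(sprintf("dataset has no '%s' table", nm))
    keep <- intersect(c(TABLE_SCHEMAS[[nm]],
                        setdiff(names(tab), TABLE_SCHEMAS[[nm]])), names(tab))
    f <- file.path(dir, paste0(nm, ".csv"))
    utils::write.csv(tab[, keep, drop = FALSE], f, row.names = FALSE, quote = TRUE)
    files <- c(files, f)
  }
  invisible(files)
}

# internal: validate one table against its schema
validate_table <- function(tab, name) {
  req <- TABLE_SCHEMAS[[name]]
  missing_cols <- setdiff(req, names(tab))
  if (length(missing_cols) > 0) {
    abort_input(sprintf("%s.csv: missing column(s) %s", name,
                        paste(missing_cols, collapse = ", ")))
  }
  num_cols <- switch(name,
    plants = c("initial_fresh_g", "final_fresh_g", "rdw_g", "sdw_g"),
    pot_weights = c("day", "weight_kg"),
    root_segments = c("depth_cm", "length_mm", "diameter_mm"))
  for (cc in num_cols) {
    v <- tab[[cc]]
    if (is.character(v)) {
      parsed <- suppressWarnings(as.numeric(ifelse(v == "", NA, v)))
      bad <- which(!is.na(v) & v != "" & is.na(parsed))
      if (length(bad) > 0) {
        abort_input(sprintf("%s.csv: non-numeric value '%s' in column '%s' at row %d",
                            name, v[bad[1]], cc, bad[1]))
      }
      tab[[cc]] <- parsed
    }
    if (!is.numeric(tab[[cc]])) {
      abort_input(sprintf("%s.csv: column '%s' must be numeric", name, cc))
    }
  }
  if (name == "pot_weights") {
    for (cc in c("is_control", "post_irrigation")) tab[[cc]] <- as.logical(tab[[cc]])
  }
  tab
}

#' Read and validate an experiment dataset from CSV
#'
#' Reads the three exchange tables written by [write_dataset()], checks the
#' documented columns (a missing column is a schema error naming it; a
#' non-numeric cell is a parse error with its row index) and returns them as
#' an `rsa_experiment`-shaped list.
#'
#' @param dir Directory holding `plants.csv`, `pot_weights.csv`,
#'   `root_segments.csv`.
#' @param design The [experiment_design()] the tables belong to (needed for
#'   layer/class edges and the experiment duration).
#' @param quiet Suppress the per-table row-count messages.
#' @return A list of class `rsa_experiment`.
#' @export
read_tables <- function(dir, design = experiment_design(), quiet = FALSE) {
  out <- list()
  for (nm in names(TABLE_SCHEMAS)) {
    f <- file.path(dir, paste0(nm, ".csv"))
    if (!file.exists(f)) abort_input(sprintf("missing input file '%s'", f))
    tab <- utils::read.csv(f, stringsAsFactors = FALSE, na.strings = "")
    tab <- validate_table(tab, nm)
    if (!quiet) message(sprintf("read %s: %d rows", basename(f), nrow(tab)))
    out[[nm]] <- tab
  }
  if (nrow(out$root_segments) == 0) {
    warning("empty root_segments table: whole-plant traits will all be zero", call. = FALSE)
  }
  out$design <- design
  out$schedule <- make_schedule(design)
  class(out) <- "rsa_experiment"
  out
}

#' Read a pipeline configuration from YAML
#'
#' Accepts a YAML file with optional blocks `design` (arguments of
#' [experiment_design()]), `effects` (arguments of [effect_config()]; set
#' `paper_pattern: true` to start from [paper_effects()]) and `pipeline`
#' (`alpha`, `seed`, `rdpi_mode`, `simulate`, `input_dir`). Unknown keys are
#' rejected.
#'
#' @param path Path to the YAML file.
#' @return A validated config list for [run_pipeline()].
#' @export
read_config <- function(path) {
  raw <- yaml::read_yaml(path)
  known_top <- c("design", "effects", "pipeline")
  bad <- setdiff(names(raw), known_top)
  if (length(bad) > 0) abort_input("unknown config block(s): ", paste(bad, collapse = ", "))
  dargs <- raw$design
  bad <- setdiff(names(dargs), names(formals(experiment_design)))
  if (length(bad) > 0) abort_input("unknown design key(s): ", paste(bad, collapse = ", "))
  design <- do.call(experiment_design, dargs %||% list())
  eargs <- raw$effects %||% list()
  paper <- isTRUE(eargs$paper_pattern)
  eargs$paper_pattern <- NULL
  bad <- setdiff(names(eargs), names(formals(effect_config)))
  if (length(bad) > 0) abort_input("unknown effects key(s): ", paste(bad, collapse = ", "))
  eargs$design <- design
  effects <- if (paper) do.call(paper_effects, eargs) else do.call(effect_config, eargs)
  pargs <- raw$pipeline %||% list()
  bad <- setdiff(names(pargs), c("alpha", "seed", "rdpi_mode", "simulate", "input_dir"))
  if (length(bad) > 0) abort_input("unknown pipeline key(s): ", paste(bad, collapse = ", "))
  list(design = design, effects = effects,
       alpha = pargs$alpha %||% 0.05,
       seed = pargs$seed %||% 1L,
       rdpi_mode = pargs$rdpi_mode %||% "pairs",
       simulate = pargs$simulate %||% TRUE,
       input_dir = pargs$input_dir)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run the whole analysis pipeline
#'
#' Ties the stages together: simulate (or read) the dataset, water
#' accounting, trait aggregation by depth layer and diameter class, RDPI,
#' then the inferential layer (assumption checks, two-way ANOVA + LSD
#' letters + regime contrasts per trait, one-way ANOVA + letters on the RDPI
#' observations, correlation matrices and correlation-matrix PCA per
#' regime). Deterministic given the seed; a run manifest records the seed,
#' a configuration hash and the row counts.
#'
#' @param config A config list as returned by [read_config()], a path to a
#'   YAML config, or NULL for the default study-pattern simulation.
#' @param seed Seed overriding the config's (default taken from the config).
#' @param out_dir Optional directory: when given, every result table is also
#'   written there as CSV.
#' @param quiet Suppress stage messages.
#' @return A result bundle (list): `experiment`, `water`, `traits_plant`,
#'   `traits_by_layer`, `traits_by_class`, `traits_layer_class`,
#'   `plant_traits`, `rdpi`, `anova` (list per trait), `letters`,
#'   `contrasts`, `rdpi_anova`, `rdpi_letters`, `assumptions`,
#'   `correlations` (per regime), `pca` (per regime), `manifest`.
#' @export
run_pipeline <- function(config = NULL, seed = NULL, out_dir = NULL, quiet = TRUE) {
  if (is.character(config)) config <- read_config(config)
  if (is.null(config)) {
    design <- experiment_design()
    config <- list(design = design, effects = paper_effects(design),
                   alpha = 0.05, seed = 1L, rdpi_mode = "pairs",
                   simulate = TRUE, input_dir = NULL)
  }
  seed <- as.integer(seed %||% config$seed %||% 1L)
  say <- function(...) if (!quiet) message(sprintf(...))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE)
    })
  }

  experiment <- stage("simulate", {
    if (isTRUE(config$simulate)) {
      generate_experiment(config$design, config$effects, seed = seed)
    } else {
      if (is.null(config$input_dir)) abort_input("simulate disabled and no input_dir given")
      read_tables(config$input_dir, config$design, quiet = quiet)
    }
  })
  say("stage simulate: %d plants", nrow(experiment$plants))

  water <- stage("water", water_results(experiment))
  le <- experiment$design$layer_edges_cm; ce <- experiment$design$class_edges_mm
  traits_plant <- stage("traits", aggregate_traits(experiment$root_segments, "plant", le, ce))
  traits_by_layer <- stage("traits", aggregate_traits(experiment$root_segments, "layer", le, ce))
  traits_by_class <- stage("traits", aggregate_traits(experiment$root_segments, "class", le, ce))
  traits_layer_class <- stage("traits", aggregate_traits(experiment$root_segments, "layer_class", le, ce))
  plant_traits <- stage("traits", plant_trait_table(experiment, water))
  say("stage traits: %d segment rows aggregated", nrow(experiment$root_segments))

  trait_cols <- c("WU", "WP", "root_shoot", "RDW", "SDW", "RL", "SA", "RV", "MRD")
  rdpi_tab <- stage("rdpi", rdpi_table(plant_traits, mode = config$rdpi_mode))
  say("stage rdpi: %d genotype x trait cells", nrow(rdpi_tab))

  anovas <- list(); letters_tabs <- list(); contrasts_tabs <- list(); assumptions <- list()
  stage("stats", {
    for (tr in trait_cols) {
      a <- two_way_anova(plant_traits, tr)
      anovas[[tr]] <- a
      res <- stats::residuals(attr(a, "fit"))
      ok <- !is.na(plant_traits[[tr]])
      grp <- interaction(plant_traits$genotype, plant_traits$regime)[ok]
      assumptions[[tr]] <- assumption_checks(res, grp, alpha = config$alpha)
      gm <- tapply(plant_traits[[tr]], plant_traits$genotype, mean, na.rm = TRUE)
      gn <- tapply(!is.na(plant_traits[[tr]]), plant_traits$genotype, sum)
      letters_tabs[[tr]] <- lsd_letters(gm, as.vector(gn), attr(a, "mse"),
                                         attr(a, "df_error"), alpha = config$alpha)
      ctr <- lapply(unique(plant_traits$genotype),
                    function(g) regime_contrast(plant_traits, tr, g, anova = a))
      contrasts_tabs[[tr]] <- do.call(rbind, ctr)
    }
  })

  rd_obs <- attr(rdpi_tab, "observations")
  rdpi_anova <- list(); rdpi_letters <- list()
  stage("stats", {
    for (tr in unique(rd_obs$trait)) {
      sub <- rd_obs[rd_obs$trait == tr, , drop = FALSE]
      a <- one_way_anova(sub$rd, sub$genotype)
      rdpi_anova[[tr]] <- a
      gm <- tapply(sub$rd, sub$genotype, mean)
      gn <- tapply(sub$rd, sub$genotype, length)
      rdpi_letters[[tr]] <- lsd_letters(gm, as.vector(gn), attr(a, "mse"),
                                         attr(a, "df_error"), alpha = config$alpha)
    }
  })

  pca_traits <- c("WP", "RL", "SA", "MRD", "RV")
  correlations <- list(); pca <- list()
  stage("stats", {
    for (rg in experiment$design$regimes) {
      sub <- plant_traits[plant_traits$regime == rg, , drop = FALSE]
      gm <- stats::aggregate(sub[trait_cols], by = list(genotype = sub$genotype),
                             FUN = mean, na.rm = TRUE)
      correlations[[rg]] <- correlation_matrix(gm[trait_cols])
      pca[[rg]] <- {
        m <- as.matrix(gm[pca_traits]); rownames(m) <- gm$genotype
        pca_correlation(m)
      }
    }
  })
  say("stage stats: done")

  manifest <- list(
    seed = seed,
    config_hash = config_hash(config),
    package_version = as.character(utils::packageVersion("rootplast")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    n_plants = nrow(experiment$plants),
    n_pot_weight_rows = nrow(experiment$pot_weights),
    n_root_segments = nrow(experiment$root_segments),
    n_rdpi_cells = nrow(rdpi_tab),
    rdpi_mode = config$rdpi_mode,
    alpha = config$alpha
  )

  bundle <- list(experiment = experiment, water = water,
                 traits_plant = traits_plant, traits_by_layer = traits_by_layer,
                 traits_by_class = traits_by_class, traits_layer_class = traits_layer_class,
                 plant_traits = plant_traits, rdpi = rdpi_tab,
                 anova = anovas, letters = letters_tabs, contrasts = contrasts_tabs,
                 rdpi_anova = rdpi_anova, rdpi_letters = rdpi_letters,
                 assumptions = assumptions,
                 correlations = correlations, pca = pca, manifest = manifest)
  if (!is.null(out_dir)) stage("write", write_bundle(bundle, out_dir))
  bundle
}

# internal: stable hash of the configuration (md5 of its deparsed form)
config_hash <- function(config) {
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(deparse(config[c("design", "effects", "alpha", "rdpi_mode", "simulate")]), f)
  unname(tools::md5sum(f))
}

# internal: write the result bundle as CSV files
write_bundle <- function(bundle, out_dir) {
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  wr <- function(x, name) utils::write.csv(x, file.path(out_dir, name), row.names = FALSE)
  write_dataset(bundle$experiment, out_dir)
  wr(bundle$water, "water_results.csv")
  wr(bundle$traits_by_layer, "traits_by_layer.csv")
  wr(bundle$traits_by_class, "traits_by_class.csv")
  wr(bundle$traits_layer_class, "traits_by_layer_class.csv")
  wr(bundle$traits_plant, "traits_plant.csv")
  wr(bundle$plant_traits, "plant_traits.csv")
  wr(bundle$rdpi, "rdpi.csv")
  wr(do.call(rbind, lapply(names(bundle$anova), function(tr) {
    cbind(trait = tr, as.data.frame(bundle$anova[[tr]]))
  })), "anova.csv")
  wr(do.call(rbind, lapply(names(bundle$letters), function(tr) {
    cbind(trait = tr, bundle$letters[[tr]])
  })), "letters.csv")
  wr(do.call(rbind, bundle$contrasts), "contrasts.csv")
  wr(do.call(rbind, lapply(names(bundle$rdpi_letters), function(tr) {
    cbind(trait = tr, bundle$rdpi_letters[[tr]])
  })), "rdpi_letters.csv")
  for (rg in names(bundle$correlations)) {
    wr(as.data.frame(bundle$correlations[[rg]]$r), sprintf("correlations_%s.csv", rg))
  }
  for (rg in names(bundle$pca)) {
    wr(as.data.frame(bundle$pca[[rg]]$loadings), sprintf("pca_loadings_%s.csv", rg))
    wr(as.data.frame(bundle$pca[[rg]]$scores), sprintf("pca_scores_%s.csv", rg))
  }
  writeLines(yaml::as.yaml(bundle$manifest), file.path(out_dir, "manifest.yaml"))
  invisible(out_dir)
}
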