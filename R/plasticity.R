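#' Relative distance between two trait values
#'
#' The building block of the relative distance plasticity index:
#' `rd = |x_b - x_a| / (x_a + x_b)`, dimensionless, in `[0, 1]` for
#' nonnegative inputs. Undefined (NA) when both values are zero.
#'
#' @param x_a,x_b Nonnegative trait values (vectorized).
#' @return Relative distance(s) in `[0, 1]`, NA where `x_a + x_b == 0`.
#' @examples
#' relative_distance(1, 3)  # 0.5
#' @export
relative_distance <- function(x_a, x_b) {
  if (any(x_a < 0, na.rm = TRUE) || any(x_b < 0, na.rm = TRUE)) {
    abort_input("trait values must be >= 0")
  }
  s <- x_a + x_b
  out <- abs(x_b - x_a) / s
  out[!is.na(s) & s == 0] <- NA_real_
  out
}

#' Relative distance plasticity index for one genotype x trait
#'
#' RDPI is the mean relative distance over every cross-condition pair of
#' individuals of the same genotype: each of the `j` well-watered individuals
#' is paired with each of the `j'` water-deficit individuals
#' (`n = j * j'` pairs), within-condition pairs are never used, and
#' `RDPI = sum(rd) / n`. Pairs with both values zero are undefined and are
#' excluded, decrementing `n`, with a warning. RDPI is 0 for a genotype whose
#' trait does not respond to the regime and approaches 1 for a maximal
#' response.
#'
#' @param values_ww,values_wd Nonnegative trait values of the individuals
#'   grown under the two regimes (both nonempty).
#' @return An object of class `rdpi_result`: a list with `rdpi`, `n`,
#'   `excluded_pairs`, the pair matrices `distances` and `rel_distances`, and
#'   the inputs.
#' @examples
#' rdpi(c(2, 2, 2), c(1, 1, 1))$rdpi  # 1/3
#' @export
rdpi <- function(values_ww, values_wd) {
  if (length(values_ww) == 0 || length(values_wd) == 0) {
    abort_input("both regimes need at least one individual")
  }
  if (any(values_ww < 0) || any(values_wd < 0)) abort_input("trait values must be >= 0")
  d <- outer(values_ww, values_wd, function(a, b) abs(b - a))
  rd <- outer(values_ww, values_wd, relative_distance)
  excluded <- sum(is.na(rd))
  if (excluded > 0) {
    warning(sprintf("%d pair(s) with both values zero excluded from RDPI", excluded),
            call. = FALSE)
  }
  n <- length(rd) - excluded
  structure(list(
    rdpi = if (n > 0) sum(rd, na.rm = TRUE) / n else NA_real_,
    n = n, excluded_pairs = excluded,
    distances = d, rel_distances = rd,
    values_ww = values_ww, values_wd = values_wd
  ), class = "rdpi_result")
}

#' @export
print.rdpi_result <- function(x, ...) {
  cat(sprintf("RDPI = %.4f over %d cross-condition pairs (%d excluded)\n",
              x$rdpi, x$n, x$excluded_pairs))
  invisible(x)
}

#' RDPI grid over genotypes and traits
#'
#' Computes one RDPI per genotype x trait from a per-plant trait table (see
#' [plant_trait_table()]). Genotypes missing one of the two regimes are
#' skipped with a warning. Two replication modes are supported for the
#' follow-up one-way ANOVA: `"pairs"` exposes every cross-condition relative
#' distance as an observation (pseudo-replicated: the `j * j'` pairs reuse
#' individuals), `"block"` pairs only individuals of the same block, giving
#' one independent rd per block.
#'
#' @param plant_traits Data frame with `genotype`, `regime`, `block` and the
#'   trait columns.
#' @param traits Character vector of trait column names (default the eight
#'   standard traits).
#' @param mode `"pairs"` (all cross-condition pairs) or `"block"`.
#' @return A data frame with one row per genotype x trait: `n`, `rdpi`,
#'   `excluded_pairs`; the per-pair observations are attached as attribute
#'   `observations` (columns `genotype`, `trait`, `rd`).
#' @export
rdpi_table <- function(plant_traits,
                       traits = c("WP", "root_shoot", "RDW", "SDW", "RL", "SA", "RV", "MRD"),
                       mode = c("pairs", "block")) {
  mode <- match.arg(mode)
  missing_tr <- setdiff(traits, names(plant_traits))
  if (length(missing_tr) > 0) {
    abort_input("trait column(s) not in table: ", paste(missing_tr, collapse = ", "))
  }
  genos <- unique(plant_traits$genotype)
  rows <- list(); obs <- list(); k <- 0L
  for (g in genos) {
    sub <- plant_traits[plant_traits$genotype == g, , drop = FALSE]
    ww <- sub[sub$regime == "WW", , drop = FALSE]
    wd <- sub[sub$regime == "WD", , drop = FALSE]
    if (nrow(ww) == 0 || nrow(wd) == 0) {
      warning(sprintf("genotype '%s' lacks one regime; skipped", g), call. = FALSE)
      next
    }
    for (tr in traits) {
      k <- k + 1L
      if (mode == "pairs") {
        r <- rdpi(ww[[tr]], wd[[tr]])
        rd_obs <- as.vector(r$rel_distances)
        rd_obs <- rd_obs[!is.na(rd_obs)]
      } else {
        blocks <- intersect(ww$block, wd$block)
        rd_obs <- unlist(lapply(blocks, function(b) {
          v <- relative_distance(ww[[tr]][ww$block == b], wd[[tr]][wd$block == b])
          v[!is.na(v)]
        }))
        r <- list(rdpi = mean(rd_obs), n = length(rd_obs),
                  excluded_pairs = nrow(ww) * nrow(wd) - length(rd_obs))
      }
      rows[[k]] <- data.frame(genotype = g, trait = tr, n = r$n,
                              rdpi = r$rdpi, excluded_pairs = r$excluded_pairs,
                              stringsAsFactors = FALSE)
      obs[[k]] <- if (length(rd_obs) > 0) {
        data.frame(genotype = g, trait = tr, rd = rd_obs, stringsAsFactors = FALSE)
      } else NULL
    }
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) abort_input("no genotype has individuals in both regimes")
  rownames(out) <- NULL
  attr(out, "observations") <- do.call(rbind, obs)
  attr(out, "mode") <- mode
  out
}
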