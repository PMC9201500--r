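#' ANOVA assumption checks
#'
#' Shapiro-Wilk normality test on the residuals and Bartlett's test of
#' homogeneity of variances across groups, as run before the ANOVA stages.
#' Degenerate inputs (groups with fewer than 2 observations, or fewer than 2
#' groups) skip the Bartlett test with a warning.
#'
#' @param residuals Numeric vector of model residuals (>= 3).
#' @param groups Grouping vector of the same length (for Bartlett).
#' @param alpha Flagging level (default 0.05).
#' @return A list with `shapiro` (statistic `W`, `p`, `ok`) and `bartlett`
#'   (statistic `K2`, `df`, `p`, `ok`; NULL when skipped).
#' @export
assumption_checks <- function(residuals, groups = NULL, alpha = 0.05) {
  if (length(residuals) < 3) abort_input("need at least 3 residuals for Shapiro-Wilk")
  sw <- stats::shapiro.test(residuals)
  out <- list(shapiro = list(W = unname(sw$statistic), p = sw$p.value,
                             ok = sw$p.value > alpha))
  out$bartlett <- NULL
  if (!is.null(groups)) {
    groups <- factor(groups)
    tab <- table(groups)
    if (length(tab) < 2 || any(tab < 2)) {
      warning("Bartlett test skipped: need >= 2 groups with >= 2 observations each",
              call. = FALSE)
    } else {
      bt <- stats::bartlett.test(residuals, groups)
      out$bartlett <- list(K2 = unname(bt$statistic), df = unname(bt$parameter),
                           p = bt$p.value, ok = bt$p.value > alpha)
    }
  }
  out
}

# internal: assemble an anova table data frame from term SS/df plus residual
build_anova_table <- function(terms, ss, df, ss_res, df_res, total_ss, total_df) {
  ms <- ss / df
  mse <- ss_res / df_res
  f <- ms / mse
  p <- stats::pf(f, df, df_res, lower.tail = FALSE)
  tab <- data.frame(
    term = c(terms, "Residuals"),
    df = c(df, df_res),
    sum_sq = c(ss, ss_res),
    mean_sq = c(ms, mse),
    F = c(f, NA),
    p = c(p, NA),
    signif = c(signif_code(p), NA),
    stringsAsFactors = FALSE
  )
  attr(tab, "mse") <- mse
  attr(tab, "df_error") <- df_res
  attr(tab, "total_ss") <- total_ss
  attr(tab, "total_df") <- total_df
  class(tab) <- c("anova_table", "data.frame")
  tab
}

#' Two-way RCBD factorial ANOVA
#'
#' Fits `value ~ block + genotype + regime + genotype:regime` with all
#' factors fixed and returns the term table (df, SS, MS, F, p, significance
#' codes). Sums of squares are Type II, which coincide with the classical
#' sequential decomposition on balanced data; unbalanced layouts are
#' accepted with a warning.
#'
#' @param data Data frame with columns `genotype`, `regime`, `block` and the
#'   trait column.
#' @param trait Name of the response column.
#' @return An `anova_table` data frame with rows block, genotype, regime,
#'   genotype:regime, Residuals; attributes `mse`, `df_error`, `fit` (the
#'   underlying `lm`).
#' @export
two_way_anova <- function(data, trait) {
  if (!trait %in% names(data)) abort_input(sprintf("no column '%s'", trait))
  d <- data.frame(value = data[[trait]],
                  genotype = factor(data$genotype),
                  regime = factor(data$regime),
                  block = factor(data$block))
  d <- d[stats::complete.cases(d), , drop = FALSE]
  if (nlevels(droplevels(d$genotype)) < 2 || nlevels(droplevels(d$regime)) < 2) {
    abort_input("genotype and regime need at least 2 levels each")
  }
  counts <- table(d$genotype, d$regime, d$block)
  if (length(unique(as.vector(counts))) > 1) {
    warning("unbalanced layout: Type II sums of squares no longer match the classical decomposition",
            call. = FALSE)
  }
  fit <- stats::lm(value ~ block + genotype + regime + genotype:regime, data = d)
  # Type II SS; a saturated (zero-residual) fit breaks the Type II machinery,
  # so fall back to the sequential table, identical on balanced data
  a2 <- tryCatch(car::Anova(fit, type = 2), error = function(e) {
    a1 <- stats::anova(fit)
    data.frame(`Sum Sq` = a1$`Sum Sq`, Df = a1$Df,
               row.names = rownames(a1), check.names = FALSE)
  })
  rn <- rownames(a2)
  res_i <- which(rn == "Residuals")
  term_i <- setdiff(seq_along(rn), res_i)
  total_ss <- sum((d$value - mean(d$value))^2)
  tab <- build_anova_table(
    terms = rn[term_i],
    ss = a2$`Sum Sq`[term_i], df = a2$Df[term_i],
    ss_res = a2$`Sum Sq`[res_i], df_res = a2$Df[res_i],
    total_ss = total_ss, total_df = nrow(d) - 1L
  )
  attr(tab, "fit") <- fit
  tab
}

#' One-way ANOVA
#'
#' Between/within decomposition for a single grouping factor, as used for the
#' RDPI values.
#'
#' @param values Numeric response vector.
#' @param groups Grouping vector (>= 2 groups).
#' @return An `anova_table` data frame (rows group, Residuals).
#' @export
one_way_anova <- function(values, groups) {
  g <- factor(groups)
  keep <- !is.na(values) & !is.na(g)
  values <- values[keep]; g <- droplevels(g[keep])
  if (nlevels(g) < 2) abort_input("need at least 2 groups")
  fit <- stats::lm(values ~ g)
  a <- stats::anova(fit)
  tab <- build_anova_table(
    terms = "group",
    ss = a$`Sum Sq`[1], df = a$Df[1],
    ss_res = a$`Sum Sq`[2], df_res = a$Df[2],
    total_ss = sum((values - mean(values))^2), total_df = length(values) - 1L
  )
  attr(tab, "fit") <- fit
  tab
}

#' Fisher's LSD compact letter display
#'
#' Pairwise least-significant-difference tests on a set of group means with a
#' pooled error: two groups differ when
#' `|mean_a - mean_b| > t(1 - alpha/2, df) * sqrt(MSE * (1/n_a + 1/n_b))`.
#' The pairwise results are summarized by an insert-and-absorb compact letter
#' display: means are sorted in decreasing order and letters assigned from
#' "a" at the top, so two groups share a letter iff they are not
#' significantly different.
#'
#' @param means Named numeric vector of group means.
#' @param n Group sizes (scalar or one per group).
#' @param mse Pooled error mean square (from the ANOVA).
#' @param df_error Error degrees of freedom.
#' @param alpha Significance level (default 0.05).
#' @return A data frame sorted by decreasing mean with columns `group`,
#'   `mean`, `n`, `letters`; attributes `lsd` (the threshold for the first
#'   pair of group sizes), `alpha` and `significant` (the pairwise logical
#'   matrix).
#' @examples
#' lsd_letters(c(a = 10, b = 9.9, c = 0), n = 3, mse = 0.01, df_error = 10)
#' @export
lsd_letters <- function(means, n, mse, df_error, alpha = 0.05) {
  if (is.null(names(means))) names(means) <- paste0("g", seq_along(means))
  if (mse < 0) abort_input("'mse' must be >= 0")
  if (df_error < 1) abort_input("'df_error' must be >= 1")
  k <- length(means)
  n <- recycle_to(n, k, "n")
  o <- order(means, decreasing = TRUE)
  means <- means[o]; n <- n[o]
  tcrit <- stats::qt(1 - alpha / 2, df_error)
  sig <- matrix(FALSE, k, k, dimnames = list(names(means), names(means)))
  for (i in seq_len(k - 1)) {
    for (j in (i + 1):k) {
      lsd_ij <- tcrit * sqrt(mse * (1 / n[i] + 1 / n[j]))
      sig[i, j] <- sig[j, i] <- abs(means[i] - means[j]) > lsd_ij
    }
  }
  # insert-and-absorb: start with one column holding all groups, split on
  # each significant pair, drop columns that become subsets of another
  cols <- list(seq_len(k))
  for (i in seq_len(k - 1)) {
    for (j in (i + 1):k) {
      if (!sig[i, j]) next
      new_cols <- list()
      for (cc in cols) {
        if (i %in% cc && j %in% cc) {
          new_cols <- c(new_cols, list(setdiff(cc, i)), list(setdiff(cc, j)))
        } else {
          new_cols <- c(new_cols, list(cc))
        }
      }
      new_cols <- unique(lapply(new_cols, sort))
      keep <- vapply(seq_along(new_cols), function(a) {
        !any(vapply(seq_along(new_cols), function(b) {
          b != a && length(new_cols[[a]]) < length(new_cols[[b]]) &&
            all(new_cols[[a]] %in% new_cols[[b]])
        }, logical(1)))
      }, logical(1))
      cols <- new_cols[keep]
    }
  }
  # order columns by the best (highest) mean they contain so 'a' sits on top
  cols <- cols[order(vapply(cols, min, numeric(1)))]
  letts <- vapply(seq_len(k), function(i) {
    paste0(letters[which(vapply(cols, function(cc) i %in% cc, logical(1)))], collapse = "")
  }, character(1))
  out <- data.frame(group = names(means), mean = unname(means), n = n,
                    letters = letts, stringsAsFactors = FALSE)
  attr(out, "lsd") <- tcrit * sqrt(mse * (1 / n[1] + 1 / n[2]))
  attr(out, "alpha") <- alpha
  attr(out, "significant") <- sig
  out
}

#' Per-genotype regime contrast
#'
#' Orthogonal contrast of the two regime means within one genotype, using the
#' pooled error of the two-way ANOVA: `estimate = mean(WW) - mean(WD)`,
#' `SE = sqrt(MSE * (1/n_WW + 1/n_WD))`, with a t test on the error df. The
#' WW - WD orientation makes the estimate positive for traits reduced by the
#' water deficit (and negative for traits, like root:shoot, that increase).
#'
#' @param data Per-plant trait table.
#' @param trait Response column name.
#' @param genotype Genotype label; must be present in both regimes.
#' @param anova Optional precomputed [two_way_anova()] for the trait (reused
#'   across genotypes to avoid refitting).
#' @return A one-row data frame: `genotype`, `trait`, `mean_ww`, `mean_wd`,
#'   `estimate`, `se`, `t`, `p`, `signif`.
#' @export
regime_contrast <- function(data, trait, genotype, anova = two_way_anova(data, trait)) {
  sub <- data[data$genotype == genotype, , drop = FALSE]
  x_ww <- sub[[trait]][sub$regime == "WW"]
  x_wd <- sub[[trait]][sub$regime == "WD"]
  x_ww <- x_ww[!is.na(x_ww)]; x_wd <- x_wd[!is.na(x_wd)]
  if (length(x_ww) == 0 || length(x_wd) == 0) {
    warning(sprintf("genotype '%s' lacks one regime; contrast skipped", genotype),
            call. = FALSE)
    return(NULL)
  }
  mse <- attr(anova, "mse"); dfe <- attr(anova, "df_error")
  est <- mean(x_ww) - mean(x_wd)
  se <- sqrt(mse * (1 / length(x_ww) + 1 / length(x_wd)))
  tval <- est / se
  p <- 2 * stats::pt(-abs(tval), dfe)
  data.frame(genotype = genotype, trait = trait,
             mean_ww = mean(x_ww), mean_wd = mean(x_wd),
             estimate = est, se = se, t = tval, p = p,
             signif = signif_code(p), stringsAsFactors = FALSE)
}

#' Regime contrasts for every genotype
#'
#' @inheritParams regime_contrast
#' @return A data frame with one row per genotype (see [regime_contrast()]).
#' @export
regime_contrasts <- function(data, trait) {
  a <- two_way_anova(data, trait)
  out <- lapply(unique(data$genotype), function(g) regime_contrast(data, trait, g, anova = a))
  do.call(rbind, out)
}

#' Pearson correlation matrix with p-values
#'
#' Pairwise Pearson correlations with two-sided p-values from
#' `t = r * sqrt((n - 2) / (1 - r^2))` on `n - 2` df, plus the significance
#' codes used in trait correlation panels. Zero-variance columns yield NA
#' correlations and are flagged with a warning.
#'
#' @param x Numeric data frame or matrix (observations x variables), at
#'   least 3 complete observations per pair.
#' @return A list with matrices `r`, `p`, `n`, `signif` (codes, NA on the
#'   diagonal).
#' @export
correlation_matrix <- function(x) {
  x <- as.matrix(x)
  if (!is.numeric(x)) abort_input("'x' must be numeric")
  p_vars <- ncol(x)
  if (p_vars < 2) abort_input("need at least 2 variables")
  sds <- apply(x, 2, stats::sd, na.rm = TRUE)
  if (any(!is.na(sds) & sds == 0)) {
    warning("zero-variance column(s): correlations undefined (NA) for ",
            paste(colnames(x)[!is.na(sds) & sds == 0], collapse = ", "), call. = FALSE)
  }
  r <- p <- nmat <- matrix(NA_real_, p_vars, p_vars,
                           dimnames = list(colnames(x), colnames(x)))
  diag(r) <- 1
  for (i in seq_len(p_vars)) {
    for (j in seq_len(p_vars)) {
      if (i >= j) next
      ok <- stats::complete.cases(x[, c(i, j)])
      n <- sum(ok)
      nmat[i, j] <- nmat[j, i] <- n
      if (n < 3 || sds[i] == 0 || sds[j] == 0 || is.na(sds[i]) || is.na(sds[j])) next
      rij <- stats::cor(x[ok, i], x[ok, j])
      r[i, j] <- r[j, i] <- rij
      if (abs(rij) < 1) {
        tval <- rij * sqrt((n - 2) / (1 - rij^2))
        p[i, j] <- p[j, i] <- 2 * stats::pt(-abs(tval), n - 2)
      } else {
        p[i, j] <- p[j, i] <- 0
      }
    }
  }
  sig <- matrix(signif_code(p), p_vars, p_vars, dimnames = dimnames(r))
  list(r = r, p = p, n = nmat, signif = sig)
}

#' Correlation-matrix PCA
#'
#' Principal component analysis on the correlation matrix of a trait table
#' (each variable standardized): eigendecomposition, variance proportions,
#' variable loadings, observation scores and biplot coordinates. A
#' deterministic sign convention is applied: each component is flipped so
#' that its largest-magnitude loading is positive. Zero-variance variables
#' are rejected.
#'
#' @param x Numeric data frame or matrix (observations x variables), >= 2
#'   observations and >= 2 variables, no missing values.
#' @return An object of class `pca_result`: `eigenvalues`, `proportion`,
#'   `cumulative`, `loadings` (variables x components), `scores`
#'   (observations x components), `biplot` (list with `obs` scores and `vars`
#'   loadings scaled by sqrt(eigenvalue), first two components), and the
#'   correlation matrix `cor`.
#' @export
pca_correlation <- function(x) {
  x <- as.matrix(x)
  if (nrow(x) < 2) abort_input("need at least 2 observations")
  if (ncol(x) < 2) abort_input("need at least 2 variables")
  if (anyNA(x)) abort_input("missing values not allowed in the PCA input")
  sds <- apply(x, 2, stats::sd)
  if (any(sds == 0)) {
    abort_input("zero-variance variable(s): ", paste(colnames(x)[sds == 0], collapse = ", "))
  }
  R <- stats::cor(x)
  ee <- eigen(R, symmetric = TRUE)
  ev <- pmax(ee$values, 0)
  load <- ee$vectors
  # sign convention: largest-magnitude loading of each component positive
  for (j in seq_len(ncol(load))) {
    i <- which.max(abs(load[, j]))
    if (load[i, j] < 0) load[, j] <- -load[, j]
  }
  dimnames(load) <- list(colnames(x), paste0("PC", seq_len(ncol(load))))
  scores <- scale(x) %*% load
  structure(list(
    eigenvalues = ev,
    proportion = ev / sum(ev),
    cumulative = cumsum(ev) / sum(ev),
    loadings = load,
    scores = scores,
    biplot = list(obs = scores[, 1:2, drop = FALSE],
                  vars = sweep(load[, 1:2, drop = FALSE], 2, sqrt(ev[1:2]), `*`)),
    cor = R
  ), class = "pca_result")
}

#' @export
print.pca_result <- function(x, ...) {
  cat("Correlation-matrix PCA\n")
  print(round(rbind(eigenvalue = x$eigenvalues,
                    proportion = x$proportion,
                    cumulative = x$cumulative), 4))
  invisible(x)
}
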