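# Independent brute-force oracles used across the suite. These deliberately
# avoid the vectorized implementation paths they are checked against.

# RDPI by explicit double loop over cross-condition pairs
rdpi_brute <- function(ww, wd) {
  s <- 0; n <- 0
  for (a in ww) {
    for (b in wd) {
      if (a + b > 0) {
        s <- s + abs(b - a) / (a + b)
        n <- n + 1
      }
    }
  }
  s / n
}

# water use by explicit interval loop (series without refill rows)
water_use_brute <- function(days, pw, cpw, pbg) {
  s <- 0
  for (i in 2:length(days)) {
    s <- s + (pw[i - 1] - pw[i]) - (cpw[i - 1] - cpw[i]) -
      pbg * (days[i] - days[i - 1]) / 1000
  }
  s
}

# trait aggregation by per-segment loop, grouped by plant x layer x class
aggregate_brute <- function(seg, layer_edges = seq(0, 40, 10), class_edges = seq(0, 4.5, 0.5)) {
  res <- list()
  for (i in seq_len(nrow(seg))) {
    d <- seg$diameter_mm[i]; L <- seg$length_mm[i]; z <- seg$depth_cm[i]
    layer <- NA
    for (l in seq_len(length(layer_edges) - 1)) {
      hi <- layer_edges[l + 1]
      if (z >= layer_edges[l] && (z < hi || (l == length(layer_edges) - 1 && z <= hi))) layer <- l
    }
    cls <- length(class_edges)  # overflow
    for (c in seq_len(length(class_edges) - 1)) {
      hi <- class_edges[c + 1]
      if (d >= class_edges[c] && (d < hi || (c == length(class_edges) - 1 && d <= hi))) cls <- c
    }
    key <- paste(seg$plant_id[i], layer, cls, sep = "|")
    if (is.null(res[[key]])) res[[key]] <- c(rl = 0, sa = 0, rv = 0, dl = 0)
    res[[key]] <- res[[key]] + c(rl = L / 10, sa = pi * d * L / 100,
                                 rv = pi * (d / 2)^2 * L / 1000, dl = d * L / 10)
  }
  res
}

# classical balanced two-way RCBD decomposition from cell means
anova_brute <- function(value, block, genotype, regime) {
  grand <- mean(value)
  ss_of <- function(f) {
    m <- tapply(value, f, mean)
    n <- tapply(value, f, length)
    sum(n * (m - grand)^2)
  }
  ss_b <- ss_of(block); ss_g <- ss_of(genotype); ss_w <- ss_of(regime)
  gw <- interaction(genotype, regime)
  m_gw <- tapply(value, gw, mean); n_gw <- tapply(value, gw, length)
  m_g <- tapply(value, genotype, mean); m_w <- tapply(value, regime, mean)
  lev <- levels(gw)
  parts <- strsplit(lev, ".", fixed = TRUE)
  ss_gw <- sum(vapply(seq_along(lev), function(i) {
    g <- parts[[i]][1]; w <- parts[[i]][2]
    n_gw[i] * (m_gw[i] - m_g[g] - m_w[w] + grand)^2
  }, numeric(1)))
  total <- sum((value - grand)^2)
  c(block = unname(ss_b), genotype = unname(ss_g), regime = unname(ss_w),
    `genotype:regime` = unname(ss_gw),
    residual = unname(total - ss_b - ss_g - ss_w - ss_gw), total = total)
}

# small balanced dataset builder for ANOVA tests
make_balanced <- function(ng = 8, nb = 3, geno_eff = 0, regime_eff = 0,
                          inter_eff = 0, sd = 1) {
  d <- expand.grid(genotype = paste0("G", seq_len(ng)), regime = c("WW", "WD"),
                   block = seq_len(nb), stringsAsFactors = FALSE)
  d$value <- geno_eff * as.integer(factor(d$genotype)) +
    regime_eff * (d$regime == "WD") +
    inter_eff * as.integer(factor(d$genotype)) * (d$regime == "WD") +
    rnorm(nrow(d), 0, sd)
  d
}
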