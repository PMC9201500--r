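test_that("assumption checks report Shapiro-Wilk and Bartlett as expected", {
  q <- qnorm(ppoints(30))  # exact normal quantiles
  out <- assumption_checks(q)
  expect_gt(out$shapiro$W, 0.99)
  # identical group variances -> Bartlett statistic 0
  x <- c(1, 2, 3, 11, 12, 13)
  g <- rep(c("a", "b"), each = 3)
  out2 <- assumption_checks(x - ave(x, g), g)
  expect_equal(out2$bartlett$K2, 0, tolerance = 1e-12)
  expect_equal(out2$bartlett$p, 1, tolerance = 1e-9)
  # heavy-tailed sample rejects normality
  set.seed(101)
  out3 <- assumption_checks(rt(100, df = 2))
  expect_lt(out3$shapiro$p, 0.05)
  expect_warning(assumption_checks(rnorm(5), groups = c("a", "a", "a", "a", "b")),
                 "skipped")
})

test_that("two-way RCBD ANOVA matches the classical decomposition oracle", {
  set.seed(31)
  for (i in 1:10) {
    d <- make_balanced(ng = 2, nb = 2, geno_eff = runif(1, 0, 2),
                       regime_eff = runif(1, 0, 2), inter_eff = runif(1, 0, 1))
    a <- two_way_anova(d, "value")
    o <- anova_brute(d$value, d$block, d$genotype, d$regime)
    expect_equal(a$sum_sq[a$term == "block"], o["block"], tolerance = 1e-9,
                 ignore_attr = TRUE)
    expect_equal(a$sum_sq[a$term == "genotype"], o["genotype"], tolerance = 1e-9,
                 ignore_attr = TRUE)
    expect_equal(a$sum_sq[a$term == "regime"], o["regime"], tolerance = 1e-9,
                 ignore_attr = TRUE)
    expect_equal(a$sum_sq[a$term == "genotype:regime"], o["genotype:regime"],
                 tolerance = 1e-9, ignore_attr = TRUE)
    expect_equal(a$sum_sq[a$term == "Residuals"], o["residual"], tolerance = 1e-9,
                 ignore_attr = TRUE)
    # partition invariants
    expect_equal(sum(a$sum_sq), attr(a, "total_ss"), tolerance = 1e-9)
    expect_equal(sum(a$df), nrow(d) - 1)
  }
})

test_that("ANOVA F is invariant to location and scale changes of the trait", {
  set.seed(55)
  d <- make_balanced(geno_eff = 0.5, regime_eff = 1)
  a <- two_way_anova(d, "value")
  d2 <- d; d2$value <- d$value + 100
  a2 <- two_way_anova(d2, "value")
  expect_equal(a$F, a2$F, tolerance = 1e-9)
  d3 <- d; d3$value <- d$value * 7 - 3
  a3 <- two_way_anova(d3, "value")
  expect_equal(a$F, a3$F, tolerance = 1e-9)
})

test_that("a pure regime effect with zero noise puts all SS on the regime term", {
  d <- make_balanced(regime_eff = 2, sd = 0)
  a <- suppressWarnings(two_way_anova(d, "value"))  # perfect fit warns in anova()
  expect_equal(a$sum_sq[a$term == "genotype"], 0, tolerance = 1e-9)
  expect_equal(a$sum_sq[a$term == "genotype:regime"], 0, tolerance = 1e-9)
  expect_gt(a$sum_sq[a$term == "regime"], 0)
})

test_that("one-way ANOVA F equals the squared pooled two-sample t", {
  set.seed(70)
  x <- rnorm(6); g <- rep(c("a", "b"), each = 3)
  a <- one_way_anova(x, g)
  tt <- t.test(x ~ g, var.equal = TRUE)
  expect_equal(a$F[1], unname(tt$statistic)^2, tolerance = 1e-9)
  expect_equal(a$p[1], tt$p.value, tolerance = 1e-9)
  # identical group means -> F = 0
  a0 <- one_way_anova(c(1, 2, 3, 1, 2, 3), g)
  expect_equal(a0$F[1], 0, tolerance = 1e-12)
  expect_error(one_way_anova(1:5, rep("a", 5)), "at least 2 groups")
})

test_that("LSD letters: degenerate and separated cases", {
  eq <- lsd_letters(c(a = 5, b = 5, c = 5), n = 3, mse = 1, df_error = 10)
  expect_true(all(eq$letters == "a"))
  sep <- lsd_letters(c(hi = 10, lo = 0), n = 3, mse = 1e-6, df_error = 10)
  expect_equal(sep$letters, c("a", "b"))
  expect_equal(sep$group, c("hi", "lo"))  # sorted descending, 'a' on top
})

test_that("LSD letter sharing agrees with the all-pairs t oracle", {
  set.seed(90)
  for (i in 1:50) {
    k <- 8
    means <- rnorm(k, 10, sample(c(0.2, 1, 3), 1))
    names(means) <- paste0("g", 1:k)
    n <- sample(2:6, k, replace = TRUE)
    mse <- runif(1, 0.1, 4)
    dfe <- sample(10:40, 1)
    alpha <- 0.05
    out <- lsd_letters(means, n, mse, dfe, alpha)
    nm <- out$group
    share <- function(a, b) {
      la <- strsplit(out$letters[out$group == a], "")[[1]]
      lb <- strsplit(out$letters[out$group == b], "")[[1]]
      length(intersect(la, lb)) > 0
    }
    for (a in 1:(k - 1)) {
      for (b in (a + 1):k) {
        ga <- nm[a]; gb <- nm[b]
        se <- sqrt(mse * (1 / n[match(ga, names(means))] + 1 / n[match(gb, names(means))]))
        tval <- (means[ga] - means[gb]) / se
        sig <- unname(2 * pt(-abs(tval), dfe) < alpha)
        expect_identical(share(ga, gb), !sig)
      }
    }
  }
})

test_that("regime contrasts use WW - WD with the pooled ANOVA error", {
  d <- make_balanced(ng = 3, nb = 3, sd = 0)
  d$value <- d$value + ifelse(d$regime == "WW", 21.3, 2.1) + rnorm(nrow(d), 0, 0.5)
  ctr <- regime_contrasts(d, "value")
  expect_equal(nrow(ctr), 3)
  expect_equal(ctr$estimate, ctr$mean_ww - ctr$mean_wd, tolerance = 1e-12)
  expect_true(all(ctr$estimate > 15))
  expect_true(all(ctr$signif %in% c("*", "**", "***")))
  # t statistic oracle from the pooled MSE
  a <- two_way_anova(d, "value")
  g1 <- d[d$genotype == "G1", ]
  est <- mean(g1$value[g1$regime == "WW"]) - mean(g1$value[g1$regime == "WD"])
  se <- sqrt(attr(a, "mse") * (2 / 3))
  expect_equal(ctr$t[ctr$genotype == "G1"], est / se, tolerance = 1e-9)
  # a trait that rises under WD yields a negative estimate
  d$value <- ifelse(d$regime == "WD", 0.12, 0.04) + rnorm(nrow(d), 0, 0.01)
  ctr2 <- regime_contrasts(d, "value")
  expect_true(all(ctr2$estimate < 0))
  # identical means -> estimate 0, ns
  d$value <- rep(1, nrow(d))
  ctr3 <- suppressWarnings(regime_contrasts(d, "value"))
  expect_true(all(abs(ctr3$estimate) < 1e-12))
})

test_that("correlation matrix matches hand values and cor.test", {
  x <- data.frame(a = c(1, 2, 3), b = c(1, 3, 2), c = c(2, 4, 6))
  out <- correlation_matrix(x)
  expect_equal(out$r["a", "b"], 0.5, tolerance = 1e-12)
  expect_equal(out$r["a", "c"], 1, tolerance = 1e-12)  # y = 2x
  expect_equal(out$r, t(out$r))
  expect_true(all(diag(out$r) == 1))
  set.seed(17)
  y <- as.data.frame(matrix(rnorm(40), 10, 4))
  oy <- correlation_matrix(y)
  ct <- cor.test(y[[1]], y[[2]])
  expect_equal(oy$r[1, 2], unname(ct$estimate), tolerance = 1e-12)
  expect_equal(oy$p[1, 2], ct$p.value, tolerance = 1e-9)
  z <- data.frame(a = rnorm(5), flat = rep(1, 5))
  expect_warning(oz <- correlation_matrix(z), "zero-variance")
  expect_true(is.na(oz$r["a", "flat"]))
})

test_that("correlation-matrix PCA: closed forms, trace and reconstruction", {
  # 2 standardized variables with correlation r -> eigenvalues 1 + r, 1 - r
  set.seed(23)
  x1 <- rnorm(50)
  x2 <- 0.6 * x1 + sqrt(1 - 0.36) * rnorm(50)
  p2 <- pca_correlation(cbind(a = x1, b = x2))
  r <- cor(x1, x2)
  expect_equal(p2$eigenvalues, c(1 + r, 1 - r), tolerance = 1e-9)
  # eigenvalue sum = number of variables; proportions sum to 1
  m <- matrix(rnorm(60), 12, 5)
  colnames(m) <- paste0("v", 1:5)
  p5 <- pca_correlation(m)
  expect_equal(sum(p5$eigenvalues), 5, tolerance = 1e-9)
  expect_equal(sum(p5$proportion), 1, tolerance = 1e-12)
  expect_true(all(p5$eigenvalues >= 0))
  # loadings reconstruct the correlation matrix
  rec <- p5$loadings %*% diag(p5$eigenvalues) %*% t(p5$loadings)
  expect_equal(unname(rec), unname(p5$cor), tolerance = 1e-9)
  # deterministic sign convention: the largest loading of each PC is positive
  for (j in 1:5) {
    expect_gt(p5$loadings[which.max(abs(p5$loadings[, j])), j], 0)
  }
  expect_error(pca_correlation(m[1, , drop = FALSE]), "2 observations")
  expect_error(pca_correlation(cbind(a = rnorm(5), b = rep(2, 5))), "zero-variance")
})

test_that("PCA agrees with princomp on shared quantities", {
  set.seed(41)
  m <- matrix(rnorm(80), 16, 5)
  colnames(m) <- paste0("v", 1:5)
  mine <- pca_correlation(m)
  ref <- princomp(m, cor = TRUE)
  expect_equal(mine$eigenvalues, unname(ref$sdev)^2, tolerance = 1e-6)
  expect_equal(abs(unclass(mine$loadings)), abs(unclass(ref$loadings)),
               tolerance = 1e-6, ignore_attr = TRUE)
})
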