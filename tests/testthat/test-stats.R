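test_that("perfect correlations and degenerate inputs", {
  x <- as.numeric(1:10)
  r1 <- suppressWarnings(pearsonBca(x, x, nBoot = 200, seed = 1))
  expect_equal(r1@r, 1)
  r2 <- suppressWarnings(pearsonBca(x, -x, nBoot = 200, seed = 1))
  expect_equal(r2@r, -1)
  expect_error(pearsonBca(rep(1, 10), x), "zero variance")
  expect_error(pearsonBca(x[1:2], x[1:2]), "at least 3")
  expect_error(pearsonBca(x, x[1:9]), "equal length")
  expect_error(pearsonBca(c(x, NA), c(x, 1)), "missing values")
})

test_that("BCa reduces to the percentile interval for symmetric, unbiased
           bootstrap distributions", {
  boots <- 0.5 + rep(c(-0.2, -0.1, -0.05, 0.05, 0.1, 0.2), 50)
  ci <- bcaInterval(boots, 0.5, jackknife = NULL)
  expect_identical(ci$method, "bca")
  pct <- quantile(boots, c(0.025, 0.975), names = FALSE, type = 6)
  expect_equal(c(ci$low, ci$high), pct, tolerance = 1e-12)
  # degenerate distribution falls back with a warning
  expect_warning(flat <- bcaInterval(rep(0.3, 50), 0.3), "degenerate")
  expect_identical(flat$method, "percentile")
})

test_that("BCa interval agrees with an independent implementation", {
  set.seed(9)
  x <- rnorm(80); y <- 0.4 * x + rnorm(80)
  ours <- pearsonBca(x, y, nBoot = 5000, seed = 3)
  set.seed(3)
  b <- boot::boot(cbind(x, y), function(d, i) cor(d[i, 1], d[i, 2]),
                  R = 5000)
  ref <- boot::boot.ci(b, type = "bca")$bca[4:5]
  expect_equal(c(ours@ciLow, ours@ciHigh), ref, tolerance = 0.02)
})

test_that("BCa 95% interval covers the true correlation at nominal rate", {
  rho <- 0.5
  cover <- 0L
  nRep <- 500L
  for (rep in seq_len(nRep)) {
    set.seed(rep)
    x <- rnorm(200)
    y <- rho * x + sqrt(1 - rho^2) * rnorm(200)
    cr <- pearsonBca(x, y, nBoot = 2000, seed = rep)
    cover <- cover + (cr@ciLow <= rho && rho <= cr@ciHigh)
  }
  expect_gte(cover / nRep, 0.93)
  expect_lte(cover / nRep, 0.97)
})

test_that("regression band implements the closed-form formula exactly", {
  set.seed(4)
  x <- c(1.2, 2.1, 2.9, 4.4, 5.0, 6.3, 7.7, 8.1, 9.5, 10.2)
  y <- 1.5 + 0.8 * x + rnorm(10, sd = 0.6)
  band <- regressionBand(x, y)
  # from-scratch evaluation of the printed formula
  n <- 10
  fit <- lm(y ~ x)
  serr <- sqrt(sum(residuals(fit)^2) / (n - 2))
  tq <- qt(0.975, n - 2)
  hw <- tq * serr * sqrt(1 / n + (x - mean(x))^2 / sum((x - mean(x))^2))
  expect_equal(band$halfWidth, hw, tolerance = 1e-12)
  expect_equal(band$fit, unname(fitted(fit)), tolerance = 1e-12)
  # at x = xbar the half-width collapses to t * s / sqrt(n)
  atMean <- regressionBand(x, y, xout = mean(x))
  expect_equal(atMean$halfWidth, tq * serr / sqrt(n), tolerance = 1e-12)
  # collinear data: zero-width band
  coll <- regressionBand(x, 2 * x + 1)
  expect_true(all(abs(coll$halfWidth) < 1e-10))
  expect_error(regressionBand(rep(2, 5), rnorm(5)), "zero variance")
})

test_that("one-way ANOVA matches hand computation and stats::aov", {
  g1 <- c(1, 2, 3, 4); g2 <- c(3, 5, 7, 9)
  res <- oneWayAnova(list(g1, g2))
  # hand-computed sums of squares
  gm <- mean(c(g1, g2))
  ssb <- 4 * (mean(g1) - gm)^2 + 4 * (mean(g2) - gm)^2
  ssw <- sum((g1 - mean(g1))^2) + sum((g2 - mean(g2))^2)
  expect_equal(res$F, (ssb / 1) / (ssw / 6), tolerance = 1e-12)
  expect_equal(res$etaSquared, ssb / (ssb + ssw), tolerance = 1e-12)
  # independent route: stats::aov on the same data
  df <- data.frame(v = c(g1, g2), g = factor(rep(1:2, each = 4)))
  tab <- summary(aov(v ~ g, data = df))[[1]]
  expect_equal(res$F, tab[1, "F value"], tolerance = 1e-10)
  expect_equal(res$p, tab[1, "Pr(>F)"], tolerance = 1e-10)
  # identical groups: F = 0, eta^2 = 0
  same <- oneWayAnova(list(c(1, 2, 3), c(1, 2, 3)))
  expect_equal(same$F, 0)
  expect_equal(same$etaSquared, 0)
  # full separation with zero within-group variance: eta^2 = 1
  sep <- oneWayAnova(list(c(2, 2), c(5, 5)))
  expect_equal(sep$etaSquared, 1)
  expect_identical(sep$p, 0)
  expect_error(oneWayAnova(list(g1)), "2 groups")
  expect_error(oneWayAnova(list(g1, 5)), "at least 2 values")
})
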