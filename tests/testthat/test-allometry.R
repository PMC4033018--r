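test_that("part-whole transform subtracts the structure from the whole", {
  tv <- part_whole_log_transform(1, 11)
  expect_equal(tv$x, 1)
  expect_equal(tv$y, 0)
  # the human whole-amygdala value in log10 units
  expect_equal(round(part_whole_log_transform(2.031, 300)$y, 2), 0.31)
  expect_error(part_whole_log_transform(5, 5), "smaller")
  expect_error(part_whole_log_transform(-1, 5), "positive")
  expect_error(part_whole_log_transform(NA, 5), "missing")
})

test_that("percent residual follows the (obs - pred)/obs * 100 convention", {
  expect_equal(percent_residual(2, 2), 0)
  expect_equal(percent_residual(1, 2), -100)
  expect_equal(percent_residual(2, 1), 50)
  # invariance to common rescaling
  expect_equal(percent_residual(0.7, 0.31), percent_residual(700, 310))
  expect_error(percent_residual(0, 1), "positive")
  expect_error(percent_residual(1, -2), "positive")
  # inverting the formula against a -312% residual for the central nucleus
  y_obs <- 0.039
  y_pred <- y_obs * (1 - (-312) / 100)
  expect_equal(percent_residual(y_obs, y_pred), -312)
  expect_equal(y_pred, 0.16068)
})

test_that("exact linear data are recovered exactly under both gates", {
  tr <- simulate_tree(6, 20, seed = 61)
  h <- seq(1.8, 2.8, length.out = 6)
  y <- -1.9 + 0.8 * h
  sp <- data.frame(species = tr$tip.label, vol = 10^y,
                   hemisphere = 10^h + 10^y)
  for (gate in c("OLS", "CONTRASTS")) {
    m <- fit_allometry(sp, "vol", tree = tr, gate = gate)
    expect_equal(m$coef[["slope"]], 0.8, tolerance = 1e-9)
    expect_equal(m$coef[["intercept"]], -1.9, tolerance = 1e-9)
    expect_equal(m$R2, 1, tolerance = 1e-9)
  }
})

test_that("reference-set rules are enforced", {
  tr <- simulate_tree(5, 20, seed = 62)
  sp <- data.frame(species = tr$tip.label, vol = c(1, 2, 3, 4, 5),
                   hemisphere = c(60, 120, 180, 240, 300))
  expect_error(fit_allometry(sp, "nope", tree = tr), "not found")
  expect_error(fit_allometry(sp, "vol", tree = tr, reference = tr$tip.label,
                             target = tr$tip.label[1]), "excluded")
  expect_error(fit_allometry(sp[1:3, ], "vol", tree = tr, gate = "OLS"),
               "at least 4")
  expect_warning(fit_allometry(sp[1:4, ], "vol", tree = tr, gate = "OLS"),
                 "little power")
})

test_that("contrasts-mode fit equals GLS under the Brownian covariance", {
  tr <- simulate_tree(10, 30, seed = 63)
  V <- bm_covariance(tr)
  set.seed(64)
  h <- setNames(rmvn_chol(V, 0.3) + 2.3, tr$tip.label)
  yl <- -1.5 + 0.7 * h + rmvn_chol(V, 0.1)
  sp <- data.frame(species = tr$tip.label, vol = 10^yl,
                   hemisphere = 10^h + 10^yl)
  m <- fit_allometry(sp, "vol", tree = tr, gate = "CONTRASTS")
  g <- gls_fit(m$x, m$y, V[names(m$x), names(m$x)])
  expect_equal(m$coef[["slope"]], g$coefficients[["slope"]],
               tolerance = 1e-8)
  expect_equal(m$coef[["intercept"]], g$coefficients[["intercept"]],
               tolerance = 1e-8)
})

test_that("rescaling volumes shifts only the intercept, by (1-b)log10(c)", {
  tr <- simulate_tree(8, 25, seed = 65)
  set.seed(66)
  h <- seq(1.9, 2.7, length.out = 8)
  yl <- -1.8 + 0.75 * h + rnorm(8, 0, 0.04)
  sp <- data.frame(species = tr$tip.label, vol = 10^yl,
                   hemisphere = 10^h + 10^yl)
  cc <- 1000  # cc -> mm^3
  sp_mm <- transform(sp, vol = vol * cc, hemisphere = hemisphere * cc)
  for (gate in c("OLS", "CONTRASTS")) {
    m1 <- fit_allometry(sp, "vol", tree = tr, gate = gate)
    m2 <- fit_allometry(sp_mm, "vol", tree = tr, gate = gate)
    expect_equal(m2$coef[["slope"]], m1$coef[["slope"]], tolerance = 1e-10)
    expect_equal(m2$R2, m1$R2, tolerance = 1e-10)
    expect_equal(m2$coef[["intercept"]] - m1$coef[["intercept"]],
                 (1 - m1$coef[["slope"]]) * log10(cc), tolerance = 1e-10)
  }
})

test_that("OLS prediction interval matches the textbook formula", {
  x <- c(1.2, 1.8, 2.1, 2.6, 3.0)
  y <- c(0.1, 0.55, 0.8, 1.25, 1.5)
  sp <- data.frame(species = paste("s", 1:5), vol = 10^y,
                   hemisphere = 10^x + 10^y)
  m <- fit_allometry(sp, "vol", gate = "OLS")
  x0 <- 2.4
  band <- predict_with_interval(m, x0, level = 0.95)
  # longhand: coefficients, s, and the new-observation variance
  b <- sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
  a <- mean(y) - b * mean(x)
  s2 <- sum((y - a - b * x)^2) / 3
  se <- sqrt(s2 * (1 + 1 / 5 + (x0 - mean(x))^2 / sum((x - mean(x))^2)))
  expect_equal(band$y_hat, a + b * x0, tolerance = 1e-12)
  expect_equal(band$upper, a + b * x0 + qt(0.975, 3) * se, tolerance = 1e-12)
  expect_equal(band$lower, a + b * x0 - qt(0.975, 3) * se, tolerance = 1e-12)
  expect_equal(band$arithmetic[["upper"]], 10^band$upper)
  # width is minimal at the reference centroid and grows away from it
  w <- function(z) {
    pb <- predict_with_interval(m, z)
    pb$upper - pb$lower
  }
  expect_lt(w(mean(x)), w(mean(x) + 0.5))
  expect_lt(w(mean(x) + 0.5), w(mean(x) + 1))
  expect_error(predict_with_interval(m, 2, level = 1.2), "level")
})

test_that("zero residual variance collapses the band onto the line", {
  tr <- simulate_tree(6, 20, seed = 67)
  h <- seq(2, 2.8, length.out = 6)
  y <- -1 + 0.6 * h
  sp <- data.frame(species = tr$tip.label, vol = 10^y,
                   hemisphere = 10^h + 10^y)
  for (gate in c("OLS", "CONTRASTS")) {
    m <- fit_allometry(sp, "vol", tree = tr, gate = gate)
    band <- predict_with_interval(m, 2.4)
    expect_equal(band$lower, band$y_hat, tolerance = 1e-7)
    expect_equal(band$upper, band$y_hat, tolerance = 1e-7)
  }
})

test_that("log-scale bounds map to arithmetic volumes by antilog", {
  # 0.14 log10 cc is 1.38 cc to printed precision
  expect_equal(round(10^0.14, 2), 1.38)
  b <- classify_in_band(1.31, lower = -0.09, upper = 0.14, y_hat = 0.05)
  expect_equal(b$classification, "within")
})
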