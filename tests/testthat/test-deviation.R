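test_that("published interval bounds and human volumes reproduce the marker pattern", {
  # Feeding the summary table's 95% PI bounds and the observed human
  # volumes through the classifier recovers the reported pattern for all
  # seven hominoid subcortical structures.
  for (i in seq_len(nrow(hominoid_printed_pi))) {
    row <- hominoid_printed_pi[i, ]
    call <- classify_in_band(row$human, row$lower, row$upper,
                             structure = row$structure)
    expect_equal(call$classification, row$expected, label = row$structure)
  }
})

test_that("classification basics: on the line, above, below, upper tail", {
  on_line <- classify_in_band(10^0.2, lower = 0.1, upper = 0.3, y_hat = 0.2)
  expect_equal(on_line$classification, "within")
  expect_equal(on_line$percent_residual, 0)
  expect_false(on_line$upper_tail_flag)

  tail_call <- classify_in_band(10^0.28, lower = 0.1, upper = 0.3,
                                y_hat = 0.2, one_sided_upper = 0.26)
  expect_equal(tail_call$classification, "within")
  expect_true(tail_call$upper_tail_flag)

  expect_equal(classify_in_band(10, 0.1, 0.3)$classification,
               "significantly_above")
  expect_equal(classify_in_band(1.01, 0.1, 0.3)$classification,
               "significantly_below")
  expect_error(classify_in_band(-1, 0, 1), "positive")
  expect_error(classify_in_band(2, 1, 0), "exceeds")
})

test_that("classification agrees between log and arithmetic space", {
  set.seed(71)
  for (i in 1:20) {
    lo <- rnorm(1); hi <- lo + runif(1, 0.05, 1)
    y <- rnorm(1, (lo + hi) / 2, 1)
    call <- classify_in_band(10^y, lo, hi)
    arith <- if (10^y > 10^hi) "significantly_above"
             else if (10^y < 10^lo) "significantly_below" else "within"
    expect_equal(call$classification, arith)
  }
})

test_that("classify_target refuses a target inside the reference set", {
  tr <- simulate_tree(6, 20, seed = 72)
  h <- seq(2, 2.8, length.out = 6)
  set.seed(73)
  y <- -1 + 0.6 * h + rnorm(6, 0, 0.03)
  sp <- data.frame(species = tr$tip.label, vol = 10^y,
                   hemisphere = 10^h + 10^y)
  m <- fit_allometry(sp, "vol", tree = tr, gate = "OLS")
  expect_error(classify_target(m, 1, 2.3, target = tr$tip.label[1]),
               "reference set")
})

test_that("mean-residual t-test has closed-form behavior", {
  tr <- simulate_tree(6, 20, seed = 74)
  h <- seq(2, 2.8, length.out = 6)
  y <- -1 + 0.6 * h
  sp <- data.frame(species = tr$tip.label, vol = 10^y,
                   hemisphere = 10^h + 10^y)
  m <- fit_allometry(sp, "vol", gate = "OLS")

  # individuals exactly on the line: t = 0, p = 1
  ind <- data.frame(volume = 10^(-1 + 0.6 * c(2.1, 2.3, 2.5)),
                    hemisphere = 10^c(2.1, 2.3, 2.5) +
                      10^(-1 + 0.6 * c(2.1, 2.3, 2.5)))
  t0 <- test_mean_residual(m, ind)
  expect_equal(t0$t, 0)
  expect_equal(t0$p, 1)
  expect_equal(t0$df, 2)

  # symmetric residuals: mean 0, p = 1
  d <- 0.05
  xs <- c(2.2, 2.2, 2.4, 2.4)
  ys <- -1 + 0.6 * xs + c(d, -d, d, -d)
  ind2 <- data.frame(volume = 10^ys, hemisphere = 10^xs + 10^ys)
  t2 <- test_mean_residual(m, ind2)
  expect_equal(t2$mean_residual, 0, tolerance = 1e-12)
  expect_equal(t2$p, 1)

  # a +0.05 log10 shift with sd 0.02 over 10 individuals is significant,
  # and t matches the closed form mean/(sd/sqrt(n))
  set.seed(75)
  xs <- runif(10, 2, 2.8)
  shift <- 0.05 + rnorm(10, 0, 0.02)
  ys <- -1 + 0.6 * xs + shift
  ind3 <- data.frame(volume = 10^ys, hemisphere = 10^xs + 10^ys)
  t3 <- test_mean_residual(m, ind3)
  expect_lt(t3$p, 0.05)
  expect_gt(t3$mean_residual, 0)
  expect_equal(t3$t, mean(shift) / (sd(shift) / sqrt(10)), tolerance = 1e-10)

  expect_error(test_mean_residual(m, ind3[1, ]), "classify_target")
})

test_that("mean-residual t-test holds its nominal type-I error", {
  tr <- simulate_tree(6, 20, seed = 76)
  h <- seq(2, 2.8, length.out = 6)
  y <- -1 + 0.6 * h
  sp <- data.frame(species = tr$tip.label, vol = 10^y,
                   hemisphere = 10^h + 10^y)
  m <- fit_allometry(sp, "vol", gate = "OLS")
  set.seed(77)
  n_reps <- 2000
  rej <- vapply(seq_len(n_reps), function(i) {
    xs <- runif(8, 2, 2.8)
    ys <- -1 + 0.6 * xs + rnorm(8, 0, 0.04)  # null: zero mean residual
    ind <- data.frame(volume = 10^ys, hemisphere = 10^xs + 10^ys)
    test_mean_residual(m, ind)$p < 0.05
  }, logical(1))
  # within 3 binomial SEs of 0.05
  expect_lt(abs(mean(rej) - 0.05), 3 * sqrt(0.05 * 0.95 / n_reps))
})

test_that("outlier screen flags only a separated species", {
  set.seed(78)
  base <- lapply(setNames(nm = paste0("sp", 1:5)), function(s)
    rnorm(4, 0, 0.05))
  rep0 <- detect_outlier_taxon(base)
  expect_length(rep0$flagged, 0)
  expect_true(isSymmetric(rep0$tukey_p) || all(is.na(rep0$tukey_p)))

  shifted <- base
  shifted$sp3 <- shifted$sp3 - 3 * 0.05
  rep1 <- detect_outlier_taxon(shifted)
  expect_equal(rep1$flagged, "sp3")
  expect_lt(rep1$p, 0.05)
  offd <- rep1$tukey_p[upper.tri(rep1$tukey_p)]
  expect_true(all(is.na(offd) | (offd >= 0 & offd <= 1)))

  # flagging is invariant to species order
  perm <- shifted[c(4, 2, 5, 1, 3)]
  expect_equal(detect_outlier_taxon(perm)$flagged, "sp3")
})

test_that("outlier screen preconditions", {
  expect_error(suppressWarnings(
    detect_outlier_taxon(list(a = c(1, 2), b = 3, c = 4))),
    "at least 3")
  expect_warning(
    detect_outlier_taxon(list(a = c(1, 2), b = c(1.1, 2.1),
                              c = c(0.9, 1.9), d = 5)),
    "single individual")
  # identical residuals: F undefined, nothing flagged
  same <- detect_outlier_taxon(list(a = c(1, 1), b = c(1, 1), c = c(1, 1)))
  expect_true(is.na(same$F))
  expect_length(same$flagged, 0)
})
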