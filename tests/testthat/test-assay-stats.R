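test_that("viability percentages follow the percent-of-control arithmetic", {
  expect_equal(viabilityPercent(0.50, c(0.5, 0.5))$group_mean_pct, 100)
  expect_equal(viabilityPercent(0.35, c(0.5, 0.5))$group_mean_pct, 70)
  expect_equal(viabilityPercent(0.35, c(0.5, 0.5), blank_od = 0.05)$group_mean_pct,
               66.666667, tolerance = 1e-6)
  v <- viabilityPercent(c(0.4, 0.3), c(0.5, 0.5))
  expect_equal(v$replicate_pct, c(80, 60))
  expect_equal(v$group_mean_pct, 70)
  # control group against itself is exactly 100 on the mean
  set.seed(2)
  ctrl <- rnorm(6, 0.5, 0.05)
  expect_equal(viabilityPercent(ctrl, ctrl)$group_mean_pct, 100)
  expect_error(viabilityPercent(0.3, c(0.1, 0.1), blank_od = 0.2), "positive")
})

test_that("cytotoxicity call is inclusive at 70% and monotone", {
  expect_identical(classifyCytotoxicity(c(70, 69.9, 100, 0)),
                   c("noncytotoxic", "cytotoxic", "noncytotoxic", "cytotoxic"))
  x <- seq(0, 120, by = 0.1)
  ok <- classifyCytotoxicity(x) == "noncytotoxic"
  expect_true(all(diff(as.integer(ok)) >= 0))
  expect_identical(sum(diff(as.integer(ok))), 1L)
  expect_true(ok[x == 70])
})

test_that("noise-free plates reproduce planted viabilities and the study's calls", {
  # emulate a dose series where high doses drop below the 70% line
  groups <- data.frame(label = c("control", "d40", "d80", "d160"),
                       concentration = c("control", "40", "80", "160"),
                       true_mean = c(0.50, 0.45, 0.30, 0.20),
                       n_replicates = 3)
  plate <- generateAssayPlates(plateSpec(groups, noise_sd = 0, seed = 1))
  ctrl <- plate$wells$od[plate$wells$group == "control"]
  pct <- vapply(c("d40", "d80", "d160"), function(g)
    viabilityPercent(plate$wells$od[plate$wells$group == g], ctrl)$group_mean_pct,
    numeric(1))
  expect_equal(unname(pct), c(90, 60, 40))
  expect_identical(unname(classifyCytotoxicity(pct)),
                   c("noncytotoxic", "cytotoxic", "cytotoxic"))
})

test_that("standard curve fits match the normal-equations oracle", {
  cv <- fitStandardCurve(c(0, 100), c(0.05, 0.55))
  expect_equal(cv@slope, 0.005, tolerance = 1e-12)
  expect_equal(cv@intercept, 0.05, tolerance = 1e-12)
  set.seed(9)
  conc <- c(0, 12.5, 25, 50, 75, 100)
  od <- 0.004 * conc + 0.06 + rnorm(6, 0, 0.01)
  cv2 <- fitStandardCurve(conc, od)
  want <- olsOracle(conc, od)
  expect_equal(cv2@slope, want$slope, tolerance = 1e-9)
  expect_equal(cv2@intercept, want$intercept, tolerance = 1e-9)
  # duplicated points leave the fit unchanged (OLS identity)
  cv3 <- fitStandardCurve(rep(conc, 2), rep(od, 2))
  expect_equal(cv3@slope, cv2@slope, tolerance = 1e-12)
  expect_error(fitStandardCurve(c(5, 5), c(0.1, 0.2)), "distinct")
})

test_that("nitrite read-off inverts the curve and clamps negatives", {
  cv <- fitStandardCurve(c(0, 100), c(0.05, 0.55))
  expect_equal(nitriteConcentration(0.30, cv), 50)
  expect_equal(nitriteConcentration(0.05, cv), 0)
  for (c0 in c(0, 1, 17.3, 80)) {
    expect_equal(nitriteConcentration(cv@slope * c0 + cv@intercept, cv), c0,
                 tolerance = 1e-9)
  }
  expect_warning(got <- nitriteConcentration(0.01, cv), "clamped")
  expect_identical(got, 0)
  expect_error(nitriteConcentration(0.3, "not a curve"), "StandardCurve")
})

test_that("pooled t-test matches the closed-form oracle", {
  res <- unpairedTTest(c(1, 2, 3), c(2, 3, 4))
  want <- pooledTOracle(c(1, 2, 3), c(2, 3, 4))
  expect_equal(res$t_statistic, -1.2247, tolerance = 1e-3)
  expect_equal(res$degrees_of_freedom, 4)
  expect_equal(res$p_value, 0.2879, tolerance = 1e-3)
  expect_equal(res$t_statistic, want$t, tolerance = 1e-12)
  expect_equal(res$p_value, want$p, tolerance = 1e-12)
  set.seed(13)
  for (i in 1:20) {
    a <- rnorm(sample(3:8, 1)); b <- rnorm(sample(3:8, 1), 0.5)
    res <- unpairedTTest(a, b)
    want <- pooledTOracle(a, b)
    expect_equal(res$t_statistic, want$t, tolerance = 1e-12)
    expect_equal(res$degrees_of_freedom, want$df)
    expect_equal(res$p_value, want$p, tolerance = 1e-12)
  }
})

test_that("t-test symmetry, identical-group and welch behaviour", {
  a <- c(1.1, 2.2, 3.0, 4.4)
  b <- c(2.0, 2.5, 3.5)
  r1 <- unpairedTTest(a, b)
  r2 <- unpairedTTest(b, a)
  expect_equal(r1$t_statistic, -r2$t_statistic, tolerance = 1e-12)
  expect_equal(r1$p_value, r2$p_value, tolerance = 1e-12)
  same <- unpairedTTest(c(2, 2, 2), c(2, 2, 2))
  expect_identical(same$t_statistic, 0)
  expect_identical(same$p_value, 1)
  # equal sizes: welch df equals pooled df and the stats coincide
  set.seed(14)
  x <- rnorm(5); y <- rnorm(5)
  y <- (y - mean(y)) / sd(y) * sd(x) + mean(y)  # force equal variances
  st <- unpairedTTest(x, y, "student")
  we <- unpairedTTest(x, y, "welch")
  expect_equal(st$t_statistic, we$t_statistic, tolerance = 1e-9)
  expect_equal(st$degrees_of_freedom, we$degrees_of_freedom, tolerance = 1e-9)
  expect_error(unpairedTTest(1, c(1, 2)), "at least two")
})

test_that("significance stars use strict thresholds, extreme wins", {
  expect_identical(significanceStars(c(0.04, 0.05, 0.00005, 0.009, 0.0009, 1)),
                   c("*", "ns", "****", "**", "***", "ns"))
  expect_identical(significanceStars(0.01), "*")     # strict at each cut
  expect_identical(significanceStars(0.001), "**")
  expect_identical(significanceStars(0.0001), "***")
  expect_error(significanceStars(1.2), "\\[0, 1\\]")
})

test_that("plate-level comparisons test each treatment against control", {
  groups <- data.frame(label = c("control", "low", "high"),
                       concentration = c("control", "10", "100"),
                       true_mean = c(0.50, 0.49, 0.20), n_replicates = 5)
  plate <- generateAssayPlates(plateSpec(groups, noise_sd = 0.02, seed = 33))
  cmp <- compareGroups(plate$wells)
  expect_identical(cmp$group, c("low", "high"))
  ctrl <- plate$wells$od[plate$wells$group == "control"]
  for (i in seq_len(nrow(cmp))) {
    g <- plate$wells$od[plate$wells$group == cmp$group[i]]
    expect_equal(cmp$p_value[i], pooledTOracle(g, ctrl)$p, tolerance = 1e-12)
  }
  expect_identical(cmp$stars[2], significanceStars(cmp$p_value[2]))
  holm <- compareGroups(plate$wells, holm = TRUE)
  expect_identical(holm$p_value, cmp$p_value)  # raw p reported, stars adjusted
  expect_identical(holm$stars,
                   significanceStars(p.adjust(cmp$p_value, "holm")))
  expect_error(compareGroups(plate$wells, control = "nope"), "control")
})
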