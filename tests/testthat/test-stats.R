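# Group-comparison statistics: sums-of-squares oracle, Dunnett
# cross-checks, Bonferroni contrasts.

test_that("one-way ANOVA F matches hand-computed sums of squares", {
  # worked example: {1,2,3} vs {4,5,6} -> SS_between 13.5, MS_within 1
  res <- oneWayAnova(c(1, 2, 3, 4, 5, 6), rep(c("a", "b"), each = 3))
  expect_equal(res$F, 13.5)
  expect_equal(c(res$df1, res$df2), c(1, 4))
  set.seed(41)
  for (i in 1:15) {
    g <- rep(letters[1:sample(2:4, 1)], times = sample(3:6, 1))
    v <- rnorm(length(g), mean = as.integer(factor(g)))
    expect_equal(oneWayAnova(v, g)$F, oracleAnovaF(v, g),
                 tolerance = 1e-10)
  }
})

test_that("degenerate constant groups are flagged with F = 0", {
  res <- oneWayAnova(rep(5, 6), rep(c("a", "b"), each = 3))
  expect_true(res$degenerate)
  expect_equal(res$F, 0)
})

test_that("Dunnett with a single treatment reduces to the pooled t test", {
  set.seed(43)
  v <- rnorm(12); g <- rep(c("ctl", "trt"), each = 6)
  d <- dunnettTest(v, g, "ctl", mcSamples = 2e5, seed = 1)
  tt <- t.test(v[g == "trt"], v[g == "ctl"], var.equal = TRUE)
  expect_equal(d$t, unname(tt$statistic), tolerance = 1e-10)
  expect_equal(d$pAdj, tt$p.value, tolerance = 0.02)
})

test_that("identical control and treatment samples give statistic 0, p near 1", {
  v <- c(1, 2, 3, 1, 2, 3, 4, 5, 6)
  g <- rep(c("ctl", "t1", "t2"), each = 3)
  d <- dunnettTest(v, g, "ctl", mcSamples = 5e4, seed = 2)
  expect_equal(d$estimate[d$comparison == "t1 - ctl"], 0)
  expect_equal(d$t[d$comparison == "t1 - ctl"], 0)
  expect_gt(d$pAdj[d$comparison == "t1 - ctl"], 0.95)
  expect_error(dunnettTest(c(1, 2, 3), c("a", "b", "c"), "a"), "degrees")
})

test_that("Dunnett adjusted p agrees with multcomp's single-step values", {
  skip_if_not_installed("multcomp")
  set.seed(47)
  v <- rnorm(20, rep(c(0, 0.5, 1, 0), each = 5))
  g <- factor(rep(c("ctl", "t1", "t2", "t3"), each = 5))
  g <- relevel(g, "ctl")
  d <- dunnettTest(v, g, "ctl", mcSamples = 2e5, seed = 3)
  fit <- multcomp::glht(stats::aov(v ~ g),
                        linfct = multcomp::mcp(g = "Dunnett"))
  ref <- summary(fit, test = multcomp::adjusted("single-step"))
  expect_equal(d$pAdj, as.numeric(ref$test$pvalues), tolerance = 0.02)
})

test_that("Dunnett Monte-Carlo critical values are stable under doubling", {
  c1 <- dunnettCritical(c(5, 5, 5), mcSamples = 2e5, seed = 1)$critical
  c2 <- dunnettCritical(c(5, 5, 5), mcSamples = 4e5, seed = 2)$critical
  expect_lt(abs(c1 - c2) / c1, 0.01)
})

test_that("two-way ANOVA detects no factor-B effect under the null", {
  set.seed(53)
  ps <- vapply(1:60, function(i) {
    a <- rep(c("wt", "mut"), each = 8)
    b <- rep(rep(c("ctl", "trt"), each = 4), 2)
    v <- rnorm(16) + ifelse(a == "wt", 0, 1)   # A effect only
    twoWayAnovaBonferroni(v, a, b)$anova$p[2]
  }, numeric(1))
  expect_gt(stats::ks.test(ps, "punif")$p.value, 0.01)
})

test_that("Bonferroni adjustment is the identity for one contrast and monotone", {
  set.seed(59)
  v <- rnorm(16); a <- rep(c("x", "y"), each = 8)
  b <- rep(rep(c("c", "t"), each = 4), 2)
  one <- twoWayAnovaBonferroni(v, a, b, contrasts = list(c("x:c", "x:t")))
  expect_equal(one$contrasts$pAdj, one$contrasts$pRaw)
  two <- twoWayAnovaBonferroni(v, a, b, contrasts = list(
    c("x:c", "x:t"), c("y:c", "y:t")))
  expect_equal(two$contrasts$pAdj,
               pmin(1, 2 * two$contrasts$pRaw))
  expect_true(all(two$contrasts$pAdj >= two$contrasts$pRaw))
  expect_error(twoWayAnovaBonferroni(rnorm(3), c("x", "x", "y"),
                                     c("c", "t", "c")), "empty cell")
})

test_that("significance tiers follow the *, **, *** convention", {
  expect_equal(significanceTier(c(0.04, 0.009, 0.0009, 0.2)),
               c("*", "**", "***", "ns"))
})

test_that("unbalanced designs use Type-II sums of squares", {
  set.seed(61)
  a <- c(rep("x", 9), rep("y", 8))
  b <- c(rep(c("c", "t"), c(5, 4)), rep(c("c", "t"), c(4, 4)))
  v <- rnorm(17)
  res <- twoWayAnovaBonferroni(v, a, b)
  expect_equal(res$type, "type-II")
  ref <- car::Anova(stats::lm(v ~ A * B,
                              data = data.frame(v = v, A = factor(a),
                                                B = factor(b))), type = 2)
  expect_equal(res$anova$F[1:3], ref[1:3, "F value"], tolerance = 1e-12)
})
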