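# Unpaired Student's t, summaries, stars, 2x2 combination analysis.

test_that("identical samples give t = 0, p = 1", {
  res <- studentsTTest(c(1, 2, 3), c(1, 2, 3))
  expect_identical(res$t_statistic, 0)
  expect_identical(res$p_value, 1)
  expect_identical(res$degrees_of_freedom, 4)
})

test_that("hand-computed pooled-variance example is reproduced", {
  # a = 1:4, b = 2:5: means 2.5/3.5, pooled var 5/3, se = sqrt(5/3 * 1/2),
  # t = -1/sqrt(5/6) = -1.095445, df = 6
  res <- studentsTTest(1:4, 2:5)
  expect_equal(res$t_statistic, -1.0954, tolerance = 1e-4)
  expect_identical(res$degrees_of_freedom, 6)
  expect_equal(res$t_statistic, -1 / sqrt(5 / 6), tolerance = 1e-12)
})

test_that("swapping groups negates t and preserves p", {
  set.seed(3)
  a <- rnorm(8); b <- rnorm(10, 0.5)
  r1 <- studentsTTest(a, b)
  r2 <- studentsTTest(b, a)
  expect_identical(r1$t_statistic, -r2$t_statistic)
  expect_identical(r1$p_value, r2$p_value)
})

test_that("t and p agree with stats::t.test to 1e-10 on random data", {
  set.seed(41)
  for (rep in 1:100) {
    na <- sample(3:20, 1); nb <- sample(3:20, 1)
    a <- rnorm(na, sd = runif(1, 0.5, 3))
    b <- rnorm(nb, mean = runif(1, -1, 1), sd = runif(1, 0.5, 3))
    mine <- studentsTTest(a, b)
    ref <- stats::t.test(a, b, var.equal = TRUE)
    expect_lt(abs(mine$t_statistic - unname(ref$statistic)), 1e-10)
    expect_lt(abs(mine$p_value - ref$p.value), 1e-10)
    expect_lt(abs(mine$degrees_of_freedom - unname(ref$parameter)), 1e-10)
    mineW <- studentsTTest(a, b, welch = TRUE)
    refW <- stats::t.test(a, b)
    expect_lt(abs(mineW$t_statistic - unname(refW$statistic)), 1e-10)
    expect_lt(abs(mineW$p_value - refW$p.value), 1e-10)
  }
})

test_that("null p-values are approximately uniform (type-I calibration)", {
  set.seed(99)
  p <- replicate(500, studentsTTest(rnorm(10), rnorm(10))$p_value)
  rate <- mean(p < 0.05)
  # binomial 3 sd around 0.05 at n = 500
  expect_lt(abs(rate - 0.05), 3 * sqrt(0.05 * 0.95 / 500))
})

test_that("degenerate zero-variance input follows the documented contract", {
  expect_identical(studentsTTest(c(2, 2, 2), c(2, 2))$p_value, 1)
  expect_error(studentsTTest(c(2, 2, 2), c(3, 3)), "zero pooled variance")
})

test_that("star mapping is pinned", {
  p <- c(0.2, 0.05, 0.049, 0.01, 0.0099, 0.001, 0.0009, NA)
  expect_identical(significanceStars(p),
                   c("ns", "ns", "*", "*", "**", "**", "***", NA))
})

test_that("group summaries compute n, mean and SEM with missing handling", {
  d <- data.frame(group_label = rep(c("A", "B", "C"), c(3, 3, 2)),
                  v = c(5, 5, 5, 1, 2, 3, NA, NA))
  s <- summarizeGroups(d, "v")
  expect_identical(s$mean[s$group == "A"], 5)
  expect_identical(s$sem[s$group == "A"], 0)
  expect_equal(s$sem[s$group == "B"], 1 / sqrt(3))
  expect_identical(s$n[s$group == "C"], 0L)
  expect_true(is.na(s$mean[s$group == "C"]))
  expect_identical(s$n_missing[s$group == "C"], 2L)
  expect_error(summarizeGroups(d, "nope"), "unknown metric")
})

test_that("single-observation groups have missing SEM", {
  d <- data.frame(group_label = c("A", "A", "B"), v = c(1, 3, 7))
  s <- summarizeGroups(d, "v")
  expect_true(is.na(s$sem[s$group == "B"]))
  expect_identical(s$mean[s$group == "B"], 7)
})

test_that("combination contrast: additive means give zero interaction", {
  d <- expand.grid(knockdown = c("NC", "si"), drug = c("vehicle", "afatinib"),
                   rep = 1:4, stringsAsFactors = FALSE)
  cellMean <- c("NC.vehicle" = 10, "NC.afatinib" = 6,
                "si.vehicle" = 6, "si.afatinib" = 2)
  noise <- rep(c(-0.3, -0.1, 0.1, 0.3), each = 4)
  d$y <- cellMean[paste(d$knockdown, d$drug, sep = ".")] + noise
  res <- combinationContrast(d, "y")
  expect_equal(res$interaction$estimate, 0)
  expect_identical(nrow(res$pairwise), 5L)
  combo <- res$pairwise[res$pairwise$group_a == "si+afatinib" &
                          res$pairwise$group_b == "NC+vehicle", ]
  expect_lt(combo$p_value, 0.001)
})

test_that("combination contrast: equal cells give p = 1 throughout", {
  d <- expand.grid(knockdown = c("NC", "si"), drug = c("vehicle", "afatinib"),
                   rep = 1:3, stringsAsFactors = FALSE)
  d$y <- rep(c(4, 4, 4), each = 4)
  res <- combinationContrast(d, "y")
  expect_true(all(res$pairwise$p_value == 1))
  expect_identical(res$interaction$estimate, 0)
})

test_that("combination contrast rejects incomplete designs", {
  d <- data.frame(knockdown = c("NC", "NC", "si", "si"),
                  drug = c("vehicle", "vehicle", "vehicle", "vehicle"),
                  y = 1:4)
  expect_error(combinationContrast(d, "y"), "two levels")
  d2 <- expand.grid(knockdown = c("NC", "si"), drug = c("vehicle", "afatinib"),
                    stringsAsFactors = FALSE)
  d2$y <- 1:4  # one observation per cell
  expect_error(combinationContrast(d2, "y"), ">= 2")
})

test_that("multiplicative combination effects are detected as interaction", {
  # multiplicative 0.6 x 0.6 on a positive metric is sub-additive on the
  # raw scale, so the additive-scale interaction is positive
  set.seed(5)
  d <- expand.grid(knockdown = c("NC", "si"), drug = c("vehicle", "afatinib"),
                   rep = 1:20, stringsAsFactors = FALSE)
  mult <- ifelse(d$knockdown == "si", 0.6, 1) *
    ifelse(d$drug == "afatinib", 0.6, 1)
  d$y <- 10 * mult + rnorm(nrow(d), sd = 0.5)
  res <- combinationContrast(d, "y")
  expect_gt(res$interaction$estimate, 0)
  combo <- res$pairwise[res$pairwise$group_a == "si+afatinib" &
                          res$pairwise$group_b == "NC+vehicle", ]
  expect_lt(combo$p_value, 0.05)
})
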