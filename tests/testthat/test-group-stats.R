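test_that("pooled t from summaries matches the textbook formula and its edge cases", {
  a <- group_summary(0.5, 0.1, 20)
  expect_equal(ttest_pooled(a, a)$t, 0)

  ## the two routes agree exactly, and swapping groups negates t
  set.seed(40)
  x <- rnorm(14); y <- rnorm(23, mean = 0.4)
  from_sum <- ttest_pooled(group_summary(mean(x), sd(x), 14),
                           group_summary(mean(y), sd(y), 23))
  from_raw <- ttest_from_samples(x, y)
  expect_equal(from_raw$t, from_sum$t, tolerance = 1e-12)
  expect_equal(from_raw$p, from_sum$p, tolerance = 1e-12)
  expect_equal(ttest_from_samples(y, x)$t, -from_raw$t, tolerance = 1e-12)
  ## cross-check against the stats package
  ref <- t.test(x, y, var.equal = TRUE)
  expect_equal(from_raw$t, unname(ref$statistic), tolerance = 1e-10)
  refw <- t.test(x, y)
  expect_equal(ttest_from_samples(x, y, welch = TRUE)$t,
               unname(refw$statistic), tolerance = 1e-10)
  expect_equal(ttest_from_samples(x, y, welch = TRUE)$df,
               unname(refw$parameter), tolerance = 1e-8)

  deg <- ttest_pooled(group_summary(1, 0, 5), group_summary(2, 0, 5))
  expect_true(deg$degenerate)
  expect_equal(deg$t, -Inf)
})

test_that("the pooled t-test is calibrated under the null", {
  set.seed(41)
  rej <- 0
  for (i in 1:10000) {
    tt <- ttest_from_samples(rnorm(15), rnorm(30))
    rej <- rej + (tt$p < 0.05)
  }
  expect_lt(abs(rej / 10000 - 0.05), 0.01)
})

test_that("Bonferroni adjustment caps, scales, and is monotone", {
  expect_equal(bonferroni(0.01, m = 5), 0.05)
  expect_equal(bonferroni(0.5, m = 4), 1)
  expect_equal(bonferroni(c(0.2, 0.7), m = 2), c(0.4, 1))
  p <- c(0.001, 0.01, 0.04)
  expect_equal(bonferroni(p, m = 3), p.adjust(p, "bonferroni"))
  expect_true(all(diff(bonferroni(sort(runif(5)), m = 5)) >= 0))
  expect_equal(bonferroni(0.3, m = 1), 0.3)
  expect_error(bonferroni(1.2), "0, 1")
  expect_error(bonferroni(c(0.1, 0.2), m = 1), "family size")
})

test_that("type-II ANOVA matches the classical equivalences", {
  set.seed(42)
  ## balanced one-factor design: type II equals classic one-way ANOVA
  d1 <- data.frame(y = rnorm(30), g = rep(letters[1:3], each = 10))
  ours <- anova_type2(d1, "y", "g")
  classic <- anova(aov(y ~ g, data = d1))
  expect_equal(ours$sum_sq[ours$term == "g"], classic["g", "Sum Sq"],
               tolerance = 1e-9)
  expect_equal(ours$statistic[ours$term == "g"], classic["g", "F value"],
               tolerance = 1e-9)

  ## balanced two-factor design: type II equals sequential type I
  d2 <- expand.grid(g = letters[1:3], h = LETTERS[1:2], rep = 1:5)
  d2$y <- rnorm(nrow(d2)) + as.integer(d2$g) * 0.5 + (d2$h == "B") * 0.7
  ours <- anova_type2(d2, "y", c("g", "h"))
  seq1 <- anova(lm(y ~ g * h, data = d2))
  for (term in c("g", "h", "g:h")) {
    expect_equal(ours$sum_sq[ours$term == term], seq1[term, "Sum Sq"],
                 tolerance = 1e-9)
  }

  ## residual row is present with the right df
  expect_equal(ours$df[ours$term == "Residual"], 30 - 6)
})

test_that("aliased terms are reported, not silently dropped", {
  set.seed(43)
  d <- expand.grid(montage = c("anodal", "cathodal"), time = c("during", "after"),
                   rep = 1:6)
  d$animal <- ifelse(d$montage == "anodal", "J", "Y")  # fully confounded
  d$y <- rnorm(nrow(d))
  out <- anova_type2(d, "y", c("montage", "time", "animal"))
  expect_true("animal" %in% out$term)
  expect_true(is.na(out$statistic[out$term == "animal"]))
  expect_false(is.na(out$statistic[out$term == "montage"]))

  ## constant response: zero sums of squares, no crash
  d$y <- 1
  flat <- anova_type2(d, "y", c("montage", "time"))
  expect_lt(max(flat$sum_sq[flat$term != "Residual"], na.rm = TRUE), 1e-20)
})
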