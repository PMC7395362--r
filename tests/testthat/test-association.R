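test_that("Wilcoxon comparison matches the enumerated exact p-value", {
  d <- data.frame(g = rep(c("A", "B"), each = 3), x = c(1, 2, 3, 4, 5, 6))
  gc <- compareGroups(d, "g", "x", test = "wilcoxon")
  expect_equal(gc$p.value, 0.1, tolerance = 1e-12)  # 2/20 assignments

  set.seed(17)
  for (n1 in 2:6) for (n2 in 2:6) {
    x <- rnorm(n1); y <- rnorm(n2)
    d <- data.frame(g = rep(c("A", "B"), c(n1, n2)), v = c(x, y))
    got <- compareGroups(d, "g", "v", test = "wilcoxon")$p.value
    expect_equal(got, exactWilcoxonP(x, y), tolerance = 1e-10,
                 info = sprintf("n1=%d n2=%d", n1, n2))
  }
})

test_that("identical groups give p at (or near) one", {
  d <- data.frame(g = rep(c("A", "B"), each = 4), x = rep(c(1, 2, 3, 4), 2))
  expect_gte(compareGroups(d, "g", "x", test = "wilcoxon")$p.value, 0.99)
  expect_gte(compareGroups(d, "g", "x", test = "t")$p.value, 0.99)
})

test_that("chi-square on a 2x2 table equals the closed-form statistic", {
  d <- data.frame(g = rep(c("A", "B"), c(50, 40)),
                  hit = c(rep(c(TRUE, FALSE), c(20, 30)),
                          rep(c(TRUE, FALSE), c(25, 15))))
  gc <- compareGroups(d, "g", "hit", test = "chisq")
  a <- 30; b <- 20; cc <- 15; dd <- 25  # table(g, hit) cell counts
  n <- a + b + cc + dd
  manual <- n * (a * dd - b * cc)^2 /
    ((a + b) * (cc + dd) * (a + cc) * (b + dd))
  expect_equal(gc$statistic, manual, tolerance = 1e-10)
  expect_equal(gc$p.value, pchisq(manual, 1, lower.tail = FALSE),
               tolerance = 1e-10)
})

test_that("Pearson r matches the direct covariance formula", {
  x <- c(1.2, 3.4, 2.2, 5.9, 4.1)
  y <- c(2.0, 3.1, 2.5, 6.2, 3.9)
  cm <- correlationMatrix(data.frame(x = x, y = y))
  manual <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(cm$r["x", "y"], manual, tolerance = 1e-10)
  # p from the exact t distribution of r
  tt <- manual * sqrt(3 / (1 - manual^2))
  expect_equal(cm$p["x", "y"], 2 * pt(-abs(tt), 3), tolerance = 1e-10)

  expect_equal(unname(diag(cm$r)), c(1, 1))
  exact <- correlationMatrix(data.frame(a = 1:4, b = -(1:4) * 2 + 7))
  expect_equal(exact$r["a", "b"], -1)
})

test_that("correlation matrix is symmetric, flags significance, keeps constants visible", {
  set.seed(23)
  d <- data.frame(a = rnorm(30), c = rep(5, 30))
  d$b <- d$a * 2 + rnorm(30, sd = 0.1)
  cm <- correlationMatrix(d)
  expect_identical(cm$r, t(cm$r))
  expect_identical(cm$flags["a", "b"], "**")
  expect_true(is.na(cm$r["a", "c"]))
  expect_identical(cm$flags["a", "c"], "NA")  # flagged, not dropped

  # Spearman is invariant under monotone transforms of either variable
  sm1 <- correlationMatrix(d[, c("a", "b")], method = "spearman")
  d2 <- data.frame(a = exp(d$a), b = d$b^3 + 10)
  sm2 <- correlationMatrix(d2, method = "spearman")
  expect_equal(sm1$r["a", "b"], sm2$r["a", "b"], tolerance = 1e-12)
})

test_that("generated covariate shifts are recovered by the group tests", {
  co <- generateCohort(cohortSpec(seed = 6))
  d <- co$covariates
  d$label <- truthLabels(co)[d$sample]
  gail <- compareGroups(d, "label", "gail", test = "t")
  expect_gt(gail$mean["Active"], gail$mean["Inactive"])
  # pairwise-complete: under-35 donors lack a Gail score but are analyzed
  # for other variables
  expect_lt(sum(gail$n), nrow(d))
  age <- compareGroups(d, "label", "age", test = "wilcoxon")
  expect_gt(age$mean["Active"], age$mean["Inactive"])
})

test_that("composition report finds the adipocyte skew of Active samples", {
  co <- generateCohort(smallSpec(seed = 51))
  rep1 <- compositionReport(co$covariates, truthLabels(co))
  adip <- rep1$table[rep1$table$compartment == "pct_adipocyte", ]
  expect_gt(adip$fold_change, 1)
  expect_lt(adip$p, 0.05)
  stromal <- rep1$table[rep1$table$compartment == "pct_stromal", ]
  expect_lt(stromal$fold_change, 1)
  expect_s3_class(rep1$plot, "ggplot")

  one <- setNames(rep("Active", nrow(co$covariates)), co$covariates$sample)
  expect_error(compositionReport(co$covariates, one), "both")
})
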