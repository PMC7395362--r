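test_that("quantile map reproduces the brute-force quantile oracle", {
  map <- fitQuantileMap(c(1, 2, 3), c(10, 20, 30))
  # grid {0, 0.5, 1}: source quantiles (1,2,3), target (10,20,30)
  expect_equal(map@sourceAnchors, c(1, 2, 3))
  expect_equal(map@targetAnchors, c(10, 20, 30))
  expect_equal(applyQuantileMap(map, c(1, 2, 3)), c(10, 20, 30))

  # source = target: applying the map is the identity (float tolerance)
  set.seed(1)
  v <- rexp(40, 1 / 10)
  self <- fitQuantileMap(v, v)
  expect_equal(applyQuantileMap(self, v), v, tolerance = 1e-12)

  # constant target: every nonzero source value maps to that constant
  const <- fitQuantileMap(c(1, 5, 9, 0), c(7, 7, 7))
  expect_equal(applyQuantileMap(const, c(0.5, 3, 100)), c(7, 7, 7))

  # all-zero source or target: identity sentinel
  expect_true(fitQuantileMap(c(0, 0), c(1, 2))@identity)
  expect_true(fitQuantileMap(c(1, 2), c(0, 0))@identity)
  expect_equal(applyQuantileMap(fitQuantileMap(c(0, 0), c(1, 2)),
                                c(3, 0, 5)), c(3, 0, 5))
})

test_that("zeros pass through and monotonicity is preserved", {
  set.seed(2)
  map <- fitQuantileMap(rexp(55, 1 / 5), rexp(96, 1 / 50))
  x <- c(0, 2, 0, 7, 1, 0, 40)
  y <- applyQuantileMap(map, x)
  expect_identical(which(y == 0), which(x == 0))
  mono <- sort(rexp(30, 1 / 5))
  expect_false(is.unsorted(applyQuantileMap(map, mono)))
  # out-of-range values clamp to the extreme target anchors
  expect_equal(applyQuantileMap(map, 1e6), max(map@targetAnchors))
  expect_equal(applyQuantileMap(map, 1e-9), min(map@targetAnchors))
})

test_that("mapped nonzero quantiles match the target within grid resolution", {
  set.seed(3)
  worst <- 0
  for (i in 1:200) {
    src <- rexp(55, 1 / runif(1, 1, 100))
    tgt <- rexp(96, 1 / runif(1, 1, 100))
    src[sample(55, 5)] <- 0
    tgt[sample(96, 8)] <- 0
    map <- fitQuantileMap(src, tgt)
    mapped <- applyQuantileMap(map, src)
    mapped_nz <- mapped[src != 0]
    tgt_nz <- tgt[tgt != 0]
    L <- min(length(mapped_nz), length(tgt_nz))
    probs <- seq(0, 1, length.out = L)
    # brute-force oracle bound: the largest gap between adjacent target
    # anchors is the resolution limit of the grid
    bound <- max(diff(unname(quantile(tgt_nz, probs, type = 7)))) + 1e-8
    d <- max(abs(quantile(mapped_nz, probs, type = 7) -
                   quantile(tgt_nz, probs, type = 7)))
    worst <- max(worst, d / bound)
    expect_lte(d, bound)
  }
  expect_lte(worst, 1)
})

test_that("tied source values map to identical outputs", {
  map <- fitQuantileMap(c(2, 2, 2, 5, 8), c(1, 2, 3, 4, 5))
  out <- applyQuantileMap(map, c(2, 2, 5))
  expect_equal(out[1], out[2])
  expect_false(is.unsorted(out))
})

test_that("batch integration preserves target values, zeros, and is idempotent", {
  co <- generateCohort(smallSpec(seed = 41))
  m <- co$expression
  int <- integrateBatches(m, "F")
  tgt <- batchLabels(m) == "F"
  expect_identical(exprValues(int)[, tgt], exprValues(m)[, tgt])
  expect_identical(exprValues(int) == 0, exprValues(m) == 0)
  twice <- integrateBatches(int, "F")
  expect_equal(exprValues(twice), exprValues(int), tolerance = 1e-10)

  single <- m[, tgt]
  expect_error(integrateBatches(single, "F"), "exactly two batches")
  expect_error(integrateBatches(m, "X"), "not present")
  three <- ExpressionExperiment(exprValues(m),
                                batch = rep(c("A", "B", "C"), length.out = ncol(m)))
  expect_error(integrateBatches(three, "A"), "exactly two batches")
})

test_that("per-gene mapping is monotone across the whole matrix", {
  co <- generateCohort(smallSpec(seed = 42))
  m <- co$expression
  int <- integrateBatches(m, "F")
  src <- batchLabels(m) != "F"
  before <- exprValues(m)[, src, drop = FALSE]
  after <- exprValues(int)[, src, drop = FALSE]
  for (g in sample(rownames(before), 25)) {
    ord <- order(before[g, ])
    expect_false(is.unsorted(after[g, ord]))
  }
})
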