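test_that("log2 median centering has the closed-form behaviour", {
  m <- toyExpr(matrix(c(1, 3, 7, 0, 0, 0), nrow = 2, byrow = TRUE,
                      dimnames = list(c("g1", "zero"),
                                      c("s1", "s2", "s3"))))
  norm <- normalizeLog2MedianCenter(m)
  # TPM (1,3,7) -> log2 (1,2,3) -> centered (-1,0,1)
  expect_equal(unname(exprValues(norm)["g1", ]), c(-1, 0, 1))
  expect_equal(unname(exprValues(norm)["zero", ]), c(0, 0, 0))
  expect_identical(exprScale(norm), "log2_median_centered")
  expect_error(normalizeLog2MedianCenter(norm), "TPM scale")
})

test_that("every gene's median is zero after centering, per batch", {
  set.seed(42)
  v <- matrix(rexp(200, 1 / 50), nrow = 20,
              dimnames = list(sprintf("g%02d", 1:20),
                              sprintf("s%02d", 1:10)))
  batch <- setNames(rep(c("F", "P"), each = 5), colnames(v))
  m <- ExpressionExperiment(v, batch = batch)
  norm <- normalizeLog2MedianCenter(m, by_batch = TRUE)
  for (b in c("F", "P")) {
    med <- apply(exprValues(norm)[, batchLabels(norm) == b], 1, median)
    expect_equal(unname(med), rep(0, 20))
  }
  all_med <- apply(exprValues(normalizeLog2MedianCenter(m, by_batch = FALSE)),
                   1, median)
  expect_equal(unname(all_med), rep(0, 20))
})

test_that("IQR gate matches a brute-force percentile oracle", {
  v <- rbind(flat = rep(0, 4),
             spread = c(-1.5, -0.5, 0.5, 1.5),
             narrow = c(-0.3, -0.1, 0.1, 0.3))
  colnames(v) <- paste0("s", 1:4)
  m <- ExpressionExperiment(v, batch = rep("F", 4),
                            scale = "log2_median_centered")
  # oracle: type-7 quantiles by hand, q(p) = x_(j) + g*(x_(j+1)-x_(j))
  oracle_iqr <- function(x) {
    x <- sort(x); n <- length(x)
    q <- function(p) { h <- (n - 1) * p + 1
      x[floor(h)] + (h - floor(h)) * (x[ceiling(h)] - x[floor(h)]) }
    q(0.75) - q(0.25)
  }
  expect_equal(unname(oracle_iqr(v["spread", ])), 1.5)
  sel <- selectVariableGenes(m, rownames(v), iqr_threshold = 0.8)
  expect_identical(sel, "spread")
  # constant gene always excluded, even at threshold zero it is not > 0
  expect_false("flat" %in% selectVariableGenes(m, rownames(v), 0))
  expect_error(selectVariableGenes(m, c("nope1", "nope2")), "none found")
})

test_that("signature score matches the printed closed forms exactly", {
  s_ab <- geneSignature("s", up = "A", down = "B")
  expect_equal(signatureScore(c(A = 3, B = 1), s_ab), 0.5,
               tolerance = 1e-12)
  expect_equal(signatureScore(c(A = 0, B = 0), s_ab), 0, tolerance = 1e-12)
  s_abc <- geneSignature("s", up = c("A", "B"), down = "C")
  expect_equal(signatureScore(c(A = 7, B = 0, C = 3), s_abc), 1 / 3,
               tolerance = 1e-12)
})

test_that("signature score invariances and the global-shift property hold", {
  set.seed(7)
  for (i in 1:20) {
    nu <- sample(1:5, 1); nd <- sample(1:5, 1)
    genes <- sprintf("g%d", seq_len(nu + nd))
    sig <- geneSignature("s", up = genes[seq_len(nu)],
                         down = genes[nu + seq_len(nd)])
    tpm <- setNames(rexp(nu + nd, 1 / 20), genes)
    s0 <- signatureScore(tpm, sig)
    # gene order is irrelevant
    expect_equal(signatureScore(sample(tpm), sig), s0)
    # doubling every TPM+1 shifts the score by (|U|-|D|)/(|U|+|D|)
    shifted <- 2 * (tpm + 1) - 1
    expect_equal(signatureScore(shifted, sig),
                 s0 + (nu - nd) / (nu + nd), tolerance = 1e-10)
  }
  # genes absent from the data drop out of sums and denominator
  sig <- geneSignature("s", up = c("A", "GHOST"), down = "B")
  expect_equal(signatureScore(c(A = 3, B = 1), sig), 0.5)
  expect_error(signatureScore(c(X = 1), sig), "no signature gene")
})

test_that("clustering splits a planted two-group cohort and is order-invariant", {
  co <- generateCohort(cohortSpec(n_samples = c(F = 60L), delta = 2,
                                  active_fraction = c(F = 0.5),
                                  zero_inflation = c(F = 0.05),
                                  n_background = 100L, seed = 5))
  norm <- normalizeLog2MedianCenter(co$expression)
  genes <- selectVariableGenes(norm, co$classifier)
  cl <- clusterPhenotypes(norm, genes)
  truth <- truthLabels(co)
  pred <- setNames(ifelse(names(truth) %in% cl[[1]], "A", "B"),
                   names(truth))
  agree <- mean((pred == "A") == (truth == "Active"))
  expect_gte(max(agree, 1 - agree), 0.95)

  perm <- sample(ncol(norm))
  cl_perm <- clusterPhenotypes(norm[, perm], genes)
  expect_identical(cl, cl_perm)
})

test_that("duplicating samples keeps the bipartition of the originals", {
  set.seed(9)
  v <- cbind(matrix(rnorm(40, 0), 10), matrix(rnorm(40, 3), 10))
  dimnames(v) <- list(paste0("g", 1:10), paste0("s", 1:8))
  m <- ExpressionExperiment(v, batch = rep("F", 8),
                            scale = "log2_median_centered")
  dup <- cbind(v, v + 1e-9)  # near-duplicates with distinct names
  colnames(dup) <- c(colnames(v), paste0(colnames(v), "bis"))
  mdup <- ExpressionExperiment(dup, batch = rep("F", 16),
                               scale = "log2_median_centered")
  cl <- clusterPhenotypes(m, rownames(v))
  cl_dup <- clusterPhenotypes(mdup, rownames(v))
  originals <- lapply(cl_dup, function(s) sort(intersect(s, colnames(v))))
  expect_setequal(originals[[1]], cl[[1]])
  expect_setequal(originals[[2]], cl[[2]])
})

test_that("clustering rejects degenerate input", {
  m <- toyExpr()
  expect_error(clusterPhenotypes(m, c("G1", "G2")), "at least 4 samples")
  same <- matrix(1, 4, 5, dimnames = list(paste0("g", 1:4), paste0("s", 1:5)))
  ms <- ExpressionExperiment(same, batch = rep("F", 5),
                             scale = "log2_median_centered")
  expect_error(clusterPhenotypes(ms, paste0("g", 1:4)), "degenerate")
})

test_that("label assignment follows the higher mean classifier score", {
  v <- rbind(UP = c(8, 9, 1, 2), DN = c(1, 2, 8, 9))
  colnames(v) <- paste0("s", 1:4)
  m <- ExpressionExperiment(v, batch = rep("F", 4))
  sig <- geneSignature("cls", up = "UP", down = "DN")
  cl <- list(c("s1", "s2"), c("s3", "s4"))
  asg <- assignLabels(cl, m, sig)
  expect_identical(asg$label, c("Active", "Active", "Inactive", "Inactive"))
  # swapping cluster input order changes nothing but the cluster ids
  asg2 <- assignLabels(rev(cl), m, sig)
  expect_identical(asg2$label, asg$label)
  # forced invariant: mean score of Active exceeds mean score of Inactive
  expect_gt(mean(asg$score[asg$label == "Active"]),
            mean(asg$score[asg$label == "Inactive"]))
  # exactly tied means must error, never silently pick a side
  v_tie <- rbind(UP = c(5, 1, 5, 1), DN = c(1, 5, 1, 5))
  colnames(v_tie) <- paste0("s", 1:4)
  m_tie <- ExpressionExperiment(v_tie, batch = rep("F", 4))
  expect_error(assignLabels(list(c("s1", "s2"), c("s3", "s4")), m_tie, sig),
               "tied")
})

test_that("differential genes recover planted signal and stay quiet on null", {
  co <- generateCohort(smallSpec(seed = 31, n_samples = c(F = 40L),
                                 active_fraction = c(F = 0.5),
                                 zero_inflation = c(F = 0.05)))
  truth <- truthLabels(co)
  dg <- diffGenes(co$expression, truth)
  planted <- c(sigUp(co$classifier), sigDown(co$classifier))
  expect_gte(mean(planted %in% dg), 0.99)

  # identical expression in every sample -> nothing is significant
  flat <- ExpressionExperiment(
    matrix(5, 10, 8, dimnames = list(paste0("g", 1:10), paste0("s", 1:8))),
    batch = rep("F", 8))
  labels <- setNames(rep(c("Active", "Inactive"), each = 4), paste0("s", 1:8))
  expect_identical(diffGenes(flat, labels), character(0))

  expect_error(diffGenes(co$expression, truth[1:4]), "at least 3")
})
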