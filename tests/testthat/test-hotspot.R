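# a hand-built 10-record table: 2 clean records plus 8 records each
# violating exactly one filter criterion
.manual_calls <- function() {
  base <- data.frame(
    sample = sprintf("s%02d", 1:10), batch = "F",
    gene = "TP53", contig = "chr17", position = 7578406L,
    ref = "G", alt = "A",
    likelihood = 10, ref_depth = 90L, alt_depth = 10L, af = 0.10,
    aa_change = "R175H", consequence = "missense_variant",
    stringsAsFactors = FALSE)
  base$likelihood[3] <- 4.9          # below likelihood threshold
  base$af[4] <- 0.019                # AF below lower bound
  base$af[5] <- 0.41                 # AF above upper bound
  base$alt_depth[6] <- 1L            # AD below threshold
  base$consequence[7] <- "synonymous_variant"
  base$aa_change[8] <- "A1V"         # absent from the AA-keyed list
  base$position[9] <- 1L             # absent from the locus-keyed list
  base$consequence[10] <- "intergenic_region"  # not predicted non-silent
  validateVariantCalls(base, tol = 1)
}

.manual_lists <- function() {
  list(hotspotList("AA-keyed", data.frame(gene = "TP53",
                                          aa_change = "R175H")),
       hotspotList("locus-keyed",
                   data.frame(gene = "TP53", contig = "chr17",
                              position = 7578406L, ref = "G", alt = "A")))
}

test_that("filter keeps exactly the records passing every criterion", {
  calls <- .manual_calls()
  kept <- filterVariants(calls, .manual_lists())
  expect_identical(kept$sample, c("s01", "s02"))
  expect_identical(filterVariants(calls[0, ], .manual_lists())$sample,
                   character(0))
})

test_that("all printed bounds are inclusive", {
  boundary <- .manual_calls()[1, ]
  boundary$likelihood <- 5
  boundary$af <- 0.02
  boundary$alt_depth <- 2L
  expect_identical(nrow(filterVariants(boundary, .manual_lists())), 1L)
  boundary$af <- 0.40
  expect_identical(nrow(filterVariants(boundary, .manual_lists())), 1L)
  boundary$af <- 0.45
  expect_identical(nrow(filterVariants(boundary, .manual_lists())), 0L)
})

test_that("filtering is a stable, idempotent subset and monotone in thresholds", {
  fx <- generateVariantFixture(300, seed = 8)
  kept <- filterVariants(fx$calls, fx$hotspots)
  expect_true(all(rownames(kept) %in% rownames(fx$calls)))
  expect_identical(kept$sample, fx$calls$sample[fx$pass])  # input order
  expect_identical(filterVariants(kept, fx$hotspots), kept)

  n0 <- nrow(kept)
  expect_gte(nrow(filterVariants(fx$calls, fx$hotspots,
                                 likelihood_min = 0)), n0)
  expect_gte(nrow(filterVariants(fx$calls, fx$hotspots,
                                 af_range = c(0, 1))), n0)
  expect_gte(nrow(filterVariants(fx$calls, fx$hotspots, ad_min = 0)), n0)
  expect_gte(nrow(filterVariants(fx$calls, list())), n0)
})

test_that("consequence keyword table classifies silent vs non-silent", {
  expect_identical(
    isSilentConsequence(c("missense_variant", "synonymous_variant",
                          "frameshift_insertion", "Splice_Site",
                          "mystery_annotation")),
    c(FALSE, TRUE, FALSE, FALSE, NA))
  # the keyword tables are config: a custom silent term
  expect_true(isSilentConsequence("benign_change",
                                  silent_keywords = "benign"))
})

test_that("burden counts every cohort sample, zero-filled", {
  expect_identical(burdenPerSample(data.frame(sample = character(0)),
                                   c("a", "b", "c")),
                   c(a = 0L, b = 0L, c = 0L))
  filtered <- data.frame(sample = c("b", "b", "b"))
  expect_identical(burdenPerSample(filtered, c("a", "b")),
                   c(a = 0L, b = 3L))

  co <- generateCohort(smallSpec(seed = 13))
  kept <- filterVariants(co$variants, co$hotspots)
  b <- burdenPerSample(kept, co$covariates$sample)
  expect_identical(b, co$truth$burden[names(b)])
})

test_that("burden association handles perfect, constant and generated cases", {
  cov <- data.frame(sample = paste0("s", 1:6), x = c(3, 1, 4, 1, 5, 9))
  burden <- setNames(rank(cov$x), cov$sample)  # identical ranks
  ba <- burdenAssociation(burden, cov, "x")
  expect_equal(ba$rho, 1)

  const <- setNames(rep(2, 6), cov$sample)
  ba0 <- burdenAssociation(const, cov, "x")
  expect_true(is.na(ba0$rho) && is.na(ba0$p))

  expect_error(burdenAssociation(burden[1:2], cov[1:2, ], "x"),
               "fewer than 3")

  co <- generateCohort(smallSpec(seed = 14))
  b <- burdenPerSample(filterVariants(co$variants, co$hotspots),
                       co$covariates$sample)
  expect_gt(burdenAssociation(b, co$covariates, "pct_adipocyte")$rho, 0)
})

test_that("burden is phenotype-independent when composition is equalized", {
  # composition identical across phenotypes => burden carries no phenotype
  # signal; Wilcoxon p-values should behave like a uniform draw
  ps <- sapply(1:6, function(s) {
    co <- generateCohort(smallSpec(
      seed = 100 + s,
      composition = list(Active = c(10, 6, 4), Inactive = c(10, 6, 4))))
    b <- burdenPerSample(filterVariants(co$variants, co$hotspots),
                         co$covariates$sample)
    d <- data.frame(burden = unname(b),
                    label = truthLabels(co)[names(b)])
    compareGroups(d, "label", "burden", test = "wilcoxon")$p.value
  })
  expect_gt(median(ps), 0.05)
  expect_gt(max(ps), 0.2)
})
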