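#' Default synthetic cohort specification
#'
#' Builds the parameter list driving [generateCohort()]. The defaults emulate
#' the structure of a two-batch normal-breast RNA-seq study: 96 samples in an
#' FFPE-processed batch `F` and 55 in a PAXgene batch `P`; roughly half of
#' each batch carrying a latent *Active* phenotype (47/96 and 31/55); a
#' classifier signature of 60 upregulated and 60 downregulated genes shifted
#' by `delta` log2 units in *Active* samples over 880 background genes; a
#' monotone per-gene affine distortion plus extra zero inflation applied to
#' batch `P`; a tissue-composition model skewing *Active* samples toward
#' adipocytes; covariate shifts (higher Gail score and age for *Active*, BMI
#' phenotype-independent); and a variant model whose per-sample hotspot
#' burden rate increases with adipocyte fraction.
#'
#' @param n_samples named integer vector, samples per batch.
#' @param active_fraction named numeric vector in (0, 1), per-batch fraction
#'   of *Active* samples.
#' @param n_signature_up,n_signature_down,n_background gene counts.
#' @param delta log2-unit mean shift of up-genes in *Active* samples (down
#'   genes shift by `-delta`); `delta = 0` gives a null cohort.
#' @param mu_range,sigma_range per-gene baseline log2 mean and sd ranges.
#' @param distort_batch batch receiving the affine log2 distortion.
#' @param slope_range,shift_range distortion slope and intercept ranges.
#' @param zero_inflation named numeric vector, per-batch probability that an
#'   entry is zeroed.
#' @param composition list of Dirichlet concentrations
#'   (adipocyte, stromal, epithelial) per phenotype.
#' @param gail_mean,gail_sd,age_mean,age_sd,bmi_mean,bmi_sd covariate model;
#'   `gail_mean`/`age_mean` are named by phenotype.
#' @param variant_rate_base,variant_rate_adip per-sample burden is
#'   Poisson(`variant_rate_base` + `variant_rate_adip` * adipocyte fraction).
#' @param af_shape Beta shape parameters for variant allele frequency.
#' @param ad_mean variant allele depth is 2 + Poisson(`ad_mean`).
#' @param fail_fraction extra non-passing variant records generated per
#'   passing record.
#' @param seed integer random seed; all outputs are bit-reproducible for a
#'   fixed seed.
#' @return a validated list of class `CohortSpec`.
#' @export
cohortSpec <- function(n_samples = c(F = 96L, P = 55L),
                       active_fraction = c(F = 47 / 96, P = 31 / 55),
                       n_signature_up = 60L, n_signature_down = 60L,
                       n_background = 880L,
                       delta = 2,
                       mu_range = c(2, 8), sigma_range = c(0.3, 0.9),
                       distort_batch = "P",
                       slope_range = c(0.8, 1.2), shift_range = c(-1, 1),
                       zero_inflation = c(F = 0.05, P = 0.10),
                       composition = list(Active = c(16, 3, 1),
                                          Inactive = c(10, 6, 4)),
                       gail_mean = c(Active = 1.46, Inactive = 1.18),
                       gail_sd = 1,
                       age_mean = c(Active = 47, Inactive = 42), age_sd = 8,
                       bmi_mean = 29.6, bmi_sd = 5,
                       variant_rate_base = 0.5, variant_rate_adip = 4,
                       af_shape = c(2, 20), ad_mean = 6,
                       fail_fraction = 0.3,
                       seed = 1L) {
  spec <- list(n_samples = n_samples, active_fraction = active_fraction,
               n_signature_up = as.integer(n_signature_up),
               n_signature_down = as.integer(n_signature_down),
               n_background = as.integer(n_background),
               delta = delta, mu_range = mu_range, sigma_range = sigma_range,
               distort_batch = distort_batch, slope_range = slope_range,
               shift_range = shift_range, zero_inflation = zero_inflation,
               composition = composition,
               gail_mean = gail_mean, gail_sd = gail_sd,
               age_mean = age_mean, age_sd = age_sd,
               bmi_mean = bmi_mean, bmi_sd = bmi_sd,
               variant_rate_base = variant_rate_base,
               variant_rate_adip = variant_rate_adip,
               af_shape = af_shape, ad_mean = ad_mean,
               fail_fraction = fail_fraction,
               seed = as.integer(seed))
  class(spec) <- "CohortSpec"
  validateCohortSpec(spec)
  spec
}

#' Validate a cohort specification
#'
#' @param spec a `CohortSpec` list (see [cohortSpec()]).
#' @return `spec`, invisibly, or an error before any sampling happens.
#' @export
validateCohortSpec <- function(spec) {
  if (any(spec$n_samples < 1))
    stop("n_samples must be positive")
  if (is.null(names(spec$n_samples)) || anyDuplicated(names(spec$n_samples)))
    stop("n_samples must be uniquely named by batch")
  if (any(spec$active_fraction <= 0) || any(spec$active_fraction >= 1))
    stop("active_fraction must lie strictly in (0, 1)")
  if (!setequal(names(spec$active_fraction), names(spec$n_samples)))
    stop("active_fraction must be named by the same batches as n_samples")
  if (spec$delta < 0)
    stop("delta must be >= 0")
  if (spec$n_signature_up < 1 || spec$n_signature_down < 1 ||
      spec$n_background < 0)
    stop("gene counts must be positive (background may be zero)")
  if (any(spec$zero_inflation < 0) || any(spec$zero_inflation >= 1))
    stop("zero_inflation must lie in [0, 1)")
  if (spec$fail_fraction < 0)
    stop("fail_fraction must be >= 0")
  invisible(spec)
}

# small curated pool of recurrent cancer-gene hotspots used by the generator;
# TP53 entries dominate, mirroring its reported predominance in normal tissue
.hotspot_pool <- function() {
  data.frame(
    gene = c("TP53", "TP53", "TP53", "TP53", "TP53", "TP53",
             "PIK3CA", "PIK3CA", "PIK3CA", "EGFR", "EGFR",
             "KRAS", "KRAS", "BRAF", "AKT1", "ERBB2", "GATA3", "IDH1"),
    aa_change = c("R175H", "R248Q", "R273H", "R282W", "G245S", "Y220C",
                  "E545K", "H1047R", "E542K", "L858R", "T790M",
                  "G12D", "G13D", "V600E", "E17K", "V777L", "M294K", "R132H"),
    contig = c(rep("chr17", 6), rep("chr3", 3), rep("chr7", 2),
               rep("chr12", 2), "chr7", "chr14", "chr17", "chr10", "chr2"),
    position = c(7578406L, 7577538L, 7577120L, 7577094L, 7577548L, 7578190L,
                 178936091L, 178952085L, 178936082L, 55259515L, 55249071L,
                 25398284L, 25398281L, 140453136L, 105246551L, 37880220L,
                 8111563L, 209113112L),
    ref = c("G", "C", "G", "G", "C", "A", "G", "A", "G", "T", "C",
            "C", "C", "A", "G", "G", "T", "C"),
    alt = c("A", "T", "A", "A", "T", "G", "A", "G", "A", "G", "T",
            "T", "T", "T", "A", "T", "A", "T"),
    stringsAsFactors = FALSE)
}

.cohort_hotspot_lists <- function() {
  pool <- .hotspot_pool()
  msk <- pool
  msk$contig <- msk$position <- msk$ref <- msk$alt <- NULL
  gtex <- pool
  gtex$aa_change <- NULL
  list(msk = hotspotList("MSK-IMPACT", msk),
       gtex = hotspotList("GTEx-expressed", gtex))
}

.rdirichlet1 <- function(alpha) {
  g <- stats::rgamma(length(alpha), shape = alpha, rate = 1)
  g / sum(g)
}

# one passing-grade variant record per row of idx into the hotspot pool
.make_pass_calls <- function(samples, batches, idx, spec) {
  pool <- .hotspot_pool()
  n <- length(idx)
  af <- pmin(0.40, pmax(0.02, stats::rbeta(n, spec$af_shape[1], spec$af_shape[2])))
  ad <- 2L + stats::rpois(n, spec$ad_mean)
  data.frame(sample = samples, batch = batches,
             gene = pool$gene[idx], contig = pool$contig[idx],
             position = pool$position[idx], ref = pool$ref[idx],
             alt = pool$alt[idx],
             likelihood = 5 + stats::rgamma(n, shape = 2, scale = 3),
             ref_depth = as.integer(round(ad * (1 - af) / af)),
             alt_depth = ad, af = af,
             aa_change = pool$aa_change[idx],
             consequence = rep("missense_variant", n),
             stringsAsFactors = FALSE)
}

.VIOLATIONS <- c("likelihood", "af_low", "af_high", "ad", "silent",
                 "not_in_msk", "not_in_gtex")

.break_one_criterion <- function(calls, kinds) {
  for (i in seq_len(nrow(calls))) {
    switch(kinds[i],
      likelihood = { calls$likelihood[i] <- stats::runif(1, 0, 4.9) },
      af_low = {
        calls$af[i] <- stats::runif(1, 0.001, 0.019)
        calls$ref_depth[i] <- as.integer(
          round(calls$alt_depth[i] * (1 - calls$af[i]) / calls$af[i]))
      },
      af_high = {
        calls$af[i] <- stats::runif(1, 0.41, 0.60)
        calls$ref_depth[i] <- as.integer(
          round(calls$alt_depth[i] * (1 - calls$af[i]) / calls$af[i]))
      },
      ad = {
        calls$alt_depth[i] <- 1L
        calls$ref_depth[i] <- as.integer(
          round((1 - calls$af[i]) / calls$af[i]))
      },
      silent = { calls$consequence[i] <- "synonymous_variant" },
      not_in_msk = {
        # break the AA key (MSK is AA-keyed); the locus key still matches GTEx
        calls$aa_change[i] <- "A1V"
      },
      not_in_gtex = {
        # break the locus key (GTEx is locus-keyed); the AA key still matches
        calls$position[i] <- 999999999L
      })
  }
  calls
}

#' Generate a synthetic two-batch cohort
#'
#' Draws a full cohort — TPM expression, covariates, variant calls — with the
#' statistical structure described in [cohortSpec()], and returns the ground
#' truth (phenotype labels, variant pass flags, burden) separately from the
#' data. Expression is generated per gene in log2 space (Gaussian), shifted
#' by `delta` on signature genes in *Active* samples, affinely distorted in
#' the `distort_batch`, back-transformed to TPM and zero-inflated.
#'
#' @param spec a [cohortSpec()] list; `spec$seed` fixes all randomness.
#' @return list with elements
#'   \describe{
#'     \item{expression}{[ExpressionExperiment-class], TPM scale}
#'     \item{covariates}{per-sample covariate data.frame}
#'     \item{variants}{variant-call data.frame (passing and failing records)}
#'     \item{classifier}{the planted [GeneSignature-class]}
#'     \item{hotspots}{list of the two [HotspotList-class] catalogues}
#'     \item{truth}{list: `phenotype` (sample/batch/phenotype data.frame),
#'       `variant_pass` (logical per variant row), `burden` (named integer
#'       per sample), `adipocyte_fraction` (named numeric per sample)}
#'   }
#' @examples
#' cohort <- generateCohort(cohortSpec(n_samples = c(F = 12L, P = 8L),
#'                                     n_background = 40L, seed = 7L))
#' dim(exprValues(cohort$expression))
#' @export
generateCohort <- function(spec = cohortSpec()) {
  validateCohortSpec(spec)
  set.seed(spec$seed)

  genes <- c(sprintf("UP%03d", seq_len(spec$n_signature_up)),
             sprintf("DN%03d", seq_len(spec$n_signature_down)),
             if (spec$n_background > 0)
               sprintf("BG%03d", seq_len(spec$n_background)))
  up <- grep("^UP", genes, value = TRUE)
  dn <- grep("^DN", genes, value = TRUE)
  G <- length(genes)

  batches <- names(spec$n_samples)
  sample_ids <- unlist(lapply(batches, function(b)
    sprintf("%s%03d", b, seq_len(spec$n_samples[[b]]))), use.names = FALSE)
  batch_of <- rep(batches, spec$n_samples)
  names(batch_of) <- sample_ids

  phenotype <- unlist(lapply(batches, function(b) {
    n <- spec$n_samples[[b]]
    na <- round(spec$active_fraction[[b]] * n)
    sample(rep(c("Active", "Inactive"), c(na, n - na)))
  }), use.names = FALSE)
  names(phenotype) <- sample_ids

  mu <- stats::runif(G, spec$mu_range[1], spec$mu_range[2])
  sig <- stats::runif(G, spec$sigma_range[1], spec$sigma_range[2])
  slope <- stats::runif(G, spec$slope_range[1], spec$slope_range[2])
  shift <- stats::runif(G, spec$shift_range[1], spec$shift_range[2])

  x <- matrix(stats::rnorm(G * length(sample_ids), mean = mu, sd = sig),
              nrow = G, dimnames = list(genes, sample_ids))
  act <- phenotype == "Active"
  x[up, act] <- x[up, act] + spec$delta
  x[dn, act] <- x[dn, act] - spec$delta
  in_dist <- batch_of == spec$distort_batch
  if (any(in_dist))
    x[, in_dist] <- slope * x[, in_dist] + shift

  tpm <- pmax(2^x - 1, 0)
  for (b in batches) {
    cols <- batch_of == b
    zi <- spec$zero_inflation[[b]]
    if (zi > 0) {
      mask <- matrix(stats::runif(G * sum(cols)) < zi, nrow = G)
      tpm[, cols][mask] <- 0
    }
  }
  expression <- ExpressionExperiment(tpm, batch = batch_of, scale = "tpm")

  comp <- t(vapply(phenotype, function(ph)
    .rdirichlet1(spec$composition[[ph]]), numeric(3)))
  colnames(comp) <- c("adipocyte", "stromal", "epithelial")

  n <- length(sample_ids)
  age <- pmin(66, pmax(27, round(stats::rnorm(n, spec$age_mean[phenotype],
                                              spec$age_sd))))
  bmi <- round(pmax(17, stats::rnorm(n, spec$bmi_mean, spec$bmi_sd)), 1)
  gail <- round(pmax(0.1, stats::rnorm(n, spec$gail_mean[phenotype],
                                       spec$gail_sd)), 2)
  gail[age < 35] <- NA  # risk tool not applicable below age 35
  covariates <- data.frame(
    sample = sample_ids, batch = unname(batch_of),
    age = age, bmi = bmi, gail = gail,
    parity = 1L + stats::rpois(n, 1.1),
    family_history = stats::runif(n) < 0.25,
    pct_adipocyte = round(100 * comp[, "adipocyte"], 1),
    pct_stromal = round(100 * comp[, "stromal"], 1),
    pct_epithelial = round(100 * comp[, "epithelial"], 1),
    tdlu_count = stats::rpois(n, 2 + 0.3 * 100 * comp[, "epithelial"]),
    adipocyte_area = round(pmax(500, 2000 + 80 * bmi +
                                  stats::rnorm(n, 0, 800))),
    stringsAsFactors = FALSE, row.names = NULL)
  validateCovariates(covariates)

  adip <- comp[, "adipocyte"]
  burden <- stats::rpois(n, spec$variant_rate_base +
                           spec$variant_rate_adip * adip)
  names(burden) <- sample_ids
  pool_n <- nrow(.hotspot_pool())
  pass_samples <- rep(sample_ids, burden)
  pass <- .make_pass_calls(pass_samples, batch_of[pass_samples],
                           sample(pool_n, sum(burden), replace = TRUE), spec)
  n_fail <- round(spec$fail_fraction * nrow(pass))
  if (n_fail > 0) {
    fail_samples <- sample(sample_ids, n_fail, replace = TRUE)
    fail <- .make_pass_calls(fail_samples, batch_of[fail_samples],
                             sample(pool_n, n_fail, replace = TRUE), spec)
    fail <- .break_one_criterion(
      fail, sample(.VIOLATIONS, n_fail, replace = TRUE))
    variants <- rbind(pass, fail)
    variant_pass <- rep(c(TRUE, FALSE), c(nrow(pass), n_fail))
  } else {
    variants <- pass
    variant_pass <- rep(TRUE, nrow(pass))
  }
  ord <- order(variants$sample)
  variants <- validateVariantCalls(variants[ord, , drop = FALSE])
  rownames(variants) <- NULL
  variant_pass <- variant_pass[ord]

  list(expression = expression,
       covariates = covariates,
       variants = variants,
       classifier = geneSignature("ActiveInactive", up = up, down = dn),
       hotspots = .cohort_hotspot_lists(),
       truth = list(
         phenotype = data.frame(sample = sample_ids,
                                batch = unname(batch_of),
                                phenotype = unname(phenotype),
                                stringsAsFactors = FALSE),
         variant_pass = variant_pass,
         burden = burden,
         adipocyte_fraction = stats::setNames(adip, sample_ids)))
}

#' Generate a variant-call fixture with ground-truth pass flags
#'
#' Produces a controlled mixture of variant records: each record is either
#' clean (passes every filter criterion) or violates exactly one criterion —
#' likelihood below 5, allele frequency below 0.02 or above 0.40, allele
#' depth below 2, a silent consequence, or absence from one of the two
#' hotspot catalogues.
#'
#' @param n_records number of records (`0` gives an empty table).
#' @param clean_fraction probability that a record is clean.
#' @param spec a [cohortSpec()] supplying the AF/AD model.
#' @param seed integer seed.
#' @return list with `calls` (validated data.frame), `pass` (logical truth
#'   flags), and `hotspots` (the two [HotspotList-class] catalogues).
#' @export
generateVariantFixture <- function(n_records, clean_fraction = 0.5,
                                   spec = cohortSpec(), seed = 1L) {
  stopifnot(n_records >= 0)
  set.seed(as.integer(seed))
  hs <- .cohort_hotspot_lists()
  if (n_records == 0) {
    calls <- .make_pass_calls(character(0), character(0), integer(0), spec)
    return(list(calls = validateVariantCalls(calls),
                pass = logical(0), hotspots = hs))
  }
  samples <- sprintf("S%03d", sample(50, n_records, replace = TRUE))
  calls <- .make_pass_calls(samples, rep("F", n_records),
                            sample(nrow(.hotspot_pool()), n_records,
                                   replace = TRUE), spec)
  clean <- stats::runif(n_records) < clean_fraction
  if (any(!clean))
    calls[!clean, ] <- .break_one_criterion(
      calls[!clean, , drop = FALSE],
      sample(.VIOLATIONS, sum(!clean), replace = TRUE))
  list(calls = validateVariantCalls(calls), pass = clean, hotspots = hs)
}
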