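#' Default run configuration
#'
#' Returns the full configuration list for [runPipeline()] with the shipped
#' defaults: IQR gate 0.8, Pearson/average-linkage clustering, target batch
#' `F`, hotspot thresholds (likelihood 5, AF 0.02-0.40, AD 2), enrichment
#' FDR q 0.10, and a synthetic cohort as input. Any element can be
#' overridden by the user's config (list or YAML file).
#'
#' @return named list of configuration values.
#' @export
defaultRunConfig <- function() {
  list(out = "activebreast_run",
       seed = 1L,
       iqr_threshold = 0.8,
       metric = "pearson",
       linkage = "average",
       target_batch = "F",
       likelihood_min = 5,
       af_min = 0.02,
       af_max = 0.40,
       ad_min = 2,
       q_threshold = 0.10,
       gsea_report = NULL,
       figures = FALSE,
       cohort = list(),          # overrides for cohortSpec()
       expr = NULL,              # optional real-data inputs
       covariates = NULL,
       variants = NULL,
       signature = NULL,
       hotspot_lists = NULL)
}

#' Validate a run configuration
#'
#' Merges user values over [defaultRunConfig()] and checks every threshold
#' before any work happens: AF bounds ordered within \[0, 1\], q and IQR
#' thresholds in range, positive depth/likelihood thresholds.
#'
#' @param config named list, or path to a YAML file.
#' @return the merged, validated configuration list.
#' @export
validateRunConfig <- function(config = list()) {
  if (is.character(config))
    config <- yaml::read_yaml(config)
  unknown <- setdiff(names(config), names(defaultRunConfig()))
  if (length(unknown))
    stop("unknown config field(s): ", paste(unknown, collapse = ", "))
  cfg <- utils::modifyList(defaultRunConfig(), config)
  if (cfg$af_min > cfg$af_max)
    stop("af_min must not exceed af_max")
  if (cfg$af_min < 0 || cfg$af_max > 1)
    stop("AF bounds must lie in [0, 1]")
  if (cfg$q_threshold < 0 || cfg$q_threshold > 1)
    stop("q_threshold must lie in [0, 1]")
  if (cfg$iqr_threshold < 0)
    stop("iqr_threshold must be >= 0")
  if (cfg$ad_min < 0)
    stop("ad_min must be >= 0")
  cfg$seed <- as.integer(cfg$seed)
  # YAML maps arrive as lists; cohortSpec expects named vectors
  cfg$cohort <- lapply(cfg$cohort, function(x)
    if (is.list(x)) unlist(x) else x)
  cfg
}

.config_hash <- function(cfg) {
  cfg$out <- NULL   # hash the analysis parameters, not the output location
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(cfg[order(names(cfg))], tmp, auto_unbox = TRUE,
                       null = "null", digits = NA)
  unname(tools::md5sum(tmp))
}

#' Run the full analysis pipeline
#'
#' Orchestrates simulate (or load) -> phenotype -> integrate -> hotspot
#' filter -> gene-set summary -> association statistics from one
#' configuration, writing every stage's output with a provenance header
#' (package version, seed, config hash) plus a manifest with file hashes.
#' Rerunning with an identical configuration reproduces identical outputs.
#' A stage failure aborts with an error naming the stage.
#'
#' @param config named list or YAML path; see [defaultRunConfig()] for the
#'   fields. With no input paths a synthetic cohort is generated from
#'   `config$cohort` overrides at `config$seed`.
#' @return invisibly, the manifest list (also written as `manifest.json`).
#' @export
runPipeline <- function(config = list()) {
  cfg <- validateRunConfig(config)
  hash <- .config_hash(cfg)
  header <- c(sprintf("activeBreast %s",
                      as.character(utils::packageVersion("activeBreast"))),
              sprintf("seed: %d", cfg$seed),
              sprintf("config: %s", hash))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE))
  }
  dir.create(cfg$out, recursive = TRUE, showWarnings = FALSE)
  path <- function(f) file.path(cfg$out, f)
  files <- character(0)

  inputs <- stage("inputs", {
    if (is.null(cfg$expr)) {
      cohort <- generateCohort(
        do.call(cohortSpec, c(cfg$cohort, list(seed = cfg$seed))))
      cohort
    } else {
      cov <- readCovariates(cfg$covariates)
      list(expression = readExpression(
             cfg$expr, stats::setNames(cov$batch, cov$sample)),
           covariates = cov,
           variants = if (!is.null(cfg$variants))
             readVariantCalls(cfg$variants),
           classifier = readSignatureTable(cfg$signature)[[1L]],
           hotspots = if (!is.null(cfg$hotspot_lists))
             lapply(cfg$hotspot_lists, function(p)
               hotspotList(basename(p), .read_table_auto(p))))
    }
  })

  labels <- stage("phenotype", {
    ph <- phenotypeCohort(inputs$expression, inputs$classifier,
                          iqr_threshold = cfg$iqr_threshold,
                          metric = cfg$metric, linkage = cfg$linkage)
    writeCovariates(ph$assignment, path("labels.csv"), header = header)
    files <- c(files, "labels.csv")
    ph$assignment
  })

  integrated <- stage("integrate", {
    out <- integrateBatches(inputs$expression, cfg$target_batch)
    writeExpression(out, path("corrected.tsv"), header = header)
    files <- c(files, "corrected.tsv")
    out
  })

  burden <- stage("hotspots", {
    if (is.null(inputs$variants)) NULL else {
      filtered <- filterVariants(inputs$variants, inputs$hotspots,
                                 likelihood_min = cfg$likelihood_min,
                                 af_range = c(cfg$af_min, cfg$af_max),
                                 ad_min = cfg$ad_min)
      writeVariantCalls(filtered, path("filtered_variants.csv"),
                        header = header)
      b <- burdenPerSample(filtered, inputs$covariates$sample)
      writeCovariates(data.frame(sample = names(b), burden = unname(b)),
                      path("burden.csv"), header = header)
      files <- c(files, "filtered_variants.csv", "burden.csv")
      b
    }
  })

  stage("genesets", {
    if (!is.null(cfg$gsea_report)) {
      rec <- readGseaReport(cfg$gsea_report)
      summary <- summarizeEnrichment(rec, q_threshold = cfg$q_threshold)
      jsonlite::write_json(summary, path("genesets_summary.json"),
                           auto_unbox = TRUE, digits = NA)
      files <- c(files, "genesets_summary.json")
    }
  })

  stage("associate", {
    comp <- compositionReport(
      inputs$covariates, labels,
      file = if (isTRUE(cfg$figures)) path("composition.png"))
    writeCovariates(comp$table, path("composition.csv"), header = header)
    files <- c(files, "composition.csv")
    lab <- stats::setNames(labels$label, labels$sample)
    d <- inputs$covariates
    d$label <- unname(lab[d$sample])
    rows <- lapply(intersect(c("gail", "age", "bmi"), colnames(d)),
                   function(v) {
      gc <- compareGroups(d, "label", v, test = "t")
      data.frame(variable = v, test = gc$test,
                 mean_active = unname(gc$mean["Active"]),
                 mean_inactive = unname(gc$mean["Inactive"]),
                 p = gc$p.value)
    })
    if (!is.null(burden)) {
      ba <- burdenAssociation(burden, inputs$covariates, "pct_adipocyte")
      rows <- c(rows, list(data.frame(
        variable = "burden_vs_pct_adipocyte", test = "spearman",
        mean_active = NA_real_, mean_inactive = NA_real_, p = ba$p)))
    }
    writeCovariates(do.call(rbind, rows), path("group_comparisons.csv"),
                    header = header)
    num <- d[, vapply(d, is.numeric, logical(1)), drop = FALSE]
    num$score <- stats::setNames(labels$score, labels$sample)[d$sample]
    cm <- correlationMatrix(num)
    utils::write.csv(round(cm$r, 6), path("correlation_matrix.csv"))
    files <- c(files, "group_comparisons.csv", "correlation_matrix.csv")
  })

  manifest <- list(
    package = "activeBreast",
    version = as.character(utils::packageVersion("activeBreast")),
    seed = cfg$seed,
    config = hash,
    files = as.list(vapply(file.path(cfg$out, files),
                           function(f) unname(tools::md5sum(f)), "")))
  names(manifest$files) <- files
  jsonlite::write_json(manifest, path("manifest.json"), auto_unbox = TRUE)
  invisible(manifest)
}
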