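#' Read a gene x sample TPM expression table
#'
#' Reads a tab-separated expression matrix (first column gene identifiers,
#' header row sample identifiers) into an [ExpressionExperiment-class].
#' Values are taken as-is: no normalization or transformation happens at read
#' time. Lines starting with `#` (provenance headers) are skipped. Genes
#' whose row is entirely missing are dropped with a warning; any remaining
#' missing value is an error.
#'
#' @param path path to a TSV file.
#' @param batch_map named character vector mapping sample identifier to batch
#'   label; every sample in the file must be present.
#' @param scale scale of the stored values, `"tpm"` (default) or
#'   `"log2_median_centered"`; the file itself does not record it.
#' @return an [ExpressionExperiment-class].
#' @seealso [writeExpression()]
#' @export
readExpression <- function(path, batch_map, scale = c("tpm", "log2_median_centered")) {
  scale <- match.arg(scale)
  tab <- utils::read.delim(path, check.names = FALSE, comment.char = "#",
                           stringsAsFactors = FALSE)
  if (ncol(tab) < 2L)
    stop("expression table needs a gene column plus at least one sample column")
  genes <- as.character(tab[[1L]])
  if (anyDuplicated(genes))
    stop("duplicated gene identifiers in ", path)
  values <- as.matrix(tab[, -1L, drop = FALSE])
  storage.mode(values) <- "double"
  rownames(values) <- genes
  all_missing <- rowSums(!is.na(values)) == 0L
  if (any(all_missing)) {
    warning(sum(all_missing), " gene(s) with all-missing rows dropped")
    values <- values[!all_missing, , drop = FALSE]
  }
  if (anyNA(values))
    stop("expression table contains missing values")
  if (identical(scale, "tpm") && min(values) < 0)
    stop("negative TPM value in ", path)
  ExpressionExperiment(values, batch = batch_map, scale = scale)
}

#' Write an expression matrix as TSV
#'
#' Inverse of [readExpression()]: first column `gene`, one column per sample.
#' Numeric values are written at full double precision so a read-back
#' reproduces them.
#'
#' @param x an [ExpressionExperiment-class].
#' @param path output path.
#' @param header optional character vector of provenance lines written as
#'   leading `#` comments.
#' @return `path`, invisibly.
#' @export
writeExpression <- function(x, path, header = NULL) {
  stopifnot(methods::is(x, "ExpressionExperiment"))
  v <- exprValues(x)
  out <- data.frame(gene = rownames(v), v, check.names = FALSE,
                    stringsAsFactors = FALSE)
  con <- file(path, "w")
  on.exit(close(con))
  if (length(header))
    writeLines(paste0("# ", header), con)
  utils::write.table(format(out, digits = 17, trim = TRUE, scientific = FALSE),
                     con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a GMT gene-set collection
#'
#' Standard GMT dialect: one set per line, tab-separated fields
#' `name`, `description`, then gene identifiers. Set names are preserved
#' verbatim (including case).
#'
#' @param path path to a `.gmt` file.
#' @return named list of character vectors (one element per set).
#' @seealso [writeGmt()]
#' @export
readGmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- vapply(fields, length, 1L) < 3L
  if (any(bad))
    stop("GMT line(s) without any gene: ",
         paste(which(bad), collapse = ", "))
  nm <- vapply(fields, `[[`, "", 1L)
  if (anyDuplicated(nm))
    stop("duplicated gene set name(s): ",
         paste(unique(nm[duplicated(nm)]), collapse = ", "))
  sets <- lapply(fields, function(f) f[-(1:2)])
  if (any(vapply(sets, length, 1L) == 0L))
    stop("empty gene set in ", path)
  names(sets) <- nm
  sets
}

#' Write a gene-set collection as GMT
#'
#' @param sets named list of character vectors.
#' @param path output path.
#' @param descriptions optional character vector of per-set descriptions
#'   (defaults to `"na"`).
#' @return `path`, invisibly.
#' @export
writeGmt <- function(sets, path, descriptions = NULL) {
  if (is.null(names(sets)) || anyDuplicated(names(sets)))
    stop("sets must be a uniquely named list")
  if (is.null(descriptions)) descriptions <- rep("na", length(sets))
  lines <- mapply(function(nm, desc, genes)
    paste(c(nm, desc, genes), collapse = "\t"),
    names(sets), descriptions, sets)
  writeLines(lines, path)
  invisible(path)
}

.read_table_auto <- function(path) {
  sep <- if (grepl("\\.tsv$|\\.txt$", path, ignore.case = TRUE)) "\t" else ","
  utils::read.table(path, sep = sep, header = TRUE, check.names = FALSE,
                    comment.char = "#", stringsAsFactors = FALSE,
                    na.strings = c("NA", ""))
}

#' Read a signature definition table
#'
#' Long-format table with columns `signature`, `gene`, `direction`
#' (`up`/`down`) and optionally `method`; CSV or TSV by extension.
#'
#' @param path path to the table.
#' @return named list of [GeneSignature-class] objects, one per signature
#'   name, in first-appearance order.
#' @export
readSignatureTable <- function(path) {
  tab <- .read_table_auto(path)
  need <- c("signature", "gene", "direction")
  if (!all(need %in% colnames(tab)))
    stop("signature table needs columns: ", paste(need, collapse = ", "))
  tab$direction <- tolower(tab$direction)
  if (!all(tab$direction %in% c("up", "down")))
    stop("direction must be 'up' or 'down'")
  out <- lapply(split(tab, factor(tab$signature, levels = unique(tab$signature))),
                function(d) {
    method <- if ("method" %in% colnames(d)) unique(d$method) else "sign_corrected_average"
    if (length(method) != 1L)
      stop("conflicting methods for signature ", d$signature[[1L]])
    geneSignature(d$signature[[1L]],
                  up = d$gene[d$direction == "up"],
                  down = d$gene[d$direction == "down"],
                  method = method)
  })
  out[unique(tab$signature)]
}

#' Write signatures as a long-format table
#'
#' @param sigs list of [GeneSignature-class] objects.
#' @param path output path (CSV or TSV by extension).
#' @return `path`, invisibly.
#' @export
writeSignatureTable <- function(sigs, path) {
  rows <- do.call(rbind, lapply(sigs, function(s)
    data.frame(signature = s@name,
               gene = c(s@up, s@down),
               direction = rep(c("up", "down"), c(length(s@up), length(s@down))),
               method = s@method, stringsAsFactors = FALSE)))
  sep <- if (grepl("\\.tsv$|\\.txt$", path, ignore.case = TRUE)) "\t" else ","
  utils::write.table(rows, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

.COVARIATE_PCT <- c("pct_adipocyte", "pct_stromal", "pct_epithelial")

#' Validate a covariate table
#'
#' Checks the invariants of the per-sample donor/histology table: unique
#' sample identifiers, percent-nuclei columns within \[0, 100\]. Missing cells
#' are permitted (association statistics use pairwise-complete records).
#'
#' @param cov data.frame with at least a `sample` column.
#' @return `cov`, invisibly, or an error.
#' @export
validateCovariates <- function(cov) {
  if (!"sample" %in% colnames(cov))
    stop("covariate table needs a 'sample' column")
  if (anyDuplicated(cov$sample))
    stop("duplicated sample identifiers in covariate table")
  for (p in intersect(.COVARIATE_PCT, colnames(cov))) {
    v <- cov[[p]]
    if (any(!is.na(v) & (v < 0 | v > 100)))
      stop(p, " must lie in [0, 100]")
  }
  invisible(cov)
}

#' Read a per-sample covariate table (CSV)
#'
#' @param path path to a CSV (TSV accepted by extension).
#' @return validated data.frame.
#' @export
readCovariates <- function(path) {
  cov <- .read_table_auto(path)
  if ("family_history" %in% colnames(cov))
    cov$family_history <- as.logical(cov$family_history)
  validateCovariates(cov)
  cov
}

#' Write a covariate table (CSV)
#'
#' @param cov data.frame.
#' @param path output path.
#' @param header optional provenance comment lines.
#' @return `path`, invisibly.
#' @export
writeCovariates <- function(cov, path, header = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (length(header)) writeLines(paste0("# ", header), con)
  utils::write.table(cov, con, sep = ",", quote = FALSE, row.names = FALSE)
  invisible(path)
}

.VARIANT_COLS <- c("sample", "gene", "contig", "position", "ref", "alt",
                   "likelihood", "ref_depth", "alt_depth", "af", "aa_change",
                   "consequence")

#' Validate a variant-call table
#'
#' Requires the canonical columns (sample, gene, contig, position, ref, alt,
#' likelihood, ref_depth, alt_depth, af, aa_change, consequence); checks
#' depth and allele-frequency invariants and flags records whose reported AF
#' disagrees with `alt_depth / (alt_depth + ref_depth)` in a new logical
#' column `af_consistent` (they are flagged, never silently dropped).
#'
#' @param calls data.frame of variant calls.
#' @param tol absolute tolerance for the AF consistency check.
#' @return the validated data.frame with an `af_consistent` column.
#' @export
validateVariantCalls <- function(calls, tol = 0.05) {
  missing <- setdiff(.VARIANT_COLS, colnames(calls))
  if (length(missing))
    stop("variant table missing columns: ", paste(missing, collapse = ", "))
  if (any(calls$alt_depth < 0) || any(calls$ref_depth < 0))
    stop("allele depths must be non-negative")
  if (any(calls$af < 0 | calls$af > 1))
    stop("allele frequency must lie in [0, 1]")
  depth <- calls$alt_depth + calls$ref_depth
  implied <- ifelse(depth > 0, calls$alt_depth / depth, NA_real_)
  calls$af_consistent <- is.na(implied) | abs(calls$af - implied) <= tol
  calls
}

#' Read a variant-call table (CSV)
#'
#' @param path path to a CSV export of the variant-call table.
#' @return validated data.frame (see [validateVariantCalls()]).
#' @export
readVariantCalls <- function(path) {
  validateVariantCalls(.read_table_auto(path))
}

#' Write a variant-call table (CSV)
#'
#' @param calls data.frame.
#' @param path output path.
#' @param header optional provenance comment lines.
#' @return `path`, invisibly.
#' @export
writeVariantCalls <- function(calls, path, header = NULL) {
  writeCovariates(calls, path, header = header)
}

#' Read a GSEA report table
#'
#' Reads the standard tab-separated GSEA report (columns `NAME`, `SIZE`,
#' `NES`, `NOM p-val`, `FDR q-val`, in any order, extra columns ignored) into
#' a tidy enrichment-record table.
#'
#' @param path path to the report TSV.
#' @param direction which phenotype the report's positive enrichment refers
#'   to, e.g. `"Active-up"`; recorded per row.
#' @return data.frame with columns `name`, `size`, `nes`, `p`, `q`,
#'   `direction`.
#' @export
readGseaReport <- function(path, direction = "Active-up") {
  tab <- utils::read.delim(path, check.names = FALSE, comment.char = "#",
                           stringsAsFactors = FALSE)
  key <- tolower(gsub("[^A-Za-z]", "", colnames(tab)))
  pick <- function(what) {
    i <- match(what, key)
    if (is.na(i)) stop("GSEA report lacks column for ", what)
    tab[[i]]
  }
  rec <- data.frame(name = as.character(pick("name")),
                    size = as.integer(pick("size")),
                    nes = as.numeric(pick("nes")),
                    p = as.numeric(pick("nompval")),
                    q = as.numeric(pick("fdrqval")),
                    direction = direction,
                    stringsAsFactors = FALSE)
  ok_p <- is.na(rec$p) | (rec$p >= 0 & rec$p <= 1)
  ok_q <- is.na(rec$q) | (rec$q >= 0 & rec$q <= 1)
  if (!all(ok_p) || !all(ok_q))
    stop("p and q values must lie in [0, 1]")
  if (any(!is.na(rec$size) & rec$size < 1))
    stop("gene set size must be >= 1")
  rec
}
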