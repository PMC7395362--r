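#' Fit a per-gene quantile map between two batches
#'
#' Pairs the empirical quantiles of the zero-excluded source values with
#' those of the zero-excluded target values on a common probability grid of
#' length `min(n_source_nonzero, n_target_nonzero)` (linear-interpolation
#' quantiles, `stats::quantile` type 7). A gene whose source or target vector
#' contains no nonzero value gets an identity sentinel map. Tied source
#' quantile values are collapsed (mapping is a function of value, not rank
#' position).
#'
#' @param source_values,target_values non-negative numeric vectors (the
#'   gene's expression in the source and target batch).
#' @param log fit the map on `log2(x + 1)` values instead of raw values
#'   (anchors are back-transformed).
#' @return a [QuantileMap-class].
#' @seealso [applyQuantileMap()], [integrateBatches()]
#' @export
fitQuantileMap <- function(source_values, target_values, log = FALSE) {
  if (any(source_values < 0) || any(target_values < 0))
    stop("expression values must be non-negative")
  s <- source_values[source_values != 0]
  t <- target_values[target_values != 0]
  if (!length(s) || !length(t))
    return(methods::new("QuantileMap", sourceAnchors = numeric(0),
                        targetAnchors = numeric(0), identity = TRUE))
  if (log) { s <- log2(s + 1); t <- log2(t + 1) }
  L <- min(length(s), length(t))
  probs <- if (L == 1L) 0.5 else seq(0, 1, length.out = L)
  sq <- unname(stats::quantile(s, probs, type = 7))
  tq <- unname(stats::quantile(t, probs, type = 7))
  if (anyDuplicated(sq)) {
    tq <- as.numeric(tapply(tq, sq, mean))   # groups sort by source value
    sq <- sort(unique(sq))
  }
  if (log) { sq <- 2^sq - 1; tq <- 2^tq - 1 }
  methods::new("QuantileMap", sourceAnchors = sq, targetAnchors = tq,
               identity = FALSE)
}

#' Apply a quantile map to expression values
#'
#' Zeros pass through as exactly zero (they were excluded from the fit and
#' are reattached after the mapping); nonzero values are transformed by
#' monotone linear interpolation between anchors, and values outside the
#' anchor range clamp to the extreme target anchors. Output order equals
#' input order.
#'
#' @param map a [QuantileMap-class] from [fitQuantileMap()].
#' @param values non-negative numeric vector.
#' @return numeric vector of mapped values.
#' @export
applyQuantileMap <- function(map, values) {
  stopifnot(methods::is(map, "QuantileMap"))
  if (any(values < 0))
    stop("expression values must be non-negative")
  if (map@identity || !length(values))
    return(values)
  out <- values
  nz <- values != 0
  if (!any(nz)) return(out)
  if (length(map@sourceAnchors) == 1L) {
    out[nz] <- map@targetAnchors
  } else {
    out[nz] <- stats::approx(map@sourceAnchors, map@targetAnchors,
                             xout = values[nz], rule = 2,
                             ties = "ordered")$y
  }
  out
}

#' Integrate two expression batches by per-gene quantile normalization
#'
#' Maps every non-target-batch gene vector onto the target batch's per-gene
#' expression distribution using [fitQuantileMap()] / [applyQuantileMap()],
#' excluding zeros from both source and target and reattaching them
#' afterwards. Target-batch values are returned unchanged. Genes that cannot
#' be mapped (all-zero in either batch) are carried unchanged and recorded in
#' `metadata(result)$unmapped_genes`.
#'
#' @param m an [ExpressionExperiment-class] on the TPM scale with exactly two
#'   batches.
#' @param target_batch batch label whose distribution is the target (the
#'   study design maps batch P into batch F space).
#' @param log perform the mapping on the log2(TPM+1) scale (default: raw
#'   TPM, since zero handling is defined on expression values).
#' @return an [ExpressionExperiment-class] with corrected source-batch
#'   values; `metadata` records `integrated`, `target_batch` and
#'   `unmapped_genes`.
#' @export
integrateBatches <- function(m, target_batch, log = FALSE) {
  stopifnot(methods::is(m, "ExpressionExperiment"))
  if (!identical(exprScale(m), "tpm"))
    stop("integration operates on the TPM scale")
  batch <- batchLabels(m)
  bs <- unique(batch)
  if (length(bs) != 2L)
    stop("exactly two batches required (pairwise integration), got ",
         length(bs))
  if (!target_batch %in% bs)
    stop("target_batch '", target_batch, "' not present")
  v <- exprValues(m)
  tgt <- batch == target_batch
  unmapped <- character(0)
  for (g in rownames(v)) {
    map <- fitQuantileMap(v[g, !tgt], v[g, tgt], log = log)
    if (map@identity) {
      unmapped <- c(unmapped, g)
    } else {
      v[g, !tgt] <- applyQuantileMap(map, v[g, !tgt])
    }
  }
  out <- ExpressionExperiment(v, batch = batch, scale = "tpm")
  S4Vectors::metadata(out)$integrated <- TRUE
  S4Vectors::metadata(out)$target_batch <- target_batch
  S4Vectors::metadata(out)$unmapped_genes <- unmapped
  out
}

#' Per-gene variance explained by batch
#'
#' Fraction of each gene's total variance explained by the batch factor
#' (between-batch sum of squares over total sum of squares), computed on
#' `log2(TPM + 1)` when the input is on the TPM scale. Used to quantify how
#' much planted batch signal integration removes.
#'
#' @param m an [ExpressionExperiment-class].
#' @param genes optional subset of genes (default: all).
#' @return named numeric vector of per-gene R-squared values (`NA` for
#'   zero-variance genes).
#' @export
batchVarianceExplained <- function(m, genes = NULL) {
  stopifnot(methods::is(m, "ExpressionExperiment"))
  v <- exprValues(m)
  if (!is.null(genes)) v <- v[genes, , drop = FALSE]
  if (identical(exprScale(m), "tpm")) v <- log2(v + 1)
  f <- factor(batchLabels(m))
  apply(v, 1L, function(x) {
    sst <- sum((x - mean(x))^2)
    if (sst == 0) return(NA_real_)
    ssb <- sum(tapply(x, f, function(g) length(g) * (mean(g) - mean(x))^2))
    ssb / sst
  })
}
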