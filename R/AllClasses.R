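#' ExpressionExperiment: a batch-annotated TPM expression container
#'
#' Thin extension of [SummarizedExperiment::SummarizedExperiment] holding a
#' genes x samples expression matrix together with a per-sample batch label
#' and an explicit scale flag. Values on the `"tpm"` scale must be
#' non-negative; `"log2_median_centered"` values are log2(TPM+1) after
#' per-gene median centering and may be negative.
#'
#' @slot . inherits all slots from `SummarizedExperiment`; the batch label
#'   lives in `colData(x)$batch` and the scale flag in `metadata(x)$scale`.
#'
#' @seealso [ExpressionExperiment()], [exprValues()], [batchLabels()],
#'   [exprScale()]
#' @export
setClass("ExpressionExperiment", contains = "SummarizedExperiment")

.EXPR_SCALES <- c("tpm", "log2_median_centered")

setValidity("ExpressionExperiment", function(object) {
  msg <- character(0)
  v <- SummarizedExperiment::assay(object)
  if (is.null(rownames(v)) || is.null(colnames(v)))
    msg <- c(msg, "gene (row) and sample (column) names are required")
  if (!is.null(rownames(v)) && anyDuplicated(rownames(v)))
    msg <- c(msg, "duplicated gene identifiers")
  if (!is.null(colnames(v)) && anyDuplicated(colnames(v)))
    msg <- c(msg, "duplicated sample identifiers")
  if (anyNA(v))
    msg <- c(msg, "expression values must not contain missing values")
  if (!"batch" %in% colnames(SummarizedExperiment::colData(object))) {
    msg <- c(msg, "colData must contain a 'batch' column")
  } else if (anyNA(SummarizedExperiment::colData(object)$batch)) {
    msg <- c(msg, "every sample needs exactly one non-missing batch label")
  }
  sc <- S4Vectors::metadata(object)$scale
  if (is.null(sc) || length(sc) != 1L || !sc %in% .EXPR_SCALES) {
    msg <- c(msg, sprintf("metadata scale must be one of: %s",
                          paste(.EXPR_SCALES, collapse = ", ")))
  } else if (identical(sc, "tpm") && length(v) && min(v) < 0) {
    msg <- c(msg, "TPM values must be non-negative")
  }
  if (length(msg)) msg else TRUE
})

#' Construct an ExpressionExperiment
#'
#' @param values numeric matrix, genes x samples, with row and column names.
#' @param batch per-sample batch labels; either a vector aligned with the
#'   columns of `values` or a named vector keyed by sample identifier.
#' @param scale `"tpm"` (default) or `"log2_median_centered"`.
#'
#' @return a validated [ExpressionExperiment-class] object.
#' @examples
#' m <- matrix(c(1, 3, 7, 0), 2, 2,
#'             dimnames = list(c("LEP", "KIT"), c("s1", "s2")))
#' x <- ExpressionExperiment(m, batch = c(s1 = "F", s2 = "P"))
#' exprValues(x)
#' @export
ExpressionExperiment <- function(values, batch, scale = c("tpm", "log2_median_centered")) {
  scale <- match.arg(scale)
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(colnames(values)))
    stop("expression matrix must have sample (column) names")
  if (!is.null(names(batch))) {
    missing <- setdiff(colnames(values), names(batch))
    if (length(missing))
      stop("samples missing from batch map: ", paste(missing, collapse = ", "))
    batch <- batch[colnames(values)]
  } else if (length(batch) == 1L) {
    batch <- rep(batch, ncol(values))
  } else if (length(batch) != ncol(values)) {
    stop("batch must have one label per sample")
  }
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(exprs = values),
    colData = S4Vectors::DataFrame(batch = as.character(batch),
                                   row.names = colnames(values)))
  S4Vectors::metadata(se)$scale <- scale
  methods::new("ExpressionExperiment", se)
}

#' GeneSignature: up/down gene sets with a scoring method
#'
#' A named expression signature made of disjoint sets of upregulated (`up`)
#' and downregulated (`down`) gene identifiers. `method` selects the scoring
#' rule: `"sign_corrected_average"` for two-sided signatures and
#' `"mean_log2_up"` for single-list signatures scored as the mean of
#' log2(TPM+1) over `up`.
#'
#' @slot name character scalar signature name.
#' @slot up character vector of upregulated gene identifiers.
#' @slot down character vector of downregulated gene identifiers.
#' @slot method scoring method.
#' @seealso [geneSignature()], [signatureScore()]
#' @export
setClass("GeneSignature",
         representation(name = "character", up = "character",
                        down = "character", method = "character"))

.SIG_METHODS <- c("sign_corrected_average", "mean_log2_up")

setValidity("GeneSignature", function(object) {
  msg <- character(0)
  if (length(object@name) != 1L || !nzchar(object@name))
    msg <- c(msg, "signature needs a non-empty name")
  if (length(intersect(object@up, object@down)))
    msg <- c(msg, sprintf("genes listed as both up and down: %s",
                          paste(intersect(object@up, object@down), collapse = ", ")))
  if (length(object@up) + length(object@down) < 1L)
    msg <- c(msg, "signature must contain at least one gene")
  if (anyDuplicated(object@up) || anyDuplicated(object@down))
    msg <- c(msg, "duplicated gene identifiers within a direction")
  if (length(object@method) != 1L || !object@method %in% .SIG_METHODS)
    msg <- c(msg, sprintf("method must be one of: %s",
                          paste(.SIG_METHODS, collapse = ", ")))
  if (length(msg)) msg else TRUE
})

#' Construct a GeneSignature
#'
#' @param name signature name.
#' @param up,down character vectors of gene identifiers (disjoint; matched
#'   case-sensitively against expression row names).
#' @param method `"sign_corrected_average"` (default) or `"mean_log2_up"`.
#' @return a validated [GeneSignature-class].
#' @examples
#' geneSignature("toy", up = c("LEP", "ADIPOQ"), down = "KIT")
#' @export
geneSignature <- function(name, up = character(0), down = character(0),
                          method = c("sign_corrected_average", "mean_log2_up")) {
  method <- match.arg(method)
  methods::new("GeneSignature", name = as.character(name),
               up = as.character(up), down = as.character(down),
               method = method)
}

#' QuantileMap: a per-gene monotone quantile-to-quantile mapping
#'
#' Pairs empirical quantiles of a zero-excluded source expression vector with
#' the matching quantiles of a target vector on a common probability grid.
#' Applying the map moves the source distribution onto the target
#' distribution; zeros are never part of the anchors and pass through
#' unchanged when the map is applied. A gene whose source or target vector is
#' all zero gets an `identity` sentinel map.
#'
#' @slot sourceAnchors,targetAnchors non-decreasing numeric vectors of equal
#'   length (empty for identity maps).
#' @slot identity logical; `TRUE` for the unzero-mappable sentinel.
#' @seealso [fitQuantileMap()], [applyQuantileMap()]
#' @export
setClass("QuantileMap",
         representation(sourceAnchors = "numeric", targetAnchors = "numeric",
                        identity = "logical"))

setValidity("QuantileMap", function(object) {
  msg <- character(0)
  if (length(object@sourceAnchors) != length(object@targetAnchors))
    msg <- c(msg, "anchor sequences must have equal length")
  if (is.unsorted(object@sourceAnchors) || is.unsorted(object@targetAnchors))
    msg <- c(msg, "anchor sequences must be non-decreasing")
  if (length(object@identity) != 1L)
    msg <- c(msg, "identity flag must be a logical scalar")
  if (length(msg)) msg else TRUE
})

#' HotspotList: a curated cancer-gene hotspot catalogue
#'
#' Entries are keyed by (gene, amino-acid change) and/or by
#' (gene, contig, position, ref, alt); matching of variant calls prefers the
#' amino-acid key and falls back to the locus key.
#'
#' @slot name list name, e.g. `"MSK-IMPACT"`.
#' @slot entries data.frame with column `gene` and at least one complete key:
#'   `aa_change`, or `contig` + `position` + `ref` + `alt`.
#' @seealso [hotspotList()], [filterVariants()]
#' @export
setClass("HotspotList",
         representation(name = "character", entries = "data.frame"))

setValidity("HotspotList", function(object) {
  msg <- character(0)
  e <- object@entries
  if (length(object@name) != 1L || !nzchar(object@name))
    msg <- c(msg, "hotspot list needs a non-empty name")
  if (!"gene" %in% colnames(e))
    msg <- c(msg, "entries need a 'gene' column")
  has_aa <- "aa_change" %in% colnames(e)
  has_locus <- all(c("contig", "position", "ref", "alt") %in% colnames(e))
  if (!has_aa && !has_locus)
    msg <- c(msg, "entries need an 'aa_change' column or contig/position/ref/alt columns")
  if (!length(msg) && nrow(e)) {
    keys <- character(0)
    if (has_aa) {
      aa <- !is.na(e$aa_change)
      keys <- c(keys, paste(e$gene[aa], e$aa_change[aa], sep = "|"))
    }
    if (has_locus) {
      loc <- !is.na(e$position)
      keys <- c(keys, paste(e$gene[loc], e$contig[loc], e$position[loc],
                            e$ref[loc], e$alt[loc], sep = "|"))
    }
    if (anyDuplicated(keys))
      msg <- c(msg, "duplicated hotspot entries for the same key")
  }
  if (length(msg)) msg else TRUE
})

#' Construct a HotspotList
#'
#' @param name list name.
#' @param entries data.frame of hotspot entries (see
#'   [HotspotList-class]).
#' @return a validated [HotspotList-class].
#' @examples
#' hotspotList("MSK-IMPACT",
#'             data.frame(gene = "TP53", aa_change = "R175H"))
#' @export
hotspotList <- function(name, entries) {
  entries <- as.data.frame(entries)
  methods::new("HotspotList", name = as.character(name), entries = entries)
}
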