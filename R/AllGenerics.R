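#' Accessors for ExpressionExperiment
#'
#' `exprValues()` returns the genes x samples expression matrix,
#' `batchLabels()` the per-sample batch labels (named by sample), and
#' `exprScale()` the scale flag (`"tpm"` or `"log2_median_centered"`).
#'
#' @param x an [ExpressionExperiment-class].
#' @return `exprValues`: numeric matrix; `batchLabels`: named character
#'   vector; `exprScale`: character scalar.
#' @name expression-accessors
NULL

#' @rdname expression-accessors
#' @export
setGeneric("exprValues", function(x) standardGeneric("exprValues"))

#' @rdname expression-accessors
#' @export
setMethod("exprValues", "ExpressionExperiment", function(x)
  SummarizedExperiment::assay(x, "exprs"))

#' @rdname expression-accessors
#' @export
setGeneric("batchLabels", function(x) standardGeneric("batchLabels"))

#' @rdname expression-accessors
#' @export
setMethod("batchLabels", "ExpressionExperiment", function(x) {
  b <- SummarizedExperiment::colData(x)$batch
  names(b) <- colnames(x)
  b
})

#' @rdname expression-accessors
#' @export
setGeneric("exprScale", function(x) standardGeneric("exprScale"))

#' @rdname expression-accessors
#' @export
setMethod("exprScale", "ExpressionExperiment", function(x)
  S4Vectors::metadata(x)$scale)

setMethod("show", "ExpressionExperiment", function(object) {
  methods::callNextMethod()
  b <- table(batchLabels(object))
  cat(sprintf("scale: %s | batches: %s\n", exprScale(object),
              paste(sprintf("%s=%d", names(b), as.integer(b)), collapse = ", ")))
})

setMethod("show", "GeneSignature", function(object) {
  cat(sprintf("GeneSignature '%s' (%s): %d up, %d down genes\n",
              object@name, object@method,
              length(object@up), length(object@down)))
})

setMethod("show", "QuantileMap", function(object) {
  if (object@identity) {
    cat("QuantileMap: identity sentinel (unzero-mappable gene)\n")
  } else {
    cat(sprintf("QuantileMap: %d anchors, source [%g, %g] -> target [%g, %g]\n",
                length(object@sourceAnchors),
                min(object@sourceAnchors), max(object@sourceAnchors),
                min(object@targetAnchors), max(object@targetAnchors)))
  }
})

setMethod("show", "HotspotList", function(object) {
  cat(sprintf("HotspotList '%s': %d entries\n", object@name,
              nrow(object@entries)))
})

#' Signature accessors
#'
#' @param x a [GeneSignature-class].
#' @return `sigUp`/`sigDown`: character vectors of gene identifiers;
#'   `sigName`: the signature name.
#' @name signature-accessors
NULL

#' @rdname signature-accessors
#' @export
setGeneric("sigUp", function(x) standardGeneric("sigUp"))

#' @rdname signature-accessors
#' @export
setMethod("sigUp", "GeneSignature", function(x) x@up)

#' @rdname signature-accessors
#' @export
setGeneric("sigDown", function(x) standardGeneric("sigDown"))

#' @rdname signature-accessors
#' @export
setMethod("sigDown", "GeneSignature", function(x) x@down)

#' @rdname signature-accessors
#' @export
setGeneric("sigName", function(x) standardGeneric("sigName"))

#' @rdname signature-accessors
#' @export
setMethod("sigName", "GeneSignature", function(x) x@name)
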