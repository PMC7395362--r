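#' Log2-transform and median-center an expression matrix
#'
#' Each TPM value becomes `log2(TPM + 1)` minus the gene's median, so every
#' gene's median is exactly zero afterwards. When `by_batch = TRUE` (the
#' default, matching batch-independent phenotyping) the median is taken
#' within each batch; otherwise across all samples.
#'
#' @param m an [ExpressionExperiment-class] on the TPM scale.
#' @param by_batch centre within batch (default) or across the whole cohort.
#' @return an [ExpressionExperiment-class] with
#'   `exprScale == "log2_median_centered"`.
#' @export
normalizeLog2MedianCenter <- function(m, by_batch = TRUE) {
  stopifnot(methods::is(m, "ExpressionExperiment"))
  if (!identical(exprScale(m), "tpm"))
    stop("input must be on the TPM scale")
  v <- exprValues(m)
  if (!length(v))
    stop("empty expression matrix")
  lv <- log2(v + 1)
  batch <- batchLabels(m)
  if (by_batch) {
    for (b in unique(batch)) {
      cols <- batch == b
      med <- apply(lv[, cols, drop = FALSE], 1L, stats::median)
      lv[, cols] <- lv[, cols, drop = FALSE] - med
    }
  } else {
    lv <- lv - apply(lv, 1L, stats::median)
  }
  ExpressionExperiment(lv, batch = batch, scale = "log2_median_centered")
}

#' Select variably expressed classifier genes by IQR
#'
#' Intersects the matrix genes with a classifier gene set and keeps genes
#' whose interquartile range of normalized values is strictly greater than
#' `iqr_threshold` (default 0.8, the shipped classifier gate). Quantiles use
#' linear interpolation between order statistics (`stats::quantile` type 7).
#' The returned genes follow the matrix row order.
#'
#' @param m an [ExpressionExperiment-class] on the
#'   `log2_median_centered` scale.
#' @param classifier_genes character vector of classifier gene identifiers
#'   (matched case-sensitively), or a [GeneSignature-class] whose up and down
#'   genes are pooled.
#' @param iqr_threshold strict lower IQR bound.
#' @return character vector of selected genes.
#' @export
selectVariableGenes <- function(m, classifier_genes, iqr_threshold = 0.8) {
  stopifnot(methods::is(m, "ExpressionExperiment"))
  if (!identical(exprScale(m), "log2_median_centered"))
    stop("input must be log2 median-centered (see normalizeLog2MedianCenter)")
  if (methods::is(classifier_genes, "GeneSignature"))
    classifier_genes <- c(sigUp(classifier_genes), sigDown(classifier_genes))
  v <- exprValues(m)
  common <- rownames(v)[rownames(v) %in% classifier_genes]
  if (!length(common))
    stop(length(classifier_genes),
         " classifier gene(s) supplied but none found in the matrix")
  iqr <- apply(v[common, , drop = FALSE], 1L, stats::IQR, type = 7)
  common[iqr > iqr_threshold]
}

#' Hierarchically cluster samples into two phenotype groups
#'
#' Agglomerative hierarchical clustering of samples on the selected-gene
#' submatrix, with distance `1 - Pearson correlation` between sample profiles
#' (or Euclidean distance) and the chosen linkage, cut into exactly two
#' clusters. The result is invariant to the input order of samples.
#'
#' @param m an [ExpressionExperiment-class] (normalized values recommended).
#' @param genes classifier genes to cluster on (>= 2).
#' @param metric `"pearson"` (default; distance `1 - r`) or `"euclidean"`.
#' @param linkage agglomeration method passed to [stats::hclust()]
#'   (default `"average"`).
#' @return list of two character vectors of sample identifiers, each sorted,
#'   ordered by decreasing cluster size (ties broken by first identifier).
#' @export
clusterPhenotypes <- function(m, genes, metric = c("pearson", "euclidean"),
                              linkage = "average") {
  stopifnot(methods::is(m, "ExpressionExperiment"))
  metric <- match.arg(metric)
  if (ncol(m) < 4L)
    stop("need at least 4 samples to cluster")
  if (length(genes) < 2L)
    stop("need at least 2 classifier genes to cluster")
  v <- exprValues(m)[genes, , drop = FALSE]
  # canonical column order so the bipartition cannot depend on input order
  v <- v[, order(colnames(v)), drop = FALSE]
  if (metric == "pearson") {
    sds <- apply(v, 2L, stats::sd)
    if (any(sds == 0))
      stop("degenerate clustering: constant sample profile(s): ",
           paste(colnames(v)[sds == 0], collapse = ", "))
    d <- stats::as.dist(1 - stats::cor(v))
  } else {
    d <- stats::dist(t(v))
  }
  if (all(d == 0))
    stop("degenerate clustering: all samples identical")
  hc <- stats::hclust(d, method = linkage)
  k2 <- stats::cutree(hc, k = 2)
  cl <- lapply(1:2, function(i) sort(names(k2)[k2 == i]))
  ord <- order(-vapply(cl, length, 1L), vapply(cl, `[[`, "", 1L))
  cl[ord]
}

.score_one <- function(tpm, sig) {
  u <- intersect(sig@up, names(tpm))
  d <- intersect(sig@down, names(tpm))
  if (sig@method == "mean_log2_up") {
    if (!length(u))
      stop("no signature gene present in the expression data")
    return(mean(log2(tpm[u] + 1)))
  }
  if (!length(u) && !length(d))
    stop("no signature gene present in the expression data")
  (sum(log2(tpm[u] + 1)) - sum(log2(tpm[d] + 1))) / (length(u) + length(d))
}

#' Sign-corrected signature score of one sample
#'
#' For a signature with upregulated set U and downregulated set D, the score
#' is
#' \deqn{S_s = \frac{\sum_{g \in U} \log_2(T_g + 1) - \sum_{g \in D} \log_2(T_g + 1)}{|U| + |D|}}
#' where \eqn{T_g} is the TPM of gene g and |U|, |D| count the signature
#' genes actually present in the data (absent genes are dropped from both
#' sums and denominator). Signatures with `method = "mean_log2_up"` score as
#' the plain mean of `log2(TPM + 1)` over the up set.
#'
#' @param tpm named non-negative numeric vector of one sample's TPM values.
#' @param sig a [GeneSignature-class].
#' @return numeric scalar score.
#' @examples
#' signatureScore(c(A = 3, B = 1), geneSignature("s", up = "A", down = "B"))
#' # (log2(4) - log2(2)) / 2 = 0.5
#' @export
signatureScore <- function(tpm, sig) {
  stopifnot(methods::is(sig, "GeneSignature"))
  if (is.null(names(tpm)))
    stop("TPM vector must be named by gene")
  if (any(tpm < 0))
    stop("TPM values must be non-negative")
  .score_one(tpm, sig)
}

#' Per-sample signature scores for a cohort
#'
#' @param m an [ExpressionExperiment-class] on the TPM scale.
#' @param sig a [GeneSignature-class].
#' @return named numeric vector, one score per sample.
#' @seealso [signatureScore()] for the formula.
#' @export
signatureScores <- function(m, sig) {
  stopifnot(methods::is(m, "ExpressionExperiment"),
            methods::is(sig, "GeneSignature"))
  if (!identical(exprScale(m), "tpm"))
    stop("signature scores are defined on TPM values")
  v <- exprValues(m)
  u <- intersect(sig@up, rownames(v))
  d <- intersect(sig@down, rownames(v))
  if (sig@method == "mean_log2_up") {
    if (!length(u)) stop("no signature gene present in the expression data")
    return(colMeans(log2(v[u, , drop = FALSE] + 1)))
  }
  if (!length(u) && !length(d))
    stop("no signature gene present in the expression data")
  (colSums(log2(v[u, , drop = FALSE] + 1)) -
     colSums(log2(v[d, , drop = FALSE] + 1))) / (length(u) + length(d))
}

#' Label two sample clusters as Active and Inactive
#'
#' Scores every clustered sample with the classifier signature (Active-up
#' genes as U, Inactive-up genes as D) and labels the cluster with the higher
#' mean score *Active*, the other *Inactive*. Exactly tied cluster means are
#' an error, never a silent coin flip.
#'
#' @param clusters list of two character vectors of sample identifiers, as
#'   returned by [clusterPhenotypes()].
#' @param m an [ExpressionExperiment-class] on the TPM scale containing the
#'   clustered samples.
#' @param classifier a [GeneSignature-class].
#' @return data.frame with columns `sample`, `batch`, `label`
#'   (`Active`/`Inactive`), `score`, `cluster`, one row per clustered sample
#'   in matrix column order.
#' @export
assignLabels <- function(clusters, m, classifier) {
  if (length(clusters) != 2L)
    stop("exactly two clusters required")
  stopifnot(methods::is(m, "ExpressionExperiment"))
  scores <- signatureScores(m, classifier)
  missing <- setdiff(unlist(clusters), names(scores))
  if (length(missing))
    stop("clustered sample(s) absent from the matrix: ",
         paste(missing, collapse = ", "))
  means <- vapply(clusters, function(s) mean(scores[s]), numeric(1))
  if (means[1] == means[2])
    stop("tied cluster mean scores; set a seed/ordering policy explicitly")
  active <- clusters[[which.max(means)]]
  ids <- colnames(m)[colnames(m) %in% unlist(clusters)]
  data.frame(sample = ids,
             batch = unname(batchLabels(m)[ids]),
             label = ifelse(ids %in% active, "Active", "Inactive"),
             score = unname(scores[ids]),
             cluster = ifelse(ids %in% clusters[[1L]], 1L, 2L),
             stringsAsFactors = FALSE)
}

#' Differentially expressed genes between Active and Inactive samples
#'
#' Per-gene two-sided Wilcoxon rank-sum test between the two label groups
#' with Benjamini-Hochberg adjustment; returns genes with adjusted p below
#' `fdr`.
#'
#' @param m an [ExpressionExperiment-class] (any scale; the test is
#'   rank-based).
#' @param labels named character vector (`Active`/`Inactive` keyed by
#'   sample), or a data.frame with `sample` and `label` columns.
#' @param fdr adjusted-p cutoff (default 0.05).
#' @return character vector of significant genes, in matrix row order.
#' @export
diffGenes <- function(m, labels, fdr = 0.05) {
  stopifnot(methods::is(m, "ExpressionExperiment"))
  if (is.data.frame(labels))
    labels <- stats::setNames(labels$label, labels$sample)
  labels <- labels[colnames(m)]
  labels <- labels[!is.na(labels)]
  grp <- split(names(labels), labels)
  if (!all(c("Active", "Inactive") %in% names(grp)))
    stop("both Active and Inactive labels must be present")
  if (any(lengths(grp[c("Active", "Inactive")]) < 3L))
    stop("each label group needs at least 3 samples")
  v <- exprValues(m)
  a <- v[, grp$Active, drop = FALSE]
  b <- v[, grp$Inactive, drop = FALSE]
  p <- vapply(seq_len(nrow(v)), function(i)
    suppressWarnings(stats::wilcox.test(a[i, ], b[i, ])$p.value), numeric(1))
  padj <- stats::p.adjust(p, method = "BH")
  rownames(v)[!is.na(padj) & padj < fdr]
}

#' Batch-wise phenotyping of a cohort
#'
#' Runs the full phenotyping workflow independently within each batch:
#' log2 median-centered normalization, IQR-gated classifier gene selection,
#' hierarchical clustering into two groups, and Active/Inactive label
#' assignment by mean classifier score. A batch in which only one label
#' occurs is flagged degenerate with a warning.
#'
#' @param m an [ExpressionExperiment-class] on the TPM scale.
#' @param classifier a [GeneSignature-class] (Active-up as up, Inactive-up as
#'   down).
#' @param iqr_threshold IQR gate for classifier genes (default 0.8).
#' @param metric,linkage clustering options, see [clusterPhenotypes()].
#' @return list with `assignment` (row-bound [assignLabels()] output across
#'   batches) and `genes` (named list of selected genes per batch).
#' @export
phenotypeCohort <- function(m, classifier, iqr_threshold = 0.8,
                            metric = "pearson", linkage = "average") {
  stopifnot(methods::is(m, "ExpressionExperiment"))
  batch <- batchLabels(m)
  parts <- lapply(unique(batch), function(b) {
    mb <- m[, batch == b]
    norm <- normalizeLog2MedianCenter(mb, by_batch = FALSE)
    genes <- selectVariableGenes(norm, classifier, iqr_threshold)
    clusters <- clusterPhenotypes(norm, genes, metric = metric,
                                  linkage = linkage)
    assignment <- assignLabels(clusters, mb, classifier)
    if (length(unique(assignment$label)) < 2L)
      warning("degenerate phenotyping in batch ", b,
              ": only one label assigned")
    list(assignment = assignment, genes = genes)
  })
  names(parts) <- unique(batch)
  list(assignment = do.call(rbind, lapply(parts, `[[`, "assignment")),
       genes = lapply(parts, `[[`, "genes"))
}

#' Phenotype heat map of classifier genes
#'
#' Renders the classifier-gene x sample matrix with samples ordered by
#' cluster and annotated by assigned label, in the style of a two-phenotype
#' expression heat map.
#'
#' @param m a normalized [ExpressionExperiment-class].
#' @param assignment data.frame from [assignLabels()]/[phenotypeCohort()].
#' @param genes classifier genes to display.
#' @param file optional output path (PNG/PDF by extension); `NULL` draws to
#'   the active device.
#' @return the `pheatmap` object, invisibly.
#' @export
plotPhenotypeHeatmap <- function(m, assignment, genes, file = NULL) {
  stopifnot(methods::is(m, "ExpressionExperiment"))
  ids <- assignment$sample[order(assignment$label, -assignment$score)]
  v <- exprValues(m)[genes, ids, drop = FALSE]
  ann <- data.frame(label = assignment$label[match(ids, assignment$sample)],
                    row.names = ids)
  ph <- pheatmap::pheatmap(v, cluster_cols = FALSE, show_colnames = FALSE,
                           annotation_col = ann, silent = !is.null(file),
                           filename = if (is.null(file)) NA else file)
  invisible(ph)
}
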