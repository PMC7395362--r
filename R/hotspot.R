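#' Classify variant consequences as silent or non-silent
#'
#' Keyword-based classification of consequence strings: synonymous /
#' no-protein-change annotations count as silent; missense, nonsense,
#' frameshift, splice, stop and start changes count as non-silent. Unmatched
#' strings return `NA` (and are never treated as predicted non-silent by the
#' filter). Both keyword tables are arguments, so the rule is visible and
#' extensible.
#'
#' @param consequence character vector of consequence annotations.
#' @param silent_keywords,nonsilent_keywords case-insensitive substrings.
#' @return logical vector: `TRUE` silent, `FALSE` non-silent, `NA` unknown.
#' @export
isSilentConsequence <- function(consequence,
    silent_keywords = c("synonymous", "silent", "no_protein_change"),
    nonsilent_keywords = c("missense", "nonsense", "frameshift", "splice",
                           "stop_gained", "stop_lost", "start_lost",
                           "inframe")) {
  lc <- tolower(consequence)
  hit <- function(keys) Reduce(`|`, lapply(keys, function(k)
    grepl(k, lc, fixed = TRUE)), rep(FALSE, length(lc)))
  out <- rep(NA, length(consequence))
  out[hit(nonsilent_keywords)] <- FALSE
  out[hit(silent_keywords)] <- TRUE
  out
}

.in_hotspot_list <- function(calls, hl) {
  e <- hl@entries
  found <- rep(FALSE, nrow(calls))
  if ("aa_change" %in% colnames(e) && any(!is.na(e$aa_change))) {
    aa <- e[!is.na(e$aa_change), ]
    found <- found | paste(calls$gene, calls$aa_change, sep = "|") %in%
      paste(aa$gene, aa$aa_change, sep = "|")
  }
  if (all(c("contig", "position", "ref", "alt") %in% colnames(e))) {
    loc <- e[!is.na(e$position), ]
    if (nrow(loc))
      found <- found |
        paste(calls$gene, calls$contig, calls$position, calls$ref,
              calls$alt, sep = "|") %in%
        paste(loc$gene, loc$contig, loc$position, loc$ref, loc$alt,
              sep = "|")
  }
  found
}

#' Filter expressed variant calls against hotspot lists
#'
#' Keeps exactly the calls satisfying all of: likelihood score >=
#' `likelihood_min`, allele frequency within `af_range` (bounds inclusive),
#' variant allele depth >= `ad_min`, a predicted non-silent amino-acid
#' change, and presence in *every* supplied hotspot list (intersection).
#' Membership in a list prefers the (gene, amino-acid change) key and falls
#' back to the (gene, contig, position, ref, alt) key. Output rows keep the
#' input order; the filter is idempotent.
#'
#' @param calls validated variant-call data.frame (see
#'   [validateVariantCalls()]).
#' @param hotspot_lists list of [HotspotList-class] objects (may be empty,
#'   in which case only the numeric criteria apply).
#' @param likelihood_min,af_range,ad_min thresholds; defaults are the
#'   shipped heuristics (5, \[0.02, 0.40\], 2).
#' @param ... keyword tables passed to [isSilentConsequence()].
#' @return the surviving subset of `calls`.
#' @export
filterVariants <- function(calls, hotspot_lists = list(),
                           likelihood_min = 5, af_range = c(0.02, 0.40),
                           ad_min = 2, ...) {
  if (!nrow(calls)) return(calls)
  if (methods::is(hotspot_lists, "HotspotList"))
    hotspot_lists <- list(hotspot_lists)
  silent <- isSilentConsequence(calls$consequence, ...)
  keep <- calls$likelihood >= likelihood_min &
    calls$af >= af_range[1] & calls$af <= af_range[2] &
    calls$alt_depth >= ad_min &
    !is.na(silent) & !silent
  for (hl in hotspot_lists)
    keep <- keep & .in_hotspot_list(calls, hl)
  calls[keep, , drop = FALSE]
}

#' Per-sample hotspot mutation burden
#'
#' Counts surviving variant calls per sample; samples with no surviving call
#' get zero.
#'
#' @param filtered filtered variant-call data.frame.
#' @param all_samples character vector of every cohort sample identifier.
#' @return named integer vector of counts, one per `all_samples`.
#' @export
burdenPerSample <- function(filtered, all_samples) {
  counts <- table(factor(filtered$sample, levels = all_samples))
  stats::setNames(as.integer(counts), all_samples)
}

#' Association between mutation burden and a covariate
#'
#' Spearman rank correlation (two-sided) between per-sample burden and a
#' covariate attribute, over pairwise-complete records. A constant burden or
#' attribute yields an explicit not-a-value result rather than an error.
#'
#' @param burden named numeric vector from [burdenPerSample()].
#' @param covariates covariate data.frame with a `sample` column.
#' @param attribute name of the covariate column, e.g. `"pct_adipocyte"`.
#' @param method `"spearman"` (default) or `"pearson"`.
#' @return list with `rho`, `p`, `n`, `method`, `attribute`.
#' @export
burdenAssociation <- function(burden, covariates, attribute,
                              method = c("spearman", "pearson")) {
  method <- match.arg(method)
  if (!attribute %in% colnames(covariates))
    stop("attribute '", attribute, "' not in covariate table")
  x <- burden[covariates$sample]
  y <- covariates[[attribute]]
  ok <- !is.na(x) & !is.na(y)
  if (sum(ok) < 3L)
    stop("fewer than 3 complete burden/covariate pairs")
  x <- x[ok]; y <- y[ok]
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    return(list(rho = NA_real_, p = NA_real_, n = sum(ok), method = method,
                attribute = attribute))
  ct <- suppressWarnings(stats::cor.test(x, y, method = method,
                                         exact = FALSE))
  list(rho = unname(ct$estimate), p = ct$p.value, n = sum(ok),
       method = method, attribute = attribute)
}
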