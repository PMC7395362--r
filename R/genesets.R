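#' Select adipose-associated gene-set names
#'
#' Keeps names containing at least one include substring and no exclude
#' substring, case-insensitively on the raw set name, preserving input
#' order. The exclude list is user-extensible (the shipped terms are not
#' exhaustive).
#'
#' @param names character vector of gene-set names.
#' @param include substrings marking adipose relevance
#'   (default `"fat"`, `"adip"`, `"lip"`).
#' @param exclude substrings that veto a match
#'   (default `"sulfate"`, `"sulfation"`).
#' @return the selected subset of `names`, in stable order.
#' @examples
#' selectAdiposeSets(c("HALLMARK_ADIPOGENESIS", "GLYCOLIPID_SULFATION",
#'                     "DNA_REPAIR"))
#' @export
selectAdiposeSets <- function(names,
                              include = c("fat", "adip", "lip"),
                              exclude = c("sulfate", "sulfation")) {
  lc <- tolower(names)
  hit <- function(keys) Reduce(`|`, lapply(tolower(keys), function(k)
    grepl(k, lc, fixed = TRUE)), rep(FALSE, length(lc)))
  names[hit(include) & !hit(exclude)]
}

#' Summarize a gene-set enrichment report at an FDR threshold
#'
#' Counts records enriched at FDR q <= `q_threshold`, overall and within the
#' adipose-named subset, with fractions reported to one decimal percent and
#' a hypergeometric tail probability for adipose over-representation among
#' the enriched sets (relative to the adipose fraction of the whole
#' compendium represented by `records`).
#'
#' @param records enrichment-record data.frame (see [readGseaReport()]);
#'   needs columns `name` and `q`.
#' @param q_threshold FDR threshold (default 0.10).
#' @param include,exclude name-filter terms passed to [selectAdiposeSets()].
#' @return list with `n_total`, `n_adipose`, `n_enriched`,
#'   `n_adipose_enriched`, `pct_adipose_of_total`, `pct_adipose_of_enriched`
#'   (both one-decimal percents), and `p_hypergeometric`.
#' @export
summarizeEnrichment <- function(records, q_threshold = 0.10,
                                include = c("fat", "adip", "lip"),
                                exclude = c("sulfate", "sulfation")) {
  if (q_threshold < 0 || q_threshold > 1)
    stop("q_threshold must lie in [0, 1]")
  if (!nrow(records))
    return(list(n_total = 0L, n_adipose = 0L, n_enriched = 0L,
                n_adipose_enriched = 0L,
                pct_adipose_of_total = 0, pct_adipose_of_enriched = 0,
                p_hypergeometric = NA_real_))
  adipose <- records$name %in%
    selectAdiposeSets(records$name, include = include, exclude = exclude)
  enriched <- !is.na(records$q) & records$q <= q_threshold
  n_total <- nrow(records)
  n_adipose <- sum(adipose)
  n_enriched <- sum(enriched)
  n_both <- sum(adipose & enriched)
  p_hyper <- if (n_enriched > 0)
    stats::phyper(n_both - 1, n_adipose, n_total - n_adipose, n_enriched,
                  lower.tail = FALSE)
  else NA_real_
  list(n_total = n_total, n_adipose = n_adipose, n_enriched = n_enriched,
       n_adipose_enriched = n_both,
       pct_adipose_of_total = round(100 * n_adipose / n_total, 1),
       pct_adipose_of_enriched = if (n_enriched > 0)
         round(100 * n_both / n_enriched, 1) else 0,
       p_hypergeometric = p_hyper)
}
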