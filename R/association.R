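#' Compare a covariate between two groups
#'
#' Two-sided group comparison of one variable between the levels of a
#' grouping column: Wilcoxon rank-sum (`"wilcoxon"`), Welch t-test (`"t"`),
#' or chi-square on a 2 x 2 table for binary variables (`"chisq"`, without
#' continuity correction so the statistic equals the classic closed form).
#' Records with a missing group or variable value are dropped pairwise.
#'
#' @param data data.frame of per-sample records.
#' @param grouping name of the grouping column (must have exactly 2
#'   non-missing levels).
#' @param variable name of the variable column (numeric, or logical/binary
#'   for `"chisq"`).
#' @param test which test to run.
#' @return a `GroupComparison` list: `variable`, `test`, `groups`, per-group
#'   `n`, `mean`, `median`, `sd`, plus `statistic` and `p.value`.
#' @examples
#' d <- data.frame(g = rep(c("A", "B"), each = 3), x = c(1, 2, 3, 4, 5, 6))
#' compareGroups(d, "g", "x", test = "wilcoxon")$p.value  # exact 0.1
#' @export
compareGroups <- function(data, grouping, variable,
                          test = c("wilcoxon", "t", "chisq")) {
  test <- match.arg(test)
  g <- data[[grouping]]
  x <- data[[variable]]
  ok <- !is.na(g) & !is.na(x)
  g <- factor(g[ok])
  x <- x[ok]
  if (nlevels(g) != 2L)
    stop("grouping must have exactly 2 levels, got ", nlevels(g))
  parts <- split(as.numeric(x), g)
  if (any(lengths(parts) < if (test == "chisq") 1L else 2L))
    stop("empty or too-small group for variable ", variable)
  ht <- switch(test,
    wilcoxon = suppressWarnings(stats::wilcox.test(parts[[1]], parts[[2]])),
    t = stats::t.test(parts[[1]], parts[[2]]),
    chisq = {
      if (!all(x %in% c(0, 1)))
        stop("chisq comparison needs a binary (0/1 or logical) variable")
      suppressWarnings(stats::chisq.test(table(g, x), correct = FALSE))
    })
  structure(list(
    variable = variable, test = test, groups = levels(g),
    n = lengths(parts),
    mean = vapply(parts, mean, numeric(1)),
    median = vapply(parts, stats::median, numeric(1)),
    sd = vapply(parts, stats::sd, numeric(1)),
    statistic = unname(ht$statistic), p.value = ht$p.value),
    class = "GroupComparison")
}

#' @export
print.GroupComparison <- function(x, ...) {
  cat(sprintf("GroupComparison of '%s' (%s test)\n", x$variable, x$test))
  for (i in 1:2)
    cat(sprintf("  %s: n=%d mean=%.4g median=%.4g sd=%.4g\n",
                x$groups[i], x$n[i], x$mean[i], x$median[i], x$sd[i]))
  cat(sprintf("  statistic=%.4g, p=%.4g\n", x$statistic, x$p.value))
  invisible(x)
}

#' All-pairs correlation matrix with significance flags
#'
#' Pairwise-complete Pearson (or Spearman) correlations between numeric
#' variables, with two-sided p-values and significance flags at p < 0.05
#' (`"*"`) and p < 0.01 (`"**"`). Pearson p-values come from the exact t
#' distribution of r. Pairs involving a constant variable or fewer than 3
#' complete observations get `NA` entries and are flagged, never silently
#' dropped. No multiple-testing correction is applied by default (raw
#' p-value flags); set `p_adjust = "BH"` to adjust the off-diagonal p-values.
#'
#' @param data data.frame of numeric variables (e.g. covariates plus
#'   signature scores).
#' @param method `"pearson"` (default) or `"spearman"`.
#' @param p_adjust `"none"` (default) or a method for [stats::p.adjust()].
#' @return a `CorrelationMatrixResult` list with symmetric matrices `r`,
#'   `p`, `n`, a character `flags` matrix, and `method`.
#' @export
correlationMatrix <- function(data, method = c("pearson", "spearman"),
                              p_adjust = "none") {
  method <- match.arg(method)
  data <- as.data.frame(data)
  num <- vapply(data, is.numeric, logical(1))
  if (!all(num))
    stop("non-numeric variable(s): ",
         paste(colnames(data)[!num], collapse = ", "))
  vars <- colnames(data)
  k <- length(vars)
  r <- p <- n <- matrix(NA_real_, k, k, dimnames = list(vars, vars))
  for (i in seq_len(k)) {
    r[i, i] <- 1; p[i, i] <- 0; n[i, i] <- sum(!is.na(data[[i]]))
    for (j in seq_len(i - 1L)) {
      x <- data[[i]]; y <- data[[j]]
      ok <- !is.na(x) & !is.na(y)
      n[i, j] <- n[j, i] <- sum(ok)
      if (sum(ok) < 3L) next
      if (stats::sd(x[ok]) == 0 || stats::sd(y[ok]) == 0) next
      ct <- suppressWarnings(stats::cor.test(x[ok], y[ok], method = method,
                                             exact = FALSE))
      r[i, j] <- r[j, i] <- unname(ct$estimate)
      p[i, j] <- p[j, i] <- ct$p.value
    }
  }
  if (!identical(p_adjust, "none")) {
    lower <- lower.tri(p)
    p[lower] <- stats::p.adjust(p[lower], method = p_adjust)
    p[upper.tri(p)] <- t(p)[upper.tri(p)]
  }
  flags <- matrix("", k, k, dimnames = list(vars, vars))
  flags[!is.na(p) & p < 0.05] <- "*"
  flags[!is.na(p) & p < 0.01] <- "**"
  flags[is.na(r)] <- "NA"
  diag(flags) <- ""
  structure(list(r = r, p = p, n = n, flags = flags, method = method),
            class = "CorrelationMatrixResult")
}

#' @export
print.CorrelationMatrixResult <- function(x, ...) {
  cat(sprintf("CorrelationMatrixResult (%s), %d variables\n",
              x$method, ncol(x$r)))
  print(round(x$r, 3))
  invisible(x)
}

#' Tissue-composition comparison between phenotypes
#'
#' Wilcoxon rank-sum comparison of each cell-composition compartment
#' (percent adipocyte, stromal, epithelial nuclei) between Active and
#' Inactive samples, with the fold change of group means, plus an optional
#' box-plot figure.
#'
#' @param cov covariate data.frame with `sample` and the compartment
#'   columns.
#' @param labels named character vector (`Active`/`Inactive` by sample) or
#'   an assignment data.frame with `sample` and `label` columns.
#' @param compartments compartment column names.
#' @param file optional figure path (written via [ggplot2::ggsave()]).
#' @return list with `table` (data.frame: compartment, group means, fold
#'   change Active/Inactive, p), `comparisons` (named `GroupComparison`
#'   list) and `plot` (ggplot object).
#' @export
compositionReport <- function(cov, labels,
                              compartments = c("pct_adipocyte", "pct_stromal",
                                               "pct_epithelial"),
                              file = NULL) {
  if (is.data.frame(labels))
    labels <- stats::setNames(labels$label, labels$sample)
  d <- cov
  d$label <- unname(labels[d$sample])
  d <- d[!is.na(d$label), , drop = FALSE]
  if (length(unique(d$label)) < 2L)
    stop("both Active and Inactive labels are required")
  comparisons <- lapply(compartments, function(comp)
    compareGroups(d, "label", comp, test = "wilcoxon"))
  names(comparisons) <- compartments
  tab <- do.call(rbind, lapply(compartments, function(comp) {
    gc <- comparisons[[comp]]
    data.frame(compartment = comp,
               mean_active = unname(gc$mean["Active"]),
               mean_inactive = unname(gc$mean["Inactive"]),
               fold_change = unname(gc$mean["Active"] / gc$mean["Inactive"]),
               p = gc$p.value, stringsAsFactors = FALSE)
  }))
  long <- do.call(rbind, lapply(compartments, function(comp)
    data.frame(label = d$label, compartment = comp, pct = d[[comp]])))
  plt <- ggplot2::ggplot(long, ggplot2::aes(x = .data$label, y = .data$pct,
                                            fill = .data$label)) +
    ggplot2::geom_boxplot(show.legend = FALSE) +
    ggplot2::facet_wrap(~compartment, scales = "free_y") +
    ggplot2::labs(x = NULL, y = "% nuclei") +
    ggplot2::theme_bw()
  if (!is.null(file))
    ggplot2::ggsave(file, plt, width = 7, height = 3.2)
  list(table = tab, comparisons = comparisons, plot = plt)
}
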