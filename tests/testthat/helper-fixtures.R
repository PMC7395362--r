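# shared fixtures, all generated in code

# small cohort for fast end-to-end tests
smallSpec <- function(...) {
  args <- list(...)
  defaults <- list(n_samples = c(F = 30L, P = 20L),
                   active_fraction = c(F = 0.5, P = 0.5),
                   n_signature_up = 20L, n_signature_down = 20L,
                   n_background = 60L)
  do.call(cohortSpec, utils::modifyList(defaults, args))
}

# tiny hand-built expression object
toyExpr <- function(values = matrix(c(1, 3, 7, 0, 2, 5), nrow = 2,
                                    byrow = TRUE,
                                    dimnames = list(c("G1", "G2"),
                                                    c("s1", "s2", "s3"))),
                    batch = c(s1 = "F", s2 = "F", s3 = "F"),
                    scale = "tpm") {
  ExpressionExperiment(values, batch = batch, scale = scale)
}

# accuracy of predicted Active/Inactive labels against truth, after the
# optimal matching of the two labels (clustering has no inherent polarity
# under the null)
labelAccuracy <- function(pred, truth, match_labels = FALSE) {
  a <- mean(pred[names(truth)] == truth)
  if (match_labels) max(a, 1 - a) else a
}

truthLabels <- function(cohort) {
  stats::setNames(cohort$truth$phenotype$phenotype,
                  cohort$truth$phenotype$sample)
}

predictedLabels <- function(ph) {
  stats::setNames(ph$assignment$label, ph$assignment$sample)
}

# independent brute-force oracle for the two-sided exact Wilcoxon rank-sum
# p-value: enumerate every assignment of ranks to group 1
exactWilcoxonP <- function(x, y) {
  n1 <- length(x)
  pooled <- c(x, y)
  ranks <- rank(pooled)
  w_obs <- sum(ranks[seq_len(n1)]) - n1 * (n1 + 1) / 2   # Mann-Whitney U
  combs <- utils::combn(length(pooled), n1)
  u_all <- apply(combs, 2L, function(idx)
    sum(ranks[idx]) - n1 * (n1 + 1) / 2)
  p_le <- mean(u_all <= w_obs)
  p_ge <- mean(u_all >= w_obs)
  min(1, 2 * min(p_le, p_ge))
}
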