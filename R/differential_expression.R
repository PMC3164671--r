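# Two-group differential expression on log2 values: per-gene Welch t test,
# Benjamini-Hochberg FDR, and the fold-change / p-value threshold filter.
# Fold changes are reported linear-scale treated/control (down-regulation
# < 1), matching how microarray target tables are usually printed.

#' Per-gene Welch two-sample t test on a log2 expression matrix
#'
#' @param expr numeric matrix, genes x samples, log2 scale, rownames =
#'   gene ids.
#' @param groups factor/character per sample with levels `control`,
#'   `treated`.
#' @return data frame: `gene_id`, `log2fc`, `fold_change`
#'   (`2^(mean_treated - mean_control)`), `p_value`, `q_value` (BH over all
#'   tested genes), `direction` (`"up"`, `"down"`, `"unchanged"`; set by
#'   sign of the fold change, before any thresholding the direction of
#'   genes with fold change 1 is `"unchanged"`).
#' @export
de_test <- function(expr, groups) {
  groups <- as.character(groups)
  if (!all(groups %in% c("control", "treated")))
    stopf("groups must be 'control' or 'treated'")
  a <- expr[, groups == "control", drop = FALSE]
  b <- expr[, groups == "treated", drop = FALSE]
  if (ncol(a) < 2L || ncol(b) < 2L) stopf("need >= 2 samples per group")
  if (anyNA(expr)) stopf("expression matrix contains missing values")
  ma <- rowMeans(a); mb <- rowMeans(b)
  va <- apply(a, 1, stats::var); vb <- apply(b, 1, stats::var)
  na <- ncol(a); nb <- ncol(b)
  se2 <- va / na + vb / nb
  tstat <- (mb - ma) / sqrt(se2)
  df <- se2^2 / ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
  p <- 2 * stats::pt(abs(tstat), df, lower.tail = FALSE)
  # degenerate rows: both variances zero
  degen <- se2 == 0
  p[degen] <- ifelse(mb[degen] == ma[degen], 1, 0)
  lfc <- mb - ma
  data.frame(gene_id = rownames(expr), log2fc = lfc, fold_change = 2^lfc,
             p_value = p, q_value = bh_fdr(p),
             direction = ifelse(lfc > 0, "up",
                                ifelse(lfc < 0, "down", "unchanged")),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Benjamini-Hochberg step-up q-values
#'
#' `q_i = min_{j: rank_j >= rank_i} p_(j) * n / rank_j`, capped at 1;
#' order-preserving with the input vector.
#'
#' @param p numeric vector of p-values in `[0, 1]`.
#' @return q-values in input order.
#' @export
bh_fdr <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE) || anyNA(p))
    stopf("p-values must lie in [0, 1]")
  n <- length(p)
  if (n == 0L) return(numeric(0))
  o <- order(p)
  q_sorted <- pmin(1, rev(cummin(rev(p[o] * n / seq_len(n)))))
  q <- numeric(n)
  q[o] <- q_sorted
  q
}

#' Apply fold-change and p-value cut-offs to DE results
#'
#' Keeps genes with `fold_change >= fc_cut` or `fold_change <= 1/fc_cut`
#' (absolute fold-change cut-off) and `p_value < p_cut`; sets direction from
#' the fold change.
#'
#' @param results data frame from [de_test()] (needs `fold_change`,
#'   `p_value`).
#' @param fc_cut absolute fold-change cut-off (>= 1; default 1.25).
#' @param p_cut p-value cut-off (default 0.05).
#' @return filtered data frame with `direction` in `{"up", "down"}`.
#' @export
apply_thresholds <- function(results, fc_cut = 1.25, p_cut = 0.05) {
  if (fc_cut < 1) stopf("fc_cut must be >= 1")
  keep <- (results$fold_change >= fc_cut |
             results$fold_change <= 1 / fc_cut) & results$p_value < p_cut
  out <- results[keep, , drop = FALSE]
  out$direction <- ifelse(out$fold_change >= 1, "up", "down")
  rownames(out) <- NULL
  out
}

#' Two-tailed Fisher exact test on a 2x2 table
#'
#' Two-tailed p is the sum of hypergeometric probabilities, over all tables
#' with the observed margins, that do not exceed the observed table's
#' probability (with a relative tolerance of 1e-7 on the comparison). Any
#' zero margin gives p = 1.
#'
#' @param a,b,c,d non-negative integer cell counts, laid out as
#'   rows = condition 1 (a, b), condition 2 (c, d).
#' @return the two-tailed p-value.
#' @export
fisher_exact_two_tailed <- function(a, b, c, d) {
  for (x in c(a, b, c, d)) if (!is_count(x)) stopf("counts must be non-negative integers")
  m <- a + b          # row 1 margin
  n2 <- c + d         # row 2 margin
  k <- a + c          # column 1 margin
  if (m == 0 || n2 == 0 || k == 0 || b + d == 0) return(1)
  support <- max(0, k - n2):min(k, m)
  probs <- stats::dhyper(support, m, n2, k)
  p_obs <- stats::dhyper(a, m, n2, k)
  p <- sum(probs[probs <= p_obs * (1 + 1e-7)])
  min(1, p)
}
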