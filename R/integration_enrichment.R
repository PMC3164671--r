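# Integration of expression-responsive genes with peak-assigned genes into a
# direct-target list, plus gene-set enrichment (one-tailed hypergeometric
# Fisher p and the conservative EASE variant) and the two-tailed
# overrepresentation test for a special gene class.

#' Intersect differential-expression calls with peak assignments
#'
#' One target per gene present in both lists; peak ids are aggregated,
#' direction comes from the sign of the log2 fold change. The operation is
#' order-independent and idempotent.
#'
#' @param de_genes data frame of threshold-filtered DE results (needs
#'   `gene_id`, `fold_change`; see [apply_thresholds()]).
#' @param assignments peak assignments from [assign_peaks()].
#' @return data frame: `gene_id`, `symbol`, `peak_ids`
#'   (comma-separated), `n_peaks`, `fold_change`, `p_value`, `direction`.
#' @export
integrate_targets <- function(de_genes, assignments) {
  common <- intersect(de_genes$gene_id, assignments$gene_id)
  empty <- data.frame(gene_id = character(), symbol = character(),
                      peak_ids = character(), n_peaks = integer(),
                      fold_change = numeric(), p_value = numeric(),
                      direction = character(), stringsAsFactors = FALSE)
  if (!length(common)) return(empty)
  common <- sort(common)
  de <- de_genes[match(common, de_genes$gene_id), , drop = FALSE]
  out <- data.frame(gene_id = common,
                    symbol = assignments$symbol[match(common,
                                                      assignments$gene_id)],
                    peak_ids = vapply(common, function(g)
                      paste(sort(unique(
                        assignments$peak_id[assignments$gene_id == g])),
                        collapse = ","), character(1)),
                    n_peaks = vapply(common, function(g)
                      length(unique(
                        assignments$peak_id[assignments$gene_id == g])),
                      integer(1)),
                    fold_change = de$fold_change,
                    p_value = de$p_value,
                    direction = ifelse(de$fold_change >= 1, "up", "down"),
                    stringsAsFactors = FALSE, row.names = NULL)
  out
}

#' Summary counts for an integrated target list
#' @param targets output of [integrate_targets()].
#' @return list with `total`, `up`, `down`.
#' @export
target_summary <- function(targets) {
  list(total = nrow(targets),
       up = sum(targets$direction == "up"),
       down = sum(targets$direction == "down"))
}

#' Gene-set enrichment with Fisher and EASE statistics
#'
#' For each set: `fisher_p` is the one-tailed hypergeometric upper-tail
#' probability of drawing at least the observed overlap; `ease_p` is the
#' same statistic with the overlap reduced by one (never below zero), a
#' conservative penalisation of single-gene overlaps. Sets are intersected
#' with the universe before testing; q-values are BH across all sets.
#'
#' @param targets character vector of target gene ids (must lie in
#'   `universe`).
#' @param collections named list of character vectors (gene sets), or a
#'   two-column data frame `set_id`, `gene_id`.
#' @param universe character vector of all testable gene ids.
#' @return data frame: `set_id`, `overlap`, `set_size`, `n_targets`,
#'   `universe_size`, `fisher_p`, `ease_p`, `q_value`.
#' @export
gene_set_enrichment <- function(targets, collections, universe) {
  universe <- unique(universe)
  if (!length(universe)) stopf("empty universe")
  targets <- unique(targets)
  if (!all(targets %in% universe))
    stopf("targets outside the universe: %s",
          paste(utils::head(setdiff(targets, universe), 3), collapse = ", "))
  if (is.data.frame(collections))
    collections <- split(collections$gene_id, collections$set_id)
  N <- length(universe); n <- length(targets)
  res <- lapply(names(collections), function(id) {
    set <- intersect(unique(collections[[id]]), universe)
    K <- length(set)
    a <- length(intersect(set, targets))
    data.frame(set_id = id, overlap = a, set_size = K, n_targets = n,
               universe_size = N,
               fisher_p = hyper_upper_tail(a, K, N, n),
               ease_p = hyper_upper_tail(max(a - 1L, 0L), K, N, n),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$q_value <- bh_fdr(out$fisher_p)
  rownames(out) <- NULL
  out
}

#' Hypergeometric upper-tail probability
#'
#' `P(X >= a)` for `X ~ Hypergeometric(K successes, N - K failures, n
#' draws)`: the one-tailed Fisher enrichment p-value.
#'
#' @param a observed overlap.
#' @param K gene-set size (successes in the universe).
#' @param N universe size.
#' @param n number of draws (target-list size).
#' @return the upper-tail probability.
#' @export
hyper_upper_tail <- function(a, K, N, n) {
  if (a <= 0) return(1)
  stats::phyper(a - 1, K, N - K, n, lower.tail = FALSE)
}

#' Two-tailed overrepresentation test for a special gene class
#'
#' Builds the 2x2 table (special vs not) x (altered vs not) over the
#' universe and delegates to [fisher_exact_two_tailed()].
#'
#' @param special_genes character vector (e.g. tissue-enriched genes).
#' @param altered_genes character vector (e.g. genes altered at p < 0.05).
#' @param universe character vector containing both.
#' @return two-tailed Fisher p-value.
#' @export
overrepresentation_test <- function(special_genes, altered_genes, universe) {
  universe <- unique(universe)
  special <- intersect(unique(special_genes), universe)
  altered <- intersect(unique(altered_genes), universe)
  a <- length(intersect(special, altered))
  b <- length(setdiff(special, altered))
  c_ <- length(setdiff(altered, special))
  d <- length(universe) - a - b - c_
  fisher_exact_two_tailed(a, b, c_, d)
}
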