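# Branch-length conservation scoring of motif instances.
#
# A motif instance found in the reference is checked in every aligned
# species; the conservation score is the total branch length of the minimal
# connected subtree (Steiner subtree) of the phylogeny spanning the species
# in which the instance is preserved. The score is in substitutions/site
# summed over edges: > 1 marks a non-trivial conserved subset of species,
# > 2 a deeply conserved one. A motif is retained when at least `min_hits`
# distinct peak sequences carry an instance above the score threshold.

#' Species in which a motif instance is preserved
#'
#' A species matches when the instance's k-mer occurs, on either strand, in
#' the species' ungapped sequence restricted to the instance's alignment
#' columns padded by `window_slack` columns on each side. The reference
#' species is always included. For PWM instances, pass the explicit matched
#' word as `kmer` (the scanner reports it) or supply `pwm`/`bg`/`z_cut` to
#' re-scan the species window at the same threshold used on the reference.
#'
#' @param block alignment block (see [read_alignment_blocks()]).
#' @param offset 0-based offset of the instance within the reference
#'   (ungapped) sequence.
#' @param kmer the instance's k-mer (used for exact matching).
#' @param window_slack padding in alignment columns (default 10).
#' @param pwm,bg,z_cut optional log-odds PWM, background model and Z cut-off
#'   for PWM-based matching instead of exact k-mer matching.
#' @return character vector of matching species (reference included).
#' @export
species_matches <- function(block, offset, kmer, window_slack = 10L,
                            pwm = NULL, bg = NULL, z_cut = NULL) {
  ref_row <- block$rows[[block$ref_species]]
  cols_per_ref <- which(strsplit(ref_row, "", fixed = TRUE)[[1]] != "-")
  k <- nchar(kmer)
  if (offset < 0L || offset + k > length(cols_per_ref))
    stopf("instance at offset %d outside block (reference length %d)",
          offset, length(cols_per_ref))
  col_lo <- max(1L, cols_per_ref[offset + 1L] - window_slack)
  col_hi <- min(nchar(ref_row), cols_per_ref[offset + k] + window_slack)
  matched <- character(0)
  for (sp in names(block$rows)) {
    if (sp == block$ref_species) { matched <- c(matched, sp); next }
    seg <- substr(block$rows[[sp]], col_lo, col_hi)
    seg <- toupper(gsub("-", "", seg, fixed = TRUE))
    if (!nzchar(seg)) next
    hit <- if (is.null(pwm)) {
      grepl(toupper(kmer), seg, fixed = TRUE) ||
        grepl(revcomp(toupper(kmer)), seg, fixed = TRUE)
    } else {
      if (nchar(seg) < nrow(pwm$weights)) FALSE
      else {
        hits <- scan_sequence(seg, pwm, both_strands = TRUE)
        nrow(hits) > 0 && any(zscore_p(hits$score, bg)$z >= z_cut)
      }
    }
    if (hit) matched <- c(matched, sp)
  }
  matched
}

#' Branch-length score of a matched species set
#'
#' Total branch length of the minimal connected subtree of `tree` spanning
#' `matched` (the union of the unique tree paths between the matched
#' leaves); 0 when only the reference matches. The score depends only on
#' the unrooted topology and branch lengths.
#'
#' @param tree an [ape::phylo] tree with branch lengths.
#' @param matched character vector of matched leaf names.
#' @param reference reference species (must be in `matched`).
#' @return the branch-length score.
#' @export
branch_length_score <- function(tree, matched, reference) {
  if (!all(matched %in% tree$tip.label))
    stopf("species not in tree: %s",
          paste(setdiff(matched, tree$tip.label), collapse = ", "))
  if (!reference %in% matched) stopf("reference must be among matched species")
  matched <- unique(matched)
  if (length(matched) < 2L) return(0)
  tips <- match(matched, tree$tip.label)
  nn <- max(tree$edge)
  parent <- integer(nn); parent_edge <- integer(nn); depth <- integer(nn)
  root <- setdiff(tree$edge[, 1], tree$edge[, 2])[1]
  # BFS orientation from the root
  kids <- split(seq_len(nrow(tree$edge)), tree$edge[, 1])
  queue <- root; depth[root] <- 0L
  while (length(queue)) {
    nd <- queue[1]; queue <- queue[-1]
    for (e in kids[[as.character(nd)]]) {
      ch <- tree$edge[e, 2]
      parent[ch] <- nd; parent_edge[ch] <- e; depth[ch] <- depth[nd] + 1L
      queue <- c(queue, ch)
    }
  }
  # union of edges on paths from the first matched tip to the others
  in_sub <- rep(FALSE, nrow(tree$edge))
  path_to_root <- function(v) {
    es <- integer(0)
    while (v != root) { es <- c(es, parent_edge[v]); v <- parent[v] }
    es
  }
  base <- path_to_root(tips[1])
  for (t in tips[-1]) {
    other <- path_to_root(t)
    # symmetric difference = path between the two tips
    in_sub[setdiff(union(base, other), intersect(base, other))] <- TRUE
  }
  sum(tree$edge.length[in_sub])
}

#' Apply the conservation retention rule to motif instances
#'
#' A motif is retained when at least `min_hits` distinct peak sequences
#' (`seq_id`) carry an instance with branch-length score strictly above
#' `bls_threshold`.
#'
#' @param instances data frame with columns `motif`, `seq_id`, `bls`.
#' @param bls_threshold score threshold (default 1).
#' @param min_hits minimal number of distinct qualifying sequences
#'   (default 4).
#' @return data frame: `motif`, `qualifying_hits`, `retained`.
#' @export
retain_motifs <- function(instances, bls_threshold = 1, min_hits = 4L) {
  if (!nrow(instances))
    return(data.frame(motif = character(), qualifying_hits = integer(),
                      retained = logical(), stringsAsFactors = FALSE))
  qual <- instances[instances$bls > bls_threshold, , drop = FALSE]
  motifs <- unique(instances$motif)
  hits <- vapply(motifs, function(m)
    length(unique(qual$seq_id[qual$motif == m])), integer(1))
  data.frame(motif = motifs, qualifying_hits = hits,
             retained = hits >= min_hits, stringsAsFactors = FALSE,
             row.names = NULL)
}

#' Score conservation of k-mer instances across alignment blocks
#'
#' Convenience wrapper: for each instance, finds its block (by `seq_id`),
#' computes the matched species set and the branch-length score.
#'
#' @param instances data frame with `seq_id`, `offset`, `kmer` (and
#'   optionally `motif`; defaults to the k-mer).
#' @param blocks list of alignment blocks with `peak_id` fields.
#' @param tree [ape::phylo] tree covering all alignment species.
#' @param window_slack passed to [species_matches()].
#' @return `instances` with added `n_species` and `bls` columns.
#' @export
score_conservation <- function(instances, blocks, tree, window_slack = 10L) {
  ids <- vapply(blocks, function(b) b$peak_id, character(1))
  sp_all <- unique(unlist(lapply(blocks, function(b) names(b$rows))))
  if (!all(sp_all %in% tree$tip.label))
    stopf("alignment names species absent from the tree: %s",
          paste(setdiff(sp_all, tree$tip.label), collapse = ", "))
  n <- nrow(instances)
  bls <- numeric(n); nsp <- integer(n)
  for (i in seq_len(n)) {
    b <- blocks[[match(instances$seq_id[i], ids)]]
    if (is.null(b)) stopf("no alignment block for %s", instances$seq_id[i])
    m <- species_matches(b, instances$offset[i], instances$kmer[i],
                         window_slack)
    nsp[i] <- length(m)
    bls[i] <- branch_length_score(tree, m, b$ref_species)
  }
  instances$n_species <- nsp
  instances$bls <- bls
  if (is.null(instances$motif)) instances$motif <- instances$kmer
  instances
}
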