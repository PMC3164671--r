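# Independent brute-force oracles and tiny fixture builders used across the
# suite. Every oracle deliberately recomputes from first principles (loops,
# enumeration) rather than calling the code path it checks.

# ---- fixture builders -------------------------------------------------------

make_peaks <- function(chrom, start, end, id = NULL, summit = NA_integer_) {
  n <- length(start)
  data.frame(peak_id = if (is.null(id)) sprintf("p%02d", seq_len(n))
               else rep_len(id, n),
             chrom = rep_len(chrom, n), start = as.integer(start),
             end = as.integer(end),
             summit_offset = rep_len(as.integer(summit), n),
             tag_count = rep_len(NA_integer_, n), stringsAsFactors = FALSE)
}

make_genes <- function(chrom, start, end, strand, id = NULL,
                       exon_starts = NULL, exon_ends = NULL) {
  n <- length(start)
  g <- data.frame(gene_id = if (is.null(id)) sprintf("g%02d", seq_len(n)) else id,
                  symbol = sprintf("Sym%02d", seq_len(n)),
                  chrom = rep_len(chrom, n), strand = rep_len(strand, n),
                  start = as.integer(start), end = as.integer(end),
                  stringsAsFactors = FALSE)
  g$exon_starts <- if (is.null(exon_starts))
    lapply(seq_len(n), function(i) g$start[i]) else exon_starts
  g$exon_ends <- if (is.null(exon_ends))
    lapply(seq_len(n), function(i) g$start[i] + 1L) else exon_ends
  g
}

random_dna <- function(n, len) {
  vapply(seq_len(n), function(i)
    paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = ""),
    character(1))
}

# ---- peak annotation oracle -------------------------------------------------

# All-pairs distance scan, entirely loop-based.
oracle_assignments <- function(peaks, genes, window = 10000, inner = 1000) {
  rows <- list()
  for (i in seq_len(nrow(peaks))) {
    anchor <- if (is.na(peaks$summit_offset[i]))
      floor((peaks$start[i] + peaks$end[i]) / 2)
    else peaks$start[i] + peaks$summit_offset[i]
    for (j in seq_len(nrow(genes))) {
      if (peaks$chrom[i] != genes$chrom[j]) next
      tss <- if (genes$strand[j] == "+") genes$start[j] else genes$end[j] - 1
      d <- anchor - tss
      if (genes$strand[j] == "-") d <- -d
      if (abs(d) > window) next
      rows[[length(rows) + 1L]] <- data.frame(
        peak_id = peaks$peak_id[i], gene_id = genes$gene_id[j],
        signed_distance = d,
        window_class = if (abs(d) <= inner) "within_1kb" else "within_10kb",
        stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) return(NULL)
  do.call(rbind, rows)
}

# Set-algebra location classifier over explicit base sets.
oracle_location <- function(peak, gene) {
  pk <- seq(peak$start, peak$end - 1)
  tss <- if (gene$strand == "+") gene$start else gene$end - 1
  if (tss %in% pk) return("tss_overlap")
  exon_bases <- unlist(lapply(seq_along(gene$exon_starts[[1]]), function(i)
    seq(gene$exon_starts[[1]][i], gene$exon_ends[[1]][i] - 1)))
  if (length(intersect(pk, exon_bases)) > 0) return("exon")
  body <- seq(gene$start, gene$end - 1)
  if (all(pk %in% body)) return("intron")
  anchor <- if (is.na(peak$summit_offset)) floor((peak$start + peak$end) / 2)
    else peak$start + peak$summit_offset
  d <- anchor - tss
  if (gene$strand == "-") d <- -d
  if (d < 0) "upstream_5prime" else "downstream_3prime"
}

# ---- statistics oracles -----------------------------------------------------

# BH step-up by the definition q_i = min_{j: p_(j) >= p_(i)} p_(j) * n / j.
oracle_bh <- function(p) {
  n <- length(p)
  r <- rank(p, ties.method = "first")
  vapply(seq_len(n), function(i) {
    js <- which(rank(p, ties.method = "first") >= r[i])
    min(1, min(p[js] * n / r[js]))
  }, numeric(1))
}

# Two-tailed Fisher by direct enumeration with factorial arithmetic.
oracle_fisher2 <- function(a, b, c, d) {
  m <- a + b; n2 <- c + d; k <- a + c
  if (m == 0 || n2 == 0 || k == 0 || b + d == 0) return(1)
  lp <- function(x) lchoose(m, x) + lchoose(n2, k - x) - lchoose(m + n2, k)
  supp <- max(0, k - n2):min(k, m)
  probs <- exp(vapply(supp, lp, numeric(1)))
  p_obs <- exp(lp(a))
  min(1, sum(probs[probs <= p_obs * (1 + 1e-7)]))
}

# Hypergeometric upper tail by summation.
oracle_hyper_upper <- function(a, K, N, n) {
  if (a <= 0) return(1)
  xs <- a:min(K, n)
  sum(exp(lchoose(K, xs) + lchoose(N - K, n - xs) - lchoose(N, n)))
}

# ---- motif oracles ----------------------------------------------------------

oracle_scan <- function(seq, weights, both_strands = TRUE) {
  revc <- function(s) paste(rev(chartr("ACGT", "TGCA",
    strsplit(s, "")[[1]])), collapse = "")
  score_one <- function(s) {
    L <- nrow(weights)
    out <- numeric(0)
    for (o in seq_len(nchar(s) - L + 1)) {
      w <- substr(s, o, o + L - 1)
      ch <- strsplit(w, "")[[1]]
      if (any(!ch %in% c("A", "C", "G", "T"))) { out[o] <- -Inf; next }
      sc <- 0
      for (j in seq_len(L))
        sc <- sc + weights[j, match(ch[j], c("A", "C", "G", "T"))]
      out[o] <- sc
    }
    out
  }
  fw <- score_one(seq)
  res <- data.frame(offset = seq_along(fw) - 1L, strand = "+", score = fw)
  if (both_strands) {
    rv <- score_one(revc(seq))
    n <- length(rv)
    res <- rbind(res, data.frame(offset = rev(seq_len(n)) - 1L, strand = "-",
                                 score = rv))
  }
  res[is.finite(res$score), ]
}

oracle_kmer_support <- function(seqs, k) {
  revc <- function(s) paste(rev(chartr("ACGT", "TGCA",
    strsplit(s, "")[[1]])), collapse = "")
  canon <- function(w) { r <- revc(w); if (w <= r) w else r }
  counts <- new.env()
  for (s in toupper(seqs)) {
    seen <- character(0)
    for (o in seq_len(max(0, nchar(s) - k + 1))) {
      w <- substr(s, o, o + k - 1)
      if (grepl("[^ACGT]", w)) next
      seen <- c(seen, canon(w))
    }
    for (w in unique(seen))
      assign(w, (if (exists(w, counts)) get(w, counts) else 0L) + 1L, counts)
  }
  out <- sort(unlist(as.list(counts)), decreasing = TRUE)
  out
}

# ---- tree oracle ------------------------------------------------------------

# Minimal connected edge subset containing all matched leaves, by exhaustive
# enumeration over edge subsets.
oracle_steiner <- function(tree, matched) {
  if (length(unique(matched)) < 2) return(0)
  ne <- nrow(tree$edge)
  tips <- match(unique(matched), tree$tip.label)
  best <- Inf
  for (mask in 0:(2^ne - 1)) {
    idx <- which(bitwAnd(mask, 2^(seq_len(ne) - 1)) > 0)
    nodes <- unique(as.vector(tree$edge[idx, , drop = FALSE]))
    if (!all(tips %in% nodes)) next
    # connectivity check over the chosen edges
    if (length(idx)) {
      comp <- nodes[1]
      repeat {
        grow <- unique(as.vector(tree$edge[idx, ][
          tree$edge[idx, 1] %in% comp | tree$edge[idx, 2] %in% comp, ]))
        if (all(grow %in% comp)) break
        comp <- unique(c(comp, grow))
      }
      if (!all(nodes %in% comp)) next
    } else if (length(tips) > 1) next
    w <- sum(tree$edge.length[idx])
    if (w < best) best <- w
  }
  best
}

random_tree <- function(n_leaves) {
  tr <- ape::rtree(n_leaves, br = function(n) runif(n, 0.05, 0.5))
  tr$tip.label <- paste0("sp", seq_len(n_leaves))
  tr
}
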