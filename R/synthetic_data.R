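# Synthetic data with known ground truth: repeat-masked genome, gene models,
# peaks with planted motif instances, alignments evolved along a phylogeny,
# and a two-group expression matrix with planted fold changes.
#
# Everything is a pure function of the config (seed mandatory), so every
# downstream stage can be tested against recorded truth.

#' Simulation configuration
#'
#' Defaults state the world the generator emulates: binding regions of
#' 61-428 bp, four replicates per expression group, planted effects of
#' 2-fold (the scale of the strongest validated targets, well above the
#' 1.25-fold detection cut-off, and large enough that a 4-vs-4 Welch test
#' at log2 noise 0.2 has >99% power) and a motif planted in 60% of peaks.
#'
#' @param genome_length genome size in bp (single chromosome `chrS`).
#' @param gc_fraction genomic GC content.
#' @param repeat_fraction fraction of positions lowercase-masked, in
#'   contiguous runs.
#' @param n_genes,n_peaks numbers of gene models and peaks.
#' @param peak_length_range inclusive range of peak lengths in bp.
#' @param motif planted motif (k-mer, uppercase).
#' @param planting_rate fraction of peaks that carry the motif; planting is
#'   count-based (exactly `floor(rate * n_peaks)` peaks, chosen by seeded
#'   shuffle).
#' @param frac_within_10kb,frac_within_1kb fractions of peaks placed with
#'   their anchor within 10 kb (respectively 1 kb) of a TSS.
#' @param n_samples_per_group expression replicates per group.
#' @param de_effect absolute planted group effect on the log2 scale.
#' @param noise_sd log2-scale replicate noise standard deviation.
#' @param frac_targets_proximal fraction of planted expression targets drawn
#'   from peak-proximal genes.
#' @param n_de_targets number of genes with a planted expression effect.
#' @param tree Newick string or `ape::phylo` tree used to evolve alignments;
#'   the reference species is the first leaf.
#' @param background_conservation_rate unused scaling reserved for background
#'   columns (0 = neutral evolution at branch lengths as given).
#' @param motif_conservation_rate in `[0,1]`; motif columns evolve with
#'   branch lengths scaled by `1 - rate` (1 = perfectly conserved).
#' @param seed RNG seed (mandatory).
#' @return a list with class `sim_config`.
#' @export
sim_config <- function(genome_length = 600000L,
                       gc_fraction = 0.42,
                       repeat_fraction = 0.2,
                       n_genes = 60L,
                       n_peaks = 50L,
                       peak_length_range = c(61L, 428L),
                       motif = "ACCACA",
                       planting_rate = 0.6,
                       frac_within_10kb = 0.7,
                       frac_within_1kb = 0.15,
                       n_samples_per_group = 4L,
                       de_effect = 1,
                       noise_sd = 0.2,
                       frac_targets_proximal = 1,
                       n_de_targets = 20L,
                       tree = default_species_tree(),
                       background_conservation_rate = 0,
                       motif_conservation_rate = 0.95,
                       seed = NULL) {
  if (is.null(seed)) stopf("sim_config: seed is mandatory")
  rates <- c(repeat_fraction, planting_rate, frac_within_10kb, frac_within_1kb,
             frac_targets_proximal, motif_conservation_rate,
             background_conservation_rate)
  if (any(rates < 0 | rates > 1)) stopf("rates must lie in [0, 1]")
  if (repeat_fraction >= 1) stopf("repeat_fraction must be < 1")
  if (gc_fraction <= 0 || gc_fraction >= 1) stopf("gc_fraction must be in (0,1)")
  if (noise_sd <= 0) stopf("noise_sd must be > 0")
  if (frac_within_1kb > frac_within_10kb)
    stopf("frac_within_1kb cannot exceed frac_within_10kb")
  if (is.character(tree)) tree <- ape::read.tree(text = tree)
  if (genome_length < 10L * max(peak_length_range))
    stopf("genome_length must be >= 10x the maximum peak length")
  structure(list(genome_length = as.integer(genome_length),
                 gc_fraction = gc_fraction,
                 repeat_fraction = repeat_fraction,
                 n_genes = as.integer(n_genes), n_peaks = as.integer(n_peaks),
                 peak_length_range = as.integer(peak_length_range),
                 motif = toupper(motif), planting_rate = planting_rate,
                 frac_within_10kb = frac_within_10kb,
                 frac_within_1kb = frac_within_1kb,
                 n_samples_per_group = as.integer(n_samples_per_group),
                 de_effect = de_effect, noise_sd = noise_sd,
                 frac_targets_proximal = frac_targets_proximal,
                 n_de_targets = as.integer(n_de_targets),
                 tree = tree,
                 background_conservation_rate = background_conservation_rate,
                 motif_conservation_rate = motif_conservation_rate,
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Default eight-species phylogeny for alignment simulation
#'
#' Branch lengths in substitutions/site; total tree length 2.17, so a fully
#' conserved instance scores well above the usual branch-length-score
#' threshold of 1 and an instance conserved only in the two closest species
#' scores well below it.
#'
#' @return Newick string; the reference species is `mm`.
#' @export
default_species_tree <- function() {
  paste0("(((mm:0.08,rn:0.09):0.25,(hg:0.07,pt:0.06):0.22):0.3,",
         "((cf:0.15,bt:0.18):0.27,(md:0.35,gg:0.1):0.1):0.25);")
}

#' Generate a repeat-masked genome
#'
#' Bases are i.i.d. at the configured GC fraction; a `repeat_fraction` of
#' positions is lowercase-masked in contiguous runs (geometric run lengths,
#' mean 300 bp), emulating a repeat-masked reference.
#'
#' @param cfg a [sim_config()].
#' @return named character vector of length 1 (chromosome `chrS`), lowercase
#'   = masked.
#' @export
generate_genome <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  with_seed(cfg$seed, {
    p <- c(A = (1 - cfg$gc_fraction) / 2, C = cfg$gc_fraction / 2,
           G = cfg$gc_fraction / 2, T = (1 - cfg$gc_fraction) / 2)
    bases <- sample(DNA_BASES, cfg$genome_length, replace = TRUE, prob = p)
    mask <- rep(FALSE, cfg$genome_length)
    if (cfg$repeat_fraction > 0) {
      target <- floor(cfg$repeat_fraction * cfg$genome_length)
      masked <- 0L
      while (masked < target) {
        run <- min(stats::rgeom(1, 1 / 300) + 50L, target - masked)
        at <- sample.int(cfg$genome_length - run + 1L, 1L)
        idx <- at:(at + run - 1L)
        new <- idx[!mask[idx]]
        mask[new] <- TRUE
        masked <- masked + length(new)
      }
    }
    bases[mask] <- tolower(bases[mask])
    stats::setNames(paste(bases, collapse = ""), "chrS")
  })
}

#' Generate gene models and peaks with planted motif instances
#'
#' Peaks are placed so that configured fractions fall within 10 kb / 1 kb of
#' a TSS; exactly `floor(planting_rate * n_peaks)` peaks (seeded shuffle)
#' receive the motif, written into the genome at a recorded offset on a
#' seeded-random strand. The returned truth object records every placement.
#'
#' @param cfg a [sim_config()].
#' @param genome genome from [generate_genome()].
#' @return list with elements `genes`, `peaks`, `genome` (with motifs written
#'   in) and `truth`.
#' @export
generate_genes_and_peaks <- function(cfg, genome) {
  stopifnot(inherits(cfg, "sim_config"))
  glen <- nchar(genome[[1]])
  chrom <- names(genome)[1]
  with_seed(cfg$seed + 1L, {
    # -- gene models: non-overlapping bodies, 2-4 exons each
    body_len <- pmax(2000L, as.integer(stats::rnbinom(cfg$n_genes, mu = 8000,
                                                      size = 3)))
    # genes occupy the first half of the chromosome; the gene-free second
    # half guarantees room for distal (intergenic) peak placement
    slots <- as.integer((glen %/% 2L) %/% cfg$n_genes)
    jitter_max <- max(1L, slots %/% 10L)
    max_body <- slots - jitter_max - 10L
    if (max_body < 1500L)
      stopf("genome too small for %d genes; enlarge genome_length", cfg$n_genes)
    body_len <- pmin(body_len, max_body)
    starts <- (seq_len(cfg$n_genes) - 1L) * slots +
      sample.int(jitter_max, cfg$n_genes, replace = TRUE)
    strand <- sample(c("+", "-"), cfg$n_genes, replace = TRUE)
    es <- vector("list", cfg$n_genes); ee <- vector("list", cfg$n_genes)
    for (i in seq_len(cfg$n_genes)) {
      nex <- sample(2:4, 1L)
      bnd <- sort(sample.int(body_len[i] - 2L, 2L * nex - 2L) )
      cuts <- c(0L, bnd, body_len[i])
      s <- starts[i] + cuts[seq(1L, length(cuts) - 1L, by = 2L)]
      e <- starts[i] + cuts[seq(2L, length(cuts), by = 2L)]
      keep <- s < e
      es[[i]] <- s[keep]; ee[[i]] <- e[keep]
    }
    genes <- data.frame(gene_id = sprintf("g%03d", seq_len(cfg$n_genes)),
                        symbol = sprintf("Gene%03d", seq_len(cfg$n_genes)),
                        chrom = chrom, strand = strand,
                        start = starts, end = starts + body_len,
                        stringsAsFactors = FALSE)
    genes$exon_starts <- es; genes$exon_ends <- ee
    tss <- ifelse(strand == "+", genes$start, genes$end - 1L)

    # -- peak placement relative to TSSs
    n <- cfg$n_peaks
    plen <- sample(seq(cfg$peak_length_range[1], cfg$peak_length_range[2]),
                   n, replace = TRUE)
    n10 <- floor(cfg$frac_within_10kb * n)
    n1 <- min(floor(cfg$frac_within_1kb * n), n10)
    class_of <- c(rep("within_1kb", n1), rep("within_10kb", n10 - n1),
                  rep("distal", n - n10))
    anchor_gene <- sample.int(cfg$n_genes, n, replace = TRUE)
    pstart <- integer(n)  # 0-based
    for (i in seq_len(n)) {
      lim <- switch(class_of[i], within_1kb = 1000L, within_10kb = 10000L,
                    distal = NA_integer_)
      ok <- FALSE; tries <- 0L
      while (!ok) {
        tries <- tries + 1L
        if (tries > 2000L)
          stopf("peak placement cap exceeded; use a larger genome")
        if (is.na(lim)) {
          cand <- sample.int(glen - plen[i] + 1L, 1L) - 1L
          anchor <- cand + plen[i] %/% 2L
          ok <- all(abs(anchor - tss) > 10000L + plen[i])
        } else {
          # strict distance bands so annotation recovers the placement class
          lo <- if (lim == 1000L) 0L else 1001L
          d <- sample(c(-1L, 1L), 1L) * sample(lo:(lim - 1L), 1L)
          anchor <- tss[anchor_gene[i]] + d
          cand <- anchor - plen[i] %/% 2L
          ok <- cand >= 0L && cand + plen[i] <= glen
        }
      }
      pstart[i] <- cand
    }
    peaks <- data.frame(peak_id = sprintf("peak_%03d", seq_len(n)),
                        chrom = chrom, start = pstart,
                        end = pstart + plen,
                        summit_offset = NA_integer_,
                        tag_count = 10L + stats::rpois(n, 40),
                        stringsAsFactors = FALSE)

    # -- count-based motif planting
    k <- nchar(cfg$motif)
    n_plant <- floor(cfg$planting_rate * n)
    planted <- sort(sample.int(n, n_plant))
    gseq <- strsplit(genome[[1]], "", fixed = TRUE)[[1]]
    pos_rec <- data.frame(peak_id = character(0), offset = integer(0),
                          strand = character(0), stringsAsFactors = FALSE)
    for (i in planted) {
      off <- sample.int(plen[i] - k + 1L, 1L) - 1L
      strand_i <- sample(c("+", "-"), 1L)
      word <- if (strand_i == "+") cfg$motif else revcomp(cfg$motif)
      at <- peaks$start[i] + off  # 0-based genome offset
      # preserve mask case at the planted positions
      old <- gseq[(at + 1L):(at + k)]
      new <- strsplit(word, "", fixed = TRUE)[[1]]
      low <- grepl("[a-z]", old)
      new[low] <- tolower(new[low])
      gseq[(at + 1L):(at + k)] <- new
      pos_rec <- rbind(pos_rec, data.frame(peak_id = peaks$peak_id[i],
                                           offset = off, strand = strand_i,
                                           stringsAsFactors = FALSE))
    }
    genome_out <- stats::setNames(paste(gseq, collapse = ""), chrom)

    truth <- list(planted_motif = cfg$motif,
                  motif_positions = pos_rec,
                  peak_gene = data.frame(peak_id = peaks$peak_id,
                                         gene_id = genes$gene_id[anchor_gene],
                                         placement = class_of,
                                         stringsAsFactors = FALSE),
                  planted_targets = NULL,
                  conserved_species = NULL,
                  seed = cfg$seed)
    list(genes = genes, peaks = peaks, genome = genome_out, truth = truth)
  })
}

#' Extract peak sequences from the genome
#' @param genome named character vector (one chromosome).
#' @param peaks peak data frame.
#' @param uppercase uppercase the result (mask ignored downstream).
#' @return named character vector of peak sequences.
#' @export
peak_sequences <- function(genome, peaks, uppercase = TRUE) {
  seqs <- substring(genome[peaks$chrom], peaks$start + 1L, peaks$end)
  if (uppercase) seqs <- toupper(seqs)
  stats::setNames(seqs, peaks$peak_id)
}

#' Evolve per-peak multi-species alignments along the phylogeny
#'
#' The tree is re-rooted at the reference species (first leaf unless given)
#' and sequences evolve away from the reference: each site substitutes along
#' an edge of length `b` with probability `1 - exp(-b)` (uniform choice among
#' the other three bases, Jukes-Cantor style). Columns covered by a planted
#' motif instance use `b * (1 - motif_conservation_rate)` instead, so a rate
#' of 1 freezes the motif in every species. Alignments are substitution-only
#' (no indels); the truth records, per instance, the species in which the
#' motif survives intact.
#'
#' @param cfg a [sim_config()].
#' @param genome genome (with motifs planted).
#' @param peaks peak data frame.
#' @param truth truth list from [generate_genes_and_peaks()].
#' @return list with `blocks` (alignment blocks) and updated `truth`
#'   (element `conserved_species`: named list, instance key
#'   `"<peak_id>:<offset>"` -> character vector of species).
#' @export
evolve_alignments <- function(cfg, genome, peaks, truth) {
  stopifnot(inherits(cfg, "sim_config"))
  tree <- cfg$tree
  if (length(tree$tip.label) < 3L) stopf("tree must have >= 3 leaves")
  ref <- tree$tip.label[1]
  rooted <- ape::root(tree, outgroup = ref, resolve.root = TRUE)
  # edges from the reference tip outward
  with_seed(cfg$seed + 2L, {
    k <- nchar(cfg$motif)
    blocks <- vector("list", nrow(peaks))
    conserved <- list()
    mp <- truth$motif_positions
    for (i in seq_len(nrow(peaks))) {
      pid <- peaks$peak_id[i]
      refseq <- toupper(substring(genome[peaks$chrom[i]],
                                  peaks$start[i] + 1L, peaks$end[i]))
      L <- nchar(refseq)
      motif_cols <- rep(FALSE, L)
      inst <- mp[mp$peak_id == pid, , drop = FALSE]
      for (j in seq_len(nrow(inst)))
        motif_cols[(inst$offset[j] + 1L):(inst$offset[j] + k)] <- TRUE
      rows <- evolve_from_reference(rooted, ref, refseq, motif_cols,
                                    cfg$motif_conservation_rate)
      blocks[[i]] <- list(ref_species = ref, ref_chrom = peaks$chrom[i],
                          ref_start = peaks$start[i], ref_end = peaks$end[i],
                          peak_id = pid, rows = rows)
      for (j in seq_len(nrow(inst))) {
        cols <- (inst$offset[j] + 1L):(inst$offset[j] + k)
        refw <- substr(refseq, cols[1], cols[k])
        ok <- vapply(rows, function(s)
          substr(s, cols[1], cols[k]) == refw, logical(1))
        conserved[[paste0(pid, ":", inst$offset[j])]] <- names(rows)[ok]
      }
    }
    truth$conserved_species <- conserved
    list(blocks = blocks, truth = truth)
  })
}

# Simulate sequences for all leaves by walking the rooted tree outward from
# the reference tip. `motif_scale` multiplies branch lengths at motif columns.
evolve_from_reference <- function(rooted, ref, refseq, motif_cols, cons_rate) {
  L <- nchar(refseq)
  nt <- length(rooted$tip.label)
  ref_tip <- match(ref, rooted$tip.label)
  # adjacency over the phylo edge matrix
  edges <- rooted$edge; lens <- rooted$edge.length
  nb <- vector("list", max(edges))
  for (e in seq_len(nrow(edges))) {
    a <- edges[e, 1]; b <- edges[e, 2]
    nb[[a]] <- rbind(nb[[a]], c(b, e))
    nb[[b]] <- rbind(nb[[b]], c(a, e))
  }
  seqs <- vector("list", max(edges))
  seqs[[ref_tip]] <- base_codes(refseq)
  scale <- ifelse(motif_cols, 1 - cons_rate, 1)
  visited <- rep(FALSE, max(edges)); visited[ref_tip] <- TRUE
  queue <- ref_tip
  while (length(queue)) {
    node <- queue[1]; queue <- queue[-1]
    for (r in seq_len(NROW(nb[[node]]))) {
      child <- nb[[node]][r, 1]; eid <- nb[[node]][r, 2]
      if (visited[child]) next
      visited[child] <- TRUE
      b <- lens[eid] * scale
      p_sub <- 1 - exp(-b)
      s <- seqs[[node]]
      hit <- stats::runif(L) < p_sub
      if (any(hit)) {
        shift <- sample.int(3L, sum(hit), replace = TRUE)
        s[hit] <- ((s[hit] - 1L + shift) %% 4L) + 1L
      }
      seqs[[child]] <- s
      queue <- c(queue, child)
    }
  }
  out <- vapply(seq_len(nt), function(t)
    paste(DNA_BASES[seqs[[t]]], collapse = ""), character(1))
  names(out) <- rooted$tip.label
  # reference row listed first
  out[c(ref, setdiff(rooted$tip.label, ref))]
}

#' Generate a two-group expression matrix with planted effects
#'
#' log2 expression = gene baseline + group effect + N(0, noise_sd). Planted
#' targets get an effect of `de_effect` with a seeded-random sign; they are
#' drawn preferentially (fraction `frac_targets_proximal`) from genes that
#' have a peak placed within 10 kb, so the integration stage has true
#' positives.
#'
#' @param cfg a [sim_config()].
#' @param genes gene data frame.
#' @param truth truth list (uses `peak_gene` to find peak-proximal genes).
#' @return list with `expr` (matrix genes x samples, log2 scale), `groups`
#'   (factor control/treated per sample) and updated `truth` (element
#'   `planted_targets`: data frame gene_id, true_log2fc).
#' @export
generate_expression <- function(cfg, genes, truth) {
  stopifnot(inherits(cfg, "sim_config"))
  if (cfg$n_samples_per_group < 2L) stopf("need >= 2 samples per group")
  with_seed(cfg$seed + 3L, {
    ng <- nrow(genes); ns <- cfg$n_samples_per_group
    proximal <- unique(truth$peak_gene$gene_id[
      truth$peak_gene$placement != "distal"])
    n_t <- min(cfg$n_de_targets, ng)
    n_prox <- min(length(proximal), floor(cfg$frac_targets_proximal * n_t))
    pick_prox <- sample(proximal, n_prox)
    rest <- setdiff(genes$gene_id, pick_prox)
    pick_rest <- if (n_t - n_prox > 0) sample(rest, n_t - n_prox) else character(0)
    target_ids <- c(pick_prox, pick_rest)
    sign <- sample(c(-1, 1), n_t, replace = TRUE)
    eff <- stats::setNames(rep(0, ng), genes$gene_id)
    if (cfg$de_effect != 0 && n_t > 0) eff[target_ids] <- sign * cfg$de_effect
    baseline <- stats::runif(ng, 6, 12)
    groups <- factor(rep(c("control", "treated"), each = ns),
                     levels = c("control", "treated"))
    mu <- outer(baseline, rep(1, 2 * ns)) +
      outer(eff, as.numeric(groups == "treated"))
    expr <- mu + matrix(stats::rnorm(ng * 2L * ns, 0, cfg$noise_sd), ng)
    rownames(expr) <- genes$gene_id
    colnames(expr) <- paste0(rep(c("ctrl", "trt"), each = ns), seq_len(ns))
    planted <- if (cfg$de_effect != 0 && n_t > 0)
      data.frame(gene_id = target_ids, true_log2fc = sign * cfg$de_effect,
                 stringsAsFactors = FALSE)
    else data.frame(gene_id = character(0), true_log2fc = numeric(0))
    truth$planted_targets <- planted
    list(expr = expr, groups = groups, truth = truth)
  })
}

#' Generate a complete synthetic dataset
#'
#' Runs all generator stages in order and returns every artefact plus the
#' full ground truth.
#'
#' @param cfg a [sim_config()].
#' @return list: `genome`, `genes`, `peaks`, `blocks`, `expr`, `groups`,
#'   `truth`, `cfg`.
#' @export
generate_dataset <- function(cfg) {
  genome <- generate_genome(cfg)
  gp <- generate_genes_and_peaks(cfg, genome)
  al <- evolve_alignments(cfg, gp$genome, gp$peaks, gp$truth)
  ex <- generate_expression(cfg, gp$genes, al$truth)
  list(genome = gp$genome, genes = gp$genes, peaks = gp$peaks,
       blocks = al$blocks, expr = ex$expr, groups = ex$groups,
       truth = ex$truth, cfg = cfg)
}
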