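# Pipeline orchestration: a declarative config drives the stages
# annotate -> DE -> integrate -> discover/scan -> conserve -> enrich, every
# stage writing a TSV stamped with the producing stage, config hash and
# seed, plus a machine-readable JSON run report with the funnel counts.

#' Default pipeline thresholds
#'
#' The stated analysis parameters: 10 kb outer / 1 kb inner TSS windows,
#' absolute 1.25-fold change with p < 0.05, motif-scan Z-score p < 0.001
#' over a 10-million-sample background, conservation score > 1 in >= 4
#' distinct binding sequences, de novo k-mer support >= 25 at k = 6 and 7.
#'
#' @return named list of thresholds.
#' @export
default_thresholds <- function() {
  list(window = 10000L, inner = 1000L, fc = 1.25, p = 0.05, z_p = 0.001,
       bls = 1.0, min_hits = 4L, min_support = 25L, k = c(6L, 7L),
       n_background = 1e7, window_slack = 10L)
}

#' Validate a pipeline configuration
#'
#' @param config list with `paths` (named: genome, peaks, genes, expr,
#'   groups, tree, alignments; optional pwms, gene_sets), `thresholds`
#'   (defaults filled from [default_thresholds()]) and `seed`.
#' @return the normalised config.
#' @export
validate_config <- function(config) {
  if (is.character(config)) config <- jsonlite::read_json(config,
                                                          simplifyVector = TRUE)
  if (is.null(config$seed)) stopf("config: seed is mandatory")
  th <- utils::modifyList(default_thresholds(),
                          as.list(config$thresholds %||% list()))
  num <- unlist(th[c("window", "inner", "fc", "p", "z_p", "bls", "min_hits",
                     "min_support", "n_background")])
  if (any(num <= 0)) stopf("config: all thresholds must be positive")
  need <- c("genome", "peaks", "genes", "expr", "tree", "alignments")
  for (nm in need) {
    p <- config$paths[[nm]]
    if (is.null(p)) stopf("config: missing path '%s'", nm)
    if (!file.exists(p)) stopf("config: file not found for '%s': %s", nm, p)
  }
  for (nm in c("pwms", "gene_sets")) {
    p <- config$paths[[nm]]
    if (!is.null(p) && !file.exists(p))
      stopf("config: file not found for '%s': %s", nm, p)
  }
  config$thresholds <- th
  config
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run the full target-identification pipeline
#'
#' @param config config list or path to a JSON config (see
#'   [validate_config()]).
#' @param out_dir run directory (created if absent).
#' @return invisibly, the run report list (also written as
#'   `report.json`).
#' @export
run_pipeline <- function(config, out_dir) {
  config <- validate_config(config)
  th <- config$thresholds
  seed <- as.integer(config$seed)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  cfg_json <- jsonlite::toJSON(config[c("paths", "thresholds", "seed")],
                               auto_unbox = TRUE, pretty = TRUE, digits = NA)
  writeLines(cfg_json, file.path(out_dir, "config.json"))
  cfg_hash <- substr(tools::md5sum(file.path(out_dir, "config.json")), 1, 12)
  stamp <- function(stage) sprintf("stage=%s config=%s seed=%d", stage,
                                   cfg_hash, seed)
  run_stage <- function(stage, expr) {
    tryCatch(expr, error = function(e)
      stopf("stage '%s' failed: %s", stage, conditionMessage(e)))
  }

  # ---- load inputs
  genome <- run_stage("load", read_fasta(config$paths$genome))
  peaks <- run_stage("load", read_bed(config$paths$peaks))
  genes <- run_stage("load", read_gene_table(config$paths$genes))
  tree <- run_stage("load", read_newick(config$paths$tree))
  blocks <- run_stage("load", read_alignment_blocks(config$paths$alignments))
  em <- run_stage("load", read_expression_tsv(config$paths$expr))

  # ---- annotate
  assignments <- run_stage("annotate",
                           assign_peaks(peaks, genes, th$window, th$inner))
  write_tsv(assignments, file.path(out_dir, "assignments.tsv"),
            stamp("annotate"))
  ann <- annotation_summary(assignments)

  # ---- differential expression
  de <- run_stage("de", de_test(em$expr, em$groups))
  write_tsv(de, file.path(out_dir, "de_results.tsv"), stamp("de"))
  de_kept <- apply_thresholds(de, th$fc, th$p)
  write_tsv(de_kept, file.path(out_dir, "de_filtered.tsv"), stamp("de"))

  # ---- integrate
  targets <- run_stage("integrate", integrate_targets(de_kept, assignments))
  write_tsv(targets, file.path(out_dir, "targets.tsv"), stamp("integrate"))
  ts <- target_summary(targets)

  # ---- de novo k-mer discovery
  seqs <- peak_sequences(genome, peaks)
  kmers <- run_stage("discover", do.call(rbind, lapply(th$k, function(k)
    discover_kmers(seqs, k, th$min_support))))
  write_tsv(kmers, file.path(out_dir, "kmers.tsv"), stamp("discover"))

  # ---- PWM scan (optional)
  pwm_hits <- NULL
  if (!is.null(config$paths$pwms)) {
    pwm_hits <- run_stage("scan", {
      recs <- read_pwm_file(config$paths$pwms)
      do.call(rbind, lapply(recs, function(r) {
        lo <- build_log_odds(r)
        bg <- sample_background(lo, genome, n = th$n_background, seed = seed)
        h <- scan_peaks(seqs, lo, bg, th$z_p)
        if (nrow(h)) cbind(motif_id = r$motif_id, h) else NULL
      }))
    })
    if (!is.null(pwm_hits))
      write_tsv(pwm_hits, file.path(out_dir, "pwm_hits.tsv"), stamp("scan"))
  }

  # ---- conservation of discovered k-mers
  retained <- run_stage("conserve", {
    blocks <- match_blocks_to_peaks(blocks, peaks)
    inst <- kmer_instances(seqs, kmers$kmer)
    if (nrow(inst)) {
      scored <- score_conservation(inst, blocks, tree, th$window_slack)
      write_tsv(scored, file.path(out_dir, "conservation.tsv"),
                stamp("conserve"))
      retain_motifs(scored, th$bls, th$min_hits)
    } else {
      data.frame(motif = character(), qualifying_hits = integer(),
                 retained = logical())
    }
  })
  write_tsv(retained, file.path(out_dir, "motif_retention.tsv"),
            stamp("conserve"))

  # ---- enrichment (optional)
  enrich <- NULL
  if (!is.null(config$paths$gene_sets) && nrow(targets)) {
    enrich <- run_stage("enrich", {
      sets <- read_tsv(config$paths$gene_sets)
      gene_set_enrichment(targets$gene_id, sets, de$gene_id)
    })
    write_tsv(enrich, file.path(out_dir, "enrichment.tsv"), stamp("enrich"))
  }

  report <- list(
    config_hash = unname(cfg_hash), seed = seed,
    n_peaks = nrow(peaks), n_genes = nrow(genes),
    peaks_within_10kb = ann$peaks_within_10kb,
    peaks_within_1kb = ann$peaks_within_1kb,
    genes_within_10kb = ann$genes_within_10kb,
    genes_within_1kb = ann$genes_within_1kb,
    n_de_tested = nrow(de), n_de_filtered = nrow(de_kept),
    targets_total = ts$total, targets_up = ts$up, targets_down = ts$down,
    n_kmers_discovered = nrow(kmers),
    n_motifs_retained = sum(retained$retained),
    n_pwm_hits = if (is.null(pwm_hits)) 0L else nrow(pwm_hits),
    n_enriched_sets = if (is.null(enrich)) 0L
      else sum(enrich$q_value < 0.05))
  jsonlite::write_json(report, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(report)
}

#' Attach peak ids to alignment blocks by reference coordinates
#'
#' Blocks read from the MAF-like format carry only reference coordinates;
#' this matches each block to the peak with the same (chrom, start, end).
#'
#' @param blocks list of alignment blocks.
#' @param peaks peak data frame.
#' @return blocks with a `peak_id` field each.
#' @export
match_blocks_to_peaks <- function(blocks, peaks) {
  key <- paste(peaks$chrom, peaks$start, peaks$end)
  lapply(blocks, function(b) {
    i <- match(paste(b$ref_chrom, b$ref_start, b$ref_end), key)
    if (is.na(i))
      stopf("alignment block %s:%d-%d matches no peak", b$ref_chrom,
            b$ref_start, b$ref_end)
    b$peak_id <- peaks$peak_id[i]
    b
  })
}

# All occurrences (either strand, forward coordinates) of each k-mer in each
# sequence, as instance records for conservation scoring.
kmer_instances <- function(seqs, kmers) {
  out <- list()
  for (km in unique(kmers)) {
    k <- nchar(km)
    words <- unique(c(km, revcomp(km)))
    for (id in names(seqs)) {
      s <- toupper(seqs[[id]])
      for (w in words) {
        hits <- gregexpr(w, s, fixed = TRUE)[[1]]
        if (hits[1] == -1L) next
        out[[length(out) + 1L]] <- data.frame(
          motif = km, seq_id = id, offset = as.integer(hits) - 1L,
          kmer = w, stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(out))
    return(data.frame(motif = character(), seq_id = character(),
                      offset = integer(), kmer = character(),
                      stringsAsFactors = FALSE))
  unique(do.call(rbind, out))
}

#' Read a TSV expression matrix with group labels
#'
#' Genes in rows; the header names samples as `sample:group` with group
#' `control` or `treated`.
#'
#' @param path TSV path.
#' @return list with `expr` (matrix) and `groups` (factor).
#' @export
read_expression_tsv <- function(path) {
  tab <- utils::read.table(path, sep = "\t", header = TRUE, row.names = 1,
                           check.names = FALSE, comment.char = "#")
  labs <- strsplit(colnames(tab), ":", fixed = TRUE)
  groups <- vapply(labs, function(x) x[2], character(1))
  if (anyNA(groups)) stopf("expression header must be 'sample:group'")
  expr <- as.matrix(tab)
  colnames(expr) <- vapply(labs, function(x) x[1], character(1))
  list(expr = expr,
       groups = factor(groups, levels = c("control", "treated")))
}

#' Write an expression matrix in the pipeline's TSV layout
#' @param expr matrix genes x samples (log2).
#' @param groups group label per sample.
#' @param path output path.
#' @export
write_expression_tsv <- function(expr, groups, path) {
  tab <- as.data.frame(expr)
  colnames(tab) <- paste0(colnames(expr), ":", as.character(groups))
  con <- file(path, "w"); on.exit(close(con))
  writeLines(paste(c("gene_id", colnames(tab)), collapse = "\t"), con)
  utils::write.table(tab, con, sep = "\t", quote = FALSE, col.names = FALSE,
                     row.names = TRUE)
  invisible(path)
}

#' Write a complete synthetic demo dataset to disk
#'
#' Generates a dataset with [generate_dataset()] and emits every file the
#' pipeline consumes (FASTA genome, BED peaks, gene table, expression TSV,
#' MAF-like alignments, Newick tree) plus a ready-to-run `config.json` and
#' a `truth.json` manifest of the planted signal.
#'
#' @param dir output directory.
#' @param seed RNG seed.
#' @param cfg optional [sim_config()]; defaults to the demo-scale world
#'   (50 peaks, 60 genes, motif planted in 30 peaks, conserved).
#' @return invisibly, the path to the written config file.
#' @export
make_demo <- function(dir, seed = 7L, cfg = NULL) {
  if (is.null(cfg)) cfg <- sim_config(seed = seed)
  dat <- generate_dataset(cfg)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  pth <- function(f) file.path(dir, f)
  write_fasta(dat$genome, pth("genome.fa"))
  write_bed(dat$peaks, pth("peaks.bed"))
  write_gene_table(dat$genes, pth("genes.tsv"))
  write_expression_tsv(dat$expr, dat$groups, pth("expression.tsv"))
  write_alignment_blocks(dat$blocks, pth("alignments.maf"))
  ape::write.tree(dat$cfg$tree, pth("tree.nwk"))
  truth <- dat$truth
  jsonlite::write_json(
    list(planted_motif = truth$planted_motif,
         n_planted_peaks = nrow(truth$motif_positions),
         planted_targets = truth$planted_targets,
         seed = cfg$seed),
    pth("truth.json"), auto_unbox = TRUE, digits = NA, pretty = TRUE)
  config <- list(paths = list(genome = pth("genome.fa"),
                              peaks = pth("peaks.bed"),
                              genes = pth("genes.tsv"),
                              expr = pth("expression.tsv"),
                              tree = pth("tree.nwk"),
                              alignments = pth("alignments.maf")),
                 thresholds = list(n_background = 50000),
                 seed = cfg$seed)
  jsonlite::write_json(config, pth("config.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(pth("config.json"))
}
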