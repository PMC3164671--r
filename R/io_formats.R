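# Readers and writers for the external formats the pipeline touches.
#
# Internal coordinate convention is 0-based half-open everywhere ([start, end),
# BED-native). Formats declared as 1-based inclusive are converted at the
# boundary and never afterwards.

# ---- primitive containers ---------------------------------------------------

#' Construct a genomic interval
#'
#' @param chrom chromosome name (non-empty string).
#' @param start 0-based inclusive start.
#' @param end exclusive end; must satisfy `start < end`.
#' @param strand `"+"`, `"-"` or `"*"` (unstranded).
#' @return a list with class `genomic_interval`.
#' @export
genomic_interval <- function(chrom, start, end, strand = "*") {
  if (!is.character(chrom) || length(chrom) != 1L || !nzchar(chrom))
    stopf("chrom must be a non-empty string")
  start <- as.integer(start); end <- as.integer(end)
  if (is.na(start) || is.na(end) || start < 0L || start >= end)
    stopf("invalid interval [%s, %s): need 0 <= start < end", start, end)
  if (!strand %in% c("+", "-", "*")) stopf("strand must be +, - or *")
  structure(list(chrom = chrom, start = start, end = end, strand = strand),
            class = "genomic_interval")
}

# ---- BED peaks --------------------------------------------------------------

#' Read ChIP-seq peaks from a BED file
#'
#' BED3/BED4/BED5: chrom, start, end, optional name, optional score
#' (interpreted as tag count). Coordinates are adopted verbatim (BED is
#' already 0-based half-open). Peaks without a name column get auto ids
#' `peak_<n>`; duplicated names are disambiguated with a numeric suffix.
#'
#' @param path path to a BED file.
#' @return a data frame with columns `peak_id`, `chrom`, `start`, `end`,
#'   `summit_offset` (NA; BED carries none), `tag_count`.
#' @export
read_bed <- function(path) {
  lines <- read_text_lines(path)
  keep <- !grepl("^(#|track|browser)", lines)
  lines <- lines[keep]
  if (length(lines) == 0L)
    return(data.frame(peak_id = character(), chrom = character(),
                      start = integer(), end = integer(),
                      summit_offset = integer(), tag_count = integer()))
  fields <- strsplit(lines, "\t", fixed = TRUE)
  n <- length(fields)
  out <- data.frame(peak_id = character(n), chrom = character(n),
                    start = integer(n), end = integer(n),
                    summit_offset = rep(NA_integer_, n),
                    tag_count = rep(NA_integer_, n))
  for (i in seq_len(n)) {
    f <- fields[[i]]
    if (length(f) < 3L) stopf("BED line %d: fewer than 3 columns", i)
    start <- suppressWarnings(as.integer(f[2]))
    end <- suppressWarnings(as.integer(f[3]))
    if (is.na(start) || is.na(end))
      stopf("BED line %d: non-integer coordinates", i)
    if (start < 0L || start >= end)
      stopf("BED line %d: invalid interval [%d, %d)", i, start, end)
    out$chrom[i] <- f[1]; out$start[i] <- start; out$end[i] <- end
    out$peak_id[i] <- if (length(f) >= 4L && nzchar(f[4])) f[4]
      else sprintf("peak_%d", i)
    if (length(f) >= 5L) {
      tc <- suppressWarnings(as.integer(f[5]))
      if (!is.na(tc) && tc >= 0L) out$tag_count[i] <- tc
    }
  }
  out$peak_id <- make.unique(out$peak_id, sep = "_dup")
  out
}

#' Write peaks to a BED file
#'
#' @param peaks peak data frame (see [read_bed()]).
#' @param path output path.
#' @export
write_bed <- function(peaks, path) {
  tc <- ifelse(is.na(peaks$tag_count), 0L, peaks$tag_count)
  writeLines(sprintf("%s\t%d\t%d\t%s\t%d", peaks$chrom, peaks$start,
                     peaks$end, peaks$peak_id, tc), path)
  invisible(path)
}

# ---- gene table -------------------------------------------------------------

#' Read gene models from a tab-delimited gene table
#'
#' Expected header: `gene_id symbol chrom strand tx_start tx_end exon_starts
#' exon_ends`. The file must declare its coordinate convention on a first
#' comment line `# coords: 0based-halfopen` or `# coords: 1based-inclusive`;
#' 1-based inclusive coordinates are converted on load. Exon lists are
#' comma-separated, ordered, and must lie within the transcript body.
#'
#' @param path path to the gene table.
#' @return data frame with columns `gene_id`, `symbol`, `chrom`, `strand`,
#'   `start`, `end` and list columns `exon_starts`, `exon_ends` (internal
#'   0-based half-open).
#' @export
read_gene_table <- function(path) {
  lines <- read_text_lines(path)
  if (length(lines) < 2L) stopf("gene table %s: missing header or data", path)
  decl <- sub("^#\\s*coords:\\s*", "", lines[1])
  if (identical(decl, lines[1]))
    stopf("gene table %s: first line must declare '# coords: ...'", path)
  if (!decl %in% c("0based-halfopen", "1based-inclusive"))
    stopf("unknown coordinate declaration '%s'", decl)
  one_based <- decl == "1based-inclusive"
  tab <- utils::read.table(text = lines[-1], sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE,
                           colClasses = c(exon_starts = "character",
                                          exon_ends = "character"))
  need <- c("gene_id", "symbol", "chrom", "strand", "tx_start", "tx_end",
            "exon_starts", "exon_ends")
  if (!all(need %in% names(tab)))
    stopf("gene table missing columns: %s",
          paste(setdiff(need, names(tab)), collapse = ", "))
  parse_pos <- function(s) as.integer(strsplit(s, ",", fixed = TRUE)[[1]])
  n <- nrow(tab)
  start <- as.integer(tab$tx_start); end <- as.integer(tab$tx_end)
  if (one_based) { start <- start - 1L }
  es <- vector("list", n); ee <- vector("list", n)
  for (i in seq_len(n)) {
    if (!tab$strand[i] %in% c("+", "-"))
      stopf("gene %s: strand must be + or -", tab$gene_id[i])
    if (start[i] >= end[i]) stopf("gene %s: empty body", tab$gene_id[i])
    s <- parse_pos(tab$exon_starts[i]); e <- parse_pos(tab$exon_ends[i])
    if (one_based) s <- s - 1L
    if (length(s) != length(e)) stopf("gene %s: ragged exon lists", tab$gene_id[i])
    if (is.unsorted(s, strictly = FALSE)) stopf("gene %s: exons unsorted", tab$gene_id[i])
    if (any(s >= e)) stopf("gene %s: empty exon", tab$gene_id[i])
    if (any(s < start[i]) || any(e > end[i]))
      stopf("gene %s: exon outside transcript body", tab$gene_id[i])
    es[[i]] <- s; ee[[i]] <- e
  }
  out <- data.frame(gene_id = tab$gene_id, symbol = tab$symbol,
                    chrom = tab$chrom, strand = tab$strand,
                    start = start, end = end, stringsAsFactors = FALSE)
  out$exon_starts <- es
  out$exon_ends <- ee
  out
}

#' Write gene models to a gene table file
#'
#' Always writes the internal `0based-halfopen` convention, declared in the
#' header comment, so `read_gene_table(write_gene_table(x))` is the identity.
#'
#' @param genes gene data frame (see [read_gene_table()]).
#' @param path output path.
#' @export
write_gene_table <- function(genes, path) {
  con <- file(path, "w"); on.exit(close(con))
  writeLines("# coords: 0based-halfopen", con)
  writeLines(paste(c("gene_id", "symbol", "chrom", "strand", "tx_start",
                     "tx_end", "exon_starts", "exon_ends"), collapse = "\t"),
             con)
  for (i in seq_len(nrow(genes))) {
    writeLines(paste(genes$gene_id[i], genes$symbol[i], genes$chrom[i],
                     genes$strand[i], genes$start[i], genes$end[i],
                     paste(genes$exon_starts[[i]], collapse = ","),
                     paste(genes$exon_ends[[i]], collapse = ","),
                     sep = "\t"), con)
  }
  invisible(path)
}

# ---- TRANSFAC-style PWMs ----------------------------------------------------

#' Read position count matrices from a TRANSFAC-like file
#'
#' Blocks of the form: an `ID <motif_id>` line, an optional `NA <name>` line,
#' an optional `P0 A C G T` column header, numbered rows `NN a c g t X` with
#' four numeric fields and a consensus letter, terminated by `//`.
#'
#' @param path path to the matrix file.
#' @return a list of PWM records, each a list with `motif_id`, `name`,
#'   `counts` (L x 4 matrix, columns A,C,G,T) and `consensus`.
#' @export
read_pwm_file <- function(path) {
  lines <- read_text_lines(path)
  records <- list()
  cur_id <- NULL; cur_name <- NA_character_
  rows <- list(); cons <- character()
  flush <- function() {
    if (is.null(cur_id)) return(invisible())
    if (length(rows) < 4L)
      stopf("PWM %s: matrix has %d rows; need length >= 4", cur_id, length(rows))
    m <- do.call(rbind, rows)
    colnames(m) <- DNA_BASES
    records[[length(records) + 1L]] <<- list(
      motif_id = cur_id, name = cur_name, counts = m,
      consensus = paste(cons, collapse = ""))
    invisible()
  }
  for (ln in lines) {
    ln <- trimws(ln)
    if (!nzchar(ln)) next
    if (grepl("^ID\\b", ln)) {
      cur_id <- trimws(sub("^ID", "", ln)); cur_name <- NA_character_
      rows <- list(); cons <- character()
    } else if (grepl("^NA\\b", ln)) {
      cur_name <- trimws(sub("^NA", "", ln))
    } else if (grepl("^P0\\b", ln) || grepl("^PO\\b", ln)) {
      next
    } else if (grepl("^//", ln)) {
      flush(); cur_id <- NULL
    } else if (grepl("^[0-9]+\\s", ln)) {
      f <- strsplit(ln, "\\s+")[[1]][-1]
      num <- suppressWarnings(as.numeric(f))
      vals <- num[!is.na(num)]
      if (length(vals) != 4L)
        stopf("PWM %s: matrix row '%s' does not have 4 numeric fields",
              if (is.null(cur_id)) "?" else cur_id, ln)
      if (any(vals < 0)) stopf("PWM %s: negative counts", cur_id)
      rows[[length(rows) + 1L]] <- vals
      letter <- f[is.na(num)]
      cons <- c(cons, if (length(letter)) letter[1] else "N")
    }
  }
  flush()
  records
}

# ---- MAF-like alignment blocks ---------------------------------------------

#' Read multi-species alignment blocks (MAF-like)
#'
#' Paragraphs of an `a` line followed by `s <species> <start> <size> <strand>
#' <srcSize> <text>` rows. The first `s` row of each block is the reference;
#' its ungapped length must equal its declared size. `<species>` may be
#' `name.chrom`; the part before the first dot is the species, the remainder
#' the reference chromosome (used for the reference row).
#'
#' @param path path to the alignment file.
#' @return list of alignment blocks: each a list with `ref_species`,
#'   `ref_chrom`, `ref_start`, `ref_end` (0-based half-open) and `rows`
#'   (named character vector of gapped sequences, equal widths).
#' @export
read_alignment_blocks <- function(path) {
  lines <- read_text_lines(path)
  blocks <- list(); cur <- NULL
  flush <- function() {
    if (is.null(cur) || length(cur$rows) == 0L) return(invisible())
    w <- nchar(cur$rows)
    if (length(unique(w)) != 1L)
      stopf("alignment block starting at %s:%d has ragged rows",
            cur$ref_chrom, cur$ref_start)
    blocks[[length(blocks) + 1L]] <<- cur
    invisible()
  }
  for (i in seq_along(lines)) {
    ln <- trimws(lines[i])
    if (!nzchar(ln) || grepl("^#", ln)) next
    if (grepl("^a\\b", ln)) { flush(); cur <- list(rows = character()) ; next }
    if (!grepl("^s\\s", ln)) next
    if (is.null(cur)) stopf("line %d: 's' row outside a block", i)
    f <- strsplit(ln, "\\s+")[[1]]
    if (length(f) < 7L) stopf("line %d: malformed 's' row", i)
    src <- f[2]
    species <- sub("\\..*$", "", src)
    start <- as.integer(f[3]); size <- as.integer(f[4])
    text <- f[7]
    ungapped <- nchar(gsub("-", "", text, fixed = TRUE))
    if (ungapped != size)
      stopf("line %d: ungapped length %d != declared size %d", i, ungapped, size)
    if (length(cur$rows) == 0L) {
      cur$ref_species <- species
      cur$ref_chrom <- if (grepl(".", src, fixed = TRUE))
        sub("^[^.]*\\.", "", src) else src
      cur$ref_start <- start
      cur$ref_end <- start + size
    }
    if (species %in% names(cur$rows))
      stopf("line %d: duplicate species '%s' in block", i, species)
    cur$rows[species] <- text
  }
  flush()
  blocks
}

#' Write alignment blocks in the MAF-like format
#' @param blocks list of alignment blocks (see [read_alignment_blocks()]).
#' @param path output path.
#' @export
write_alignment_blocks <- function(blocks, path) {
  con <- file(path, "w"); on.exit(close(con))
  for (b in blocks) {
    writeLines("a", con)
    for (sp in names(b$rows)) {
      text <- b$rows[[sp]]
      size <- nchar(gsub("-", "", text, fixed = TRUE))
      if (sp == b$ref_species) {
        writeLines(sprintf("s %s.%s %d %d + %d %s", sp, b$ref_chrom,
                           b$ref_start, size, b$ref_end, text), con)
      } else {
        writeLines(sprintf("s %s 0 %d + %d %s", sp, size, size, text), con)
      }
    }
    writeLines("", con)
  }
  invisible(path)
}

# ---- Newick trees -----------------------------------------------------------

#' Read a phylogenetic tree from a Newick file
#'
#' Thin wrapper over [ape::read.tree()] that enforces the invariants the
#' conservation module relies on: unique leaf names and non-negative branch
#' lengths.
#'
#' @param path path to a Newick file.
#' @return an [ape::phylo] tree.
#' @export
read_newick <- function(path) {
  tree <- ape::read.tree(path)
  if (is.null(tree)) stopf("could not parse Newick file %s", path)
  if (anyDuplicated(tree$tip.label))
    stopf("Newick tree has duplicated leaf names")
  if (is.null(tree$edge.length))
    stopf("Newick tree has no branch lengths")
  if (any(tree$edge.length < 0)) stopf("negative branch length in tree")
  tree
}

# ---- FASTA ------------------------------------------------------------------

#' Read a (possibly repeat-masked) genome FASTA
#'
#' Case is preserved: lowercase letters mark repeat-masked positions.
#'
#' @param path path to a FASTA file.
#' @return named character vector, one element per sequence.
#' @export
read_fasta <- function(path) {
  s <- Biostrings::readBStringSet(path)
  out <- as.character(s)
  names(out) <- sub("\\s.*$", "", names(s))
  out
}

#' Write sequences to FASTA (case preserved)
#' @param seqs named character vector.
#' @param path output path.
#' @param width line wrap width.
#' @export
write_fasta <- function(seqs, path, width = 70L) {
  Biostrings::writeXStringSet(Biostrings::BStringSet(seqs), path, width = width)
  invisible(path)
}

# ---- TSV --------------------------------------------------------------------

#' Write a data frame as TSV
#'
#' @param records data frame.
#' @param path output path.
#' @param header_comment optional comment lines written before the header.
#' @export
write_tsv <- function(records, path, header_comment = NULL) {
  con <- file(path, "w"); on.exit(close(con))
  if (!is.null(header_comment))
    writeLines(paste0("# ", header_comment), con)
  utils::write.table(records, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Read a TSV written by [write_tsv()]
#' @param path input path.
#' @return data frame.
#' @export
read_tsv <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE, comment.char = "#",
                    stringsAsFactors = FALSE, check.names = FALSE)
}

# Tolerates \r\n line endings and trailing blank lines.
read_text_lines <- function(path) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  lines <- readLines(path, warn = FALSE)
  lines <- sub("\r$", "", lines)
  while (length(lines) && !nzchar(lines[length(lines)]))
    lines <- lines[-length(lines)]
  lines
}
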