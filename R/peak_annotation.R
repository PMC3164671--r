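# Peak-to-gene annotation: TSS distance windows and genomic context classes.
#
# A peak is anchored at its summit (if known) or region midpoint; it is
# assigned to every gene whose TSS lies within the outer window (default
# 10 kb), with a 1 kb inner window flag, and classified against the gene
# structure with precedence tss_overlap > exon > intron > upstream/downstream.

#' Transcription start site of a gene model
#'
#' Internal 0-based convention: for a `+` gene the TSS is `start`; for a `-`
#' gene it is `end - 1`, the last covered base.
#'
#' @param genes gene data frame (one or more rows).
#' @return integer vector of TSS positions.
#' @export
tss_of <- function(genes) {
  if (any(!genes$strand %in% c("+", "-")))
    stopf("tss_of: unstranded gene model")
  ifelse(genes$strand == "+", genes$start, genes$end - 1L)
}

#' Anchor position of a peak
#'
#' Summit position when `summit_offset` is present, otherwise the region
#' midpoint `floor((start + end) / 2)`.
#'
#' @param peaks peak data frame.
#' @return integer vector of anchor positions.
#' @export
anchor_of <- function(peaks) {
  mid <- (peaks$start + peaks$end) %/% 2L
  ifelse(is.na(peaks$summit_offset), mid, peaks$start + peaks$summit_offset)
}

#' Assign peaks to genes by TSS distance
#'
#' Emits one assignment per (peak, gene) pair whose anchor lies within
#' `window` bp of the gene's TSS on the same chromosome. `signed_distance`
#' is negative when the anchor is 5' (upstream) of the TSS in the gene's
#' orientation. Each assigned peak gets exactly one `nearest = TRUE` row
#' (minimal |distance|, ties broken by lexicographic `gene_id`).
#'
#' @param peaks peak data frame.
#' @param genes gene data frame.
#' @param window outer window in bp (default 10000).
#' @param inner inner window in bp (default 1000).
#' @return data frame: `peak_id`, `gene_id`, `symbol`, `signed_distance`,
#'   `window_class` (`within_1kb`/`within_10kb`), `location_class`,
#'   `nearest`.
#' @export
assign_peaks <- function(peaks, genes, window = 10000L, inner = 1000L) {
  empty <- data.frame(peak_id = character(), gene_id = character(),
                      symbol = character(), signed_distance = integer(),
                      window_class = character(), location_class = character(),
                      nearest = logical(), stringsAsFactors = FALSE)
  if (nrow(peaks) == 0L || nrow(genes) == 0L) return(empty)
  anchors <- anchor_of(peaks)
  tss <- tss_of(genes)
  out <- vector("list", nrow(peaks))
  for (i in seq_len(nrow(peaks))) {
    same <- which(genes$chrom == peaks$chrom[i])
    if (!length(same)) next
    delta <- anchors[i] - tss[same]           # genome orientation
    hit <- same[abs(delta) <= window]
    if (!length(hit)) next
    d <- anchors[i] - tss[hit]
    signed <- ifelse(genes$strand[hit] == "+", d, -d)
    loc <- vapply(seq_along(hit), function(j)
      classify_location(peaks[i, , drop = FALSE],
                        genes[hit[j], , drop = FALSE]), character(1))
    df <- data.frame(peak_id = peaks$peak_id[i], gene_id = genes$gene_id[hit],
                     symbol = genes$symbol[hit],
                     signed_distance = as.integer(signed),
                     window_class = ifelse(abs(signed) <= inner,
                                           "within_1kb", "within_10kb"),
                     location_class = loc, nearest = FALSE,
                     stringsAsFactors = FALSE)
    ord <- order(abs(df$signed_distance), df$gene_id)
    df$nearest[ord[1]] <- TRUE
    out[[i]] <- df
  }
  out <- out[!vapply(out, is.null, logical(1))]
  if (!length(out)) return(empty)
  do.call(rbind, out)
}

#' Classify the genomic context of a peak relative to a gene
#'
#' Precedence: `tss_overlap` if the region contains the TSS; else `exon` if
#' the region overlaps any exon; else `intron` if the region lies entirely
#' inside the transcript body; else `upstream_5prime` / `downstream_3prime`
#' by the anchor's position in gene orientation.
#'
#' @param peak one-row peak data frame.
#' @param gene one-row gene data frame.
#' @return one of `"tss_overlap"`, `"exon"`, `"intron"`,
#'   `"upstream_5prime"`, `"downstream_3prime"`.
#' @export
classify_location <- function(peak, gene) {
  s <- peak$start[1]; e <- peak$end[1]
  tss <- tss_of(gene)
  if (tss >= s && tss < e) return("tss_overlap")
  es <- gene$exon_starts[[1]]; ee <- gene$exon_ends[[1]]
  if (any(s < ee & e > es)) return("exon")
  if (s >= gene$start[1] && e <= gene$end[1]) return("intron")
  anchor <- anchor_of(peak)
  d <- anchor - tss
  if (gene$strand[1] == "-") d <- -d
  if (d < 0) "upstream_5prime" else "downstream_3prime"
}

#' Summarise an assignment table into the annotation funnel counts
#'
#' @param assignments output of [assign_peaks()].
#' @return list with peak-level and gene-level counts for each window class.
#' @export
annotation_summary <- function(assignments) {
  w1 <- assignments[assignments$window_class == "within_1kb", , drop = FALSE]
  list(peaks_within_10kb = length(unique(assignments$peak_id)),
       peaks_within_1kb = length(unique(w1$peak_id)),
       genes_within_10kb = length(unique(assignments$gene_id)),
       genes_within_1kb = length(unique(w1$gene_id)))
}
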