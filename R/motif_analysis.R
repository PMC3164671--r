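# PWM log-odds scanning against an empirically sampled genomic background,
# degenerate-consensus pattern search, and de novo k-mer discovery with
# reverse-complement collapsing.
#
# Scores are log2-odds sums; significance is a Z-score against the mean/sd
# of scores at randomly sampled unmasked genome locations (one-sided upper
# tail by default: only high scores indicate motif matches).

#' Build a log2-odds PWM from a count matrix
#'
#' `weight[i, b] = log2(((count[i, b] + pseudocount * bg[b]) /
#' (rowsum + pseudocount)) / bg[b])`. The default pseudocount of 0.25
#' (Laplace-style, spread over the background) keeps weights finite when
#' counts contain zeros.
#'
#' @param record PWM record from [read_pwm_file()] (count form).
#' @param background base frequencies, named A,C,G,T, summing to 1.
#' @param pseudocount total pseudocount weight (> 0).
#' @return list with `motif_id`, `weights` (L x 4 log2-odds matrix),
#'   `background`, `pseudocount`, `consensus`.
#' @export
build_log_odds <- function(record, background = c(A = 0.25, C = 0.25,
                                                  G = 0.25, T = 0.25),
                           pseudocount = 0.25) {
  if (pseudocount <= 0) stopf("pseudocount must be > 0")
  background <- background[DNA_BASES]
  if (abs(sum(background) - 1) > 1e-6) stopf("background must sum to 1")
  counts <- record$counts
  rs <- rowSums(counts)
  if (any(rs == 0)) stopf("PWM %s: zero count row", record$motif_id)
  w <- log2(sweep(counts + pseudocount * rep(background, each = nrow(counts)),
                  1, rs + pseudocount, "/"))
  w <- sweep(w, 2, log2(background), "-")
  list(motif_id = record$motif_id, weights = unname(w),
       background = background, pseudocount = pseudocount,
       consensus = record$consensus)
}

# Score every window start of a coded sequence (1..4, NA for N) with an
# L x 4 weight matrix; windows containing NA get -Inf.
score_positions <- function(codes, weights) {
  L <- nrow(weights)
  n <- length(codes) - L + 1L
  if (n < 1L) return(numeric(0))
  s <- numeric(n)
  bad <- rep(FALSE, n)
  for (j in seq_len(L)) {
    cj <- codes[j:(j + n - 1L)]
    na <- is.na(cj)
    bad <- bad | na
    cj[na] <- 1L
    s <- s + weights[j, cj]
  }
  s[bad] <- -Inf
  s
}

#' Scan a sequence with a log-odds PWM
#'
#' Scores every window on the forward strand and (optionally) the reverse
#' complement; minus-strand hits are reported in forward coordinates
#' (offset of the window's leftmost base). Windows containing `N` (or any
#' non-ACGT character, e.g. soft-masked lowercase is uppercased first)
#' score `-Inf` and are dropped.
#'
#' @param seq a DNA string.
#' @param pwm log-odds PWM from [build_log_odds()].
#' @param both_strands scan the reverse complement too (default TRUE).
#' @return data frame: `offset` (0-based), `strand`, `score`.
#' @export
scan_sequence <- function(seq, pwm, both_strands = TRUE) {
  L <- nrow(pwm$weights)
  if (nchar(seq) < L) stopf("sequence shorter than the motif")
  codes <- base_codes(seq)
  fw <- score_positions(codes, pwm$weights)
  out <- data.frame(offset = seq_along(fw) - 1L, strand = "+", score = fw,
                    stringsAsFactors = FALSE)
  if (both_strands) {
    rc <- base_codes(revcomp(seq))
    rv <- score_positions(rc, pwm$weights)
    # window starting at offset o of the revcomp covers forward offset
    # (n - L - o) .. so report in + coordinates
    n <- length(rv)
    out <- rbind(out, data.frame(offset = rev(seq_len(n)) - 1L, strand = "-",
                                 score = rv, stringsAsFactors = FALSE))
  }
  out <- out[is.finite(out$score), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Empirically sample a PWM score background from the genome
#'
#' Samples `n` window start positions uniformly with replacement from the
#' positions whose full window is unmasked (uppercase) and N-free, scores
#' the forward strand, and records the mean and standard deviation. The
#' field-scale default is ten million samples; scale `n` down for tests.
#'
#' @param pwm log-odds PWM.
#' @param genome named character vector (lowercase = repeat-masked).
#' @param n number of sampled locations (default 1e7).
#' @param seed RNG seed (mandatory; recorded in the model).
#' @return list (`motif_id`, `mean`, `sd`, `n`, `seed`).
#' @export
sample_background <- function(pwm, genome, n = 1e7, seed) {
  if (missing(seed)) stopf("sample_background: seed is mandatory")
  L <- nrow(pwm$weights)
  seqs <- genome
  # valid starts per chromosome: window entirely unmasked uppercase ACGT
  all_scores <- with_seed(seed, {
    valid <- list()
    for (ch in names(seqs)) {
      good <- strsplit(seqs[[ch]], "", fixed = TRUE)[[1]] %in% DNA_BASES
      ok_start <- stats::filter(as.numeric(good), rep(1, L), sides = 1)
      ok_start <- which(!is.na(ok_start) & ok_start == L) - L + 1L
      valid[[ch]] <- ok_start
    }
    counts <- vapply(valid, length, integer(1))
    if (sum(counts) < 1000L)
      stopf("fewer than 1,000 valid background positions")
    pick_ch <- sample(names(seqs), n, replace = TRUE, prob = counts)
    scores <- numeric(n)
    for (ch in names(seqs)) {
      idx <- which(pick_ch == ch)
      if (!length(idx)) next
      starts <- valid[[ch]][sample.int(counts[[ch]], length(idx),
                                       replace = TRUE)]
      codes <- base_codes(seqs[[ch]])
      svec <- numeric(length(idx))
      for (j in seq_len(L))
        svec <- svec + pwm$weights[j, codes[starts + j - 1L]]
      scores[idx] <- svec
    }
    scores
  })
  m <- mean(all_scores); s <- stats::sd(all_scores)
  if (!is.finite(s) || s == 0)
    stopf("degenerate background: score standard deviation is zero")
  list(motif_id = pwm$motif_id, mean = m, sd = s, n = as.integer(n),
       seed = as.integer(seed))
}

#' Z-score and normal-tail p-value for a PWM score
#'
#' @param score raw log-odds score(s).
#' @param bg background model from [sample_background()].
#' @param two_sided use a two-sided p (default FALSE: only high scores
#'   indicate matches).
#' @return data frame with `z` and `p`.
#' @export
zscore_p <- function(score, bg, two_sided = FALSE) {
  if (bg$sd <= 0) stopf("background sd must be > 0")
  z <- (score - bg$mean) / bg$sd
  p <- stats::pnorm(z, lower.tail = FALSE)
  if (two_sided) p <- 2 * stats::pnorm(abs(z), lower.tail = FALSE)
  data.frame(z = z, p = pmin(p, 1))
}

#' Scan peak sequences and report hits below a Z-score p cut-off
#'
#' @param seqs named character vector of peak sequences.
#' @param pwm log-odds PWM.
#' @param bg background model.
#' @param p_cut Z-score p-value cut-off (default 0.001).
#' @param both_strands scan both strands.
#' @return data frame: `seq_id`, `offset`, `strand`, `score`, `z`, `p`.
#' @export
scan_peaks <- function(seqs, pwm, bg, p_cut = 0.001, both_strands = TRUE) {
  out <- lapply(names(seqs), function(id) {
    hits <- scan_sequence(seqs[[id]], pwm, both_strands)
    if (!nrow(hits)) return(NULL)
    zp <- zscore_p(hits$score, bg)
    hits$z <- zp$z; hits$p <- zp$p
    hits <- hits[hits$p < p_cut, , drop = FALSE]
    if (!nrow(hits)) return(NULL)
    cbind(seq_id = id, hits, stringsAsFactors = FALSE)
  })
  out <- out[!vapply(out, is.null, logical(1))]
  if (!length(out))
    return(data.frame(seq_id = character(), offset = integer(),
                      strand = character(), score = numeric(), z = numeric(),
                      p = numeric(), stringsAsFactors = FALSE))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Expand a degenerate consensus pattern into explicit k-mers
#'
#' Supports bracket classes (`"AG[AT]GTG"`) and slash alternatives, where
#' `"X/Y"` means X or Y at one position (`"AGG/TTCA"` expands to AGGTCA and
#' AGTTCA).
#'
#' @param pattern pattern string over A,C,G,T with `[..]` and `/`.
#' @return character vector of explicit k-mers (full cartesian expansion).
#' @export
expand_pattern <- function(pattern) {
  chars <- strsplit(toupper(pattern), "", fixed = TRUE)[[1]]
  classes <- list()
  i <- 1L
  while (i <= length(chars)) {
    ch <- chars[i]
    if (ch == "[") {
      j <- i + 1L
      cls <- character(0)
      while (j <= length(chars) && chars[j] != "]") {
        cls <- c(cls, chars[j]); j <- j + 1L
      }
      if (j > length(chars)) stopf("unterminated '[' in pattern %s", pattern)
      if (!length(cls)) stopf("empty class in pattern %s", pattern)
      classes[[length(classes) + 1L]] <- cls
      i <- j + 1L
    } else if (ch == "/") {
      stopf("malformed pattern %s: '/' without preceding base", pattern)
    } else {
      if (!ch %in% DNA_BASES) stopf("invalid character '%s' in pattern", ch)
      cls <- ch
      while (i + 1L <= length(chars) && chars[i + 1L] == "/") {
        if (i + 2L > length(chars))
          stopf("malformed pattern %s: trailing '/'", pattern)
        alt <- chars[i + 2L]
        if (!alt %in% DNA_BASES) stopf("invalid alternative '%s'", alt)
        cls <- c(cls, alt)
        i <- i + 2L
      }
      classes[[length(classes) + 1L]] <- cls
      i <- i + 1L
    }
  }
  grids <- expand.grid(classes, stringsAsFactors = FALSE)
  unique(apply(as.matrix(grids), 1, paste, collapse = ""))
}

#' Fraction of sequences containing at least one of a set of k-mers
#'
#' @param seqs character vector of sequences.
#' @param kmers character vector of explicit k-mers.
#' @param both_strands also search the reverse complement (default TRUE).
#' @return the fraction in `[0, 1]`.
#' @export
fraction_containing <- function(seqs, kmers, both_strands = TRUE) {
  if (!length(seqs)) stopf("no sequences given")
  if (!length(kmers)) stopf("k-mer set is empty")
  up <- toupper(seqs)
  probe <- if (both_strands) unique(c(kmers, revcomp(kmers))) else kmers
  hit <- rep(FALSE, length(up))
  for (k in probe) hit <- hit | grepl(k, up, fixed = TRUE)
  mean(hit)
}

#' De novo k-mer motif discovery by exhaustive enumeration
#'
#' Counts, for every k-mer, the number of distinct sequences containing it
#' on either strand (reverse complements collapsed to the lexicographically
#' smaller canonical form). Motifs with support >= `min_support` are ranked
#' by support descending, ties by background z descending (when a scoring
#' function is supplied) then lexicographically.
#'
#' @param seqs named character vector of sequences.
#' @param k motif width, 4..12.
#' @param min_support minimal number of distinct supporting sequences
#'   (>= 2; the field-scale default for ~1,400 binding regions is 25).
#' @param zscore_fun optional `function(kmer) -> z` used for tie-breaking.
#' @return data frame: `kmer` (canonical), `k`, `support`, `rank`.
#' @export
discover_kmers <- function(seqs, k, min_support = 25L, zscore_fun = NULL) {
  if (k < 4L || k > 12L) stopf("k must be in [4, 12]")
  if (min_support < 2L) stopf("min_support must be >= 2")
  up <- toupper(seqs)
  if (all(nchar(up) < k)) stopf("all sequences shorter than k")
  per_seq <- lapply(up, function(s) {
    n <- nchar(s) - k + 1L
    if (n < 1L) return(character(0))
    words <- substring(s, seq_len(n), seq_len(n) + k - 1L)
    words <- words[!grepl("[^ACGT]", words)]
    unique(canonical_kmer(words))
  })
  support <- table(unlist(per_seq))
  support <- support[support >= min_support]
  if (!length(support))
    return(data.frame(kmer = character(), k = integer(), support = integer(),
                      rank = integer(), stringsAsFactors = FALSE))
  kmer <- names(support)
  sup <- as.integer(support)
  z <- if (is.null(zscore_fun)) rep(0, length(kmer))
    else vapply(kmer, zscore_fun, numeric(1))
  ord <- order(-sup, -z, kmer)
  data.frame(kmer = kmer[ord], k = k, support = sup[ord],
             rank = seq_along(ord), stringsAsFactors = FALSE)
}
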