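# Internal helpers shared across modules.

#' @keywords internal
"_PACKAGE"

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed))
    stop("seed must be a single non-missing number")
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv(), inherits = FALSE) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

DNA_BASES <- c("A", "C", "G", "T")

#' Reverse complement of DNA strings
#'
#' Vectorised over `x`; case is preserved, `N` maps to `N`.
#'
#' @param x character vector of DNA sequences.
#' @return character vector of reverse complements.
#' @export
revcomp <- function(x) {
  comp <- chartr("ACGTacgtNn", "TGCAtgcaNn", x)
  vapply(strsplit(comp, "", fixed = TRUE),
         function(ch) paste(rev(ch), collapse = ""), character(1))
}

#' Canonical (strand-collapsed) form of k-mers
#'
#' Lexicographic minimum of each k-mer and its reverse complement, so
#' strand-equivalent words collapse to one key.
#'
#' @param x character vector of k-mers.
#' @return character vector of canonical forms.
#' @export
canonical_kmer <- function(x) {
  rc <- revcomp(x)
  ifelse(x <= rc, x, rc)
}

# Map A/C/G/T (any case) to 1..4; anything else (N, mask artefacts) -> NA.
base_codes <- function(seq) {
  ch <- strsplit(toupper(seq), "", fixed = TRUE)[[1]]
  match(ch, DNA_BASES)
}

stopf <- function(...) stop(sprintf(...), call. = FALSE)

# 1-based inclusive [a, b] -> internal 0-based half-open [a - 1, b).
from_1based <- function(a, b) list(start = a - 1L, end = b)

is_count <- function(x) is.numeric(x) && length(x) == 1L && !is.na(x) &&
  x >= 0 && x == floor(x)
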