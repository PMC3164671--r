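# motif_analysis: log-odds construction, scanning, background, patterns,
# k-mer discovery.

uniform_pwm <- function(L = 6L) {
  build_log_odds(list(motif_id = "U", name = "U",
                      counts = matrix(1, L, 4,
                                      dimnames = list(NULL, c("A","C","G","T"))),
                      consensus = strrep("N", L)))
}

test_that("log-odds weights follow the smoothing formula", {
  # uniform counts + uniform background -> all-zero weights
  expect_true(all(abs(uniform_pwm()$weights) < 1e-12))

  # one-hot rows: consensus achieves the column-max sum
  counts <- matrix(0, 4, 4, dimnames = list(NULL, c("A","C","G","T")))
  counts[1, "T"] <- 10; counts[2, "G"] <- 10; counts[3, "T"] <- 10
  counts[4, "G"] <- 10
  pwm <- build_log_odds(list(motif_id = "M", counts = counts,
                             consensus = "TGTG"))
  hits <- scan_sequence("TGTG", pwm, both_strands = FALSE)
  expect_equal(hits$score[1], sum(apply(pwm$weights, 1, max)))

  # arbitrary cell against a literal recomputation
  set.seed(501)
  counts <- matrix(sample(0:9, 24, TRUE) + 1, 6, 4,
                   dimnames = list(NULL, c("A","C","G","T")))
  bg <- c(A = 0.3, C = 0.2, G = 0.2, T = 0.3)
  pwm <- build_log_odds(list(motif_id = "R", counts = counts,
                             consensus = "NNNNNN"), bg, pseudocount = 0.25)
  i <- 3L; b <- 2L  # row 3, base C
  manual <- log2(((counts[i, b] + 0.25 * bg[[b]]) /
                    (sum(counts[i, ]) + 0.25)) / bg[[b]])
  expect_equal(pwm$weights[i, b], unname(manual), tolerance = 1e-12)

  counts[2, ] <- 0
  expect_error(build_log_odds(list(motif_id = "Z", counts = counts,
                                   consensus = "NNNNNN")), "zero count")
})

test_that("scanning equals the naive double-loop scorer and is strand symmetric", {
  set.seed(502)
  pwm <- build_log_odds(list(
    motif_id = "M", counts = matrix(sample(1:9, 24, TRUE), 6, 4,
                                    dimnames = list(NULL, c("A","C","G","T"))),
    consensus = "NNNNNN"))
  seq <- random_dna(1, 200)
  got <- scan_sequence(seq, pwm)
  exp <- oracle_scan(seq, pwm$weights)
  key <- function(d) paste(d$offset, d$strand)
  m <- match(key(exp), key(got))
  expect_false(anyNA(m))
  expect_equal(got$score[m], exp$score, tolerance = 1e-12)

  # reverse-complementing the input permutes but preserves the score multiset
  got_rc <- scan_sequence(revcomp(seq), pwm)
  expect_equal(sort(got_rc$score), sort(got$score), tolerance = 1e-12)

  # N windows are dropped
  nseq <- paste0(substr(seq, 1, 50), "N", substr(seq, 52, 200))
  got_n <- scan_sequence(nseq, pwm)
  dropped <- setdiff(got$offset[got$strand == "+"],
                     got_n$offset[got_n$strand == "+"])
  expect_setequal(dropped, 45:50)
  expect_error(scan_sequence("ACG", pwm), "shorter")
})

test_that("background sampling is seeded, bounded and guards degeneracy", {
  set.seed(503)
  genome <- c(chrS = paste(sample(c("A","C","G","T"), 50000, TRUE,
                                  prob = c(.3,.2,.2,.3)), collapse = ""))
  pwm <- build_log_odds(list(
    motif_id = "M", counts = matrix(sample(1:9, 24, TRUE), 6, 4,
                                    dimnames = list(NULL, c("A","C","G","T"))),
    consensus = "NNNNNN"))
  b1 <- sample_background(pwm, genome, n = 20000, seed = 9L)
  b2 <- sample_background(pwm, genome, n = 20000, seed = 9L)
  expect_identical(b1, b2)
  b3 <- sample_background(pwm, genome, n = 5000, seed = 10L)
  # two independent estimates of the same mean: 4 standard errors apart max
  expect_lt(abs(b1$mean - b3$mean), 4 * b1$sd / sqrt(5000))

  expect_error(sample_background(uniform_pwm(), genome, n = 2000, seed = 1L),
               "degenerate")
  masked <- c(chrS = tolower(genome[[1]]))
  expect_error(sample_background(pwm, masked, n = 1000, seed = 1L),
               "1,000 valid")
})

test_that("masked and N positions never enter the background sample", {
  set.seed(504)
  # genome whose only unmasked windows sit in one clean stretch
  clean <- paste(sample(c("A","C","G","T"), 3000, TRUE), collapse = "")
  genome <- c(chrS = paste0(strrep("n", 500), clean, strrep("acgt", 200)))
  pwm <- build_log_odds(list(
    motif_id = "M", counts = matrix(sample(1:9, 24, TRUE), 6, 4,
                                    dimnames = list(NULL, c("A","C","G","T"))),
    consensus = "NNNNNN"))
  bg <- sample_background(pwm, genome, n = 2000, seed = 2L)
  expect_true(is.finite(bg$mean) && bg$sd > 0)
})

test_that("z-scores and normal tail p-values", {
  bg <- list(motif_id = "M", mean = 2, sd = 0.5, n = 1000L, seed = 1L)
  zp <- zscore_p(2, bg)
  expect_equal(zp$z, 0)
  expect_equal(zp$p, 0.5)
  # z at the 99.9th percentile of the standard normal
  zp2 <- zscore_p(2 + 0.5 * qnorm(0.999), bg)
  expect_equal(round(zp2$p, 4), 0.001)
  expect_equal(round(zscore_p(2 + 0.5 * 3.0902, bg)$p, 4), 0.001)
  scores <- seq(0, 5, by = 0.1)
  expect_true(all(diff(zscore_p(scores, bg)$p) < 0))  # strictly decreasing
  two <- zscore_p(2 - 1, bg, two_sided = TRUE)
  expect_equal(two$p, 2 * pnorm(-2))
})

test_that("degenerate patterns expand to the printed k-mer sets", {
  expect_setequal(expand_pattern("AGG/TTCA"), c("AGGTCA", "AGTTCA"))
  expect_setequal(expand_pattern("AG[AT]GTG"), c("AGAGTG", "AGTGTG"))
  expect_equal(expand_pattern("GGATCA"), "GGATCA")
  expect_setequal(expand_pattern("A[CG]G/TT"),
                  c("ACGT", "ACTT", "AGGT", "AGTT"))
  expect_error(expand_pattern("AG[AT"), "unterminated")
  expect_error(expand_pattern("/AG"), "without preceding")
  expect_error(expand_pattern("AG/"), "trailing")
})

test_that("fraction_containing counts sequences, not occurrences", {
  coup <- unique(c(expand_pattern("AGG/TTCA"), expand_pattern("TGTACT")))
  expect_equal(fraction_containing("AGGTCANNN", coup), 1.0)
  expect_equal(fraction_containing(c("CCCCCCCC", "GGGGGGGG"), coup), 0.0)
  # reverse-complement detection
  expect_equal(fraction_containing(revcomp("TTGTACTT"), "TGTACT"), 1.0)
  expect_equal(fraction_containing(revcomp("TTGTACTT"), "TGTACT",
                                   both_strands = FALSE), 0.0)

  set.seed(505)
  seqs <- random_dna(100, 60)
  carry <- sample(100, 32)
  for (i in carry)
    seqs[i] <- paste0(substr(seqs[i], 1, 20), "AGTTCA",
                      substr(seqs[i], 27, 60))
  got <- fraction_containing(seqs, coup)
  naive <- mean(vapply(seqs, function(s)
    any(vapply(c(coup, revcomp(coup)), function(k)
      grepl(k, s, fixed = TRUE), logical(1))), logical(1)))
  expect_equal(got, naive)
  expect_gte(got, 0.32)   # all planted carriers count
  # monotone under k-mer set growth
  expect_lte(fraction_containing(seqs, coup[1]), got)
  expect_error(fraction_containing(character(0), coup), "no sequences")
  expect_error(fraction_containing(seqs, character(0)), "empty")
})

test_that("k-mer discovery matches exhaustive counting and canonicalises strands", {
  set.seed(506)
  seqs <- random_dna(20, 40)
  got <- discover_kmers(seqs, k = 4, min_support = 2)
  sup <- oracle_kmer_support(seqs, 4)
  sup <- sup[sup >= 2]
  expect_setequal(got$kmer, names(sup))
  expect_equal(got$support, unname(sup[got$kmer]))
  expect_true(all(diff(got$support) <= 0))  # ranked by support desc

  # invariance under reverse-complementing any subset of the input
  flip <- seqs
  idx <- sample(20, 8)
  flip[idx] <- revcomp(flip[idx])
  got_flip <- discover_kmers(flip, k = 4, min_support = 2)
  expect_equal(got_flip[order(got_flip$kmer), c("kmer", "support")],
               got[order(got$kmer), c("kmer", "support")],
               ignore_attr = TRUE)

  # planted motif wins
  planted <- random_dna(50, 80)
  for (i in 1:30)
    planted[i] <- paste0(substr(planted[i], 1, 30), "ACCACA",
                         substr(planted[i], 37, 80))
  top <- discover_kmers(planted, k = 6, min_support = 25)
  expect_equal(top$kmer[1], canonical_kmer("ACCACA"))
  expect_gte(top$support[1], 30)

  expect_error(discover_kmers(seqs, k = 3, min_support = 2), "k must")
  expect_error(discover_kmers(seqs, k = 6, min_support = 1), "min_support")
  expect_error(discover_kmers(c("ACG", "TTA"), k = 6, min_support = 2),
               "shorter")
})
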