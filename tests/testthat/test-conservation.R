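# conservation: per-species matching, branch-length (Steiner subtree)
# scoring, and the retention rule.

toy_block <- function(rows, ref = "mm", chrom = "chrS", start = 0L) {
  size <- nchar(gsub("-", "", rows[[ref]], fixed = TRUE))
  list(ref_species = ref, ref_chrom = chrom, ref_start = start,
       ref_end = start + size, peak_id = "p1", rows = rows)
}

test_that("species matching: identical rows all match, gap rows never do", {
  rows <- c(mm = "ACGTACCACAGT", rn = "ACGTACCACAGT", hg = "ACGTACCACAGT")
  b <- toy_block(rows)
  expect_setequal(species_matches(b, 4L, "ACCACA"), c("mm", "rn", "hg"))

  rows2 <- c(mm = "ACGTACCACAGT", rn = strrep("-", 12))
  expect_equal(species_matches(toy_block(rows2), 4L, "ACCACA"), "mm")

  # reverse-complement occurrences count
  rows3 <- c(mm = "ACGTACCACAGT", rn = paste0("AC", revcomp("ACCACA"), "TTTT"))
  expect_setequal(species_matches(toy_block(rows3), 4L, "ACCACA"),
                  c("mm", "rn"))

  expect_error(species_matches(b, 10L, "ACCACA"), "outside")
})

test_that("species matching with gapped references follows alignment columns", {
  # reference has a gap; instance at ungapped offset 2 maps past it
  rows <- c(mm = "AC--GTACCACA", rn = "ACGGGTACCACA")
  b <- toy_block(rows)
  expect_setequal(species_matches(b, 4L, "ACCACA", window_slack = 0L),
                  c("mm", "rn"))
  # slack 0 and a shifted instance in the other species: no match
  rows2 <- c(mm = "AAAAACCACAAAAAAAAA", rn = "AAAAAAAAAAAAACCACA")
  expect_equal(species_matches(toy_block(rows2), 4L, "ACCACA",
                               window_slack = 0L), "mm")
  # generous slack finds it
  expect_setequal(species_matches(toy_block(rows2), 4L, "ACCACA",
                                  window_slack = 10L), c("mm", "rn"))
})

test_that("species matching equals a naive per-species search on random data", {
  set.seed(601)
  for (rep in 1:40) {
    width <- 40L
    species <- c("mm", "rn", "hg", "cf")
    rows <- setNames(random_dna(4, width), species)
    b <- toy_block(rows)
    off <- sample(0:(width - 6L), 1)
    kmer <- substr(rows[["mm"]], off + 1, off + 6)
    slack <- sample(0:8, 1)
    got <- species_matches(b, off, kmer, window_slack = slack)
    lo <- max(1, off + 1 - slack); hi <- min(width, off + 6 + slack)
    naive <- species[vapply(species, function(sp) {
      seg <- substr(rows[[sp]], lo, hi)
      sp == "mm" || grepl(kmer, seg, fixed = TRUE) ||
        grepl(revcomp(kmer), seg, fixed = TRUE)
    }, logical(1))]
    expect_setequal(got, naive)
  }
})

test_that("branch-length score equals exhaustive Steiner enumeration", {
  set.seed(602)
  for (n_leaves in c(4, 5, 6, 7, 8)) {
    tr <- random_tree(n_leaves)
    ref <- tr$tip.label[1]
    for (rep in 1:4) {
      sz <- sample(1:n_leaves, 1)
      matched <- unique(c(ref, sample(tr$tip.label, sz)))
      got <- branch_length_score(tr, matched, ref)
      expect_equal(got, oracle_steiner(tr, matched), tolerance = 1e-10)
    }
    # degenerate and saturated sets
    expect_equal(branch_length_score(tr, ref, ref), 0)
    expect_equal(branch_length_score(tr, tr$tip.label, ref),
                 sum(tr$edge.length), tolerance = 1e-12)
  }
  tr <- random_tree(5)
  expect_error(branch_length_score(tr, c("sp1", "nope"), "sp1"), "not in tree")
  expect_error(branch_length_score(tr, c("sp1", "sp2"), "sp3"), "reference")
})

test_that("branch-length score is re-rooting invariant and monotone", {
  set.seed(603)
  tr <- random_tree(7)
  ref <- "sp1"
  matched <- c("sp1", "sp3", "sp5")
  base <- branch_length_score(tr, matched, ref)
  for (node in c("sp2", "sp4", "sp6")) {
    rr <- ape::root(tr, outgroup = node, resolve.root = TRUE)
    expect_equal(branch_length_score(rr, matched, ref), base,
                 tolerance = 1e-10)
  }
  # adding species never decreases the score
  for (add in setdiff(tr$tip.label, matched)) {
    expect_gte(branch_length_score(tr, c(matched, add), ref) + 1e-12, base)
  }
})

test_that("retention needs the threshold crossed in enough distinct sequences", {
  inst <- data.frame(motif = "ACCACA",
                     seq_id = c("p1", "p2", "p3", "p4"),
                     bls = rep(1.5, 4))
  expect_true(retain_motifs(inst)$retained)          # boundary: exactly 4

  one_peak <- data.frame(motif = "ACCACA", seq_id = rep("p1", 10),
                         bls = rep(1.5, 10))
  r <- retain_motifs(one_peak)
  expect_equal(r$qualifying_hits, 1L)
  expect_false(r$retained)

  at_thresh <- data.frame(motif = "M", seq_id = paste0("p", 1:5),
                          bls = rep(1.0, 5))
  expect_equal(retain_motifs(at_thresh)$qualifying_hits, 0L)  # strict >

  # raising either threshold never retains a previously dropped motif
  set.seed(604)
  inst2 <- data.frame(motif = sample(c("A", "B"), 30, TRUE),
                      seq_id = sample(paste0("p", 1:8), 30, TRUE),
                      bls = runif(30, 0, 3))
  base <- retain_motifs(inst2, 1, 4)
  stricter <- retain_motifs(inst2, 2, 4)
  more_hits <- retain_motifs(inst2, 1, 6)
  for (m in base$motif) {
    expect_true(!stricter$retained[stricter$motif == m] ||
                  base$retained[base$motif == m])
    expect_true(!more_hits$retained[more_hits$motif == m] ||
                  base$retained[base$motif == m])
  }
})

test_that("score_conservation ties instances, blocks and tree together", {
  cfg <- sim_config(genome_length = 60000L, n_genes = 8L, n_peaks = 10L,
                    peak_length_range = c(61L, 150L), planting_rate = 1,
                    motif_conservation_rate = 1, seed = 11L)
  dat <- generate_dataset(cfg)
  seqs <- peak_sequences(dat$genome, dat$peaks)
  inst <- kmer_instances(seqs, "ACCACA")
  sc <- score_conservation(inst, dat$blocks, cfg$tree)
  expect_true(all(sc$bls <= sum(cfg$tree$edge.length) + 1e-12))
  planted_keys <- paste0(dat$truth$motif_positions$peak_id, ":",
                         dat$truth$motif_positions$offset)
  sc_keys <- paste0(sc$seq_id, ":", sc$offset)
  # every planted, fully conserved instance scores the whole tree
  m <- match(planted_keys, sc_keys)
  expect_false(anyNA(m))
  expect_equal(sc$bls[m], rep(sum(cfg$tree$edge.length), length(m)),
               tolerance = 1e-12)

  bad_tree <- ape::read.tree(text = "(x:1,y:1);")
  expect_error(score_conservation(inst, dat$blocks, bad_tree), "absent")
})
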