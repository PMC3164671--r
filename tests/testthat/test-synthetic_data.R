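# synthetic_data: determinism, truth consistency, planted-signal structure.

small_cfg <- function(...) {
  args <- utils::modifyList(list(genome_length = 60000L, n_genes = 8L,
                                 n_peaks = 12L,
                                 peak_length_range = c(61L, 200L),
                                 seed = 42L),
                            list(...))
  do.call(sim_config, args)
}

test_that("generate_genome hits the configured GC content and mask fraction", {
  cfg <- sim_config(genome_length = 10000L, gc_fraction = 0.5,
                    repeat_fraction = 0, n_genes = 2L, n_peaks = 2L,
                    peak_length_range = c(61L, 100L), seed = 5L)
  g <- generate_genome(cfg)
  bases <- strsplit(g[[1]], "")[[1]]
  expect_false(any(bases %in% letters))         # repeat_fraction 0
  freq <- table(factor(bases, levels = c("A", "C", "G", "T"))) / 10000
  # binomial 3 sigma at n = 10,000 and p = 0.25
  expect_true(all(abs(freq - 0.25) < 3 * sqrt(0.25 * 0.75 / 10000) + 0.015))
  gc <- mean(bases %in% c("C", "G"))
  expect_lt(abs(gc - 0.5), 0.03)

  cfg2 <- sim_config(genome_length = 50000L, repeat_fraction = 0.3,
                     n_genes = 2L, n_peaks = 2L,
                     peak_length_range = c(61L, 100L), seed = 5L)
  g2 <- generate_genome(cfg2)
  masked <- mean(grepl("[a-z]", strsplit(g2[[1]], "")[[1]]))
  expect_gte(masked, 0.29)         # planted in contiguous runs up to target
  expect_lt(masked, 0.45)
})

test_that("generators are pure functions of the config", {
  cfg <- small_cfg()
  d1 <- generate_dataset(cfg)
  d2 <- generate_dataset(cfg)
  expect_identical(d1$genome, d2$genome)
  expect_identical(d1$peaks, d2$peaks)
  expect_identical(d1$expr, d2$expr)
  expect_identical(d1$truth$motif_positions, d2$truth$motif_positions)
  d3 <- generate_dataset(small_cfg(seed = 43L))
  expect_false(identical(d1$genome, d3$genome))
})

test_that("count-based planting is exact and truth verifies by substring lookup", {
  cfg <- small_cfg(planting_rate = 0.6)
  dat <- generate_dataset(cfg)
  expect_equal(nrow(dat$truth$motif_positions), floor(0.6 * 12))
  seqs <- peak_sequences(dat$genome, dat$peaks)
  mp <- dat$truth$motif_positions
  k <- nchar(cfg$motif)
  for (i in seq_len(nrow(mp))) {
    word <- substr(seqs[[mp$peak_id[i]]], mp$offset[i] + 1, mp$offset[i] + k)
    expected <- if (mp$strand[i] == "+") cfg$motif else revcomp(cfg$motif)
    expect_identical(word, expected)
  }
  # both strands get used eventually
  big <- generate_dataset(small_cfg(n_peaks = 40L, planting_rate = 1))
  expect_setequal(unique(big$truth$motif_positions$strand), c("+", "-"))
})

test_that("planting_rate 1 places the motif in every peak", {
  dat <- generate_dataset(small_cfg(planting_rate = 1))
  seqs <- peak_sequences(dat$genome, dat$peaks)
  hit <- vapply(seqs, function(s)
    grepl("ACCACA", s, fixed = TRUE) || grepl(revcomp("ACCACA"), s,
                                              fixed = TRUE), logical(1))
  expect_true(all(hit))
})

test_that("frac_within_10kb 0 yields no TSS-window assignments", {
  dat <- generate_dataset(small_cfg(frac_within_10kb = 0, frac_within_1kb = 0))
  asn <- assign_peaks(dat$peaks, dat$genes)
  expect_equal(nrow(asn), 0L)
})

test_that("fully conserved motifs survive in all species; zero branch lengths freeze everything", {
  cfg <- small_cfg(motif_conservation_rate = 1)
  dat <- generate_dataset(cfg)
  leaves <- cfg$tree$tip.label
  total_len <- sum(cfg$tree$edge.length)
  for (sps in dat$truth$conserved_species) {
    expect_setequal(sps, leaves)
    expect_equal(branch_length_score(cfg$tree, sps, "mm"), total_len)
  }

  frozen <- ape::read.tree(text = "((mm:0,rn:0):0,(hg:0,gg:0):0);")
  cfg0 <- small_cfg(tree = NULL)
  cfg0$tree <- frozen
  dat0 <- generate_dataset(cfg0)
  for (b in dat0$blocks)
    expect_true(all(b$rows == toupper(b$rows[["mm"]])))
})

test_that("deep unconserved trees rarely preserve the motif in all leaves", {
  deep <- ape::read.tree(text = "((mm:2,rn:2):2,(hg:2,gg:2):2);")
  cfg <- small_cfg(motif_conservation_rate = 0, n_peaks = 40L,
                   planting_rate = 1, tree = NULL)
  cfg$tree <- deep
  dat <- generate_dataset(cfg)
  full <- vapply(dat$truth$conserved_species, function(s)
    length(s) == length(deep$tip.label), logical(1))
  # survival of a 6-mer over >= 4 subs/site paths is essentially nil
  expect_lt(mean(full), 0.05)
})

test_that("noise-free-limit expression reproduces planted fold changes", {
  cfg <- small_cfg(de_effect = log2(1.25), noise_sd = 1e-9)
  dat <- generate_dataset(cfg)
  de <- de_test(dat$expr, dat$groups)
  pt <- dat$truth$planted_targets
  fc <- de$fold_change[match(pt$gene_id, de$gene_id)]
  expect_equal(fc, 2^pt$true_log2fc, tolerance = 1e-6)
  others <- setdiff(de$gene_id, pt$gene_id)
  expect_equal(de$fold_change[match(others, de$gene_id)],
               rep(1, length(others)), tolerance = 1e-6)
})

test_that("config invariants are enforced", {
  expect_error(sim_config(seed = NULL), "seed")
  expect_error(sim_config(repeat_fraction = 1, seed = 1), "repeat_fraction")
  expect_error(sim_config(planting_rate = 1.2, seed = 1), "rates")
  expect_error(sim_config(noise_sd = 0, seed = 1), "noise_sd")
  expect_error(sim_config(genome_length = 1000, seed = 1), "10x")
  expect_error(generate_expression(small_cfg(n_samples_per_group = 1L),
                                   NULL, NULL), ">= 2 samples")
})
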