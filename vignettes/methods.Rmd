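---
title: "Methods: integrative transcription-factor target identification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: integrative transcription-factor target identification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(striatarget)
```

## The model

A transcription factor (TF) that directly regulates a gene should leave
two independent footprints: a binding event near the gene (a ChIP-seq
peak) and an expression change when the TF's dosage is perturbed. Neither
footprint alone is convincing — binding is often non-functional, and
expression changes are riddled with secondary effects — so the package's
central object is the *intersection*: a gene is called a direct target
only when it is both peak-proximal and differentially expressed. The
remaining stages characterize the binding itself: which sequence motifs
recur in the peaks, and which motif instances are old enough in
evolutionary time to be plausibly functional.

Everything downstream of peak calling and expression normalization is in
scope; peak calling, array/sequencing preprocessing and probe mapping are
not — peaks arrive as BED, expression as a normalized log2 matrix.

## Coordinates

All internal coordinates are 0-based half-open (`[start, end)`), the BED
convention. Gene tables must declare their convention in a header line
(`# coords: 0based-halfopen` or `1based-inclusive`); 1-based inclusive
spans `[a, b]` convert as `[a-1, b)`, an exact bijection that preserves
length. Converting once at the boundary removes the classic off-by-one
drift between browser-style spans and tool output. For a `-` strand gene
the TSS is `end - 1`, the last covered base.

## Peak annotation

A peak is anchored at its summit when one is recorded, else at its
midpoint — the summit is the best point estimate of the binding site, the
midpoint its neutral fallback; the choice matters only for peaks wider
than the distance bands. The anchor is compared with every TSS on the
same chromosome: within 10,000 bp yields an assignment, within 1,000 bp
additionally flags the inner window. Signed distance is negative upstream
*in the gene's orientation*. All genes within the window are kept (a peak
between two promoters is evidence for both), with `nearest = TRUE` on the
minimal-distance gene, ties broken lexicographically so reruns are
stable. Context classes follow strict precedence — TSS overlap, then exon
overlap, then intron (peak wholly inside the body), then
upstream/downstream of the anchor — so each (peak, gene) pair has exactly
one class. Isoforms are separate gene models sharing a symbol; collapsing
happens at reporting, matching transcript-level annotation practice.

## Differential expression

Per gene, Welch's unequal-variance *t* on log2 values; fold change is
reported on the linear scale treated/control so down-regulation reads as
FC < 1 (0.623 means a 1.6-fold drop). A moderated test (limma-style
shrinkage) would gain power at n = 4, but the thresholds — |FC| ≥ 1.25
and p < 0.05 — are the procedure's defined surface, and they are
test-agnostic; Welch keeps the stage free of empirical-Bayes internals
and exactly checkable against an independent implementation. Degenerate
rows (zero variance in both groups) get p = 1 when means agree and p = 0
otherwise, never NaN. BH q-values use the step-up rule with monotonicity
enforcement; the threshold filter deliberately uses p, not q, as its
default gate (the q column is reported for the caller).

## Motif scanning and the empirical background

TRANSFAC-style count matrices become log2-odds weights with a total
pseudocount of λ = 0.25 spread over the background frequencies
(`w[i,b] = log2(((c[i,b] + λ π_b) / (Σ c[i,·] + λ)) / π_b)`) — zeros are
common in curated matrices and must not produce −∞. Windows containing
`N` or masked bases score −∞ and are dropped rather than imputed. Both
strands are scanned; minus-strand hits are reported in forward
coordinates.

Significance uses an *empirical* null: sample window positions uniformly
with replacement from the unmasked genome (10⁷ at field scale;
configurable down for tests, ≥ 1,000 valid positions enforced), score
them, and convert observed scores to Z-scores against the sampled
mean/SD. The p-value is the one-sided upper normal tail — only high
scores indicate matches; a two-sided option exists for symmetry checks.
The normal approximation on a discrete score distribution is only
approximately calibrated in the extreme tail; the calibration test allows
for that slack explicitly.

De novo discovery replaces EM-based motif finding with exhaustive k-mer
enumeration at k = 6–7: support is the number of distinct sequences
containing the k-mer on either strand, reverse complements collapsed to
the lexicographically smaller form. Enumeration is deterministic,
oracle-checkable and exactly reproduces the "recurs in ≥ 25 sequences"
retention logic. Degenerate patterns (`AG[AT]GTG`, `AGG/TTCA` where the
slash marks a single variable position) expand to explicit k-mer sets
before searching.

## Conservation: branch-length score

For each motif instance, every aligned species either preserves the
instance (the k-mer occurs, either strand, within ± 10 alignment columns
of the instance — slack absorbs small alignment wobble) or does not. The
conservation score is the total branch length of the minimal connected
subtree of the phylogeny spanning the preserving species (the Steiner
subtree on leaves; equivalently the union of pairwise paths). The score
is parameter-free, depends only on the unrooted topology, and is
monotone: adding a species never decreases it. A published Bayesian
variant of this score exists but its exact formula is not reproducible
from public description; the deterministic subtree score preserves the
scale semantics the retention rule relies on — > 1 substitution/site
marks non-trivial conservation, > 2 deep conservation. The retention rule
itself is the defined procedure: keep a motif iff > 1 is reached in ≥ 4
*distinct* peak sequences (multiple instances in one peak count once).

## Enrichment statistics

Gene-set enrichment is the one-tailed hypergeometric upper tail
`P(X ≥ a)`; the EASE variant recomputes it with `a − 1` successes, a
conservative penalty that sends single-gene overlaps to p = 1. Sets are
intersected with the universe first; the universe defaults to the genes
actually tested for DE (the detectable-gene universe of the platform),
not the whole genome. The two-tailed Fisher exact test (for
overrepresentation questions) sums hypergeometric probabilities ≤ the
observed table's probability, with a 1 + 10⁻⁷ relative tolerance on the
comparison, matching standard practice.

## The synthetic world

The generator states one fixed world; its defaults are not tuned per
test:

* **Genome** 600 kb, GC 0.42 (mammalian-like), 20% repeat-masked in
  contiguous runs (geometric, mean 300 bp). Genes occupy the first half
  of the chromosome so truly intergenic peak placement is feasible.
* **Peaks** 50 regions of 61–428 bp (the reported ChIP size range);
  70% placed with anchors within 10 kb of a TSS (15 percentage points
  within 1 kb), the rest > 10 kb from every TSS.
* **Motif** `ACCACA` (a reported 6-mer) planted in exactly
  `floor(0.6 × 50) = 30` peaks — count-based planting by seeded shuffle,
  not per-peak Bernoulli, so tests can assert exact counts — on a random
  strand per instance, exercising reverse-complement handling.
* **Expression** 4 replicates per group (the study design), log2 noise
  SD 0.2 (typical array replicate noise), 20 planted targets drawn from
  peak-proximal genes with a ±1 log2 effect (2-fold). The effect size is
  a design decision: the detection cut-off is 1.25-fold, and the
  strongest printed validated targets change ~1.9–0.55-fold; a Welch
  4-vs-4 test at noise 0.2 has > 99% joint power (p < 0.05 and
  |FC| ≥ 1.25) at 2-fold, so the ≥ 90%-recovery acceptance check tests
  pipeline correctness, not sampling luck. At 1.5-fold the same power is
  ~85% and the check would be a coin flip.
* **Alignments** evolve outward from the reference leaf of an 8-species
  tree (total length 2.17 substitutions/site) under Jukes–Cantor-style
  substitution: per edge of length `b`, each site substitutes with
  probability `1 − exp(−b)`, uniformly to another base. Motif columns use
  `b × (1 − motif_conservation_rate)` (default 0.95, i.e. strong but not
  perfect constraint). Re-rooting the tree at the reference keeps the
  reference alignment row identical to the genome, which the truth
  bookkeeping and the annotation of planted instances rely on. No indels
  are simulated.

What the generator does *not* emulate: read-level noise, fragment-size
effects and summit uncertainty, probe effects, correlated expression
between genes, alignment errors and indels, non-uniform background
composition. A green suite therefore establishes that the *computations*
are correct and calibrated on a clean world — not that the thresholds are
optimal for real data.

## Numerical and degenerate-input choices

* RNG state is saved and restored around every seeded generator; each
  stage derives its own sub-seed, so stages are independently
  reproducible.
* Background sampling refuses degenerate nulls (SD = 0) and genomes with
  < 1,000 valid window positions.
* Fisher's test returns 1 whenever a margin is zero; BH on an empty
  vector returns an empty vector; empty peak or gene lists flow through
  annotation and integration as empty outputs, not errors.
* Duplicate BED names are suffixed, never dropped — silent deduplication
  would corrupt peak counts.
* Ties in nearest-gene assignment and k-mer ranking break
  lexicographically, making every output order deterministic.

## Known limitations

Single-TSS gene models (isoforms must be separate rows); hard-call
species matching rather than probabilistic alignment weighting; the
normal tail approximation for scan p-values is conservative only in
moderate tails; the pipeline CLI reads JSON configs (no YAML parser in
the supported dependency set); enrichment collections are user-supplied
two-column tables, not a bundled annotation database.
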