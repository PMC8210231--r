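---
title: "Screening non-coding recurrent mutations: methods and design"
author: "ncrmscreen authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Screening non-coding recurrent mutations: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ncrmscreen)
```

## The problem

Somatic mutations in the 98% of the genome that does not code for protein
are hard to interpret: there is no reading frame to disrupt, and the
sheer number of non-coding variants in tumor catalogs swamps any manual
curation. `ncrmscreen` implements a recurrence-based screen for candidate
cancer-related non-coding recurrent mutations (CNRMs): genomic positions
mutated in at least two independent tumor samples, across at least two
cancer types, that additionally carry the hallmarks of a functional
regulatory element — open chromatin, participation in a chromatin
interaction, and a predicted transcription-factor binding site (TFBS).
The rationale is probabilistic: given the genome's length, independent
samples hitting the same base by chance is rare, so recurrence across
samples and cancer types enriches for positions under positive selection
or at least mechanistically special, while the cross-cancer-type
requirement removes artifacts of localized, cancer-type-specific
mutational processes (for example UV-driven hotspots at transcription
factor binding sites in melanoma).

## The filtering cascade

The screen consumes two cohorts: a curated discovery catalog ("cohort 1",
with per-record tissue, individual, somatic-confirmation and SNP
annotations, as in COSMIC's non-coding variant set) and a WGS validation
cohort with linked expression data ("cohort 2", as in TCGA). Ten criteria
are applied in a fixed order, each logged in a funnel report:

1.  records from haematopoietic and lymphoid tissue are removed (solid
    tumors only);
2.  one sample is kept per individual;
3.  only mutations confirmed somatic in tumor plus matched normal are
    kept;
4.  mutations flagged as germline SNPs are removed;
5.  exonic mutations are removed (exon union over all transcripts of the
    gene annotation);
6.  positions mutated in ≥ 2 distinct samples are called recurrent, and
    of these only positions spanning ≥ 2 cancer types are kept;
7.  positions must also be mutated in cohort 2;
8.  positions must fall in open-chromatin peaks (ATAC-seq);
9.  positions must fall inside an anchor of a chromatin interaction
    (3C/4C/5C/Hi-C/ChIA-PET/Capture-C/IM-PET);
10. positions must fall inside a predicted TFBS with database match
    score ≥ 400.

Recurrence identity is by position `(chrom, pos)` only, not by allele:
this is what makes the downstream pattern-consistency classification
meaningful (a position is "same" when every supporting sample carries
the identical substitution, "different" otherwise). Consistent
substitutions are collapsed to the standard pyrimidine-reference
six-class spectrum (C>A, C>G, C>T, T>A, T>C, T>G) by
reverse-complementing purine-reference substitutions.

Criteria 1–4 are record-level predicates and commute; criteria 8–10 are
containment predicates and also commute in their final set. The fixed
order exists purely so funnel counts are comparable between runs; the
test suite verifies order-invariance of the final set separately.

Two deliberate tie-breaks, where the procedure as published leaves the
choice open, are: individual-level deduplication keeps the
lexicographically smallest sample identifier, and the coding-enrichment
check (observed exonic fraction against the exonic share of the genome)
is a one-sided exact binomial test.

## Coordinate conventions

Internally every interval is a Bioconductor `GRanges`, i.e. 1-based
closed — the native convention of the R genomics stack that this package
builds on. The 0-based half-open formats (BED/narrowPeak, the paired-
interval interaction dialect, the TFBS site table) are converted at
ingest and back-converted at export; GTF and mutation positions are
1-based on disk and stay 1-based. The BED line `chr1 99 100` therefore
denotes exactly the 1-based position 100, and the round trip through any
reader/writer pair is the identity. Mutations are single-nucleotide
substitutions only: indels and multi-nucleotide records are rejected at
ingest with a logged count, because both the pattern spectrum and the
motif-impact statistic are defined for single-base changes. Chromosome
names are normalized to the `chrN` form.

## Motif impact: the delta-bit statistic

For a position frequency matrix with per-base frequencies $p_{b,i}$, the
information content of column $i$ is

$$C_i = 2 + \sum_{b \in \{A,C,G,T\}} p_{b,i} \log_2 p_{b,i},$$

with $0 \cdot \log_2 0 = 0$, so $C_i$ ranges from 0 bits (uninformative
column) to 2 bits (invariant column). No pseudocounts are added: the
zero-frequency rule above handles empty cells.

A substitution at motif column $i$ changing base `ref` to `alt` is scored
by the change in sequence-logo letter height:

$$\Delta\mathrm{bit} = (p_{alt,i} - p_{ref,i}) \cdot C_i.$$

Negative values mean the mutation moves away from the preferred base of
an informative column — a weakened site. This letter-height convention
was chosen because it reproduces the intended sign semantics (mutations
at conserved consensus bases score negative) and is the convention of
sequence-logo practice; a log-ratio alternative
($\log_2 p_{alt} - \log_2 p_{ref}$) is available via the `method`
argument of `delta_bit()` for users who prefer an odds-style score, with
the caveat that it is infinite at zero frequencies. The statistic is
antisymmetric in (ref, alt) under both conventions.

For minus-strand sites the motif is read on the reverse strand: the
column index is reversed and the alleles complemented before lookup.
Per-site averages count each sample's mutation once. The expected
average delta-bit under random mutation placement is estimated by
resampling: draw `n_draw` mutations from the pool of all TFBS mutations
(default 100), average their delta-bits, repeat `n_reps` times (default
1000), and report the mean of the per-repetition averages. Sampling is
without replacement within a repetition and independent across
repetitions, under a mandatory seed.

## Resampling enrichment nulls

`resample_open_chromatin_fraction()` asks whether a focal mutation set is
enriched in open chromatin relative to a background catalog: each
repetition draws `n_draw` background mutations (without replacement by
default; a flag enables replacement) and records the fraction inside the
peak set. Empirical p-values use the bias-avoiding
$(r + 1)/(n_{\mathrm{reps}} + 1)$ estimator; both tails are exposed and the
two-sided p is twice the smaller tail, capped at 1. Because the in-peak
fraction lives on a lattice, tied null values make this estimator
conservative rather than exactly uniform — the test suite checks
validity ($P(p \le \alpha) \le \alpha$) and exchangeability via
randomized tie-broken ranks rather than naive uniformity.

The per-peak rate comparison (`per_peak_mutation_rate()`) splits peaks by
whether they contain a recurrent position and compares per-sample
mutation rates between the two groups with a two-sided Wilcoxon rank-sum
test (tie-corrected normal approximation; p fixed at 1 when every rate is
identical, and flagged as undefined when a partition is empty).

## Expression association

Target genes are assigned through chromatin interactions: gene G is a
candidate target of site S when some interaction has one anchor
overlapping S and the other anchor containing G's TSS, anchors being
treated symmetrically.

Because per-cancer-type sample sizes are small, expression is integrated
across cancer types as z-scores computed per gene within each cancer
type over **all** of that type's samples (sample SD, denominator
$n - 1$); the z-score reference population is thus mutated plus
wild-type samples together. Strata with fewer than two samples or zero
variance are masked and excluded from testing. The downstream test is
rank-based, so results are invariant to any monotone per-type
transformation of the raw expression scale.

For every site with at least `min_mutated` (default 5) mutated samples
having expression data — samples with *any* mutation in the site,
recurrent or not, since any regulatory-element mutation may affect the
target — each target gene is tested mutated-vs-wild-type with a
two-sided Wilcoxon rank-sum test. When both groups have at most 8
observations the exact permutation distribution is enumerated (valid
with ties, where the large-sample approximation degrades); otherwise the
tie-corrected normal approximation is used. Benjamini–Hochberg
adjustment is applied once across all (site, gene) tests of the screen;
the significance threshold is FDR < 0.25 with P < 0.1 reported per test,
and the family size is surfaced in the results so the threshold
sensitivity is visible. Wild-type means "no mutation in this site":
samples with any mutation in the site are excluded from the comparison
group.

Two companion checks guard the thresholds. The neighbor-specificity
table re-runs the identical test on the k nearest genes by TSS distance
(default k = 4, configurable per locus) without multiplicity adjustment:
a specific regulatory effect should light up the focal gene only. The
FDR-validation simulation draws random gene sets and random
pseudo-mutated sample splits (defaults 1000 genes, 38 vs the rest, 100
repetitions), runs the full test-plus-BH machinery per repetition, and
counts FDR < 0.25 discoveries; with no true signal this measures the
false-discovery yield of the chosen threshold. A `mutated_samples`
argument can pin the carrier set, turning the same machinery into a
power check against planted effects.

## The synthetic cohort generator

`generate_cohort()` builds a complete, seeded fixture bundle emulating
the structure of the real inputs: a toy genome (default 2 chromosomes ×
1 Mb) with evenly spaced 6 kb genes of 3 exons each; a curated cohort
(default 60 samples) and a WGS cohort (default 80 samples) over four
cancer-type labels; ~30 background SNVs per sample; open-chromatin peaks
covering ≈ 8% of the genome (matching the genome-wide open-chromatin
fraction a screen of this kind assumes); background interaction anchor
pairs; five strong-consensus motifs (consensus frequency 0.85) with
planted site instances; and a log-normal expression matrix.

Seven planted CNRMs satisfy all ten criteria by construction: each sits
at the most informative consensus column of a planted TFBS (score
≥ 480) inside a peak that is itself an interaction anchor whose partner
anchor contains the target gene's TSS, and is carried by 3 cohort-1
samples spanning ≥ 2 cancer types and 6 cohort-2 samples. The planted
alternate allele is the column's least-frequent base, so the expected
delta-bit sign is negative. Eleven decoys each fail exactly one named
criterion (hematopoietic tissue, duplicate individual, unconfirmed
somatic, SNP flag, exonic, single sample, single cancer type, absent
from cohort 2, outside peaks, anchor-less peak, sub-threshold site
score). Background mutation positions are drawn disjoint from all
planted/decoy positions, and background peaks and anchors are kept out
of a ±1.5 kb window around every engineered locus so that each decoy
fails only its own criterion and target-gene assignment stays exactly as
planted.

Expression effects default to a 2 within-type-SD down-shift in all
planted sites' target genes for the mutated samples (the screen's
working regime; all three published example loci show decreased
expression). The effect size, the affected fraction and every density
above are configuration fields. What the generator does *not* emulate —
mutational signatures and trinucleotide context, copy-number structure,
purity/batch covariates, realistic peak-width and interaction-distance
distributions — bounds what passing tests show about real data: they
validate the screening logic and its statistics, not robustness to those
biological confounders.

Problem sizes in the shipped test suite (cohorts of 45–90 samples,
15–30 mutations per sample, 10–50 seeds per property) were chosen so
that every stochastic check has comfortable Monte Carlo margins while
the suite stays quick to run.

## Numerical and degenerate-input choices

- PFM columns must sum to 1 within 1e-6 at use and 1e-9 after parsing;
  zero-total count columns are a format error.
- Empty stages propagate gracefully: an empty CNRM set yields empty
  delta-bit and association reports, not an error.
- `six_class_spectrum` proportions are exact rational counts over the
  "same" subset and sum to 1 within 1e-12.
- Funnel retention percentages are rounded to 0.1 for reporting only;
  internal counts are integers.
- Every resampling routine takes a mandatory seed, restores the caller's
  RNG state, and is bit-reproducible; pipeline outputs embed a hash of
  the parameter set so identical configurations are recognizable.

## Known limitations

- Recurrence counts distinct sample identifiers after deduplication;
  cohorts whose sample/individual mapping is unreliable will over- or
  under-count recurrence.
- The screen treats peak sets from different cancer types as a merged
  union; cancer-type-specific chromatin is not modeled.
- The delta-bit statistic scores single substitutions against a fixed
  PFM; it is not a binding-affinity model, and sites are consumed from a
  precomputed prediction table rather than re-scanned.
- BH is applied across the whole screen as one family; analysts wanting
  per-site or per-gene families should adjust the exported per-test
  p-values themselves.
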