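---
title: "Post-assembly diagnostics: models, thresholds and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Post-assembly diagnostics: models, thresholds and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

contigqc implements the diagnostic analyses that follow a long-read genome
assembly: deciding, contig by contig, what each sequence most plausibly is
(autosome, sex chromosome, collapsed repeat, contaminant), and
characterising the variant landscape, phasing structure and comparative
completeness of the result. This vignette explains the underlying models,
the tunable parameters, what the synthetic-data generator does and does not
emulate, and the design decisions taken where conventions genuinely differ
between tools.

## The per-contig diagnostic model

A haploid assembly of a diploid individual carries several recognisable
contig populations, and three cheap statistics separate them:

* **Read depth at two MAPQ strata.** Median per-base depth is computed
  once over all primary alignments and once restricted to mapping quality
  strictly greater than 20 (`mapq_min` in `threshold_config()`; the strict
  inequality is deliberate). In a male individual, autosomes sit at the
  primary depth mode and the X/Y contigs at roughly half of it — depth is
  bimodal. Collapsed repeats are the diagnostic exception: many copies of
  the genomic repeat pile their reads onto one assembled copy, so all-read
  depth is far *above* the autosomal mode while confidently-placed (high
  MAPQ) reads almost vanish.
* **Unique k-mer fraction.** For each contig we count every k-mer
  (k = 21 by default) and report the fraction of *distinct* k-mers seen
  exactly once. Sequence assembled from low-complexity tandem arrays has
  almost no unique 21-mers; ordinary unique sequence is close to 1.0.
  K-mers are canonicalised (a k-mer and its reverse complement count as
  one) because genomes are double-stranded; both the canonicalisation and
  the distinct-vs-positional convention are switchable, since published
  descriptions of "fraction of k-mers present once" are ambiguous on both
  points. Distinct + canonical is the default.
* **Telomere-motif enrichment.** Non-overlapping occurrences of TTAGGG
  and its reverse complement are counted per contig and expressed as fold
  enrichment over the assembly-wide motif density. Collapsed subtelomeric
  arrays are typically several-fold enriched; the flag threshold is
  4-fold. The baseline is assembly-wide rather than restricted to
  nonrepetitive contigs — the alternative was considered and makes almost
  no numerical difference because nonrepetitive sequence dominates total
  length, but assembly-wide is the simpler contract.

`classify_contigs()` applies the rules in a fixed order: collapsed repeat
(unique k-mer fraction < 0.90) first, then sex candidate, then autosomal,
else unresolved. Collapsed wins deliberately: a collapsed contig's
high-MAPQ depth is an artefact of ambiguous placement, so its depth is not
evidence about copy number.

Depth cutoffs are *relative*: sex candidates fall below 30/52 of the
estimated primary mode and autosomes above 45/52 of it. At a primary mode
of 52-fold these reproduce the absolute cutoffs (<30, >45) used at the
coverage the defaults emulate, but the same rules transfer unchanged to a
simulation — or a resequencing run — at any other coverage.

### Depth-mode estimation

`estimate_depth_modes()` builds a length-weighted histogram of per-contig
median depths at bin width 1, smooths it with a centered moving average
(window 5), and takes the two highest local maxima at least 10 bins apart;
the primary mode is the higher-depth peak. Two numerical details matter.
Median over an even count is the mean of the central pair (depths are
integers, so halves occur). And because smoothing flattens an isolated
spike into a plateau whose leftmost bin would otherwise win, each selected
peak is snapped to the heaviest raw bin within the smoothing half-window.

## MinHash contaminant screening

Contigs are screened against two reference genomes — the expected
conspecific and a suspected contaminant — by Mash distance. Each sequence
is reduced to the `sketch_size` smallest 64-bit hashes of its canonical
21-mers (500,000 by default at genome scale; far fewer suffices for small
inputs). The hash is a fixed splitmix64 finalizer truncated to 53 bits, so
sketches are exactly representable as R doubles and reproducible across
platforms. The bottom-sketch estimator of the Jaccard index j feeds the
distance

d = -(1/k) ln( 2j / (1 + j) ),

with d = 0 at j = 1 and a cap of 1 at j = 0. When a sketch holds a
sequence's full hash set the estimator degenerates to the exact Jaccard,
which the tests exploit.

Sketch distances are unreliable for very short contigs. Below
`small_contig_bp` (default 10,000 bp — a documented judgement call; the
operational cutoff used at genome scale is not published), or when a
contig shares no sketch hashes with either reference, the screen falls
back to alignments: the single longest aligned block (PAF column 11) to
each reference is compared, ties and absent alignments leaving the contig
unresolved. Summed block length is available behind a flag but the single
longest block is the default, matching the longest-aligned-region rule the
screen reimplements.

## Dual-caller variant consensus

Long-read callers emit bimodal quality distributions: an error mode and a
true-call mode. `detect_quality_dip()` finds the valley — integer-bin
histogram, window-3 smoothing, the two largest local maxima at least 10
units apart, and the minimum bin strictly between them, leftmost on ties.
The detection the pipeline emulates was originally done by eye; the
smoothing window, separation and tie-break are therefore package choices,
documented and configurable. Filtering keeps calls with quality *strictly
above* the threshold. A unimodal histogram returns the configured
fallback (14 by default, 20 being typical for the second caller the
defaults model).

Before intersection, records are normalized: multiallelics split, shared
prefix/suffix trimmed, indels left-aligned by the standard
truncate-or-extend-left loop against the assembly. Intersection matches on
(contig, position, ref, alt) exactly. Insertion/deletion designation is
relative to the haploid assembly — at a heterozygous indel the assembly
arbitrarily carries one allele, so the labels have no deeper meaning, and
the package keeps them only as bookkeeping.

Genic partitioning anchors each variant at its first altered base (the
record position for SNVs, the next base for normalized indels — interval
semantics for indel overlap are a package choice), with exon taking
precedence over intron. Exonic depletion is reported as genome exonic
fraction divided by variant exonic fraction, rounded to one decimal in
reports; the indel frame spectrum splits indel lengths by divisibility by
3 per region; per-gene statistics count exonic 1-bp indels per exonic kbp
with a log2 gene-length binning. SNP densities by contig class default to
heterozygous genotypes only.

## Phase blocks

Blocks per contig are distinct PS values among phased heterozygous
records. Contigs whose het records carry no PS at all are counted
unphased and excluded from the single-block and three-or-fewer fractions;
whether published fractions of this kind include variant-free contigs is
usually unstated, so the denominator policy is recorded in the output and
an all-contigs alternative is selectable.

## BUSCO comparison

Category percentages use the sum of the four categories (single, duplicated,
missing, fragmented) as denominator, which reproduces published compleasm
tables to the printed decimal. Rounding is half away from zero — two
decimals for percentages, nearest integer for cross-species means — and
means include the focal species by default (the bundled table's printed
duplicated mean, 116, only arises under that convention; a flag excludes
the focal species). Upset analysis partitions the BUSCO universe by exact
presence pattern, so cardinalities sum to the universe size; ties in the
ranking break by pattern bit-order. The ancestral-loss adjustment
subtracts BUSCOs missing in *every* species from each species' missing
count and from the lineage total, separating clade-level gene loss from
assembly error.

## The synthetic-data generator

Every stage is testable without external data because the generator emits
a genome whose truth is known by construction:

* ~20 contigs, ~5 Mbp total: 12 autosomal (250–350 kbp, GC 0.41), 4
  sex-linked (150–250 kbp, GC 0.40), 3 collapsed (60–120 kbp, GC 0.44,
  a 50-bp tandem unit soft-masked lowercase plus a 5-kbp telomere array),
  1 contaminant (30–60 kbp) from a distinct composition model (GC 0.55,
  independent k-mer source).
* Depth targets 52× (autosomal), 26× (sex), 150× (collapsed), with
  collapsed-contig reads mapped at MAPQ 0 with probability 0.95 —
  the ambiguous-placement proxy; reads are error-free, ungapped and
  sequence-free (SAM SEQ `*`), because every diagnostic consumes
  placement, span and MAPQ only, and exact reads make the pileup oracle
  exact.
* Heterozygous SNVs at 2.4/kbp (autosomal) and 0.12/kbp (sex) — a 20-fold
  contrast; indels at 0.5/kbp with exonic thinning (keep 0.3) and further
  frameshift thinning (keep 0.2, i.e. a 5× frame-disruption suppression).
* Gene models at 9 genes/Mbp with exon/intron means 156/1,605 bp, which
  yields a genome ~0.8% exonic and ~6.6% intronic — the proportions of an
  annotated delphinid assembly.
* Two call sets share every true variant; each adds 30% caller-specific
  false calls. Quality modes (error/true) are N(8,2)/N(30,6.5) and
  N(12,2.5)/N(38,7), chosen once so the mixture valleys sit at 14 and 20;
  the planted valley recorded in the truth tables is the numerical argmin
  of the realized mixture, not an assumed constant.
* Phase blocks are planted by quota — 55% of het-bearing contigs in one
  block, 80% in at most three — then realized as contiguous cuts of each
  contig's sorted het positions, PS being the position of the block's
  first record.
* The BUSCO fixture plants 33 ids missing in all species, the requested
  lineage-specific sets verbatim, and leaves the remainder single-copy in
  a universe of 12,234.
* The contaminant screen's references are the host contigs (respectively
  the contaminant source) mutated at 2 substitutions per 100 bp, the
  divergence scale of a congeneric reference genome.

What the generator does **not** emulate — and what passing tests therefore
do not establish about real data: sequencing error and its interaction
with variant calling; realistic read-length distributions; GC-coverage
bias; structural variation; haplotype-switch errors within phase blocks;
mosaic repeat structure (collapsed contigs are pure tandem arrays);
fragmented or duplicated BUSCO statuses arising from real misassembly.
Real inputs arrive through the same FASTA/SAM/VCF/GFF3/PAF/TSV readers,
so the pipeline applies unchanged; only the guarantees are weaker.

All randomness flows through one seeded generator per invocation (the
caller's RNG state is untouched), and identical spec + seed gives
byte-identical FASTA/SAM/VCF/GFF3/TSV output.

## Problem sizes and runtime

The default synthetic genome (~5 Mbp, ~52,000 simulated reads, ~14,000
variant calls, a 12,234-id BUSCO universe) runs the full pipeline in about
a minute on one CPU; the test suite uses a ~0.3 Mbp variant of the same
spec for module tests and the full default for the end-to-end recovery
checks. These sizes were chosen to keep every k-mer, pileup and
interval computation exactly checkable against brute-force oracles while
still exhibiting the depth bimodality, quality valleys and density
contrasts the methods detect. One statistic is materially noisy at this
scale: the sex class carries only ~110 expected SNVs (~0.9 Mbp at
0.12/kbp), so the recovered autosomal:sex density ratio has a sampling
coefficient of variation near 10% around its planted 20-fold value.

## Interface notes

The package is driven from R: tibble-in/tibble-out functions, a
`run_pipeline()` orchestrator with per-stage manifests and checksum-based
caching, and `plot_*()`/`autoplot()`/`tidy()`/`glance()` methods for the
result objects. No shell entry point is shipped — `run_pipeline()` plus
the IO functions are the pipeline interface, and `scripts/acceptance.R`
shows a complete scripted invocation.

## Known limitations

* Depth-mode estimation assumes an integer-binned, reasonably populated
  histogram; with very few contigs the secondary mode may be missed
  (single-contig input returns that contig's depth and no secondary).
* The sex/autosome split is purely depth-based; pseudoautosomal regions
  and X-autosome translocations are out of scope.
* The contaminant screen is a two-reference comparison, not taxonomic
  classification.
* `small_contig_bp` (10 kbp) and the dip-detection smoothing parameters
  are judgement calls; both are exposed in the configuration objects.
* Ins/del designation, and therefore the ins:del ratio of a call set, is
  an artefact of the haploid reference state.
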