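---
title: "Methods: small RNA-seq annotation, novel miRNA discovery and X-inactivation inference"
author: "parthenomir"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: small RNA-seq annotation, novel miRNA discovery and X-inactivation inference}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(parthenomir)
```

## The problem

Parthenogenetic primate embryonic stem cells carry two maternal genomes,
and one of the open questions about any female ESC line is the activity
state of its X chromosomes: has one X been silenced (the somatic default),
or are both active (common in early or na&iuml;ve pluripotent states)?
Small RNA sequencing answers several questions at once for such lines:
which miRNAs they express, whether novel (unannotated) miRNAs are present,
how expression compares between lines, and -- because miRNA output scales
with gene dosage -- whether X-linked miRNAs are expressed at a one-X or a
two-X level.

`parthenomir` implements that complete analysis as a tested pipeline:

1. **Read cleaning** -- 3' adaptor trimming and removal of contaminant,
   too-short/too-long and low-quality reads ("clean reads", 18--30 nt).
2. **Tag collapsing** -- unique sequences with per-sample read counts.
3. **Exact genomic mapping and priority annotation** -- each tag resolves
   to exactly one class under
   `rRNA (Genbank) > rRNA (Rfam) > known miRNA > repeat > exon > intron`,
   with mapped-but-unannotated tags labelled `unann`.
4. **Novel miRNA calling** -- unannotated tag loci are excised with
   flanking sequence, folded, and accepted only if they look like Dicer
   substrates (stable stem, mature on one arm, homogeneous 5' ends).
5. **Quantification** -- TPM (`count / clean_total * 1e6`), a Poisson
   random-bin noise filter, and 10-kb genomic cluster grouping.
6. **Differential expression** -- exact two-library count tests with
   fold-change and significance flags.
7. **XCI inference** -- chromosome-wide log2 ratios against a male
   baseline with chromosome 1 as a control.

A synthetic-data module generates toy genomes and libraries with complete
ground truth, so every stage is verifiable at desk scale without any
external download.

## The synthetic study

`sim_config()` fixes the study conditions; `generate_toy_genome()` and
`simulate_library()` realise them.

* **Genome**: `n_autosomes` autosomes plus a chrX (default 3 + X at
  200 kb each).  Planted elements:
  * *known miRNAs* (8 per chromosome) -- perfect-complement hairpins:
    mature arm (19--26 nt) + 4 nt GC-rich stem extension + 10 nt
    A/C loop + the reverse complement of extension and arm.  The
    extension keeps the mature arm at least 2 nt away from the terminal
    loop, and the A/C loop cannot pair with itself.
  * *cluster groups* -- 3 precursors with first nucleotides 2.5--4 kb
    apart (within the 10-kb rule); all other miRNA-class loci are spaced
    more than 10 kb apart so the planted clusters are exactly the true
    clusters.
  * *novel miRNAs* -- hairpins identical in construction to known ones
    but absent from the annotation, so their reads surface as `unann`.
  * *noise miRNAs* -- annotated precursors with sporadic expression
    (a fraction of a read expected per library), the targets of the
    noise filter.
  * *decoys* -- loci with no complementarity whose reads scatter their
    5' ends over six positions; they must be rejected by the hairpin
    and Dicer criteria.
  * *feature tracks* -- rRNA (Genbank and Rfam tiers), repeats, exons,
    introns, which receive degradation reads.
* **Libraries**: expected counts per locus are lognormal within each
  class; reads are Poisson draws around them.  Clean-read composition is
  roughly 60% known miRNA, 15% other annotated classes and 25%
  unannotated (novel + background), mirroring what deep ESC small RNA
  libraries look like after annotation.  Raw reads are a fixed 35 nt:
  insert + 3' adaptor, truncated.  5% adaptor-free contaminants and 5%
  low-quality reads (mean Phred < 20, drawn far below the threshold) are
  added on top.  Insert lengths follow a distribution over 19--28 nt
  peaked at 22--23 nt; a 35-nt raw read cannot carry a longer insert and
  still leave the 6-base adaptor overlap the trimmer needs, which is also
  why the simulator refuses mature arms longer than
  `raw_read_len - min_adaptor_overlap`.
* **X dosage**: samples are `male`, `one_active_X` or `two_active_X`;
  the last multiplies the expected output of every X-linked miRNA by
  `xci_ratio` (default 2) and leaves autosomes untouched.  chrX carries a
  fixed ~8% share of each class's expression, as in real libraries where
  the dominant miRNA clusters are autosomal; this keeps the autosomal
  TPM dilution caused by doubled X output small (about -0.07 log2), so
  chromosome 1 profiles stay parallel across samples.
* **Reproducibility**: every library draws from an RNG stream derived
  from the config seed and the sample name, so adding a sample never
  changes another sample's reads.

What the simulation deliberately does **not** model: sequencing errors
(beyond whole-read low quality), isomiRs and RNA editing, imperfect
biological hairpins, multi-mapping repeat families, GC or ligation bias.
Passing the truth-recovery suite therefore demonstrates correctness of
the computations, not robustness to every artefact of real libraries.

## Read cleaning

The trimmer scans each read left to right and accepts the first position
where a prefix of the adaptor, at least `min_overlap = 6` bases long,
matches with at most one mismatch per 10 aligned bases (configurable;
zero for exact matching).  Reads with no detectable adaptor or containing
`N` are contaminants.  After trimming, inserts shorter than 18 nt, longer
than 30 nt, or with mean Phred quality below 20 are removed -- each read
is booked into exactly one counter, and
`clean = raw - contaminant - too_small - too_long - low_quality` holds
exactly.  The retained window and the <18 nt rule follow the clean-read
definition this pipeline reproduces; the upper bound and the quality
threshold are declared defaults, since the original filtering criteria
beyond "low-quality" are not public.

## Mapping and priority annotation

Tags are matched exactly against both strands (Biostrings `matchPDict`
behind the `map_tags()` surface, verified in the tests against a naive
position-by-position scan).  Feature overlap is any shared base, in
half-open coordinates, strand-blind for category resolution.  When a tag
overlaps features of several classes, the highest-priority class wins;
the whole tag count goes to that single class, which is how the
category proportions stay a partition of the clean total.

Known-miRNA assignment is a coordinate rule: a same-strand hit
overlapping a precursor, preferring hits within 3 nt of the annotated
mature arm, then the precursor whose mature start is nearest (ties by
name).  This replaces a sequence-similarity catalog search, which needs
an aligner and adds nothing on a toy genome where matches are exact.

One artefact of exact matching on perfect hairpins is worth knowing: the
reverse complement of a mature tag *is* the star-arm sequence, so a tag
also hits the star locus on the opposite strand.  Both hits fall inside
the same precursor, so annotation is unaffected, but the novel-miRNA
caller can report one hairpin locus on both strands; consumers counting
loci should reduce calls strand-blind (the acceptance script does).

## Novel miRNA calling

Unannotated mapped tags (per sample, merged when their loci overlap on
one strand, and supported by at least `min_support = 3` reads -- a
support floor is standard in hairpin callers, and the Dicer criterion is
meaningless for a single read) are excised in two windows: the locus as
putative 5' arm extended 150 nt downstream, and as putative 3' arm
extended 150 nt upstream.

Folding is weighted base-pair maximisation (dynamic programming over
nested structures; GC = 3, AU = 2, GU = 1, minimum loop 3).  The reported
`mfe` is the negated pair weight -- declared score units, deliberately
**not** comparable to thermodynamic kcal/mol; the acceptance threshold
`mfe_max = -18` is calibrated to this score.  Tie-breaking is
deterministic (unpaired preferred, then the smallest outer index), and
the tests pin the score to an independent memoised recursion and, at
small lengths, to exhaustive enumeration of every nested pairing.

A candidate is accepted only if, in order: (a) `mfe <= -18`;
(b) at least 16 base pairs connect the mature arm to the opposite arm
(pairs of one nested stem all lie on one side, so this is the count of
mature positions paired across the loop); (c) the mature tag sits
entirely on one arm -- no pairing within itself, at most 2 stray pairs to
the minority side -- and ends at least 2 nt before the terminal loop;
(d) at least 90% of supporting reads share one 5' start (the sequencing
signature of a precise Dicer cut); (e) the mature is 18--26 nt.  The
first failed criterion is recorded as the rejection reason.  All
thresholds are exposed; none are claimed to equal the original tool's
internal settings, which were never published.

A locus is called in a sample if either window passes, and the shared
list keeps loci called in every sample (same strand, >= 1 base overlap).
On the default simulation the caller recovers 100% of planted hairpins
and accepts no decoys (acceptance suite: >= 90% and <= 5% over three
seeds).

## Quantification, noise filtering, clusters

TPM is exact: `count / clean_total * 1e6`.  The noise filter samples
10,000 random 50-bp bins per chromosome, counts mapped-read starts per
bin, sets the background rate lambda to the mean bin count, and finds the
smallest count `c*` whose upper-tail Poisson probability is below 1e-4;
a miRNA survives if its TPM reaches `max(3, TPM(c*))` in at least one
sample.  The 3-TPM floor and the Poisson criterion are combined with
`max` because how the two interacted originally is ambiguous; both are
reported.  Note the threshold's scale behaviour: lambda is proportional
to depth/genome-length, so on a multi-gigabase genome the Poisson term
is far below the 3-TPM floor (the floor dominates), while on a compact
toy genome the mean bin count is inflated by the miRNA loci themselves
and the Poisson term dominates.  The planted expressed miRNAs sit far
above either value, and the sporadic loci far below, so the filter's
behaviour is fully exercised either way.

Clusters chain miRNAs along each chromosome whose precursor *first
nucleotides* (strand-aware: the 5' end of the hairpin transcript) are at
most 10,000 bases apart, inclusive -- "within 10 kb" read inclusively,
with single-linkage chaining because genomic miRNA clusters are
conventionally maximal runs, not all-pairs cliques.  The output is a
partition, invariant to row order, and ranked by summed TPM.

## Differential expression

For two unreplicated libraries the comparison conditions on the summed
count: under equal relative expression, the count in library A given the
total is binomial with probability `nA / (nA + nB)`.  This exact
conditional Poisson test is the test to which the classic two-library
posterior-predictive test is asymptotically equivalent; the conditional
form was chosen because it is *exactly* antisymmetric -- swapping the
libraries provably negates every log ratio and preserves every p-value,
which the property suite asserts.  Ratios are
`log2((TPM_A + pc) / (TPM_B + pc))` with a 0.5-TPM pseudocount applied
only when a side is zero; flags require fold change > 2 and p < 0.05.
No multiple-testing correction is applied, matching the analysis this
package reproduces; the p-values are reported so callers can adjust.
Sample-level structure uses average-linkage clustering on
`1 - Pearson(log2(TPM + 1))`.

## X-inactivation inference

For each chromosome the baseline is the per-miRNA median TPM over male
samples (zero-baseline miRNAs are flagged and excluded -- no meaningful
ratio exists).  A sample's profile is `log2((TPM + 0.5*) / (baseline +
0.5*))` in position order (*pseudocount only when a side is zero), with a
centered moving average (default window 5 miRNAs; near the ends the
window is anchored inside the series at full width, so a window equal to
the series length averages the whole series everywhere).  The window
size is a declared default: the visualisation tool originally used for
these plots does not document one.

The caller compares a female sample's X-linked log2 ratios against the
pooled reference samples' X ratios with a two-sided Mann--Whitney test,
and runs the identical comparison on chromosome 1 as a control.  Two
design choices matter here:

* **Effect-size gating.**  A rank test's null rejection rate is ~5%
  no matter how small the noise, so raw p-values alone cannot give a
  decisive caller.  The X is considered elevated only when the test is
  significant *and* the elevation (median X ratio minus median chr1
  ratio) exceeds `elevation_min = 0.5` (~1.4-fold) -- well below the 1.0
  expected for a doubled X, well above noise.  Symmetrically, the chr1
  control flags an artefact only when significant *and* shifted by more
  than `elevation_min`, which is exactly the signature of a global
  scaling (library-size) artefact; a global 2x scaling of one sample
  makes the control fire and the call `indeterminate`, never
  `two_active_X`.
* **Calls.**  `two_active_X` = X elevated and control clean;
  `one_active_X` = X not elevated and control clean; anything else --
  shifted control, or fewer than 3 informative X miRNAs --
  `indeterminate`.

On the default study (8 X-linked miRNAs, 200k reads, two male
references) both regimes are recovered in 20/20 simulated replicates and
the chromosome 1 control never fires; accuracy at a tenth of the depth
is reported by the simulation harness but not asserted.

## Problem sizes and numerical conventions

* Coordinates are 0-based half-open internally; GFF3 (1-based closed)
  and BED (0-based half-open) conversion happens only in the I/O layer.
* Default test/acceptance sizes: 4 x 200 kb genome, 200k reads per
  library, 4 libraries for the study fixture; 20 hairpins + 20 decoys
  on a 4 x 400 kb genome (3 seeds) for truth recovery; 20 XCI
  replicates per regime; 200 folding oracle cases at lengths <= 25;
  1000 random annotation fixtures.  These sizes make the whole suite
  run in minutes on one core while keeping every statistical check
  comfortably powered.
* RNG: a single base seed drives the genome and all libraries through
  derived per-sample streams; all acceptance computations are
  reproducible from one `--seed`.

## Known limitations

* The exact-match mapper is deliberate (toy genomes, error-free reads);
  there is no mismatch-tolerant alignment, so it must not be pointed at
  real sequencing data without replacing the mapping stage.
* The folding score is a weighted pair count, not a nearest-neighbour
  energy model; thresholds tuned for RNAfold energies do not transfer.
* Perfect-complement planted hairpins make acceptance-by-construction
  testable but are easier targets than real precursors with bulges; the
  decoy rejection results bound false positives only under this model.
* Two-library DE without replicates measures sampling noise, not
  biological variability; flags should be read as "larger than counting
  noise", as in the design it reproduces.
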