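---
title: "Screening circular RNAs for coding potential: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Screening circular RNAs for coding potential: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(circscreen)
```

## The screen

Circular RNAs (circRNAs) arise when a downstream splice donor is joined
covalently to an upstream splice acceptor (backsplicing). A subset of
circRNAs is translated, and because the template is circular, the ribosome
can read through the backsplice junction — in some cases for more than one
full turn, so that the second pass reads the same nucleotides in a shifted
frame and appends a peptide segment that exists nowhere in the linear
proteome. Such junction-derived micropeptides are attractive tumour-specific
targets.

`circscreen` implements a complete discovery screen for such candidates
from bulk RNA-seq of paired tumour/normal tissue:

1. **Backsplice junction detection** from reads that fail to map linearly,
   by exact-match terminal anchors placed in head-to-tail orientation,
   breakpoint extension, and GT/AG splice-flank validation.
2. **Quantification and differential expression**: junction reads scaled to
   RPM, genes to FPKM; features selected at |log2FC| >= 1 with p < 0.05
   (circRNAs) or FDR < 0.05 (genes).
3. **Rolling-ORF annotation** of called circles, flagging junction-spanning
   and >360° ORFs and deriving the frameshift C-terminal peptide.
4. **Correlation-phenotype GSEA**: genes ranked by Pearson correlation with
   a circle's abundance profile; enrichment of an immune marker set scored
   by the weighted Kolmogorov–Smirnov running sum with a permutation p.
5. **Prioritization**: upregulated circles with junction-spanning ORFs
   under 100 aa, ranked by fold change; a *hit* additionally shows negative
   enrichment of the NK activation set below the configured p cut.

Every stage is exercised against a seeded synthetic-data generator whose
planted truth (junctions, fold changes, correlation structure) is recorded,
so recovery is checkable without any external data.

## Junction detection model

Reads are first mapped against the linear references (genome chromosomes
plus spliced transcripts) by non-overlapping k-mer seeds and full-length
Hamming verification; a read is *mapped* if it matches contiguously
end-to-end with at most `m = 2` substitutions on either strand. The
per-sample mapped totals become the RPM denominators.

From each unmapped read the terminal 20-mers are taken verbatim as anchors.
An anchor placement is *unique* iff it has exactly one perfect match
genome-wide (both strands); reads with ambiguous or unplaced anchors are
discarded. A provisional junction requires both anchors on one chromosome
and strand with the right anchor upstream of the left one (head-to-tail)
within a 100 kb span cap. The breakpoint is then slid across the read so
that the whole read aligns as suffix-of-circle + prefix-of-circle within the
same substitution budget, and the genomic flanks must read `GT` after the
donor and `AG` before the acceptor on the template strand (equivalently
`AC`/`CT` on the plus strand for minus-strand circles). When several
breakpoints validate, the one with the fewest substitutions wins (ordinary
alignment scoring); among equal scores the leftmost acceptor wins and the
tie is flagged — an arbitrary but deterministic rule.

Support counting collapses exact duplicate read sequences (PCR-duplicate
collapse); a candidate needs at least two unique junction reads in at least
one sample. "Unique" is interpreted as *distinct read sequence*, the
standard meaning in junction-support counting. Candidates can be annotated
known/novel against a user-supplied junction catalogue (BED); no remote
lookup is performed.

Deliberate limitations: single-end evidence only, no indels at the
breakpoint, no trans-chromosomal fusions, and reads that wrap a circle more
than once (circle shorter than the read) or cross an internal splice
junction of a multi-exon circle in the same read as the backsplice are not
recoverable by single-breakpoint genomic extension. The simulator therefore
plants circles at least as long as the read length.

## Rolling translation

A circular sequence of length `L` is represented with the junction at
offset 0 (first base = acceptor side). For every ATG start offset
(including starts that wrap across the junction), codons are consumed
around the circle until the first in-frame stop or until `3L` nt have been
read. Three passes are exhaustive: translation state is periodic with
period `3L`, so an ORF without a stop in three passes never terminates; it
is reported with `has_stop = FALSE` and its peptide capped at `3L` nt with
an explicit `truncated` flag rather than silently shortened.

Bookkeeping conventions (the junction has no canonical origin in the
literature, so these are fixed here and tested): translation *crosses* the
junction whenever a consumed codon (stop included) contains a position
congruent to 0 beyond the start; `spans_junction` means at least one
crossing; `exceeds_360` means the ORF plus its stop codon outspan the
circumference (`nt_length + 3 > L`). Start codons are ATG only; stops are
TAA/TAG/TGA under the standard code.

The **frameshift-derived unique C-terminus** is defined as the peptide
suffix translated after the ribosome *re-enters sequence already traversed
in an earlier pass*: residues from codon index `ceiling(L/3)` onward,
counted from the start codon. When `L` is a multiple of 3 the frame never
shifts and the segment is empty. An alternative convention counts residues
from the first junction crossing instead of from re-entry; the two differ
by the distance between the start codon and the junction. This package uses
the re-entry definition throughout because it is intrinsic to the ORF (it
does not depend on where the start sits relative to the junction) and it is
what "frameshifted re-reading of already-translated sequence" means
literally. For a 253-nt circle with a 92-aa ORF the re-entry definition
yields `92 - ceiling(253/3) = 7` frameshifted residues; conventions that
count from the junction crossing can yield a few more, depending on the
start offset.

`circ_demo_sequence()` provides a *synthetic* worked example: a designed
253-nt circle (two exons of 100 + 153 nt in the demo annotation) whose
single rolling ORF starts at the junction, spans more than 360°, and
encodes 92 aa — the geometry of the known glioblastoma circRNA-encoded
92-aa peptide. Only the geometry is reproduced; the bases are generated,
not natural.

## Differential expression stand-in

The screen's thresholds are contractual (|log2FC| >= 1; p < 0.05 for
circRNAs, BH-FDR < 0.05 for genes) but the original negative-binomial count
machinery is deliberately not reproduced. Instead `de_test()` computes
`log2FC = log2(mean_T + pc) - log2(mean_N + pc)` on the raw scale and a
two-sided paired t test (Welch when unpaired) on `log2(value + pc)`, with a
pseudocount of 0.5 chosen because junction counts are sparse. The stand-in
is recorded in the result object (`$method`) and report. Its operating
characteristics are themselves part of the test suite: the null
false-positive rate at p < 0.05 is 0.05 within three binomial standard
errors over 1000 simulated features, and planted |log2FC| = 2 effects at
residual SD 0.25 with 6 pairs are recovered with sensitivity >= 0.95.
Features with degenerate variance get p = 1 with a warning rather than an
error. No dispersion modelling, TMM, or batch correction is attempted.

## Correlation GSEA

Genes are ranked by the signed sample Pearson correlation between their
abundance and the circle's RPM profile (ties broken lexicographically;
constant genes get r = 0 and a flag). The enrichment score is the classic
weighted Kolmogorov–Smirnov running-sum extremum with weight exponent 1 by
default (0 available). In the pipeline, correlations are computed on
`log2(x + pc)` abundances: junction-read RPM profiles are strongly
right-skewed, and raw-scale Pearson correlations are otherwise dominated by
one or two samples.

Two permutation nulls are implemented:

* **Gene-set permutation** (`gsea_test()`): random same-size gene sets.
  Cheap, calibrated for *independent* sets (permutation p uniform; a KS
  check is part of the acceptance suite), and the right null for asking
  "is this specific ranking extreme relative to arbitrary sets?".
* **Phenotype (sample) permutation** (`gsea_sample_test()`): the circle's
  profile is permuted across samples and the entire ranking recomputed per
  permutation. This preserves gene-gene correlation. The pipeline uses this
  null for its hit decision, because co-regulated marker panels (here the
  27 NK activation genes, which share a latent factor by construction and
  in real tissue) drift as a block: under gene-set permutation, a chance
  correlation between any tested circle and that block produces extreme
  enrichment scores and saturated p values. Phenotype permutation absorbs
  exactly that block drift into the null. With 24 libraries there are far
  more distinct permutations than the 2000 drawn.

p values use the add-one correction `(1 + #{|ES_null| >= |ES|}) /
(n_perm + 1)`, so p = 0 is never reported; NES divides ES by the mean
|null ES| of the same sign.

## The synthetic study and its defaults

The generator's defaults describe the demo study the package screens:

* **Cohort**: 12 tumour/normal pairs (24 single-end libraries of 150-nt
  reads, 4000 reads each at substitution rate 0.001) — the paired-cohort
  design of a small clinical RNA-seq study, scaled to desk size.
* **Genome**: 2 chromosomes x 80 kb at GC 0.45, 72 multi-exon genes whose
  exon boundaries all carry template-strand GT/AG flanks (so every
  contiguous exon block is a valid backsplice substrate).
* **Circles**: one planted positive — the designed 253-nt / 92-aa circle,
  upregulated at log2FC 2.5 — among 205 single-exon decoys, five of them
  genuinely upregulated (log2FC 1.5) so the ORF and enrichment filters are
  actually exercised. Circle abundances carry shared per-pair log-normal
  effects (SD 1 on log2) plus residual noise (SD 0.3), mimicking
  patient-to-patient variation in a paired design.
* **Expression**: 2000 background genes plus the 27-gene NK activation
  marker set, generated anti-correlated (target r = -0.8, noise SD 0.3)
  with the log2 *condition-centred* abundance of the positive circle — the
  scale on which the pipeline measures correlations, and the strength
  expected of a direct transcriptional repressor of the marker programme.
  Centring removes the tumour/normal shift from the planted association,
  so NK suppression tracks the positive circle's patient-level expression
  specifically rather than tumour status generically — without it, every
  upregulated decoy would inherit the anti-correlation through the shared
  condition axis and the screen could not single out one circle even in
  principle. The NK genes do, as in real data, remain mutually correlated,
  which is why the hit decision uses the phenotype-permutation null.
* **Hit rule**: negative NK enrichment at p < 0.01 over 2000 phenotype
  permutations. With 12 pairs, the permutation null for a coherent
  27-gene block is wide (the block drifts with the chance correlation
  between any profile and its latent factor, SD about `1/sqrt(n - 1)`), so
  the cut balances power against that drift; with roughly three candidate
  circles per run surviving the upregulation and ORF filters and a uniform
  null p for unrelated circles, the expected number of chance hits per
  screen stays near 0.015.

What the simulation does *not* emulate: sequencing error profiles beyond
i.i.d. substitutions, indels, paired-end fragments, rRNA contamination,
positional coverage bias, isoform mixtures, and count overdispersion beyond
the log-normal sample effects. Passing the recovery tests therefore
demonstrates the correctness of the algorithms under their stated
contracts, not performance on real libraries.

## Numerical and degenerate-input choices

* Coordinates are 0-based half-open everywhere in memory; GFF3 output is
  1-based closed, BED 0-based half-open, per those formats.
* Junctions are stored as `(acceptor_pos < donor_pos)` on the genome with a
  strand flag; minus-strand flanks are validated through the complement
  signature rather than by reverse-complementing the genome.
* Breakpoints are ranked by substitution count, then leftmost acceptor,
  then plus-strand signature; equal-score ties are flagged. A consequence
  worth knowing: when the sequence around a true junction admits an
  alternative shifted breakpoint that aligns *equally well* and carries a
  valid splice signature (which requires a local sequence identity between
  the acceptor and donor neighbourhoods), the reported coordinates are the
  leftmost of the equivalent pair — an ambiguity intrinsic to
  flank-validated breakpoint extension (the supporting reads carry
  `tie = TRUE`).
* The multinomial read sampler weights templates by abundance x length
  (fragment sampling); rolling circles draw start offsets uniformly on
  `[0, L)`.
* A single global seed fans out to per-stage child seeds via a fixed affine
  map (`stage_seed()`), keeping stages independently reproducible; all
  derived seeds stay below 2^31.
* Degenerate inputs are contracts, not crashes: empty FASTQ partitions
  cleanly, constant phenotype profiles and gene rows are rejected or
  flagged, degenerate DE variance yields p = 1 with a warning, and a gene
  set covering the whole ranked list is flagged `degenerate` rather than
  scored.

## Problem sizes used by the validation suite

The acceptance properties run at fixed sizes chosen to make their
statistical tolerances meaningful on a single CPU: 1000 random circles
(30-600 nt) for the rolling-ORF oracle equivalence; 20 planted circles over
a ~50x linear background for junction recovery; 1000 null and 300 planted
features for DE calibration and power; 500 replicate random sets and 200
replicate planted sets for GSEA calibration and power; and three full
screen replicates for end-to-end recovery. The same quantities are
recomputed from scratch by `scripts/acceptance.R`.

## Known limitations

* Anchor placement demands perfect 20-mer matches; a substitution inside
  both anchors (or one anchor of a short read) loses the read. This is the
  fixed-length exact-match contract, not an aligner.
* The detector requires the whole read to align as one suffix+prefix pair:
  circles shorter than the read and backsplice reads that also cross an
  internal splice junction are not called.
* The DE stand-in assumes approximate log-normality; heavy overdispersion
  or zero inflation would need count models out of scope here.
* Gene-set permutation is anticonservative for internally correlated sets;
  use the phenotype-permutation mode (the pipeline default) when the set is
  a co-regulated panel.
* The screen interrogates one pathway family at a time; no multiple-testing
  correction across pathway collections is applied.
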