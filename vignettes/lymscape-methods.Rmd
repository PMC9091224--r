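---
title: "Methods: hotspot detection, signature decomposition and cohort statistics in lymscape"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: hotspot detection, signature decomposition and cohort statistics in lymscape}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lymscape)
```

lymscape re-implements, as a tested and reusable pipeline, the analytical
stages of a whole-genome/transcriptome study of central nervous system
lymphoma: kataegis hotspot detection, supervised mutational-signature
decomposition, copy-number segment post-processing, tumor-in-normal
contamination rescue, telomere-content estimation, multi-source variant
integration and expression quantification. Every stage runs on synthetic
cohorts produced by a seeded generator, so the whole pipeline is exercisable
and testable without access to controlled patient data. This vignette
documents the models, the tunable parameters and the numerical choices the
package makes where the underlying procedures leave them open.

## Coordinates and containers

All internal coordinates are 0-based half-open; the converters to the
1-based inclusive conventions of VCF and GTF live only in the readers and
writers (`read_variants()`, `read_gene_models()` and friends). Contig names
are matched exactly — no "chr" prefix normalization — because silent
renaming hides data errors. Strand is carried but ignored by every overlap
computation; the integration rules are strand-agnostic.

## Kataegis detection

A hotspot is operationalized as at least 6 somatic SNV sites whose mean
intermutational distance (IMD), `(last − first)/(n − 1)`, is at most
1000 bp; the boundary value 1000 passes. `detect_hotspots()` enumerates,
per sample and contig, every run of consecutive sorted SNV sites satisfying
the rule, and merges overlapping or adjacent qualifying runs into maximal
regions, recomputing the member count and mean IMD from the final member
set. Sites — not alleles — are the spatial unit, so multi-allelic records
count once. The procedure is order-independent and is checked against an
exhaustive window-enumeration oracle on hundreds of random instances.

Hotspot genes are genes whose body intersects at least one region in at
least one sample (`annotate_hotspot_genes()`). Frequencies between
subgroups are compared with a two-sided Fisher exact test using the
point-probability rule — the sum of table probabilities not exceeding the
observed one — which reproduces the printed values for the published
2×2 tables (e.g. 11/30 vs 0/13 gives p ≈ 0.019, where a one-sided test
would give ≈ 0.0095). `test_expression_by_kataegis()` summarizes each gene
as `log2(mean TPM + 1)` over samples and applies a one-sided Wilcoxon
rank-sum test (hotspot genes higher) per biotype; rank tests are invariant
to monotone transforms, so only the per-gene mean is consequential.

## Mutational signatures

`build_sbs96_catalog()` maps each SNV to one of the 96 single-base
substitution channels (pyrimidine reference strand, trinucleotide context,
channels ordered A[C>A]A … T[T>G]T). SNVs disagreeing with the reference
base or lacking a flank at a contig edge are skipped and tallied.

`decompose_lcd()` performs the supervised linear combination decomposition:
for each sample it solves `min ‖c − S·e‖₂, e ≥ 0` with an in-package
Lawson–Hanson active-set solver (`nnls_fit()`; exact KKT conditions at
convergence, dual tolerance 1e-10), then zeroes every signature whose
relative exposure falls below its signature-specific cutoff and re-solves
over the survivors. By default this zero-and-refit loop runs to a fixed
point (at most 20 rounds), which is order-independent; `single_pass = TRUE`
gives the one-round variant. Cutoffs ship as an editable vector with an
all-zero default — their calibration against external training corpora is
out of scope, so they are inputs, not outputs. Indel catalogs are accepted
as precomputed channel matrices; the indel-context classifier itself is a
separate sub-project and is not reimplemented. Exposure contrasts between
subgroups use the two-sided Mann–Whitney U test on normalized exposures.

## Copy-number segment post-processing

`smooth_segments()` applies a three-stage merging cascade to
allele-specific segments: (1) neighbors in the same rounded copy-number
state deviating by < 0.5 copies when the smaller is < 20 kb, < 0.3 copies
otherwise; (2) segments < 500 kb forced into their closer neighbor, with
closeness the L1 distance over (total, A, B) and ties going left;
(3) segments < 2 Mb deviating by < 0.4 copies from the closer same-state
neighbor. Merged segments take the length-weighted mean of the copy
numbers and the union of the intervals, so covered length and the
length-weighted genome-wide mean copy number are conserved exactly.

Three choices here are deliberately pinned down because the procedure
description leaves them open and the results depend on them:

* **Rounding** is half-away-from-zero (2.5 → 3), fixed for
  reproducibility.
* **Copy-number state** means the rounded minor/major allele pair, not the
  total alone. With a total-only criterion, copy-neutral LOH segments —
  which share their total with balanced neighbors — merge into them, which
  both destroys genuine cnLOH events and, through length-weighted allele
  averaging, manufactures spurious whole-contig cnLOH calls. The segments
  are allele-specific and stage 2 explicitly uses allele-specific
  distances, so the allele-state reading is applied uniformly.
* **Merge order and termination**: within a stage, the leftmost applicable
  merge is applied first and the scan restarts; the three-stage cascade
  then repeats until a global fixed point. A single pass is not idempotent
  (a stage-2/3 merge can create a pair stage 1 would merge), and without a
  pinned order the fixpoint depends on traversal details. With both pinned,
  the output is idempotent and equal to an independently written
  implementation of the same contract, which the test suite verifies on
  hundreds of random chains.

Gains and losses are segments whose rounded total exceeds or falls short of
the rounded ploidy. Arm-level events require strictly more than 30% of an
arm altered (a whole-chromosome mode is available via `level =
"chromosome"` for the variant of the rule stated at chromosome scale).
cnLOH is defined as minor allele rounding to 0 at a total matching the
ploidy — a definition inferred from usage, since the term is used without
one. The fraction of aberrant genome is the covered proportion with
`|tcn − ploidy| > 0.7` or in LOH (minor allele < 0.5 at total ≥ 0.5).

## Tumor-in-normal rescue

`run_tinda()` clusters paired B-allele frequencies (control, tumor) of
germline-annotated positions — after dropping common-variant positions —
with a seeded full-covariance Gaussian-mixture EM (k-means++-style
initialization from the seed, single restart, tolerance 1e-6, at most 500
iterations, k = 9 components). Clusters in which at least 75% of positions
lie above the identity line (tumor VAF > control VAF) are called
tumor-in-normal and their points are reclassified as somatic. The 75%
comparison is inclusive (`strict = TRUE` switches to a strict reading).

One guard is essential: a fixed-k mixture over-segments a single symmetric
germline BAF cloud into spatial slivers, and a sliver on the upper side of
the identity line is internally ~100% "above" without being contamination.
Components whose fitted means lie within `merge_radius` (default 0.1 VAF
units, about twice the binomial standard deviation at 100× depth) are
therefore coalesced by single linkage before the identity-line test.
Without this step the false-rescue rate on the default simulation is ~0.24;
with it, rescue recall is 1.0 and false rescues 0 (50-seed medians). The
published workflow delegates clustering to an external package whose exact
EM is out of scope here, so the clustering contract is behavioral —
separation of the contamination cloud from the germline clouds — and is
guarded by exactly that simulation property.

## Telomere content

A read of length L is telomeric when it carries at least
`round(6·L/100)` non-overlapping occurrences (greedy, left to right) of the
four most common telomeric repeat types (TTAGGG, TCAGGG, TGAGGG, TTGGGG) or
their reverse complements; the half-up rounding of the per-read threshold
is documented and configurable because the published scaling rule does not
state it. Only unmapped reads or reads with mapping quality below 8 are
eligible. Telomere content is telomeric reads per million reads with GC
content in [48, 52]% (inclusive bounds on `(G+C)/L·100`). Tumor content is
corrected for tumor cell content as
`T_corrected = (T − C·(1 − TCC))/TCC`, which assumes admixed normal cells
share the control's content; the correction satisfies `TCC = 1 ⇒ T` and
`T = C ⇒ C` identically and inverts purity mixing exactly, all of which
are tested to numerical precision. Negative corrected values are reported
as-is with a flag. Content–expression association uses the Pearson
correlation test without multiplicity correction.

## Variant integration and cohort statistics

Somatic indels observed as germline in two or more patients are removed
from every sample as recurrent artifacts. SV breakpoint ends are annotated
independently as *direct* (inside a gene body), *near* (within 100 kb) and
*closest* (nearest gene on the contig, ties to the smaller start
coordinate, distance measured to the gene body); only direct hits enter
oncoprint recurrence, while near/closest are kept as an auxiliary table for
regulatory-hit analyses. Focal copy-number events are gain/loss segments
covering at most 30% of their arm — the complement of the chromosome-level
rule, documented as an inference — and annotate any gene they overlap even
partially. The alteration matrix admits coding small variants
(nonsynonymous, stop gain/loss, splicing, frameshift, non-frameshift),
exonic ncRNA variants, direct SV hits and focal CNAs; recurrence counts
samples, not events.

Subgroup frequency contrasts report a two-sided Fisher p (uncorrected, as
the source figure legends state) and a Haldane–Anscombe log2 fold change,
`log2(((k_A+0.5)/(n_A+1))/((k_B+0.5)/(n_B+1)))`, which is finite for empty
cells. Pairwise mutual exclusivity and co-occurrence over genes with
recurrence ≥ 5 use Fisher's left and right tails respectively, each
Benjamini–Hochberg adjusted across tested pairs separately per tail. All
tails agree with closed-form hypergeometric expressions to 1e-12 in the
tests.

## Expression

TPM and FPKM exclude genes on chromosomes X, Y and MT and genes of rRNA or
tRNA biotype from the library-size denominator (they bias library-size
estimation); excluded genes still receive values against the included-gene
denominator, so TPM over included genes sums to one million per sample.
The immunoglobulin constant-gene profile reports `log2(TPM+1)` over the
IGHM/IGHG/IGHA/IGHD/IGHE/IGKC/IGLC panel and the argmax isotype per sample.
The dilution emulator mixes a tumor and a background profile at fractions
0, 0.2, 0.4, 0.6, 0.8 of background, resampling multinomially at the tumor
library size; a nonnegative regression on the two pure profiles recovers
the fraction within ±0.05 at the default library sizes. Z-scores use the
sample (n−1) standard deviation on `log2(TPM+1)`, documented because the
convention is not stated; constant genes get z = 0.

## The synthetic cohort generator

`simulate_cohort()` produces, deterministically from a seed, a complete
cohort: genome, gene panel, per-sample variants, segments, SV breakpoints,
BAF point sets, read sets, a counts matrix and a ground-truth ledger for
every implant. Defaults are cohort-scale where the emulated analysis fixes
them and desk-scale otherwise:

* two subgroups of 30 and 13 samples — the sizes behind the printed
  hotspot contrasts;
* a toy genome of 3 × 10 Mb contigs with arms split 45%/55%, chosen so
  brute-force oracles remain feasible;
* background SNV rate 6/Mb, the order of magnitude of ~20k SNVs on a human
  genome; implanted kataegis clusters of 6–18 SNVs at mean spacing 200 bp
  (well inside the detection rule), biased 0.8 toward TpC contexts to
  emulate the AID/APOBEC flavor without asserting it in tests;
* SNV channels drawn genome-consistently from a synthetic three-signature
  reference (flat, C>T-concentrated, T>C-concentrated) so that catalog
  construction and decomposition close the loop; the signature matrix is a
  synthetic stand-in, not a published reference;
* arm gains/losses implanted at fractions 0.4–1.0, cnLOH as near-whole-arm
  events (0.75–1.0, reflecting that copy-neutral LOH is typically
  arm-scale), focal events of 0.3–1 Mb placed outside implanted arm events
  so ledger fractions stay exact, and copy-number jitter of 0.05;
* tumor-in-normal contamination 0.1 with 2000 germline and 200
  misclassified-somatic positions at depth 100 and tumor VAF 0.5;
* telomere read sets with planted contents of 20 000 (tumor) and 10 000
  (control) per million GC-matched reads — scaled up from realistic values
  so that desk-sized read sets (3000 background reads) contain a
  double-digit number of telomeric reads;
* negative-binomial expression (dispersion 0.3) with an IGHM-high first
  subgroup and a distinct brain-like background profile for the dilution
  emulator.

The generator emulates the statistical structure each stage assumes —
multinomial channel sampling, binomial BAF noise, negative-binomial counts,
uniform background SNV placement outside implants — but not read-level
error models, FFPE artifacts, a realistic human genome, or correlated
structural/copy-number events. Passing tests therefore demonstrate that
the algorithms implement their contracts and recover planted structure
under the stated noise; they do not certify performance on real tumors.

## Problem sizes and determinism

The test suite and the acceptance script use 200 random instances of up to
100 SNVs for the detector oracle, 50 seeded replicates at 5000
mutations/sample for exposure recovery, 200 random segment chains for the
cascade, 50 seeded contamination simulations, and the default cohort for
end-to-end checks — sizes chosen so every oracle remains exhaustive and a
full run stays in the minutes range on a laptop. Every stochastic step
takes an explicit seed; identical spec and seed give byte-identical
bundles, and pipeline reruns are checksum-identical.

## Known limitations

The cutoff calibration for signature-specific thresholds, the indel
channel classifier, driver-significance methods, consensus clustering and
survival analyses are intentionally out of scope. The EM clustering in the
rescue stage is a behavioral stand-in for the published tool's clustering;
its guarantees are the simulation-recovery properties, not equality with
that tool's labels. Arm-event recovery guarantees hold for implants
altering > 35% of an arm on full-length (multi-Mb) arms; on much smaller
toy contigs the 500 kb / 2 Mb stage bounds dominate everything, which is a
property of the published bounds, not of the implementation.
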