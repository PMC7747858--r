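---
title: "Comparing paired primary lung tumor and brain metastasis exomes"
author: "pairedexome"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparing paired primary lung tumor and brain metastasis exomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pairedexome)
```

# The problem

When a lung tumor seeds a brain metastasis (BM), the two lesions share a
common clonal ancestor but then accumulate mutations independently.
Comparing a patient's primary tumor exome with the paired BM exome
separates the *trunk* of that evolution (variants present in both
compartments) from the compartment-private *branches*, and highlights
genes and chromosomal regions recurrently altered during the metastatic
step.  Two features make this setting awkward for standard somatic
pipelines: there is often no matched normal tissue (so germline variants
must be removed using population catalogs), and presence/absence calls
between the two compartments must be made on read-level evidence rather
than on caller output alone, because a variant "absent" from a call set
may simply sit below the caller's threshold.

`pairedexome` implements this comparison as a rule-based pipeline over
plain per-sample tables: variant calls with read counts and annotations,
and binned coverage.  Every stage is exercised end-to-end against a
seeded synthetic cohort generator with known ground truth.

# Somatic variant identification without a matched normal

Two filters are applied per sample, in order.

**Reliability.**  A variant is retained iff

* total depth $\ge 10$ reads,
* variant-supporting reads $\ge 3$,
* variant allele fraction (VAF) $\ge 15\%$, and
* QPHRED $\ge 20$ for SNVs, $\ge 30$ for indels.

All bounds are inclusive.  VAF comparisons are computed in exact integer
arithmetic (`alt_reads * 10^6 >= depth * round(vaf * 10^6)`) so evidence
sitting exactly on a boundary — 3 variant reads in 20 — is treated
inclusively rather than at the mercy of floating-point rounding.  A
zero-depth site fails, without dividing by zero.

**Germline exclusion.**  Variants found in a local germline catalog
(standing in for 1000 Genomes / EVS / ExAC extracts) at population
frequency $\ge 10^{-5}$ are excluded; the match is allele-exact on
(chrom, pos, ref, alt) because catalog frequencies are allele-specific.
Strictly rarer and absent variants are retained as putatively somatic.
"Variant calls" is read as variant-supporting reads throughout; the
source protocol uses the two terms interchangeably and read counts are
the only interpretation available in the input contract.

The attrition report attributes each removed variant to exactly one rule
(quality first, then germline), and `qc_pipeline()` is idempotent.

# Three-way paired classification

For each patient the QC'd primary and BM variant sets are aligned on
exact allele identity, then:

* a primary variant is **shared** iff supported by $\ge 2$ BM reads
  making up $\ge 5\%$ of BM reads at the site, else
  **primary-specific**;
* a variant seen only in the BM is **metastasis-specific** iff supported
  by $\ge 3$ BM reads at $\ge 15\%$, with $\le 1$ primary read at
  strictly $< 5\%$ of primary reads.

A variant passing QC in both compartments is decided by the sharing rule
(the rules are directional: one starts from the primary call set).  A BM
variant failing the metastasis-specific rule is reported as
`unresolved` rather than silently dropped; the source procedure does not
define this cell, and auditability argues for keeping it visible.  The
opposite compartment's evidence at sites missing from its QC'd table is
taken from an optional per-site lookup table (the synthetic generator
always emits per-site depth in both compartments; real-data users should
supply pileup-derived depths).  Zero BM coverage makes the sharing
proportion unsatisfiable (primary-specific); zero primary coverage with
zero supporting reads counts as primary proportion 0.

These rules are deliberately tested twice: once through the package and
once through an independently coded literal transcription of the rule
text, on $10^4$ random evidence tuples plus a forced grid of boundary
values (exactly 5%, 15%, and 1/2/3 supporting reads).

# Copy-number alterations from paired coverage

Per-bin log ratios are $\log_2$ of BM over primary depth after
library-size normalization (each sample's bins divided by that sample's
total).  Normalization is the default but optional: it shifts all bins
by a constant when a real alteration changes one sample's total, and the
mode-based zero level (below) absorbs exactly that kind of offset, so
both configurations yield the same calls.  Bins with raw primary depth
below 10 (the same evidence floor used for variants) or non-positive BM
depth are masked and belong to no segment.

**Segmentation** is circular binary segmentation (CBS), reimplemented:
on the circularized per-chromosome sequence, the arc $(i, j]$ maximizing

$$T(i,j) = \frac{|\bar{x}_{arc} - \bar{x}_{comp}|}{\hat\sigma\sqrt{1/k + 1/(n-k)}}$$

is accepted as a change if its permutation p-value (default 1,000
permutations, $(c+1)/(B+1)$ convention) is below $\alpha = 0.01$, and
the resulting intervals are segmented recursively.  Both the arc and its
complement must hold at least 3 bins.  Ties keep the first arc in
lexicographic scan order, and the permutation loop exits early once
acceptance is impossible, which changes no decision.  The inner loop is
compiled (Rcpp) and driven by R's RNG, so results are reproducible under
`set.seed()`.  Split-undoing (as in the reference CBS implementations)
is intentionally not implemented; a consequence, visible in validation,
is that a long altered segment is occasionally fragmented into
consecutive segments of the same state.  Downstream consumers therefore
evaluate and report *regions* — maximal runs of same-state segments —
which is also how recovery of planted segments is scored.

**Zero level.**  The copy-neutral baseline is the most frequent smoothed
value: a histogram over segment means, weighted by segment bin counts,
with fixed width 0.05 log2 units (safely below the 0.15 calling
threshold); the returned zero is the weighted mean of the values in the
modal bin.  Breaks are anchored at the data minimum, making the
estimator exactly translation-equivariant.  A tie between modal bins is
broken toward the candidate nearest 0, with a warning.

**Calling** is by strict thresholds around zero: gain above
$zero + 0.15$, deletion below $zero - 0.15$, high-level amplification
above $zero + 2$ and homozygous deletion below $zero - 2$ (the extreme
labels subsume the milder ones).  A value exactly at a threshold stays
in the milder class.  Since the zero level shifts with the data, state
calls are invariant under adding a constant to all bins.

`recurrent_regions()` counts, per bin, the patients carrying a gain-like
or deletion-like segment and reports maximal runs reaching a patient
threshold — coordinates only; mapping to cytogenetic band names would
need an external cytoband table and is out of scope.

# Mutational spectra and clustering

Each somatic SNV is classified by its substitution type and the bases
directly 5′ and 3′ of the mutated base.  Purine-reference mutations are
reverse-complemented (alleles complemented, flanks complemented and
swapped) so every mutation maps into the six pyrimidine-referenced
types; the 96 categories are ordered substitution-major, then 5′ base,
then 3′ base, alphabetically.  Counts conserve the SNV total (indels and
ambiguous-base records contribute nothing), and the spectrum of a record
set equals the spectrum of its reverse complement.

Samples are compared on proportion-normalized spectra: PCA on
mean-centered proportions, and hierarchical clustering of cosine
distances with Ward linkage.  One caveat is documented rather than
corrected: Ward's minimum-variance derivation assumes squared Euclidean
distances, so applying the Ward update (`stats::hclust(method =
"ward.D")`) to a cosine dissimilarity matrix is mathematically
non-standard.  It is done here because it is the stated procedure being
reproduced; cosine distance makes the embedding scale-free, which is the
property that matters for count data of varying depth.  Dendrograms are
serialized as Newick with labels and merge heights; all-zero spectra are
excluded with a warning.

# Trunk/branch trees and recurrence

Per patient, the classification counts map directly onto a two-leaf
tree, `((primary:n_p,met:n_m)trunk:n_s);`, whose trunk length is the
shared count.  Across patients, `recurrent_genes()` tallies genes hit by
metastasis-specific variants in multiple *distinct* patients (two hits
in one BM count once), restricted by default to non-synonymous
consequences (missense, nonsense, splice, frameshift, in-frame indel).
`annotate_cancer_genes()` flags variants in a user-supplied cancer-gene
list and counts flagged non-synonymous SNVs and indels per
classification status; `domain_overlap()` joins variants carrying a
protein position to covering functional domains (1-based inclusive
bounds) to produce lollipop-plot-ready tables.  Protein positions are an
input column from upstream annotation, never computed here.

# The synthetic cohort generator

The generator is first-class, tested code, and its defaults are the
study conditions the pipeline targets: 7 patients (14 samples), median
per-site depth 135X, and per patient 138 truncal, 3 primary-private and
52 metastasis-acquired somatic variants — matching the observed medians
of the paired-cohort design being emulated — plus 200 germline variants
present in both compartments.  Mechanisms:

* per-site depth Poisson around the median depth, floored at 1;
* variant-supporting reads Binomial(depth, VAF); germline VAF fixed at
  0.5 (diploid heterozygote); truncal VAF 0.40 and private VAF 0.35,
  typical clonal fractions for high-cellularity exomes;
* QPHRED Normal(60, 5), truncated at 0 and rounded — comfortably above
  both quality floors, because the generator's role is separable
  ground truth, not caller-error emulation;
* substitution types drawn with C>A-dominant weights (0.35, 0.08, 0.27,
  0.08, 0.14, 0.08 over C>A, C>G, C>T, T>A, T>C, T>G), a smoking-like
  profile; each SNV is placed on either strand with probability 1/2 so
  strand collapse is genuinely exercised; flanking bases uniform;
* chromosomes are synthetic (`chr1..chr4`, 150 bins of 10 kb); no
  reference genome is needed because trinucleotide contexts travel as
  input columns;
* coverage: primary depth log-normal around 135X per bin
  (sd 0.1 log2 units); BM depth is primary times $2^{\rho}$ for planted
  segments of log ratio $\rho$ (defaults: +0.6 over 50 bins of chr2,
  −0.7 over 50 bins of chr3, echoing recurrent arm-level gain/loss
  patterns), times independent bin noise;
* one metastasis-private missense variant in a designated synthetic
  gene (`METREC1`) is planted in the first three patients, mirroring the
  pattern of a gene recurrently mutated in three BMs;
* every sample table carries a row for each patient-level variant site
  (`alt_reads = 0` where the variant is absent), so paired
  classification always has per-site depth in both compartments;
* germline sites take even and somatic sites odd coordinates, so a
  somatic variant can never collide with another patient's catalog
  entry — the separable conditions stay separable by construction.

What the generator does **not** emulate: tumor purity and subclonal
structure (a single VAF per origin class; the emulated protocol assessed
cellularity histologically but reported no values, so purity is not
modeled rather than guessed), sequencing error, mapping artifacts,
GC-content waves in coverage, indel realignment ambiguity, and linkage
between variants.  Passing tests on this cohort therefore demonstrate
that the *rules* are implemented exactly and recover planted structure
under calibrated noise — not that the pipeline is robust to impure,
artifact-laden real tumors.

# Numerical and design choices

* Fraction thresholds compare scaled integers (`* 10^6`), making
  inclusive/exclusive senses exact for any realistic depth.
* CBS: $\alpha = 0.01$, 1,000 permutations, minimum width 3 bins —
  configuration values with logged provenance, since the emulated
  protocol delegates them to its segmentation library without stating
  them.  The run manifest labels every parameter `stated` or `assumed`.
* Zero-level histogram width 0.05; tie toward 0.
* "Above"/"below" thresholds are strict; boundary values take the
  milder label.
* Clustering determinism: fixed input order, `hclust`'s deterministic
  tie handling, and seeds threaded through every stochastic step.
* Degenerate inputs: empty tables flow through with empty outputs and
  zero attrition; all-masked chromosomes produce an empty segmentation
  with a warning; all-zero spectra are excluded with a warning; a
  bimodal zero-level tie warns.

Validation problem sizes (chosen to probe each property at meaningful
resolution): $10^4$ evidence tuples plus a boundary grid for the
classification oracle; 100 sequences of up to 50 bins against a
brute-force arc search; 100 simulations of a 35-bin, $|\rho| = 0.6$
segment in 120 bins at noise sd 0.1 for breakpoint recovery; 20 seeded
six-sample cohorts from disjoint context profiles for cluster recovery;
and the default 7-patient cohort for end-to-end ground-truth recovery.

# Limitations

* Only 1 primary + 1 BM per patient; no multi-region designs, no
  cancer-cell-fraction or clonality estimation.
* No absolute copy number, purity/ploidy or GC correction; coordinates
  only, no cytoband names.
* No signature decomposition against reference signature catalogs and
  no transcription-strand bias (that would need gene-strand annotation
  not present in the input contract).
* Germline exclusion is only as good as the supplied catalog; a real
  analysis should use current population databases.
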