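---
title: "Annotating and classifying putative loss-of-function variants"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Annotating and classifying putative loss-of-function variants}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Putative loss-of-function (pLoF) variants — single-nucleotide variants that
introduce a premature stop codon, small insertions/deletions that shift the
reading frame, and substitutions that destroy a canonical splice site — are
among the most consequential variants in a human genome, yet their clinical
interpretation is far from binary. Some pLoF alleles segregate at high
frequency in healthy cohorts; others cause recessive disease only when both
copies are lost; a minority act dominantly because the gene is
haploinsufficient. `plofpred` implements a full annotation-and-prediction
pipeline for this problem: it calls pLoF consequences against gene models,
computes a 108-slot feature bundle, emits annotation-artifact flags, and
classifies each truncating variant into **benign**, **recessive**
disease-causing, or **dominant** disease-causing, with calibrated
three-class probabilities and a High/Low confidence label.

Because the real training resources for this task (disease mutation
databases, population cohorts, curated domain and interaction annotations)
are licensed or large, the package ships a first-class synthetic fixture
generator that reproduces the *shapes* of all of those inputs with
controllable statistical structure. Every claim the test suite makes is a
property of the algorithms, demonstrated on that synthetic world.

## Consequence calling

Variants (VCF or 5-column tab input) are normalized to minimal,
left-aligned representation before calling. Per overlapping transcript:

* **premature_stop** — an SNV inside the CDS whose alternate codon is
  TAA/TAG/TGA and whose reference codon is not already a stop;
* **frameshift** — an indel fully inside the CDS whose length change is not
  a multiple of 3. Its CDS anchor is the first coding base altered after
  normalization (the convention matters for the position-dependent features
  below; indels that straddle a CDS/intron boundary are logged as
  splice-region events and not called);
* **splice_donor / splice_acceptor** — an SNV at one of the two canonical
  intronic bases at either end of an intron, resolved in transcript
  orientation (the donor is the GT end, the acceptor the AG end).

Coordinate conventions are confined to one module: GTF and VCF coordinates
are 1-based and closed; the stop codon is included in the CDS (the fixture
generator emits gene models that way). Internally each transcript carries
explicit genome↔spliced-CDS position maps, so mapping is exact on both
strands and is exercised by exhaustive round-trip tests.

## The feature bundle

The classifier consumes a fixed registry of 108 named slots
(`feature_registry()`), grouped into families:

* **consequence** — call category, identity of the introduced stop codon,
  frameshift phase, length of the affected intron;
* **position** — CDS position and fraction, distance to the last exon-exon
  junction, fraction of protein truncated, exon index, intron geometry, GC
  content;
* **nmd** — nonsense-mediated decay candidacy. A stop is an NMD candidate
  when its distance to the last exon–exon junction, measured in spliced
  nucleotides **at the first base of the stop codon**, is strictly greater
  than 50 nt; single-exon transcripts escape. The threshold position of the
  measurement (first vs. last base of the codon) is not fixed by the 50-nt
  rule as usually stated; the first base was chosen and is configurable
  (`rule_nt` argument). For frameshifts, the shifted frame is rescanned and
  the rule is applied at the first novel stop; a frameshift creating no new
  stop (stop-loss-like) is treated as escaping.
* **domain** — for each of seven kinds (PFAM, SMART, SCOP, signal peptide,
  transmembrane, PTM sites, disordered residues): does the truncation point
  (protein position `ceil(cds_pos/3)`) hit an interval, and are intervals
  of that kind lost downstream (an interval starting at or after the
  truncation point counts as lost)?
* **conservation** — GERP score at the variant site (mean over deleted
  bases for deletions; for insertions, the mean of the two flanking
  reference bases — an anchor convention we fixed since "mean over affected
  bases" is ambiguous for insertions); fraction of the truncated coding
  region inside constrained elements, counted in nucleotides; dN/dS
  lookups.
* **network** — direct dominant/recessive disease-gene neighbours and the
  unweighted shortest path to the nearest disease gene in a
  protein–protein interaction graph (0 for a disease gene itself, missing
  when unreachable), plus centrality lookups.
* **frequency** — allele frequencies in three reference cohorts. A variant
  absent from a cohort gets frequency 0 with a presence indicator of −1,
  rather than a missing value: absence from a large cohort is informative,
  not unobserved.
* **gene / expression** — per-gene variation densities, constraint
  percentages, average heterozygosity (`sum(2pq)/l`), miRNA target counts,
  expression in 25 tissues, and an entropy-based tissue specificity
  `1 − H/log2(25)` (1 = single-tissue, 0 = uniform; the exact normalization
  of the underlying entropy method is a design choice documented here).

Binary slots are encoded −1/+1; absences are recorded as `NA` and handled
by the classifier's imputation, never silently zeroed.

## Artifact flags

Independently of the features, each call is annotated with flags marking
likely annotation or mapping artifacts: `lof_anc` (the "LoF" allele is the
ancestral state), `near_start` (first 5% of the CDS, boundary inclusive:
`cds_fraction <= 0.05`), `near_end` (last 5%: `> 0.95`),
`alt_canonical_site` (a splice SNV whose *alternate* allele creates GT/AG,
i.e. restores a canonical site), `noncanonical_splice_flank` (the adjacent
exon is flanked by a non-GT..AG intron), `small_intron` (intron < 15 nt),
and `segdup`/`paralog`/`pseudogene` membership tests against supplied
homology tracks. The 5% boundary conventions are inclusive on the start
side and exclusive on the end side; this is asserted by an exhaustive sweep
test. Flags are reported alongside predictions and deliberately kept out of
the feature registry.

## The classifier

Training examples are premature-stop variants labeled benign / recessive /
dominant, with their gene of origin. The training scheme is:

1. **Per-gene subsampling.** Each replicate keeps at most one variant per
   gene for the benign and recessive classes and at most three per gene for
   the dominant class (dominant training sets are concentrated in few
   genes), sampled uniformly under the replicate's seed, preferring the
   gene's longest transcript.
2. **Encoding and imputation.** Missing values are replaced by the
   equal-weight mean of the three per-class training means of the column
   ("weighted average of the prediction classes"; a class-prior-weighted
   variant is available via `weights = "prior"`). Imputed binary slots are
   thresholded at 0 back to −1/+1 so encoded matrices are strictly binary
   there. Imputation constants are fit on training data only and frozen for
   prediction.
3. **Stratified random forest.** Each replicate grows a forest (default
   500 trees — forest hyperparameters are not externally constrained, so we
   chose a common default and exposed it) with a class-balanced bootstrap
   per tree (equalized `sampsize` with `strata`), which is what keeps the
   three-class training balanced despite unequal class sizes.
4. **Cross-validation.** Each replicate records a 10-fold cross-validated
   multiclass AUC (Hand-and-Till M: the average over class pairs of the
   symmetrized two-class ranking probabilities, ties counting 0.5). Folds
   are stratified by class and **grouped by gene** — no gene contributes to
   both train and test folds. Gene grouping is our design choice: gene-level
   features are constant within a gene, and ungrouped folds would leak them.
5. **Ensembling.** Steps 1–4 repeat 40 times by default (tests and the
   acceptance script use 10 replicates to keep runtimes modest; the scheme
   is unchanged). Predicted probabilities are across-replicate means
   (renormalized), the predicted class is the argmax, and exact ties
   resolve to the least pathogenic class (benign, then recessive) — a
   deliberately conservative clinical convention.

**Confidence.** From the across-replicate dispersion, each class gets a
95% interval `mean ± 1.96·SD/sqrt(n_replicates)`. A prediction is labeled
*Low* confidence when the predicted class's lower bound overlaps the upper
bound of either other class, else *High*. With fewer than two replicates
confidence is Low by definition.

## The synthetic world

`fixture_config()` fixes the study conditions. Defaults: 50 benign genes ×
3 variants, 15 dominant genes × 10 variants, 50 recessive genes × 3
variants (450 labeled premature stops — dominant variants concentrated in
few genes, echoing the per-gene skew of real dominant training data);
transcripts of 2–6 exons, 360–1200 nt CDS, 5% single-exon, 15% of genes
with a second transcript; 5% noncanonical and 5% small introns; 5%
missingness; a 40-node background interaction network carrying the disease
labels; 20% of genes held out gene-wise.

`effect_size` (default 3, in within-class SD units) scales *every*
class-dependent signal: Gaussian mean shifts of gene-level covariates,
per-base GERP means, constrained-element coverage, network wiring rates to
disease genes, allele-frequency presence and magnitude (kept moderate so
that classification does not hinge on the frequency family alone), the
positional bias of planted stops (benign drift 3′-ward, dominant 5′-ward),
and expression breadth. At `effect_size = 0` the three classes are
exchangeable by construction — a property the suite checks with
Kolmogorov–Smirnov tests — so the label-permutation null and the
effect-size dial are coherent.

What the generator does *not* emulate: realistic human genome composition,
mutation-rate heterogeneity, linkage between variants, errors in gene
models beyond noncanonical introns, and any correlation structure between
feature families beyond their shared class labels. Passing tests therefore
demonstrate correctness of the algorithms and the end-to-end learnability
of a planted signal — not clinical performance on real cohorts.

## Numerical and degenerate-input choices

* Zero-length truncation ⇒ conservation fraction 0; all-zero expression ⇒
  specificity missing; heterozygosity with `l = 0` is an error.
* A feature column entirely missing in training is dropped with a warning;
  a class absent from a fold's training split skips that fold; a class with
  fewer genes than folds reduces the fold count with a warning.
* Probabilities are renormalized to sum to 1 (tolerance 1e−9) after
  replicate averaging.
* All randomness flows from explicit seeds (replicate seeds derived from a
  base seed and recorded in the model), so two runs of any pipeline stage
  are byte-identical.

## Problem sizes used in the checks

The test suite and the acceptance script run at deliberately modest scale,
chosen as the smallest sizes that still exercise every code path:
exhaustive mutagenesis on ~1 kb CDS fixtures on both strands; a 1020-nt
flag sweep; ≥100 random fixtures per closed-form formula at 1e−12 relative
tolerance; and a 450-example corpus with 10 forest replicates for the
end-to-end checks (10-fold gene-grouped cross-validation throughout).

## Limitations

* The consequence caller handles SNVs and simple indels; multi-nucleotide
  substitutions and structural variants are out of scope, as are splice
  predictions beyond the two canonical intronic positions.
* Splice-site calls are annotated and flagged but not classified: the
  model is defined for truncating (stop/frameshift) variants, and
  frameshifts are scored with the stop-trained model.
* Homology flags are membership tests against supplied tracks; the package
  does not discover homology itself.
* Real-data performance depends on the quality of the annotation tracks
  supplied; the synthetic world cannot validate that.
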