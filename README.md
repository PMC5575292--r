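# plofpred

Annotation and three-class pathogenicity prediction for putative
loss-of-function (pLoF) variants: premature-stop SNVs, frameshift indels,
and canonical splice-site variants.

## What it does and for whom

Not every protein-truncating variant is pathogenic, and not every
pathogenic one acts the same way: many pLoF alleles are benign, many cause
disease only when homozygous (recessive), and a minority are dominant
because one working gene copy is not enough (haploinsufficiency). For
anyone building or studying variant-interpretation pipelines, `plofpred`
provides the full chain:

1. **Consequence calling** — variants (VCF or 5-column tab) are normalized
   (minimal, left-aligned) and called per overlapping transcript as
   `premature_stop`, `frameshift`, `splice_donor`, or `splice_acceptor`.
2. **Feature annotation** — a fixed 108-slot registry: functional-domain
   hit/loss geometry (PFAM/SMART/SCOP/signal peptide/transmembrane/PTM/
   disorder), nonsense-mediated decay candidacy, conservation (site GERP,
   constrained-element content of the truncated region, dN/dS), protein–
   protein-interaction proximity to disease genes, cohort allele
   frequencies, and per-gene covariates including average heterozygosity
   and entropy-based tissue specificity.
3. **Artifact flags** — `lof_anc`, `near_start`, `near_end`,
   `alt_canonical_site`, `noncanonical_splice_flank`, `small_intron`,
   `segdup`, `paralog`, `pseudogene`.
4. **Classification** — an ensemble of stratified random forests (40
   replicates by default), each trained on a per-gene-subsampled,
   class-balanced corpus, yielding three class probabilities, an argmax
   class, and a High/Low confidence label from cross-replicate dispersion.

Everything runs against a synthetic fixture world (genome, gene models,
annotation tracks, labeled corpus) generated by the package itself, so no
external downloads are needed to exercise or test any part of the
pipeline.

## The model in brief

* **NMD rule**: a premature stop is an NMD candidate iff its distance to
  the last exon–exon junction (spliced nucleotides, measured at the first
  base of the stop codon) is > 50 nt; single-exon transcripts escape.
* **Heterozygosity**: `sum(2 p q) / l` over a transcript's SNPs with minor
  allele frequency `p`, reference frequency `q`, CDS length `l`.
* **Tissue specificity**: `1 − H / log2(25)` with `H` the Shannon entropy
  of the normalized 25-tissue expression profile.
* **Imputation**: missing feature values become the equal-weight mean of
  the three per-class training means; binary features live on {−1, +1}.
* **Multiclass AUC** (Hand-and-Till):
  `M = 2/(c(c−1)) · Σ_{i<j} (Â(i|j)+Â(j|i))/2`, with `Â(i|j)` the
  probability that a random class-i example outranks a random class-j
  example on the class-i score (ties 0.5). Cross-validation is 10-fold,
  class-stratified, and gene-grouped.
* **Confidence**: per-class 95% intervals `mean ± 1.96·SD/√n` across
  replicates; *Low* iff the predicted class's interval overlaps another
  class's.

## Worked example

```r
library(plofpred)

# A complete synthetic study: genome, gene models, tracks, labeled corpus
cfg   <- fixture_config(seed = 7)        # 450 labeled premature stops
world <- make_fixture_world(cfg, "fixtures")

model <- train_ensemble(world$corpus, n_replicates = 10, base_seed = 7)
model
#> <EnsembleModel: 10 replicates, 108 features, mean CV AUC 1.000>

pred <- predict(model, world$holdout)
head(cbind(round(pred[, 1:3], 3), pred[, 7:8],
           truth = world$holdout$label), 5)
#>   p_benign p_recessive p_dominant predicted_class confidence  truth
#> 1    0.898       0.100      0.002          benign       High benign
#> 2    0.895       0.102      0.003          benign       High benign
#> 3    0.892       0.106      0.003          benign       High benign
#> 4    0.918       0.077      0.005          benign       High benign
#> 5    0.882       0.111      0.007          benign       High benign

precision_recall(world$holdout$label, pred$predicted_class)
#>       class precision recall
#> 1    benign         1      1
#> 2  dominant         1      1
#> 3 recessive         1      1
```

The three probabilities sum to 1; the class is the argmax (ties resolve to
the least pathogenic class); at the default effect size the planted class
signal is strong, so the gene-disjoint holdout is classified perfectly and
every call is High confidence. Lower `fixture_config(effect_size = ...)`
to create confusable regimes.

Annotation of a variant file against a reference directory (the fixture
world doubles as one) and the three-file output contract — a summarized
VCF, an extensive stop/frameshift table, and a splice-site table:

```r
run_annotate(world$paths$vcf, reference_dir = world$paths$dir,
             out_dir = "annotated", model = model)
```

A thin command-line wrapper with `annotate`, `train`, `predict`, and
`make-fixtures` subcommands is installed at
`system.file("scripts", "plofpred", package = "plofpred")`.

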