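# mthet — age-related mtDNA heteroplasmy analysis in blood

Somatic mitochondrial DNA (mtDNA) single-nucleotide variants accumulate in
blood with age, observed in bulk sequencing as heteroplasmy fractions
(HL = alt reads / site reads). Their accrual is well described by a
two-step mechanism: replication errors seed *cryptic* mutations in single
cells at undetectable cell fraction, and age-related clonal hematopoiesis
(CH) expands one cell's lineage, carrying its mutations up to detectable
bulk heteroplasmy. `mthet` implements the analysis chain for cohort-scale
heteroplasmy callsets built around that mechanism, for statistical
geneticists and mtDNA biologists working with biobank-style data:

- **Callset QC** — sample filters (contamination > 2%, haplogroup
  conflicts, mtCN < 50 for variant work), genotype recoding
  (HL < 0.01 → reference-homoplasmic), the per-person Poisson detection
  threshold *t* = min{k : P(X < k) ≥ 0.95}, X ~ Poisson(mean nuclear
  coverage), applied to alt allele depth, and the published 5-variant
  NUMT-artefact blacklist.
- **mtDNA copy number** — mtCN = 2 × (mean mtDNA coverage)/(mean nuclear
  coverage), with natural-spline residualisation of log mtCN against draw
  time, date, centre, month, fasting and blood-composition covariates.
- **Mutational spectrum** — strand-resolved classification (reference
  C/A → light strand, G/T complemented to heavy), Ori region 16172–210,
  age-accumulating classes (A>G either strand, C>T heavy, outside Ori),
  trinucleotide contexts (192 strand-resolved categories, 96 collapsed),
  possible-variant-normalized per-person mean counts, and per-signature
  linear SBS correlation with Bonferroni correction.
- **Selection** — all 49,704 possible SNVs of the canonical genome,
  consequences under the vertebrate mitochondrial code, heteroplasmy-binned
  dN/dS = (observed/possible nonsynonymous) / (observed/possible
  synonymous) restricted to the age-accumulating classes, with a 1000-draw
  per-individual sampling null.
- **CH comparisons** — exact age/sex-matched control resampling
  (difference statistic with resampling SE, normal or permutation p),
  sibling variant sharing, ±100 kb proximity locus clumping, IVW
  effect-size regression (weights 1/(SEx²·SEy²)), and covariate-adjusted
  logistic disease association.
- **Synthetic cohorts** — `simulate_cohort()` generates reference genomes,
  gene models and callsets under the two-step mechanism with binomial read
  sampling against Poisson coverage, CH clonal expansion, sibling pairs
  with transmitted variants, and injectable phenotype odds ratios, so the
  whole chain runs with no restricted data.

## Worked example

```r
library(mthet)

ref   <- generate_reference(16569, placeholder_positions = 3107, seed = 1)
genes <- generate_gene_model(ref, 5, c(heavy = 4, light = 1), seed = 2)
sim   <- simulate_cohort(ref, genes, cohort_config(n_samples = 2000), seed = 3)

qc  <- filter_samples(sim$samples, "variants")
thr <- setNames(poisson_detection_threshold(qc$kept$mean_nuc_coverage),
                qc$kept$sample_id)
cs  <- recode_genotypes(sim$callset[sim$callset$sample_id %in% qc$kept$sample_id, ])
cs  <- apply_blacklist(apply_hl_filter(cs, "burden", thr))$callset
cs  <- annotate_consequence(cs, genes, ref)

burden <- compute_snv_burden(cs, qc$kept, "age_accumulating")
possible <- annotate_consequence(enumerate_possible_snvs(ref), genes, ref)
nd <- sampling_null_dnds(cs, possible, "GENE01", hl_bin = c(0, 0.95),
                         n_reps = 1000, seed = 4)
```

which prints (via the `sprintf` calls in `analysis/`-style drivers):

```
kept 1954 of 2000 samples; 2366 QC-pass heteroplasmic SNVs
mean age-accumulating burden 0.98; slope 0.225 per decade
GENE01 dN/dS = 0.94 (null median 1.02, 95% envelope 0.76-1.38)
```

Reading the numbers: 46 samples fail QC (contamination or low mtCN); the
average person carries about one detectable age-accumulating heteroplasmy,
rising by ~0.23 per decade of age — the detected tail of the cryptic
mutation load, amplified in CH carriers; and the neutral generator yields a
gene dN/dS statistically indistinguishable from its sampling-null envelope,
as it should in the absence of selection.

The `analysis/` directory contains the full numbered workflow
(`01_simulate_cohort.R` … `06_associations.R`); each step is a thin driver
over the package functions that prints what it found and writes its tables
under `results/`.

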