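---
title: "Modelling and measuring age-related mtDNA heteroplasmy in blood"
author: "mthet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling and measuring age-related mtDNA heteroplasmy in blood}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The scientific problem

Blood accumulates somatic mitochondrial DNA (mtDNA) single-nucleotide
variants with age. In bulk short-read sequencing each variant is observed as
a *heteroplasmy fraction* (HL) — the proportion of a person's mtDNA
molecules carrying the allele — and detection competes against two
adversaries: reads misassigned from nuclear segments of mitochondrial origin
(NUMTs), and the simple binomial thinning of low-fraction alleles at finite
coverage. The package implements a complete analysis chain for cohort-scale
heteroplasmy callsets:

1. sample- and variant-level quality control, including a per-person
   Poisson read-depth detection threshold;
2. mtDNA copy-number (mtCN) estimation and covariate residualisation;
3. strand- and region-aware mutational spectrum statistics with
   trinucleotide contexts and SBS-signature correlation;
4. nonparametric dN/dS with a per-individual sampling null;
5. clonal-hematopoiesis (CH) comparisons via exact age/sex-matched
   resampling, sibling variant sharing, proximity locus clumping,
   inverse-variance-weighted (IVW) effect-size regression, and logistic
   disease association.

Because the motivating datasets are access-controlled biobanks, the package
ships a synthetic cohort generator that reproduces the statistical structure
these analyses assume, so every stage is tested end-to-end with no
downloads.

## The two-step generative model

The generator (`cohort_config()`, `simulate_cohort()`) encodes a two-step
mechanism:

* **Step 1 — cryptic mutation.** Replication errors deposit mutations in
  single cells at negligible cell fraction. Per person, the number of
  cryptic mutations of class $c$ is Poisson with mean
  $\text{age} \times r_c$; each receives a cell fraction drawn from a Beta
  distribution concentrated near zero, so almost none are visible in bulk.
* **Step 2 — clonal expansion.** CH status is Bernoulli with
  logistic-in-age probability. A carrier's expanded clone descends from one
  cell, so a configurable subset of their cryptic mutations (those on the
  clone's lineage) jumps to bulk fraction equal to the clonal fraction.

Observed calls are then produced exactly as a caller would see them: site
depth $DP \sim \text{Poisson}(\text{mean mtDNA coverage})$, alt depth
$AD \sim \text{Binomial}(DP, \text{HL}_\text{true})$, a record is emitted
only when $AD \ge 1$, and the reported HL is $AD/DP$. The detection
threshold therefore interacts with coverage exactly as in real callsets.

Two deliberate asymmetries:

* Only the *cryptic* (age-rate) mutations can ride the expanded clone.
  Baseline-class and transmitted variants are modelled as carried uniformly
  across cells — and expanding one clone does not change the bulk fraction
  of an allele that every cell carries equally. This is the same argument
  that distinguishes inherited from somatic heteroplasmies under clonal
  expansion, and it is what makes CH enrichment specific to the
  age-accumulating classes.
* Cryptic (age-rate) mutations arise in the non-Ori ("Other") region only,
  matching the definition of the age-accumulating classes; baseline classes
  arise genome-wide. Whether cryptic mutations arise during embryogenesis or
  through life is observationally equivalent in this model (both give
  expected counts proportional to age at draw); `cohort_config(timing=)`
  records the intended interpretation without changing the arithmetic.

### Default parameters (the study conditions)

| parameter | default | rationale |
|---|---|---|
| per-year cryptic rates | C>T heavy 0.04, A>G heavy 0.05, A>G light 0.015 | strand-biased, A>G- and C>T-heavy process; gives a mean detected age-accumulating burden near 1 per person at cohort ages |
| baseline class rates | 0.1–0.4 expected count, age-flat | non-accumulating background classes |
| cell fraction (non-clone) | Beta(0.3, 30) | mean ≈ 0.01, mass near zero: cryptic |
| CH prevalence | logistic(−8 + 0.08·age) | few percent in mid-life, rising with age |
| clonal fraction | Beta(2, 6) | typical detected clone sizes, mean 0.25 |
| clone carriage probability | 0.25 | fraction of a carrier's cryptic mutations on the clone lineage |
| mean mtDNA coverage | lognormal(log 2000, 0.3) | consensus-aligned mtDNA coverage scale |
| mean nuclear coverage | N(30, 3), truncated at 5 | standard WGS depth; drives both the detection threshold and mtCN |
| ages | uniform over [18, 90] | flat design, no demographic realism intended |

These defaults were fixed once when the generator was written. They are the
conditions under which the test suite and the acceptance script operate.

## Quality control

**Sample level** (`filter_samples()`): removal for overlapping
homoplasmies, mtDNA or nuclear contamination estimates above 2%, multiple
haplogroup-defining variants at low heteroplasmy, or pilot-phase
collection; variant-mode analyses additionally drop samples with raw
mtCN < 50 (low mtCN inflates NUMT contamination risk, copy-number analyses
keep these). Each removed sample is logged with exactly one primary reason,
in the rule order above, so QC reports reconcile by construction.

**Genotype recoding** (`recode_genotypes()`): caller-flagged genotypes are
dropped; HL < 0.01 is recoded homoplasmic for the *reference* allele (we
read "homoplasmic recessive" as "variant absent", the only interpretation
consistent with downstream counting); missing genotypes become homoplasmic
reference only when site coverage is at least 100.

**Detection threshold** (`poisson_detection_threshold()`): the burden
callset keeps an SNV only if its alt depth reaches
$t = \min\{k : P(X < k) \ge q\}$, $X \sim \text{Poisson}(\lambda)$ with
$\lambda$ the person's mean *nuclear* coverage and $q = 0.95$. The nuclear
basis follows the method's definition; a `basis = "mito"` option is exposed
because the threshold is sometimes described relative to mtDNA coverage.
Ties resolve to the smallest qualifying integer; the implementation is
`qpois(q, lambda) + 1` and the tests pin it to a brute-force cumulative-pmf
oracle.

**Heteroplasmy filters** (`apply_hl_filter()`): `common` mode keeps
0.05 ≤ HL ≤ 0.95 (both bounds inclusive); `burden` mode keeps SNVs (never
indels) with HL ≤ 0.95 and AD ≥ t. The 0.95 upper bound is treated as
inclusive; the boundary affects few records and the choice is recorded
here.

**Blacklist** (`default_blacklist()`, `apply_blacklist()`,
`derive_blacklist()`): five published variant identities whose detections
rose more than 500% under the lenient filter while recurring more than 30
times are shipped as the packaged default. The derivation *rule* is also
provided as a function over lenient/strict callset pairs, but the published
list is not re-derived (it requires the two original cohorts).

## Copy number

`raw_mtcn()` is twice the ratio of mean mtDNA to mean nuclear coverage;
`mean_nuclear_coverage()` reconstructs the denominator from alignment
metrics. `adjust_mtcn()` residualises log mtCN against draw time (natural
spline, 5 df), assessment date (natural spline with knots every 91 days
anchored at the earliest date), centre, month and fasting-time indicators
(fasting clamped to [1, 18] hours), and the supplied blood-composition
variables, after blanking blood measurements more than 4 SD from their
mean. Rows with any missing covariate are dropped from the fit rather than
imputed. Natural-spline basis conventions differ across ecosystems, so the
tests assert residual *properties* (independent covariates leave the
residual essentially the centred log raw value; an injected smooth
draw-time effect is removed; residual mean is zero) rather than
coefficients. Which blood variables enter is cohort-specific, so the
function takes an explicit `blood_vars` list.

## Mutational spectrum

The reference sequence represents the light strand. `classify_variants()`
reports C/A-reference variants on the light strand as-is and complements
G/T-reference variants onto the heavy strand, giving six substitution
classes per strand. The Ori control region is positions 16172–210,
*inclusive on both ends*, wrapping the origin ("between ... and" read
inclusively; the handful of boundary positions do not move any result).
For toy genomes the reference object carries proportionally scaled Ori
bounds so the same code paths run at any length. The age-accumulating
classes are A>G on either strand plus C>T on the heavy strand, outside
Ori.

Contexts are strand-specific 3-mers (`trinucleotide_context()`), reverse
complemented for heavy-strand variants; windows touching the placeholder
position are unusable and excluded from context tables. The category
system is 6 classes × 16 flank pairs × 2 strands = 192; collapsing strands
gives the standard 96.

`normalized_mean_counts()` divides the mean per-person count (over *all*
QC-pass samples, zero-count people included) by the number of possible
variants in the category (`count_possible()`), so rates are comparable
across strands and regions with different base abundance. Denominators are
available both per class and per context; both normalisations are exposed
because figure-level conventions vary. Age strata default to 5-year bins
within a configurable window (18–90 or 40–70 in the motivating cohorts).

`sbs_correlation()` fits one simple linear regression per signature on the
96-category axis and Bonferroni-corrects over the number of signatures
supplied (86 in the published catalogue). Because the strand-resolved
categories are C/A-referenced while SBS catalogues are
pyrimidine-referenced, `cosmic96_spectrum()` re-expresses A>* categories as
their T>* complements with reverse-complemented context. The comparison is
run per strand by default (the collapse from 192 to 96 is not uniquely
defined); a pooled mode is a one-line `cosmic96_spectrum()` call over both
strands. A constant signature is aliased with the intercept and reported
with `NA` slope rather than an error.

## Selection (dN/dS)

`enumerate_possible_snvs()` expands every informative position into its
three alternates (49,704 rows for the canonical genome with one
placeholder). `annotate_consequence()` translates the affected codon before
and after substitution under the vertebrate mitochondrial code
(Biostrings code table 2); identical amino acid (including stop-retained)
is synonymous, change to stop is pLoF, any other change is nonsynonymous;
positions outside genes are noncoding.

`compute_dnds()` is the observed/possible ratio estimator: dN = observed
nonsynonymous records / possible nonsynonymous variants, dS likewise,
restricted — numerator *and* denominator — to the same class subset
(age-accumulating by default). Three conventions are fixed and documented:

* Observed counting is per (sample, variant) record, because the sampling
  null preserves per-individual counts; a variant recurring in many people
  counts once per person.
* pLoF variants sit in neither dN nor dS by default (the ratio names
  nonsynonymous vs synonymous); `include_plof = TRUE` folds them into dN.
* Heteroplasmy bins default to [0, 0.05), [0.05, 0.2), [0.2, 0.5),
  [0.5, 0.95]; the bin edges are configurable because no canonical edges
  exist, and the top edge is inclusive.

`sampling_null_dnds()` draws, for each individual and class, that
individual's observed count of variants *without replacement* from the
gene's possible variants of the class ("without replacement" is
per-individual-per-replicate: one person cannot draw a site twice, two
people can share one), recomputes dN/dS identically on each of 1000
replicate callsets, and reports the null median, the 2.5–97.5% envelope
and the observed percentile. dS = 0 replicates are reported as `NA` and a
degenerate all-zero null is reported as such rather than erroring.

The self-consistency test treats the observed data as one extra null draw
and checks that its percentile is uniform. Because dN/dS at small counts is
discrete, the test uses a randomized probability integral transform (ties
broken uniformly), which is *exactly* uniform under exchangeability — the
raw percentile is still what the user-facing function reports.

## Clonal-hematopoiesis comparisons

`match_controls()` builds R control sets (R = 500 in the motivating
analysis; the drivers here use 100–200) with exactly the CH group's
multiset of (integer age, sex) — exactness is asserted on every set, every
run. Ages are matched on integer years; the method statement does not fix a
granularity and integer years is the natural resolution of the input.

`matched_difference_test()` evaluates any per-category statistic on the CH
group and every control set; the control point estimate is the mean over
sets, its SE the SD over sets, and the difference statistic is summarised
the same way and tested against zero (two-sided), Bonferroni-corrected
(factor 192 for strand-resolved context tables). Differences are computed
in the same normalized units as the spectrum module when the statistic is a
normalized count. Two p-value methods are provided:

* `method = "normal"` — the z test on the resampling SE, matching the
  reference analysis. At biobank scale (control pools hundreds of times the
  CH group, R = 500) this is well calibrated. In small cohorts it is mildly
  anti-conservative, because the resampling SD reflects only the
  control-side variability and the finite control pool.
* `method = "permutation"` — the two-sided rank of the CH statistic among
  the control-set statistics, exactly calibrated under exchangeability at
  any cohort size. The type-I acceptance test uses this method; the test
  suite verifies its error rate stays at or below nominal under the null
  configuration (clone carriage switched off).

`sibling_sharing()` keeps variants seen in at least 5 individuals
cohort-wide (artefact guard), takes sibling 1 as the lexically smaller
sample id (deterministic; a randomized option exists because the
orientation is stated only as arbitrary), and reports the proportion of
sibling-1 variants found in sibling 2 at *any* heteroplasmy, per
sibling-1 HL bin, with exact binomial intervals.

`clump_loci()` merges significant variants (p < 5e-5) whose ±100 kb windows
overlap, per chromosome, and reports the most significant variant as the
locus lead. `ivw_effect_correlation()` regresses outcome on exposure effect
sizes with weights $1/(SE_x^2 \cdot SE_y^2)$, through the origin by default
(the MR-IVW convention; an intercept option exists), assuming exposure
alleles are pre-oriented risk-increasing. `disease_association()` is the
covariate-adjusted logistic fit (age, sex, age×sex, age², age²×sex,
ancestry, haplogroup indicators) with never-smoker filtering and exclusion
of ancestry groups with fewer than 3 individuals in either phenotype class;
(quasi-)separation is detected from degenerate fitted probabilities plus an
absurd burden standard error and flagged instead of reported.
`mean_positional_score()` joins an externally supplied per-position
constraint score table and reports per-group means ± SE; the bundled driver
uses a synthetic score table, labelled as such.

## Numerical and degenerate-input conventions

* Circular coordinates wrap at both ends (`wrap_position()`); the
  placeholder base N never enters denominators, contexts or gene models.
* Zero-variant samples are explicit zeros in every burden and mean-count
  computation, never dropped.
* Empty strata, empty test arms, all-zero null draws and dS = 0 all return
  flagged missing values with the structure intact, rather than errors;
  genuinely inconsistent inputs (ref mismatch, missing thresholds,
  infeasible matching strata, rank-deficient designs) error with the
  offending item named.
* Determinism: every stochastic routine takes a seed and identical seeds
  give byte-identical outputs.

## Problem sizes in the test suite

The packaged checks run at desk scale, chosen to keep the full suite at a
couple of minutes while leaving comfortable statistical margins: cohorts of
5,000 (pooled to 50,000 for rate calibration), 500 replications for the
dN/dS percentile-uniformity check (300 null draws each), 500 null cohorts
of 600 people for matched-test calibration, and n = 20,000 for odds-ratio
recovery. The acceptance script (`scripts/acceptance.R`) regenerates a
4,000-person cohort and recomputes every headline quantity from scratch at
the seed given on the command line.

## What the synthetic data does and does not show

Passing tests demonstrate that the statistical machinery is correct under
the generator's assumptions: Poisson mutation counts, independent binomial
read sampling, a single expanded clone, uniform ages, exchangeable
individuals. Real callsets violate several of these — NUMT misalignment is
structured rather than Poisson, sequencing error is context-dependent,
multiple clones coexist, haplogroups structure both the spectrum and the
denominators, and blood-cell composition confounds mtCN. The QC layer
exists precisely because of those violations, but the tests here validate
its *logic*, not its sufficiency on any particular real dataset. Results on
real cohorts should be accompanied by the same diagnostics the drivers
print: QC reconciliation counts, threshold distributions, null envelopes
and matched-control calibration.
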