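---
title: "Methods: depth-based CNV calling and variant interpretation for a retinal gene panel"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: depth-based CNV calling and variant interpretation for a retinal gene panel}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(retpanel)
```

# Scope

`retpanel` implements the computational core of a targeted
gene-capture diagnostic workflow for inherited retinal dystrophies
(retinitis pigmentosa and related conditions). A capture panel
enriches the exons of a few hundred disease genes; samples are pooled
20–30 to a capture batch and sequenced to several hundred fold. From
there the package covers four analyses:

1. **Panel QC** — coverage-threshold fractions over target and flank,
   poor-exon flagging, downsampling saturation curves, and pairwise
   reproducibility correlations.
2. **CNV detection** — exon-level read-depth z-scores within a batch,
   a bilateral cutoff, segmentation into multi-exon calls, and
   zygosity assignment.
3. **Variant interpretation** — a four-step filtering cascade,
   inheritance-mode matching, confidence grouping, and family
   segregation checks.
4. **Accuracy evaluation** — base-resolution confusion matrices and
   the derived sensitivity/specificity/precision/accuracy metrics.

Because no patient sequencing data ship with the package, a
synthetic-data module generates depth matrices, per-base depth
tracks, annotated variant tables and family genotypes with known
truth; every downstream module is validated against that truth.

Primary alignment, base calling, SNV/indel calling and all wet-lab
steps are out of scope: the package starts from per-exon mean depths,
per-base depth tracks and annotated variant tables.

# The depth model and the CNV statistic

## Normalization

Let $d_{se}$ be the mean depth of sample $s$ over exon $e$. The
normalized depth is

$$\bar X_{se} = \mathrm{Nom}_{se} = \frac{d_{se}}{\bar d_s},$$

where $\bar d_s$ is the sample's mean depth over the whole target.
`normalize_depth()` computes $\bar d_s$ as the exon-length-weighted
mean — the per-base mean depth of the target — because a "mean depth
over all target regions" is naturally a per-base quantity; an
unweighted mean over exons is available (`weighted = FALSE`). The
weighted choice makes the length-weighted mean of $\mathrm{Nom}$
exactly 1 within each sample, and the whole pipeline invariant to
scaling any sample's depths by a positive constant (library size
cancels).

## Batch statistics and z-score

Within one capture batch, each exon gets a mean $\mu_e$ and standard
deviation $\sigma_e$ of $\mathrm{Nom}_{se}$ across the $N$ batch
samples, and each cell a z-score

$$z_{se} = \frac{\bar X_{se} - \mu_e}{\sigma_e}.$$

Cells with $z < -2.58$ are deletion evidence, $z > +2.58$ duplication
evidence. The bilateral 2.58 cutoff leaves 99.01% of a standard
normal inside, i.e. it filters out over 99% of copy-neutral cells;
`pnorm(2.58) - pnorm(-2.58)` reproduces that number. The statistic is
only defined within a batch — samples captured and sequenced together
share an efficiency profile — so depth matrices are strictly
per-batch and the caller first verifies that all pairwise Pearson
correlations of per-exon depths exceed 0.7
(`check_batch_correlation()`). A failing precondition aborts calling
unless `force = TRUE`.

Numerical choices:

* $\sigma_e$ uses the $n-1$ sample SD; batches are small (20–30), so
  the distinction matters.
* $\sigma_e = 0$ (all samples identical at an exon) is degenerate but
  legal input: the exon gets $z = 0$ and an "uninformative" flag
  rather than an error.
* A batch needs at least 3 samples; below that the SD is meaningless.

## Estimating μ and σ under contamination

The formula above reads literally as "all samples of the batch,
including the one under test", and that is the default
(`method = "all"`). It has a known weakness: a strong CNV inflates
$\sigma_e$ and biases every $z$ at that exon toward 0. The effect is
mild for one carrier in twenty but decisive when several relatives in
the same batch share a deletion — a realistic situation, since
probands and family members are typically captured together. With a
proband (ratio 0) plus two heterozygous carriers (ratio 0.5) among 20
samples, the all-sample $\sigma$ at the deleted exons grows to
roughly 0.25, and the carriers' $z \approx -1.8$: the carriers become
undetectable by construction. Notably, family carriers *are* expected
to show $|z| > 2.58$ in this workflow, which is only possible if the
reference statistics effectively exclude the CNV carriers.

Two alternatives are therefore provided:

* `method = "loo"` — leave-one-out $\mu, \sigma$ per sample. Protects
  against self-inflation but not against relatives sharing the CNV.
* `method = "masked"` — per exon, estimate $\mu, \sigma$ from the
  copy-neutral samples only: an initial median/MAD screen (at 2
  robust SDs) seeds an exclusion set, then mean/SD are iteratively
  refined, excluding samples with $|z|$ above the cutoff and
  re-admitting anything within it. The screen threshold only affects
  initialization; the converged reference set is governed by the
  cutoff. This is the method of choice when a batch may contain
  related carriers, and the one used by the package's family-CNV
  validation experiment.

Under the null the masked estimator is somewhat anticonservative
(flag rate near 5% rather than ~1%, because trimming shrinks
$\sigma$); the default `"all"` estimator keeps the nominal ~1% rate.
This trade-off is deliberate: calibration by default, robustness on
request.

## Segmentation and zygosity

Within each sample and gene, maximal runs of consecutive panel exons
flagged in the same direction merge into one call. By default every
spanned exon must pass the cutoff (`max_gap_exons = 0`); setting
`max_gap_exons = 1` bridges single-exon dropouts, which matches the
observation that carriers of a real multi-exon deletion occasionally
miss the threshold at one low-efficiency exon ("almost all" exons
above cutoff). Calls never span gene boundaries.

Deletion zygosity comes from the mean normalized depth over the
span: below 0.25 homozygous, 0.25–0.75 heterozygous. These bounds are
the midpoints between the expected ratios 0 (homozygous deletion),
0.5 (heterozygous deletion) and 1 (neutral); they are configurable
because no published rule exists. Duplications get `NA` — a 3-copy
gain (expected ratio 1.5) is too close to noise for a reliable
het/hom split at these batch sizes.

# The interpretation cascade

Four steps, in a fixed order, each returning a subset of its input:

1. **Consequence** (`step1_consequence`): keep nonsense, missense,
   frameshift and inframe coding indels, and splice-region/intronic
   records within ±10 bp of an exon boundary. Offsets are measured
   from the exon boundary in 0-based half-open coordinates, positive
   into the intron.
2. **Public allele frequency** (`step2_population_af`): drop
   variants with frequency **strictly greater than** 0.01 in *any
   one* of the three population databases; an absent frequency is
   unobserved and passes.
3. **Internal control database** (`step2b_internal_control`): drop
   variants at ≥ 0.05 in the internal cohort of sequenced normals.
   The looser threshold reflects the smaller internal cohort (an
   allele seen a few times among 200 normals still may be rare). The
   two thresholds are deliberately kept as two separate settings.
4. **Predictor consensus** (`step3_prediction_consensus`): novel
   missense variants need at least 2 of 5 predictors (SIFT,
   PolyPhen2, MutationTaster, FATHMM, PhyloP) calling damage, where
   PhyloP counts as damage iff its score is strictly positive.
   "Possibly damaging" normalizes to damage at ingest; a missing
   predictor output counts as non-damage (conservative). All other
   survivors pass untouched.

**Inheritance matching** (`match_inheritance`): per gene, recessive
disease is solved by a homozygous variant or two heterozygous
variants (assumed in trans when no family data resolve phase — the
assumption is recorded on the diagnosis); dominant by one variant in
a dominant-capable gene; X-linked by a hemizygous (or homozygous
female) variant. A single het in a recessive-only gene stays
unsolved. When several genes qualify, all are reported, ranked by
confidence group then by reported-allele count.

**CNV fallback** (`step4_cnv_fallback`): only when the first three
stages leave a sample unsolved. A homozygous deletion in a recessive
gene solves alone; a heterozygous deletion pairs with a surviving het
variant in the same recessive gene, or solves a dominant gene alone.
A deletion allele counts as novel truncating evidence for grouping
(Group 2 at best), since a deletion is never a "reported" point
mutation and always disrupts the product.

**Confidence groups** (`assign_confidence_group`): Group 1 — every
causal allele previously reported pathogenic; Group 2 — at least one
novel truncating allele, where novel coding indels (including inframe
ones) count as truncating-equivalent; Group 3 — only novel
missense/splice alleles. A mixed diagnosis (one reported allele plus
one novel missense) is not covered by the first two definitions and
falls to Group 3 by the rules as stated; the diagnosis carries a flag
so a reviewer can upgrade it manually.

**Segregation** (`check_segregation`): dominant — affected members
carry the allele, unaffected carry none; recessive — affected carry
the full configuration, unaffected never do, and for compound
heterozygotes each parent of an affected child must supply one of the
two alleles (trans check); X-linked — affected males hemizygous,
unaffected males non-carriers.

# The synthetic-data generator

`simulate_depth_matrix()` models a capture batch as: a per-exon
capture efficiency shared by the batch, drawn lognormal with log-sd
0.3 (mean 1) — or passed in explicitly to emulate repeated capture
experiments of one probe design — times a per-(sample, exon)
negative-binomial draw around `mean_depth × efficiency ×
copy_ratio`. Defaults are 20 samples at 400-fold, matching a standard
pooled capture batch. The NB overdispersion `dispersion = 0.01`
gives the normalized depth a coefficient of variation near 10%,
which reproduces both the >0.7 inter-sample depth correlations of a
reproducible capture and a realistic CNV signal-to-noise;
`dispersion = 0` is the exact noise-free limit used by algebraic
tests. Copy ratios are restricted to 0, 0.5, 1, 1.5 — germline CNV
states; mosaics are out of scope.

`simulate_base_depths()` emits integer per-base read counts over
target and flank (flank at 0.74 relative efficiency, roughly the
observed 295- vs 400-fold split), and `downsample_track()` thins
those counts binomially — expectation-exact, without modelling
individual reads. `simulate_variants()` plants diagnoses that satisfy
every cascade step by construction and surrounds them with background
variants that each violate at least one rule (non-protein-changing,
common in a public database, common internally, or novel missense
with under two damaging predictors). `simulate_family()` produces
Mendelian-consistent nuclear families for ad/ar/xl diagnoses.

What the generator does **not** emulate: GC-content and mappability
effects on capture efficiency, correlated noise along the genome,
mosaic copy states, read-level artifacts, indel representation
ambiguity, and the real spectrum of allele frequencies. Passing
tests therefore demonstrate the pipeline's internal correctness and
its operating characteristics under a plausible noise model — not
performance on real patient batches.

# Validation experiments and problem sizes

The test-suite and the acceptance script (`scripts/acceptance.R`)
recompute, from scratch, at sizes chosen to keep the whole suite in
minutes:

* **Accuracy arithmetic** — the confusion matrix built from two
  911-site call sets sharing 868 sites over a 1,505,712 bp exon
  region yields TN = 1,504,758 and prints sensitivity 95.3%,
  specificity 99.997%, precision 95.3%, accuracy 99.994%, maximum
  FP/FN rate 4.7% (rounding half-up; 1 decimal for
  sensitivity/precision/rates, 3 for specificity/accuracy, chosen so
  printed reports carry information at their scale).
* **Null calibration** — a copy-neutral 20 × 500 batch at 400×:
  the default estimator flags ~0.4–1% of cells at |z| > 2.58,
  comfortably under 5%.
* **CNV recovery** — a 10-exon homozygous deletion (exons 17–26 of
  the 26-exon gene) plus two heterozygous carriers in a 20-sample
  batch over a ~1100-exon panel, 100 replicates with the masked
  estimator: the homozygous deletion is recovered as exactly one
  full-span homozygous call in ≥95% of replicates, both carriers
  receive overlapping heterozygous deletion calls in ~100%, and
  ~97% of carrier exons individually exceed the cutoff.
* **Cascade exactness** — a 5-patient planted cohort with 400
  violating background variants: the solved set equals the truth
  table exactly, confidence groups included.
* **Segregation closure** — 100 simulated recessive trios all pass
  `check_segregation`.

The real cohort's headline numbers that depend on patient data (400×
mean depth, 96.85% of bases at 20×, the 64.6% diagnostic yield)
cannot be recomputed without that data; the package reproduces the
computations, and its synthetic experiments check the properties
those numbers instantiate.

# Known limitations

* The z statistic assumes most of the batch is copy-neutral at any
  exon; a CNV shared by more than ~40% of a batch defeats even the
  masked estimator.
* Duplication power is intrinsically low at ratio 1.5 with 10% noise;
  the package reports duplications but makes no zygosity claim.
* Site matching in the concordance module is exact on
  (chrom, pos, ref, alt); discordant indel representations of the
  same event count as disagreements.
* The interpreter's in-trans assumption for two heterozygous variants
  without family data is recorded but unverifiable from a single
  sample.
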