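---
title: "Methods: pathway-level susceptibility analysis with pathrisk"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: pathway-level susceptibility analysis with pathrisk}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pathrisk)
```

## The problem

Familial breast cancer (FBC) risk is only partially explained by known
high-penetrance variants such as pathogenic BRCA1/2 mutations. Because
different women may carry different rare variants that disrupt the same
signaling network, single-gene association tests are underpowered for the
shared downstream biology. `pathrisk` implements a pathway-level strategy:
curated gene sets are the analysis unit, and evidence that a pathway
separates women who developed FBC from family-history controls is gathered
from two independent data types — expression profiles of peripheral blood
mononuclear cells and germline exome variants — then combined across
cohorts by rank consistency.

The pipeline has four computational arms:

1. **Expression classification.** For each pathway, an RBF-kernel support
   vector machine is trained on the pathway's member genes only, and its
   cross-validated AUC measures how well the pathway's expression separates
   cases from family-history controls. Significance is an empirical
   permutation P: the fraction of label-shuffled AUCs strictly exceeding
   the observed AUC.
2. **Variant burden.** Annotated germline variants pass a filtering cascade
   (population and background allele frequencies, internal carrier
   frequency, exon proximity, predicted severity), are collapsed to binary
   gene- and pathway-level "mutated" indicators, and pathway mutation
   rates are compared with a one-sided unconditional (Barnard) exact test.
3. **Evidence combination.** Per-dataset P-values are combined by
   rank-consistency (with Fisher, Wilkinson minimum-P, and Edgington sum-p
   alternatives and Storey q-values), and two exclusion filters remove
   pathways whose signal looks like a treatment effect or is specific to
   one BRCA subgroup.
4. **Morphometry.** Fluorescence microscopy fields of primary mammary
   epithelial cells are quantified (cell-area fraction, nuclei count,
   cell-size metric, the three shortest inter-nucleus distances, stain-area
   fractions) and compared between high-risk and control groups with Welch
   t-tests.

Everything is exercisable on synthetic cohorts with known ground truth; the
generators are first-class, tested code.

## Classification details

**Gene ranking.** Genes within a pathway are ranked by recursive feature
elimination: each round fits a linear max-margin model, scores genes by
squared weight, and removes the lowest-scoring 10% (rounded up); once fewer
than 1% of the initial genes remain, one gene is removed per round. The
reversed elimination order is the ranking. Ranking is linear even though
final classification is RBF: the RBF kernel has no per-gene weight, and
this split mirrors the common attribute-evaluator/classifier toolchain
pairing. Constant genes receive zero weight and rank last, with ties broken
deterministically by column order.

**Panel size.** Cross-validated AUC is evaluated for the top 25, 50, ...,
300 ranked genes (panel sizes exceeding the pathway are replaced by the
full set; a pathway smaller than 25 contributes its full set). The best k
wins; ties go to the smallest k (parsimony). The same seeded, stratified
fold assignment is reused across the grid so panel sizes are compared on
identical splits.

**Scoring.** Each sample's score comes from a model never trained on it
(stratified ten-fold cross-validation on the discovery design;
leave-one-out for the small normal-breast data sets; train/test transfer
across cohorts). Genes are z-scored with training-fold statistics only. The
SVM cost parameter is tuned per outer fold by inner cross-validation over
{0.01, 0.1, 1, 10, 100} (tuning can be disabled, fixing the cost, for
reduced-scale simulation studies). The RBF bandwidth uses the median
heuristic on the scaled training rows — the literature leaves it
unspecified, and the median heuristic is a standard label-free default.
User-facing scores are calibrated to [0, 1] by a Platt-style sigmoid fitted
to training-fold decision values. We fit this sigmoid explicitly rather
than relying on libsvm's built-in probability machinery, which proved
numerically unstable (occasionally inverting scores) on small
well-separated folds and is not bit-reproducible; calibration is monotone,
so AUC is identical either way.

**Permutation P.** P = (number of permuted AUCs strictly greater than
observed) / B, exactly the plain fraction, so P can be 0; an optional
(r+1)/(B+1) correction is available but off by default. Permutations reuse
the observed gene panel and the cost chosen on observed labels. The default
scheme permutes labels *within* cross-validation folds: because the
observed folds are stratified, this preserves the per-fold class balance
exactly, making the permutation test exact conditionally on the fold
assignment and per-fold class counts, and it allows the per-fold scaling
and the label-free kernel bandwidth to be precomputed once. A global
scheme (all labels reshuffled, folds re-stratified per permutation) is
available via `perm_scheme = "global"`, and `perm_refit` re-runs ranking
and panel-size selection inside each permutation for the fully nested
null. One scheme we tried and rejected: globally reshuffling labels while
keeping the folds fixed is markedly anti-conservative (training folds
become class-imbalanced, biasing permuted AUCs below one half), roughly
doubling the nominal rejection rate — the calibration suite guards against
this.

**Treatment-effect filter.** Women who developed cancer received therapy;
a pathway whose scores differ between family-history controls and
non-family-history women (two-sided t-test, P < 0.05) may be tracking
treatment exposure rather than inherited risk and is flagged. In the
pipeline this is one test per pathway, and both comparison groups are
scored by the *same* model (trained on the discovery cohort's
family-history samples): mixing cross-validated scores for one group with
transfer-model scores for the other puts two differently calibrated score
sources in one t-test and flags spuriously — precisely on the pathways
with real signal, where calibration differs most.

**BRCA-subgroup filter.** To keep pathways common to carriers and BRCAX
women rather than specific to either, the pipeline flags pathways whose
mutation rates differ between BRCA1/2 carriers and BRCAX women (the
unconditional exact test applied once in each direction, either direction
P < 0.05). A two-sided t-test comparing the subgroups' expression-based
pathway scores is reported alongside for inspection but does not flag by
default — the combination of multiple subgroup tests inflates the
per-pathway exclusion rate well beyond the nominal level.

## Variant cascade details

Rules are applied in a fixed order, and each excluded variant is attributed
to the first rule it fails, which makes the per-rule exclusion counts
well-defined and conserving (input = retained + sum of exclusions):

1. reference-population minor allele frequency > 1%;
2. background-cohort frequency > 3% (a looser bound, since a cancer-cohort
   background may be enriched for susceptibility variants);
3. carried by > 15% of study samples (carrier fraction, not allele
   frequency — the source text is ambiguous and carrier fraction is the
   natural unit for binarized data);
4. outside primary-transcript exons ± 2 bp (splice-site allowance);
5. effect rules: severity LOW/MODIFIER dropped; HIGH retained; MODERATE
   InDels retained; missense SNVs retained only when called deleterious by
   the aggregated predictor; other MODERATE SNVs dropped;
6. missense SNVs lacking a deleteriousness call (dropped by default,
   configurable).

Heterozygous and homozygous carriage are treated identically. Deleterious
calls are consumed as an input column; the upstream predictors are out of
scope.

**Frequent-gene exclusion.** Genes mutated in a large fraction of
background germline samples are unlikely to drive susceptibility and add
noise when pathways are binarized. The exclusion threshold is selected on
an even grid over 0.2%–10% (50 candidates) at the lower endpoint of the
largest adjacent drop in the excluded-gene count. We take the lower
endpoint deliberately: it is the last threshold that still excludes the
block of frequent genes responsible for the drop, which is the point of the
procedure. The full count-vs-threshold curve is returned so the choice is
auditable. BRCA1/2 are always kept.

**Barnard's test.** The unconditional exact one-sided P uses the
pooled-variance score statistic; the nuisance success probability is
maximized over a 0.001-step grid with local refinement by `optimize`.
The open-interval boundary is handled analytically: when the observed
statistic is ≤ 0 the region contains the all-zero table, the supremum is
approached as the nuisance probability tends to 0, and P = 1 is returned
exactly. The implementation agrees with a brute-force enumeration oracle
(dense fixed grid, no refinement, boundary-packed grid points) to within
1e-6 over all tables with group sizes up to 8.

## Evidence combination details

**Rank consistency.** Within each data set, pathways are ranked by
ascending P and scaled to (rank − 0.5)/N; per pathway, the mean scaled rank
over its m observed data sets is referred to the null that scaled ranks are
i.i.d. Uniform(0, 1). We evaluate this null with the exact Irwin–Hall
distribution of the sum of m uniforms rather than the frequently used
normal approximation. The two agree closely in the distribution body, but
for the configurations that matter here — a pathway ranked near the top of
every data set — the normal tail overstates the exact tail by several
orders of magnitude (e.g. ~6e-5 vs ~8e-11 for a pathway top-ranked in all
five of 100), and a Monte-Carlo oracle confirms the exact form. The normal
approximation remains available via `approx = "normal"`. Because only
within-dataset ranks enter, the combination is invariant to monotone
transforms of the per-dataset P-values. Pathways missing from a data set
are combined over their observed m and flagged, not imputed.

**Alternative combiners.** Fisher (−2Σlog p against chi-square with 2m
df), Wilkinson at k = 1 (Beta(1, m) tail of the minimum), Edgington's
sum-p (Irwin–Hall tail). All reduce to the identity at m = 1. Storey
q-values use the 0.05–0.95 lambda grid with a df = 3 smoothing spline
evaluated at 0.95.

**Concordance.** Per shared gene, Spearman correlation between binary
mutation status and expression; Fisher-transformed z-scores scaled by
sqrt(n − 3); empirical null by central matching (median location, IQR/1.349
scale), pi0 from Storey's estimator on the implied null P-values, and
local fdr = pi0·f0(z)/f(z) with a kernel density for f. The selection
cutoff (default 0.2) is a parameter, since the literature states neither
the estimator nor the cutoff. Genes with constant mutation vectors are
skipped and counted. Below ten usable genes the density estimate is
unreliable and the two-sided null P is used as a conservative local-fdr
proxy.

## Morphometry details

Segmentation uses a contrast stretch, a global Otsu threshold,
morphological closing (disc brush, diameter 5), and hole filling; nuclei
counting adds watershed on the distance map and a minimum particle area of
30 px at the synthetic scale (configurable — the original macro parameters
are not published in the text). Background subtraction for stain channels
uses the median intensity outside the cell mask as a scalar background
level: a full rolling-ball analog would erase large uniform features at the
synthetic scale, where stains are near-binary, while the scalar estimate
removes uniform offsets and is exact on the generator's geometry. The
stain threshold is an Otsu split computed over the cell region only, so
bright stain is separated from diffuse cytoplasmic signal rather than from
the (dominant) dark background. The
cell-size metric is 100 × (cell-area fraction)/(nuclei count) — percent of
field per nucleus. Fields, not patients, are the unit of the Welch t-tests;
per-patient aggregation is left to the caller's data frame.

## Synthetic data: what it emulates and what it does not

The generators define the study conditions used by every validation:

* **Cohorts.** 40 family-history cases, 40 family-history controls, 20
  non-family-history women (half with sporadic cancer), allocated
  deterministically; 40% of family-history women are BRCA1/2 carriers,
  mirroring the discovery-cohort composition. Two cohorts play the
  train/validate roles.
* **Expression.** 100 disjoint pathways of 10–30 genes; within-pathway
  exchangeable correlation 0.2; normalized-scale Gaussian noise; a 1 SD
  mean shift added to 30% of the member genes of the 5 causal pathways, in
  cases only. Clinical covariates cover 80% of samples and are linearly
  linked to 5% of genes, exercising the confounder screen in its
  partial-coverage regime.
* **Variants.** Per-gene Bernoulli carriage at rate 0.01 (no linkage —
  matching the gene-level binarization, which discards multiplicity), plus
  pathway-level carrier probability 0.35 for cases versus 0.05 for
  controls in causal pathways. Every planted variant passes the cascade;
  decoys failing each rule exercise the exclusion counts. Background gene
  frequencies contain a 10-gene block at 5% against a <0.15% bulk, giving
  the threshold-selection procedure a constructed breakpoint at 4.8% (the
  last grid candidate below the block).
* **Microscopy.** Nuclei are disks (radius 6 px) at clustered (control) or
  dispersed (high-risk) centers in a 192-px field; the cell region is the
  union of larger disks and is constrained to be simply connected (a ring
  of cells enclosing a background pocket would make "area covered by
  cells" ill-defined for a hole-filling segmentation, so such
  configurations are re-drawn). Stain channels carry a diffuse cytoplasmic
  base over the whole cell body plus bright stain on a known fraction of
  the cell pixels farthest from the nuclei (cortical F-actin, peripheral
  focal adhesions), at higher coverage for the dispersed phenotype — the
  direction reported for high-risk cells.

Passing tests on these conditions show that the machinery is correct and
calibrated, not that real cohorts would yield the same pathways: the
generator has no batch effects, no probe-level noise, no linkage
disequilibrium, no pathway overlap (pathways are generated disjoint, so a
planted signal is never multiplied across sets — real collections overlap
heavily), and its mutation–expression link is absent unless a test
constructs one.

## Numerical choices and degenerate inputs

* Stratified fold assignment deals each class round-robin in a seeded
  random order; a training fold containing one class is an error (the
  stratification prevents it whenever class counts allow).
* AUC is the rank-sum form of the pairwise Mann–Whitney probability (ties
  count 1/2); its 95% CI is DeLong's, via pROC.
* Permutation-P comparisons use a 1e-12 epsilon so floating-point noise
  cannot turn a tie into a strict exceedance.
* Irwin–Hall evaluation reflects the upper half (F(x) = 1 − F(m − x)) to
  avoid alternating-series cancellation.
* Combination methods clamp P = 0 to the smallest positive double with a
  warning.
* The covariate screen groups covariates by missingness pattern and fits
  each group's joint linear model on its complete cases, testing each
  factor by single-term deletion F-tests (order-invariant; whole factors,
  not dummy levels). Zero-variance covariates are dropped with a warning;
  an over-parameterized group is an error instructing covariate reduction.
  No multiplicity correction is applied at this screen — it is an
  exclusion filter, deliberately permissive at P < 0.01.
* Blank images yield empty masks and zero fractions; fields without nuclei
  are excluded from the cell-size metric with a warning; fewer than two
  nuclei yield no distances.

## Reduced-scale study sizes

Simulation-based checks run at sizes chosen to make the whole suite
practical on a single CPU while keeping every estimate's sampling error
well inside its acceptance band: permutation-null calibration uses 500
replicates at B = 199 with two-fold cross-validation and fixed cost;
null-AUC centring uses 100 pathways at five-fold; end-to-end recovery runs
five seeds at B = 99 with three-fold cross-validation; Barnard's oracle
sweep covers all tables with group sizes up to 8. The full-scale settings
(ten-fold, B = 1000, nested cost tuning) remain the package defaults.

## Known limitations

* The per-pathway SVM treats genes as exchangeable features; no pathway
  topology is used.
* The rank-consistency null assumes independent data sets; shared samples
  across data types violate this mildly, as in the original design.
* The local-fdr fit is a simple central-matching estimator; heavy-tailed
  alternatives can inflate the estimated null scale and make selection
  conservative.
* The morphometry defaults are validated against synthetic geometry only;
  real micrographs will need the brush, particle-area, and background
  parameters revisited.
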