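---
title: "Methods: evolution-aware prediction of pharmacogenetic variants"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: evolution-aware prediction of pharmacogenetic variants}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The scientific problem

Pharmacogenomic annotation suffers from a strong European ascertainment
bias: most variants known to modify drug response were discovered in
European-ancestry cohorts, although the majority of pharmacogene variation
segregates outside Europe. Unlike disease variants, functional
pharmacogenetic (PGx) variants are often *common* — many have been pushed
up in frequency by positive selection on metabolism and immune-response
genes — so prediction tools tuned to rare, deleterious variation perform
poorly on them. `pgxpredict` implements a pipeline built around that
observation ("common treatment, common variant"): it tests pharmacogenes
for enrichment among adaptive-signature loci, assembles an evolutionary +
protein-feature model matrix for missense variants, trains
class-imbalance-aware tree-ensemble classifiers to recognize annotated
pharmacovariants, and summarizes how predicted variants distribute across
populations and clinical-annotation categories.

## Enrichment testing

`permutation_enrichment()` re-draws a signature set of the observed size
uniformly without replacement from the assumed gene universe (29,521 genes
at genome scale) and counts pharmacogene overlaps. The permutation p-value
is the *inclusive* upper tail — the fraction of null draws with overlap
greater than or equal to the observed overlap — so `observed = 0` always
gives p = 1, and a zero count is reported as "< 1/n" while 0.0 is stored.
A complementary normal-approximation p-value standardizes the observed
overlap by the permutation null's mean and standard deviation and takes
the **upper** normal tail; the directional (enrichment) alternative is a
deliberate choice, since the scientific hypothesis is one-sided. Under
uniform sampling only pharmacogene membership matters, so the permutation
draws indices with the first *K* marked as pharmacogenes, which makes each
permutation O(signature size). For any small universe the permutation
p-value converges to the hypergeometric upper tail, which the test suite
uses as an independent oracle.

## The model matrix

Each missense variant carries 14 predictors in a fixed canonical order
(`PGX_PREDICTORS`): global minor allele frequency (0–1), a candidate
adaptive polymorphism (CAP) flag, evolutionary time span (0–2774),
evolutionary probability of the non-reference and reference alleles (0–1),
evolutionary rate (0–57,405), and eight binary UniProt feature-track flags
(topological domain, chain, domain, helix, repeat, proteome, disulfide,
variants). The last two tracks have no discussed biological meaning and
are treated as opaque binary annotations. Variants lacking any
evolutionary statistic are *dropped*, not imputed — this retention rule is
part of the method's definition — and missing MAF is likewise an exclusion
(logged in the drop log) because the analysis never defines an imputation.

Coordinates: variant positions are 1-based (VCF convention); BED tracks
are 0-based half-open. `read_bed_tracks()` converts intervals to 1-based
closed ranges at parse time, so presence is simply positional overlap. A
variant at 1-based position 11 overlaps BED interval (10, 20); position 10
does not; position 20 does; position 21 does not. Strand is ignored.

## SMOTE inside resampling

Annotated pharmacovariants are ~3% of the data, so training data are
balanced with SMOTE: each minority point spawns `perc_over/100` synthetic
points at `x + u (x_nn - x)` with `u ~ U(0, 1)` and `x_nn` one of its `k`
nearest minority neighbors (Euclidean distance over all 14 predictors with
binary flags as 0/1 and no scaling, matching the conventional wrapped
implementation; a standardize-first option exists but is off by default).
Binary columns copy parent or neighbor uniformly per column. The majority
class is then downsampled to `perc_under/100` times the number of
synthetic points. Defaults `k = 5`, `perc_over = 200`, `perc_under = 200`
are the wrapped implementation's defaults; the source analysis names none.
Degenerate cases are defined rather than fatal: a singleton minority class
yields copies with a warning; a majority class smaller than the
undersampling request is kept whole with a warning. Ties among equidistant
neighbors break by lowest row index. Balancing happens *inside each
resample* (the quoted training-control usage implies within-resample
sampling, which is also the leakage-safe reading): the assessment fold
never contributes parents or neighbors, which the provenance records make
auditable.

## Cross-validated training and model selection

`stratified_partition()` holds out 30% of each class. Training uses
5-fold, 10-repeat stratified cross-validation (50 resamples). Within each
resample every hyperparameter configuration is fitted on the same
SMOTE-balanced analysis data and scored on the untouched assessment fold
at threshold 0.5; the configuration with the highest mean *sensitivity*
(the analysis' stated selection metric, reflecting higher confidence in
true positives than in putative negatives) wins, and a final model is
refitted on the SMOTE-balanced full training set. Resample summaries use
type-7 (linear interpolation) quantiles. The positive class is "annotated
PGx" throughout; AUC is computed by midranks, which equals exhaustive
pair counting with ties worth one half.

Three learners share one second-order, level-wise, histogram-based tree
grower written in C++ (features are quantile-binned into at most 64 bins,
the standard approximate-split device of modern boosting libraries):

* `gradient_boosted_trees` — logistic-loss Newton boosting with L2 leaf
  regularization (the analysis' chosen family);
* `random_forest` — bootstrap aggregation of Gini trees with per-node
  feature subsampling (`mtry`);
* `logit_boost` — classic additive logistic boosting with depth-1 stumps.

Hyperparameter grids default to small documented sets — boosting: trees
{100, 300} x depth {2, 4, 6} x learning rate {0.1, 0.3}; forest: `mtry`
{floor(sqrt(p)), floor(p/3)} at 300 trees; LogitBoost: {20, 50}
iterations — because the original analysis used framework defaults it
never lists. Boosted fits are sequential, so the grid's tree-count axis is
evaluated by staging one long fit; results are identical to separate fits.
Variable importance is total split gain per feature, rescaled so the top
variable is exactly 100. All randomness (partition, folds, SMOTE,
bootstrap) derives deterministically from one master seed; the C++ RNG is
self-contained so fits are bit-identical across platforms.

`predict_new()` defines a "newly predicted" pharmacovariant as an
unannotated variant whose predicted probability reaches the threshold
(0.5 everywhere by default — the analysis never states one; it is a
documented, overridable decision).

## The synthetic world

The generator states one fixed world, used by every test: 20,000 missense
variants in the pharmacogene subset of a 2000-gene universe (5%
pharmacogenes), split 3% annotated PGx / 7% "to-be-predicted" PGx
(functional but unlabeled) / 90% neutral. Functional classes draw MAF from
Beta(2, 5) and carry CAPs with probability 0.4; neutral variants draw MAF
from Beta(0.5, 20) with CAP probability 0.05. These magnitudes — and the
mildly class-informative evolutionary and feature-flag distributions — are
artifact choices: the source never quantifies class separation, only its
direction (functional variants are dramatically commoner, and MAF then CAP
dominate importance). They were chosen once to reproduce that qualitative
structure and are not tuned.

Population allele frequencies follow a Balding–Nichols model: panel
frequency ~ Beta(p(1−F)/F, (1−p)(1−F)/F) around global frequency `p`,
with one interpretable divergence parameter `F` (default FST = 0.08, a
typical human between-population value). `F = 0` degenerates to exact
equality; monomorphic sites stay fixed. The "to-be-predicted" class gets a
logit-scale frequency bump (+0.3) in the seven African panels, emulating
the reported modest African excess of newly predicted variants. The
generator produces feature tables only — no haplotypes, no linkage, no
coalescent — so a green test establishes that the pipeline recovers the
engineered signal structure, not that the learned model generalizes to
real genomes.

## Numerical and design notes

* Permutation tail: inclusive (`>=`), per the method's definition.
* Quantiles: type 7 everywhere (the default of the analysis environment).
* Histogram split finding caps at 64 bins; with 14 predictors of which 9
  are binary this loses essentially nothing and makes training ~30x
  faster than exact greedy scans.
* The degenerate normal empirical p-value (null sd = 0) is an error, not
  NA silently.
* Venn "presence" is AF > 0 (any observed copy) by default; an
  AF ≥ 1/(2N) rule is available via `presence_threshold`.
* Drug-count categories default to unit bins over observed counts; the
  original figure's bin boundaries are not recoverable from the text.
* LogitBoost abstentions: the in-package learner never abstains;
  `evaluate_test(count_abstentions =)` defines both readings for external
  score sets with missing predictions.
* Learner backends are implemented in-package (no tree-ensemble library is
  available in the supported environment); the learner *contracts* —
  probabilistic binary classifiers with gain importance — are what the
  pipeline depends on.

## Known limitations

The synthetic world has independent features given class (no linkage
between protein-feature flags), a single global divergence parameter, and
no sequence context, so it cannot exercise liftover, consequence calling,
or LD-driven confounding. Real-data reproduction of the published
headline numbers requires the external resources (reference panel
genotypes, curated annotations, feature tracks, comparator scores) and is
out of scope; the package ships the machinery, not the data.
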