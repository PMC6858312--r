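---
title: "Classifying cancer type from somatic alterations: models and methods"
author: "OncoVote"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying cancer type from somatic alterations: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(OncoVote)
```

## The problem

Somatic alterations are strongly tissue-specific: which genes are hit, how
many mutations a tumour accumulates, which trinucleotide contexts its
substitutions prefer, and which chromosomal regions are amplified or deleted
all vary systematically with the tumour's type of origin. OncoVote turns
this observation into a supervised classifier: given a cohort of tumours
with somatic variant calls (MAF), copy-number profiles (gene-level log2
ratios or SEG segments), and type labels, it builds a feature matrix,
reduces it by supervised selection, and predicts the cancer type with a
soft-voting ensemble of a multilayer perceptron (MLP) and a random forest,
evaluated by nested cross-validation.

## The feature model

Each sample becomes one row of a five-block vector, in fixed order:

1. **Gene-level mutation profile** (one column per gene): the number of
   protein-altering SNVs and indels in that gene. Which MAF
   `Variant_Classification` values count as protein-altering is a
   configurable set (`proteinAlteringClasses()`); the default covers
   missense, nonsense, nonstop, splice-site, frameshift and in-frame
   indels, and translation-start-site changes.
2. **Two mutation rates**: total SNV+indel count per megabase of sequenced
   territory, and the fraction of schema genes carrying at least one
   variant. The territory defaults to 38 Mb, a typical exome footprint;
   any per-Mb denominator can be supplied because the appropriate callable
   territory depends on the assay.
3. **Six mutation spectra**: the proportions of a sample's SNVs in the
   pyrimidine-referenced substitution classes C>A, C>G, C>T, T>A, T>C,
   T>G. A purine-referenced call (e.g. G>A) is mapped to its
   reverse-complement class (C>T); its flanks are swapped and complemented.
4. **96 mutation signatures**: proportions over trinucleotide contexts
   ({A,C,G,T} x 6 spectra x {A,C,G,T}), keys like `"CCT.C>T"`. Flanking
   bases come either from `context5`/`context3` columns on the variant
   records or from a reference FASTA via `fetchContext()`. An unknown ("N")
   flank removes the SNV from both numerator and denominator.
5. **Gene-level copy number** (one column per gene, prefixed `cnv:`): log2
   tumour/normal copy ratios, either passed through from a gene-level
   matrix or computed as the length-weighted mean of overlapping SEG
   segments. Missing genes or samples are zero-filled — log2 ratio 0 is
   copy-neutral — with a warning (a hard-error mode is available).

Spectra and signatures are per-sample proportions rather than counts, so
mutation burden is carried only by the rate block; a counts mode is not
needed for classification and deliberately not exposed. Two invariants pin
the encoding down: representing every SNV on the opposite strand leaves
blocks 3-4 unchanged, and summing the 16 signature proportions of one
spectrum class returns that spectrum's proportion exactly.

## Supervised feature selection

With tens of thousands of mostly-zero columns, selection both speeds up
training and removes noise features. Three supervised selectors share one
interface (`selectK()`):

* **Extra-trees importance**: an extremely randomized forest is fitted to
  the raw values (trees are scale-invariant, so no standardization) and the
  top-k features by mean impurity decrease are kept.
* **LASSO**: class labels become signed one-vs-rest indicator targets (+1 /
  -1) and one L1-penalized least-squares regression is fitted per class on
  standardized features; a feature is kept when any class gives it a
  nonzero coefficient. The signed encoding makes the univariate solution
  the classic soft-threshold of the feature-target covariance.
* **L1 squared-hinge linear classifier (LSVC)**: per-class linear decision
  functions $f_c(x) = w_c^\top x + b_c$ minimizing
  $$\frac{1}{n}\sum_i \sum_{c \ne y_i} \max(0,\, 1 + f_c(x_i) -
  f_{y_i}(x_i))^2 \;+\; \frac{1}{C}\sum_c \lVert w_c \rVert_1 .$$
  The budget form of the constraint ($\sum_c \lVert w_c\rVert_1 \le
  \varepsilon$) is implemented in this equivalent Lagrangian form; the
  `penalty` C is the inverse regularization strength, and the mapping is
  monotone, so any target support size reachable under a budget is
  reachable under a penalty. The smooth part is differentiable, so the
  solver is FISTA (accelerated proximal gradient) with soft-threshold
  proximal steps — which produce exact zeros — gradient-based adaptive
  restart, a Lipschitz step from a power-iteration bound on the design's
  largest singular value, unpenalized intercepts, and a windowed objective
  convergence check. `lsvcObjective()` exposes the objective as a pure
  function so tests can compare the solver against brute-force search.

L1 selection is scale-sensitive, so `makeSelectionProblem()` freezes
per-feature population (1/n) means and standard deviations from the
training rows; held-out rows are always transformed with those frozen
statistics. Constant features get scale 1 so the transform is total.

`selectK()` reaches a requested support size k for the L1 methods by
bisection on the log of the regularization strength, bracketed at
[1e-4, 1e4], stopping inside a ±5% window (configurable) or after 40
probes; a persistent overshoot is truncated to exactly k by coefficient
magnitude, ties broken toward the lower feature index (a rule used for
every tie in the package, for determinism). LSVC probes warm-start from the
nearest previously-probed regularization. The probe path is recorded so the
monotonicity of support size in regularization strength can be asserted.

## Classification and the ensemble

Four base classifiers sit behind one contract — `predictProba()` returns
non-negative per-class rows summing to one, in the class order fixed at fit
time:

* **MLP** (the reference architecture): ReLU hidden layers (default three
  of 2048 units), softmax output, multinomial cross-entropy, Adam (default
  learning rate 1e-5), 40% inverted dropout on hidden layers during
  training only, and early stopping on a stratified validation split
  (default 10%), restoring the best-validation weights. The implementation
  is plain dense linear algebra in R; training is exactly reproducible
  given the seed. A class with fewer than two training samples cannot
  donate a validation row and raises an error rather than silently
  degrading.
* **Random forest**: 500 Gini trees by default, probabilities as vote
  fractions.
* **OvR linear SVM**: one binary linear SVM per class; probabilities are
  the softmax of the per-class decision values (Platt scaling available by
  flag).
* **KNN**: k = 5 neighbour vote fractions.

The ensemble (`trainEnsemble()`, `ensemblePredict()`) averages the MLP's
and the forest's probability rows and takes the argmax, ties to the lowest
class index. Averaging two well-calibrated but differently-biased models
(a smooth linear-ish decision surface and an axis-aligned one) is the
classic variance-reduction argument for soft voting; the pairwise agreement
table (`pairwiseAgreement()`) quantifies how complementary two classifiers
are via inclusion-exclusion on their correctly-predicted sample sets.

## Nested cross-validation

`nestedCV()` estimates generalization with stratified outer folds (default
10) while an inner stratified 10-fold loop, run only on the outer-training
rows, picks the selector method and feature count from a grid (default 5,
10, 15, 20% of the dimension; ties prefer the smaller k, then LSVC before
LASSO before extra-trees). Standardization, selection and training are all
refitted on outer-training rows only; a leakage guard (`assertNoLeakage()`)
aborts if any held-out sample identifier ever reaches a fitting step. One
MLP/forest pair is trained per outer fold on the selected features. When
the grid holds a single (method, k) pair the inner loop is skipped — its
estimate could not change the choice — which keeps single-configuration
runs cheap without touching the contract.

Per-class metrics follow the usual definitions (precision, recall, F1 with
the 0/0 convention, macro F1 as the mean of per-class F1). Because
"per-class accuracy" is ambiguous in multi-class reports, the per-class
table exposes both candidates: pooled recall and the fold-averaged
within-fold recall; they coincide when folds are balanced.

`ablationStudy()` quantifies each feature block's contribution by plain
10-fold cross-validation of a random forest on cumulative block prefixes
(default order: profile, rates, spectra, copy number, signatures), and
`rankImportance()` reports the forest's impurity importances with schema
names attached.

## The synthetic cohort: what it emulates and what it does not

`simulateCohort()` generates a labeled multi-class cohort in which every
signal the pipeline is designed to exploit is planted explicitly and
recorded in a truth object:

* per-type **driver genes** absorbing a fixed share (default 0.5) of each
  SNV's gene assignment — deliberately the strongest planted signal, so the
  importance ranking has an unambiguous expected head;
* per-type **signature vectors** putting 60% of mass on 8 type-specific
  "hot" trinucleotide contexts (disjoint between types) over a shared
  Dirichlet background — so the planted signature features are a
  well-defined set; optionally the hot contexts are confined to a single
  substitution class, which makes the 6-class spectrum marginals
  uninformative and isolates the signal in the signature block (used by the
  ablation tests);
* per-type **copy-number shifts** (default N(0.4, 0.2) over N(0, 0.1)
  noise, a clearly detectable but not dominant focal-gain magnitude) on a
  per-type gene set;
* lognormal per-sample mutation burden (median 30 SNVs, log-sd 0.5), ~10%
  additional context-free indels, and emission of about half the SNVs in
  purine-strand representation so pyrimidine normalization is exercised end
  to end.

Two fully-specified scales are fixed as study conditions: `tiny` (3 types x
30 samples; 200 mutation and 100 copy-number genes; 404 features) for unit
tests, and `desk` (6 types x 200 samples; 2,000 + 1,000 genes; 3,104
features) for end-to-end evaluation. Desk-scale runs in the test-suite and
the acceptance script use a reduced MLP (two hidden layers of 64 units,
learning rate 1e-3, at most 60 epochs) and a capped LSVC budget (80
iterations per probe at tolerance 1e-5); these sizes were chosen so a full
desk evaluation completes on a single CPU in minutes while leaving the
planted signal comfortably recoverable.

The generator reproduces the *structure* of real cohorts, not their
difficulty: planted effects are strong and independent, burdens are
type-homogeneous, there is no subclonality, no germline contamination, no
platform batch effects, and no correlation between driver status and
copy-number state. Passing the desk-scale checks therefore demonstrates
that the machinery is correct — features encode what they should, selectors
find what is there, the ensemble does not lose accuracy, leakage is
impossible — and deliberately does not forecast accuracy on real tumour
cohorts, whose class overlap is far larger.

## Numerical and design choices

* "2048 parameters per hidden layer" is read as 2048 units; a literal
  parameter count would be inconsistent with a 35,565-input first layer.
* Eq-style LASSO weights follow the 1/(2n) sum-of-squares convention; a
  weight stated for the 1/n convention is twice ours.
* Spectrum/signature rows of a sample with no eligible SNVs are all-zero
  rather than NA, keeping the matrix dense and models unconditional.
* Chromosome names are matched verbatim; no "chr" normalization is
  attempted.
* BED input (0-based half-open) is converted on read to the 1-based
  inclusive coordinates used everywhere internally (MAF convention).
* All displayed percentages are rounded to two decimals for printing only;
  every comparison and stored value is full precision.
* Fold assignment deals each class's shuffled samples through one global
  rotating pointer, guaranteeing fold sizes within one sample overall and
  per class.

## Known limitations

The MLP is a plain dense implementation: adequate for post-selection
dimensions (thousands of inputs), but it will not exploit a GPU and at the
full 35,565-feature scale with 2048-unit layers, training time is
substantial. The OvR-SVM probability construction (softmax over decision
values) is a ranking-preserving convenience, not a calibrated probability;
it is a baseline, not an ensemble member. glmnet's coordinate descent and
the FISTA solver identify supports, not exact coefficient paths, so
support sizes at very weak regularization can jitter by a few features on
separable data; the select-to-k controller's truncation step absorbs this.
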