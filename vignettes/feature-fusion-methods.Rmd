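---
title: "Detecting suicidal ideation by feature fusion: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting suicidal ideation by feature fusion: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sidefuse)
```

## The problem

Short social-media posts occasionally contain explicit expressions of
suicidal ideation — a stated plan, a named method. Screening such posts
automatically is a severely imbalanced binary classification problem: in the
kind of microblog corpus this package targets, roughly 1 post in 18 is
positive (the default generator emulates 2,272 positive against 37,950
negative posts). `sidefuse` implements a feature-fusion stacked ensemble for
this task, together with everything needed to exercise it end to end:
corpus and lexicon I/O, three feature families, feature selection and
combination, a cross-validated model zoo, a stacking meta-classifier, a
baseline comparison harness, and a synthetic corpus generator.

## The three feature families

**BSC — basic statistical characteristics.** Per post: the share of tokens
falling in each category of a LIWC-style category lexicon; positive and
negative sentiment-word rates from a merged polarity lexicon (sources are
merged by majority vote, with tied words dropped — sentiment dictionaries
disagree, and a tie carries no usable signal); the rates of degree adverbs
at four intensity levels (emotional-intensity proxies); per-risk-emoji
counts plus a total emoji count; and a one-hot encoding of the posting time
over eight 3-hour bins. Word-category features are length-normalized rates
because raw counts confound post length; emoji occurrences are kept as raw
counts because they are rare events whose absolute number is the signal.
Bin 0 is anchored at midnight with half-open intervals `[3i, 3i+3)` — the
anchor is a convention, and midnight is the natural one for circadian
structure such as late-night posting.

**RFS — risk factors for suicide.** A 13-category risk dictionary (the
structure of published Chinese suicide dictionaries: self-harm methods,
trauma, relations, psychiatric and somatic symptoms, anger/hopelessness,
and so on) yields one rate column per category plus one overall risk-word
rate, 14 columns total. Emitting both the per-category rates and the total
is a superset of either reading of "frequency of suicide words" and loses
no information.

**WEC — word-embedding clustering.** Skip-gram embeddings (negative
sampling, d = 100, window 5, 5 epochs, `min_count` 2, single worker so the
result is a pure function of the seed) are trained on the input corpus
itself. Candidate keywords are the unique content-POS tokens present in the
embedding vocabulary. They are clustered by plain Lloyd K-means — random
initial centers drawn among the candidate vectors, Euclidean
nearest-centroid assignment with ties to the lowest cluster id, mean
updates, stop on stable assignments; an emptied cluster is re-seeded with
the point farthest from its center. Within each cluster, candidates are
ranked by distance to the centroid and the nearest `m` are selected.
Per-post WEC features are each selected keyword's rate plus one aggregate
rate per cluster. The K-means loop is deliberately hand-written at this
level of explicitness: the clustering procedure is part of the method, and
its tie-breaks, stopping rule and empty-cluster handling are pinned by
tests against a brute-force oracle. A mean-embedding representation of the
selected keywords is available behind `representation = "mean-embedding"`
but is not the default — keyword rates keep the block sparse,
interpretable, and structurally parallel to the other two families.

Defaults that the source method leaves open, fixed here once: k = 10
clusters (with `silhouette_sweep()` available to choose differently),
m = 20 keywords per cluster, Euclidean distance throughout, and top-m
rather than a distance threshold for "determine keywords according to
distance size".

## Feature selection and the three combination regimes

High-dimensional sparse text features invite overfitting; the pipeline uses
extremely-randomized-trees importance selection (`n_trees = 500` by
default, gini or entropy impurity) to reduce each matrix. The keep rule is
a cumulative-importance fraction (default 0.95) or a top-k count. Three
combination regimes are supported and named in the field's notation:
`A + B` (direct concatenation), `(A-fs) + (B-fs)` (select within each
family, then concatenate), and `(A + B)-fs` (concatenate, then select
jointly). The regimes are genuinely different: only joint selection can
retain a pair of columns that are informative together but useless alone,
and the test suite pins this with an XOR construction split across two
blocks.

Because selection looks at labels, fitting it on the full dataset before
cross-validation leaks information. The default here refits the selector
inside every training fold; `in_fold_selection = FALSE` reproduces the
traditional whole-data variant for fidelity comparisons. This is the one
deliberate deviation from common practice in this literature, chosen as
correctness-by-default.

## Model zoo, cross-validation, and the stacked ensemble

Twelve classifiers are evaluated per feature set, all at default
parameters: SVMs with linear, RBF, polynomial and sigmoid kernels
(libsvm via e1071), Gaussian naive Bayes, 5-nearest-neighbors, logistic
regression with L1 and L2 penalties at a unit-strength penalty
(glmnet at lambda = 1/n), decision trees under gini and entropy
(rpart, grown full depth), and extremely randomized trees under gini and
entropy (100 trees). Evaluation is stratified 5-fold cross-validation —
stratified because at a 5.6% positive rate plain folds can lose the
minority class — with accuracy, F1, precision and recall computed on the
pooled out-of-fold predictions, the positive (suicidal) class being the
target. The fold assignment is a function of (labels, k, seed) only, so
every model sees identical folds and leaderboards are paired. The best
model per feature set is the pooled-accuracy winner, ties broken by F1 and
then zoo order.

The fusion ensemble takes a list of feature-set recipes that jointly cover
all three families (at least two sets). Each set's chosen base classifier
produces out-of-fold positive-class probabilities; these form the
meta-feature matrix for a logistic meta-classifier (L2 penalty, intercept
included). Probabilities rather than hard labels are used as meta-features
— they dominate in standard stacking and keep the meta-model non-trivial.
After meta-training, base models are refit on all training data for
deployment. Reported fusion metrics come from an outer stratified 5-fold
loop wrapped around the entire fit (nested CV), so no reported number is
computed on posts the fitted ensemble saw; whether the original
experimental design did this is unclear, and nesting is the conservative
choice. `enumerate_paper_feature_sets()` lists the eleven reference
configurations, including the headline pairing of a jointly selected
BSC+RFS set with a selected WEC set.

The baseline harness runs, under the same folds: random forests with gini
and entropy impurity, tree- and linear-boosted gradient boosting (xgboost;
the generic gradient-boosting row uses the classic depth-3/0.1-rate
settings), AdaBoost over depth-1 trees, bagging over full trees, classic
stacking whose bases all see the same joint feature matrix, and a
majority-class dummy that anchors the accuracy floor. The forest learner
behind random forests, bagging, and the ET zoo members is the package's own
compiled implementation, because the contrast between gini and entropy
impurity — present throughout the comparison tables — must be expressible
for both split-search styles.

## The synthetic corpus generator

The generator is a first-class module, not a test hack: it defines the
study conditions under which everything else is validated. Each post draws
a length from a rounded log-normal (mean about 25 tokens), then emits
tokens from a mixture of one latent topic (8 topics by default, giving
skip-gram something to cluster), a common function-word pool, and the
fixture lexicons at class-conditional rates. The positive class multiplies
selected category rates by enrichment factors — defaults: risk-dictionary
words x6, negative sentiment x3, positive sentiment x0.6 — so risk and
negative-emotion vocabulary are over-expressed exactly where the real
phenomenon over-expresses them. Posting times are drawn from per-class
distributions over the eight 3-hour bins, with the positive class shifted
toward late night (the literature ties sleep disruption to risk, but
reports no distribution; the skew here is a chosen free parameter, not an
empirical value). Emoji counts are Poisson with a higher risk-emoji share
in the positive class. All randomness flows from the single seed in the
config, and the same seed reproduces the corpus byte for byte.

What the generator does *not* emulate: real lexical semantics, grammar,
topic drift, duplicate/repost structure, or the annotation noise of human
labeling. Passing tests on this corpus therefore demonstrate that the
pipeline recovers planted class-conditional structure of the kind the
method assumes — not that it would achieve any particular accuracy on real
microblog text.

## Numerical choices and degenerate inputs

* K-means ties go to the lowest cluster id; keyword-distance ties break
  lexicographically; selector importance ties break by column name — every
  ordering in the pipeline is total, which is what makes byte-identical
  reruns possible.
* kNN on sparse rate features meets thousands of exactly tied distances; a
  deterministic tie-break column at the 1e-6 scale (far below any real
  distance contrast) resolves them.
* glmnet is fit along a decreasing lambda path down to the 1/n target
  (warm starts); a cold single small lambda does not converge reliably.
* Posts with no lexicon hits produce all-zero feature rows by definition;
  empty corpora, single-class labels, selection fractions outside (0, 1],
  k exceeding the candidate count, and coverage-violating ensembles are
  rejected with errors.
* Skip-gram and forest code are single-threaded with own RNGs seeded from
  the user seed, so results do not depend on thread scheduling or R's
  global RNG state.

## Problem sizes used by the shipped checks

The test suite and the acceptance script exercise the pipeline at desk
scale: corpora of 300-4,000 posts at a 10% positive rate (5 seeds for the
signal-recovery properties), a 2,000-post corpus and 10-20 permutations for
the leakage null, 60 random instances of at most 8 points for the K-means
oracle, and a 500-post corpus for the byte-identity rerun. The structural
checks (class counts 2,272/37,950, 8 time bins, 13 risk categories, 11
reference configurations) run at the full default corpus size. These sizes
were chosen so the whole validation runs comfortably on one core while
leaving every distributional property testable; the package itself has no
such limits.

## Known limitations

* Synthetic vocabulary only; no tokenizer or POS tagger is bundled — input
  is expected pre-segmented (the tokenization interface is pluggable by
  design, and an identity tokenizer is the default).
* The per-post WEC featurization is one reasonable reading of an
  under-specified step; the mean-embedding alternative ships behind a flag.
* Single-level stacking only; no probability calibration analysis.
* The paper-style whole-data selection mode exists for comparison but is
  knowingly leaky; it is not the default and should not be used for
  reported metrics.
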