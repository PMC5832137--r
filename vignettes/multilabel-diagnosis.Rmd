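---
title: "Multilabel diagnosis classification for sectioned clinical records"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multilabel diagnosis classification for sectioned clinical records}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

An admitting diagnosis in a first-course clinical record is rarely a single
item: an obstetric admission typically carries two or three diagnoses drawn
from a large, heavily skewed label inventory, and the evidence for them is
spread over free-text sections — chief complaints, physical examinations,
obstetric examinations, auxiliary examinations. Predicting the diagnosis
set from the section text is therefore a *multilabel* classification
problem: each record is one instance, each standardized diagnosis one
label, and a classifier must both rank all labels for the record and commit
to a bipartition (predicted set).

`mldx` implements that pipeline end to end: a synthetic corpus generator
with planted, recoverable structure; label-space standardization and
reduction; two text-feature extractors (topic proportions and word-vector
averages); four multilabel classifiers; the five ranking-based evaluation
measures; and cross-validated experiment drivers (the numbered scripts
under `analysis/`).

Real first-course corpora are private. The package is therefore built to be
*testable without any external data*: every experiment runs on corpora from
its own generator, whose ground truth is known.

## Synthetic corpus model

`generate_corpus()` draws, per corpus:

* **Label frequencies.** Labels are ranked and weighted by a power law
  `rank^-s` (`label_skew`, default `s = 1.5`), giving the strong
  head/tail imbalance characteristic of diagnosis inventories.
* **Per-record label sets.** The number of labels per record (cardinality)
  follows a truncated-geometric distribution on 1..8 calibrated so its mean
  is 2.67 (`cardinality_from_mean()`); labels are drawn without replacement
  proportionally to their frequency weights. Support 1..8 and mean 2.67
  mirror the reported shape of real obstetric admitting diagnoses.
* **Text.** Each label has one dominant topic in a planted topic-word
  matrix (rows drawn from a symmetric Dirichlet, `dirichlet_beta = 0.1`;
  smaller values give sparser, better-separated topics). A label's
  topic-affinity row puts mass `1 - noise_floor` (default 0.95) on its
  dominant topic and spreads `noise_floor = 0.05` uniformly. A record's
  topic mixture is the normalized sum of its labels' affinity rows plus a
  small pseudo-count (`dirichlet_alpha = 0.005`, about 0.3 total pseudo-mass
  against a mean signal mass of 2.67 — enough to avoid zero probabilities
  without drowning the signal). Section token counts are Poisson with means
  15/25/20/15, and each token is emitted by drawing a topic from the
  mixture, then a word from that topic — the standard latent Dirichlet
  allocation generative process.

This makes diagnoses statistically recoverable from text by construction
("strong signal"), with `noise_floor` as the difficulty knob. What the
generator deliberately does **not** emulate: clinical language (tokens are
synthetic strings such as `w0017`), label co-occurrence structure beyond
what shared sampling induces (the real-world statistics report only
marginal frequencies, so any co-occurrence model would be invented),
temporal record sequences, and privacy artifacts. Passing tests on this
corpus demonstrate that the algorithms are implemented correctly and can
recover planted structure — not that they reach any particular performance
on real clinical text.

## Preprocessing and the label space

Cleaning follows the usual record-hygiene steps: exact-duplicate removal;
among same-id records the most complete (then latest) wins;
records with no section content, or with a record time before their
reference (admission) time, are dropped. `split_sections()` structures raw
text by heading patterns in *text* order, and `tokenize()` is a greedy
longest-match dictionary tokenizer with a whitespace/punctuation fallback —
a deterministic, language-agnostic stand-in for a full segmenter.

Diagnoses that are *results of calculation* (gestational age "pregnancy
28+2 weeks", gravida/para counts) are excluded from the label candidates.
The remaining raw labels are standardized by `merge_labels()`:
pairwise cosine similarity of term-frequency vectors over the tokenized
label strings, single-linkage clustering at a threshold (default 0.8), and
the most frequent member as each cluster's canonical form. A manual expert
review obviously cannot be part of an automated package; the threshold is
the automated surrogate, and all merges are recorded in the `merge_map` for
audit. The threshold is a free parameter — no reference value exists for
it — so it is exposed rather than hidden.

`filter_labels_by_frequency()` builds the nested label sets used by the
experiments: floor 1 keeps everything, floor 2 drops singletons, floor 11
keeps labels seen at least 11 times. The floor-11 reading resolves an
internal inconsistency in the source material (the prose says "less than
10" but the reported set sizes only add up when frequency ≤ 10 is
removed); the implementation keeps frequency ≥ 11.

## Features

**Topic proportions.** `fit_lda()` is collapsed Gibbs sampling with the
textbook conditional; `doc_topic_features()` returns the smoothed
document-topic estimator. Two numerical choices matter:

* *Sweep averaging.* A single final Gibbs state is a high-variance draw
  from the posterior; averaging the estimator over the last half of the
  sweeps (`avg_sweeps`, on by default) gives a much lower-variance estimate
  of the same posterior mean and markedly better downstream features. The
  final-state estimator remains available (`use_mean = FALSE`).
* *Hyperparameters.* Defaults `alpha = 50/K`, `beta = 0.01` are common
  collapsed-Gibbs practice. For feature extraction on short
  (~75-token) records the experiments use `alpha = 0.1`: with sharp
  record-level mixtures a large `alpha` forces topic mixing and blurs the
  features. Both are configurable everywhere.

Held-out records get features by *fold-in*: their assignments are sampled
with the fitted word-topic counts frozen, so no test token influences any
fitted parameter.

A single Gibbs chain can mis-resolve rare topics (a label seen a handful
of times may not earn a clean topic in one run). The pipelines therefore
support concatenating the feature blocks of several independently seeded
chains (`lda_chains`); blocks are joined, never averaged, because topics
are not aligned across chains. Two chains measurably sharpen
nearest-neighbor classification on the default corpus; a third adds
nothing, so 2 is the value the end-to-end checks use.

**Word-vector averages.** `fit_skipgram()` trains skip-gram embeddings by
maximizing the average log probability of context words within a window
(default 5). With `n_negative = 0` the exact softmax is used — feasible at
synthetic vocabulary sizes and exactly differentiable, which is what the
gradient finite-difference tests check — while `n_negative = 5` (default
for runs) uses negative sampling with the customary unigram^0.75 noise
distribution and linearly decaying learning rate. The classic initial
rate 0.025 assumes many passes over a large corpus; on desk-scale corpora
trained for a few epochs the pipelines default to 0.05, without which
high-dimensional embeddings stay undertrained relative to low-dimensional
ones. `doc_vector()` averages
the input vectors of in-vocabulary tokens; out-of-vocabulary tokens are
skipped and an all-out-of-vocabulary document yields a zero vector with a
warning.

**Hellinger map.** For distance-based classification on probability
features the pipelines can apply the element-wise square root
(`feature_map = "sqrt"`), under which Euclidean distance approximates
Hellinger distance between topic distributions. It is a monotone
re-embedding of the simplex, not a new feature type.

## Classifiers

All four expose `fit`, scores (a ranking function over labels), and a
bipartition consistent with a stated threshold rule; all are deterministic
given a seed.

**Pairwise-ranking network (BP-MLL-style).** A single-hidden-layer tanh
network trained on the pairwise exponential ranking loss
`mean over (k in Y, l not in Y) of exp(-(c_k - c_l))`, which pushes every
relevant label's output above every irrelevant one's. Implementation
choices: inputs are standardized inside the fit (probability features are
O(1/K) in magnitude, and unscaled inputs stall the input-weight gradients);
training is seeded minibatch stochastic gradient descent (default batch 20,
`Inf` gives full-batch descent with a provably monotone loss at small
steps); instances whose label set is empty or complete have no ranking
pairs and are skipped with a warning. Because the loss only constrains the
*order* of outputs, the bipartition threshold `t(x)` is fitted afterwards by
linear least squares from score rows to each training row's
error-minimizing threshold — the standard completion for this family of
models. The legacy sum-of-squares objective with bipolar targets is kept
(`legacy_squared_loss()`) as the reference this loss was designed to
replace.

**Multilabel k-nearest neighbors.** Per-label MAP estimation from the
count of positive neighbors among the k nearest training points (Euclidean
distance, self excluded, index-ordered ties), with Laplace-smoothed priors
`(s + n_j)/(2s + p)` and neighbor-count conditionals. Defaults `k = 10`,
`s = 1`. The entire construction is checked against an independent
brute-force Bayesian computation in the tests.

**Random k-labelsets.** `m` distinct random labelsets of size `k_r`
(defaults 3 and `2Q` — the method's customary choices), one label-powerset
multiclass base classifier per set, vote-fraction scores, bipartition at
1/2. Labels no set covers score 0 with a warning.

**Classifier chain.** One binary classifier per label along a chain
(label-space order by default, seeded random order available), each
consuming the true earlier labels at training time and hard 0/1
predictions at test time.

The base learner for the last two is pluggable; the default
(`make_logistic_learner()`) uses ridge logistic regression for binary
problems and weight-decayed multinomial regression for the powerset
problems, which tolerates the singleton classes rare label combinations
produce. Degenerate single-class responses become constant predictors with
a warning rather than errors, so filtered label sets evaluate robustly.

## Evaluation

The five standard ranking-based measures: Hamming loss (symmetric
difference rate of the bipartition), one-error (top-ranked label not
relevant), coverage (depth to cover all relevant labels, minus one),
ranking loss (mis-ordered (relevant, irrelevant) pairs, ties counted as
violations), and average precision. Ranks are deterministic: ties break by
ascending label index, since the measures are otherwise undefined under
ties. Degenerate rows (no relevant label; for ranking loss also no
irrelevant label) are excluded per measure with a warning instead of
failing the evaluation. All five are verified against an independent
enumeration oracle on hundreds of random small instances, exactly.

`cross_validate()` partitions instances at random (seeded), refits the
feature extractor and the classifier on each training fold only, and
reports per-fold values with mean ± sample standard deviation — the
protocol behind every experiment table. Several classifiers sharing
identical feature settings can be passed together so the feature extractor
is fitted once per fold. How the original study produced its ± figures is
not stated; seeded k-fold cross-validation (default 10-fold; the
classifier-comparison and sweep experiments use 3 folds, the trend checks
2) is this package's protocol, and every report records its seed and fold
count.

## Problem sizes and determinism

The default synthetic scale — 2,000 records, 60 labels, 2,000 token types,
~75 tokens per record — was chosen so that the full pipeline, the sweeps,
and the test suite all run on a single desk CPU; a realistic corpus scale
(tens of thousands of records, hundreds of labels) is a configuration
away, not a code change. The end-to-end
checks use 10-fold cross-validation on two-chain topic features (600
Gibbs sweeps each, averaged over the last 300); topic-recovery checks use
1,000 single-label documents over a 300-word vocabulary; sweep
comparisons use 2 or 3 folds. Every stochastic step — corpus generation, Gibbs
initialization and sweeps, embedding initialization and negative sampling,
weight initialization, minibatch shuffling, fold splits, labelset draws —
runs under an explicit seed through R's RNG, and reruns with the same seed
are byte-identical, including the report files (which deliberately contain
no timestamps).

## Known limitations

* Synthetic text has no syntax, no discourse, and no annotation noise;
  absolute performance numbers on it say nothing about real corpora.
* Label co-occurrence in the generator is an artifact of frequency-weighted
  sampling, so methods that model label dependence (the chain; the
  labelset ensemble) are exercised but not stress-tested.
* The tokenizer is not a morphological segmenter; with an empty dictionary
  it is plain whitespace/punctuation splitting.
* The temporal-consistency check is a generic record-time-versus-reference
  comparison, not an encoding of domain-specific treatment logic.
* Exact-softmax skip-gram training is quadratic in vocabulary size and is
  intended for verification-scale corpora; negative sampling is the
  practical path.
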