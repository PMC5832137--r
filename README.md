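# mldx — multilabel diagnosis classification for sectioned clinical records

Admitting diagnoses in first-course clinical records are sets, not single
codes: a typical obstetric admission carries two to three diagnoses from a
large, heavily skewed label inventory, and the supporting evidence is
spread over four free-text sections (chief complaints, physical
examinations, obstetric examinations, auxiliary examinations). `mldx`
treats diagnosis assistance as a multilabel classification problem over
such records and provides the full pipeline:

* **Synthetic corpus generator** — seeded corpora with planted topic–label
  structure (power-law label frequencies, 1–8 labels per record with mean
  2.67, four token sections per record), so every downstream stage is
  testable without any private clinical data.
* **Preprocessing** — record deduplication and temporal-consistency
  filtering, heading-based sectioning, greedy longest-match dictionary
  tokenization, exclusion of calculated diagnoses (gestational age,
  gravida/para), label standardization by cosine similarity of semantic
  vectors with single-linkage merging, and frequency-floor reduction of
  the label set.
* **Features** — document-topic proportions from collapsed-Gibbs latent
  Dirichlet allocation (with sweep-averaged estimators and fold-in for
  held-out records), and mean-pooled skip-gram document vectors (exact
  softmax for verification, negative sampling for scale).
* **Classifiers** — a pairwise-ranking neural network trained on the
  exponential ranking loss over (relevant, irrelevant) label pairs with a
  learned bipartition threshold (BP-MLL style); multilabel k-nearest
  neighbors (Bayesian posterior from neighbor counts); random k-labelsets
  (label-powerset ensemble with vote-fraction scores); and classifier
  chains. Each exposes fit, ranking scores f(x, y), and a bipartition
  h(x).
* **Evaluation** — Hamming loss, one-error, coverage, ranking loss, and
  average precision, with deterministic tie handling, plus seeded k-fold
  cross-validation reporting mean ± standard deviation.

For instance, average precision rewards placing every relevant label near
the top of the ranking:

    AP(f) = (1/p) Σ_i (1/|Y_i|) Σ_{y ∈ Y_i}
            |{y' ∈ Y_i : rank_f(x_i, y') ≤ rank_f(x_i, y)}| / rank_f(x_i, y)

and the ranking network minimizes

    E_i = (1/(|Y_i||Ȳ_i|)) Σ_{(k,l) ∈ Y_i × Ȳ_i} exp(−(c_k − c_l)).

## Worked example

```r
library(mldx)

# a seeded corpus: 300 records, 20 diagnosis labels, strong planted signal
gen <- generate_corpus(synthetic_config(n_records = 300, n_labels = 20,
                                        vocab_size = 500, seed = 7))
raw   <- unlist(lapply(gen$corpus, `[[`, "diagnoses"))
space <- merge_labels(raw)
Y     <- build_label_matrix(gen$corpus, space)

# topic features + multilabel kNN, 3-fold cross-validation
cfg <- pipeline_config(feature = "lda", classifier = "mlknn",
                       K = 20, lda_alpha = 0.1, lda_iter = 200,
                       feature_map = "sqrt",
                       classifier_params = list(k = 5))
cross_validate(gen$corpus, Y, cfg, n_folds = 3, seed = 1)
```

```
mlknn on lda features, 3-fold cross-validation (seed 1)
  hamming_loss       0.0398 ± 0.0150
  one_error          0.0433 ± 0.0252
  coverage           3.7333 ± 0.7868
  ranking_loss       0.0510 ± 0.0199
  average_precision  0.9127 ± 0.0352
```

Read: on held-out records the top-ranked diagnosis is wrong about 4% of
the time, about 4% of label decisions are wrong (Hamming), and relevant
diagnoses sit near the top of the ranking (AP 0.91) — the planted
topic–label signal is recovered from text alone. The `analysis/` scripts
run the same machinery at the full default scale (2,000 records, 60
labels): corpus generation, label standardization, feature export, the
classifier × label-set-size comparison, and the topic-count and
vector-dimension sweeps, writing tables under `results/`.

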