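#!/usr/bin/env Rscript
# Standardize the diagnosis label space of the generated corpus: exclude
# calculated diagnoses, merge alternative written forms by semantic cosine
# similarity, and report the frequency-floor reductions (all labels; drop
# singletons; keep frequency >= 11) that define the nested label sets used
# by the experiments.

library(mldx)

corpus <- read_corpus("results/corpus.jsonl")

raw <- unlist(lapply(corpus, function(r) exclude_calculated_labels(r$diagnoses)))
space <- merge_labels(raw, threshold = 0.8)
cat(sprintf("standardized label space: %d labels (from %d raw occurrences)\n",
            length(space$labels), length(raw)))

Y <- build_label_matrix(corpus, space)
for (floor in c(1, 2, 11)) {
  red <- filter_labels_by_frequency(Y, space, floor)
  cat(sprintf("frequency floor %2d: %3d labels, %d records kept\n",
              floor, length(red$space$labels), nrow(red$matrix)))
}

write_label_space(space, "results/label_space")
cat("label space -> results/label_space.labels.tsv / .merges.tsv\n")
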