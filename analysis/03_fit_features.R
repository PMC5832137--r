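#!/usr/bin/env Rscript
# Fit the two feature extractors on the full corpus and export the feature
# matrices: document-topic proportions from collapsed-Gibbs LDA (K = 60)
# and mean-pooled skip-gram document vectors (T = 100). These are the
# representations the classifiers consume; the cross-validated experiments
# in 04/05 refit them inside each training fold.

library(mldx)

corpus <- read_corpus("results/corpus.jsonl")
dd <- corpus_documents(corpus)

cat("fitting topic model (K = 60, 800 sweeps)...\n")
tm <- fit_lda(dd$docs, K = 60, vocab = dd$vocab, alpha = 0.1,
              n_iter = 800, seed = 101)
theta <- doc_topic_features(tm)
write_features(theta, "results/features_topics.tsv")
cat(sprintf("topic features: %d x %d -> results/features_topics.tsv\n",
            nrow(theta), ncol(theta)))

cat("training skip-gram embeddings (T = 100, 3 epochs)...\n")
em <- fit_skipgram(dd$docs, dd$vocab, dim = 100, window = 5, epochs = 3,
                   n_negative = 5, seed = 102)
write_embeddings(em, "results/embeddings.vec")
docvecs <- doc_vector_features(em, corpus)
write_features(docvecs, "results/features_docvecs.tsv")
cat(sprintf("document vectors: %d x %d -> results/features_docvecs.tsv\n",
            nrow(docvecs), ncol(docvecs)))
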