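#!/usr/bin/env Rscript
# Generate the default synthetic corpus of sectioned first-course records
# (2,000 records, 60 diagnosis labels, 2,000 token types) and write it as
# JSON-lines together with its planted truth summary.
#
# The corpus emulates the statistical shape of an obstetric EMR dataset:
# four text sections per record, 1-8 diagnoses per record with mean 2.67,
# and a heavily skewed label frequency distribution. Labels carry signal
# through planted topics, so the diagnoses are predictable from the text.

library(mldx)

dir.create("results", showWarnings = FALSE)
cfg <- synthetic_config(seed = 20260929L)
gen <- generate_corpus(cfg)

write_corpus(gen$corpus, "results/corpus.jsonl")

card <- lengths(gen$truth$per_record_labels)
cat(sprintf("generated %d records; label cardinality min %d / mean %.2f / max %d\n",
            length(gen$corpus), min(card), mean(card), max(card)))

freq <- table(unlist(lapply(gen$corpus, `[[`, "diagnoses")))
cat(sprintf("%d distinct labels; %d singletons; %d with frequency 2-10\n",
            length(freq), sum(freq == 1), sum(freq >= 2 & freq <= 10)))
saveRDS(gen$truth, "results/truth.rds")
cat("corpus -> results/corpus.jsonl; planted truth -> results/truth.rds\n")
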