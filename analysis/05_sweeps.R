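#!/usr/bin/env Rscript
# Second and third experiment axes, on the smallest (frequency >= 11)
# label set: sweep the topic count K of the LDA feature and the dimension
# T of the skip-gram document vectors, cross-validating every classifier
# at each point. The emitted series (one row per classifier x K, resp. T)
# are ready for plotting AP against the swept axis.

library(mldx)

cfg <- experiment_config(
  synthetic = synthetic_config(seed = 20260929L),
  min_keep_freq = 11L,
  classifiers = c("mlknn", "bpmll", "rakel", "cc"),
  K_list = c(40L, 60L, 80L),
  T_list = c(10L, 50L, 100L),
  n_folds = 3L,
  seed = 72L,
  output_dir = "results",
  pipeline_defaults = list(
    lda_alpha = 0.1, lda_iter = 600, foldin_iter = 150,
    sg_epochs = 3,
    classifier_params = list(
      mlknn = list(k = 10),
      bpmll = list(hidden_frac = 1, epochs = 200, batch_size = 20))))

topics <- run_topic_sweep(cfg)
cat("topic sweep ->", topics$path, "\n")

dims <- run_dim_sweep(cfg)
cat("dimension sweep ->", dims$path, "\n")

best <- dims$table[which.max(dims$table$average_precision), ]
cat(sprintf("best sweep point: %s at T = %d (AP %.4f)\n",
            best$classifier, best$T, best$average_precision))
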