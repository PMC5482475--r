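#!/usr/bin/env Rscript
# Study 2: the true network is sparse (20% of pairs at weight 0.2). Here
# the sparsity assumption is correct: eLasso keeps false positives out,
# while the dense estimators (unregularized, rank-2) cannot produce zeros.

library(isingbet)
dir.create("results", showWarnings = FALSE)

cfg <- study_config("sparse_truth", node_count = 10L,
                    n_grid = c(100L, 250L, 500L, 1000L), reps = 20L,
                    methods = c("nodewise", "elasso", "rank_k"), seed = 1L)
res <- run_study(cfg, keep_fits = FALSE)
write_metrics_table(res, "results/study2_sparse_truth_metrics.csv")
write_edge_list(res$truth, "results/study2_true_network.tsv")

agg <- aggregate(cbind(sensitivity, specificity, estimated_density)
                 ~ method + n, data = res$records, FUN = mean)
print(agg, digits = 3)
cat("\neLasso keeps specificity near 1 at every n; the unregularized and\n",
    "rank-2 fits are dense, so their specificity is ~0 (all pairs 'edges').\n")
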