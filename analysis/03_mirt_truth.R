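#!/usr/bin/env Rscript
# Study 3: data are generated by the two-disorder comorbidity MIRT model
# (19 symptoms, trait correlation 0.55, two mutually exclusive symptom
# pairs, four bridge pairs). The induced Ising network is dense and
# neither sparse nor exactly low rank. A large-sample unregularized fit
# serves as the proxy truth; estimators are then scored against it at
# realistic sample sizes.

library(isingbet)
dir.create("results", showWarnings = FALSE)

cfg <- study_config("mirt_truth", n_grid = c(250L, 1000L), reps = 10L,
                    methods = c("nodewise", "elasso", "rank_k"),
                    proxy_n = 200000L, seed = 1L)
res <- run_study(cfg, keep_fits = FALSE)
write_metrics_table(res, "results/study3_mirt_truth_metrics.csv")
write_edge_list(res$truth, "results/study3_proxy_truth_network.tsv")

W <- res$truth$weights
bridges <- rbind(c(7, 16), c(8, 17), c(9, 18), c(10, 19))
cat("Proxy truth (nodewise fit on", cfg$proxy_n, "draws):\n")
cat("  exclusivity edges D2-D3, G6-G7:", W[2, 3], W[16, 17], "\n")
cat("  bridge edges:", W[bridges], "\n")
cat("  clustering contrast (bridges excluded):",
    clustering_contrast(ising_model(rep(0, 19), W),
                        rep(c("dysthymia", "gad"), c(10, 9)), bridges), "\n\n")
agg <- aggregate(cbind(sensitivity, estimated_density, weight_correlation)
                 ~ method + n, data = res$records, FUN = mean)
print(agg, digits = 3)
cat("\nAt n = 1000 eLasso returns a much sparser network than the dense\n",
    "proxy truth; the rank-2 fit recovers the clustering but misses the\n",
    "negative exclusivity and positive bridge deviations.\n")
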