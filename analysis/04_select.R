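#!/usr/bin/env Rscript
# Stage 4: sequence-specific signature derivation.
#
# On the reference (nn) feature table per sequence: Spearman redundancy
# filtering (|rs| <= 0.80), then stability selection over 50 subsamples
# (90% each; a feature counts a hit when univariate Cox p<0.05, survival
# random forest permutation importance > 0, and lasso Cox all select it)
# with a 95% hit threshold. Per-method marginal counts are exported so the
# joint rule can be audited against the union alternative.
#
# Reads:  results/cohort.rds, results/features.rds
# Writes: results/signature_<seq>.json, results/signatures.rds

library(radnorm)

cohort <- readRDS("results/cohort.rds")
features <- readRDS("results/features.rds")

signatures <- list()
for (sq in names(features)) {
  X <- as.matrix(features[[sq]][["nn"]][, -1])
  kept <- redundancy_filter(X, cohort$clinical, 0.8)
  cat(sprintf("%s: redundancy filter kept %d / %d features\n",
              sq, length(kept), ncol(X)))
  sc <- selection_config(n_subsamples = 50, hit_threshold = 48,
                         rf_num_trees = 100, seed = 11)
  rep_ <- suppressWarnings(
    stability_select(X[, kept, drop = FALSE], cohort$clinical, sc))
  signatures[[sq]] <- rep_
  print(rep_)
  jsonlite::write_json(
    list(signature = rep_$signature, hits = as.list(rep_$hits),
         method_hits = as.data.frame(rep_$method_hits)),
    sprintf("results/signature_%s.json", sq), auto_unbox = TRUE)
}
saveRDS(signatures, "results/signatures.rds")
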