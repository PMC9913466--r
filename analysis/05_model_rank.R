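#!/usr/bin/env Rscript
# Stage 5: survival models and method ranking.
#
# For every (sequence, method, bin count): fit the Cox model (10-fold CV
# Harrell concordance + AIC) and the Poisson survival regression (10-fold
# CV MSE of the event indicator against the expected event count, log
# follow-up offset, + AIC) on the signature columns; then rank methods by
# the composite standardized score (mean of the four oriented z-scores,
# metrics first averaged over bin counts).
#
# Reads:  results/cohort.rds, results/features.rds, results/signatures.rds
# Writes: results/metrics.csv, results/ranking_<seq>.csv

library(radnorm)

cohort <- readRDS("results/cohort.rds")
features <- readRDS("results/features.rds")
signatures <- readRDS("results/signatures.rds")

all_metrics <- NULL
for (sq in names(features)) {
  sig <- signatures[[sq]]$signature
  if (length(sig) == 0) {
    cat(sq, ": empty signature, skipping models\n")
    next
  }
  sig_core <- sub("^[^|]*\\|", "", sig)
  bins <- sort(unique(attr(features[[sq]][["nn"]], "metadata")$bins))
  for (m in names(features[[sq]])) {
    Fm <- as.matrix(features[[sq]][[m]][, -1])
    colnames(Fm) <- sub("^[^|]*\\|", "", colnames(Fm))
    for (bc in bins) {
      take <- sig_core[grepl(sprintf("\\|%d$", bc), sig_core)]
      if (length(take) == 0) take <- sig_core
      mr <- metrics_record(Fm[, take, drop = FALSE], cohort$clinical,
                           k = 10, seed = 7, sequence = sq, method = m,
                           bin_count = bc)
      all_metrics <- rbind(all_metrics, mr)
    }
  }
  rk <- ranking_score(all_metrics[all_metrics$sequence == sq, ])
  write.csv(rk, sprintf("results/ranking_%s.csv", sq), row.names = FALSE)
  cat(sprintf("\n%s ranking (top 5):\n", sq))
  print(head(rk[, c("method", "score", "cv_cindex", "cv_mse")], 5),
        row.names = FALSE)
}
write.csv(all_metrics, "results/metrics.csv", row.names = FALSE)
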