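#!/usr/bin/env Rscript
# Stage 6: cross-method feature robustness and comparison arms.
#
# Per signature feature: the 16x16 Spearman matrix of its patient vector
# across normalization methods; a feature is stable when >= 12 methods are
# pairwise correlated above rs = 0.8 (exact max-clique on the thresholded
# graph). Then: (a) before/after metrics restricting the top-ranked
# method's model to the stable subset, and (b) the three-arm comparison
# ComBat-alone vs top image method vs combined, on shared folds.
#
# Reads:  results/{cohort,features,signatures}.rds, results/ranking_<seq>.csv
# Writes: results/stability_screen_<seq>.csv, results/before_after_<seq>.csv,
#         results/three_arm_<seq>.csv

library(radnorm)

cohort <- readRDS("results/cohort.rds")
features <- readRDS("results/features.rds")
signatures <- readRDS("results/signatures.rds")

for (sq in names(features)) {
  sig <- signatures[[sq]]$signature
  if (length(sig) == 0) next
  sig_core <- sub("^[^|]*\\|", "", sig)
  tabs <- lapply(features[[sq]], function(ft) {
    M <- as.matrix(ft[, -1])
    colnames(M) <- sub("^[^|]*\\|", "", colnames(M))
    M
  })
  mats <- lapply(sig_core, function(f) {
    vecs <- sapply(names(tabs), function(m) tabs[[m]][, f])
    suppressWarnings(method_correlation(vecs))
  })
  names(mats) <- sig_core
  scr <- stable_feature_screen(mats, rs_threshold = 0.8, min_methods = 12)
  write.csv(scr, sprintf("results/stability_screen_%s.csv", sq),
            row.names = FALSE)
  cat(sprintf("%s: %d / %d signature features stable across >= 12 methods\n",
              sq, sum(scr$stable), nrow(scr)))

  rk <- read.csv(sprintf("results/ranking_%s.csv", sq))
  top <- rk$method[1]
  ba <- before_after_compare(tabs[[top]], cohort$clinical, sig_core,
                             intersect(scr$feature[scr$stable],
                                       colnames(tabs[[top]])),
                             k = 10, seed = 7)
  write.csv(ba, sprintf("results/before_after_%s.csv", sq), row.names = FALSE)
  cat(sprintf("%s top method %s: C-I %.3f -> %.3f after stability screen\n",
              sq, top, ba$cv_cindex[1], ba$cv_cindex[2]))

  top_img <- rk$method[!rk$method %in% c("combat", "nn")][1]
  arm <- combined_combat_image_in(features[[sq]][["nn"]][, -1],
                                  features[[sq]][[top_img]][, -1],
                                  cohort$clinical, sig_core, k = 10, seed = 7)
  write.csv(arm, sprintf("results/three_arm_%s.csv", sq), row.names = FALSE)
  cat(sprintf("%s three arms (combat / %s / combined): C-I %s\n\n",
              sq, top_img,
              paste(sprintf("%.3f", arm$cv_cindex), collapse = " / ")))
}
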