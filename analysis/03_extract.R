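#!/usr/bin/env Rscript
# Stage 3: radiomics feature extraction and the ComBat arm.
#
# For each normalized dataset, ROI-restricted features are extracted from
# the original image at two bin counts (16, 32) -- a scaled-down version
# of the full design (12 derived images x 5 bin counts), keeping this
# driver desk-sized (150 patients); the full composition (1144 columns per bin count) is
# exercised by the test suite. The ComBat dataset is the nn feature table
# harmonized across scanner batches with age/grade/gender preserved.
#
# Reads:  results/cohort.rds
# Writes: results/features.rds and per-dataset CSVs under results/features/

library(radnorm)

cohort <- readRDS("results/cohort.rds")
methods <- setdiff(normalization_methods(), "combat")
cfg <- extraction_config(bin_counts = c(16, 32), images = "original",
                         include_shape = FALSE)

features <- list()
dir.create("results/features", recursive = TRUE, showWarnings = FALSE)
for (sq in names(cohort$volumes)) {
  features[[sq]] <- list()
  for (m in methods) {
    nv <- normalize_dataset(cohort$volumes[[sq]], cohort$masks, m)
    ft <- build_feature_table(nv, cohort$masks, cfg, method_id = m)
    rm(nv); invisible(gc(FALSE))
    features[[sq]][[m]] <- ft
    write.csv(ft, sprintf("results/features/%s_%s.csv", sq, m),
              row.names = FALSE)
  }
  # feature-based arm: ComBat on the nn table
  nn <- features[[sq]][["nn"]]
  adj <- combat_fit_apply(as.matrix(nn[, -1]), cohort$clinical)
  cb <- nn
  cb[, -1] <- adj
  colnames(cb)[-1] <- sub("^nn\\|", "combat|", colnames(cb)[-1])
  attr(cb, "metadata") <- parse_feature_names(colnames(cb)[-1])
  features[[sq]][["combat"]] <- cb
  write.csv(cb, sprintf("results/features/%s_combat.csv", sq),
            row.names = FALSE)
  cat(sprintf("%s: %d datasets x %d patients x %d feature columns\n",
              sq, length(features[[sq]]), nrow(nn), ncol(nn) - 1))
}
saveRDS(features, "results/features.rds")
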