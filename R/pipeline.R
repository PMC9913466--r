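# End-to-end orchestration of the benchmarking study: simulate a cohort,
# normalize with every requested method, extract features at the
# configured bin counts, harmonize the ComBat arm, derive signatures,
# fit survival models, rank methods, and screen for cross-method feature
# robustness. Each stage writes CSV/JSON artifacts with provenance so
# reruns with the same configuration reproduce the outputs bit for bit.

#' Pipeline run configuration
#'
#' The default is the desk-scale study profile: 64^3 volumes, 120
#' patients, two sequences, 200 stability subsamples (a scaled-down
#' version of the full design, which uses 1000 subsamples).
#'
#' @param cohort a `cohort_config`
#' @param methods normalization method ids to evaluate (always includes
#'   "nn")
#' @param extraction an `extraction_config`
#' @param selection a `selection_config`
#' @param k_folds CV folds for the survival models
#' @param model_seed fold-assignment seed
#' @param use_true_masks use the phantom's known tissue memberships for
#'   mask-based methods (FALSE re-estimates them by fuzzy c-means)
#' @return object of class `run_config`
#' @export
run_config <- function(cohort = cohort_config(sequences = c("T1wce", "FLAIR")),
                       methods = normalization_methods(),
                       extraction = extraction_config(),
                       selection = selection_config(n_subsamples = 200,
                                                    hit_threshold = 190),
                       k_folds = 10, model_seed = 1L,
                       use_true_masks = TRUE) {
  stopifnot(inherits(cohort, "cohort_config"),
            all(methods %in% normalization_methods()),
            inherits(extraction, "extraction_config"),
            inherits(selection, "selection_config"))
  structure(list(cohort = cohort, methods = union(methods, "nn"),
                 extraction = extraction, selection = selection,
                 k_folds = k_folds, model_seed = as.integer(model_seed),
                 use_true_masks = use_true_masks),
            class = "run_config")
}

masks_for_norm <- function(cohort, use_true_masks, sequence) {
  if (use_true_masks) return(cohort$masks)
  lapply(seq_along(cohort$masks), function(i) {
    v <- cohort$volumes[[sequence]][[i]]
    m <- cohort$masks[[v$patient_id]]
    seg <- segment_tissues(v, m$brain > 0)
    list(brain = m$brain, csf = seg$csf, gm = seg$gm, wm = seg$wm,
         roi = m$roi)
  })
}

#' Run the full benchmarking pipeline
#'
#' Stages: normalize (x methods) -> extract (x bin counts) -> ComBat arm
#' -> redundancy filter + stability selection (on the non-normalized
#' dataset, so every method is scored on the same signature columns) ->
#' CPH/POI models per method and bin count -> ranking -> robustness screen
#' -> before/after comparison.
#'
#' @param config a `run_config`
#' @param outdir optional directory; when given, tables are written there
#' @param cohort optionally a pre-generated cohort (from
#'   [generate_cohort()] with `config$cohort`)
#' @return list: `cohort`, `features` (nested per sequence/method),
#'   `signatures`, `metrics`, `rankings`, `screens`, `comparisons`
#' @export
run_pipeline <- function(config = run_config(), outdir = NULL, cohort = NULL) {
  if (is.null(cohort)) cohort <- generate_cohort(config$cohort)
  img_methods <- setdiff(config$methods, "combat")
  out <- list(cohort = cohort, features = list(), signatures = list(),
              metrics = NULL, rankings = list(), screens = list(),
              comparisons = list())
  for (sq in config$cohort$sequences) {
    nmasks <- masks_for_norm(cohort, config$use_true_masks, sq)
    names(nmasks) <- names(cohort$masks)
    feats <- list()
    for (m in img_methods) {
      nv <- normalize_dataset(cohort$volumes[[sq]], nmasks, m)
      feats[[m]] <- build_feature_table(nv, cohort$masks, config$extraction,
                                        method_id = m)
    }
    if ("combat" %in% config$methods) {
      nnX <- as.matrix(feats[["nn"]][, -1, drop = FALSE])
      adj <- combat_fit_apply(nnX, cohort$clinical)
      cb <- feats[["nn"]]
      cb[, -1] <- adj
      colnames(cb)[-1] <- sub("^nn\\|", "combat|", colnames(cb)[-1])
      attr(cb, "metadata") <- parse_feature_names(colnames(cb)[-1])
      feats[["combat"]] <- cb
    }
    out$features[[sq]] <- feats
    # signature on the reference (nn) dataset
    ref <- feats[["nn"]]
    Xref <- as.matrix(ref[, -1, drop = FALSE])
    kept <- redundancy_filter(Xref, cohort$clinical,
                              config$selection$redundancy_rs)
    rep_ <- stability_select(Xref[, kept, drop = FALSE], cohort$clinical,
                             config$selection)
    out$signatures[[sq]] <- rep_
    sig <- rep_$signature
    if (length(sig) == 0) next
    sig_core <- sub("^[^|]*\\|", "", sig)
    # per-method metrics, one record per bin count
    mrows <- list()
    for (m in names(feats)) {
      Fm <- as.matrix(feats[[m]][, -1, drop = FALSE])
      colnames(Fm) <- sub("^[^|]*\\|", "", colnames(Fm))
      meta <- parse_feature_names(paste0(m, "|", colnames(Fm)))
      for (bc in config$extraction$bin_counts) {
        take <- sig_core[sig_core %in% colnames(Fm)]
        take_bc <- take[grepl(sprintf("\\|%d$", bc), take) |
                          grepl("\\|0$", take)]
        if (length(take_bc) == 0) take_bc <- take
        mrows[[paste(sq, m, bc)]] <-
          metrics_record(Fm[, take_bc, drop = FALSE], cohort$clinical,
                         config$k_folds, config$model_seed,
                         sequence = sq, method = m, bin_count = bc)
      }
    }
    met <- do.call(rbind, mrows)
    out$metrics <- rbind(out$metrics, met)
    out$rankings[[sq]] <- ranking_score(met)
    # robustness screen across methods
    mats <- list()
    for (f in sig_core) {
      vecs <- sapply(names(feats), function(m) {
        Fm <- as.matrix(feats[[m]][, -1, drop = FALSE])
        colnames(Fm) <- sub("^[^|]*\\|", "", colnames(Fm))
        if (f %in% colnames(Fm)) Fm[, f] else rep(NA_real_, nrow(Fm))
      })
      mats[[f]] <- method_correlation(vecs)
    }
    scr <- stable_feature_screen(mats)
    out$screens[[sq]] <- scr
    stable <- scr$feature[scr$stable]
    top_m <- out$rankings[[sq]]$method[1]
    Ftop <- as.matrix(feats[[top_m]][, -1, drop = FALSE])
    colnames(Ftop) <- sub("^[^|]*\\|", "", colnames(Ftop))
    out$comparisons[[sq]] <- list(
      before_after = before_after_compare(Ftop, cohort$clinical, sig_core,
                                          intersect(stable, colnames(Ftop)),
                                          config$k_folds, config$model_seed),
      three_arm = {
        top_img <- out$rankings[[sq]]$method[
          !out$rankings[[sq]]$method %in% c("combat", "nn")][1]
        combined_combat_image_in(feats[["nn"]][, -1], feats[[top_img]][, -1],
                                 cohort$clinical, sig_core,
                                 config$k_folds, config$model_seed)
      })
  }
  if (!is.null(outdir)) write_pipeline_outputs(out, outdir)
  out
}

write_pipeline_outputs <- function(res, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  write.csv(res$cohort$clinical, file.path(outdir, "clinical.csv"),
            row.names = FALSE)
  if (!is.null(res$metrics))
    write.csv(res$metrics, file.path(outdir, "metrics.csv"), row.names = FALSE)
  for (sq in names(res$rankings))
    write.csv(res$rankings[[sq]],
              file.path(outdir, sprintf("ranking_%s.csv", sq)),
              row.names = FALSE)
  for (sq in names(res$signatures))
    jsonlite::write_json(
      list(signature = res$signatures[[sq]]$signature,
           hits = as.list(res$signatures[[sq]]$hits),
           method_hits = as.data.frame(res$signatures[[sq]]$method_hits)),
      file.path(outdir, sprintf("signature_%s.json", sq)), auto_unbox = TRUE)
  for (sq in names(res$screens))
    write.csv(res$screens[[sq]],
              file.path(outdir, sprintf("stability_screen_%s.csv", sq)),
              row.names = FALSE)
  invisible(outdir)
}
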