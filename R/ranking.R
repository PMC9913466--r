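# Method ranking and cross-method feature robustness. Normalization
# methods are ranked per sequence by a composite standardized score of
# four model metrics (CV concordance, CV MSE, and the two AICs, each
# z-scored across methods and oriented so larger is better). Signature
# features are screened for robustness by requiring a mutually correlated
# set of methods (pairwise Spearman above threshold).

#' Composite ranking score for normalization methods
#'
#' Metrics are first averaged over bin counts per method; each of
#' {mean C-I, mean MSE, mean AIC_cph, mean AIC_poi} is z-standardized
#' across methods (a zero-variance column contributes 0), oriented so
#' larger is better (MSE and AICs negated), and the score is the mean of
#' the four oriented z-scores. Ties break by C-I, then method id.
#'
#' @param metrics data.frame of [metrics_record()] rows for one cohort and
#'   sequence (any number of bin counts per method)
#' @return data.frame ordered by descending score: method, score, the four
#'   component z-scores, and the bin-averaged metrics
#' @export
ranking_score <- function(metrics) {
  stopifnot(all(c("method", "cv_cindex", "cv_mse", "aic_cph", "aic_poi")
                %in% names(metrics)))
  agg <- aggregate(metrics[, c("cv_cindex", "cv_mse", "aic_cph", "aic_poi")],
                   by = list(method = metrics$method), FUN = mean)
  if (nrow(agg) < 3) stop("ranking_score: need at least 3 methods")
  zcol <- function(x) {
    s <- sd(x)
    if (s == 0) rep(0, length(x)) else (x - mean(x)) / s
  }
  z_ci <- zcol(agg$cv_cindex)
  z_mse <- -zcol(agg$cv_mse)
  z_aic_cph <- -zcol(agg$aic_cph)
  z_aic_poi <- -zcol(agg$aic_poi)
  score <- (z_ci + z_mse + z_aic_cph + z_aic_poi) / 4
  out <- data.frame(method = agg$method, score = score,
                    z_cindex = z_ci, z_mse = z_mse,
                    z_aic_cph = z_aic_cph, z_aic_poi = z_aic_poi,
                    cv_cindex = agg$cv_cindex, cv_mse = agg$cv_mse,
                    aic_cph = agg$aic_cph, aic_poi = agg$aic_poi,
                    stringsAsFactors = FALSE)
  out[order(-out$score, -out$cv_cindex, out$method), ]
}

#' Cross-method Spearman correlation matrix for one feature
#'
#' @param vectors named list (or matrix columns) of the feature's
#'   per-patient values under each normalization method, identical patient
#'   ordering
#' @return symmetric Spearman correlation matrix (unit diagonal);
#'   zero-variance vectors correlate 0 with everything (with a warning)
#' @export
method_correlation <- function(vectors) {
  M <- if (is.matrix(vectors)) vectors else do.call(cbind, vectors)
  stopifnot(nrow(M) >= 10)
  zv <- apply(M, 2, sd) == 0
  if (any(zv)) warning("method_correlation: zero-variance vector(s): ",
                       paste(colnames(M)[zv], collapse = ", "))
  R <- suppressWarnings(cor(M, method = "spearman"))
  R[is.na(R)] <- 0
  diag(R) <- 1
  R
}

# exact maximum clique on a small adjacency matrix (branch and bound)
max_clique_size <- function(adj) {
  n <- nrow(adj)
  best <- 0
  best_set <- integer(0)
  ord <- order(rowSums(adj), decreasing = TRUE)
  expand <- function(current, candidates) {
    if (length(candidates) == 0) {
      if (length(current) > best) {
        best <<- length(current); best_set <<- current
      }
      return(invisible(NULL))
    }
    if (length(current) + length(candidates) <= best) return(invisible(NULL))
    for (ii in seq_along(candidates)) {
      v <- candidates[ii]
      rest <- candidates[-seq_len(ii)]
      expand(c(current, v), rest[adj[v, rest]])
    }
    invisible(NULL)
  }
  expand(integer(0), ord)
  list(size = best, members = sort(best_set))
}

#' Screen signature features for cross-method robustness
#'
#' A feature is stable iff there exists a set of at least `min_methods`
#' methods that are pairwise correlated above `rs_threshold` (exact
#' maximum-clique search on the thresholded correlation graph).
#'
#' @param matrices named list of per-feature correlation matrices from
#'   [method_correlation()]
#' @param rs_threshold pairwise Spearman threshold (default 0.8)
#' @param min_methods minimum mutually correlated set size (default 12)
#' @return data.frame per feature: `feature`, `stable`, `clique_size`,
#'   plus attribute `cliques` (the member sets)
#' @export
stable_feature_screen <- function(matrices, rs_threshold = 0.8,
                                  min_methods = 12) {
  res <- lapply(names(matrices), function(f) {
    R <- matrices[[f]]
    adj <- R > rs_threshold
    diag(adj) <- FALSE
    mc <- max_clique_size(adj)
    # a single method is trivially a "set" of size 1
    size <- max(mc$size, 1L)
    list(feature = f, stable = size >= min_methods, clique_size = size,
         members = if (mc$size > 0) colnames(R)[mc$members]
                   else colnames(R)[1])
  })
  out <- data.frame(feature = vapply(res, `[[`, "", "feature"),
                    stable = vapply(res, `[[`, TRUE, "stable"),
                    clique_size = vapply(res, function(r)
                      as.integer(r$clique_size), 1L),
                    stringsAsFactors = FALSE)
  attr(out, "cliques") <- lapply(res, `[[`, "members")
  out
}

boot_ci <- function(x, n_boot = 1000, seed = 1L) {
  x <- x[is.finite(x)]
  if (length(x) < 2) return(c(lo = NA_real_, hi = NA_real_))
  bs <- with_seed(seed, replicate(n_boot, mean(sample(x, replace = TRUE))))
  quantile(bs, c(0.025, 0.975), names = FALSE)
}

#' Model performance before vs after restricting to stable features
#'
#' Refits the CPH and POI models with only the robust (stable) subset of
#' the signature and reports both metric sets with 95% bootstrap
#' confidence intervals over the fold-level values, plus the deltas.
#'
#' @param features numeric matrix containing at least the signature columns
#' @param clinical data.frame with `os_days`, `event`
#' @param signature character vector of signature feature columns
#' @param stable_subset character vector (subset of `signature`)
#' @param k number of folds
#' @param seed fold seed shared by both arms
#' @return data.frame with rows "before" and "after" (after is a sentinel
#'   row of NAs when the stable subset is empty) and a `delta` attribute
#' @export
before_after_compare <- function(features, clinical, signature,
                                 stable_subset, k = 10, seed = 1L) {
  stopifnot(length(signature) >= 1)
  run <- function(cols) {
    cph <- fit_cph_cv(features[, cols, drop = FALSE], clinical, k, seed)
    poi <- fit_poisson_cv(features[, cols, drop = FALSE], clinical, k, seed)
    ci_ci <- boot_ci(cph$fold_cindex, seed = seed)
    ci_mse <- boot_ci(poi$fold_mse, seed = seed)
    data.frame(cv_cindex = cph$cv_cindex, ci_lo = ci_ci[1], ci_hi = ci_ci[2],
               cv_mse = poi$cv_mse, mse_lo = ci_mse[1], mse_hi = ci_mse[2],
               n_features = length(cols))
  }
  before <- run(signature)
  if (length(stable_subset) == 0) {
    after <- before; after[1, ] <- NA; after$n_features <- 0
  } else {
    after <- run(stable_subset)
  }
  out <- rbind(cbind(arm = "before", before), cbind(arm = "after", after))
  rownames(out) <- NULL
  attr(out, "delta") <- c(d_cindex = after$cv_cindex - before$cv_cindex,
                          d_mse = after$cv_mse - before$cv_mse)
  out
}

#' Three-arm comparison: ComBat alone, image normalization alone, combined
#'
#' Arm (a) harmonizes the non-normalized features with ComBat; arm (b)
#' uses the top image-based method's features as-is; arm (c) applies
#' ComBat to the image-normalized features. All arms share fold
#' assignments and seeds.
#'
#' @param nn_features feature matrix from the non-normalized dataset
#' @param img_features feature matrix from the top image-based method
#' @param clinical clinical table with batch_id, age, grade, gender
#' @param signature character vector of feature columns to model (column
#'   names must exist in both matrices up to the method prefix)
#' @param k folds
#' @param seed shared fold seed
#' @return data.frame with one metrics row per arm
#' @export
combined_combat_image_in <- function(nn_features, img_features, clinical,
                                     signature, k = 10, seed = 1L) {
  strip <- function(x) sub("^[^|]*\\|", "", x)
  pick <- function(M, cols) {
    m <- as.matrix(M)
    colnames(m) <- strip(colnames(m))
    # signature ids may carry a method prefix or already be stripped
    cols <- ifelse(cols %in% colnames(m), cols, strip(cols))
    if (!all(cols %in% colnames(m)))
      stop("combined_combat_image_in: signature columns missing from table")
    m[, cols, drop = FALSE]
  }
  Xnn <- pick(nn_features, signature)
  Ximg <- pick(img_features, signature)
  arms <- list(
    combat = combat_fit_apply(Xnn, clinical),
    image_in = Ximg,
    combined = combat_fit_apply(Ximg, clinical))
  do.call(rbind, lapply(names(arms), function(a) {
    r <- metrics_record(arms[[a]], clinical, k, seed, method = a)
    r$arm <- a
    r
  }))
}
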