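# Overall-survival signature derivation: Spearman redundancy filtering
# followed by three-method stability selection (univariate Cox, survival
# random forest, lasso Cox) over repeated 90% subsamples; features selected
# in at least 95% of subsamples by all three methods form the signature.

#' Stability-selection configuration
#'
#' @param redundancy_rs Spearman threshold above which a feature is
#'   considered redundant (default 0.80)
#' @param n_subsamples number of random subsamples (1000 at full scale;
#'   scaled-down runs use fewer with the same 95% hit fraction)
#' @param holdout_fraction fraction left out per subsample (0.10)
#' @param hit_threshold minimum number of subsamples a feature must be
#'   selected in (default 95% of `n_subsamples`)
#' @param univariate_alpha Wald p-value cutoff for the univariate Cox
#'   selector (0.05)
#' @param rf_num_trees trees per survival random forest
#' @param seed master seed
#' @return object of class `selection_config`
#' @export
selection_config <- function(redundancy_rs = 0.80, n_subsamples = 1000,
                             holdout_fraction = 0.10,
                             hit_threshold = ceiling(0.95 * n_subsamples),
                             univariate_alpha = 0.05,
                             rf_num_trees = 500, seed = 1L) {
  stopifnot(holdout_fraction > 0, holdout_fraction < 0.5,
            hit_threshold <= n_subsamples, redundancy_rs > 0)
  structure(list(redundancy_rs = redundancy_rs,
                 n_subsamples = as.integer(n_subsamples),
                 holdout_fraction = holdout_fraction,
                 hit_threshold = as.integer(hit_threshold),
                 univariate_alpha = univariate_alpha,
                 rf_num_trees = as.integer(rf_num_trees),
                 seed = as.integer(seed)),
            class = "selection_config")
}

#' Spearman redundancy filter
#'
#' Features are ordered by descending univariate concordance with survival
#' (using `max(C, 1-C)` so the feature's sign does not matter); scanning in
#' that order, a feature is kept iff its absolute Spearman correlation with
#' every already-kept feature is at or below the threshold. Deterministic.
#'
#' @param features numeric matrix, rows = patients
#' @param clinical data.frame with `os_days`, `event`
#' @param rs_threshold Spearman cutoff (default 0.80)
#' @return character vector of kept column names (in scan order)
#' @export
redundancy_filter <- function(features, clinical, rs_threshold = 0.80) {
  X <- as.matrix(features)
  stopifnot(nrow(X) >= 2)
  conc <- apply(X, 2, function(x) {
    if (sd(x) == 0) return(0)
    ci <- tryCatch(harrell_cindex(x, clinical$os_days, clinical$event),
                   error = function(e) 0.5)
    max(ci, 1 - ci)
  })
  ord <- order(conc, decreasing = TRUE)
  R <- suppressWarnings(cor(X, method = "spearman"))
  R[is.na(R)] <- 0
  kept <- integer(0)
  for (jj in ord) {
    if (all(abs(R[jj, kept]) <= rs_threshold)) kept <- c(kept, jj)
  }
  colnames(X)[kept]
}

#' Per-subsample three-method feature selection
#'
#' On one 90% subsample: (a) univariate Cox with Wald p below alpha;
#' (b) survival random forest with positive permutation importance;
#' (c) lasso Cox (penalty minimizing the inner 5-fold CV deviance)
#' with a nonzero coefficient.
#'
#' @param features numeric matrix (redundancy-filtered)
#' @param clinical data.frame with `os_days`, `event`
#' @param config a `selection_config`
#' @param subsample_seed seed for this subsample (drawn from the config's
#'   counter scheme by [stability_select()])
#' @return list of three character vectors: `cph`, `rf`, `lasso`, plus the
#'   subsample indices
#' @export
subsample_select <- function(features, clinical, config = selection_config(),
                             subsample_seed = 1L) {
  X <- as.matrix(features)
  n <- nrow(X)
  m <- n - floor(config$holdout_fraction * n)
  idx <- with_seed(subsample_seed, sort(sample.int(n, m)))
  Xs <- X[idx, , drop = FALSE]
  cl <- clinical[idx, , drop = FALSE]
  y <- survival::Surv(cl$os_days, cl$event)

  # (a) univariate Cox Wald p < alpha
  pvals <- apply(Xs, 2, function(x) {
    if (sd(x) == 0) return(1)
    f <- tryCatch(suppressWarnings(
      survival::coxph(y ~ z, data = data.frame(z = as.numeric(scale(x))))),
      error = function(e) NULL)
    if (is.null(f) || is.na(coef(f))) return(1)
    summary(f)$coefficients[1, "Pr(>|z|)"]
  })
  sel_cph <- colnames(Xs)[pvals < config$univariate_alpha]

  # (b) survival random forest, positive permutation importance
  dat <- data.frame(Xs, check.names = FALSE)
  names(dat) <- paste0("f", seq_len(ncol(Xs)))
  dat$time <- cl$os_days; dat$status <- cl$event
  rf <- ranger::ranger(survival::Surv(time, status) ~ ., data = dat,
                       num.trees = config$rf_num_trees,
                       importance = "permutation",
                       seed = subsample_seed, num.threads = 1,
                       min.node.size = 10)
  sel_rf <- colnames(Xs)[rf$variable.importance > 0]

  # (c) lasso Cox, CV-optimal penalty, nonzero coefficient
  sel_lasso <- character(0)
  if (sum(cl$event) >= 10) {
    cvfit <- tryCatch(with_seed(subsample_seed, suppressWarnings(
      glmnet::cv.glmnet(scale(Xs), y, family = "cox", nfolds = 5,
                        nlambda = 50))),
      error = function(e) NULL)
    if (!is.null(cvfit)) {
      b <- as.numeric(coef(cvfit, s = "lambda.min"))
      sel_lasso <- colnames(Xs)[b != 0]
    }
  }
  list(cph = sel_cph, rf = sel_rf, lasso = sel_lasso, indices = idx)
}

#' Stability selection of an overall-survival signature
#'
#' Runs [subsample_select()] on `n_subsamples` subsamples (seeds derived by
#' the fixed counter scheme, so the run is reproducible and extensible); a
#' feature scores a hit in a subsample iff all three methods select it.
#' Features with hits at or above the threshold form the signature.
#' Per-method marginal counts are reported so the alternative union rule
#' can be audited.
#'
#' @param features numeric matrix (redundancy-filtered)
#' @param clinical data.frame with `os_days`, `event`
#' @param config a `selection_config`
#' @return object of class `signature_report`: `signature` (character),
#'   `hits` (joint per-feature counts), `method_hits` (matrix), `config`
#' @export
stability_select <- function(features, clinical, config = selection_config()) {
  X <- as.matrix(features)
  feats <- colnames(X)
  hits <- setNames(integer(length(feats)), feats)
  mh <- matrix(0L, length(feats), 3,
               dimnames = list(feats, c("cph", "rf", "lasso")))
  for (s in seq_len(config$n_subsamples)) {
    sel <- subsample_select(X, clinical, config,
                            subsample_seed = derive_seed(config$seed, s))
    joint <- Reduce(intersect, sel[c("cph", "rf", "lasso")])
    hits[joint] <- hits[joint] + 1L
    for (mname in c("cph", "rf", "lasso"))
      mh[sel[[mname]], mname] <- mh[sel[[mname]], mname] + 1L
  }
  sig <- feats[hits >= config$hit_threshold]
  if (length(sig) == 0)
    warning("stability_select: empty signature")
  structure(list(signature = sig, hits = hits, method_hits = mh,
                 config = config),
            class = "signature_report")
}

#' @export
print.signature_report <- function(x, ...) {
  cat(sprintf("<signature_report: %d/%d features selected (threshold %d/%d)>\n",
              length(x$signature), length(x$hits),
              x$config$hit_threshold, x$config$n_subsamples))
  if (length(x$signature)) print(utils::head(sort(x$hits[x$signature],
                                                  decreasing = TRUE), 20))
  invisible(x)
}
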