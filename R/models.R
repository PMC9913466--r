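# Survival modelling of radiomics signatures: Cox proportional hazards and
# Poisson survival regression (event indicator with log follow-up time as
# offset), evaluated by 10-fold cross-validated Harrell concordance and
# mean squared error, plus full-data AIC.

#' Harrell's concordance index
#'
#' Over comparable pairs (t_i < t_j with event_i = 1): concordant when
#' risk_i > risk_j; tied risks earn 0.5 credit.
#'
#' @param risk numeric risk scores (higher = shorter expected survival)
#' @param time follow-up times
#' @param event event indicators (1 = death observed)
#' @return concordance in [0, 1]
#' @export
harrell_cindex <- function(risk, time, event) {
  n <- length(risk)
  stopifnot(length(time) == n, length(event) == n, n >= 2)
  comp <- 0; conc <- 0
  ev <- which(event == 1)
  if (length(ev) == 0) stop("harrell_cindex: no comparable pairs (no events)")
  for (i in ev) {
    later <- time > time[i]
    m <- sum(later)
    if (m == 0) next
    comp <- comp + m
    conc <- conc + sum(risk[i] > risk[later]) + 0.5 * sum(risk[i] == risk[later])
  }
  if (comp == 0) stop("harrell_cindex: no comparable pairs")
  conc / comp
}

#' Akaike information criterion
#' @param loglik maximized log-likelihood
#' @param n_params number of estimated parameters
#' @return `2 * n_params - 2 * loglik`
#' @export
aic <- function(loglik, n_params) 2 * n_params - 2 * loglik

# stratified k-fold assignment (by event status), deterministic given seed
make_folds <- function(event, k, seed) {
  n <- length(event)
  fold <- integer(n)
  with_seed(seed, {
    for (g in unique(event)) {
      idx <- sample(which(event == g))
      fold[idx] <- rep_len(seq_len(k), length(idx))
    }
  })
  fold
}

scale_train_apply <- function(Xtr, Xte) {
  mu <- colMeans(Xtr)
  sg <- apply(Xtr, 2, sd)
  sg[sg == 0] <- 1
  list(tr = sweep(sweep(Xtr, 2, mu), 2, sg, "/"),
       te = sweep(sweep(Xte, 2, mu), 2, sg, "/"))
}

#' Cross-validated Cox proportional-hazards model
#'
#' Features are standardized inside each training fold; Cox fits use Efron
#' tie handling with a small ridge penalty floor for numerical stability.
#' Returns the mean held-out Harrell concordance over `k` folds and the AIC
#' of the full-data fit (parameters = number of features).
#'
#' @param features numeric matrix/data.frame of signature features
#' @param clinical data.frame with `os_days` and `event` (row-matched)
#' @param k number of folds (default 10)
#' @param seed fold-assignment seed
#' @param ridge ridge penalty floor
#' @return list: `cv_cindex`, `aic`, `fold_cindex`, `loglik`
#' @export
fit_cph_cv <- function(features, clinical, k = 10, seed = 1L, ridge = 1e-6) {
  X <- as.matrix(features)
  stopifnot(nrow(X) == nrow(clinical), ncol(X) >= 1)
  if (sum(clinical$event) < k)
    stop("fit_cph_cv: fewer events than folds")
  y <- survival::Surv(clinical$os_days, clinical$event)
  # ridge floor keeps the penalized partial likelihood bounded, so
  # monotone-likelihood (separation) cases still yield finite coefficients
  cox_fit <- function(Xs, ys) {
    d <- as.data.frame(Xs)
    names(d) <- paste0("x", seq_len(ncol(Xs)))
    fml <- stats::as.formula(paste(
      "ys ~ survival::ridge(", paste(names(d), collapse = ","),
      ", theta =", format(ridge, scientific = FALSE), ", scale = FALSE)"))
    d$ys <- ys
    suppressWarnings(
      survival::coxph(fml, data = d, ties = "efron",
                      control = survival::coxph.control(iter.max = 100)))
  }
  fold <- make_folds(clinical$event, k, seed)
  fold_ci <- rep(NA_real_, k)
  for (f in seq_len(k)) {
    tr <- fold != f; te <- !tr
    sc <- scale_train_apply(X[tr, , drop = FALSE], X[te, , drop = FALSE])
    fit <- cox_fit(sc$tr, y[tr])
    beta <- coef(fit)
    beta[is.na(beta)] <- 0
    lp <- as.numeric(sc$te %*% beta)
    fold_ci[f] <- tryCatch(
      harrell_cindex(lp, clinical$os_days[te], clinical$event[te]),
      error = function(e) NA_real_)
  }
  scf <- scale_train_apply(X, X)
  full <- cox_fit(scf$tr, y)
  ll <- full$loglik[length(full$loglik)]
  list(cv_cindex = mean(fold_ci, na.rm = TRUE), aic = aic(ll, ncol(X)),
       fold_cindex = fold_ci, loglik = ll)
}

#' Cross-validated Poisson survival regression
#'
#' Event indicator modelled as Poisson with log follow-up time offset:
#' `d_i ~ Poisson(mu_i)`, `log mu_i = log(os_days_i) + x_i beta + b0`.
#' Per held-out fold, MSE is the mean squared difference between the event
#' indicator and the predicted expected event count; AIC comes from the
#' full-data fit.
#'
#' @inheritParams fit_cph_cv
#' @return list: `cv_mse`, `aic`, `fold_mse`, `loglik`
#' @export
fit_poisson_cv <- function(features, clinical, k = 10, seed = 1L) {
  X <- as.matrix(features)
  stopifnot(nrow(X) == nrow(clinical))
  if (sum(clinical$event) < k)
    stop("fit_poisson_cv: fewer events than folds")
  off <- log(clinical$os_days)
  fit_poi <- function(Xs, d, o) {
    dat <- as.data.frame(Xs)
    names(dat) <- paste0("x", seq_len(ncol(Xs)))
    dat$d <- d; dat$o <- o
    fml <- stats::as.formula(paste("d ~", paste(names(dat)[seq_len(ncol(Xs))],
                                                collapse = "+"), "+ offset(o)"))
    suppressWarnings(stats::glm(fml, family = stats::poisson(), data = dat))
  }
  fold <- make_folds(clinical$event, k, seed)
  fold_mse <- rep(NA_real_, k)
  for (f in seq_len(k)) {
    tr <- fold != f; te <- !tr
    sc <- scale_train_apply(X[tr, , drop = FALSE], X[te, , drop = FALSE])
    fit <- fit_poi(sc$tr, clinical$event[tr], off[tr])
    beta <- coef(fit)
    beta[is.na(beta)] <- 0
    mu <- exp(beta[1] + as.numeric(sc$te %*% beta[-1]) + off[te])
    if (any(!is.finite(mu))) stop("fit_poisson_cv: divergent predictions")
    fold_mse[f] <- mean((clinical$event[te] - mu)^2)
  }
  scf <- scale_train_apply(X, X)
  full <- fit_poi(scf$tr, clinical$event, off)
  ll <- as.numeric(stats::logLik(full))
  list(cv_mse = mean(fold_mse, na.rm = TRUE),
       aic = aic(ll, length(coef(full))),
       fold_mse = fold_mse, loglik = ll)
}

#' Fit both survival models and collect the metrics record
#'
#' @inheritParams fit_cph_cv
#' @param sequence,method,bin_count metadata recorded in the output row
#' @return one-row data.frame: cv_cindex, cv_mse, aic_cph, aic_poi plus
#'   metadata; fold-level values in attributes
#' @export
metrics_record <- function(features, clinical, k = 10, seed = 1L,
                           sequence = NA, method = NA, bin_count = NA) {
  cph <- fit_cph_cv(features, clinical, k, seed)
  poi <- fit_poisson_cv(features, clinical, k, seed)
  out <- data.frame(sequence = sequence, method = method,
                    bin_count = bin_count,
                    cv_cindex = cph$cv_cindex, cv_mse = poi$cv_mse,
                    aic_cph = cph$aic, aic_poi = poi$aic,
                    n_features = ncol(as.matrix(features)),
                    stringsAsFactors = FALSE)
  attr(out, "fold_cindex") <- cph$fold_cindex
  attr(out, "fold_mse") <- poi$fold_mse
  out
}
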