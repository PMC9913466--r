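# Empirical-Bayes ComBat batch harmonization of radiomics feature tables.
# Parametric location/scale model: per feature, batch means are shrunk
# toward a normal prior and batch variances toward an inverse-gamma prior
# (both fit across features by method of moments), then removed while
# covariate effects (age, grade, gender) are preserved.

#' Fit-and-apply parametric empirical-Bayes ComBat harmonization
#'
#' Per feature: fit grand mean + covariates (age standardized, grade IV and
#' male gender as 0/1 indicators) by least squares; standardize residuals by
#' the pooled variance; estimate per-batch location (gamma-hat) and scale
#' (delta-hat squared) effects; shrink them via the parametric EB iteration
#' to gamma-star / delta-star; adjust the data and restore the pooled scale
#' and covariate effects.
#'
#' @param features numeric matrix or data.frame, rows = patients, columns =
#'   features (no missing values)
#' @param clinical data.frame with one row per patient (same order as
#'   `features`) carrying `batch_id`, `age`, `grade`, `gender`
#' @param parametric must be TRUE (parametric EB path only)
#' @param conv relative convergence tolerance of the EB iteration
#' @param max_iter maximum EB iterations per batch
#' @param return_model also return the fitted `combat_model`
#' @return harmonized feature matrix with the input's dim names (and, if
#'   `return_model`, a list with elements `adjusted` and `model`)
#' @export
combat_fit_apply <- function(features, clinical, parametric = TRUE,
                             conv = 1e-4, max_iter = 100,
                             return_model = FALSE) {
  stopifnot(isTRUE(parametric), nrow(clinical) == NROW(features))
  Y <- as.matrix(features)
  if (any(!is.finite(Y))) stop("combat_fit_apply: missing/non-finite feature values")
  n <- nrow(Y); p <- ncol(Y)
  batch <- factor(clinical$batch_id)
  nb <- table(batch)
  if (any(nb < 2)) {
    bad <- names(nb)[nb < 2]
    stop("combat_fit_apply: singleton batch(es): ", paste(bad, collapse = ", "))
  }
  if (nlevels(batch) < 2) {
    out <- Y
    if (return_model) return(list(adjusted = out, model = NULL))
    return(out)
  }
  # skip zero-variance features (passed through unchanged)
  fvar <- apply(Y, 2, var)
  keep <- fvar > 0
  if (any(!keep))
    warning("combat_fit_apply: skipping ", sum(!keep), " zero-variance feature(s)")
  Yk <- Y[, keep, drop = FALSE]
  pk <- ncol(Yk)

  Zcov <- cbind(age = as.numeric(scale(clinical$age)),
                gradeIV = as.numeric(clinical$grade == "IV"),
                genderM = as.numeric(clinical$gender == "M"))
  # drop constant covariate columns (degenerate cohorts)
  Zcov <- Zcov[, apply(Zcov, 2, function(z) var(z) > 0), drop = FALSE]
  Bmat <- stats::model.matrix(~ 0 + batch)
  X <- cbind(Bmat, Zcov)
  if (qr(X)$rank < ncol(X))
    stop("combat_fit_apply: design matrix not full rank (batch confounded with covariates)")
  bhat <- solve(crossprod(X), crossprod(X, Yk))        # (B + q) x pk
  nB <- nlevels(batch)
  grand <- crossprod(nb / n, bhat[seq_len(nB), , drop = FALSE])  # 1 x pk
  stand_mean <- matrix(grand, n, pk, byrow = TRUE)
  if (ncol(Zcov) > 0)
    stand_mean <- stand_mean +
      Zcov %*% bhat[-seq_len(nB), , drop = FALSE]
  resid <- Yk - X %*% bhat
  var_pooled <- colMeans(resid^2)                      # denominator n
  sdp <- matrix(sqrt(var_pooled), n, pk, byrow = TRUE)
  Zd <- (Yk - stand_mean) / sdp

  gamma_hat <- do.call(rbind, lapply(levels(batch), function(b)
    colMeans(Zd[batch == b, , drop = FALSE])))
  delta_hat <- do.call(rbind, lapply(levels(batch), function(b)
    apply(Zd[batch == b, , drop = FALSE], 2, var)))
  rownames(gamma_hat) <- rownames(delta_hat) <- levels(batch)
  # EB hyperpriors by method of moments (need >= 2 features; with fewer,
  # the across-feature prior is undefined and the raw location/scale
  # estimates are used unshrunk)
  gamma_bar <- rowMeans(gamma_hat)
  t2 <- apply(gamma_hat, 1, var)
  ap <- apply(delta_hat, 1, function(d) {
    m <- mean(d); s2 <- var(d); (2 * s2 + m^2) / s2
  })
  bp <- apply(delta_hat, 1, function(d) {
    m <- mean(d); s2 <- var(d); (m * s2 + m^3) / s2
  })
  gamma_star <- gamma_hat; delta_star <- delta_hat
  eb <- pk >= 2 && all(is.finite(t2)) && all(is.finite(ap)) &&
    all(is.finite(bp))
  if (eb) for (bi in seq_len(nB)) {
    b <- levels(batch)[bi]
    Zb <- Zd[batch == b, , drop = FALSE]
    nbb <- nrow(Zb)
    g_old <- gamma_hat[bi, ]; d_old <- delta_hat[bi, ]
    for (it in seq_len(max_iter)) {
      g_new <- (nbb * t2[bi] * gamma_hat[bi, ] + d_old * gamma_bar[bi]) /
        (nbb * t2[bi] + d_old)
      sum2 <- colSums((Zb - matrix(g_new, nbb, pk, byrow = TRUE))^2)
      d_new <- (0.5 * sum2 + bp[bi]) / (nbb / 2 + ap[bi] - 1)
      change <- max(abs(g_new - g_old) / pmax(abs(g_old), 1e-12),
                    abs(d_new - d_old) / pmax(abs(d_old), 1e-12))
      g_old <- g_new; d_old <- d_new
      if (change < conv) break
    }
    gamma_star[bi, ] <- g_old
    delta_star[bi, ] <- pmax(d_old, 1e-12)
  }

  adj <- Zd
  for (bi in seq_len(nB)) {
    sel <- batch == levels(batch)[bi]
    nbb <- sum(sel)
    adj[sel, ] <- (Zd[sel, , drop = FALSE] -
                     matrix(gamma_star[bi, ], nbb, pk, byrow = TRUE)) /
      matrix(sqrt(delta_star[bi, ]), nbb, pk, byrow = TRUE)
  }
  Yadj <- adj * sdp + stand_mean
  out <- Y
  out[, keep] <- Yadj
  dimnames(out) <- dimnames(Y)
  if (!return_model) return(out)
  list(adjusted = out,
       model = structure(list(batch_levels = levels(batch),
                              gamma_hat = gamma_hat, gamma_star = gamma_star,
                              delta_hat = delta_hat, delta_star = delta_star,
                              gamma_bar = gamma_bar, t2 = t2,
                              a_prior = ap, b_prior = bp,
                              var_pooled = var_pooled, kept = keep),
                         class = "combat_model"))
}
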