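# Composite method ranking and the cross-method robustness screen.

toy_metrics <- function(df) {
  data.frame(method = df$method, cv_cindex = df$ci, cv_mse = df$mse,
             aic_cph = df$a1, aic_poi = df$a2, stringsAsFactors = FALSE)
}

test_that("ranking scores match spreadsheet arithmetic on a 3-method toy table", {
  m <- toy_metrics(data.frame(method = c("a", "b", "c"),
                              ci = c(0.70, 0.65, 0.60),
                              mse = c(0.20, 0.25, 0.30),
                              a1 = c(900, 950, 1000),
                              a2 = c(400, 420, 440)))
  rk <- ranking_score(m)
  z <- function(x) (x - mean(x)) / sd(x)
  expected_a <- mean(c(z(c(0.7, 0.65, 0.6))[1], -z(c(0.2, 0.25, 0.3))[1],
                       -z(c(900, 950, 1000))[1], -z(c(400, 420, 440))[1]))
  expect_equal(rk$score[rk$method == "a"], expected_a, tolerance = 1e-12)
  expect_equal(rk$method, c("a", "b", "c"))
  # component z-scores sum to zero
  expect_equal(sum(rk$z_cindex), 0, tolerance = 1e-9)
  expect_equal(sum(rk$z_mse), 0, tolerance = 1e-9)
  expect_equal(sum(rk$score), 0, tolerance = 1e-9)
})

test_that("ranking is invariant to affine rescaling of a metric column and handles ties", {
  m <- toy_metrics(data.frame(method = c("a", "b", "c", "d"),
                              ci = c(0.70, 0.65, 0.60, 0.62),
                              mse = c(0.20, 0.25, 0.30, 0.28),
                              a1 = c(900, 950, 1000, 980),
                              a2 = c(400, 420, 440, 430)))
  rk1 <- ranking_score(m)
  m2 <- m; m2$aic_cph <- 3 * m$aic_cph + 100
  rk2 <- ranking_score(m2)
  expect_equal(rk1$score, rk2$score, tolerance = 1e-12)
  # identical metrics for every method -> all scores 0, documented order
  m3 <- toy_metrics(data.frame(method = c("b", "a", "c"),
                               ci = 0.6, mse = 0.2, a1 = 900, a2 = 400))
  rk3 <- ranking_score(m3)
  expect_equal(rk3$score, rep(0, 3))
  expect_equal(rk3$method, c("a", "b", "c"))   # tie-break by method id
  # strict dominance on all four metrics ranks first
  expect_equal(ranking_score(m)$method[1], "a")
  expect_error(ranking_score(m[1:2, ]), "at least 3")
})

test_that("bin counts are averaged per method before standardization", {
  m <- rbind(
    toy_metrics(data.frame(method = "a", ci = c(0.6, 0.8), mse = 0.2,
                           a1 = 900, a2 = 400)),
    toy_metrics(data.frame(method = "b", ci = c(0.7, 0.7), mse = 0.2,
                           a1 = 900, a2 = 400)),
    toy_metrics(data.frame(method = "c", ci = c(0.5, 0.7), mse = 0.2,
                           a1 = 900, a2 = 400)))
  rk <- ranking_score(m)
  expect_equal(rk$cv_cindex[rk$method == "a"], 0.7)
  expect_equal(rk$score[rk$method == "a"], rk$score[rk$method == "b"])
})

test_that("method correlation matrix behaves at the fixed points and under nulls", {
  set.seed(20)
  x <- rnorm(100)
  M <- cbind(m1 = x, m2 = exp(x), m3 = sample(x))
  R <- method_correlation(M)
  expect_equal(diag(R), c(m1 = 1, m2 = 1, m3 = 1))
  expect_equal(R["m1", "m2"], 1)               # monotone transform
  expect_lt(abs(R["m1", "m3"]), 0.25)          # independent permutation
  expect_true(isSymmetric(R))
  Mz <- cbind(M, flat = rep(1, 100))
  expect_warning(Rz <- method_correlation(Mz), "zero-variance")
  expect_equal(unname(Rz["flat", "m1"]), 0)
})

test_that("the robustness screen classifies block-correlation structures exactly", {
  mk <- function(sizes, rho = 0.95) {
    n <- sum(sizes)
    R <- diag(n)
    start <- cumsum(c(1, head(sizes, -1)))
    for (b in seq_along(sizes)) {
      i <- start[b]:(start[b] + sizes[b] - 1)
      R[i, i] <- rho; diag(R) <- 1
    }
    colnames(R) <- rownames(R) <- paste0("m", 1:n)
    R
  }
  mats <- list(all16 = mk(16),            # one 16-block
               block11 = mk(c(11, 5)),    # 11 correlated + 5 singletons
               block12 = mk(c(12, 4)))
  scr <- stable_feature_screen(mats, rs_threshold = 0.8, min_methods = 12)
  expect_equal(scr$stable, c(TRUE, FALSE, TRUE))
  expect_equal(scr$clique_size, c(16L, 11L, 12L))
  # threshold 0 stabilizes everything (every off-diagonal > 0 not required:
  # negative entries fail; use the all-positive matrices here)
  scr0 <- stable_feature_screen(mats, rs_threshold = 0, min_methods = 16)
  expect_true(scr0$stable[1])
  # monotonicity in both thresholds
  for (th in c(0.5, 0.9, 0.96)) {
    s_th <- stable_feature_screen(mats, rs_threshold = th, min_methods = 12)
    expect_true(all(s_th$clique_size <= scr0$clique_size))
  }
  s_strict <- stable_feature_screen(mats, rs_threshold = 0.8, min_methods = 13)
  expect_true(all(s_strict$stable <= scr$stable))
})

test_that("before/after comparison has zero deltas for the full signature and ordered CIs", {
  set.seed(22)
  n <- 90
  x1 <- rnorm(n); x2 <- rnorm(n)
  X <- cbind(a = x1, b = x2, c = rnorm(n))
  cl <- data.frame(os_days = rexp(n, exp(x1) / 300), event = 1L)
  full <- before_after_compare(X, cl, signature = c("a", "b"),
                               stable_subset = c("a", "b"), k = 5, seed = 2)
  expect_equal(attr(full, "delta"), c(d_cindex = 0, d_mse = 0))
  expect_true(all(full$ci_lo <= full$cv_cindex + 1e-12 &
                    full$cv_cindex <= full$ci_hi + 1e-12))
  # dropping the prognostic feature lowers concordance
  drop <- before_after_compare(X, cl, signature = c("a", "b"),
                               stable_subset = "b", k = 5, seed = 2)
  expect_lt(attr(drop, "delta")["d_cindex"], 0)
  # empty stable subset yields the sentinel row
  none <- before_after_compare(X, cl, signature = c("a", "b"),
                               stable_subset = character(0), k = 5, seed = 2)
  expect_true(is.na(none$cv_cindex[none$arm == "after"]))
})

test_that("the three-arm ComBat comparison shares folds and flattens batch effects", {
  set.seed(23)
  n <- 80
  x <- rnorm(n)
  batch <- rep(c("b1", "b2"), each = n / 2)
  noise <- matrix(rnorm(n * 2), n)
  shift <- (batch == "b2") * 2
  Xnn <- cbind(f1 = x + noise[, 1] * 0.3 + shift, f2 = rnorm(n) + shift)
  colnames(Xnn) <- c("s|f1", "s|f2")
  Ximg <- cbind(x + noise[, 1] * 0.3, rnorm(n))
  colnames(Ximg) <- c("s|f1", "s|f2")
  cl <- data.frame(os_days = rexp(n, exp(x) / 300), event = 1L,
                   batch_id = batch, age = rnorm(n, 55, 10),
                   grade = sample(c("III", "IV"), n, TRUE),
                   gender = sample(c("M", "F"), n, TRUE))
  out <- combined_combat_image_in(Xnn, Ximg, cl,
                                  signature = colnames(Xnn), k = 5, seed = 3)
  expect_equal(out$arm, c("combat", "image_in", "combined"))
  expect_true(all(is.finite(out$cv_cindex)))
})
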