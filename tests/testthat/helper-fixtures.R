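# Shared fixtures, built in code and cached for the session.

.fixture_env <- new.env(parent = emptyenv())

# small deterministic phantom cohort reused across tests
tiny_cohort <- function() {
  if (is.null(.fixture_env$tiny)) {
    .fixture_env$tiny <- generate_cohort(cohort_config(
      n_patients = 20, n_batches = 2, sequences = c("T1wce", "FLAIR"),
      grid_shape = c(32, 32, 32), noise_sd = 5, seed = 42))
  }
  .fixture_env$tiny
}

# noiseless cohort: no scanner effect at all (gain 1, offset 0, no bias,
# no noise), all four sequences
clean_cohort <- function() {
  if (is.null(.fixture_env$clean)) {
    .fixture_env$clean <- generate_cohort(cohort_config(
      n_patients = 20, n_batches = 2,
      sequences = c("T1w", "T1wce", "T2w", "FLAIR"),
      grid_shape = c(32, 32, 32), batch_gain_sd = 0, batch_offset_sd = 0,
      bias_field_amplitude = 0, noise_sd = 0, seed = 7))
  }
  .fixture_env$clean
}

# three-plateau volume: csf/gm/wm intensity plateaus with tiny jitter so
# density estimates are well defined
plateau_volume <- function(levels = c(100, 300, 500), sequence = "T1w",
                           jitter_sd = 1, seed = 3) {
  d <- c(24, 24, 24)
  r <- array(0, d)
  ctr <- (d + 1) / 2
  for (k in 1:d[3]) for (j in 1:d[2]) for (i in 1:d[1])
    r[i, j, k] <- sqrt(sum(((c(i, j, k) - ctr) / (0.45 * d))^2))
  brain <- r <= 1
  v <- array(0, d)
  v[brain & r > 0.8] <- levels[1]
  v[brain & r <= 0.8 & r > 0.5] <- levels[2]
  v[brain & r <= 0.5] <- levels[3]
  set.seed(seed)
  v[brain] <- v[brain] + rnorm(sum(brain), 0, jitter_sd)
  list(vol = scan_volume(v, c(2, 2, 2), sequence), brain = brain,
       masks = list(brain = brain * 1,
                    csf = (brain & r > 0.8) * 1,
                    gm = (brain & r <= 0.8 & r > 0.5) * 1,
                    wm = (brain & r <= 0.5) * 1))
}

# brute-force O(n^2) concordance oracle (independent of the implementation)
cindex_oracle <- function(risk, time, event) {
  num <- 0; den <- 0
  n <- length(risk)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    if (event[i] == 1 && time[i] < time[j]) {
      den <- den + 1
      if (risk[i] > risk[j]) num <- num + 1
      else if (risk[i] == risk[j]) num <- num + 0.5
    }
  }
  num / den
}

# brute-force symmetric GLCM by explicit pair enumeration over the 13
# direction offsets
glcm_oracle <- function(labels, ng) {
  d <- dim(labels)
  dirs <- rbind(c(1,0,0), c(0,1,0), c(0,0,1), c(1,1,0), c(1,-1,0),
                c(1,0,1), c(1,0,-1), c(0,1,1), c(0,1,-1), c(1,1,1),
                c(1,1,-1), c(1,-1,1), c(1,-1,-1))
  P <- matrix(0, ng, ng)
  for (dd in seq_len(nrow(dirs))) {
    off <- dirs[dd, ]
    for (k in seq_len(d[3])) for (j in seq_len(d[2])) for (i in seq_len(d[1])) {
      a <- labels[i, j, k]
      if (a == 0) next
      i2 <- i + off[1]; j2 <- j + off[2]; k2 <- k + off[3]
      if (i2 < 1 || i2 > d[1] || j2 < 1 || j2 > d[2] || k2 < 1 || k2 > d[3])
        next
      b <- labels[i2, j2, k2]
      if (b == 0) next
      P[a, b] <- P[a, b] + 1
      P[b, a] <- P[b, a] + 1
    }
  }
  P
}

# simulated feature table with known batch effects and covariate signal
simulate_batch_features <- function(n_per_batch = 50, p = 20, gamma = 2,
                                    delta = 1.5, beta_age = 0.5, seed = 1) {
  set.seed(seed)
  n <- 2 * n_per_batch
  batch <- rep(c("b1", "b2"), each = n_per_batch)
  age <- rnorm(n, 55, 10)
  grade <- sample(c("III", "IV"), n, replace = TRUE)
  gender <- sample(c("M", "F"), n, replace = TRUE)
  # location-scale batch effect on the noise; covariate effect added after
  Y <- matrix(rnorm(n * p), n, p)
  shift <- batch == "b2"
  Y[shift, ] <- Y[shift, ] * delta + gamma
  Y <- Y + beta_age * matrix(scale(age), n, p)
  colnames(Y) <- paste0("f", seq_len(p))
  list(Y = Y,
       clinical = data.frame(patient_id = paste0("p", seq_len(n)),
                             batch_id = batch, age = age, grade = grade,
                             gender = gender,
                             os_days = rexp(n, 1 / 300), event = 1L,
                             stringsAsFactors = FALSE))
}
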