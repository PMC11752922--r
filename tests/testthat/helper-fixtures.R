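# Shared fixtures. Heavy objects (calibrated generator specs) are computed
# once per test run and cached.

.fixture_env <- new.env(parent = emptyenv())

# Fully calibrated Table-style generator specs at production Monte-Carlo
# scale (marginals analytic + MC-verified; copula loadings iterated at 2e5).
calibrated_fixture <- function() {
  if (is.null(.fixture_env$specs)) {
    specs <- table1_specs()
    marginals <- suppressWarnings(
      calibrate_marginals(specs$marginals, n_mc = 2e5, seed = 20260))
    copula <- calibrate_latent(specs$copula, marginals, n_mc = 2e5,
                               seed = 20260)
    .fixture_env$specs <- list(marginals = marginals, copula = copula)
  }
  .fixture_env$specs
}

# Marginals only, cheaper verification draw (enough for mechanistic cohorts).
marginals_fixture <- function() {
  if (is.null(.fixture_env$marginals)) {
    specs <- table1_specs()
    .fixture_env$marginals <- suppressWarnings(
      calibrate_marginals(specs$marginals, n_mc = 2e4, seed = 20261))
  }
  .fixture_env$marginals
}

# A small hand-built schema-valid cohort.
toy_cohort <- function(n = 6, los = NULL) {
  if (is.null(los)) los <- seq(2, length.out = n)
  tibble::tibble(
    age = seq(40, 80, length.out = n), sex = rep_len(c(1, 0), n),
    BMI = seq(20, 30, length.out = n), lactate = seq(1, 4, length.out = n),
    AF = rep_len(c(0, 0, 1), n), SBP = seq(80, 120, length.out = n),
    DBP = seq(45, 60, length.out = n), MBP = seq(55, 75, length.out = n),
    PF = seq(150, 400, length.out = n), GCS = rep_len(c(8, 12, 15), n),
    VASO = rep_len(c(1, 0), n), MV = rep_len(c(0, 1), n),
    UR = seq(500, 2500, length.out = n), Plt = seq(90, 300, length.out = n),
    Bil = seq(0.5, 2, length.out = n), Cr = seq(0.8, 3, length.out = n),
    ICU_LOS = los)
}

# Planted-mechanism cohort with additive and interaction signal, the study
# conditions for ablation and learnability checks.
signal_mechanism <- function() {
  mechanism_spec(
    additive = c(GCS = -1.2, MV = 1.4, PF = -0.9, lactate = 0.5),
    interactions = list(list(features = c("GCS", "MV"), weight = 0.8),
                        list(features = c("PF", "VASO"), weight = -0.6)),
    noise_sd = 0.5)
}

noise_mechanism <- function(noise_sd = 2) {
  mechanism_spec(additive = numeric(), interactions = list(),
                 noise_sd = noise_sd)
}

# Small fast model/training configs for harness tests.
tiny_mconfig <- function(mode = "both", seed = 1) {
  los_config(d = 4, n_heads = 2, ffn_hidden = 8, mode = mode, seed = seed)
}
fast_tconfig <- function(max_epochs = 3, seed = 1) {
  train_config(max_epochs = max_epochs, patience = max_epochs, seed = seed)
}

# Independent type-7 quantile oracle: sort + linear interpolation between
# order statistics, written without stats::quantile.
quantile7_oracle <- function(x, p) {
  x <- sort(x)
  n <- length(x)
  h <- (n - 1) * p + 1
  lo <- floor(h)
  hi <- ceiling(h)
  x[lo] + (h - lo) * (x[hi] - x[lo])
}
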