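# Toy models used throughout: plain R functions of a feature matrix, so the
# Shapley machinery is exercised independently of the transformer.

lin_model <- function(w, a = 0) function(X) a + drop(X %*% w)

test_that("a constant model attributes nothing", {
  f <- function(X) rep(4.77, nrow(X))
  bg <- matrix(rnorm(12), 4, 3, dimnames = list(NULL, c("a", "b", "c")))
  att <- shapley_exact(f, c(a = 1, b = 2, c = 3), bg)
  expect_equal(att$base_value, 4.77)
  expect_equal(unname(att$phi), rep(0, 3))
  expect_equal(att$prediction, 4.77)
})

test_that("exact Shapley recovers the linear-model closed form", {
  set.seed(21)
  w <- c(1.5, -2, 0.5, 3)
  f <- lin_model(w, a = 5)
  bg <- matrix(rnorm(40), 10, 4,
               dimnames = list(NULL, paste0("f", 1:4)))
  x <- rnorm(4); names(x) <- paste0("f", 1:4)
  att <- shapley_exact(f, x, bg)
  expect_equal(unname(att$phi), unname(w * (x - colMeans(bg))),
               tolerance = 1e-9)
  # efficiency: base + sum(phi) = prediction, and prediction = f(x)
  expect_equal(att$base_value + sum(att$phi), att$prediction,
               tolerance = 1e-12)
  expect_equal(att$prediction, 5 + sum(w * x), tolerance = 1e-12)
})

test_that("exact Shapley matches a hand-enumerated 2-feature computation", {
  f <- function(X) X[, 1] * X[, 2]            # interaction-only model
  bg <- matrix(c(0, 2,    # feature 1 values
                 1, 3),   # feature 2 values
               2, 2, dimnames = list(NULL, c("u", "v")))
  x <- c(u = 4, v = 5)
  # hand enumeration: v({}) = mean(0*1, 2*3) = 3; v({u}) = mean(4*1, 4*3) = 8;
  # v({v}) = mean(0*5, 2*5) = 5; v({u,v}) = 20.
  # phi_u = 1/2*(8-3) + 1/2*(20-5) = 10; phi_v = 1/2*(5-3) + 1/2*(20-8) = 7.
  att <- shapley_exact(f, x, bg)
  expect_equal(att$base_value, 3)
  expect_equal(att$prediction, 20)
  expect_equal(unname(att$phi), c(10, 7), tolerance = 1e-12)
})

test_that("a provably ignored feature gets exactly zero attribution", {
  f <- function(X) 2 * X[, 1] - X[, 3]        # column 2 is a dummy
  bg <- matrix(rnorm(30), 10, 3, dimnames = list(NULL, c("a", "dummy", "c")))
  att <- shapley_exact(f, c(a = 1, dummy = 9, c = -1), bg)
  expect_identical(unname(att$phi[2]), 0)
})

test_that("symmetric features receive equal attribution", {
  f <- function(X) X[, 1] + X[, 2] + 0.5 * X[, 1] * X[, 2]
  bgcol <- rnorm(8)
  bg <- cbind(s1 = bgcol, s2 = bgcol)         # identical background columns
  att <- shapley_exact(f, c(s1 = 1.3, s2 = 1.3), bg)
  expect_equal(att$phi[["s1"]], att$phi[["s2"]], tolerance = 1e-12)
})

test_that("sampled Shapley is seeded, efficient, and converges to the oracle", {
  set.seed(31)
  f <- function(X) X[, 1] * X[, 2] - 2 * X[, 3] + X[, 4]^2
  bg <- matrix(rnorm(32), 8, 4, dimnames = list(NULL, paste0("f", 1:4)))
  x <- c(f1 = 1, f2 = -0.5, f3 = 2, f4 = 0.8)
  exact <- shapley_exact(f, x, bg)

  s1 <- shapley_sampled(f, x, bg, n_permutations = 50, seed = 9)
  s2 <- shapley_sampled(f, x, bg, n_permutations = 50, seed = 9)
  expect_identical(s1$phi, s2$phi)
  # efficiency holds by telescoping even at few permutations
  expect_equal(s1$base_value + sum(s1$phi), s1$prediction, tolerance = 1e-12)
  expect_equal(s1$prediction, exact$prediction, tolerance = 1e-12)

  big <- shapley_sampled(f, x, bg, n_permutations = 2000, seed = 10)
  se <- pmax(big$phi_se, 1e-12)
  expect_true(all(abs(big$phi - exact$phi) <= 3 * se + 1e-9))

  # median absolute error shrinks as permutations grow
  errs <- vapply(c(10, 100, 1000), function(np) {
    s <- shapley_sampled(f, x, bg, n_permutations = np, seed = 12)
    median(abs(s$phi - exact$phi))
  }, 1.0)
  expect_true(all(diff(errs) < 0))
})

test_that("importance summaries rank by mean absolute contribution", {
  f <- lin_model(c(3, -1, 0.2))
  bg <- matrix(rnorm(30), 10, 3, dimnames = list(NULL, c("a", "b", "c")))
  atts <- lapply(1:4, function(i) {
    x <- rnorm(3); names(x) <- c("a", "b", "c")
    shapley_exact(f, x, bg)
  })
  imp <- importance_summary(atts)
  expect_equal(imp$mean_abs_phi, sort(imp$mean_abs_phi, decreasing = TRUE))
  expect_equal(nrow(imp), 3)
  # single attribution: ranking by its own |phi|
  one <- importance_summary(atts[1])
  expect_equal(one$mean_abs_phi,
               unname(sort(abs(atts[[1]]$phi), decreasing = TRUE)))
  # duplicating the list does not change the summary
  expect_equal(importance_summary(c(atts, atts)), imp)
  bad <- atts
  names(bad[[2]]$phi) <- c("x", "y", "z")
  expect_error(importance_summary(bad), "disagree")
  expect_s3_class(autoplot(imp), "ggplot")
})

test_that("force-plot export round-trips with the efficiency identity", {
  f <- lin_model(c(2, -1))
  bg <- matrix(rnorm(10), 5, 2, dimnames = list(NULL, c("a", "b")))
  att <- shapley_exact(f, c(a = 0.5, b = 1.5), bg)
  path <- withr::local_tempfile(fileext = ".csv")
  df <- force_export(att, path)
  expect_equal(nrow(df), 2 + 2)               # features + base + prediction
  back <- readr::read_csv(path, show_col_types = FALSE)
  base <- back$value[back$item == "base_value"]
  pred <- back$value[back$item == "prediction"]
  expect_equal(sum(back$phi, na.rm = TRUE), pred - base, tolerance = 1e-9)
})

test_that("the shap background subsample is seeded and bounded", {
  coh <- toy_cohort(30)
  bg <- shap_background(coh, n = 8, seed = 2)
  expect_equal(nrow(bg), 8)
  expect_identical(bg, shap_background(coh, n = 8, seed = 2))
  expect_identical(shap_background(coh, n = 50, seed = 2), coh)
})

test_that("attributions work end to end on a trained model", {
  m <- marginals_fixture()
  coh <- generate_mechanistic(150, m, signal_mechanism(), seed = 18)
  fit <- losformer_train(coh[1:110, ], coh[111:150, ], tiny_mconfig(),
                         fast_tconfig(max_epochs = 2))
  bg <- shap_background(coh[1:110, ], n = 12, seed = 3)
  att <- shapley_sampled(fit, coh[120, ], bg, n_permutations = 20, seed = 4)
  expect_equal(att$base_value + sum(att$phi), att$prediction,
               tolerance = 1e-10)
  expect_equal(att$prediction, predict(fit, coh[120, ]), tolerance = 1e-10)
  expect_named(att$phi, feature_names())
})
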