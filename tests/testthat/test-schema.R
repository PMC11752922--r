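test_that("default schema has the expected structure", {
  sch <- sepsis_schema()
  expect_equal(nrow(sch), 17)
  expect_equal(length(feature_names(sch)), 16)
  expect_equal(sum(sch$role == "target"), 1)
  expect_equal(target_name(sch), "ICU_LOS")
  expect_equal(sch$unit[sch$role == "target"], "days")
  expect_setequal(sch$name[sch$kind == "binary"], c("sex", "AF", "VASO", "MV"))
  expect_equal(sch$kind[sch$name == "GCS"], "integer")
  expect_false(any(duplicated(sch$name)))
  expect_equal(sch$name[1:3], c("age", "sex", "BMI"))
})

test_that("cohort CSV round-trips exactly and coerces binary labels", {
  coh <- toy_cohort(5, los = c(2.25, 3.5, 4.125, 6.875, 1.03125))
  path <- withr::local_tempfile(fileext = ".csv")
  write_cohort(coh, path)
  back <- read_cohort(path)
  expect_identical(as.data.frame(back), as.data.frame(coh))

  # text labels for binaries, shuffled column order
  raw <- coh
  raw$sex <- ifelse(raw$sex == 1, "male", "female")
  raw$MV <- ifelse(raw$MV == 1, "yes", "no")
  raw <- raw[rev(names(raw))]
  readr::write_csv(raw, path)
  back2 <- read_cohort(path)
  expect_equal(names(back2), sepsis_schema()$name)
  expect_identical(back2$sex, coh$sex)
  expect_identical(back2$MV, coh$MV)
})

test_that("cohort validation names the offending row and column", {
  coh <- toy_cohort(4)
  expect_error(validate_cohort(coh[setdiff(names(coh), "GCS")]), "GCS")
  bad <- coh; bad$sex[3] <- "maybe"
  expect_error(validate_cohort(bad), "sex.*row 3|row 3.*sex")
  bad2 <- coh; bad2$age[2] <- NA
  expect_error(validate_cohort(bad2), "age")
  bad3 <- coh; bad3$ICU_LOS[1] <- -2
  expect_error(validate_cohort(bad3), "ICU_LOS")
  bad4 <- coh; bad4$GCS[2] <- 7.4
  expect_error(validate_cohort(bad4), "whole number")
})

test_that("iqr_bounds matches its derived examples", {
  expect_equal(iqr_bounds(rep(4, 10)), c(lower = 4, upper = 4))
  expect_equal(iqr_bounds(1:8), c(lower = -2.5, upper = 11.5))
  expect_equal(iqr_bounds(c(0, 10, 20, 30, 40)), c(lower = -20, upper = 60))
  expect_error(iqr_bounds(1:3), "at least 4")
})

test_that("iqr_bounds agrees with an independent quantile oracle", {
  set.seed(99)
  for (i in 1:200) {
    x <- rnorm(sample(4:40, 1), sd = runif(1, 0.5, 20))
    q1 <- quantile7_oracle(x, 0.25)
    q3 <- quantile7_oracle(x, 0.75)
    expect_equal(iqr_bounds(x),
                 c(lower = q1 - 1.5 * (q3 - q1), upper = q3 + 1.5 * (q3 - q1)),
                 tolerance = 1e-12)
  }
})

test_that("filter_outliers drops exactly the out-of-fence rows", {
  coh <- toy_cohort(5, los = c(2, 3, 4, 5, 100))
  res <- filter_outliers(coh)
  expect_equal(res$report$n_excluded, 1)
  expect_equal(nrow(res$cohort), 4)
  expect_false(100 %in% res$cohort$ICU_LOS)

  inside <- toy_cohort(8, los = seq(2, 9))
  res2 <- filter_outliers(inside)
  expect_equal(res2$report$n_excluded, 0)
  expect_identical(as.data.frame(res2$cohort), as.data.frame(inside))
})

test_that("filter_outliers conserves rows and keeps only in-fence targets", {
  set.seed(7)
  for (i in 1:25) {
    n <- sample(10:80, 1)
    coh <- toy_cohort(n, los = rlnorm(n, meanlog = 1.4, sdlog = 0.6))
    res <- filter_outliers(coh)
    expect_equal(nrow(res$cohort) + res$report$n_excluded, n)
    expect_true(all(res$cohort$ICU_LOS >= res$report$lower_bound))
    expect_true(all(res$cohort$ICU_LOS <= res$report$upper_bound))
  }
})

test_that("standardizer matches hand values and the fit-apply identity", {
  coh <- toy_cohort(3)
  coh$age <- c(1, 2, 3)
  std <- fit_standardizer(coh, columns = "age")
  expect_equal(std$mean, 2)
  expect_equal(std$sd, 1)

  coh$age <- c(10, 20, 15)
  std2 <- fit_standardizer(coh, columns = "age")
  out <- apply_standardizer(coh, std2)
  expect_equal(mean(out$age), 0, tolerance = 1e-12)
  expect_equal(sd(out$age), 1, tolerance = 1e-12)

  # two-point column: z-scores are +/- 1/sqrt(2)
  two <- toy_cohort(2)
  two$BMI <- c(10, 20)
  s <- fit_standardizer(two, columns = "BMI")
  z <- apply_standardizer(two, s)$BMI
  expect_equal(z, c(-1, 1) / sqrt(2), tolerance = 1e-12)

  const <- toy_cohort(4); const$Plt <- rep(100, 4)
  expect_error(fit_standardizer(const, columns = "Plt"), "Plt")
  expect_error(fit_standardizer(toy_cohort(4), columns = "MV"), "binary")
  expect_error(apply_standardizer(two["age"], s), "BMI")
})

test_that("standardizing twice re-centers (not idempotent)", {
  coh <- toy_cohort(5)
  std <- fit_standardizer(coh, columns = "age")
  once <- apply_standardizer(coh, std)
  twice <- apply_standardizer(once, std)
  expect_false(isTRUE(all.equal(once$age, twice$age)))
})

test_that("make_split produces the documented geometry", {
  sp <- make_split(100, seed = 3)
  expect_equal(length(sp$test_indices), 20)
  expect_equal(vapply(sp$folds, length, 1L), rep(20L, 4))

  sp521 <- make_split(521, seed = 1)
  expect_equal(length(sp521$test_indices), 104)
  expect_equal(sort(vapply(sp521$folds, length, 1L), decreasing = TRUE),
               c(105L, 104L, 104L, 104L))

  expect_identical(make_split(57, seed = 9), make_split(57, seed = 9))
  expect_error(make_split(4, k = 4), "at least")
})

test_that("make_split partitions indices exactly across n", {
  for (n in c(10, 11, 23, 57, 100, 263, 521, 600)) {
    sp <- make_split(n, seed = n)
    all_idx <- c(sp$test_indices, unlist(sp$folds))
    expect_equal(sort(all_idx), seq_len(n))
    expect_equal(length(all_idx), n)  # no duplicates given the sort equality
    expect_lte(diff(range(vapply(sp$folds, length, 1L))), 1)
  }
})

test_that("split plans and reports serialize to JSON and back", {
  sp <- make_split(50, seed = 2)
  path <- withr::local_tempfile(fileext = ".json")
  write_plan(sp, path)
  back <- read_split(path)
  expect_equal(back$test_indices, sp$test_indices)
  expect_equal(back$folds, sp$folds)

  rep_path <- withr::local_tempfile(fileext = ".json")
  res <- filter_outliers(toy_cohort(10, los = c(seq(2, 9), 3, 50)))
  write_plan(res$report, rep_path)
  parsed <- jsonlite::read_json(rep_path, simplifyVector = TRUE)
  expect_equal(parsed$n_excluded, res$report$n_excluded)
  expect_equal(parsed$upper_bound, res$report$upper_bound)
})
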