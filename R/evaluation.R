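# Regression metrics, the four-fold cross-validation protocol with a common
# held-out test set, the head-mode ablation suite, the feature-target
# correlation report, and calibration-pair export.

check_lengths <- function(y, yhat) {
  if (length(y) != length(yhat)) {
    stop(sprintf("y and yhat differ in length (%d vs %d)",
                 length(y), length(yhat)), call. = FALSE)
  }
}

#' Coefficient of determination
#'
#' `1 - sum((y - yhat)^2) / sum((y - mean(y))^2)`. Can be negative when the
#' model underperforms the mean predictor.
#'
#' @param y Observed values (not constant, length >= 2).
#' @param yhat Predicted values.
#' @return R-squared.
#' @export
r_squared <- function(y, yhat) {
  check_lengths(y, yhat)
  if (length(y) < 2) stop("need at least 2 observations", call. = FALSE)
  ss_tot <- sum((y - mean(y))^2)
  if (ss_tot == 0) {
    stop("y is constant; R-squared is undefined (zero total variance)",
         call. = FALSE)
  }
  1 - sum((y - yhat)^2) / ss_tot
}

#' Mean absolute error
#' @inheritParams r_squared
#' @return MAE, in the units of `y` (days for LOS).
#' @export
mae <- function(y, yhat) {
  check_lengths(y, yhat)
  mean(abs(y - yhat))
}

#' Root mean squared error
#'
#' The square root of the mean squared difference. (The plain mean squared
#' difference is the MSE; the root is applied so the result is in days.)
#'
#' @inheritParams r_squared
#' @return RMSE, in the units of `y`.
#' @export
rmse <- function(y, yhat) {
  check_lengths(y, yhat)
  sqrt(mean((y - yhat)^2))
}

metric_row <- function(y, yhat) {
  tibble::tibble(r2 = r_squared(y, yhat), mae = mae(y, yhat),
                 rmse = rmse(y, yhat), n = length(y))
}

#' Four-fold cross-validation of the skip-token model
#'
#' Implements the evaluation protocol: 20% of the cohort is held out as a
#' common test set; the remaining pool is split into `k` folds; for each
#' fold, a model is trained on the other `k - 1` folds with that fold as the
#' early-stopping validation set, then evaluated on the common test set.
#' Reported metrics are per-fold test-set R-squared/MAE/RMSE and their
#' across-fold mean and SD.
#'
#' By default each fold's feature standardizer is fitted on that fold's
#' training rows only (no information flows from validation or test rows);
#' `paper_mode = TRUE` fits it on the full cohort instead, mimicking a
#' whole-dataset standardization step.
#'
#' @param data A preprocessed cohort (outliers already filtered).
#' @param mconfig A `los_config`; fold f uses weight-init seed
#'   `mconfig$seed + f - 1`.
#' @param tconfig A `los_train_config`; fold f uses shuffle seed
#'   `tconfig$seed + 1000 * f`.
#' @param split_seed Seed for the split plan.
#' @param schema A `los_schema`.
#' @param test_fraction,k Split geometry (defaults 0.2 and 4).
#' @param paper_mode Fit the standardizer on all rows (leaky, but mirrors
#'   whole-dataset standardization).
#' @param keep_fits Keep the 4 fitted models in the result.
#' @return A `los_cv`: `per_fold` metrics tibble, `summary` (mean/sd per
#'   metric), `split`, `predictions` (test-set predictions per fold), and
#'   optionally `fits`.
#' @export
crossvalidate <- function(data, mconfig = los_config(),
                          tconfig = train_config(), split_seed = 1,
                          schema = sepsis_schema(), test_fraction = 0.2,
                          k = 4, paper_mode = FALSE, keep_fits = FALSE) {
  split <- make_split(nrow(data), test_fraction = test_fraction, k = k,
                      seed = split_seed)
  test <- data[split$test_indices, , drop = FALSE]
  y_test <- test[[target_name(schema)]]
  all_idx <- seq_len(nrow(data))
  per_fold <- list(); preds <- list(); fits <- list()
  for (f in seq_len(k)) {
    val_idx <- split$folds[[f]]
    train_idx <- setdiff(all_idx, c(split$test_indices, val_idx))
    std <- if (paper_mode) fit_standardizer(data, schema) else NULL
    mcf <- mconfig; mcf$seed <- mconfig$seed + f - 1L
    tcf <- tconfig; tcf$seed <- tconfig$seed + 1000L * f
    fit <- losformer_train(data[train_idx, , drop = FALSE],
                           data[val_idx, , drop = FALSE],
                           mcf, tcf, schema = schema, standardizer = std)
    yhat <- predict(fit, test)
    per_fold[[f]] <- dplyr::mutate(metric_row(y_test, yhat), fold = f,
                                   best_epoch = fit$best_epoch,
                                   .before = 1)
    preds[[f]] <- yhat
    if (keep_fits) fits[[f]] <- fit
  }
  per_fold <- dplyr::bind_rows(per_fold)
  summary <- tidyr::pivot_longer(per_fold[c("fold", "r2", "mae", "rmse")],
                                 c("r2", "mae", "rmse"),
                                 names_to = "metric", values_to = "value")
  summary <- dplyr::summarise(dplyr::group_by(summary, .data$metric),
                              mean = mean(.data$value),
                              sd = stats::sd(.data$value), .groups = "drop")
  structure(list(per_fold = per_fold, summary = summary, split = split,
                 predictions = do.call(cbind, preds), y_test = y_test,
                 fits = if (keep_fits) fits else NULL,
                 mconfig = mconfig, tconfig = tconfig),
            class = "los_cv")
}

#' @export
print.los_cv <- function(x, ...) {
  cat(sprintf("<los_cv> %d folds, common test set of %d rows\n",
              nrow(x$per_fold), length(x$y_test)))
  s <- x$summary
  for (m in c("r2", "mae", "rmse")) {
    r <- s[s$metric == m, ]
    cat(sprintf("  %-4s %.3f +/- %.3f\n", m, r$mean, r$sd))
  }
  invisible(x)
}

#' Per-fold metrics of a cross-validation result
#' @param x A `los_cv`.
#' @param ... Unused.
#' @return Tibble of per-fold test-set metrics.
#' @export
tidy.los_cv <- function(x, ...) x$per_fold

#' Across-fold summary of a cross-validation result
#' @param x A `los_cv`.
#' @param ... Unused.
#' @return One-row tibble with mean and sd of each metric.
#' @export
glance.los_cv <- function(x, ...) {
  s <- x$summary
  out <- as.list(stats::setNames(s$mean, s$metric))
  names(out) <- paste0(names(out), "_mean")
  sds <- as.list(stats::setNames(s$sd, paste0(s$metric, "_sd")))
  tibble::as_tibble(c(out, sds))[c("r2_mean", "r2_sd", "mae_mean", "mae_sd",
                                   "rmse_mean", "rmse_sd")]
}

#' Calibration plot of a cross-validation result
#'
#' Observed vs predicted LOS on the common test set, one panel per fold,
#' with the identity line.
#'
#' @param object A `los_cv`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.los_cv <- function(object, ...) {
  k <- ncol(object$predictions)
  df <- tibble::tibble(
    fold = factor(rep(seq_len(k), each = length(object$y_test))),
    observed = rep(object$y_test, k),
    predicted = as.vector(object$predictions))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$observed, y = .data$predicted)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2,
                         colour = "grey50") +
    ggplot2::geom_point(alpha = 0.4, size = 0.8) +
    ggplot2::facet_wrap(~fold, labeller = ggplot2::label_both) +
    ggplot2::labs(x = "Observed ICU LOS (days)",
                  y = "Predicted ICU LOS (days)") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Head-mode ablation suite
#'
#' Cross-validates the model under each head mode (`global_only`: CLS token
#' alone; `local_only`: projected feature tokens alone; `both`: the
#' skip-connected fusion) over a set of seeds. Within a seed all modes share
#' an identical split plan, so the comparison is controlled.
#'
#' @param data A preprocessed cohort.
#' @param mconfig,tconfig Base configurations; seeds are offset per run.
#' @param seeds Integer vector of replicate seeds.
#' @param modes Head modes to compare.
#' @param schema A `los_schema`.
#' @return A `los_ablation`: tibble with one row per (mode, seed) holding
#'   across-fold mean metrics, with a per-mode summary in attribute
#'   `"summary"`.
#' @export
ablation_suite <- function(data, mconfig = los_config(),
                           tconfig = train_config(), seeds = 1:5,
                           modes = c("global_only", "local_only", "both"),
                           schema = sepsis_schema()) {
  if (length(seeds) < 1) stop("need at least one seed", call. = FALSE)
  rows <- list()
  for (s in seeds) {
    for (mode in modes) {
      mcf <- mconfig; mcf$mode <- mode; mcf$seed <- mconfig$seed + 100L * s
      tcf <- tconfig; tcf$seed <- tconfig$seed + 100L * s
      cv <- crossvalidate(data, mcf, tcf, split_seed = s, schema = schema)
      g <- glance(cv)
      rows[[length(rows) + 1]] <- tibble::tibble(
        mode = mode, seed = s, r2 = g$r2_mean, mae = g$mae_mean,
        rmse = g$rmse_mean)
    }
  }
  out <- dplyr::bind_rows(rows)
  summary <- dplyr::summarise(
    dplyr::group_by(out, .data$mode),
    dplyr::across(c("r2", "mae", "rmse"),
                  list(mean = mean, sd = stats::sd, median = stats::median)),
    .groups = "drop")
  structure(out, summary = summary, class = c("los_ablation", class(out)))
}

#' Feature--target correlation report
#'
#' Pearson correlation of every non-target feature with the target (for 0/1
#' binary features this is the point-biserial correlation), with a two-sided
#' p-value from the exact t-transform `t = r * sqrt((n-2)/(1-r^2))` on
#' `n - 2` degrees of freedom. p-values below 0.01 are formatted "< 0.01",
#' matching the conventional table style.
#'
#' @param data A validated cohort (n >= 3).
#' @param schema A `los_schema`.
#' @return Tibble with `feature`, `coefficient`, `p_value`, `p_formatted`.
#' @export
correlation_report <- function(data, schema = sepsis_schema()) {
  n <- nrow(data)
  if (n < 3) stop("need at least 3 rows for a correlation report", call. = FALSE)
  y <- data[[target_name(schema)]]
  purrr::map_dfr(feature_names(schema), function(nm) {
    x <- data[[nm]]
    if (stats::sd(x) == 0 || stats::sd(y) == 0) {
      stop(sprintf("column '%s' (or the target) is constant; correlation undefined",
                   nm), call. = FALSE)
    }
    r <- stats::cor(x, y)
    tval <- r * sqrt((n - 2) / (1 - r^2))
    p <- 2 * stats::pt(-abs(tval), df = n - 2)
    tibble::tibble(feature = nm, coefficient = r, p_value = p,
                   p_formatted = ifelse(p < 0.01, "< 0.01",
                                        sprintf("%.2f", p)))
  })
}

#' Export calibration pairs for plotting
#'
#' Writes one row per prediction: observed, predicted, and the residual from
#' the identity line (predicted - observed), as CSV.
#'
#' @param y Observed LOS (days).
#' @param yhat Predicted LOS (days).
#' @param path Output CSV path.
#' @return The exported tibble, invisibly.
#' @export
calibration_export <- function(y, yhat, path) {
  check_lengths(y, yhat)
  df <- tibble::tibble(observed = y, predicted = yhat,
                       residual = yhat - y)
  readr::write_csv(df, path, progress = FALSE)
  invisible(df)
}

#' Mean-predictor baseline metrics
#'
#' Predicts the training-set mean LOS for every test row. By construction
#' its test R-squared is near zero (exactly zero when test and train means
#' coincide); any useful model should beat it.
#'
#' @param train_data,test_data Cohort tibbles.
#' @param schema A `los_schema`.
#' @return One-row metrics tibble (`r2`, `mae`, `rmse`, `n`).
#' @export
baseline_mean_predictor <- function(train_data, test_data,
                                    schema = sepsis_schema()) {
  tgt <- target_name(schema)
  yhat <- rep(mean(train_data[[tgt]]), nrow(test_data))
  metric_row(test_data[[tgt]], yhat)
}
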