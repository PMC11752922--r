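# Shapley attribution for model predictions: exact enumeration over all
# feature coalitions (the oracle) and a permutation-sampling estimator.
# The value of a coalition S is the marginal expectation: the mean model
# prediction over background rows whose S-features are replaced by the
# explained patient's values.

# Accepts either a prediction function (matrix of raw feature rows ->
# numeric) or a fitted losformer.
as_model_fun <- function(model, schema = sepsis_schema()) {
  if (is.function(model)) return(model)
  if (inherits(model, "losformer")) {
    feats <- feature_names(model$schema)
    return(function(X) {
      colnames(X) <- feats
      predict(model, tibble::as_tibble(X))
    })
  }
  stop("model must be a function or a losformer fit", call. = FALSE)
}

prepare_xbg <- function(x, background, schema) {
  if (is.data.frame(background)) {
    feats <- intersect(feature_names(schema), names(background))
    background <- as.matrix(background[feats])
  }
  if (is.data.frame(x)) x <- unlist(x[colnames(background)])
  x <- as.numeric(x)
  if (length(x) != ncol(background)) {
    stop("x and background disagree on feature count", call. = FALSE)
  }
  if (nrow(background) == 0) stop("background must be non-empty", call. = FALSE)
  list(x = x, bg = background)
}

coalition_value <- function(f, mask_bits, x, bg) {
  X <- bg
  if (any(mask_bits)) {
    X[, mask_bits] <- matrix(x[mask_bits], nrow(bg), sum(mask_bits),
                             byrow = TRUE)
  }
  mean(f(X))
}

#' Exact Shapley attribution by coalition enumeration
#'
#' Enumerates all `2^col` feature coalitions; the value of a coalition is
#' the mean prediction over the background rows with the coalition's
#' features set to the explained row's values. Satisfies efficiency exactly:
#' `base_value + sum(phi) = prediction`.
#'
#' Cost grows as `2^col * nrow(background)` model evaluations, so this is
#' the slow oracle; use [shapley_sampled()] beyond a handful of features.
#'
#' @param model A prediction function (`matrix -> numeric`) or a `losformer`
#'   fit.
#' @param x The patient row to explain: named numeric vector or one-row
#'   cohort tibble (raw day/unit scale).
#' @param background Background cohort (tibble or matrix of feature rows).
#' @param schema A `los_schema`.
#' @return A `los_attribution`: `base_value` (mean background prediction),
#'   `phi` (named per-feature contributions, days), `prediction`,
#'   `n_permutations = NA` (exact), `method = "exact"`.
#' @export
shapley_exact <- function(model, x, background, schema = sepsis_schema()) {
  f <- as_model_fun(model, schema)
  pb <- prepare_xbg(x, background, schema)
  col <- length(pb$x)
  if (col > 16) stop("exact enumeration supports at most 16 features",
                     call. = FALSE)
  bits <- 2^(seq_len(col) - 1)
  n_masks <- 2^col
  v <- numeric(n_masks)
  masks <- lapply(seq_len(n_masks) - 1, function(m) bitwAnd(m, bits) > 0)
  for (m in seq_len(n_masks)) {
    v[m] <- coalition_value(f, masks[[m]], pb$x, pb$bg)
  }
  sizes <- vapply(masks, sum, 1L)
  # Shapley kernel weights by coalition size
  w <- factorial(seq_len(col) - 1) * factorial(col - seq_len(col)) /
    factorial(col)
  phi <- numeric(col)
  for (i in seq_len(col)) {
    without_i <- which(!vapply(masks, `[`, TRUE, i))
    with_i <- without_i + bits[i]
    phi[i] <- sum(w[sizes[without_i] + 1] * (v[with_i] - v[without_i]))
  }
  names(phi) <- colnames(pb$bg)
  new_attribution(base_value = v[1], phi = phi, prediction = v[n_masks],
                  x = stats::setNames(pb$x, colnames(pb$bg)),
                  n_permutations = NA_integer_, seed = NA_integer_,
                  method = "exact")
}

#' Permutation-sampling Shapley attribution
#'
#' Averages marginal contributions over random feature orderings: along one
#' permutation, features are added one at a time and each feature is
#' credited with the change in coalition value it causes. Each permutation's
#' contributions telescope exactly to `prediction - base_value`, so
#' efficiency holds by construction; Monte-Carlo error affects only the
#' allocation among features.
#'
#' @inheritParams shapley_exact
#' @param n_permutations Number of sampled permutations (>= 1).
#' @param seed Integer seed.
#' @return A `los_attribution` with `method = "sampled"` and per-feature
#'   Monte-Carlo standard errors in `phi_se`.
#' @export
shapley_sampled <- function(model, x, background, n_permutations = 200,
                            seed = 1, schema = sepsis_schema()) {
  if (n_permutations < 1) stop("n_permutations must be >= 1", call. = FALSE)
  f <- as_model_fun(model, schema)
  pb <- prepare_xbg(x, background, schema)
  col <- length(pb$x)
  nbg <- nrow(pb$bg)
  base_value <- mean(f(pb$bg))
  perms <- with_seed(seed, replicate(n_permutations, sample.int(col),
                                     simplify = FALSE))
  contrib <- matrix(0, n_permutations, col)
  for (p in seq_len(n_permutations)) {
    perm <- perms[[p]]
    # rows for all col prefixes at once: one model call per permutation
    Xbig <- pb$bg[rep(seq_len(nbg), col), , drop = FALSE]
    mask <- rep(FALSE, col)
    for (j in seq_len(col)) {
      mask[perm[j]] <- TRUE
      rows <- (j - 1) * nbg + seq_len(nbg)
      Xbig[rows, mask] <- matrix(pb$x[mask], nbg, sum(mask), byrow = TRUE)
    }
    vals <- colMeans(matrix(f(Xbig), nbg, col))
    contrib[p, perm] <- diff(c(base_value, vals))
  }
  phi <- colMeans(contrib)
  phi_se <- apply(contrib, 2, stats::sd) / sqrt(n_permutations)
  names(phi) <- names(phi_se) <- colnames(pb$bg)
  new_attribution(base_value = base_value, phi = phi,
                  prediction = base_value + sum(phi),
                  x = stats::setNames(pb$x, colnames(pb$bg)),
                  n_permutations = as.integer(n_permutations),
                  seed = as.integer(seed), method = "sampled",
                  phi_se = phi_se)
}

new_attribution <- function(base_value, phi, prediction, x, n_permutations,
                            seed, method, phi_se = NULL) {
  structure(list(base_value = base_value, phi = phi, prediction = prediction,
                 x = x, n_permutations = n_permutations, seed = seed,
                 method = method, phi_se = phi_se),
            class = "los_attribution")
}

#' @export
print.los_attribution <- function(x, ...) {
  cat(sprintf("<los_attribution> (%s) base %.3f days -> prediction %.3f days\n",
              x$method, x$base_value, x$prediction))
  top <- sort(abs(x$phi), decreasing = TRUE)
  top <- names(top)[seq_len(min(3, length(top)))]
  cat("  largest contributions:",
      paste(sprintf("%s %+0.3f", top, x$phi[top]), collapse = ", "), "\n")
  invisible(x)
}

#' Per-feature contributions of an attribution
#' @param x A `los_attribution`.
#' @param ... Unused.
#' @return Tibble with `feature`, `value` (raw feature value), `phi` (days),
#'   and `phi_se` where available.
#' @export
tidy.los_attribution <- function(x, ...) {
  out <- tibble::tibble(feature = names(x$phi), value = unname(x$x),
                        phi = unname(x$phi))
  if (!is.null(x$phi_se)) out$phi_se <- unname(x$phi_se)
  out
}

#' Mean-|phi| importance summary over a set of attributions
#'
#' @param attributions List of `los_attribution` objects over the same
#'   feature set.
#' @return A `los_importance` tibble with `feature` and `mean_abs_phi`
#'   (days), sorted descending; the ranking is the field order of a SHAP
#'   importance bar plot.
#' @export
importance_summary <- function(attributions) {
  if (length(attributions) == 0) stop("no attributions given", call. = FALSE)
  feats <- names(attributions[[1]]$phi)
  for (a in attributions) {
    if (!identical(names(a$phi), feats)) {
      stop("attributions disagree on feature set", call. = FALSE)
    }
  }
  phis <- do.call(rbind, lapply(attributions, function(a) abs(a$phi)))
  out <- tibble::tibble(feature = feats,
                        mean_abs_phi = unname(colMeans(phis)))
  out <- dplyr::arrange(out, dplyr::desc(.data$mean_abs_phi))
  structure(out, class = c("los_importance", class(out)))
}

#' Importance bar chart
#' @param object A `los_importance`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.los_importance <- function(object, ...) {
  df <- tibble::as_tibble(object)
  df$feature <- factor(df$feature, levels = rev(df$feature))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$mean_abs_phi, y = .data$feature)) +
    ggplot2::geom_col(fill = "#4477AA") +
    ggplot2::labs(x = "mean |Shapley value| (days)", y = NULL) +
    ggplot2::theme_minimal()
}

#' Export force-plot data for one attribution
#'
#' CSV with one record per feature (name, raw value, phi) plus the base
#' value and prediction summary records: `col + 2` rows in total, enough to
#' redraw a force plot.
#'
#' @param attribution A `los_attribution`.
#' @param path Output CSV path.
#' @return The exported tibble, invisibly.
#' @export
force_export <- function(attribution, path) {
  df <- tibble::tibble(
    item = c("base_value", names(attribution$phi), "prediction"),
    value = c(attribution$base_value, unname(attribution$x),
              attribution$prediction),
    phi = c(NA_real_, unname(attribution$phi), NA_real_))
  readr::write_csv(df, path, progress = FALSE, na = "")
  invisible(df)
}

#' Seeded background subsample for Shapley attribution
#'
#' @param data A cohort tibble (typically training rows).
#' @param n Maximum background size (default 64).
#' @param seed Integer seed.
#' @return A tibble of at most `n` rows.
#' @export
shap_background <- function(data, n = 64, seed = 1) {
  if (nrow(data) <= n) return(data)
  idx <- with_seed(seed, sample.int(nrow(data), n))
  data[sort(idx), , drop = FALSE]
}
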