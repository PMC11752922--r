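# Training loop: Adam with staircase exponential learning-rate decay,
# mean-squared-error loss on raw-day targets, per-epoch seeded shuffling,
# validation-MAE early stopping with best-weight restoration.

#' Training configuration
#'
#' @param lr0 Initial learning rate (default 1e-3).
#' @param decay_rate Multiplicative decay factor (default 0.96).
#' @param decay_every Apply the decay every this many steps (default 10).
#' @param decay_unit What a "step" means for the decay schedule: `"epoch"`
#'   (default) or `"optimizer_step"`. With a few hundred training rows at
#'   batch size 32, per-optimizer-step decay collapses the learning rate
#'   within tens of epochs; the per-epoch reading keeps it in a trainable
#'   range and is the default.
#' @param batch_size Minibatch size (default 32).
#' @param max_epochs Epoch cap (default 300).
#' @param patience Early-stopping patience in epochs without validation-MAE
#'   improvement (default 30).
#' @param seed Seed controlling shuffling (weight init is seeded by the
#'   model configuration).
#' @return A `los_train_config` list.
#' @export
train_config <- function(lr0 = 1e-3, decay_rate = 0.96, decay_every = 10,
                         decay_unit = c("epoch", "optimizer_step"),
                         batch_size = 32, max_epochs = 300, patience = 30,
                         seed = 1) {
  decay_unit <- match.arg(decay_unit)
  stopifnot(lr0 > 0, decay_rate > 0, decay_rate <= 1, batch_size >= 1)
  structure(list(lr0 = lr0, decay_rate = decay_rate,
                 decay_every = as.integer(decay_every),
                 decay_unit = decay_unit, batch_size = as.integer(batch_size),
                 max_epochs = as.integer(max_epochs),
                 patience = as.integer(patience), seed = as.integer(seed)),
            class = "los_train_config")
}

#' Learning rate at a given step
#'
#' Staircase schedule: `lr0 * decay_rate ^ floor(step / decay_every)`.
#' `step` is zero-based and counted in the configuration's `decay_unit`.
#'
#' @param step Non-negative step index.
#' @param config A `los_train_config`.
#' @return The learning rate.
#' @examples
#' lr_at(0, train_config())   # 1e-3
#' lr_at(10, train_config())  # 9.6e-4
#' @export
lr_at <- function(step, config = train_config()) {
  stopifnot(all(step >= 0))
  config$lr0 * config$decay_rate^floor(step / config$decay_every)
}

# ---- parameter-tree flattening ------------------------------------------

tree_flatten <- function(x) {
  if (is.list(x)) return(unlist(lapply(x, tree_flatten), use.names = FALSE))
  as.numeric(x)
}

tree_unflatten <- function(vec, skeleton) {
  pos <- 0L
  walk <- function(s) {
    if (is.list(s)) return(lapply(s, walk))
    n <- length(s)
    out <- vec[(pos + 1L):(pos + n)]
    pos <<- pos + n
    if (!is.null(dim(s))) dim(out) <- dim(s)
    out
  }
  walk(skeleton)
}

cohort_xy <- function(data, schema) {
  feats <- feature_names(schema)
  list(X = as.matrix(data[feats]), y = data[[target_name(schema)]])
}

#' Train the skip-token transformer
#'
#' Minimizes mean-squared error on raw-day LOS targets with Adam and the
#' staircase learning-rate schedule of [lr_at()]. Rows are reshuffled every
#' epoch (seeded); validation MAE is tracked per epoch; training stops after
#' `patience` epochs without improvement and the best-validation weights are
#' restored. A trailing minibatch of fewer than 2 rows is dropped (batch
#' normalization needs at least 2 rows).
#'
#' @param train_data,val_data Cohort tibbles on the raw day scale.
#' @param mconfig A `los_config`.
#' @param tconfig A `los_train_config`.
#' @param schema A `los_schema`.
#' @param standardizer A fitted `los_standardizer`, or `NULL` (default) to
#'   fit one on `train_data`. Features are standardized internally; the
#'   target is never standardized, so errors are in days.
#' @param verbose Print per-epoch progress.
#' @return A `losformer` fit: `params` (best weights), `history` (per-epoch
#'   tibble of train loss and validation MAE), `best_epoch`, `lr_trace`,
#'   `standardizer`, and the configurations.
#' @export
losformer_train <- function(train_data, val_data, mconfig = los_config(),
                            tconfig = train_config(),
                            schema = sepsis_schema(), standardizer = NULL,
                            verbose = FALSE) {
  if (nrow(train_data) == 0 || nrow(val_data) == 0) {
    stop("training and validation sets must be non-empty", call. = FALSE)
  }
  if (is.null(standardizer)) {
    standardizer <- fit_standardizer(train_data, schema)
  }
  tr <- cohort_xy(apply_standardizer(train_data, standardizer), schema)
  va <- cohort_xy(apply_standardizer(val_data, standardizer), schema)
  n <- nrow(tr$X)

  params <- init_params(mconfig)
  skel <- params$trainable
  theta <- tree_flatten(skel)
  m <- numeric(length(theta)); v <- numeric(length(theta))
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8

  best_params <- params; best_mae <- Inf; best_epoch <- 0L
  history <- list(); lr_trace <- numeric(0)
  global_step <- 0L; stall <- 0L

  for (epoch in seq_len(tconfig$max_epochs)) {
    order_idx <- with_seed(tconfig$seed + epoch, sample.int(n))
    losses <- numeric(0)
    for (start in seq(1L, n, by = tconfig$batch_size)) {
      idx <- order_idx[start:min(start + tconfig$batch_size - 1L, n)]
      if (length(idx) < 2) next
      lr <- if (tconfig$decay_unit == "epoch") {
        lr_at(epoch - 1L, tconfig)
      } else {
        lr_at(global_step, tconfig)
      }
      fw <- forward_pass(params, tr$X[idx, , drop = FALSE], training = TRUE)
      params <- fw$params                    # carries updated BN statistics
      resid <- fw$pred - tr$y[idx]
      loss <- mean(resid^2)
      if (!is.finite(loss)) {
        stop(sprintf("non-finite training loss at epoch %d", epoch),
             call. = FALSE)
      }
      g <- tree_flatten(backward_pass(params, fw$cache,
                                      2 * resid / length(idx)))
      global_step <- global_step + 1L
      m <- b1 * m + (1 - b1) * g
      v <- b2 * v + (1 - b2) * g^2
      mhat <- m / (1 - b1^global_step)
      vhat <- v / (1 - b2^global_step)
      theta <- tree_flatten(params$trainable) - lr * mhat / (sqrt(vhat) + eps)
      params$trainable <- tree_unflatten(theta, skel)
      losses <- c(losses, loss)
      lr_trace <- c(lr_trace, lr)
    }
    val_mae <- mean(abs(predict_batch(va$X, params) - va$y))
    history[[epoch]] <- tibble::tibble(epoch = epoch,
                                       train_loss = mean(losses),
                                       val_mae = val_mae)
    if (verbose) {
      message(sprintf("epoch %3d  loss %.4f  val MAE %.4f", epoch,
                      mean(losses), val_mae))
    }
    if (val_mae < best_mae - 1e-12) {
      best_mae <- val_mae; best_epoch <- epoch; best_params <- params
      stall <- 0L
    } else {
      stall <- stall + 1L
      if (stall >= tconfig$patience) break
    }
  }

  structure(list(params = best_params,
                 history = dplyr::bind_rows(history),
                 best_epoch = best_epoch, best_val_mae = best_mae,
                 lr_trace = lr_trace, standardizer = standardizer,
                 mconfig = mconfig, tconfig = tconfig, schema = schema),
            class = "losformer")
}

#' Predict ICU LOS from a fitted model
#'
#' @param object A `losformer` fit.
#' @param newdata A cohort tibble (raw day scale); the fit's stored
#'   standardizer is applied to the features.
#' @param ... Unused.
#' @return Numeric vector of predicted LOS in days.
#' @export
predict.losformer <- function(object, newdata, ...) {
  X <- cohort_xy(apply_standardizer(newdata, object$standardizer),
                 object$schema)$X
  predict_batch(X, object$params)
}

#' @export
print.losformer <- function(x, ...) {
  cat(sprintf("<losformer> mode=%s d=%d heads=%d blocks=%d (%d parameters)\n",
              x$mconfig$mode, x$mconfig$d, x$mconfig$n_heads,
              x$mconfig$n_blocks, n_parameters(x$mconfig)))
  if (is.null(x$history)) {
    cat(sprintf("  restored from checkpoint; best epoch %d\n", x$best_epoch))
  } else {
    cat(sprintf("  trained %d epoch(s); best epoch %d, validation MAE %.4f days\n",
                nrow(x$history), x$best_epoch, x$best_val_mae))
  }
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Per-epoch training history of a fit
#' @param x A `losformer` fit.
#' @param ... Unused.
#' @return Tibble with columns `epoch`, `train_loss`, `val_mae`.
#' @export
tidy.losformer <- function(x, ...) x$history

#' One-row summary of a fit
#' @param x A `losformer` fit.
#' @param ... Unused.
#' @return Tibble with `best_epoch`, `best_val_mae`, `n_epochs`,
#'   `n_parameters`, `mode`.
#' @export
glance.losformer <- function(x, ...) {
  tibble::tibble(best_epoch = x$best_epoch, best_val_mae = x$best_val_mae,
                 n_epochs = if (is.null(x$history)) NA_integer_
                            else nrow(x$history),
                 n_parameters = n_parameters(x$mconfig),
                 mode = x$mconfig$mode)
}

#' Save model parameters to a portable JSON checkpoint
#'
#' @param object A `losformer` fit or `los_params`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
save_model <- function(object, path) {
  if (inherits(object, "losformer")) {
    payload <- list(kind = "losformer_fit",
                    params = serialize_params(object$params),
                    standardizer = unclass(object$standardizer),
                    best_epoch = object$best_epoch,
                    tconfig = unclass(object$tconfig))
  } else {
    payload <- list(kind = "losformer_params",
                    params = serialize_params(object))
  }
  payload$format_version <- 1L
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns")
  invisible(path)
}

serialize_params <- function(params) {
  list(config = unclass(params$config),
       theta = tree_flatten(params$trainable),
       bn = params$bn)
}

#' Load a checkpoint written by [save_model()]
#' @param path Checkpoint path.
#' @return A `losformer` fit or `los_params`, matching what was saved.
#' @export
load_model <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  cfg <- do.call(los_config, x$params$config[c("col", "d", "n_heads",
                                               "n_blocks", "ffn_hidden",
                                               "mode", "shared_tokenizer",
                                               "seed")])
  params <- init_params(cfg)
  params$trainable <- tree_unflatten(as.numeric(x$params$theta),
                                     params$trainable)
  params$bn <- lapply(x$params$bn, as.numeric)
  if (identical(x$kind, "losformer_params")) return(params)
  std <- tibble::as_tibble(x$standardizer)
  class(std) <- c("los_standardizer", class(std))
  structure(list(params = params, history = NULL,
                 best_epoch = x$best_epoch, best_val_mae = NA_real_,
                 lr_trace = NULL, standardizer = std, mconfig = cfg,
                 tconfig = do.call(train_config, x$tconfig),
                 schema = sepsis_schema()),
            class = "losformer")
}
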