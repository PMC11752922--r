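# The skip-token transformer regressor.
#
# Architecture: input batch norm -> per-feature affine tokenizer with a
# zero-initialized trainable CLS token -> multi-head self-attention encoder
# block(s) (post-norm, residual, ReLU FFN) -> batch norm over all token
# activations -> skip-connected head fusing the CLS token (global) with a
# dense projection of the flattened feature tokens (local) -> 1-unit output.
#
# Forward and backward passes are written directly in R matrix algebra; the
# token batch is laid out as a (B*T) x d matrix with position-major row
# blocks (rows (t-1)*B + 1..B hold token t for the whole batch, t = 1 being
# the CLS position).

.bn_eps <- 1e-5
.ln_eps <- 1e-5

#' Model configuration
#'
#' @param col Number of input features (default 16).
#' @param d Embedding dimension (default 40; must be divisible by `n_heads`).
#' @param n_heads Number of attention heads (default 5).
#' @param n_blocks Number of encoder blocks (default 1).
#' @param ffn_hidden Hidden width of the position-wise feedforward network
#'   (default `4 * d`).
#' @param mode Head mode: `"both"` fuses CLS and feature tokens,
#'   `"global_only"` uses the CLS token alone, `"local_only"` the feature
#'   tokens alone. These are the three ablation settings.
#' @param shared_tokenizer If `TRUE`, all feature positions share one
#'   scalar-to-d embedding map instead of per-position maps.
#' @param seed Seed for weight initialization.
#' @return A `los_config` list.
#' @export
los_config <- function(col = 16, d = 40, n_heads = 5, n_blocks = 1,
                       ffn_hidden = 4 * d,
                       mode = c("both", "global_only", "local_only"),
                       shared_tokenizer = FALSE, seed = 1) {
  mode <- match.arg(mode)
  if (d %% n_heads != 0) {
    stop(sprintf("embedding dimension d = %d is not divisible by n_heads = %d",
                 d, n_heads), call. = FALSE)
  }
  if (d < n_heads) stop("d must be >= n_heads", call. = FALSE)
  structure(list(col = as.integer(col), d = as.integer(d),
                 n_heads = as.integer(n_heads), n_blocks = as.integer(n_blocks),
                 ffn_hidden = as.integer(ffn_hidden), mode = mode,
                 shared_tokenizer = shared_tokenizer, seed = as.integer(seed)),
            class = "los_config")
}

glorot <- function(nr, nc) {
  lim <- sqrt(6 / (nr + nc))
  matrix(stats::runif(nr * nc, -lim, lim), nr, nc)
}

#' Initialize model parameters
#'
#' All weights are drawn from a seed-deterministic Glorot-uniform
#' initializer, except the CLS token, which is exactly zero (zero
#' initialization of the CLS embedding stabilizes early training), and batch
#' norm, which starts at the identity (gamma 1, beta 0, running mean 0,
#' running variance 1).
#'
#' @param config A `los_config`.
#' @return A `los_params` list with elements `trainable` (weight tree),
#'   `bn` (running batch-norm statistics) and `config`.
#' @export
init_params <- function(config) {
  col <- config$col; d <- config$d; h <- config$ffn_hidden
  n_emb <- if (config$shared_tokenizer) 1L else col
  trainable <- with_seed(config$seed, {
    blocks <- lapply(seq_len(config$n_blocks), function(i) {
      list(Wq = glorot(d, d), bq = numeric(d),
           Wk = glorot(d, d), bk = numeric(d),
           Wv = glorot(d, d), bv = numeric(d),
           Wo = glorot(d, d), bo = numeric(d),
           ln1g = rep(1, d), ln1b = numeric(d),
           W1 = glorot(d, h), b1 = numeric(h),
           W2 = glorot(h, d), b2 = numeric(d),
           ln2g = rep(1, d), ln2b = numeric(d))
    })
    list(bn_in_g = rep(1, col), bn_in_b = numeric(col),
         cls = numeric(d),                    # zero-initialized CLS token
         Wemb = glorot(n_emb, d), bemb = matrix(0, n_emb, d),
         blocks = blocks,
         bn_post_g = rep(1, (col + 1) * d), bn_post_b = numeric((col + 1) * d),
         Wf = glorot(col * d, d), bf = numeric(d),
         Wt = glorot(d, d), bt = numeric(d),
         Wh = glorot(d, 1), bh = 0)
  })
  structure(list(trainable = trainable,
                 bn = list(in_mean = numeric(col), in_var = rep(1, col),
                           post_mean = numeric((col + 1) * d),
                           post_var = rep(1, (col + 1) * d)),
                 config = config),
            class = "los_params")
}

#' Count trainable parameters of a configuration
#'
#' The count is `2*col` (input BN) `+ d` (CLS) `+ 2*n_emb*d` (tokenizer)
#' `+ n_blocks * (4*(d^2+d) + 2*d*h + h + d + 4*d)` (encoder)
#' `+ 2*(col+1)*d` (post BN) `+ col*d*d + d` (local fusion) `+ d^2 + d`
#' (skip dense) `+ d + 1` (head), with `n_emb = 1` under a shared tokenizer
#' and `col` otherwise.
#'
#' @param config A `los_config`.
#' @return Integer parameter count.
#' @export
n_parameters <- function(config) {
  col <- config$col; d <- config$d; h <- config$ffn_hidden
  n_emb <- if (config$shared_tokenizer) 1L else col
  per_block <- 4 * (d * d + d) + (d * h + h) + (h * d + d) + 4 * d
  2 * col + d + 2 * n_emb * d + config$n_blocks * per_block +
    2 * (col + 1) * d + (col * d * d + d) + (d * d + d) + (d + 1)
}

# row-block index helper: rows of token t (1-based position incl. CLS at 1)
tok_rows <- function(t, B) (t - 1L) * B + seq_len(B)

# add a row vector to every row / scale every column: rep(each=) avoids
# sweep()'s dispatch and aperm overhead in the training hot path
add_rowvec <- function(M, v) M + rep(v, each = nrow(M))
mul_cols <- function(M, v) M * rep(v, each = nrow(M))
sub_cols <- function(M, v) M - rep(v, each = nrow(M))

# ---- forward pass --------------------------------------------------------

# X: B x col matrix of standardized features. Returns list(pred, cache).
forward_pass <- function(params, X, training = FALSE, update_bn = training,
                         bn_momentum = 0.9) {
  cfg <- params$config
  tr <- params$trainable
  col <- cfg$col; d <- cfg$d; Tn <- col + 1L
  B <- nrow(X)
  if (ncol(X) != col) {
    stop(sprintf("expected %d feature columns, got %d", col, ncol(X)),
         call. = FALSE)
  }
  cache <- list(B = B, training = training)

  # input batch norm (per feature channel)
  if (training) {
    mu <- colMeans(X)
    vr <- colMeans(X^2) - mu^2
  } else {
    mu <- params$bn$in_mean; vr <- params$bn$in_var
  }
  inv_sd <- 1 / sqrt(vr + .bn_eps)
  Xhat <- mul_cols(sub_cols(X, mu), inv_sd)
  Xbn <- add_rowvec(mul_cols(Xhat, tr$bn_in_g), tr$bn_in_b)
  cache$X <- X; cache$Xhat <- Xhat; cache$in_inv_sd <- inv_sd
  if (update_bn) {
    params$bn$in_mean <- bn_momentum * params$bn$in_mean + (1 - bn_momentum) * mu
    params$bn$in_var <- bn_momentum * params$bn$in_var + (1 - bn_momentum) * vr
  }

  # tokenizer: CLS at position 1, feature i at position i+1
  Z <- matrix(0, B * Tn, d)
  Z[tok_rows(1L, B), ] <- rep(tr$cls, each = B)
  for (i in seq_len(col)) {
    j <- if (cfg$shared_tokenizer) 1L else i
    Z[tok_rows(i + 1L, B), ] <-
      add_rowvec(outer(Xbn[, i], tr$Wemb[j, ]), tr$bemb[j, ])
  }
  cache$Xbn <- Xbn

  # encoder blocks. Attention is evaluated for the whole batch at once:
  # with the position-major layout, column k of the (B*Tn) x d token matrix
  # reinterprets as a B x Tn matrix, so per-sample score matrices stack into
  # a B x Tn^2 matrix (score of query i, key j in column (i-1)*Tn + j) and
  # the softmax/context reductions become indicator-matrix products.
  heads <- cfg$n_heads; dk <- d %/% heads
  scale <- 1 / sqrt(dk)
  rep_q <- rep(seq_len(Tn), each = Tn)    # query index i per score column
  rep_k <- rep(seq_len(Tn), times = Tn)   # key index j per score column
  J_q <- matrix(0, Tn * Tn, Tn); J_q[cbind(seq_len(Tn * Tn), rep_q)] <- 1
  J_k <- matrix(0, Tn * Tn, Tn); J_k[cbind(seq_len(Tn * Tn), rep_k)] <- 1
  cache$blocks <- vector("list", cfg$n_blocks)
  for (l in seq_len(cfg$n_blocks)) {
    bp <- tr$blocks[[l]]
    bc <- list(Zin = Z)
    QKV <- add_rowvec(Z %*% cbind(bp$Wq, bp$Wk, bp$Wv),
                      c(bp$bq, bp$bk, bp$bv))
    Q <- QKV[, seq_len(d), drop = FALSE]
    K <- QKV[, d + seq_len(d), drop = FALSE]
    V <- QKV[, 2L * d + seq_len(d), drop = FALSE]
    H <- matrix(0, B * Tn, d)
    A_heads <- vector("list", heads)
    for (hh in seq_len(heads)) {
      cols <- (hh - 1L) * dk + seq_len(dk)
      S2 <- matrix(0, B, Tn * Tn)
      for (k in cols) {
        Qm <- matrix(Q[, k], B, Tn)
        Km <- matrix(K[, k], B, Tn)
        S2 <- S2 + Qm[, rep_q, drop = FALSE] * Km[, rep_k, drop = FALSE]
      }
      S2 <- S2 * scale
      E <- exp(S2 - max(S2))
      den <- E %*% J_q
      A2 <- E / den[, rep_q, drop = FALSE]
      for (k in cols) {
        Vm <- matrix(V[, k], B, Tn)
        H[, k] <- (A2 * Vm[, rep_k, drop = FALSE]) %*% J_q
      }
      A_heads[[hh]] <- A2
    }
    O <- add_rowvec(H %*% bp$Wo, bp$bo)
    R1 <- Z + O
    # layer norm 1 (per token over d)
    m1 <- rowMeans(R1)
    c1 <- R1 - m1
    v1 <- rowMeans(c1^2)
    is1 <- 1 / sqrt(v1 + .ln_eps)
    N1 <- c1 * is1
    Z1 <- add_rowvec(mul_cols(N1, bp$ln1g), bp$ln1b)
    # feedforward
    U <- add_rowvec(Z1 %*% bp$W1, bp$b1)
    Ur <- pmax(U, 0)
    Fo <- add_rowvec(Ur %*% bp$W2, bp$b2)
    R2 <- Z1 + Fo
    m2 <- rowMeans(R2)
    c2 <- R2 - m2
    v2 <- rowMeans(c2^2)
    is2 <- 1 / sqrt(v2 + .ln_eps)
    N2 <- c2 * is2
    Z2 <- add_rowvec(mul_cols(N2, bp$ln2g), bp$ln2b)
    bc$Q <- Q; bc$K <- K; bc$V <- V; bc$A <- A_heads; bc$H <- H
    bc$N1 <- N1; bc$is1 <- is1; bc$Z1 <- Z1; bc$U <- U; bc$Ur <- Ur
    bc$N2 <- N2; bc$is2 <- is2
    cache$blocks[[l]] <- bc
    Z <- Z2
  }

  # reshape to B x (Tn*d): column (t-1)*d + k holds token t, dim k
  M <- matrix(0, B, Tn * d)
  for (t in seq_len(Tn)) {
    M[, (t - 1L) * d + seq_len(d)] <- Z[tok_rows(t, B), , drop = FALSE]
  }
  # post-encoder batch norm, each of the Tn*d activations its own channel
  if (training) {
    pmu <- colMeans(M)
    pvr <- colMeans(M^2) - pmu^2
  } else {
    pmu <- params$bn$post_mean; pvr <- params$bn$post_var
  }
  pinv <- 1 / sqrt(pvr + .bn_eps)
  Mhat <- mul_cols(sub_cols(M, pmu), pinv)
  Mbn <- add_rowvec(mul_cols(Mhat, tr$bn_post_g), tr$bn_post_b)
  cache$Mhat <- Mhat; cache$post_inv_sd <- pinv
  if (update_bn) {
    params$bn$post_mean <- bn_momentum * params$bn$post_mean + (1 - bn_momentum) * pmu
    params$bn$post_var <- bn_momentum * params$bn$post_var + (1 - bn_momentum) * pvr
  }

  CLS <- Mbn[, seq_len(d), drop = FALSE]
  Fp <- Mbn[, (d + 1L):(Tn * d), drop = FALSE]   # flattened feature tokens
  f <- add_rowvec(Fp %*% tr$Wf, tr$bf)
  Sv <- switch(cfg$mode,
               both = CLS + f,
               global_only = CLS,
               local_only = f)
  Tsc <- add_rowvec(Sv %*% tr$Wt, tr$bt)
  pred <- drop(Tsc %*% tr$Wh) + tr$bh
  cache$CLS <- CLS; cache$Fp <- Fp; cache$f <- f; cache$Sv <- Sv; cache$Tsc <- Tsc
  list(pred = pred, cache = cache, params = params)
}

# ---- backward pass -------------------------------------------------------

# dpred: vector length B of dL/dpred. Returns gradient tree matching
# params$trainable. Assumes the cache came from a training-mode forward.
backward_pass <- function(params, cache, dpred) {
  cfg <- params$config
  tr <- params$trainable
  col <- cfg$col; d <- cfg$d; Tn <- col + 1L
  B <- cache$B
  g <- list()

  dTsc <- outer(dpred, drop(tr$Wh))
  g$Wh <- cbind(drop(crossprod(cache$Tsc, dpred)))
  g$bh <- sum(dpred)
  dSv <- tcrossprod(dTsc, tr$Wt)
  g$Wt <- crossprod(cache$Sv, dTsc)
  g$bt <- colSums(dTsc)

  dCLS <- matrix(0, B, d); df <- matrix(0, B, d)
  if (cfg$mode == "both") { dCLS <- dSv; df <- dSv }
  if (cfg$mode == "global_only") dCLS <- dSv
  if (cfg$mode == "local_only") df <- dSv
  g$Wf <- crossprod(cache$Fp, df)
  g$bf <- colSums(df)
  dFp <- tcrossprod(df, tr$Wf)
  dMbn <- cbind(dCLS, dFp)

  # post batch norm backward (training statistics)
  g$bn_post_g <- colSums(dMbn * cache$Mhat)
  g$bn_post_b <- colSums(dMbn)
  dMhat <- mul_cols(dMbn, tr$bn_post_g)
  dM <- mul_cols(sub_cols(dMhat, colMeans(dMhat)) -
                   cache$Mhat * rep(colMeans(dMhat * cache$Mhat), each = B),
                 cache$post_inv_sd)

  # back to token layout
  dZ <- matrix(0, B * Tn, d)
  for (t in seq_len(Tn)) {
    dZ[tok_rows(t, B), ] <- dM[, (t - 1L) * d + seq_len(d), drop = FALSE]
  }

  heads <- cfg$n_heads; dk <- d %/% heads
  scale <- 1 / sqrt(dk)
  rep_q <- rep(seq_len(Tn), each = Tn)
  rep_k <- rep(seq_len(Tn), times = Tn)
  J_q <- matrix(0, Tn * Tn, Tn); J_q[cbind(seq_len(Tn * Tn), rep_q)] <- 1
  J_k <- matrix(0, Tn * Tn, Tn); J_k[cbind(seq_len(Tn * Tn), rep_k)] <- 1
  g$blocks <- vector("list", cfg$n_blocks)
  for (l in rev(seq_len(cfg$n_blocks))) {
    bp <- tr$blocks[[l]]
    bc <- cache$blocks[[l]]
    gb <- list()
    # layer norm 2 backward
    gb$ln2g <- colSums(dZ * bc$N2)
    gb$ln2b <- colSums(dZ)
    dN2 <- mul_cols(dZ, bp$ln2g)
    dR2 <- (dN2 - rowMeans(dN2) - bc$N2 * rowMeans(dN2 * bc$N2)) * bc$is2
    # FFN backward
    dFo <- dR2
    gb$W2 <- crossprod(bc$Ur, dFo)
    gb$b2 <- colSums(dFo)
    dUr <- tcrossprod(dFo, bp$W2)
    dU <- dUr * (bc$U > 0)
    gb$W1 <- crossprod(bc$Z1, dU)
    gb$b1 <- colSums(dU)
    dZ1 <- dR2 + tcrossprod(dU, bp$W1)
    # layer norm 1 backward
    gb$ln1g <- colSums(dZ1 * bc$N1)
    gb$ln1b <- colSums(dZ1)
    dN1 <- mul_cols(dZ1, bp$ln1g)
    dR1 <- (dN1 - rowMeans(dN1) - bc$N1 * rowMeans(dN1 * bc$N1)) * bc$is1
    # attention backward
    dO <- dR1
    gb$Wo <- crossprod(bc$H, dO)
    gb$bo <- colSums(dO)
    dH <- tcrossprod(dO, bp$Wo)
    dQ <- matrix(0, B * Tn, d)
    dK <- matrix(0, B * Tn, d)
    dV <- matrix(0, B * Tn, d)
    for (hh in seq_len(heads)) {
      cols <- (hh - 1L) * dk + seq_len(dk)
      A2 <- bc$A[[hh]]
      dA2 <- matrix(0, B, Tn * Tn)
      for (k in cols) {
        dHm <- matrix(dH[, k], B, Tn)
        Vm <- matrix(bc$V[, k], B, Tn)
        dA2 <- dA2 + dHm[, rep_q, drop = FALSE] * Vm[, rep_k, drop = FALSE]
        dV[, k] <- (A2 * dHm[, rep_q, drop = FALSE]) %*% J_k
      }
      srow <- (dA2 * A2) %*% J_q
      dS2 <- A2 * (dA2 - srow[, rep_q, drop = FALSE])
      for (k in cols) {
        Km <- matrix(bc$K[, k], B, Tn)
        Qm <- matrix(bc$Q[, k], B, Tn)
        dQ[, k] <- (dS2 * Km[, rep_k, drop = FALSE]) %*% J_q * scale
        dK[, k] <- (dS2 * Qm[, rep_q, drop = FALSE]) %*% J_k * scale
      }
    }
    Zin <- bc$Zin
    gb$Wq <- crossprod(Zin, dQ); gb$bq <- colSums(dQ)
    gb$Wk <- crossprod(Zin, dK); gb$bk <- colSums(dK)
    gb$Wv <- crossprod(Zin, dV); gb$bv <- colSums(dV)
    dZ <- dR1 + tcrossprod(dQ, bp$Wq) + tcrossprod(dK, bp$Wk) +
      tcrossprod(dV, bp$Wv)
    g$blocks[[l]] <- gb[c("Wq", "bq", "Wk", "bk", "Wv", "bv", "Wo", "bo",
                          "ln1g", "ln1b", "W1", "b1", "W2", "b2",
                          "ln2g", "ln2b")]
  }

  # tokenizer backward
  g$cls <- colSums(dZ[tok_rows(1L, B), , drop = FALSE])
  n_emb <- if (cfg$shared_tokenizer) 1L else col
  g$Wemb <- matrix(0, n_emb, d)
  g$bemb <- matrix(0, n_emb, d)
  dXbn <- matrix(0, B, col)
  for (i in seq_len(col)) {
    j <- if (cfg$shared_tokenizer) 1L else i
    dZt <- dZ[tok_rows(i + 1L, B), , drop = FALSE]
    g$Wemb[j, ] <- g$Wemb[j, ] + drop(crossprod(dZt, cache$Xbn[, i]))
    g$bemb[j, ] <- g$bemb[j, ] + colSums(dZt)
    wj <- if (cfg$shared_tokenizer) tr$Wemb[1L, ] else tr$Wemb[i, ]
    dXbn[, i] <- dZt %*% wj
  }

  # input batch norm backward
  g$bn_in_g <- colSums(dXbn * cache$Xhat)
  g$bn_in_b <- colSums(dXbn)
  # (gradient w.r.t. raw inputs not needed)
  g[c("bn_in_g", "bn_in_b", "cls", "Wemb", "bemb", "blocks", "bn_post_g",
      "bn_post_b", "Wf", "bf", "Wt", "bt", "Wh", "bh")]
}

# ---- user-facing single-sample views ------------------------------------

#' Tokenize one standardized feature vector
#'
#' Applies the per-position affine embedding: feature i becomes
#' `x_i * W_i + b_i` (a d-vector) and the zero-initialized trainable CLS
#' vector is prepended at position 1, giving a `(col+1) x d` token matrix.
#' Input batch normalization is not applied here; see [predict_batch()] for
#' the full composition.
#'
#' @param x Numeric vector of length `col` (standardized features).
#' @param params A `los_params`.
#' @return A `(col+1) x d` token matrix; row 1 is the CLS token.
#' @export
embed_tokens <- function(x, params) {
  cfg <- params$config
  if (length(x) != cfg$col) {
    stop(sprintf("expected %d features, got %d", cfg$col, length(x)),
         call. = FALSE)
  }
  tr <- params$trainable
  out <- matrix(0, cfg$col + 1L, cfg$d)
  out[1L, ] <- tr$cls
  for (i in seq_len(cfg$col)) {
    j <- if (cfg$shared_tokenizer) 1L else i
    out[i + 1L, ] <- x[i] * tr$Wemb[j, ] + tr$bemb[j, ]
  }
  out
}

#' Run the attention encoder block(s) on one token matrix
#'
#' Standard post-norm transformer encoder: multi-head scaled dot-product
#' self-attention (`softmax(Q K' / sqrt(dk)) V`, heads concatenated and
#' projected), residual + layer norm, position-wise ReLU feedforward,
#' residual + layer norm. Shape `(col+1) x d` is preserved.
#'
#' @param tokens A `(col+1) x d` token matrix.
#' @param params A `los_params`.
#' @param return_attention If `TRUE`, attaches the per-block attention
#'   arrays (`Tn x Tn x n_heads`) as attribute `"attention"`.
#' @return The encoded token matrix.
#' @export
attention_encoder <- function(tokens, params, return_attention = FALSE) {
  cfg <- params$config
  Tn <- cfg$col + 1L
  if (!is.matrix(tokens) || nrow(tokens) != Tn || ncol(tokens) != cfg$d) {
    stop(sprintf("tokens must be a %d x %d matrix", Tn, cfg$d), call. = FALSE)
  }
  tr <- params$trainable
  heads <- cfg$n_heads; dk <- cfg$d %/% heads
  scale <- 1 / sqrt(dk)
  Z <- tokens
  att <- list()
  for (l in seq_len(cfg$n_blocks)) {
    bp <- tr$blocks[[l]]
    Q <- add_rowvec(Z %*% bp$Wq, bp$bq)
    K <- add_rowvec(Z %*% bp$Wk, bp$bk)
    V <- add_rowvec(Z %*% bp$Wv, bp$bv)
    H <- matrix(0, Tn, cfg$d)
    A_l <- array(0, dim = c(Tn, Tn, heads))
    for (hh in seq_len(heads)) {
      cols <- (hh - 1L) * dk + seq_len(dk)
      S <- tcrossprod(Q[, cols, drop = FALSE], K[, cols, drop = FALSE]) * scale
      S <- S - apply(S, 1, max)
      E <- exp(S)
      A <- E / rowSums(E)
      H[, cols] <- A %*% V[, cols, drop = FALSE]
      A_l[, , hh] <- A
    }
    R1 <- Z + add_rowvec(H %*% bp$Wo, bp$bo)
    N1 <- (R1 - rowMeans(R1)) / sqrt(rowMeans((R1 - rowMeans(R1))^2) + .ln_eps)
    Z1 <- add_rowvec(sweep(N1, 2, bp$ln1g, "*"), bp$ln1b)
    Fo <- add_rowvec(pmax(add_rowvec(Z1 %*% bp$W1, bp$b1), 0) %*% bp$W2, bp$b2)
    R2 <- Z1 + Fo
    N2 <- (R2 - rowMeans(R2)) / sqrt(rowMeans((R2 - rowMeans(R2))^2) + .ln_eps)
    Z <- add_rowvec(sweep(N2, 2, bp$ln2g, "*"), bp$ln2b)
    att[[l]] <- A_l
  }
  if (return_attention) attr(Z, "attention") <- att
  Z
}

#' Skip-connected token head on encoded tokens
#'
#' Splits the encoded token matrix into the CLS token (global summary) and
#' the feature-wise tokens (local detail), projects the flattened feature
#' tokens to a d-vector `f`, fuses per the ablation mode (`both`:
#' `Dense(CLS + f)`; `global_only`: `Dense(CLS)`; `local_only`: `Dense(f)`),
#' and maps through the 1-unit output layer. The post-encoder batch
#' normalization is applied internally using the stored running statistics.
#'
#' @param tokens Encoded `(col+1) x d` token matrix.
#' @param params A `los_params`.
#' @param mode Head mode; defaults to the configuration's mode.
#' @return A single predicted LOS in days.
#' @export
skip_token_head <- function(tokens, params, mode = params$config$mode) {
  cfg <- params$config
  if (!mode %in% c("both", "global_only", "local_only")) {
    stop(sprintf("unknown head mode '%s'", mode), call. = FALSE)
  }
  tr <- params$trainable
  d <- cfg$d; Tn <- cfg$col + 1L
  v <- as.vector(t(tokens))                 # position-major flatten
  vhat <- (v - params$bn$post_mean) / sqrt(params$bn$post_var + .bn_eps)
  vbn <- vhat * tr$bn_post_g + tr$bn_post_b
  CLS <- vbn[seq_len(d)]
  Fp <- vbn[(d + 1L):(Tn * d)]
  f <- drop(Fp %*% tr$Wf) + tr$bf
  s <- switch(mode, both = CLS + f, global_only = CLS, local_only = f)
  tsc <- drop(s %*% tr$Wt) + tr$bt
  drop(tsc %*% tr$Wh) + tr$bh
}

#' Predict LOS for a batch of standardized feature rows
#'
#' Full evaluation-mode composition: input batch norm (running statistics)
#' -> tokenizer -> encoder block(s) -> post-encoder batch norm (running
#' statistics) -> skip-token head. Deterministic and independent of batch
#' composition.
#'
#' @param X Numeric matrix `B x col` of standardized features.
#' @param params A `los_params`.
#' @return Numeric vector of `B` predictions in days.
#' @export
predict_batch <- function(X, params) {
  if (!is.matrix(X)) X <- matrix(X, nrow = 1)
  forward_pass(params, X, training = FALSE)$pred
}
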