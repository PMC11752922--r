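test_that("initialization zeroes the CLS token and is seed-deterministic", {
  cfg <- los_config(d = 40, n_heads = 5, seed = 12)
  p <- init_params(cfg)
  expect_identical(p$trainable$cls, numeric(40))
  p2 <- init_params(cfg)
  expect_identical(p, p2)
  p3 <- init_params(los_config(d = 40, n_heads = 5, seed = 13))
  expect_false(identical(p$trainable$Wemb, p3$trainable$Wemb))
  expect_error(los_config(d = 41, n_heads = 5), "divisible")
})

test_that("parameter count formula matches the actual parameter tree", {
  for (cfg in list(los_config(), tiny_mconfig(),
                   los_config(col = 7, d = 10, n_heads = 2, n_blocks = 3),
                   los_config(d = 20, shared_tokenizer = TRUE))) {
    p <- init_params(cfg)
    expect_equal(length(losformer:::tree_flatten(p$trainable)),
                 n_parameters(cfg))
  }
})

test_that("tokenizer is a per-position affine map with CLS at row 1", {
  cfg <- los_config(col = 4, d = 3, n_heads = 1, seed = 5)
  p <- init_params(cfg)
  # zero input, zero biases: all feature tokens zero, CLS row = CLS vector
  p0 <- p; p0$trainable$bemb[] <- 0
  tok0 <- embed_tokens(rep(0, 4), p0)
  expect_equal(tok0[1, ], p0$trainable$cls)
  expect_equal(tok0[-1, ], matrix(0, 4, 3))

  set.seed(1)
  x <- rnorm(4)
  tok <- embed_tokens(x, p)
  # brute-force per-position recomputation
  manual <- rbind(p$trainable$cls,
                  t(vapply(1:4, function(i) {
                    x[i] * p$trainable$Wemb[i, ] + p$trainable$bemb[i, ]
                  }, numeric(3))))
  expect_equal(tok, manual, tolerance = 1e-12)

  # locality: doubling x_3 changes only token row 4, linearly
  x2 <- x; x2[3] <- 2 * x[3]
  tok2 <- embed_tokens(x2, p)
  expect_equal(tok2[-4, ], tok[-4, ])
  expect_equal(tok2[4, ] - p$trainable$bemb[3, ],
               2 * (tok[4, ] - p$trainable$bemb[3, ]))
  expect_error(embed_tokens(rep(0, 5), p), "expected 4")
})

test_that("attention rows are probability vectors and symmetry is preserved", {
  cfg <- los_config(col = 6, d = 8, n_heads = 2, seed = 2)
  p <- init_params(cfg)
  set.seed(3)
  tok <- matrix(rnorm(7 * 8), 7, 8)
  enc <- attention_encoder(tok, p, return_attention = TRUE)
  for (A in attr(enc, "attention")) {
    for (h in seq_len(dim(A)[3])) {
      expect_true(all(A[, , h] >= 0))
      expect_equal(rowSums(A[, , h]), rep(1, 7), tolerance = 1e-6)
    }
  }
  # identical tokens at every position -> identical outputs at every position
  same <- matrix(rep(rnorm(8), each = 7), 7, 8)
  enc_same <- attention_encoder(same, p)
  expect_equal(enc_same, matrix(rep(enc_same[1, ], each = 7), 7, 8),
               tolerance = 1e-9)
})

test_that("single-head attention matches an independent softmax oracle", {
  cfg <- los_config(col = 2, d = 2, n_heads = 1, n_blocks = 1,
                    ffn_hidden = 3, seed = 8)
  p <- init_params(cfg)
  tr <- p$trainable; bp <- tr$blocks[[1]]
  tok <- matrix(c(0.5, -1, 2, 0.3, -0.7, 1.1), 3, 2)

  # oracle: step-by-step scaled dot-product attention + FFN + post-norm
  Q <- tok %*% bp$Wq + matrix(bp$bq, 3, 2, byrow = TRUE)
  K <- tok %*% bp$Wk + matrix(bp$bk, 3, 2, byrow = TRUE)
  V <- tok %*% bp$Wv + matrix(bp$bv, 3, 2, byrow = TRUE)
  S <- Q %*% t(K) / sqrt(2)
  A <- t(apply(S, 1, function(r) exp(r) / sum(exp(r))))
  H <- A %*% V
  R1 <- tok + H %*% bp$Wo + matrix(bp$bo, 3, 2, byrow = TRUE)
  ln <- function(M, g, b) {
    t(apply(M, 1, function(r) {
      (r - mean(r)) / sqrt(mean((r - mean(r))^2) + 1e-5) * g + b
    }))
  }
  Z1 <- ln(R1, bp$ln1g, bp$ln1b)
  FF <- pmax(Z1 %*% bp$W1 + matrix(bp$b1, 3, 3, byrow = TRUE), 0) %*% bp$W2 +
    matrix(bp$b2, 3, 2, byrow = TRUE)
  oracle <- ln(Z1 + FF, bp$ln2g, bp$ln2b)

  expect_equal(attention_encoder(tok, p), oracle, tolerance = 1e-6)
})

test_that("skip-token head implements the three fusion modes", {
  cfg <- los_config(col = 3, d = 2, n_heads = 1, ffn_hidden = 4, seed = 4)
  p <- init_params(cfg)
  tok <- matrix(seq(0.1, 0.8, length.out = 8), 4, 2)

  # all head weights zero -> prediction 0
  pz <- p
  pz$trainable$Wf[] <- 0; pz$trainable$bf[] <- 0
  pz$trainable$Wt[] <- 0; pz$trainable$bt[] <- 0
  pz$trainable$Wh[] <- 0; pz$trainable$bh <- 0
  expect_equal(skip_token_head(tok, pz), 0)

  # global mode ignores the feature tokens entirely
  tok2 <- tok; tok2[2:4, ] <- tok[2:4, ] + 5
  expect_equal(skip_token_head(tok, p, mode = "global_only"),
               skip_token_head(tok2, p, mode = "global_only"))

  # both mode equals the brute-force evaluation of the fusion equations
  tr <- p$trainable
  v <- as.vector(t(tok))
  vbn <- (v - p$bn$post_mean) / sqrt(p$bn$post_var + 1e-5) *
    tr$bn_post_g + tr$bn_post_b
  CLS <- vbn[1:2]; Fp <- vbn[3:8]
  f <- drop(Fp %*% tr$Wf) + tr$bf
  manual <- drop((drop((CLS + f) %*% tr$Wt) + tr$bt) %*% tr$Wh) + tr$bh
  expect_equal(skip_token_head(tok, p, mode = "both"), manual,
               tolerance = 1e-12)
  expect_error(skip_token_head(tok, p, mode = "nope"), "unknown head mode")
})

test_that("zeroed local fusion reduces both-mode to the global-only family", {
  cfg <- los_config(col = 3, d = 2, n_heads = 1, ffn_hidden = 4, seed = 9)
  p <- init_params(cfg)
  p$trainable$Wf[] <- 0; p$trainable$bf[] <- 0
  tok <- matrix(rnorm(8), 4, 2)
  expect_equal(skip_token_head(tok, p, mode = "both"),
               skip_token_head(tok, p, mode = "global_only"),
               tolerance = 1e-12)
})

test_that("evaluation-mode predictions are batch-composition invariant", {
  cfg <- los_config(col = 5, d = 6, n_heads = 3, seed = 21)
  p <- init_params(cfg)
  set.seed(6)
  X <- matrix(rnorm(40 * 5), 40, 5)
  batch_pred <- predict_batch(X, p)
  solo <- vapply(1:10, function(i) predict_batch(X[i, , drop = FALSE], p), 1.0)
  expect_equal(batch_pred[1:10], solo, tolerance = 1e-6)

  same_rows <- X[rep(3, 7), ]
  expect_equal(predict_batch(same_rows, p), rep(batch_pred[3], 7),
               tolerance = 1e-9)
  expect_error(predict_batch(X[, 1:3], p), "expected 5")
})

test_that("feature permutation with matching parameter blocks is a no-op", {
  cfg <- los_config(col = 6, d = 4, n_heads = 2, seed = 31)
  p <- init_params(cfg)
  set.seed(11)
  # randomize BN running stats so the invariance exercises them too
  p$bn$in_mean <- rnorm(6); p$bn$in_var <- runif(6, 0.5, 2)
  p$bn$post_mean <- rnorm(7 * 4); p$bn$post_var <- runif(7 * 4, 0.5, 2)
  X <- matrix(rnorm(8 * 6), 8, 6)
  base <- predict_batch(X, p)

  perm <- c(4, 1, 6, 2, 5, 3)
  q <- p
  q$trainable$Wemb <- p$trainable$Wemb[perm, ]
  q$trainable$bemb <- p$trainable$bemb[perm, ]
  q$trainable$bn_in_g <- p$trainable$bn_in_g[perm]
  q$trainable$bn_in_b <- p$trainable$bn_in_b[perm]
  q$bn$in_mean <- p$bn$in_mean[perm]
  q$bn$in_var <- p$bn$in_var[perm]
  d <- 4
  blk <- function(t) (t - 1) * d + seq_len(d)       # channel block of token t
  ch_perm <- c(blk(1), unlist(lapply(perm + 1, blk)))
  q$trainable$bn_post_g <- p$trainable$bn_post_g[ch_perm]
  q$trainable$bn_post_b <- p$trainable$bn_post_b[ch_perm]
  q$bn$post_mean <- p$bn$post_mean[ch_perm]
  q$bn$post_var <- p$bn$post_var[ch_perm]
  row_perm <- unlist(lapply(perm, blk))             # Wf rows skip the CLS block
  q$trainable$Wf <- p$trainable$Wf[row_perm, ]

  expect_equal(predict_batch(X[, perm], q), base, tolerance = 1e-6)
})

test_that("analytic gradients match central finite differences", {
  cfg <- los_config(col = 3, d = 4, n_heads = 2, n_blocks = 1,
                    ffn_hidden = 6, seed = 7)
  p <- init_params(cfg)
  set.seed(42)
  p$trainable$cls <- rnorm(4, sd = 0.3)   # exercise the CLS gradient path
  X <- matrix(rnorm(15), 5, 3)
  y <- rnorm(5, mean = 5)
  theta0 <- losformer:::tree_flatten(p$trainable)
  lossfn <- function(theta) {
    pp <- p
    pp$trainable <- losformer:::tree_unflatten(theta, p$trainable)
    fw <- losformer:::forward_pass(pp, X, training = TRUE, update_bn = FALSE)
    mean((fw$pred - y)^2)
  }
  fw <- losformer:::forward_pass(p, X, training = TRUE, update_bn = FALSE)
  g <- losformer:::tree_flatten(
    losformer:::backward_pass(p, fw$cache, 2 * (fw$pred - y) / 5))
  eps <- 1e-5
  idx <- sort(sample(length(theta0), 150))
  num <- vapply(idx, function(i) {
    tp <- theta0; tp[i] <- tp[i] + eps; f1 <- lossfn(tp)
    tp[i] <- theta0[i] - eps
    (f1 - lossfn(tp)) / (2 * eps)
  }, 1.0)
  rel <- abs(num - g[idx]) / pmax(1e-4, abs(num) + abs(g[idx]))
  expect_lt(max(rel), 1e-4)
})

test_that("checkpoints round-trip through JSON", {
  cfg <- tiny_mconfig(seed = 17)
  p <- init_params(cfg)
  set.seed(2)
  X <- matrix(rnorm(6 * 16), 6, 16)
  path <- withr::local_tempfile(fileext = ".json")
  save_model(p, path)
  p2 <- load_model(path)
  expect_equal(predict_batch(X, p2), predict_batch(X, p), tolerance = 1e-12)
})
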