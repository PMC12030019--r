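test_that("sparsity measure matches the entrywise oracle", {
  set.seed(11)
  Q <- matrix(rnorm(12), 6, 2)
  K <- matrix(rnorm(10), 5, 2)
  expect_equal(sparsity_measure(Q, K), oracle_sparsity(Q, K), tolerance = 1e-12)

  # all scores equal (constant rows) -> gap 0 for every query
  Qc <- matrix(1, 4, 3)
  Kc <- matrix(1, 5, 3)
  expect_equal(sparsity_measure(Qc, Kc), rep(0, 4), tolerance = 1e-12)

  # queries orthogonal to every key -> all scores 0 -> gap 0
  Qo <- cbind(rnorm(4), 0)
  Ko <- cbind(0, rnorm(5))
  expect_equal(sparsity_measure(Qo, Ko), rep(0, 4), tolerance = 1e-12)
})

test_that("dominant query count follows round(c ln L) with clamping", {
  expect_identical(dominant_query_count(164), 25L)
  expect_identical(dominant_query_count(1), 1L)
  expect_identical(dominant_query_count(2, c_factor = 100), 2L)
})

test_that("probsparse attention with u = L_Q equals dense attention", {
  set.seed(12)
  for (rep in 1:10) {
    L <- sample(4:16, 1); d <- sample(2:4, 1); Lk <- sample(4:16, 1)
    Q <- matrix(rnorm(L * d), L, d)
    K <- matrix(rnorm(Lk * d), Lk, d)
    V <- matrix(rnorm(Lk * d), Lk, d)
    expect_lt(max(abs(probsparse_attention(Q, K, V, u = L) -
                        oracle_dense_attention(Q, K, V))), 1e-6)
  }
})

test_that("non-dominant queries fall back to the time-mean of V", {
  set.seed(13)
  d <- 2
  # one clearly dominant query (aligned with a key), others orthogonal
  K <- rbind(c(10, 0), c(0, 1), c(0, -1))
  V <- matrix(rnorm(6), 3, 2)
  Q <- rbind(c(5, 0), c(0, 1e-8), c(0, -1e-8))
  out <- probsparse_attention(Q, K, V, u = 1)
  # dominant row: softmax heavily on key 1 -> close to V[1, ]
  w <- exp(c(50, 0, 0) / sqrt(d) - 50 / sqrt(d))
  w <- w / sum(w)
  expect_equal(out[1, ], colSums(w * V), tolerance = 1e-6)
  expect_equal(out[2, ], colMeans(V), tolerance = 1e-9)
  expect_equal(out[3, ], colMeans(V), tolerance = 1e-9)
})

test_that("attention rows are convex combinations of V rows", {
  set.seed(14)
  L <- 12; d <- 4
  Q <- matrix(rnorm(L * d), L, d)
  K <- matrix(rnorm(L * d), L, d)
  # V = identity recovers the attention weights themselves
  W <- probsparse_attention(Q, K, diag(L), u = 5)
  expect_true(all(W >= -1e-9))
  expect_equal(unname(rowSums(W)), rep(1, L), tolerance = 1e-6)
  expect_error(probsparse_attention(Q, K, diag(L), u = 0), ">= 1")
})

test_that("compiled multi-head kernel agrees with the plain implementation", {
  set.seed(16)
  L <- 10; d <- 4
  Q <- matrix(rnorm(L * d), L, d)
  K <- matrix(rnorm(L * d), L, d)
  V <- matrix(rnorm(L * d), L, d)
  for (u in c(3L, 10L)) {
    expect_equal(growcast:::.mha_forward(Q, K, V, 1L, 1L, FALSE, u)$out,
                 probsparse_attention(Q, K, V, u = u), tolerance = 1e-10)
  }
})

test_that("distill layer halves length via conv-ELU-maxpool", {
  set.seed(15)
  X <- matrix(rnorm(164 * 4), 164, 4)
  expect_identical(nrow(distill_layer(X)), 82L)
  # repeated application: 164 -> 82 -> 41 -> 21
  X2 <- distill_layer(X)
  X3 <- distill_layer(X2)
  X4 <- distill_layer(X3)
  expect_identical(c(nrow(X2), nrow(X3), nrow(X4)), c(82L, 41L, 21L))

  # identity convolution on a nonnegative ramp: ELU is identity, pooling
  # takes the stride-2 max over the (2j-1, 2j, 2j+1) neighborhood
  L <- 10
  ramp <- matrix(seq_len(L), L, 1)
  out <- distill_layer(ramp)
  expected <- vapply(seq_len(ceiling(L / 2)), function(j) {
    max(ramp[intersect(c(2 * j - 1, 2 * j, 2 * j + 1), seq_len(L)), 1])
  }, numeric(1))
  expect_equal(as.numeric(out), expected)
  expect_error(distill_layer(matrix(1, 1, 3)), ">= 2")
})

test_that("forward pass is deterministic, length-correct and time-sensitive", {
  cfg <- tiny_config()
  season <- tiny_season(seed = 21)
  fm <- season_features(season, end_row = 240L)
  p <- growcast:::init_informer(cfg, ncol(fm$features), 4L, seed = 3)
  ck <- structure(list(params = p, cfg = cfg), class = "growcast_checkpoint")
  w <- growcast:::assemble_window(fm, cfg, 240L)
  y1 <- informer_forward(ck, w$encX, w$decX)
  y2 <- informer_forward(ck, w$encX, w$decX)
  expect_identical(y1, y2)
  expect_length(y1, cfg$pred_len)
  expect_length(informer_forward(structure(list(
    params = growcast:::init_informer(informer_config(), 18L, 4L, seed = 1),
    cfg = informer_config()), class = "growcast_checkpoint"),
    matrix(0.5, 164, 18), matrix(0.5, 306, 4)), 150L)

  # shuffling the encoder's time axis changes the output
  yshuf <- informer_forward(ck, w$encX[sample(nrow(w$encX)), ], w$decX)
  expect_gt(max(abs(yshuf - y1)), 1e-8)
})

test_that("zero-weight network yields a constant trajectory", {
  cfg <- tiny_config()
  p <- growcast:::init_informer(cfg, 6L, 4L, seed = 1)
  p <- lapply(p, function(x) x * 0)
  ck <- structure(list(params = p, cfg = cfg), class = "growcast_checkpoint")
  y <- informer_forward(ck, matrix(0.3, cfg$seq_len, 6),
                        matrix(0, cfg$label_len + cfg$pred_len, 4))
  expect_equal(y, rep(0, cfg$pred_len), tolerance = 1e-12)
})

test_that("model gradients agree with finite differences on a tiny instance", {
  set.seed(33)
  cfg <- informer_config(seq_len = 12, label_len = 8, pred_len = 6,
                         d_model = 8, n_heads = 2, d_ff = 16, lstm_hidden = 4)
  enc_in <- 5; dec_in <- 4; B <- 2
  p <- growcast:::init_informer(cfg, enc_in, dec_in, seed = 7)
  encX <- matrix(rnorm(B * cfg$seq_len * enc_in), B * cfg$seq_len, enc_in)
  decX <- matrix(rnorm(B * 14 * dec_in), B * 14, dec_in)
  Y <- matrix(rnorm(B * cfg$pred_len), B, cfg$pred_len)
  loss <- function(p) {
    mean((growcast:::model_fwd(p, cfg, encX, decX, B)$yhat - Y)^2)
  }
  fw <- growcast:::model_fwd(p, cfg, encX, decX, B)
  gr <- growcast:::model_bwd(p, cfg, fw, 2 * (fw$yhat - Y) / length(Y), B)
  eps <- 1e-5
  for (nm in c("emb.enc.W", "enc1.att.qW", "distill.W2", "dec1.cross.kW",
               "dec1.ff.W1", "proj.W", "lstm.W", "lstm.wd")) {
    g <- as.numeric(gr[[nm]])
    ii <- sample(length(g), min(3, length(g)))
    for (i in ii) {
      p2 <- p; p2[[nm]][i] <- p2[[nm]][i] + eps
      p3 <- p; p3[[nm]][i] <- p3[[nm]][i] - eps
      fd <- (loss(p2) - loss(p3)) / (2 * eps)
      expect_equal(g[i], fd, tolerance = 1e-4)
    }
  }
})
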