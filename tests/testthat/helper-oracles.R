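# Independent brute-force oracles used to freeze expected values. These stay
# deliberately naive (scalar loops, direct formula evaluation) and never call
# the code paths they check.

# Quantile by sorting and linear interpolation at fractional rank p * (n - 1).
oracle_quantile <- function(v, p) {
  s <- sort(v)
  h <- p * (length(s) - 1)
  lo <- floor(h) + 1
  hi <- ceiling(h) + 1
  s[lo] + (h - floor(h)) * (s[hi] - s[lo])
}

# Dense scaled-dot-product attention, one query row at a time.
oracle_dense_attention <- function(Q, K, V) {
  d <- ncol(Q)
  out <- matrix(0, nrow(Q), ncol(V))
  for (i in seq_len(nrow(Q))) {
    s <- numeric(nrow(K))
    for (j in seq_len(nrow(K))) s[j] <- sum(Q[i, ] * K[j, ]) / sqrt(d)
    w <- exp(s - max(s))
    w <- w / sum(w)
    for (j in seq_len(nrow(K))) out[i, ] <- out[i, ] + w[j] * V[j, ]
  }
  out
}

# Max-minus-mean score gap per query, entrywise.
oracle_sparsity <- function(Q, K) {
  d <- ncol(Q)
  m <- numeric(nrow(Q))
  for (i in seq_len(nrow(Q))) {
    s <- numeric(nrow(K))
    for (j in seq_len(nrow(K))) s[j] <- sum(Q[i, ] * K[j, ]) / sqrt(d)
    m[i] <- max(s) - mean(s)
  }
  m
}

# One LSTM cell step evaluated unit by unit with scalar arithmetic.
oracle_lstm_step <- function(x_t, h_prev, C_prev, params) {
  hid <- params$hidden
  hx <- c(h_prev, x_t)
  h <- C <- numeric(hid)
  for (u in seq_len(hid)) {
    f <- 1 / (1 + exp(-(sum(params$w_f[u, ] * hx) + params$b_f[u])))
    i <- 1 / (1 + exp(-(sum(params$w_i[u, ] * hx) + params$b_i[u])))
    g <- tanh(sum(params$w_c[u, ] * hx) + params$b_c[u])
    o <- 1 / (1 + exp(-(sum(params$w_o[u, ] * hx) + params$b_o[u])))
    C[u] <- C_prev[u] * f + i * g
    h[u] <- o * tanh(C[u])
  }
  list(h = h, C = C)
}

# Geometric-series closed form of the EWMA recursion with S_1 = y_1.
oracle_ewma <- function(y, alpha) {
  n <- length(y)
  s <- numeric(n)
  for (t in seq_len(n)) {
    acc <- (1 - alpha)^(t - 1) * y[1]
    if (t > 1) {
      for (j in 2:t) acc <- acc + alpha * (1 - alpha)^(t - j) * y[j]
    }
    s[t] <- acc
  }
  s
}

# Piecewise trajectory rising to a peak at `peak` then strictly decreasing
# steeply enough that the decline onset is detected at the peak index.
make_peak_traj <- function(n, peak, lo = 0.2, hi = 0.8) {
  c(seq(lo, hi, length.out = peak), seq(hi, 0.05, length.out = n - peak + 1)[-1])
}

# Tiny model configuration for fast training tests.
tiny_config <- function(...) {
  informer_config(seq_len = 48L, label_len = 24L, pred_len = 36L,
                  d_model = 16L, n_heads = 4L, d_ff = 32L, lstm_hidden = 8L,
                  stride = 12L, ...)
}

# Short simulated season for tiny trainings.
tiny_season <- function(seed = 5L, horizon_days = 14) {
  simulate_season(simulator_config(horizon_days = horizon_days, seed = seed),
                  irrigation_hours = c(216L))
}
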