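#' Number of dominant queries for ProbSparse attention
#'
#' u = c * ln(L_Q), rounded to the nearest integer and clamped to [1, L_Q].
#'
#' @param L_Q query sequence length.
#' @param c_factor sampling factor (default 5).
#' @return Integer count of dominant queries.
#' @examples
#' dominant_query_count(164)  # 26
#' @export
dominant_query_count <- function(L_Q, c_factor = 5) {
  if (L_Q < 1) stop("`L_Q` must be >= 1")
  max(1L, min(as.integer(L_Q), as.integer(round(c_factor * log(L_Q)))))
}

#' Sparsity measure of attention queries
#'
#' For each query q_i, the gap between the maximum and the mean of its scaled
#' scores against all keys: max_j(q_i k_j' / sqrt(d)) - mean_j(q_i k_j' /
#' sqrt(d)). Queries whose score distribution is far from uniform (large gap)
#' are the informative ones that ProbSparse attention keeps.
#'
#' @param Q query matrix, L_Q x d.
#' @param K key matrix, L_K x d.
#' @return Numeric vector of length L_Q.
#' @export
sparsity_measure <- function(Q, K) {
  Q <- as.matrix(Q); K <- as.matrix(K)
  d <- ncol(Q)
  if (d == 0L || ncol(K) != d) stop("Q and K must share a positive dimension d")
  S <- Q %*% t(K) / sqrt(d)
  apply(S, 1, max) - rowMeans(S)
}

#' ProbSparse scaled dot-product attention
#'
#' Computes attention in which only the `u` queries with the largest
#' [sparsity_measure()] receive softmax(QK'/sqrt(d)) V; the remaining queries
#' fall back to the time-mean of V (uniform weights). With `u = nrow(Q)` the
#' result equals full dense attention.
#'
#' @param Q,K,V query (L_Q x d), key (L_K x d) and value (L_K x d_v) matrices.
#' @param u number of dominant queries; default `dominant_query_count(nrow(Q),
#'   c_factor)`.
#' @param c_factor sampling factor used when `u` is not given (default 5).
#' @return Output matrix L_Q x d_v.
#' @examples
#' Q <- matrix(rnorm(12), 6, 2); K <- matrix(rnorm(10), 5, 2)
#' V <- matrix(rnorm(10), 5, 2)
#' probsparse_attention(Q, K, V, u = 3)
#' @export
probsparse_attention <- function(Q, K, V, u = NULL, c_factor = 5) {
  Q <- as.matrix(Q); K <- as.matrix(K); V <- as.matrix(V)
  d <- ncol(Q)
  if (d == 0L) stop("d must be positive")
  if (ncol(K) != d || nrow(K) != nrow(V)) {
    stop("Q, K, V shapes do not conform")
  }
  if (is.null(u)) u <- dominant_query_count(nrow(Q), c_factor)
  u <- as.integer(u)
  if (u < 1L) stop("`u` must be >= 1")
  if (u > nrow(Q)) stop("`u` must not exceed L_Q")
  S <- Q %*% t(K) / sqrt(d)
  M <- apply(S, 1, max) - rowMeans(S)
  sel <- order(M, decreasing = TRUE)[seq_len(u)]
  out <- matrix(colMeans(V), nrow(Q), ncol(V), byrow = TRUE)
  for (i in sel) {
    w <- exp(S[i, ] - max(S[i, ]))
    w <- w / sum(w)
    out[i, ] <- as.numeric(w %*% V)
  }
  out
}

#' Self-attention distilling layer
#'
#' The conv -> ELU -> max-pool stage inserted between encoder attention
#' blocks: a causal 1-D convolution over time (kernel width 3), an ELU
#' nonlinearity, and max-pooling with kernel 3 / stride 2 / right padding,
#' which maps a length-L sequence to length ceiling(L / 2).
#'
#' @param X sequence matrix, L x d_model (L >= 2).
#' @param weights list with `W1`, `W2`, `W3` (d x d convolution taps, applied
#'   to lags 2, 1, 0) and bias `b` (length d). Default: identity convolution
#'   (W3 = I, W1 = W2 = 0, b = 0).
#' @return Matrix ceiling(L / 2) x d_model.
#' @export
distill_layer <- function(X, weights = NULL) {
  X <- as.matrix(X)
  L <- nrow(X); d <- ncol(X)
  if (L < 2L) stop("sequence length must be >= 2")
  if (is.null(weights)) {
    weights <- list(W1 = matrix(0, d, d), W2 = matrix(0, d, d),
                    W3 = diag(d), b = rep(0, d))
  }
  out <- conv_causal3(X, weights, B = 1L, L = L)
  out <- elu(out)
  maxpool3_s2(out, B = 1L, L = L)$out
}

# ELU and its derivative (on the pre-activation)
elu <- function(x) ifelse(x > 0, x, exp(pmin(x, 0)) - 1)
elu_grad <- function(x) ifelse(x > 0, 1, exp(pmin(x, 0)))

# Causal width-3 1-D convolution over time on row-block matrices.
# W1 acts on lag 2, W2 on lag 1, W3 on lag 0; positions before the block
# start contribute zero.
conv_causal3 <- function(X, w, B, L) {
  s1 <- shift_rows(X, 1L, B, L)
  s2 <- shift_rows(X, 2L, B, L)
  out <- s2 %*% w$W1 + s1 %*% w$W2 + X %*% w$W3
  sweep(out, 2, w$b, "+")
}

conv_causal3_bwd <- function(dOut, X, w, B, L) {
  s1 <- shift_rows(X, 1L, B, L)
  s2 <- shift_rows(X, 2L, B, L)
  dX <- dOut %*% t(w$W3) +
    unshift_rows(dOut %*% t(w$W2), 1L, B, L) +
    unshift_rows(dOut %*% t(w$W1), 2L, B, L)
  list(
    dX = dX,
    dW1 = t(s2) %*% dOut,
    dW2 = t(s1) %*% dOut,
    dW3 = t(X) %*% dOut,
    db = colSums(dOut)
  )
}

# Shift each within-block row index forward by `s` (rows falling before the
# block start become zero).
shift_rows <- function(X, s, B, L) {
  n <- B * L
  pos <- ((seq_len(n) - 1L) %% L)
  src <- seq_len(n) - s
  bad <- pos < s
  src[bad] <- 1L
  out <- X[src, , drop = FALSE]
  out[bad, ] <- 0
  out
}

# Adjoint of shift_rows: scatter rows back by `s` within blocks.
unshift_rows <- function(X, s, B, L) {
  n <- B * L
  pos <- ((seq_len(n) - 1L) %% L)
  out <- matrix(0, n, ncol(X))
  keep <- pos >= s
  out[which(keep) - s, ] <- X[keep, , drop = FALSE]
  out
}

# Max-pool kernel 3 / stride 2 / right padding within each length-L block.
# Output block length is ceiling(L / 2). Returns pooled matrix and the
# elementwise source-row choice (1, 2, 3) for the backward scatter.
maxpool3_s2 <- function(X, B, L) {
  L2 <- ceiling(L / 2)
  d <- ncol(X)
  base <- rep((0:(B - 1)) * L, each = L2)
  j <- rep(seq_len(L2), B)
  i1 <- 2L * j - 1L
  i2 <- 2L * j
  i3 <- 2L * j + 1L
  gather <- function(i) {
    ok <- i <= L
    src <- base + pmin(i, L)
    M <- X[src, , drop = FALSE]
    M[!ok, ] <- -Inf
    M
  }
  a1 <- gather(i1); a2 <- gather(i2); a3 <- gather(i3)
  m <- pmax(a1, a2, a3)
  # first index attaining the max wins ties
  amax <- matrix(3L, nrow(m), d)
  amax[a2 == m] <- 2L
  amax[a1 == m] <- 1L
  list(out = m, amax = amax, idx = list(i1 = base + i1, i2 = base + i2, i3 = base + i3,
                                        ok3 = i3 <= L), L2 = L2)
}

maxpool3_s2_bwd <- function(dOut, pool, B, L) {
  d <- ncol(dOut)
  dX <- matrix(0, B * L, d)
  pick <- list(pool$idx$i1, pool$idx$i2, pool$idx$i3)
  for (k in 1:3) {
    mask <- pool$amax == k
    if (!any(mask)) next
    rows <- pick[[k]]
    ok <- rows <= rep((1:B) * L, each = pool$L2)
    contrib <- dOut * mask
    contrib[!ok, ] <- 0
    rows_c <- pmin(rows, B * L)
    # rows within one k are distinct, so matrix-index assignment accumulates safely
    dX[rows_c, ] <- dX[rows_c, ] + contrib
  }
  dX
}
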