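#' LSTM gate parameters
#'
#' Weight/bias blocks of a single LSTM cell. Every block multiplies the
#' concatenated vector `c(h_prev, x_t)`; gates use the logistic function, the
#' candidate state uses tanh.
#'
#' @param w_f,w_i,w_c,w_o weight matrices, `hidden x (hidden + input_dim)`,
#'   for the forget gate, input gate, candidate state and output gate.
#' @param b_f,b_i,b_c,b_o bias vectors of length `hidden`.
#' @return A list of class `lstm_params`.
#' @export
lstm_params <- function(w_f, b_f, w_i, b_i, w_c, b_c, w_o, b_o) {
  blocks <- list(w_f = as.matrix(w_f), w_i = as.matrix(w_i),
                 w_c = as.matrix(w_c), w_o = as.matrix(w_o))
  hid <- nrow(blocks$w_f)
  din <- ncol(blocks$w_f) - hid
  if (din < 1L) stop("weight blocks must accept c(h_prev, x_t)")
  for (w in blocks) {
    if (nrow(w) != hid || ncol(w) != hid + din) stop("gate weight shapes are inconsistent")
  }
  p <- c(blocks, list(b_f = as.numeric(b_f), b_i = as.numeric(b_i),
                      b_c = as.numeric(b_c), b_o = as.numeric(b_o)))
  for (b in p[c("b_f", "b_i", "b_c", "b_o")]) {
    if (length(b) != hid) stop("bias length must equal hidden size")
  }
  p$hidden <- hid
  p$input_dim <- din
  class(p) <- "lstm_params"
  p
}

#' Zero-initialized LSTM parameters
#' @param hidden hidden-state width.
#' @param input_dim input width (default 1).
#' @return An [lstm_params()] object with all weights and biases zero.
#' @export
lstm_params_zero <- function(hidden, input_dim = 1L) {
  z <- matrix(0, hidden, hidden + input_dim)
  b <- rep(0, hidden)
  lstm_params(z, b, z, b, z, b, z, b)
}

#' One LSTM cell step
#'
#' Computes f_t = sigma(w_f [h, x] + b_f), i_t = sigma(w_i [h, x] + b_i),
#' candidate C~ = tanh(w_c [h, x] + b_c), o_t = sigma(w_o [h, x] + b_o),
#' C_t = C_{t-1} * f_t + i_t * C~, h_t = o_t * tanh(C_t) (elementwise).
#'
#' @param x_t input vector at time t.
#' @param h_prev previous hidden state (length `hidden`).
#' @param C_prev previous cell state (length `hidden`).
#' @param params an [lstm_params()].
#' @return A list with `h`, `C`, and the gate activations `f`, `i`, `o`,
#'   `c_tilde`.
#' @export
lstm_cell_step <- function(x_t, h_prev, C_prev, params) {
  if (!inherits(params, "lstm_params")) stop("`params` must be lstm_params")
  if (length(x_t) != params$input_dim || length(h_prev) != params$hidden ||
      length(C_prev) != params$hidden) {
    stop("input/state shapes do not conform to the parameter blocks")
  }
  hx <- c(h_prev, x_t)
  sig <- function(z) 1 / (1 + exp(-z))
  f <- sig(as.numeric(params$w_f %*% hx) + params$b_f)
  i <- sig(as.numeric(params$w_i %*% hx) + params$b_i)
  ct <- tanh(as.numeric(params$w_c %*% hx) + params$b_c)
  o <- sig(as.numeric(params$w_o %*% hx) + params$b_o)
  C <- C_prev * f + i * ct
  h <- o * tanh(C)
  list(h = h, C = C, f = f, i = i, o = o, c_tilde = ct)
}

#' Refine a predicted trajectory with an LSTM pass
#'
#' Runs the cell along the trajectory and adds a linear readout of the hidden
#' state to the input (residual form), so a zero-parameter refiner is the
#' identity. Optional per-hour covariates (e.g. the moisture-deficit channel)
#' are concatenated to the scalar trajectory input at each step.
#'
#' @param trajectory numeric status vector.
#' @param params an [lstm_params()] with `input_dim = 1 + ncol(covariates)`.
#' @param head list with readout weights `W` (`hidden x 1`) and bias `b`.
#' @param covariates optional numeric matrix, one row per hour.
#' @return Refined numeric vector, same length as `trajectory`.
#' @export
refine_sequence <- function(trajectory,
                            params = lstm_params_zero(32L),
                            head = list(W = matrix(0, params$hidden, 1), b = 0),
                            covariates = NULL) {
  if (length(trajectory) < 1L) stop("`trajectory` must be non-empty")
  if (anyNA(trajectory) || any(!is.finite(trajectory))) {
    stop("`trajectory` must be finite")
  }
  if (!is.null(covariates)) {
    covariates <- as.matrix(covariates)
    if (nrow(covariates) != length(trajectory)) {
      stop("`covariates` must have one row per trajectory hour")
    }
  }
  h <- rep(0, params$hidden)
  C <- rep(0, params$hidden)
  out <- numeric(length(trajectory))
  for (t in seq_along(trajectory)) {
    x_t <- if (is.null(covariates)) trajectory[t] else c(trajectory[t], covariates[t, ])
    st <- lstm_cell_step(x_t, h, C, params)
    h <- st$h
    C <- st$C
    out[t] <- trajectory[t] + as.numeric(crossprod(head$W, h)) + head$b
  }
  out
}

#' Extract the LSTM refiner from a trained checkpoint
#'
#' @param ckpt a `growcast_checkpoint`.
#' @return A list with `params` ([lstm_params()]) and `head` usable with
#'   [refine_sequence()].
#' @export
as_lstm_params <- function(ckpt) {
  W <- ckpt$params[["lstm.W"]]
  b <- ckpt$params[["lstm.b"]]
  hid <- ckpt$cfg$lstm_hidden
  i1 <- 1:hid; i2 <- hid + i1; i3 <- 2L * hid + i1; i4 <- 3L * hid + i1
  list(
    params = lstm_params(
      w_f = t(W[, i1]), b_f = b[i1],
      w_i = t(W[, i2]), b_i = b[i2],
      w_c = t(W[, i3]), b_c = b[i3],
      w_o = t(W[, i4]), b_o = b[i4]
    ),
    head = list(W = ckpt$params[["lstm.rW"]], b = ckpt$params[["lstm.rb"]])
  )
}
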