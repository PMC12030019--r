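test_that("zero-parameter cell gives the sigma(0) = 0.5 closed form", {
  p <- lstm_params_zero(3L)
  st <- lstm_cell_step(0.7, rep(0, 3), rep(0, 3), p)
  expect_equal(st$f, rep(0.5, 3))
  expect_equal(st$i, rep(0.5, 3))
  expect_equal(st$o, rep(0.5, 3))
  expect_equal(st$c_tilde, rep(0, 3))
  expect_equal(st$C, rep(0, 3))
  expect_equal(st$h, rep(0, 3))
})

test_that("saturated gates reach the closed-form limit", {
  hid <- 2L
  z <- matrix(0, hid, hid + 1L)
  big <- rep(50, hid)
  p <- lstm_params(z, big, z, big, z, big, z, big)
  cval <- c(0.3, -0.2)
  st <- lstm_cell_step(0, rep(0, hid), cval, p)
  # f, i, o -> 1 and c_tilde -> tanh(50) ~ 1, so C -> C_prev + 1
  expect_equal(st$C, cval + 1, tolerance = 1e-6)
  expect_equal(st$h, tanh(cval + 1), tolerance = 1e-6)
})

test_that("random cell matches the scalar-loop oracle", {
  set.seed(17)
  hid <- 2L
  mk <- function() matrix(rnorm(hid * (hid + 1)), hid, hid + 1)
  p <- lstm_params(mk(), rnorm(hid), mk(), rnorm(hid),
                   mk(), rnorm(hid), mk(), rnorm(hid))
  x <- rnorm(1); h0 <- rnorm(hid); C0 <- rnorm(hid)
  st <- lstm_cell_step(x, h0, C0, p)
  orc <- oracle_lstm_step(x, h0, C0, p)
  expect_equal(st$h, orc$h, tolerance = 1e-12)
  expect_equal(st$C, orc$C, tolerance = 1e-12)
  expect_error(lstm_cell_step(c(1, 2), h0, C0, p), "conform")
})

test_that("hidden-state outputs stay inside the tanh envelope", {
  set.seed(18)
  hid <- 4L
  mk <- function() matrix(rnorm(hid * (hid + 1), sd = 2), hid, hid + 1)
  p <- lstm_params(mk(), rnorm(hid), mk(), rnorm(hid),
                   mk(), rnorm(hid), mk(), rnorm(hid))
  h <- rep(0, hid); C <- rep(0, hid)
  for (t in 1:30) {
    st <- lstm_cell_step(rnorm(1), h, C, p)
    expect_true(all(abs(st$h) <= st$o))
    h <- st$h; C <- st$C
  }
})

test_that("convex cell update is bounded by input extremes when i + f = 1", {
  # harness: force i_t = 1 - f_t by symmetric biases and zero weights,
  # then C_t is a convex combination of C_prev and c_tilde
  hid <- 1L
  z <- matrix(0, hid, hid + 1)
  p <- lstm_params(z, 0.7, z, -0.7, z, 5, z, 0)
  C <- 0.2
  for (t in 1:20) {
    st <- lstm_cell_step(0, rep(0, hid), C, p)
    expect_equal(st$f + st$i, 1, tolerance = 1e-12)
    expect_true(st$C >= min(C, st$c_tilde) - 1e-12 &&
                  st$C <= max(C, st$c_tilde) + 1e-12)
    C <- st$C
  }
})

test_that("zero refiner is the identity and lengths are preserved", {
  traj <- sin(seq(0, 3, length.out = 150)) / 2 + 0.5
  out <- refine_sequence(traj)
  expect_identical(out, traj)
  expect_length(refine_sequence(runif(150)), 150L)
  expect_error(refine_sequence(numeric(0)), "non-empty")
  expect_error(refine_sequence(c(1, Inf)), "finite")
})

test_that("constant input drives the refined output to a fixed point", {
  set.seed(19)
  hid <- 3L
  mk <- function() matrix(rnorm(hid * (hid + 1), sd = 0.5), hid, hid + 1)
  p <- lstm_params(mk(), rnorm(hid, sd = 0.2), mk(), rnorm(hid, sd = 0.2),
                   mk(), rnorm(hid, sd = 0.2), mk(), rnorm(hid, sd = 0.2))
  head <- list(W = matrix(rnorm(hid, sd = 0.3), hid, 1), b = 0)
  out <- refine_sequence(rep(0.6, 400), p, head)
  # independent fixed-point iteration of the same recursion
  h <- rep(0, hid); C <- rep(0, hid)
  for (t in 1:400) { st <- lstm_cell_step(0.6, h, C, p); h <- st$h; C <- st$C }
  expect_equal(out[400], 0.6 + sum(head$W * h) + head$b, tolerance = 1e-9)
  expect_lt(abs(out[400] - out[399]), 1e-6)
})

test_that("checkpoint refiner blocks reproduce the batched training pass", {
  cfg <- tiny_config(epochs = 1L)
  season <- tiny_season(seed = 23)
  fm <- season_features(season, end_row = 300L)
  ck <- train_model(fm, cfg, seed = 2)
  lp <- as_lstm_params(ck)
  traj <- runif(40, 0.3, 0.7)
  cov <- matrix(runif(40, 0, 0.2), 40, 1)
  ours <- refine_sequence(traj, lp$params, lp$head, covariates = cov)
  # the training-side pass on the same sequence (single-sample batch)
  fwd <- growcast:::lstm_fwd_batch(ck$params, matrix(traj, 1), cfg$lstm_hidden,
                                   D = matrix(cov, 1))
  wd_term <- ck$params[["lstm.wd"]] * cumsum(cov[, 1] > 0) / 24
  expect_equal(as.numeric(fwd$out), ours + wd_term, tolerance = 1e-9)
})
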