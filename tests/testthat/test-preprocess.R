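test_that("gaussian kernel matches the direct density evaluation", {
  k <- gaussian_kernel(sigma = 2, radius = 8)
  x <- -8:8
  direct <- exp(-x^2 / (2 * 4)) / (2 * sqrt(2 * pi))
  expect_equal(k, direct / sum(direct), tolerance = 1e-12)
  expect_equal(sum(k), 1, tolerance = 1e-12)
  # default sigma = 10 kernel is normalized too
  expect_equal(sum(gaussian_kernel(10)), 1, tolerance = 1e-12)
})

test_that("gaussian smoothing preserves constants and recovers an impulse kernel", {
  expect_equal(gaussian_smooth(rep(3.7, 50), sigma = 4), rep(3.7, 50),
               tolerance = 1e-12)
  n <- 41
  imp <- numeric(n); imp[21] <- 1
  sm <- gaussian_smooth(imp, sigma = 2, radius = 8)
  expect_equal(sm[13:29], gaussian_kernel(2, 8), tolerance = 1e-12)
  expect_error(gaussian_smooth(1:10, sigma = 0), "positive")
  expect_error(gaussian_smooth(c(1, NA, 3), sigma = 2), "missing")
})

test_that("gaussian smoothing is shift-equivariant away from boundaries", {
  set.seed(1)
  x <- rnorm(200)
  s <- 5L
  a <- gaussian_smooth(x, sigma = 3)
  b <- gaussian_smooth(c(rnorm(s), x), sigma = 3)
  expect_equal(a[30:150], b[(30 + s):(150 + s)], tolerance = 1e-10)
})

test_that("quartile summary matches the sort-and-interpolate oracle", {
  v <- c(1, 2, 3, 4, 5, 6, 7, 8)
  qs <- quartile_summary(v)
  q1 <- oracle_quantile(v, 0.25); q3 <- oracle_quantile(v, 0.75)
  expect_equal(qs$q1, q1)
  expect_equal(qs$q2, oracle_quantile(v, 0.5))
  expect_equal(qs$q3, q3)
  expect_equal(qs$iqr, q3 - q1)
  expect_equal(qs$lower_bound, q1 - 1.5 * (q3 - q1))
  expect_equal(qs$upper_bound, q3 + 1.5 * (q3 - q1))
  set.seed(42)
  for (n in c(5, 9, 40)) {
    w <- rnorm(n)
    qsw <- quartile_summary(w)
    expect_equal(qsw$q1, oracle_quantile(w, 0.25), tolerance = 1e-12)
    expect_equal(qsw$q3, oracle_quantile(w, 0.75), tolerance = 1e-12)
  }
})

test_that("quartile summary handles degenerate and spiked inputs", {
  qs <- quartile_summary(rep(2, 10))
  expect_equal(qs$iqr, 0)
  expect_equal(qs$lower_bound, 2)
  expect_equal(qs$upper_bound, 2)
  spiked <- c(rep(0, 31), 100)
  qs2 <- quartile_summary(spiked)
  expect_equal(qs2$upper_bound, 0)
  expect_true(100 > qs2$upper_bound)
  expect_error(quartile_summary(c(1, 2, 3)), "at least 4")
})

test_that("outlier screening flags exactly the injected spikes", {
  clean <- sin(seq(0, 8 * pi, length.out = 300))
  qs <- quartile_summary(clean)
  res <- screen_outliers(clean, qs)
  expect_false(any(res$flags))
  expect_identical(res$cleaned, clean)

  spiked <- c(rep(0, 31), 100)
  qs2 <- quartile_summary(spiked)
  res2 <- screen_outliers(spiked, qs2)
  expect_identical(which(res2$flags), 32L)
  expect_equal(res2$cleaned[32], 0)

  set.seed(7)
  base <- rnorm(400)
  qs3 <- quartile_summary(base)
  k <- 12
  pos <- sample(400, k)
  spikes <- base
  spikes[pos] <- qs3$upper_bound + runif(k, 1, 5)
  res3 <- screen_outliers(spikes, quartile_summary(spikes))
  # recomputed fences shift a little; every injected spike must be caught
  expect_true(all(res3$flags[pos]))
  expect_equal(mean(res3$cleaned[res3$flags]),
               mean(spikes[!res3$flags]), tolerance = 1e-12)
})

test_that("screening flags are invariant under adding a constant", {
  set.seed(8)
  x <- rnorm(200)
  x[c(10, 50)] <- c(30, -30)
  f1 <- screen_outliers(x, quartile_summary(x))$flags
  f2 <- screen_outliers(x + 17, quartile_summary(x + 17))$flags
  expect_identical(f1, f2)
})

test_that("linear interpolation recovers affine signals exactly", {
  t <- 0:40
  y <- 2 * t + 1
  gap <- y
  gap[c(3, 4, 5, 12, 30:35)] <- NA
  expect_equal(interpolate_missing(gap, t), y, tolerance = 1e-12)

  expect_equal(interpolate_missing(c(4, NA, 10), c(0, 1, 2)), c(4, 7, 10))

  # multi-hour interior gap follows the chord between bracketing observations
  z <- c(1, NA, NA, NA, 9)
  expect_equal(interpolate_missing(z, 0:4), c(1, 3, 5, 7, 9))

  # boundary gaps extend the nearest observed value
  b <- c(NA, NA, 5, 7, NA)
  expect_equal(interpolate_missing(b, 0:4), c(5, 5, 5, 7, 7))

  expect_error(interpolate_missing(c(NA, 2, NA), 0:2), "at least 2")
})

test_that("min-max scaling round-trips and maps columns into [0, 1]", {
  set.seed(3)
  X <- cbind(a = rnorm(50, 100, 20), b = runif(50, -5, 5), c = rep(2, 50))
  sc <- fit_minmax(X)
  S <- apply_minmax(sc, X)
  expect_true(all(S[, c("a", "b")] >= 0 & S[, c("a", "b")] <= 1))
  expect_equal(invert_minmax(sc, S), X, tolerance = 1e-9, ignore_attr = TRUE)
})

test_that("feature assembly emits layer differences, adjacent means and target", {
  ts <- seq(as.POSIXct("2024-04-01", tz = "UTC"), by = "hour", length.out = 72)
  mk <- function(m, air = TRUE) {
    d <- data.frame(soil_temp_C = rep(18, 72), soil_moist_pct = m,
                    soil_cond_uScm = rep(150, 72))
    if (air) { d$air_temp_C <- rep(17, 72); d$air_hum_pct <- rep(70, 72) }
    d
  }
  n1 <- sensor_frame(ts, mk(rep(30, 72)), node = 1)
  n2 <- sensor_frame(ts, mk(rep(20, 72), air = FALSE), node = 2)
  status <- seq(0.2, 0.4, length.out = 72)
  fm <- build_features(n1, n2, status)
  raw_diff <- invert_minmax(fm$scaler, fm$features)[, "soil_moist_pct_diff"]
  raw_mean <- invert_minmax(fm$scaler, fm$features)[, "soil_moist_pct_mean"]
  expect_equal(unname(raw_diff), rep(10, 72), tolerance = 1e-9)
  expect_equal(unname(raw_mean), rep(25, 72), tolerance = 1e-9)
  expect_true(all(fm$features >= 0 & fm$features <= 1))
  expect_true(all(fm$target >= 0 & fm$target <= 1))

  # identical nodes give identically-zero difference columns
  n2b <- sensor_frame(ts, mk(rep(30, 72), air = FALSE), node = 2)
  fmb <- build_features(n1, n2b, status)
  rawb <- invert_minmax(fmb$scaler, fmb$features)
  expect_equal(unname(rawb[, "soil_temp_C_diff"]), rep(0, 72), tolerance = 1e-9)
  expect_equal(unname(rawb[, "soil_moist_pct_diff"]), rep(0, 72), tolerance = 1e-9)
})

test_that("preprocess_frame screens, imputes and smooths every channel", {
  season <- tiny_season(seed = 9)
  art <- inject_artifacts(season$node1, spike_prob = 0.01, drop_prob = 0.01,
                          seed = 2)
  out <- preprocess_frame(art$frame)
  expect_false(anyNA(as.matrix(out$frame[, channels(out$frame)])))
  expect_true(all(out$qc$n_imputed >= 0))
  expect_identical(out$qc$channel, channels(season$node1))
})
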