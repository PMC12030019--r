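test_that("same seed reproduces the season exactly", {
  cfg <- simulator_config(horizon_days = 10, seed = 31)
  a <- simulate_season(cfg, irrigation_hours = c(120L))
  b <- simulate_season(cfg, irrigation_hours = c(120L))
  expect_identical(a$status, b$status)
  expect_identical(as.data.frame(a$node1), as.data.frame(b$node1))
  expect_identical(a$truth$moist_true, b$truth$moist_true)
})

test_that("simulated channels respect physical bounds", {
  cfg <- simulator_config(horizon_days = 30, seed = 32,
                          anomaly = list(spike_prob = 0))
  s <- simulate_season(cfg, irrigation_hours = c(216L, 432L))
  expect_true(all(s$node1$soil_moist_pct >= 0 & s$node1$soil_moist_pct <= 100))
  expect_true(all(s$node2$soil_moist_pct >= 0 & s$node2$soil_moist_pct <= 100))
  expect_true(all(s$node1$air_hum_pct >= 0 & s$node1$air_hum_pct <= 100))
  expect_true(all(s$status >= 0 & s$status <= 1))
  w <- cfg$weather
  expect_true(all(abs(s$node1$air_temp_C - w$air_temp_mean) <=
                    w$air_temp_amp + 6 * w$temp_noise_sd))
})

test_that("noise-free depletion exits the band at the analytic hour", {
  cfg <- simulator_config(
    horizon_days = 15, seed = 33,
    soil = list(noise_sd = 0, depletion_jitter_sd = 0),
    weather = list(temp_noise_sd = 0, hum_noise_sd = 0),
    cond = list(noise_sd = 0),
    growth = list(noise_sd = 0)
  )
  s <- simulate_season(cfg)
  onset <- s$truth$stress_onsets$onset_h[1]
  expect_identical(onset, analytic_band_exit(cfg))
  # moisture strictly decreasing without irrigation
  expect_true(all(diff(s$truth$moist_true) < 0))
  # status rises inside the band and falls after the exit
  expect_true(all(diff(s$truth$status_true[1:(onset - 1)]) > 0))
  expect_true(all(diff(s$truth$status_true[onset:(15 * 24)]) < 0))
})

test_that("generous weekly irrigation keeps the crop inside the band", {
  cfg <- simulator_config(horizon_days = 28, seed = 34,
                          soil = list(replenish_jump = 28),
                          growth = list(noise_sd = 0))
  s <- simulate_season(cfg, irrigation_hours = seq(168L, 672L, by = 168L))
  expect_true(all(is.na(s$truth$stress_onsets$onset_h)))
  expect_true(all(diff(s$truth$status_true) >= 0))
})

test_that("artifact injection is the identity at zero probabilities", {
  s <- tiny_season(seed = 35)
  art <- inject_artifacts(s$node1, spike_prob = 0, drop_prob = 0, seed = 1)
  expect_identical(as.data.frame(art$frame), as.data.frame(s$node1))
  expect_false(any(art$spike_mask))
  expect_false(any(art$missing_mask))
})

test_that("injected spikes are recovered by quartile-fence screening", {
  s <- simulate_season(simulator_config(horizon_days = 30, seed = 36))
  art <- inject_artifacts(s$node1, spike_prob = 0.01, spike_mult = 10,
                          drop_prob = 0, seed = 3)
  n_spikes <- sum(art$spike_mask)
  expect_gt(n_spikes, 10)
  hits <- 0L
  for (ch in channels(art$frame)) {
    scr <- screen_outliers_windowed(art$frame[[ch]])
    hits <- hits + sum(scr$flags & art$spike_mask[, ch])
  }
  expect_gte(hits / n_spikes, 0.9)
})

test_that("missing-cell injection matches its binomial expectation and imputes", {
  s <- simulate_season(simulator_config(horizon_days = 42, seed = 37))
  art <- inject_artifacts(s$node1, spike_prob = 0, drop_prob = 0.01, seed = 4)
  n_cells <- nrow(art$frame) * length(channels(art$frame))
  n_missing <- sum(art$missing_mask)
  # ~ Binomial(n, 0.01): stay within 4 standard deviations of the mean
  expect_lt(abs(n_missing - 0.01 * n_cells), 4 * sqrt(n_cells * 0.01 * 0.99))
  clean <- preprocess_frame(art$frame)
  expect_false(anyNA(as.matrix(clean$frame[, channels(clean$frame)])))
  expect_true(all(clean$qc$n_imputed >= 0))
})
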