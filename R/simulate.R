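#' Synthetic greenhouse simulator configuration
#'
#' Bundles every knob of the seeded greenhouse simulator. Defaults emulate the
#' study conditions the package targets: hourly sampling; two soil nodes (10 cm
#' and 20 cm depth, the deeper one damped and lagged); diurnal air/soil
#' temperature and humidity cycles bounded by a plateau greenhouse climate;
#' exponential inter-irrigation soil-moisture depletion with replenishment
#' jumps at irrigation events (band exit roughly 9 days after replenishment);
#' and a [0, 1] growth-status signal that rises logistically while moisture
#' sits inside the favorable band and decays outside it.
#'
#' @param horizon_days simulated season length in days.
#' @param seed integer seed; every random draw flows from it.
#' @param soil list: `initial_moist` (%), `depletion_per_day` (exponential
#'   rate per day), `replenish_jump` (% added per irrigation, capped at 100),
#'   `band` (favorable moisture band, %), `noise_sd` (observation noise, %),
#'   `depletion_jitter_sd` (log-sd of the per-cycle depletion-rate multiplier).
#' @param node2 list: `damp` (deep-node damping factor) and `lag_h` (hours).
#' @param weather list of diurnal means/amplitudes and noise SDs.
#' @param cond list: conductivity `base` (uS/cm), irrigation `jump`, hourly
#'   `decay`, `noise_sd`.
#' @param growth list: `rate_per_h` (logistic growth inside the band),
#'   `decay_per_h` (decay outside), `status0`, `noise_sd`.
#' @param anomaly list: `spike_prob`, `spike_mult` (spikes injected at
#'   `spike_mult` times the channel SD by [inject_artifacts()]).
#' @param missing list: `drop_prob` for [inject_artifacts()].
#' @param start season start instant (POSIXct or string, UTC).
#' @return A list of class `simulator_config`.
#' @export
simulator_config <- function(horizon_days = 50,
                             seed = 1L,
                             soil = list(),
                             node2 = list(),
                             weather = list(),
                             cond = list(),
                             growth = list(),
                             anomaly = list(),
                             missing = list(),
                             start = "2024-04-01 00:00:00") {
  cfg <- list(
    horizon_days = horizon_days,
    seed = as.integer(seed),
    soil = utils::modifyList(list(
      initial_moist = 62, depletion_per_day = 0.08, replenish_jump = 36,
      band = c(30, 75), noise_sd = 0.3, depletion_jitter_sd = 0.04
    ), soil),
    node2 = utils::modifyList(list(damp = 0.6, lag_h = 3L), node2),
    weather = utils::modifyList(list(
      air_temp_mean = 17, air_temp_amp = 6, soil_temp_mean = 18,
      soil_temp_amp = 3, hum_mean = 70, hum_amp = 10,
      temp_noise_sd = 0.3, hum_noise_sd = 1
    ), weather),
    cond = utils::modifyList(list(
      base = 150, jump = 15, decay = 0.02, noise_sd = 1
    ), cond),
    growth = utils::modifyList(list(
      rate_per_h = 0.004, decay_per_h = 0.004, status0 = 0.15, noise_sd = 0.01
    ), growth),
    anomaly = utils::modifyList(list(spike_prob = 0, spike_mult = 10), anomaly),
    missing = utils::modifyList(list(drop_prob = 0), missing),
    start = as.POSIXct(start, tz = "UTC")
  )
  if (cfg$soil$band[1] >= cfg$soil$band[2]) stop("favorable band must have lo < hi")
  if (cfg$soil$depletion_per_day < 0 || cfg$growth$rate_per_h < 0 ||
      cfg$growth$decay_per_h < 0) {
    stop("rates must be non-negative")
  }
  if (cfg$anomaly$spike_prob < 0 || cfg$anomaly$spike_prob > 1 ||
      cfg$missing$drop_prob < 0 || cfg$missing$drop_prob > 1) {
    stop("probabilities must lie in [0, 1]")
  }
  if (cfg$horizon_days < 1) stop("horizon must be at least 1 day")
  class(cfg) <- "simulator_config"
  cfg
}

#' Simulate a greenhouse season with known ground truth
#'
#' Generates hourly sensor frames for two soil nodes, the observed growth
#' status, and a truth log recording true soil moisture, true status, and the
#' first stress-onset hour (true moisture below the favorable band) after each
#' irrigation event. Fully reproducible from `cfg$seed`.
#'
#' @param cfg a [simulator_config()].
#' @param irrigation_hours integer hours (0-based, hour 0 = season start) at
#'   which irrigation replenishes soil moisture. Hour 0 is implicit: the
#'   season starts freshly irrigated at `soil$initial_moist`.
#' @return A list of class `greenhouse_season`: `node1`, `node2`
#'   ([sensor_frame()]s), `status` (observed, in [0, 1]), `timestamps`, and
#'   `truth` (list with `moist_true`, `status_true`, `stress_onsets` data
#'   frame, `irrigation_hours`, `config`).
#' @export
simulate_season <- function(cfg = simulator_config(), irrigation_hours = integer()) {
  if (!inherits(cfg, "simulator_config")) stop("`cfg` must be a simulator_config")
  H <- as.integer(round(cfg$horizon_days * 24))
  if (H < 24L) stop("horizon must be at least 1 day")
  irrigation_hours <- sort(unique(as.integer(irrigation_hours)))
  irrigation_hours <- irrigation_hours[irrigation_hours > 0 & irrigation_hours <= H]

  set.seed(cfg$seed)
  # draw all noise up-front so the path is a deterministic function of the
  # irrigation schedule (closed-loop scheduling relies on this)
  noise <- list(
    m1 = stats::rnorm(H, 0, cfg$soil$noise_sd),
    m2 = stats::rnorm(H, 0, cfg$soil$noise_sd),
    st1 = stats::rnorm(H, 0, cfg$weather$temp_noise_sd),
    st2 = stats::rnorm(H, 0, cfg$weather$temp_noise_sd),
    at = stats::rnorm(H, 0, cfg$weather$temp_noise_sd),
    ah = stats::rnorm(H, 0, cfg$weather$hum_noise_sd),
    c1 = stats::rnorm(H, 0, cfg$cond$noise_sd),
    c2 = stats::rnorm(H, 0, cfg$cond$noise_sd),
    status = stats::rnorm(H, 0, cfg$growth$noise_sd),
    jitter = exp(stats::rnorm(200, 0, cfg$soil$depletion_jitter_sd))
  )
  sim_season_core(cfg, irrigation_hours, H, noise)
}

# Deterministic season path given pre-drawn noise.
sim_season_core <- function(cfg, irrigation_hours, H, noise) {
  lo <- cfg$soil$band[1]; hi <- cfg$soil$band[2]
  m_true <- numeric(H)
  s_true <- numeric(H)
  m <- cfg$soil$initial_moist
  s <- cfg$growth$status0
  cycle <- 1L
  rate_h <- cfg$soil$depletion_per_day * noise$jitter[cycle] / 24
  for (t in seq_len(H)) {
    if (t %in% irrigation_hours) {
      m <- min(100, m + cfg$soil$replenish_jump)
      cycle <- cycle + 1L
      rate_h <- cfg$soil$depletion_per_day * noise$jitter[min(cycle, length(noise$jitter))] / 24
    }
    m <- m * exp(-rate_h)
    if (m >= lo && m <= hi) {
      s <- s + cfg$growth$rate_per_h * s * (1 - s)
    } else {
      s <- s - cfg$growth$decay_per_h * s
    }
    s <- min(1, max(0, s))
    m_true[t] <- m
    s_true[t] <- s
  }

  ts <- cfg$start + 3600 * seq_len(H)
  hour <- as.numeric(format(ts, "%H", tz = "UTC"))
  diurn <- sin(2 * pi * (hour - 9) / 24)
  lag <- cfg$node2$lag_h
  damp <- cfg$node2$damp
  lag_idx <- pmax(seq_len(H) - lag, 1L)
  band_mid <- mean(cfg$soil$band)

  clamp01 <- function(x, a, b) pmin(b, pmax(a, x))
  m1_obs <- clamp01(m_true + noise$m1, 0, 100)
  m2_obs <- clamp01(band_mid + damp * (m_true[lag_idx] - band_mid) + noise$m2, 0, 100)

  st1 <- cfg$weather$soil_temp_mean + cfg$weather$soil_temp_amp * diurn + noise$st1
  st2 <- cfg$weather$soil_temp_mean +
    damp * cfg$weather$soil_temp_amp * diurn[lag_idx] + noise$st2
  at <- cfg$weather$air_temp_mean + cfg$weather$air_temp_amp * diurn + noise$at
  ah <- clamp01(cfg$weather$hum_mean - cfg$weather$hum_amp * diurn + noise$ah, 0, 100)

  cond_dev <- numeric(H)
  dev <- 0
  for (t in seq_len(H)) {
    if (t %in% irrigation_hours) dev <- dev + cfg$cond$jump
    dev <- dev * (1 - cfg$cond$decay)
    cond_dev[t] <- dev
  }
  c1 <- cfg$cond$base + cond_dev + noise$c1
  c2 <- cfg$cond$base + damp * cond_dev[lag_idx] + noise$c2

  status_obs <- clamp01(s_true + noise$status, 0, 1)

  events <- c(0L, irrigation_hours)
  onset <- rep(NA_integer_, length(events))
  for (k in seq_along(events)) {
    upper <- if (k < length(events)) events[k + 1L] else H
    span <- which(m_true < lo)
    span <- span[span > events[k] & span <= upper]
    if (length(span)) onset[k] <- span[1]
  }
  stress_onsets <- data.frame(cycle_start_h = events, onset_h = onset)

  node1 <- sensor_frame(ts, data.frame(
    soil_temp_C = st1, soil_moist_pct = m1_obs, soil_cond_uScm = c1,
    air_temp_C = at, air_hum_pct = ah
  ), field_id = "A1", node = 1L)
  node2 <- sensor_frame(ts, data.frame(
    soil_temp_C = st2, soil_moist_pct = m2_obs, soil_cond_uScm = c2
  ), field_id = "A1", node = 2L)

  structure(
    list(
      node1 = node1, node2 = node2, status = status_obs, timestamps = ts,
      truth = list(
        moist_true = m_true, status_true = s_true,
        stress_onsets = stress_onsets,
        irrigation_hours = irrigation_hours, config = cfg
      )
    ),
    class = "greenhouse_season"
  )
}

#' @export
print.greenhouse_season <- function(x, ...) {
  on <- x$truth$stress_onsets
  cat(sprintf(
    "<greenhouse_season> %d h, %d irrigation events, %d stress onsets\n",
    length(x$status), length(x$truth$irrigation_hours), sum(!is.na(on$onset_h))
  ))
  invisible(x)
}

#' Inject sensor artifacts with a recorded truth mask
#'
#' Adds spike outliers (at `spike_mult` times the channel standard deviation,
#' random sign) and missing cells to a sensor frame, and records where, so
#' that screening/imputation recall and precision are measurable.
#'
#' @param frame a [sensor_frame()].
#' @param spike_prob per-cell spike probability.
#' @param spike_mult spike magnitude in channel SDs (default 10).
#' @param drop_prob per-cell missing probability.
#' @param seed integer seed.
#' @return A list: `frame` (corrupted copy), `spike_mask`, `missing_mask`
#'   (logical matrices, rows = hours, columns = channels).
#' @export
inject_artifacts <- function(frame, spike_prob = 0.01, spike_mult = 10,
                             drop_prob = 0.01, seed = 1L) {
  validate_sensor_frame(frame)
  set.seed(as.integer(seed))
  chans <- channels(frame)
  n <- nrow(frame)
  spike_mask <- matrix(FALSE, n, length(chans), dimnames = list(NULL, chans))
  missing_mask <- spike_mask
  out <- frame
  for (j in seq_along(chans)) {
    v <- out[[chans[j]]]
    sdv <- stats::sd(v, na.rm = TRUE)
    sp <- stats::runif(n) < spike_prob
    sgn <- sample(c(-1, 1), n, replace = TRUE)
    v[sp] <- v[sp] + sgn[sp] * spike_mult * sdv
    dr <- stats::runif(n) < drop_prob
    v[dr] <- NA_real_
    spike_mask[, j] <- sp & !dr
    missing_mask[, j] <- dr
    out[[chans[j]]] <- v
  }
  list(frame = out, spike_mask = spike_mask, missing_mask = missing_mask)
}

#' Analytic favorable-band exit time of the noise-free simulator
#'
#' With zero noise and no irrigation, true moisture is
#' `initial * exp(-r t / 24)`; the first stressed hour is the smallest integer
#' t with moisture below the band floor.
#'
#' @param cfg a [simulator_config()].
#' @return Hour index (integer) of the first stressed hour.
#' @export
analytic_band_exit <- function(cfg) {
  r <- cfg$soil$depletion_per_day / 24
  t_exact <- log(cfg$soil$initial_moist / cfg$soil$band[1]) / r
  as.integer(floor(t_exact) + 1L)
}
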