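#' Detect the decline onset of a status trajectory
#'
#' Scans a (smoothed) status trajectory for the first index t* at which the
#' signal strictly decreases for `k` consecutive hourly steps and, by the end
#' of that run, has fallen at least `delta` below its running maximum. To
#' screen out transient dips at the start of a forecast horizon, the
#' candidate additionally must satisfy one of two conditions: growth occurred
#' before it (the running maximum exceeds the starting value by `delta / 2`),
#' or the decline persists (the trajectory does not recover above
#' running-max minus `delta / 2` within the following `recover_h` hours).
#' Transient forecast artifacts recover; real stress declines do not. If no
#' index qualifies the trajectory length is returned as a no-warning
#' sentinel.
#'
#' @param trajectory numeric status vector (length >= `k + 1`).
#' @param k consecutive strict decreases required (default 6).
#' @param delta minimum drop below the running maximum, in normalized status
#'   units (default 0.05: above the forecaster's wiggle floor, well below the
#'   depth of a sustained stress decline).
#' @param recover_h persistence window for the no-recovery condition
#'   (default 24 h).
#' @return Integer onset index (hours from the forecast origin), or
#'   `length(trajectory)` if no decline is found.
#' @export
detect_decline_onset <- function(trajectory, k = 6L, delta = 0.05,
                                 recover_h = 24L) {
  n <- length(trajectory)
  k <- as.integer(k)
  if (n < k + 1L) stop("trajectory shorter than the consecutive-decline window")
  dec <- diff(trajectory) < 0
  runmax <- cummax(trajectory)
  grown <- runmax >= trajectory[1] + delta / 2
  for (t in seq_len(n - k)) {
    if (all(dec[t:(t + k - 1L)]) &&
        runmax[t + k] - trajectory[t + k] >= delta) {
      if (grown[t + k]) return(t)
      tail_idx <- (t + k):min(n, t + k + as.integer(recover_h))
      if (all(trajectory[tail_idx] < runmax[t + k] - delta / 2)) return(t)
    }
  }
  n
}

#' Ensemble decision from repeated forecasts
#'
#' Applies [detect_decline_onset()] to each of the repeated prediction runs,
#' averages the per-run onsets (rounded to the nearest hour), and converts the
#' ensemble onset into an irrigation warning: the warning is issued at the
#' forecast origin for a predicted decline `ensemble_onset_h` hours later. The
#' calendar warning date is `date(origin) + round(onset / 24)` days (warnings
#' are scheduled at day granularity). If any run finds no decline the decision
#' is flagged `no_decline`.
#'
#' @param runs list of smoothed status trajectories (default protocol: 3 runs).
#' @param origin forecast origin (POSIXct).
#' @param k,delta decline-detector parameters, see [detect_decline_onset()].
#' @param irrigation_volume_L advisory irrigation volume attached to the
#'   decision (default 85 L).
#' @return A list with `bundle` (class `forecast_bundle`: `runs`,
#'   `per_run_onset_h`, `ensemble_onset_h`, `origin`, `no_decline`) and
#'   `decision` (class `intervention_decision`: `origin`, `warn_at`,
#'   `warn_date`, `lead_h`, `irrigation_volume_L`, `no_decline`).
#' @examples
#' peaky <- function(pk) c(seq(0.2, 0.8, length.out = pk),
#'                         seq(0.8, 0.05, length.out = 150 - pk))
#' res <- ensemble_decide(lapply(c(71, 69, 73), peaky),
#'                        as.POSIXct("2024-05-06", tz = "UTC"))
#' res$bundle$ensemble_onset_h  # 71
#' @export
ensemble_decide <- function(runs, origin, k = 6L, delta = 0.05,
                            irrigation_volume_L = 85) {
  if (!is.list(runs) || length(runs) < 1L) stop("`runs` must be a non-empty list")
  origin <- as.POSIXct(origin, tz = "UTC")
  onsets <- vapply(runs, detect_decline_onset, integer(1), k = k, delta = delta)
  lens <- vapply(runs, length, integer(1))
  no_decline <- any(onsets == lens)
  ensemble <- as.integer(round(mean(onsets)))
  bundle <- structure(
    list(runs = runs, per_run_onset_h = onsets, ensemble_onset_h = ensemble,
         origin = origin, no_decline = no_decline),
    class = "forecast_bundle"
  )
  warn_at <- origin + 3600 * ensemble
  decision <- structure(
    list(origin = origin, warn_at = warn_at,
         warn_date = as.Date(origin, tz = "UTC") + round(ensemble / 24),
         lead_h = ensemble, irrigation_volume_L = irrigation_volume_L,
         no_decline = no_decline),
    class = "intervention_decision"
  )
  list(bundle = bundle, decision = decision)
}

#' @export
print.forecast_bundle <- function(x, ...) {
  cat(sprintf("<forecast_bundle> %d runs, onsets {%s} h -> ensemble %d h%s\n",
              length(x$runs), paste(x$per_run_onset_h, collapse = ", "),
              x$ensemble_onset_h, if (x$no_decline) " [no decline in some run]" else ""))
  invisible(x)
}

#' @export
print.intervention_decision <- function(x, ...) {
  if (x$no_decline) {
    cat("<intervention_decision> no decline predicted within the horizon\n")
  } else {
    cat(sprintf("<intervention_decision> warn issued %s for predicted decline %s (lead %d h), advise %g L\n",
                format(x$origin), format(x$warn_at), x$lead_h, x$irrigation_volume_L))
  }
  invisible(x)
}

#' Train an ensemble and decide the next irrigation time
#'
#' The repeated-prediction protocol: train `n_runs` models with seeds
#' `seed, seed + 1, ...`, forecast the status trajectory from the origin with
#' each, smooth each trajectory, and average the detected decline onsets into
#' one irrigation warning.
#'
#' @param fm a [build_features()] feature matrix ending at the forecast origin.
#' @param cfg an [informer_config()].
#' @param seed base integer seed; run r uses `seed + r - 1`.
#' @param n_runs number of repeated predictions (default 3).
#' @param origin_row forecast origin row (default the last row).
#' @param k,delta decline-detector parameters.
#' @param irrigation_volume_L advisory volume for the decision.
#' @return As [ensemble_decide()], plus `checkpoints` (the trained models).
#' @export
ensemble_forecast <- function(fm, cfg = informer_config(), seed = 1L,
                              n_runs = 3L, origin_row = nrow(fm$features),
                              k = 6L, delta = 0.05, irrigation_volume_L = 85) {
  ckpts <- lapply(seq_len(n_runs), function(r) {
    train_model(fm, cfg, seed = as.integer(seed) + r - 1L)
  })
  runs <- lapply(ckpts, function(ck) {
    forecast_status(fm, ck, origin_row = origin_row)$smoothed
  })
  res <- ensemble_decide(runs, fm$timestamps[origin_row], k = k, delta = delta,
                         irrigation_volume_L = irrigation_volume_L)
  res$checkpoints <- ckpts
  res
}

#' Closed-loop irrigation scheduling on the synthetic greenhouse
#'
#' Co-simulates a season under either a fixed weekly calendar or the
#' event-triggered policy, in which each irrigation is placed at the ensemble
#' warning time predicted from the data observed so far (after a post-
#' irrigation cooldown during which fresh data are collected).
#'
#' @param sim_cfg a [simulator_config()]; its `horizon_days` is the loop horizon.
#' @param policy `"event"` or `"fixed"`.
#' @param ckpts list of trained checkpoints used for the event policy's
#'   repeated predictions (ignored for `"fixed"`).
#' @param cooldown_h hours of data collection after an irrigation before the
#'   next forecast is issued (default 120 = about 5 days).
#' @param fixed_period_h fixed-policy irrigation period (default 168 = weekly).
#' @param volume_fixed_L fixed-policy volume per event (default 135 L).
#' @param volume_event_L event-policy advisory volume (default 85 L).
#' @param k,delta decline-detector parameters.
#' @return A list: `log` (data frame: date, field, volume_L, hour),
#'   `n_events`, `season` (the final simulated season), `policy`,
#'   `status_drawdown` (largest drop of true status below its running
#'   maximum, a stress indicator).
#' @export
closed_loop_schedule <- function(sim_cfg, policy = c("event", "fixed"),
                                 ckpts = NULL, cooldown_h = 120L,
                                 fixed_period_h = 168L,
                                 volume_fixed_L = 135, volume_event_L = 85,
                                 k = 6L, delta = 0.05) {
  policy <- match.arg(policy)
  H <- as.integer(round(sim_cfg$horizon_days * 24))
  if (policy == "fixed") {
    events <- seq(0L, H - 1L, by = as.integer(fixed_period_h))
    season <- simulate_season(sim_cfg, irrigation_hours = events[events > 0])
    volume <- volume_fixed_L
  } else {
    if (is.null(ckpts) || !length(ckpts)) {
      stop("event policy needs trained checkpoints")
    }
    cfg <- ckpts[[1]]$cfg
    events <- integer()
    last_event <- 0L
    guard <- 0L
    repeat {
      guard <- guard + 1L
      if (guard > 50L) break
      origin <- max(last_event + as.integer(cooldown_h), cfg$seq_len)
      if (origin >= H) break
      season <- simulate_season(sim_cfg, irrigation_hours = events)
      fm <- season_features(season, end_row = origin,
                            scalers = ckpts[[1]]$scalers)
      runs <- lapply(ckpts, function(ck) {
        forecast_status(fm, ck, origin_row = origin)$smoothed
      })
      dec <- ensemble_decide(runs, season$timestamps[origin], k = k, delta = delta,
                             irrigation_volume_L = volume_event_L)
      if (dec$bundle$no_decline) {
        # nothing predicted within the horizon: look again after pred_len hours
        last_event <- origin + cfg$pred_len - as.integer(cooldown_h)
        next
      }
      w <- origin + dec$bundle$ensemble_onset_h
      if (w >= H) break
      events <- c(events, w)
      last_event <- w
    }
    season <- simulate_season(sim_cfg, irrigation_hours = events)
    events <- c(0L, events)
    volume <- volume_event_L
  }
  events_all <- events
  s_true <- season$truth$status_true
  drawdown <- max(cummax(s_true) - s_true)
  log <- data.frame(
    date = as.Date(sim_cfg$start + 3600 * events_all, tz = "UTC"),
    field = field_id(season$node1),
    volume_L = volume,
    hour = events_all
  )
  list(log = log, n_events = nrow(log), season = season, policy = policy,
       status_drawdown = drawdown)
}

#' Build a feature matrix from a simulated season
#'
#' Convenience wrapper: cleans both node frames with [preprocess_frame()] and
#' assembles the model-ready [build_features()] matrix from the first
#' `end_row` hours.
#'
#' @param season a [simulate_season()] result.
#' @param end_row last row (hour) to include; default the whole season.
#' @param preprocess run the screen/impute/smooth pipeline first (default TRUE).
#' @param sigma,window_h [preprocess_frame()] parameters.
#' @param scalers optional list with `scaler` and `target_scaler` (e.g. a
#'   checkpoint's `scalers`) applied instead of refitting; keeps deployment
#'   features on the training scale.
#' @return A [build_features()] feature matrix.
#' @export
season_features <- function(season, end_row = length(season$status),
                            preprocess = TRUE, sigma = 10, window_h = 216L,
                            scalers = NULL) {
  idx <- seq_len(end_row)
  cut_frame <- function(fr) {
    out <- fr[idx, , drop = FALSE]
    attr(out, "field_id") <- attr(fr, "field_id")
    attr(out, "node") <- attr(fr, "node")
    class(out) <- c("sensor_frame", "data.frame")
    out
  }
  n1 <- cut_frame(season$node1)
  n2 <- cut_frame(season$node2)
  if (preprocess) {
    n1 <- preprocess_frame(n1, sigma = sigma, window_h = window_h)$frame
    n2 <- preprocess_frame(n2, sigma = sigma, window_h = window_h)$frame
  }
  status <- season$status[idx]
  if (anyNA(status)) status <- interpolate_missing(status)
  build_features(n1, n2, status,
                 scaler = scalers$scaler,
                 target_scaler = scalers$target_scaler)
}
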