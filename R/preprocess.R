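#' Discrete Gaussian smoothing kernel
#'
#' Evaluates the Gaussian density exp(-x^2 / (2 sigma^2)) / (sigma sqrt(2 pi))
#' at integer offsets -radius..radius and renormalizes the weights to unit sum,
#' so that convolution preserves constants exactly.
#'
#' @param sigma kernel standard deviation in samples; the package default for
#'   sensor denoising is 10.
#' @param radius truncation half-width in samples; defaults to `ceiling(4 * sigma)`.
#' @return Numeric vector of length `2 * radius + 1` summing to 1.
#' @export
gaussian_kernel <- function(sigma, radius = ceiling(4 * sigma)) {
  if (!is.numeric(sigma) || length(sigma) != 1L || !is.finite(sigma) || sigma <= 0) {
    stop("`sigma` must be a single positive number")
  }
  radius <- as.integer(radius)
  if (radius < 1L) stop("`radius` must be >= 1")
  x <- (-radius):radius
  w <- exp(-x^2 / (2 * sigma^2)) / (sigma * sqrt(2 * pi))
  w / sum(w)
}

#' Gaussian denoising of an hourly series
#'
#' Convolves a complete (no `NA`) series with a normalized discrete Gaussian
#' kernel. Boundaries are handled by mirror reflection of the series
#' (`edge_mode = "reflect"`, the default) or by repeating the edge value
#' (`"nearest"`).
#'
#' @param series numeric vector without missing values.
#' @param sigma kernel standard deviation in samples (default 10).
#' @param radius truncation half-width in samples (default `ceiling(4 * sigma)`).
#' @param edge_mode `"reflect"` or `"nearest"` boundary rule.
#' @return Smoothed numeric vector, same length as `series`.
#' @examples
#' gaussian_smooth(sin(1:100 / 5) + rnorm(100, sd = 0.1), sigma = 3)
#' @export
gaussian_smooth <- function(series, sigma = 10, radius = ceiling(4 * sigma),
                            edge_mode = c("reflect", "nearest")) {
  edge_mode <- match.arg(edge_mode)
  if (anyNA(series)) stop("`series` must not contain missing values; impute first")
  n <- length(series)
  if (n < 1L) stop("`series` must have length >= 1")
  w <- gaussian_kernel(sigma, radius)
  r <- (length(w) - 1L) %/% 2L
  idx <- pad_indices(n, r, edge_mode)
  padded <- series[idx]
  out <- stats::filter(padded, w, method = "convolution", sides = 2)
  as.numeric(out[(r + 1L):(r + n)])
}

# Mirror/nearest padding index vector of length n + 2r for a length-n series.
pad_indices <- function(n, r, edge_mode) {
  i <- (1L - r):(n + r)
  if (edge_mode == "nearest") {
    return(pmin(pmax(i, 1L), n))
  }
  # edge-inclusive reflection: ... 3 2 1 | 1 2 .. n | n n-1 n-2 ...
  period <- 2L * n
  j <- (i - 1L) %% period
  ifelse(j < n, j + 1L, period - j)
}

#' Quartile summary with Tukey fences
#'
#' Computes Q1/Q2/Q3 by linear interpolation between order statistics
#' (fractional rank `p * (n - 1)`), the interquartile range IQR = Q3 - Q1, and
#' the outlier fences Q1 - 1.5 IQR and Q3 + 1.5 IQR used to screen sensor
#' spikes.
#'
#' @param values numeric vector of at least 4 non-missing values.
#' @return A list of class `quartile_summary` with elements `q1`, `q2`, `q3`,
#'   `iqr`, `lower_bound`, `upper_bound`.
#' @examples
#' quartile_summary(c(1, 2, 3, 4, 5, 6, 7, 8))
#' @export
quartile_summary <- function(values) {
  if (anyNA(values)) stop("`values` must not contain missing values")
  if (length(values) < 4L) stop("need at least 4 values for a quartile summary")
  q <- unname(stats::quantile(values, probs = c(0.25, 0.5, 0.75), type = 7))
  iqr <- q[3] - q[1]
  structure(
    list(
      q1 = q[1], q2 = q[2], q3 = q[3], iqr = iqr,
      lower_bound = q[1] - 1.5 * iqr,
      upper_bound = q[3] + 1.5 * iqr
    ),
    class = "quartile_summary"
  )
}

#' @export
print.quartile_summary <- function(x, ...) {
  cat(sprintf(
    "<quartile_summary> Q1=%.4g Q2=%.4g Q3=%.4g IQR=%.4g fences=[%.4g, %.4g]\n",
    x$q1, x$q2, x$q3, x$iqr, x$lower_bound, x$upper_bound
  ))
  invisible(x)
}

#' Screen outliers against quartile fences
#'
#' Flags values outside `[lower_bound, upper_bound]` of a [quartile_summary()]
#' and replaces them with the mean of the unflagged values.
#'
#' @param series numeric vector without missing values.
#' @param summary a `quartile_summary`, typically computed from `series` (or
#'   from the window of data the series was cut from).
#' @return A list with `flags` (logical vector) and `cleaned` (numeric vector).
#' @export
screen_outliers <- function(series, summary) {
  if (!inherits(summary, "quartile_summary")) {
    stop("`summary` must be a quartile_summary")
  }
  if (anyNA(series)) stop("`series` must not contain missing values")
  flags <- series < summary$lower_bound | series > summary$upper_bound
  if (all(flags)) stop("all points flagged as outliers; degenerate data")
  repl <- mean(series[!flags])
  cleaned <- series
  cleaned[flags] <- repl
  list(flags = flags, cleaned = cleaned)
}

#' Windowed outlier screening of one channel
#'
#' Cuts the series into consecutive windows (default 9 days = 216 h), computes
#' the quartile fences inside each window, and replaces flagged cells with the
#' window mean of the unflagged cells. Cells that are `NA` are passed through
#' untouched (impute afterwards).
#'
#' @param series numeric vector, possibly with `NA` cells.
#' @param window_h window length in hours (default 216).
#' @return A list with `flags` and `cleaned` as in [screen_outliers()].
#' @export
screen_outliers_windowed <- function(series, window_h = 216L) {
  n <- length(series)
  flags <- rep(FALSE, n)
  cleaned <- series
  starts <- seq(1L, n, by = window_h)
  for (s in starts) {
    e <- min(s + window_h - 1L, n)
    idx <- s:e
    obs <- idx[!is.na(series[idx])]
    if (length(obs) < 4L) next
    qs <- quartile_summary(series[obs])
    f <- series[obs] < qs$lower_bound | series[obs] > qs$upper_bound
    if (all(f)) next
    flags[obs[f]] <- TRUE
    cleaned[obs[f]] <- mean(series[obs[!f]])
  }
  list(flags = flags, cleaned = cleaned)
}

#' Linear interpolation of missing cells
#'
#' Replaces interior `NA` cells with the straight line through the bracketing
#' observed points evaluated at the missing timestamp. Leading/trailing gaps,
#' which have no bracketing neighbor on one side, take the nearest observed
#' value.
#'
#' @param series numeric vector with `NA` cells.
#' @param timestamps numeric or POSIXct sampling instants (default the index).
#' @return Numeric vector with no missing cells; observed cells are untouched.
#' @examples
#' interpolate_missing(c(4, NA, 10))  # -> 4 7 10
#' @export
interpolate_missing <- function(series, timestamps = seq_along(series)) {
  if (length(series) != length(timestamps)) {
    stop("`series` and `timestamps` must have equal length")
  }
  obs <- which(!is.na(series))
  if (length(obs) < 2L) stop("need at least 2 observed cells to interpolate")
  if (length(obs) == length(series)) return(series)
  t_num <- as.numeric(timestamps)
  out <- stats::approx(t_num[obs], series[obs], xout = t_num,
                       method = "linear", rule = 2)$y
  out
}

#' Fit a per-column min-max scaler
#'
#' @param x numeric matrix.
#' @return List of class `minmax_scaler` with `min` and `range` per column
#'   (zero ranges are replaced by 1 so constant columns map to 0).
#' @export
fit_minmax <- function(x) {
  x <- as.matrix(x)
  mn <- apply(x, 2, min)
  mx <- apply(x, 2, max)
  rg <- mx - mn
  rg[rg == 0] <- 1
  structure(list(min = mn, range = rg), class = "minmax_scaler")
}

#' Apply a min-max scaler (map training columns into [0, 1])
#' @param scaler a `minmax_scaler` from [fit_minmax()].
#' @param x numeric matrix with the same columns the scaler was fitted on.
#' @return Scaled matrix.
#' @export
apply_minmax <- function(scaler, x) {
  x <- as.matrix(x)
  sweep(sweep(x, 2, scaler$min, "-"), 2, scaler$range, "/")
}

#' Invert a min-max scaler
#' @inheritParams apply_minmax
#' @return Matrix on the original scale.
#' @export
invert_minmax <- function(scaler, x) {
  x <- as.matrix(x)
  sweep(sweep(x, 2, scaler$range, "*"), 2, scaler$min, "+")
}

#' Clean one sensor frame: screen, impute, smooth
#'
#' Applies, per channel and in this order: windowed quartile-fence outlier
#' screening, linear imputation of missing cells, and Gaussian denoising.
#'
#' @param frame a [sensor_frame()].
#' @param sigma Gaussian kernel standard deviation in samples (default 10).
#' @param window_h outlier-screening window in hours (default 216 = 9 days).
#' @return A list with `frame` (cleaned `sensor_frame`) and `qc`, a per-channel
#'   data frame of flagged and imputed cell counts.
#' @export
preprocess_frame <- function(frame, sigma = 10, window_h = 216L) {
  validate_sensor_frame(frame)
  chans <- channels(frame)
  qc <- data.frame(channel = chans, n_flagged = 0L, n_imputed = 0L)
  out <- frame
  for (i in seq_along(chans)) {
    v <- frame[[chans[i]]]
    scr <- screen_outliers_windowed(v, window_h = window_h)
    qc$n_flagged[i] <- sum(scr$flags)
    v <- scr$cleaned
    qc$n_imputed[i] <- sum(is.na(v))
    if (anyNA(v)) v <- interpolate_missing(v, frame$timestamp)
    out[[chans[i]]] <- gaussian_smooth(v, sigma = sigma)
  }
  list(frame = out, qc = qc)
}

#' Assemble the model-ready feature matrix
#'
#' Combines two soil nodes (10 cm and 20 cm depth) and the hourly growth-status
#' target into one matrix holding: the raw channels, per-variable soil-layer
#' differences (node1 - node2), per-variable adjacent-sensor means, the lagged
#' status target, and calendar features (hour-of-day sine/cosine and a scaled
#' hour index). All columns and the target are min-max scaled into [0, 1]; the
#' scaler is retained for inversion.
#'
#' @param node1 `sensor_frame` for the 10 cm node (must also carry the air
#'   channels `air_temp_C`, `air_hum_pct`).
#' @param node2 `sensor_frame` for the 20 cm node (soil channels only used).
#' @param status numeric growth-status series on the same hourly grid, in [0, 1].
#' @param lag lag (hours) of the lagged-status column (default 1).
#' @param band_lo favorable soil-moisture band floor (%); stored for the
#'   forecaster's moisture-deficit channel (default 30).
#' @param scaler,target_scaler optional pre-fitted [fit_minmax()] scalers
#'   (e.g. from the training data of a checkpoint); when NULL they are fitted
#'   on the supplied data.
#' @return A list of class `feature_matrix`: `timestamps`, `features` (scaled
#'   T x F matrix), `target` (scaled status), `scaler`, `target_scaler`,
#'   `time_cols` (names of the calendar columns, which are also known for
#'   future instants).
#' @export
build_features <- function(node1, node2, status, lag = 1L, band_lo = 30,
                           scaler = NULL, target_scaler = NULL) {
  validate_sensor_frame(node1)
  validate_sensor_frame(node2)
  if (nrow(node1) != nrow(node2) ||
      any(abs(as.numeric(node1$timestamp) - as.numeric(node2$timestamp)) > 1e-6)) {
    stop("node frames are not aligned on the same hourly grid")
  }
  if (length(status) != nrow(node1)) {
    stop("`status` must match the hourly grid of the node frames")
  }
  if (anyNA(status)) stop("`status` must be complete; impute first")
  soil_vars <- c("soil_temp_C", "soil_moist_pct", "soil_cond_uScm")
  for (v in soil_vars) {
    if (is.null(node1[[v]]) || is.null(node2[[v]])) {
      stop("both nodes must carry channel `", v, "`")
    }
    if (anyNA(node1[[v]]) || anyNA(node2[[v]])) {
      stop("feature channels must be complete; run preprocess_frame() first")
    }
  }
  feats <- list()
  for (v in soil_vars) {
    feats[[paste0(v, "_n1")]] <- node1[[v]]
    feats[[paste0(v, "_n2")]] <- node2[[v]]
    feats[[paste0(v, "_diff")]] <- node1[[v]] - node2[[v]]
    feats[[paste0(v, "_mean")]] <- (node1[[v]] + node2[[v]]) / 2
  }
  for (v in c("air_temp_C", "air_hum_pct")) {
    if (!is.null(node1[[v]])) feats[[v]] <- node1[[v]]
  }
  lag <- as.integer(lag)
  lagged <- c(rep(status[1], lag), status[seq_len(length(status) - lag)])
  feats[["status_lag"]] <- lagged
  tf <- time_features(node1$timestamp)
  for (nm in colnames(tf)) feats[[nm]] <- tf[, nm]
  X <- do.call(cbind, feats)
  colnames(X) <- names(feats)
  if (is.null(scaler)) scaler <- fit_minmax(X)
  tsc <- if (is.null(target_scaler)) {
    fit_minmax(matrix(status, ncol = 1, dimnames = list(NULL, "status")))
  } else {
    target_scaler
  }
  structure(
    list(
      timestamps = node1$timestamp,
      features = apply_minmax(scaler, X),
      target = as.numeric(apply_minmax(tsc, matrix(status, ncol = 1))),
      scaler = scaler,
      target_scaler = tsc,
      time_cols = colnames(tf),
      band_lo = band_lo
    ),
    class = "feature_matrix"
  )
}

# Calendar features usable for both observed and future instants.
time_features <- function(timestamps) {
  h <- as.numeric(format(timestamps, "%H", tz = attr(timestamps, "tzone") %||% "UTC"))
  t0 <- as.numeric(timestamps[1])
  hrs <- (as.numeric(timestamps) - t0) / 3600
  cbind(
    hour_sin = sin(2 * pi * h / 24),
    hour_cos = cos(2 * pi * h / 24),
    t_scaled = hrs / 2400
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.feature_matrix <- function(x, ...) {
  cat(sprintf("<feature_matrix> %d hourly rows x %d columns (target in [%.3f, %.3f])\n",
              nrow(x$features), ncol(x$features), min(x$target), max(x$target)))
  invisible(x)
}
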