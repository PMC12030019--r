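#' Hourly multivariate sensor frame
#'
#' A `sensor_frame` is a data frame with a POSIXct `timestamp` column on a
#' strict 1-hour grid plus one numeric column per sensor channel (e.g.
#' `soil_temp_C`, `soil_moist_pct`, `soil_cond_uScm`, `air_temp_C`,
#' `air_hum_pct`). Missing readings are `NA`. The plot label and sensor node
#' (1 = 10 cm depth, 2 = 20 cm depth) travel as attributes.
#'
#' @param timestamps POSIXct vector, strictly increasing, 1 h spacing.
#' @param data data frame (or named list) of numeric channels, one value per
#'   timestamp; `NA` marks a missing reading.
#' @param field_id plot label such as `"A1"`.
#' @param node integer sensor node id.
#' @return An object of class `sensor_frame`.
#' @examples
#' ts <- seq(as.POSIXct("2024-04-01", tz = "UTC"), by = "hour", length.out = 48)
#' sf <- sensor_frame(ts, data.frame(soil_moist_pct = runif(48, 30, 60)))
#' @export
sensor_frame <- function(timestamps, data, field_id = "A1", node = 1L) {
  if (!inherits(timestamps, "POSIXct")) {
    stop("`timestamps` must be POSIXct")
  }
  data <- as.data.frame(data)
  if (nrow(data) != length(timestamps)) {
    stop("`data` must have one row per timestamp")
  }
  x <- cbind(data.frame(timestamp = timestamps), data)
  attr(x, "field_id") <- field_id
  attr(x, "node") <- as.integer(node)
  class(x) <- c("sensor_frame", "data.frame")
  validate_sensor_frame(x)
  x
}

validate_sensor_frame <- function(x) {
  ts <- x$timestamp
  if (length(ts) < 2L) stop("sensor_frame needs at least 2 rows")
  dt <- diff(as.numeric(ts))
  if (any(dt <= 0)) stop("timestamps must be strictly increasing")
  if (any(abs(dt - 3600) > 1e-6)) stop("timestamps must be on a 1-hour grid")
  nm <- names(x)
  if (anyDuplicated(nm)) stop("column names must be unique")
  chans <- setdiff(nm, "timestamp")
  if (length(chans) < 1L) stop("sensor_frame needs at least one channel")
  for (ch in chans) {
    if (!is.numeric(x[[ch]])) stop("channel `", ch, "` must be numeric")
  }
  invisible(x)
}

#' @export
print.sensor_frame <- function(x, ...) {
  cat(sprintf(
    "<sensor_frame> field %s, node %d: %d hourly rows x %d channels (%s .. %s)\n",
    attr(x, "field_id"), attr(x, "node"), nrow(x), ncol(x) - 1L,
    format(x$timestamp[1]), format(x$timestamp[nrow(x)])
  ))
  n_na <- sum(is.na(as.matrix(x[, -1, drop = FALSE])))
  cat(sprintf("  channels: %s\n  missing cells: %d\n",
              paste(setdiff(names(x), "timestamp"), collapse = ", "), n_na))
  invisible(x)
}

#' Channel names of a sensor frame
#' @param x a `sensor_frame`.
#' @return Character vector of channel (non-timestamp) column names.
#' @export
channels <- function(x) setdiff(names(x), "timestamp")

#' Plot label of a sensor frame
#' @param x a `sensor_frame`.
#' @return The field/plot label.
#' @export
field_id <- function(x) attr(x, "field_id")
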