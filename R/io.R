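#' Read hourly sensor tables from CSV
#'
#' Expects comma-separated UTF-8 text with a header row and columns
#' `timestamp` (ISO-8601), `field`, `node`, plus one column per sensor
#' channel; empty cells are missing readings. Rows are sorted into time order
#' on read. Unknown columns are kept (with a warning); duplicate timestamps
#' within one (field, node) series are an error.
#'
#' @param path CSV file path.
#' @param field,node optional filters selecting one series.
#' @return A single [sensor_frame()] if exactly one (field, node) combination
#'   remains, otherwise a named list of them (`"<field>.<node>"`).
#' @export
read_sensor_csv <- function(path, field = NULL, node = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  req <- c("timestamp", "field", "node")
  if (!all(req %in% names(raw))) {
    stop("sensor CSV needs columns: ", paste(req, collapse = ", "))
  }
  known <- c(req, "soil_temp_C", "soil_moist_pct", "soil_cond_uScm",
             "air_temp_C", "air_hum_pct")
  extra <- setdiff(names(raw), known)
  if (length(extra)) {
    warning("unknown columns retained: ", paste(extra, collapse = ", "))
  }
  if (!is.null(field)) raw <- raw[raw$field %in% field, , drop = FALSE]
  if (!is.null(node)) raw <- raw[raw$node %in% node, , drop = FALSE]
  if (!nrow(raw)) stop("no rows after filtering")
  out <- list()
  for (f in unique(raw$field)) {
    for (nd in unique(raw$node[raw$field == f])) {
      sub <- raw[raw$field == f & raw$node == nd, , drop = FALSE]
      ts <- as.POSIXct(sub$timestamp, tz = "UTC",
                       tryFormats = c("%Y-%m-%dT%H:%M:%OSZ",
                                      "%Y-%m-%dT%H:%M:%OS",
                                      "%Y-%m-%d %H:%M:%OS",
                                      "%Y-%m-%d %H:%M",
                                      "%Y-%m-%d"))
      if (anyNA(ts)) stop("unparseable timestamps in ", f, " node ", nd)
      if (anyDuplicated(ts)) {
        stop("duplicate timestamps for field ", f, " node ", nd)
      }
      ord <- order(ts)
      chan_cols <- setdiff(names(sub), req)
      dat <- sub[ord, chan_cols, drop = FALSE]
      dat[] <- lapply(dat, as.numeric)
      out[[paste0(f, ".", nd)]] <- sensor_frame(ts[ord], dat, field_id = f,
                                                node = as.integer(nd))
    }
  }
  if (length(out) == 1L) out[[1]] else out
}

#' Write sensor frames to the CSV dialect [read_sensor_csv()] consumes
#'
#' @param frames a [sensor_frame()] or list of them.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_sensor_csv <- function(frames, path) {
  if (inherits(frames, "sensor_frame")) frames <- list(frames)
  rows <- lapply(frames, function(fr) {
    cbind(
      data.frame(
        timestamp = format(fr$timestamp, "%Y-%m-%dT%H:%M:%SZ", tz = "UTC"),
        field = field_id(fr), node = attr(fr, "node")
      ),
      as.data.frame(fr)[, channels(fr), drop = FALSE]
    )
  })
  all_cols <- Reduce(union, lapply(rows, names))
  rows <- lapply(rows, function(r) {
    for (m in setdiff(all_cols, names(r))) r[[m]] <- NA
    r[, all_cols, drop = FALSE]
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE, na = "")
  invisible(path)
}

#' Pipeline run configuration
#'
#' Collects every knob of [run_pipeline()] in one serializable list: the seed,
#' the simulator settings (or input CSV paths), the forecasting window and
#' training settings, and the decision parameters. The configuration is echoed
#' verbatim into every output manifest.
#'
#' @param seed master seed; all randomness in the run flows from it.
#' @param out_dir output directory for artifacts.
#' @param simulate if TRUE generate the season with [simulate_season()];
#'   otherwise read `node1_csv`/`node2_csv`/`status_csv`.
#' @param sim list of [simulator_config()] overrides.
#' @param irrigation_hours irrigation schedule for the simulated season.
#' @param window list of [informer_config()] overrides.
#' @param n_runs repeated predictions in the ensemble (default 3).
#' @param k,delta decline-detector parameters.
#' @param irrigation_volume_L advisory volume.
#' @param node1_csv,node2_csv,status_csv input paths when `simulate = FALSE`
#'   (`status_csv` needs columns `timestamp`, `status`).
#' @return A list of class `run_config`.
#' @export
run_config <- function(seed = 1L, out_dir = tempfile("growcast_run_"),
                       simulate = TRUE, sim = list(),
                       irrigation_hours = c(240L, 480L, 720L, 960L),
                       window = list(), n_runs = 3L,
                       k = 6L, delta = 0.05, irrigation_volume_L = 85,
                       node1_csv = NULL, node2_csv = NULL, status_csv = NULL) {
  cfg <- list(seed = as.integer(seed), out_dir = out_dir, simulate = simulate,
              sim = sim, irrigation_hours = as.integer(irrigation_hours),
              window = window, n_runs = as.integer(n_runs), k = as.integer(k),
              delta = delta, irrigation_volume_L = irrigation_volume_L,
              node1_csv = node1_csv, node2_csv = node2_csv,
              status_csv = status_csv)
  class(cfg) <- "run_config"
  cfg
}

#' Read a run configuration from JSON
#' @param path JSON file with [run_config()] fields.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  vals <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(run_config, vals)
}

pipeline_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    stop(sprintf("[stage %s] %s", stage, conditionMessage(e)), call. = FALSE)
  })
}

#' Run the full forecasting and decision pipeline
#'
#' Executes: data acquisition (simulate or read) -> preprocessing and feature
#' assembly -> ensemble training and repeated prediction -> decline-onset
#' decision -> artifact writing. Every artifact carries the configuration and
#' seed. A failure in any stage aborts with a stage-labeled error.
#'
#' @param config a [run_config()].
#' @return Invisibly, a list with `decision`, `bundle`, `qc`, and `paths`
#'   (decision JSON, QC JSON).
#' @export
run_pipeline <- function(config = run_config()) {
  if (!inherits(config, "run_config")) stop("`config` must be a run_config")
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)

  acquired <- pipeline_stage("acquire", {
    if (isTRUE(config$simulate)) {
      sim_cfg <- do.call(simulator_config,
                         c(config$sim, list(seed = config$seed)))
      season <- simulate_season(sim_cfg, irrigation_hours = config$irrigation_hours)
      list(node1 = season$node1, node2 = season$node2, status = season$status,
           timestamps = season$timestamps)
    } else {
      n1 <- read_sensor_csv(config$node1_csv)
      n2 <- read_sensor_csv(config$node2_csv)
      if (is.list(n1) && !inherits(n1, "sensor_frame")) n1 <- n1[[1]]
      if (is.list(n2) && !inherits(n2, "sensor_frame")) n2 <- n2[[1]]
      st <- utils::read.csv(config$status_csv)
      list(node1 = n1, node2 = n2, status = as.numeric(st$status),
           timestamps = n1$timestamp)
    }
  })

  prep <- pipeline_stage("preprocess", {
    p1 <- preprocess_frame(acquired$node1)
    p2 <- preprocess_frame(acquired$node2)
    status <- acquired$status
    if (anyNA(status)) status <- interpolate_missing(status)
    fm <- build_features(p1$frame, p2$frame, status)
    list(fm = fm, qc = rbind(cbind(node = 1L, p1$qc), cbind(node = 2L, p2$qc)))
  })

  wcfg <- pipeline_stage("configure", do.call(informer_config, config$window))

  res <- pipeline_stage("forecast", {
    ensemble_forecast(prep$fm, wcfg, seed = config$seed,
                      n_runs = config$n_runs, k = config$k,
                      delta = config$delta,
                      irrigation_volume_L = config$irrigation_volume_L)
  })

  paths <- pipeline_stage("report", {
    manifest <- config
    class(manifest) <- NULL
    manifest$out_dir <- NULL
    dec <- res$decision
    decision_json <- file.path(config$out_dir, "decision.json")
    jsonlite::write_json(
      list(
        origin = format(dec$origin, "%Y-%m-%dT%H:%M:%SZ", tz = "UTC"),
        per_run_onset_h = res$bundle$per_run_onset_h,
        ensemble_onset_h = res$bundle$ensemble_onset_h,
        warn_at = format(dec$warn_at, "%Y-%m-%dT%H:%M:%SZ", tz = "UTC"),
        warn_date = format(dec$warn_date),
        lead_h = dec$lead_h,
        no_decline = dec$no_decline,
        irrigation_volume_L = dec$irrigation_volume_L,
        config = manifest
      ),
      decision_json, auto_unbox = TRUE, digits = NA
    )
    qc_json <- file.path(config$out_dir, "qc.json")
    jsonlite::write_json(prep$qc, qc_json, dataframe = "rows", digits = NA)
    list(decision = decision_json, qc = qc_json)
  })

  invisible(list(decision = res$decision, bundle = res$bundle, qc = prep$qc,
                 paths = paths))
}
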