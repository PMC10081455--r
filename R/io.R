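#' Read an observation table from delimited text
#'
#' Expects a comma-separated file with header
#' `unit_id,obs_id,duration,count[,covariate...,outcome]`. Counts are
#' validated as non-negative integers (raw event numbers, never rates) and
#' durations as positive.
#'
#' @param path file path.
#' @param duration_unit `"hours"` (default) or `"minutes"`; minute durations
#'   are converted to hours on read.
#' @return validated data.frame.
#' @export
read_observation_table <- function(path, duration_unit = c("hours", "minutes")) {
  duration_unit <- match.arg(duration_unit)
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  df <- read.csv(path, stringsAsFactors = FALSE)
  needed <- c("unit_id", "obs_id", "duration", "count")
  miss <- setdiff(needed, names(df))
  if (length(miss)) {
    stop("observation table is missing columns: ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  if (duration_unit == "minutes") df$duration <- df$duration / 60
  validate_observation_table(df)
  df
}

#' Write an observation table
#' @param table observation table.
#' @param path destination file.
#' @export
write_observation_table <- function(table, path) {
  validate_observation_table(table)
  write.csv(table, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read raw event series from delimited text
#'
#' Format: header `unit_id,obs_id,duration,time`, one row per event;
#' an observation with zero events appears once with an empty `time` cell.
#'
#' @param path file path.
#' @return list of [event_series()].
#' @export
read_event_series <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  df <- read.csv(path, stringsAsFactors = FALSE, na.strings = c("", "NA"))
  needed <- c("unit_id", "obs_id", "duration", "time")
  miss <- setdiff(needed, names(df))
  if (length(miss)) {
    stop("event series file is missing columns: ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  key <- paste(df$unit_id, df$obs_id, sep = "\r")
  lapply(split(df, factor(key, levels = unique(key))), function(d) {
    event_series(d$unit_id[1], d$obs_id[1], d$duration[1],
                 sort(d$time[!is.na(d$time)]))
  }) |> unname()
}

#' Write event series to delimited text
#' @param series an [event_series()] or list of them.
#' @param path destination file.
#' @export
write_event_series <- function(series, path) {
  if (inherits(series, "event_series")) series <- list(series)
  rows <- lapply(series, function(s) {
    if (length(s$times)) {
      data.frame(unit_id = s$unit_id, obs_id = s$obs_id,
                 duration = s$duration, time = s$times)
    } else {
      data.frame(unit_id = s$unit_id, obs_id = s$obs_id,
                 duration = s$duration, time = NA_real_)
    }
  })
  df <- do.call(rbind, rows)
  df$time[is.na(df$time)] <- ""
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Generate the bundled example studies (Studies A, B, C)
#'
#' Deterministic observation tables for three studies of the same simulated
#' population — mean rate 10 events/hour, rate SD 3 (expected CV 0.3),
#' expected-scale ICC 0.5 — observed for 2, 1 and 0.5 hours (mean counts
#' 20, 10, 5). Used across the test suite and examples.
#'
#' @param dir directory to write `study_A.csv`, `study_B.csv`, `study_C.csv`
#'   into, or `NULL` (default) to return the tables without writing.
#' @param seed integer seed (fixed seed gives byte-identical files).
#' @param n_units,obs_per_unit study dimensions.
#' @return named list of the three observation tables (invisibly when
#'   writing).
#' @export
make_fixtures <- function(dir = NULL, seed = 20230404, n_units = 200,
                          obs_per_unit = 5) {
  durations <- c(A = 2, B = 1, C = 0.5)
  out <- lapply(seq_along(durations), function(i) {
    simulate_study(mean_rate = 10, cv_exp = 0.3, icc_exp = 0.5,
                   n_units = n_units, obs_per_unit = obs_per_unit,
                   duration = durations[[i]],
                   seed = as.integer(seed) + i - 1L)
  })
  names(out) <- names(durations)
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    for (nm in names(out)) {
      write_observation_table(out[[nm]],
                              file.path(dir, paste0("study_", nm, ".csv")))
    }
    return(invisible(out))
  }
  out
}
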