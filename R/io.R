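#' Read and write the package's CSV interchange formats
#'
#' Activity records are stored as `datetime,counts`; light-logger records
#' as `datetime,lux` (with logger range metadata in an optional JSON
#' sidecar); schedules as `day,pulse_start_hours,duration_hours`;
#' regimens as `datetime,lux`; twilight tables as `day,dawn_h,dusk_h`.
#' All datetimes are written in UTC as `%Y-%m-%d %H:%M:%S`.
#'
#' @param record,log,schedule,regimen the object to write.
#' @param path file path.
#' @name circapulse-io
NULL

.fmt_dt <- function(t0, i, bin_minutes) {
  format(t0 + (i - 1) * bin_minutes * 60, "%Y-%m-%d %H:%M:%S", tz = "UTC")
}

#' @rdname circapulse-io
#' @export
write_activity_csv <- function(record, path) {
  stopifnot(inherits(record, "activity_record"))
  df <- data.frame(datetime = .fmt_dt(record$start_datetime,
                                      seq_along(record$counts),
                                      record$bin_minutes),
                   counts = record$counts)
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname circapulse-io
#' @param bin_minutes bin width, minutes (checked against the timestamps).
#' @param animal_id label for the record.
#' @export
read_activity_csv <- function(path, bin_minutes = 5, animal_id = "file") {
  df <- read.csv(path, stringsAsFactors = FALSE)
  stopifnot(all(c("datetime", "counts") %in% names(df)))
  t <- as.POSIXct(df$datetime, tz = "UTC")
  if (nrow(df) > 1) {
    step <- as.numeric(difftime(t[2], t[1], units = "mins"))
    if (abs(step - bin_minutes) > 1e-6)
      stop("timestamp step (", step, " min) does not match bin_minutes")
  }
  activity_record(df$counts, bin_minutes, t[1], animal_id)
}

#' @rdname circapulse-io
#' @param sidecar logical; also write `<path>.json` with
#'   `range_min,range_max,basal`.
#' @export
write_light_log_csv <- function(log, path, sidecar = TRUE) {
  stopifnot(inherits(log, "light_log_record"))
  df <- data.frame(datetime = .fmt_dt(log$start_datetime,
                                      seq_along(log$lux), log$bin_minutes),
                   lux = log$lux)
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  if (sidecar) {
    meta <- sprintf('{"range_min": %g, "range_max": %g, "basal": %g}',
                    log$range_min, log$range_max, log$basal)
    writeLines(meta, paste0(path, ".json"))
  }
  invisible(path)
}

#' @rdname circapulse-io
#' @param range_min,range_max logger range, lux (overridden by a sidecar
#'   file `<path>.json` when present).
#' @export
read_light_log_csv <- function(path, bin_minutes = 5, range_min = 0.3,
                               range_max = 19000, animal_id = "file") {
  df <- read.csv(path, stringsAsFactors = FALSE)
  stopifnot(all(c("datetime", "lux") %in% names(df)))
  side <- paste0(path, ".json")
  if (file.exists(side)) {
    meta <- .parse_flat_json(readLines(side, warn = FALSE))
    range_min <- meta[["range_min"]] %||% range_min
    range_max <- meta[["range_max"]] %||% range_max
  }
  t <- as.POSIXct(df$datetime, tz = "UTC")
  light_log_record(df$lux, bin_minutes, range_min, range_max, t[1], animal_id)
}

# one-level {"k": num, ...} parser for the sidecar (no dependency needed)
.parse_flat_json <- function(txt) {
  txt <- paste(txt, collapse = "")
  txt <- gsub("[{}\"]", "", txt)
  parts <- strsplit(txt, ",")[[1]]
  kv <- strsplit(parts, ":")
  out <- lapply(kv, function(p) as.numeric(trimws(p[2])))
  names(out) <- vapply(kv, function(p) trimws(p[1]), character(1))
  out
}

#' @rdname circapulse-io
#' @export
write_schedule_csv <- function(schedule, path) {
  stopifnot(inherits(schedule, "pulse_schedule"))
  df <- data.frame(day = schedule$day,
                   pulse_start_hours = schedule$pulse_start,
                   duration_hours = attr(schedule, "pulse_duration"))
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname circapulse-io
#' @export
write_regimen_csv <- function(regimen, path) {
  stopifnot(inherits(regimen, "light_regimen"))
  df <- data.frame(datetime = .fmt_dt(regimen$start_datetime,
                                      seq_along(regimen$lux),
                                      regimen$resolution_min),
                   lux = regimen$lux)
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname circapulse-io
#' @export
read_twilight_csv <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  stopifnot(all(c("day", "dawn_h", "dusk_h") %in% names(df)))
  df
}

#' @rdname circapulse-io
#' @export
write_periodogram_csv <- function(periodogram, path) {
  stopifnot(inherits(periodogram, "chi_sq_periodogram"))
  write.csv(as.data.frame(periodogram), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @param periodogram a `chi_sq_periodogram`.
#' @rdname circapulse-io
#' @export
write_markers_csv <- function(markers, path) {
  stopifnot(inherits(markers, "phase_markers"))
  write.csv(as.data.frame(markers), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @param markers a `phase_markers` object.
#' @rdname circapulse-io
#' @export
write_trajectory_csv <- function(traj, path) {
  stopifnot(inherits(traj, "circadian_trajectory"))
  df <- as.data.frame(traj)
  names(df) <- c("time_h", "x1", "x2", "phase_h", "amplitude")
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @param traj a `circadian_trajectory`.
#' @rdname circapulse-io
#' @export
write_prc_csv <- function(prc, path) {
  stopifnot(inherits(prc, "prc"))
  df <- as.data.frame(prc)
  names(df) <- c("ct_h", "shift_h")
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @param prc a `prc` object.
#' @rdname circapulse-io
NULL
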