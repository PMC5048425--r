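#' Detect light-exposure episodes in a logger record
#'
#' An exposure episode is a maximal run of consecutive bins whose value
#' strictly exceeds the record's basal (lowest) value; ties at basal are
#' darkness. An episode spanning midnight is attributed to the day of its
#' first sample.
#'
#' @param log a [light_log_record()].
#' @return Data frame with one row per episode: `start`, `end`
#'   (POSIXct; `end` is the end of the last supra-basal bin), `start_h`
#'   (clock hours of the first bin), `peak_lux`, `day_index` (1-based day
#'   of the episode start) and `n_bins`. A constant record yields zero
#'   rows with a warning.
#' @export
detect_exposure_episodes <- function(log) {
  stopifnot(inherits(log, "light_log_record"))
  if (length(log$lux) == 0) stop("empty record")
  basal <- min(log$lux)
  above <- log$lux > basal
  if (!any(above)) {
    warning("constant record: no supra-basal samples, no episodes")
    return(data.frame(start = as.POSIXct(character(0), tz = "UTC"),
                      end = as.POSIXct(character(0), tz = "UTC"),
                      start_h = numeric(0), peak_lux = numeric(0),
                      day_index = integer(0), n_bins = integer(0)))
  }
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  keep <- which(r$values)
  bin_s <- log$bin_minutes * 60
  s_idx <- starts[keep]
  e_idx <- ends[keep]
  start_t <- log$start_datetime + (s_idx - 1) * bin_s
  data.frame(
    start = start_t,
    end = log$start_datetime + e_idx * bin_s,
    start_h = (((s_idx - 1) * log$bin_minutes) / 60) %% 24,
    peak_lux = vapply(seq_along(keep),
                      function(j) max(log$lux[s_idx[j]:e_idx[j]]), numeric(1)),
    day_index = ((s_idx - 1) * log$bin_minutes) %/% (24 * 60) + 1L,
    n_bins = e_idx - s_idx + 1L
  )
}

#' Daily light-exposure histogram in 15-minute bins
#'
#' Counts supra-basal samples (or sums their lux, `weight = "lux"`) per
#' 15-minute clock bin across days, excluding the first and last calendar
#' days (release and recapture) when `exclude_first_last` is set.
#'
#' @param log a [light_log_record()].
#' @param exclude_first_last drop the first and last days; requires >= 3
#'   days of data.
#' @param weight `"count"` (default: number of supra-basal samples) or
#'   `"lux"` (sum of supra-basal lux values).
#' @return An object of class `exposure_histogram`: data frame with 96
#'   rows, columns `bin_start_h` and `exposure`, with attributes
#'   `days_included`, `mode_h` (bin start of the maximal bin) and
#'   `weight`.
#' @export
exposure_histogram <- function(log, exclude_first_last = TRUE,
                               weight = c("count", "lux")) {
  stopifnot(inherits(log, "light_log_record"))
  weight <- match.arg(weight)
  n_days_total <- ceiling(length(log$lux) * log$bin_minutes / (24 * 60))
  days <- seq_len(n_days_total)
  if (exclude_first_last) {
    if (n_days_total < 3)
      stop("need >= 3 days to exclude the release and recapture days")
    days <- days[-c(1, length(days))]
  }
  basal <- min(log$lux)
  i <- seq_along(log$lux)
  minute <- (i - 1) * log$bin_minutes
  day_i <- minute %/% (24 * 60) + 1L
  clock_bin <- (minute %% (24 * 60)) %/% 15L    # 0..95
  sel <- log$lux > basal & day_i %in% days
  w <- if (weight == "count") rep(1, length(i)) else log$lux
  acc <- tapply(w[sel], factor(clock_bin[sel], levels = 0:95), sum)
  acc[is.na(acc)] <- 0
  out <- data.frame(bin_start_h = (0:95) * 0.25, exposure = as.numeric(acc))
  attr(out, "days_included") <- days
  attr(out, "mode_h") <- out$bin_start_h[which.max(out$exposure)]
  attr(out, "weight") <- weight
  class(out) <- c("exposure_histogram", "data.frame")
  out
}

#' Check for supra-threshold light outside civil twilight
#'
#' Lists every sample brighter than `threshold` lux whose clock time falls
#' outside that day's `[dawn, dusk]` civil-twilight interval. Compliant
#' records (no light at night) yield zero rows.
#'
#' @param log a [light_log_record()].
#' @param twilight data frame with columns `day`, `dawn_h`, `dusk_h`
#'   covering every day of the record, or a length-2 numeric
#'   `c(dawn, dusk)` applied to all days.
#' @param threshold lux; default 1.2.
#' @return Data frame with one row per violation: `datetime`, `day_index`,
#'   `clock_h`, `lux`.
#' @export
night_exposure_check <- function(log, twilight = c(7.5, 19.0),
                                 threshold = 1.2) {
  stopifnot(inherits(log, "light_log_record"))
  n_days <- ceiling(length(log$lux) * log$bin_minutes / (24 * 60))
  tw <- .twilight_table(twilight, n_days)
  i <- seq_along(log$lux)
  minute <- (i - 1) * log$bin_minutes
  day_i <- minute %/% (24 * 60) + 1L
  clock_h <- (minute %% (24 * 60)) / 60
  dawn <- tw$dawn_h[match(day_i, tw$day)]
  dusk <- tw$dusk_h[match(day_i, tw$day)]
  bad <- log$lux > threshold & (clock_h < dawn | clock_h >= dusk)
  data.frame(datetime = log$start_datetime + (i[bad] - 1) * log$bin_minutes * 60,
             day_index = day_i[bad], clock_h = clock_h[bad],
             lux = log$lux[bad])
}
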