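#' Pulse schedules: one brief light pulse per day
#'
#' A `pulse_schedule` holds the skeleton of a single-pulse light regimen:
#' one pulse start time (decimal clock hours) per calendar day, together
#' with the pulse duration and the dispersion window the starts were drawn
#' from. Constant darkness (DD) is the empty schedule.
#'
#' @param day integer day indices (1-based).
#' @param pulse_start decimal clock hours in `[0, 24)`, one per day.
#' @param pulse_duration pulse length in hours (> 0).
#' @param window_start start of the dispersion window, clock hours.
#' @param window_length length `I` of the dispersion window, hours.
#' @param seed the seed used to draw the starts, or `NULL`.
#' @return An object of class `pulse_schedule`: a data frame with columns
#'   `day` and `pulse_start`, carrying `pulse_duration`, `window_start`,
#'   `window_length` and `seed` as attributes.
#' @seealso [random_pulse_schedule()], [fixed_pulse_schedule()],
#'   [dd_schedule()], [schedule_to_regimen()]
#' @export
pulse_schedule <- function(day, pulse_start, pulse_duration,
                           window_start, window_length, seed = NULL) {
  stopifnot(length(day) == length(pulse_start))
  if (pulse_duration <= 0) stop("pulse_duration must be > 0")
  if (window_length <= 0 || window_length > 24)
    stop("window_length must lie in (0, 24]")
  if (length(pulse_start) && (any(pulse_start < 0) || any(pulse_start >= 24)))
    stop("pulse_start values must lie in [0, 24)")
  out <- data.frame(day = as.integer(day), pulse_start = as.numeric(pulse_start))
  attr(out, "pulse_duration") <- pulse_duration
  attr(out, "window_start") <- window_start %% 24
  attr(out, "window_length") <- window_length
  attr(out, "seed") <- seed
  class(out) <- c("pulse_schedule", "data.frame")
  out
}

#' Draw a random single-pulse schedule
#'
#' One pulse per day, with the start time drawn independently and uniformly
#' on the 5-minute grid spanning the dispersion window, such that the whole
#' pulse fits inside the window: starts lie in
#' `[window_start, window_start + I - pulse_duration]` (modulo 24).
#'
#' @param window_start clock hours at which the dispersion window opens.
#' @param I window length in hours; must satisfy `I >= pulse_duration`.
#' @param pulse_duration pulse length in hours; default 1.
#' @param n_days number of days (>= 1).
#' @param seed integer seed for reproducible draws; the global RNG state is
#'   left untouched. `NULL` uses (and advances) the current RNG.
#' @param grid_min granularity of the random draw in minutes; default 5,
#'   matching the recording resolution.
#' @return A [pulse_schedule()].
#' @examples
#' s <- random_pulse_schedule(6, I = 8, pulse_duration = 1, n_days = 30, seed = 1)
#' range(s$pulse_start) # within [6, 13]
#' @export
random_pulse_schedule <- function(window_start, I, pulse_duration = 1,
                                  n_days, seed = NULL, grid_min = 5) {
  if (I < pulse_duration)
    stop("invalid window: I (", I, " h) is shorter than the pulse (",
         pulse_duration, " h)")
  if (I > 24) stop("invalid window: I must be <= 24 h")
  if (n_days < 1) stop("n_days must be >= 1")
  slots <- round((I - pulse_duration) * 60 / grid_min) + 1L
  draw <- function() {
    idx <- sample.int(slots, n_days, replace = TRUE) - 1L
    (window_start + idx * grid_min / 60) %% 24
  }
  starts <- if (is.null(seed)) draw() else withr::with_seed(seed, draw())
  pulse_schedule(seq_len(n_days), starts, pulse_duration,
                 window_start, I, seed)
}

#' Fixed-time single daily pulse (LD1:23 and its generalisations)
#'
#' Equivalent to [random_pulse_schedule()] with `I == pulse_duration`
#' (degenerate window: every start identical).
#'
#' @param pulse_time clock hours of the daily pulse.
#' @param pulse_duration pulse length in hours; default 1.
#' @param n_days number of days (>= 1).
#' @return A [pulse_schedule()].
#' @export
fixed_pulse_schedule <- function(pulse_time, pulse_duration = 1, n_days) {
  if (n_days < 1) stop("n_days must be >= 1")
  pulse_schedule(seq_len(n_days), rep(pulse_time %% 24, n_days),
                 pulse_duration, pulse_time, pulse_duration, seed = NULL)
}

#' Constant darkness (DD) schedule
#'
#' The empty schedule: no pulses over `n_days` days.
#'
#' @param n_days number of days.
#' @param pulse_duration nominal pulse duration carried for rendering
#'   compatibility; no pulse is emitted.
#' @return A [pulse_schedule()] with zero rows and attribute
#'   `n_days` giving the schedule span.
#' @export
dd_schedule <- function(n_days, pulse_duration = 1) {
  out <- pulse_schedule(integer(0), numeric(0), pulse_duration,
                        window_start = 0, window_length = 24, seed = NULL)
  attr(out, "n_days") <- as.integer(n_days)
  out
}

#' Number of days a schedule spans
#' @param schedule a [pulse_schedule()].
#' @return integer day count.
#' @export
schedule_days <- function(schedule) {
  if (nrow(schedule) > 0L) max(schedule$day) else attr(schedule, "n_days") %||% 0L
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Shift a schedule in clock time
#'
#' Displaces the dispersion window and every pulse start by `delta` hours,
#' modulo 24 (used for the "delayed window" control: same dispersion, later
#' clock times).
#'
#' @param schedule a [pulse_schedule()].
#' @param delta displacement in hours; positive = later clock time.
#' @return The shifted [pulse_schedule()].
#' @export
shift_schedule <- function(schedule, delta) {
  stopifnot(inherits(schedule, "pulse_schedule"))
  out <- pulse_schedule(schedule$day,
                        (schedule$pulse_start + delta) %% 24,
                        attr(schedule, "pulse_duration"),
                        (attr(schedule, "window_start") + delta) %% 24,
                        attr(schedule, "window_length"),
                        attr(schedule, "seed"))
  attr(out, "n_days") <- attr(schedule, "n_days")
  out
}

#' Light regimens: piecewise-constant illuminance series
#'
#' @param lux numeric vector of illuminance samples.
#' @param resolution_min minutes per sample.
#' @param background_lux constant background level (dim red light treated as
#'   darkness); all samples are `>= background_lux`.
#' @param start_datetime calendar origin (POSIXct, UTC recommended).
#' @return An object of class `light_regimen`.
#' @export
light_regimen <- function(lux, resolution_min, background_lux = 0,
                          start_datetime = as.POSIXct("2015-07-01", tz = "UTC")) {
  if (background_lux < 0) stop("background_lux must be >= 0")
  if (any(lux < background_lux)) stop("all samples must be >= background_lux")
  structure(list(lux = as.numeric(lux),
                 resolution_min = resolution_min,
                 background_lux = background_lux,
                 start_datetime = start_datetime),
            class = "light_regimen")
}

#' @export
print.light_regimen <- function(x, ...) {
  cat(sprintf("<light_regimen> %d samples @ %g min (%.1f days), background %g lux, max %g lux\n",
              length(x$lux), x$resolution_min,
              length(x$lux) * x$resolution_min / 60 / 24,
              x$background_lux, max(x$lux)))
  invisible(x)
}

#' Duration of a regimen in hours
#' @param regimen a [light_regimen()].
#' @return hours.
#' @export
regimen_duration <- function(regimen) {
  length(regimen$lux) * regimen$resolution_min / 60
}

#' Render a pulse schedule as an illuminance time series
#'
#' Produces the piecewise-constant regimen: `background` lux everywhere
#' except during scheduled pulses, which read `L` lux. A DD (empty)
#' schedule renders as constant background. Pulses whose window placement
#' makes them cross midnight spill into the next day; a pulse extending
#' past the final day is clipped with a warning.
#'
#' @param schedule a [pulse_schedule()].
#' @param L pulse illuminance in lux (`> background`).
#' @param background background illuminance in lux.
#' @param resolution_min sample width in minutes; must divide the pulse
#'   duration and 24 h evenly.
#' @param start_datetime calendar origin of day 1.
#' @return A [light_regimen()] spanning `schedule_days(schedule)` days.
#' @examples
#' reg <- schedule_to_regimen(fixed_pulse_schedule(12, 1, 3), L = 1000)
#' sum(reg$lux > 0) # 3 days x 12 five-minute samples
#' @export
schedule_to_regimen <- function(schedule, L, background = 0, resolution_min = 5,
                                start_datetime = as.POSIXct("2015-07-01", tz = "UTC")) {
  stopifnot(inherits(schedule, "pulse_schedule"))
  if (L <= background) stop("L must exceed background")
  dur <- attr(schedule, "pulse_duration")
  if (abs((dur * 60) %% resolution_min) > 1e-9)
    stop("resolution_min must divide the pulse duration evenly")
  if ((24 * 60) %% resolution_min != 0)
    stop("resolution_min must divide 24 h evenly")
  n_days <- schedule_days(schedule)
  spd <- 24 * 60 / resolution_min            # samples per day
  n <- n_days * spd
  lux <- rep(background, n)
  if (nrow(schedule) > 0L) {
    k <- round(dur * 60 / resolution_min)    # samples per pulse
    first <- (schedule$day - 1L) * spd +
      round(schedule$pulse_start * 60 / resolution_min) + 1L
    for (j in seq_along(first)) {
      idx <- first[j]:(first[j] + k - 1L)
      if (any(idx > n)) {
        warning("pulse on day ", schedule$day[j], " clipped at series end")
        idx <- idx[idx <= n]
      }
      lux[idx] <- L
    }
  }
  light_regimen(lux, resolution_min, background, start_datetime)
}
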