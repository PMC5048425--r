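#' Wheel-running activity records
#'
#' Timestamped non-negative count bins (default 5 min), the unit of all
#' rhythm analysis.
#'
#' @param counts non-negative integer counts per bin.
#' @param bin_minutes bin width, minutes.
#' @param start_datetime calendar origin (POSIXct).
#' @param animal_id label.
#' @return An object of class `activity_record`.
#' @export
activity_record <- function(counts, bin_minutes = 5,
                            start_datetime = as.POSIXct("2015-07-01", tz = "UTC"),
                            animal_id = "sim") {
  counts <- as.integer(round(counts))
  if (any(counts < 0)) stop("counts must be non-negative")
  structure(list(counts = counts, bin_minutes = bin_minutes,
                 start_datetime = start_datetime, animal_id = animal_id),
            class = "activity_record")
}

#' @export
print.activity_record <- function(x, ...) {
  cat(sprintf("<activity_record> '%s': %d bins @ %g min (%.1f days), total %d counts\n",
              x$animal_id, length(x$counts), x$bin_minutes,
              length(x$counts) * x$bin_minutes / 60 / 24, sum(x$counts)))
  invisible(x)
}

#' Number of whole days in a record
#' @param record an [activity_record()] or [light_log_record()].
#' @return integer number of complete days.
#' @export
record_days <- function(record) {
  (length(record$counts %||% record$lux) * record$bin_minutes) %/% (24 * 60)
}

# nocturnal gate on oscillator phase: active when the phase angle is within
# pi*gate_fraction of the subjective-night centre (CT18, theta = pi)
.night_gate <- function(phase_h, gate_fraction) {
  theta <- (phase_h * pi / 12) %% (2 * pi)
  d <- abs(((theta - pi) + pi) %% (2 * pi) - pi)
  d <= pi * gate_fraction + 1e-12
}

#' Generate gated activity counts from an oscillator trajectory
#'
#' Counts are emitted in 5-min bins: inside the subjective-night gate (a
#' phase window of width `gate_fraction` of the cycle centred on subjective
#' night, CT18) the expectation is `mean_counts`; outside it is zero.
#' With `dispersion > 0` counts are negative-binomial (mean `mean_counts`,
#' size `dispersion`); `dispersion = 0` gives deterministic (noiseless)
#' counts.
#'
#' @param traj a `circadian_trajectory` from [simulate_oscillator()],
#'   sampled on the activity bin grid.
#' @param gate_fraction fraction of the cycle spent active, in (0, 1).
#' @param mean_counts expected counts per active bin.
#' @param dispersion negative-binomial size parameter; 0 = noiseless.
#' @param seed optional integer seed (global RNG preserved).
#' @param start_datetime calendar origin.
#' @param animal_id label.
#' @return An [activity_record()] with one bin per trajectory sample.
#' @export
activity_from_trajectory <- function(traj, gate_fraction = 0.5,
                                     mean_counts = 20, dispersion = 0,
                                     seed = NULL,
                                     start_datetime = as.POSIXct("2015-07-01", tz = "UTC"),
                                     animal_id = "sim") {
  stopifnot(inherits(traj, "circadian_trajectory"))
  if (gate_fraction <= 0 || gate_fraction >= 1)
    stop("gate_fraction must lie in (0, 1)")
  bin_minutes <- attr(traj, "sample_h") * 60
  phase <- traj$phase_h[-nrow(traj)]          # phase at each bin start
  gate <- .night_gate(phase, gate_fraction)
  n <- length(gate)
  draw <- function() {
    counts <- numeric(n)
    if (dispersion > 0) {
      counts[gate] <- rnbinom(sum(gate), mu = mean_counts, size = dispersion)
    } else {
      counts[gate] <- round(mean_counts)
    }
    counts
  }
  counts <- if (is.null(seed) || dispersion == 0) draw() else withr::with_seed(seed, draw())
  activity_record(counts, bin_minutes, start_datetime, animal_id)
}

#' Square-wave free-running activity fixture
#'
#' Oscillator-free generator with exact ground-truth period `tau`: counts
#' follow a square-wave gate of duty `gate_fraction`, active when
#' `(t - onset_h) mod tau < gate_fraction * tau` evaluated at bin starts,
#' optionally with negative-binomial noise on the active bins.
#'
#' @param tau ground-truth period in hours, in (20, 28).
#' @param gate_fraction active fraction of the cycle.
#' @param mean_counts expected counts per active bin.
#' @param noise negative-binomial size parameter; 0 = noiseless.
#' @param n_days record length, days.
#' @param seed optional integer seed.
#' @param onset_h clock hours of the first activity onset.
#' @param bin_minutes bin width, minutes.
#' @return An [activity_record()]; the true period is stored in attribute
#'   `true_tau`.
#' @export
synthetic_free_run <- function(tau, gate_fraction = 1/3, mean_counts = 20,
                               noise = 0, n_days = 30, seed = NULL,
                               onset_h = 12, bin_minutes = 5) {
  if (tau <= 20 || tau >= 28) stop("tau must lie in (20, 28) hours")
  n <- n_days * 24 * 60 / bin_minutes
  t <- (seq_len(n) - 1) * bin_minutes / 60
  gate <- ((t - onset_h) %% tau) < gate_fraction * tau - 1e-9
  draw <- function() {
    counts <- numeric(n)
    if (noise > 0) {
      counts[gate] <- rnbinom(sum(gate), mu = mean_counts, size = noise)
    } else {
      counts[gate] <- round(mean_counts)
    }
    counts
  }
  counts <- if (is.null(seed) || noise == 0) draw() else withr::with_seed(seed, draw())
  rec <- activity_record(counts, bin_minutes)
  attr(rec, "true_tau") <- tau
  rec
}

#' Field light-logger records
#'
#' Per-bin maxima of an underlying 1-min illuminance process, clipped to
#' the logger range.
#'
#' @param lux per-bin maximum illuminance, lux.
#' @param bin_minutes bin width, minutes.
#' @param range_min,range_max logger detection range, lux.
#' @param start_datetime calendar origin.
#' @param animal_id label.
#' @return An object of class `light_log_record`; `basal` is the lowest
#'   value in the record.
#' @export
light_log_record <- function(lux, bin_minutes = 5, range_min = 0.3,
                             range_max = 19000,
                             start_datetime = as.POSIXct("2015-07-01", tz = "UTC"),
                             animal_id = "logger") {
  lux <- pmin(pmax(as.numeric(lux), range_min), range_max)
  structure(list(lux = lux, bin_minutes = bin_minutes,
                 range_min = range_min, range_max = range_max,
                 basal = min(lux), start_datetime = start_datetime,
                 animal_id = animal_id),
            class = "light_log_record")
}

#' @export
print.light_log_record <- function(x, ...) {
  cat(sprintf("<light_log_record> '%s': %d bins @ %g min (%.1f days), range [%g, %g] lux, basal %g\n",
              x$animal_id, length(x$lux), x$bin_minutes,
              length(x$lux) * x$bin_minutes / 60 / 24,
              x$range_min, x$range_max, x$basal))
  invisible(x)
}

# von Mises sampler (Best & Fisher 1979 rejection scheme); mu in radians
.rvonmises <- function(n, mu, kappa) {
  if (!is.finite(kappa)) return(rep(mu, n))
  if (kappa < 1e-8) return(runif(n, -pi, pi) + mu)
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + b^2) / (2 * b)
  out <- numeric(n)
  for (i in seq_len(n)) {
    repeat {
      u1 <- runif(1); u2 <- runif(1); u3 <- runif(1)
      z <- cos(pi * u1)
      f <- (1 + r * z) / (r + z)
      cc <- kappa * (r - f)
      if (cc * (2 - cc) - u2 > 0 || log(cc / u2) + 1 - cc >= 0) {
        out[i] <- mu + sign(u3 - 0.5) * acos(f)
        break
      }
    }
  }
  out
}

#' Generate a synthetic field light-logger record
#'
#' Emulates the structure of field logger records from semi-natural
#' enclosures: each day has at least one brief light-exposure episode at an
#' irregular time; episode start times follow a unimodal circular (von
#' Mises) distribution centred at midday; episode illuminance sits at or
#' near the logger's upper detection limit (clipped); no suprathreshold
#' (> 1.2 lux by default) light occurs outside civil twilight. The
#' underlying process is simulated at 1-min resolution and downsampled to
#' per-5-min maxima, the dialect real loggers record.
#'
#' @param n_days days to generate.
#' @param episodes_per_day_mean mean episodes per day (zero-truncated
#'   Poisson; every day has at least one).
#' @param episode_duration_mean mean episode duration, minutes (>= 1).
#' @param midday_concentration von Mises concentration of episode start
#'   times about midday; `Inf` puts every episode exactly at midday.
#' @param twilight data frame with columns `day`, `dawn_h`, `dusk_h`
#'   (civil twilight, clock hours), or a length-2 numeric `c(dawn, dusk)`
#'   recycled to all days. Default `c(7.5, 19.0)` (austral winter).
#' @param midday_h centre of the episode-start distribution, clock hours.
#' @param range_min,range_max logger detection range, lux.
#' @param night_threshold lux level that must never occur outside
#'   twilight.
#' @param seed optional integer seed.
#' @param max_tries redraws allowed per episode before erroring.
#' @return A [light_log_record()] at 5-min resolution; the generated
#'   episode table (1-min truth) is stored in attribute `episodes`.
#' @export
synthetic_light_log <- function(n_days, episodes_per_day_mean = 4,
                                episode_duration_mean = 5,
                                midday_concentration = 2,
                                twilight = c(7.5, 19.0), midday_h = 12,
                                range_min = 0.3, range_max = 19000,
                                night_threshold = 1.2, seed = NULL,
                                max_tries = 1000) {
  if (episodes_per_day_mean < 1)
    stop("episodes_per_day_mean must be >= 1 (every day has an episode)")
  tw <- .twilight_table(twilight, n_days)
  if (any(tw$dusk_h - tw$dawn_h < 1))
    stop("twilight window too short to place episodes")
  gen <- function() {
    lux1 <- rep(0, n_days * 24 * 60)          # 1-min underlying process
    eps <- list()
    for (d in seq_len(n_days)) {
      # align placement limits to the 5-min bin grid so that downsampled
      # bin timestamps can never straddle the twilight limits
      dawn <- ceiling(tw$dawn_h[d] * 12) / 12
      dusk <- floor(tw$dusk_h[d] * 12) / 12
      k <- .rztpois(1, episodes_per_day_mean)
      for (e in seq_len(k)) {
        ok <- FALSE
        for (try in seq_len(max_tries)) {
          start_h <- (midday_h + .rvonmises(1, 0, midday_concentration) * 12 / pi) %% 24
          dur_min <- 1 + rpois(1, max(episode_duration_mean - 1, 0))
          if (start_h >= dawn && start_h + dur_min / 60 <= dusk) { ok <- TRUE; break }
        }
        if (!ok) stop("could not place an episode inside the twilight window")
        peak <- range_max * exp(rnorm(1, 0, 0.2))
        i0 <- (d - 1) * 24 * 60 + floor(start_h * 60) + 1
        idx <- i0:(i0 + dur_min - 1)
        lux1[idx] <- pmax(lux1[idx], peak)
        eps[[length(eps) + 1]] <- data.frame(day = d, start_h = start_h,
                                             duration_min = dur_min)
      }
    }
    list(lux1 = lux1, episodes = do.call(rbind, eps))
  }
  g <- if (is.null(seed)) gen() else withr::with_seed(seed, gen())
  lux5 <- apply(matrix(g$lux1, nrow = 5), 2, max)  # per-5-min maxima
  rec <- light_log_record(lux5, 5, range_min, range_max)
  attr(rec, "episodes") <- g$episodes
  attr(rec, "twilight") <- tw
  rec
}

# zero-truncated Poisson
.rztpois <- function(n, lambda) {
  out <- rpois(n, lambda)
  while (any(out == 0)) out[out == 0] <- rpois(sum(out == 0), lambda)
  out
}

.twilight_table <- function(twilight, n_days) {
  if (is.numeric(twilight) && length(twilight) == 2) {
    data.frame(day = seq_len(n_days), dawn_h = twilight[1], dusk_h = twilight[2])
  } else {
    stopifnot(is.data.frame(twilight),
              all(c("day", "dawn_h", "dusk_h") %in% names(twilight)))
    missing <- setdiff(seq_len(n_days), twilight$day)
    if (length(missing))
      stop("missing twilight for day ", missing[1])
    twilight[match(seq_len(n_days), twilight$day), ]
  }
}
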