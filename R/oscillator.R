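#' Limit-cycle circadian oscillator parameters
#'
#' The oscillator is a two-variable radially relaxing limit-cycle
#' (Poincare-type amplitude-phase) model with gated photic forcing,
#' \deqn{\dot x = \gamma x (1 - r) - (2\pi/\tau)\, y +
#'       K\,\Lambda(L(t))\,\max(0, -x),
#'       \qquad \dot y = \gamma y (1 - r) + (2\pi/\tau)\, x,}
#' with \eqn{r = \sqrt{x^2+y^2}}. Unforced, it has a unique attracting
#' limit cycle of radius 1 and period `tau`; `stiffness` (\eqn{\gamma}) is
#' the amplitude relaxation rate (slow relaxation makes the oscillator
#' integrate successive pulses "sluggishly", the property thought to
#' underlie entrainment by randomly timed pulses), and `coupling` (K)
#' scales the photic force on the first state variable. The sensitivity
#' factor \eqn{s(x) = \max(0,-x) + \epsilon} gates light action to the
#' half-cycle where \eqn{x<0} (subjective night), which yields the
#' canonical nocturnal-rodent weak (type-1) phase response curve: delays
#' in early subjective night, advances in late subjective night, and a
#' dead zone throughout subjective day. The small `dead_zone_leak`
#' (\eqn{\epsilon}) keeps the dead zone weakly responsive rather than
#' absolute, setting how quickly an out-of-phase oscillator is captured
#' by a new schedule.
#'
#' Illuminance is converted to normalised forcing by the saturating map
#' \deqn{\Lambda(L) = \log(1 + L/L_{ref}) / \log(1 + L_{sat}/L_{ref}),}
#' so that \eqn{\Lambda(0)=0}, \eqn{\Lambda} is increasing, and
#' \eqn{\Lambda(L_{sat}) = 1}. Defaults are calibrated so a 1-h pulse at
#' 1,000 lux (the "strong" intensity) yields a weak type-1 phase response
#' curve with maximal shifts of 1-2 h, entrainment survives dispersion
#' windows up to about 15 h at 1,000 lux but fails at a 20-h window, and a
#' 15-h window fails at 100 lux.
#'
#' @param tau intrinsic free-running period, hours.
#' @param stiffness amplitude relaxation rate, 1/h.
#' @param coupling photic forcing amplitude per unit normalised light.
#' @param dead_zone_leak basal photic sensitivity during subjective day,
#'   as a fraction of the peak subjective-night sensitivity.
#' @param lux_ref reference illuminance of the saturating lux map, lux.
#' @param lux_sat illuminance mapped to forcing 1, lux.
#' @return An object of class `oscillator_params`.
#' @export
oscillator_params <- function(tau = 23.75, stiffness = 0.1, coupling = 0.7,
                              dead_zone_leak = 0.25, lux_ref = 1000,
                              lux_sat = 1000) {
  if (tau <= 0) stop("tau must be > 0")
  if (stiffness <= 0) stop("stiffness must be > 0")
  if (coupling < 0) stop("coupling must be >= 0")
  if (dead_zone_leak < 0) stop("dead_zone_leak must be >= 0")
  if (lux_ref <= 0 || lux_sat <= 0) stop("lux map constants must be > 0")
  structure(list(tau = tau, stiffness = stiffness, coupling = coupling,
                 dead_zone_leak = dead_zone_leak,
                 lux_ref = lux_ref, lux_sat = lux_sat),
            class = "oscillator_params")
}

#' @export
print.oscillator_params <- function(x, ...) {
  cat(sprintf(paste0("<oscillator_params> tau = %.2f h, stiffness = %.3g /h, ",
                     "coupling = %.3g, dead-zone leak = %.3g, ",
                     "lux map ref/sat = %g/%g lux\n"),
              x$tau, x$stiffness, x$coupling, x$dead_zone_leak,
              x$lux_ref, x$lux_sat))
  invisible(x)
}

#' Saturating lux-to-forcing map
#'
#' @param lux illuminance values, lux.
#' @param params an [oscillator_params()].
#' @return Normalised forcing in `[0, ...)`; 0 at 0 lux, 1 at `lux_sat`.
#' @export
lux_to_forcing <- function(lux, params) {
  log1p(lux / params$lux_ref) / log1p(params$lux_sat / params$lux_ref)
}

# phase convention: theta = atan2(y, x), circadian hours = theta * 12/pi,
# circadian time CT = (theta*12/pi + 6) mod 24 so that CT6 is mid
# subjective day (zero of the PRC) and subjective night is centred at CT18.
.theta_to_ct <- function(theta) (theta * 12 / pi + 6) %% 24
.ct_to_theta <- function(ct) (ct - 6) * pi / 12

#' State on the unforced limit cycle at a given circadian time
#'
#' @param params an [oscillator_params()].
#' @param ct circadian time, hours (CT6 = mid subjective day).
#' @return Numeric length-2 state `(x, y)`.
#' @export
limit_cycle_state <- function(params, ct = 6) {
  th <- .ct_to_theta(ct)
  c(cos(th), sin(th))
}

.unwrap <- function(theta) {
  if (length(theta) < 2) return(theta)
  d <- diff(theta)
  d <- (d + pi) %% (2 * pi) - pi
  theta[1] + c(0, cumsum(d))
}

#' Integrate the oscillator under a light regimen
#'
#' Fixed-step 4th-order Runge-Kutta integration (compiled), with the
#' photic forcing active exactly where the regimen illuminance exceeds its
#' background. The default step is `resolution_min/60/substeps` hours
#' (0.5 min), below the 0.01-h step at which step-halving changes the
#' final phase by well under 1e-3 h.
#'
#' @param params an [oscillator_params()].
#' @param regimen a [light_regimen()].
#' @param initial_state length-2 state; default: on the limit cycle at CT6.
#' @param t_end hours to integrate; default the whole regimen; must not
#'   exceed the regimen duration.
#' @param substeps RK4 steps per regimen sample.
#' @return A `circadian_trajectory`: data frame with columns `time_h`,
#'   `x1`, `x2`, `phase_h` (unwrapped, circadian hours: 24 h per cycle) and
#'   `amplitude` (radial distance to the cycle centroid at the origin),
#'   sampled at regimen-sample boundaries, with the parameters and sampling
#'   step as attributes.
#' @export
simulate_oscillator <- function(params, regimen, initial_state = NULL,
                                t_end = NULL, substeps = 10) {
  stopifnot(inherits(params, "oscillator_params"),
            inherits(regimen, "light_regimen"))
  sample_h <- regimen$resolution_min / 60
  if (is.null(t_end)) t_end <- regimen_duration(regimen)
  if (t_end > regimen_duration(regimen) + 1e-9)
    stop("t_end exceeds the regimen duration")
  n <- round(t_end / sample_h)
  if (is.null(initial_state)) initial_state <- limit_cycle_state(params)
  lux <- regimen$lux[seq_len(n)]
  forcing <- ifelse(lux > regimen$background_lux,
                    params$coupling * (lux_to_forcing(lux, params) -
                                       lux_to_forcing(regimen$background_lux, params)),
                    0)
  st <- rk4_limit_cycle(initial_state, params$tau, params$stiffness,
                        forcing, sample_h, as.integer(substeps),
                        params$dead_zone_leak %||% 0)
  theta <- .unwrap(atan2(st[, 2], st[, 1]))
  out <- data.frame(time_h = seq(0, by = sample_h, length.out = n + 1),
                    x1 = st[, 1], x2 = st[, 2],
                    phase_h = theta * 12 / pi,
                    amplitude = sqrt(st[, 1]^2 + st[, 2]^2))
  attr(out, "params") <- params
  attr(out, "sample_h") <- sample_h
  class(out) <- c("circadian_trajectory", "data.frame")
  out
}

#' Free-running period from Poincare-section crossings
#'
#' Integrates the unforced oscillator and estimates the period from
#' successive upward crossings of the section `x2 = 0, x1 > 0` (linear
#' interpolation between samples), discarding initial transient cycles.
#'
#' @param params an [oscillator_params()].
#' @param n_cycles cycles used for the estimate.
#' @param transient_cycles cycles discarded before measuring.
#' @return Estimated period, hours; consistency-checked to be within 0.5%
#'   of `params$tau`.
#' @export
free_running_period <- function(params, n_cycles = 20, transient_cycles = 5) {
  days <- ceiling((n_cycles + transient_cycles + 2) * params$tau / 24)
  reg <- schedule_to_regimen(dd_schedule(days), L = 1, background = 0)
  reg$lux[] <- 0 # truly dark; schedule_to_regimen needs L > background
  traj <- simulate_oscillator(params, reg,
                              initial_state = c(0.5, 0)) # off-cycle start
  cross <- .section_crossings(traj)
  if (length(cross) < transient_cycles + n_cycles + 1)
    stop("model degeneracy: no sustained limit cycle detected")
  cross <- cross[-seq_len(transient_cycles)]
  per <- mean(diff(cross))
  if (abs(per - params$tau) / params$tau > 0.005)
    stop(sprintf("dynamics period %.3f h inconsistent with tau = %.3f h",
                 per, params$tau))
  per
}

# times (h) of upward crossings of y = 0 with x > 0
.section_crossings <- function(traj) {
  y <- traj$x2
  x <- traj$x1
  t <- traj$time_h
  i <- which(y[-length(y)] < 0 & y[-1] >= 0 & x[-1] > 0)
  t[i] + (t[i + 1] - t[i]) * (-y[i]) / (y[i + 1] - y[i])
}

#' Phase response curve to a single light pulse
#'
#' For each probe circadian time, the oscillator starts on the limit cycle,
#' receives one pulse of the given duration and illuminance beginning at
#' that phase, then free-runs; the steady-state shift is the phase
#' difference (pulsed minus unperturbed control, in hours; positive =
#' advance) measured `settle_cycles` cycles later, wrapped to (-12, 12].
#'
#' @param params an [oscillator_params()].
#' @param pulse_duration pulse length, hours.
#' @param lux pulse illuminance.
#' @param n_phases number of probe phases on the 0-24 h circadian-time
#'   grid (>= 12).
#' @param settle_cycles free-running cycles before the shift is read out
#'   (>= 5).
#' @return An object of class `prc`: data frame with columns `ct_h` (probe
#'   circadian time) and `shift_h`.
#' @export
phase_response_curve <- function(params, pulse_duration = 1, lux = 1000,
                                 n_phases = 24, settle_cycles = 8) {
  if (n_phases < 12) stop("n_phases must be >= 12")
  if (settle_cycles < 5) stop("settle_cycles must be >= 5")
  cts <- seq(0, 24, length.out = n_phases + 1)[seq_len(n_phases)]
  days <- ceiling((settle_cycles + 2) * params$tau / 24)
  sched <- pulse_schedule(1L, 0, pulse_duration, 0, 24)
  reg_pulse <- schedule_to_regimen(sched, L = max(lux, 1e-9), background = 0)
  if (lux == 0) reg_pulse$lux[] <- 0
  n_pad <- (days - 1) * 24 * 12
  reg_pulse$lux <- c(reg_pulse$lux[seq_len(24 * 12)], rep(0, n_pad))
  reg_dark <- reg_pulse
  reg_dark$lux[] <- 0
  shifts <- vapply(cts, function(ct) {
    s0 <- limit_cycle_state(params, ct)
    tp <- simulate_oscillator(params, reg_pulse, initial_state = s0)
    tc <- simulate_oscillator(params, reg_dark, initial_state = s0)
    d <- tail(tp$phase_h, 1) - tail(tc$phase_h, 1)
    ((d + 12) %% 24) - 12
  }, numeric(1))
  out <- data.frame(ct_h = cts, shift_h = shifts)
  class(out) <- c("prc", "data.frame")
  attr(out, "pulse_duration") <- pulse_duration
  attr(out, "lux") <- lux
  out
}

#' Amplitude relaxation time
#'
#' Starts the unforced oscillator off-cycle at radius `1 - perturbation`
#' and returns the time for the amplitude deviation `|r - 1|` to decay to
#' `1/e` of its initial value (threshold crossing with linear
#' interpolation). Decreases as `stiffness` increases.
#'
#' @param params an [oscillator_params()].
#' @param perturbation fractional amplitude perturbation in (0, 1).
#' @return Relaxation time, hours (0 for a zero perturbation).
#' @export
relaxation_time <- function(params, perturbation = 0.5) {
  if (perturbation < 0 || perturbation >= 1)
    stop("perturbation must lie in [0, 1)")
  if (perturbation == 0) return(0)
  days <- ceiling(10 / params$stiffness / 24) + 2
  reg <- light_regimen(rep(0, days * 24 * 12), 5, 0)
  traj <- simulate_oscillator(params, reg,
                              initial_state = c(1 - perturbation, 0))
  dev <- abs(traj$amplitude - 1)
  target <- dev[1] / exp(1)
  i <- which(dev <= target)[1]
  if (is.na(i)) stop("amplitude did not relax within the integration span")
  if (i == 1) return(0)
  t <- traj$time_h
  t[i - 1] + (t[i] - t[i - 1]) * (dev[i - 1] - target) / (dev[i - 1] - dev[i])
}

#' Fraction of replicates entrained across dispersion windows
#'
#' For each window length `I`, runs seeded random-pulse regimens (preceded
#' by days of DD), generates activity from the trajectory, estimates the
#' trailing-window period and classifies it against the 24 h +/- 10 min
#' criterion; returns the fraction of replicates entrained per `I`.
#'
#' @param params an [oscillator_params()].
#' @param lux pulse illuminance.
#' @param I_grid vector of window lengths, hours.
#' @param days days of the pulse regimen (>= 30 recommended).
#' @param replicates seeded replicates per window.
#' @param seed integer master seed.
#' @param dd_days days of DD preceding the pulse stage.
#' @param pulse_duration pulse length, hours.
#' @return Data frame with columns `I`, `n`, `entrained`, `fraction`.
#' @export
entrainment_range <- function(params, lux = 1000, I_grid = seq(8, 22, by = 1),
                              days = 40, replicates = 10, seed = 1,
                              dd_days = 10, pulse_duration = 1) {
  res <- lapply(I_grid, function(I) {
    lab <- vapply(seq_len(replicates), function(r) {
      run <- simulate_pulse_run(params, I = I, lux = lux, days = days,
                                dd_days = dd_days,
                                pulse_duration = pulse_duration,
                                seed = seed * 10000 + round(I * 100) + r)
      run$classification$label
    }, character(1))
    data.frame(I = I, n = replicates, entrained = sum(lab == "entrained"))
  })
  out <- do.call(rbind, res)
  out$fraction <- out$entrained / out$n
  out
}

#' Run one random-pulse regimen end to end
#'
#' Convenience wrapper: DD then a random-pulse stage, noiseless gated
#' activity from the trajectory, trailing-15-day period estimate and
#' entrainment classification.
#'
#' @param params an [oscillator_params()].
#' @param I window length, hours.
#' @param lux pulse illuminance.
#' @param days pulse-stage days.
#' @param dd_days preceding DD days.
#' @param pulse_duration pulse length, hours.
#' @param seed integer seed for the schedule draw.
#' @param window_start window opening, clock hours; default centres the
#'   window on 12:00.
#' @param initial_state optional oscillator state at the start of DD.
#' @return List with elements `schedule`, `trajectory`, `record`,
#'   `estimate` and `classification`.
#' @export
simulate_pulse_run <- function(params, I, lux = 1000, days = 40, dd_days = 10,
                               pulse_duration = 1, seed = 1,
                               window_start = NULL, initial_state = NULL) {
  if (is.null(window_start)) window_start <- (12 - I / 2) %% 24
  sched <- random_pulse_schedule(window_start, I, pulse_duration,
                                 n_days = days, seed = seed)
  reg <- schedule_to_regimen(sched, L = lux)
  if (dd_days > 0) {
    reg$lux <- c(rep(reg$background_lux, dd_days * 24 * 12), reg$lux)
    reg$start_datetime <- reg$start_datetime - dd_days * 86400
  }
  traj <- simulate_oscillator(params, reg, initial_state = initial_state)
  rec <- activity_from_trajectory(traj, dispersion = 0,
                                  start_datetime = reg$start_datetime)
  est <- estimate_period(rec, analysis_days = 15)
  list(schedule = sched, trajectory = traj, record = rec,
       estimate = est, classification = classify_entrainment(est$periodogram))
}
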