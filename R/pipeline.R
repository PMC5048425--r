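#' Stage constructors for in-silico experiments
#'
#' An experiment is an ordered list of regimen stages run with the
#' oscillator state carried across transitions (so transients at regimen
#' changes are captured). Pulse stages must last at least 29 days, the
#' minimum treatment length of the laboratory protocols.
#'
#' @param days stage length, days.
#' @return A stage description list.
#' @name experiment-stages
NULL

#' @rdname experiment-stages
#' @export
stage_dd <- function(days = 40) {
  list(type = "dd", days = days, label = "DD")
}

#' @rdname experiment-stages
#' @param pulse_time clock hours of the fixed daily pulse.
#' @param L pulse illuminance, lux.
#' @export
stage_fixed <- function(pulse_time = 12, L = 1000, days = 40) {
  list(type = "fixed", pulse_time = pulse_time, L = L, days = days,
       label = "LD1:23")
}

#' @rdname experiment-stages
#' @param I dispersion-window length, hours.
#' @param window_start window opening, clock hours; `NULL` centres the
#'   window on 12:00.
#' @param shift additional clock displacement of the window, hours
#'   (e.g. +6 for the delayed-window control stage).
#' @export
stage_random <- function(I, L = 1000, days = 40, window_start = NULL,
                         shift = 0) {
  if (is.null(window_start)) window_start <- (12 - I / 2) %% 24
  list(type = "random", I = I, L = L, days = days,
       window_start = (window_start + shift) %% 24,
       label = sprintf("I=%gh L=%glux%s", I, L,
                       if (shift != 0) sprintf(" (shifted %+gh)", shift) else ""))
}

#' Assemble an experiment configuration
#'
#' @param stages list of stages from [stage_dd()], [stage_fixed()],
#'   [stage_random()].
#' @param oscillator an [oscillator_params()].
#' @param behavior list of activity-generator settings:
#'   `gate_fraction`, `mean_counts`, `dispersion`.
#' @param analysis list of analysis settings: `analysis_days`, `alpha`,
#'   `criterion_min`, `p_min`, `p_max`.
#' @param pulse_duration pulse length, hours.
#' @param seed integer master seed.
#' @return An object of class `experiment_config`.
#' @export
experiment_config <- function(stages, oscillator = oscillator_params(),
                              behavior = list(), analysis = list(),
                              pulse_duration = 1, seed = 1) {
  if (length(stages) == 0) stop("stage list must be nonempty")
  for (s in stages) {
    if (s$type != "dd" && s$days < 29)
      stop("pulse stages must last >= 29 days (stage '", s$label, "')")
  }
  behavior <- utils::modifyList(
    list(gate_fraction = 0.5, mean_counts = 20, dispersion = 5), behavior)
  analysis <- utils::modifyList(
    list(analysis_days = 15, alpha = 0.05, criterion_min = 10,
         p_min = 20, p_max = 28), analysis)
  structure(list(stages = stages, oscillator = oscillator,
                 behavior = behavior, analysis = analysis,
                 pulse_duration = pulse_duration, seed = as.integer(seed)),
            class = "experiment_config")
}

#' Read an experiment configuration from YAML
#'
#' Expected layout: top-level `seed`, `pulse_duration_hours`, optional
#' `oscillator` (tau, stiffness, coupling, lux_ref, lux_sat), `behavior`,
#' `analysis`, and a list `stages` of entries with `type` (dd / fixed /
#' random) and the fields of the corresponding stage constructor
#' (`days`, `I_hours`, `L_lux`, `window_start`, `shift`, `pulse_time`).
#'
#' @param path YAML file path.
#' @return An [experiment_config()].
#' @export
read_experiment_config <- function(path) {
  y <- yaml::read_yaml(path)
  osc <- do.call(oscillator_params, y$oscillator %||% list())
  stages <- lapply(y$stages, function(s) {
    switch(s$type,
      dd = stage_dd(days = s$days %||% 40),
      fixed = stage_fixed(pulse_time = s$pulse_time %||% 12,
                          L = s$L_lux %||% 1000, days = s$days %||% 40),
      random = stage_random(I = s$I_hours, L = s$L_lux %||% 1000,
                            days = s$days %||% 40,
                            window_start = s$window_start,
                            shift = s$shift %||% 0),
      stop("unknown stage type: ", s$type))
  })
  experiment_config(stages, oscillator = osc,
                    behavior = y$behavior %||% list(),
                    analysis = y$analysis %||% list(),
                    pulse_duration = y$pulse_duration_hours %||% 1,
                    seed = y$seed %||% 1)
}

#' Run a full in-silico experiment
#'
#' Builds each stage's light regimen (with per-stage schedule seeds
#' derived from the master seed), integrates the oscillator continuously
#' across all stages (state carried over at every transition), generates
#' one activity record per stage from the corresponding trajectory
#' segment, and applies the rhythm analyses to each stage's trailing
#' window: period estimate, entrainment classification, phase markers,
#' phase dispersion (entrained stages only), side bands, and a
#' descriptive transient length (days until the trailing-window
#' classification first equals, and then stays at, the stage's final
#' classification).
#'
#' @param config an [experiment_config()].
#' @param verbose print one line per stage.
#' @return An object of class `experiment_report`: list with `stages` (one
#'   result list per stage: `label`, `period`, `classification`,
#'   `markers`, `dispersion`, `side_bands`, `transient_days`,
#'   `record`), `config` and `package_version`. Regenerable identically
#'   from the same config.
#' @export
run_experiment <- function(config, verbose = FALSE) {
  stopifnot(inherits(config, "experiment_config"))
  n_stages <- length(config$stages)
  stage_seeds <- withr::with_seed(config$seed,
                                  sample.int(.Machine$integer.max, n_stages))
  t0 <- as.POSIXct("2015-07-01", tz = "UTC")
  # render the concatenated regimen
  lux_all <- numeric(0)
  sched_list <- vector("list", n_stages)
  for (k in seq_len(n_stages)) {
    s <- config$stages[[k]]
    sched <- switch(s$type,
      dd = dd_schedule(s$days, config$pulse_duration),
      fixed = fixed_pulse_schedule(s$pulse_time, config$pulse_duration, s$days),
      random = random_pulse_schedule(s$window_start, s$I,
                                     config$pulse_duration, s$days,
                                     seed = stage_seeds[k]))
    sched_list[[k]] <- sched
    reg_k <- if (s$type == "dd") {
      light_regimen(rep(0, s$days * 24 * 12), 5, 0, t0)
    } else {
      schedule_to_regimen(sched, L = s$L, background = 0,
                          resolution_min = 5, start_datetime = t0)
    }
    lux_all <- c(lux_all, reg_k$lux)
  }
  regimen <- light_regimen(lux_all, 5, 0, t0)
  traj <- simulate_oscillator(config$oscillator, regimen)
  b <- config$behavior
  a <- config$analysis
  # per-stage activity + analysis
  results <- vector("list", n_stages)
  offset_bins <- 0L
  for (k in seq_len(n_stages)) {
    s <- config$stages[[k]]
    nb <- s$days * 24 * 12
    idx <- (offset_bins + 1L):(offset_bins + nb + 1L)  # +1: closing sample
    seg <- traj[idx, ]
    class(seg) <- class(traj)
    attr(seg, "sample_h") <- attr(traj, "sample_h")
    rec <- activity_from_trajectory(seg, gate_fraction = b$gate_fraction,
                                    mean_counts = b$mean_counts,
                                    dispersion = b$dispersion,
                                    seed = stage_seeds[k] %% 100000L + 7L,
                                    start_datetime = t0 + offset_bins * 300)
    ak <- a
    ak$analysis_days <- min(a$analysis_days, s$days)  # short stages analysed whole
    est <- estimate_period(rec, analysis_days = ak$analysis_days,
                           p_min = a$p_min, p_max = a$p_max, alpha = a$alpha)
    cls <- classify_entrainment(est$periodogram, a$criterion_min)
    ref <- if (!is.na(est$period)) est$period else 24
    trail <- activity_record(tail(rec$counts,
                                  ak$analysis_days * 24 * 60 / rec$bin_minutes),
                             rec$bin_minutes, rec$start_datetime)
    markers <- detect_phase_markers(trail, ref)
    disp <- if (cls$label == "entrained")
      tryCatch(phase_dispersion(markers, cls), error = function(e) NULL)
    sb <- detect_side_bands(est$periodogram)
    trans <- .transient_days(rec, cls, ak)
    if (verbose)
      message(sprintf("stage %d [%s]: %s (period %s h), transient %s d",
                      k, s$label, cls$label,
                      ifelse(is.na(cls$period), "-", format(cls$period)),
                      ifelse(is.na(trans), "-", trans)))
    results[[k]] <- list(label = s$label, period = cls$period,
                         classification = cls, markers = markers,
                         dispersion = disp, side_bands = sb,
                         transient_days = trans, record = rec)
    offset_bins <- offset_bins + nb
  }
  structure(list(stages = results, config = config,
                 package_version = as.character(utils::packageVersion("circapulse"))),
            class = "experiment_report")
}

# days until the trailing-window classification first equals the final one
# and remains there; NA when the stage never stabilises
.transient_days <- function(rec, final_cls, a) {
  total_days <- record_days(rec)
  if (total_days <= a$analysis_days) return(NA_integer_)
  labs <- vapply(seq(a$analysis_days, total_days), function(d) {
    sub <- activity_record(rec$counts[seq_len(d * 24 * 60 / rec$bin_minutes)],
                           rec$bin_minutes, rec$start_datetime)
    est <- estimate_period(sub, analysis_days = a$analysis_days,
                           p_min = a$p_min, p_max = a$p_max, alpha = a$alpha)
    classify_entrainment(est$periodogram, a$criterion_min)$label
  }, character(1))
  stable_from <- which(rev(cumprod(rev(labs == final_cls$label))) == 1)[1]
  if (is.na(stable_from)) return(NA_integer_)
  as.integer(stable_from - 1L)  # 0 = classified as final from the first window
}

#' @export
print.experiment_report <- function(x, ...) {
  cat("<experiment_report>\n")
  for (k in seq_along(x$stages)) {
    s <- x$stages[[k]]
    cat(sprintf("  %d. %-22s %-12s period %s h\n", k, s$label,
                s$classification$label,
                ifelse(is.na(s$period), "-", format(s$period, digits = 5))))
  }
  invisible(x)
}

#' Replicate an experiment and summarise entrained fractions
#'
#' Runs `n_replicates` seeded, independent copies of the experiment
#' (replicate seeds derived from the master seed) and tabulates the
#' fraction of replicates classified entrained per stage, with
#' Clopper-Pearson 95% binomial confidence intervals.
#'
#' @param config an [experiment_config()].
#' @param n_replicates number of replicates (>= 1).
#' @param seed master seed; `NULL` uses the config's seed.
#' @return Data frame with columns `stage`, `label`, `n`, `entrained`,
#'   `fraction`, `ci_lo`, `ci_hi`; the individual reports are in
#'   attribute `reports`.
#' @export
replicate_experiments <- function(config, n_replicates = 10, seed = NULL) {
  stopifnot(inherits(config, "experiment_config"))
  if (n_replicates < 1) stop("n_replicates must be >= 1")
  seed <- seed %||% config$seed
  rep_seeds <- withr::with_seed(seed, sample.int(.Machine$integer.max,
                                                 n_replicates))
  reports <- lapply(rep_seeds, function(s) {
    cfg <- config
    cfg$seed <- s
    run_experiment(cfg)
  })
  n_stages <- length(config$stages)
  rows <- lapply(seq_len(n_stages), function(k) {
    labs <- vapply(reports, function(r) r$stages[[k]]$classification$label,
                   character(1))
    e <- sum(labs == "entrained")
    ci <- stats::binom.test(e, n_replicates)$conf.int
    data.frame(stage = k, label = config$stages[[k]]$label,
               n = n_replicates, entrained = e, fraction = e / n_replicates,
               ci_lo = ci[1], ci_hi = ci[2])
  })
  out <- do.call(rbind, rows)
  attr(out, "reports") <- reports
  out
}
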