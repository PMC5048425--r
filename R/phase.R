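# circular helpers on an arbitrary period (hours on a circle of length P)
.circ_mean_h <- function(hours, weights = NULL, period = 24) {
  th <- hours * 2 * pi / period
  if (is.null(weights)) weights <- rep(1, length(th))
  s <- sum(weights * sin(th))
  c <- sum(weights * cos(th))
  (atan2(s, c) * period / (2 * pi)) %% period
}

.circ_sd_h <- function(hours, period = 24) {
  th <- hours * 2 * pi / period
  rbar <- sqrt(mean(sin(th))^2 + mean(cos(th))^2)
  rbar <- min(rbar, 1)
  sqrt(-2 * log(rbar)) * period / (2 * pi)
}

#' Activity phase markers: onset, offset, centre of gravity
#'
#' The record is folded at `reference_period`; each complete cycle is
#' processed independently. The activity bout is located as the longest
#' circular run of bins whose smoothed counts (centred circular moving
#' average of `smoothing_window` bins) exceed `threshold_fraction` times
#' the cycle mean; its endpoints are then refined to the first and last
#' bins within that run whose raw counts exceed the same threshold.
#' `onset` and `offset` are the within-cycle hours (bin starts) of those
#' endpoint bins. The centre of gravity (CoG) is the circular weighted
#' mean angle `atan2(sum a_i sin th_i, sum a_i cos th_i)` over all bins of
#' the cycle, `th_i` the bin-start angle and `a_i` its counts, converted
#' to hours.
#'
#' Cycles with no counts yield `NA` markers (flagged, not fabricated).
#'
#' @param record an [activity_record()] covering at least 2 cycles.
#' @param reference_period fold period, hours (typically from
#'   [estimate_period()]).
#' @param smoothing_window moving-average width, bins (default 6 = 30 min).
#' @param threshold_fraction threshold as a fraction of the cycle mean.
#' @return An object of class `phase_markers`: data frame with columns
#'   `cycle`, `onset_h`, `offset_h`, `cog_h` (hours within the cycle), and
#'   attribute `reference_period`.
#' @export
detect_phase_markers <- function(record, reference_period,
                                 smoothing_window = 6,
                                 threshold_fraction = 0.5) {
  stopifnot(inherits(record, "activity_record"))
  bin_h <- record$bin_minutes / 60
  P <- round(reference_period / bin_h)
  if (abs(P * bin_h - reference_period) > 1e-9)
    stop("reference_period must lie on the bin grid")
  n_cycles <- length(record$counts) %/% P
  if (n_cycles < 2) stop("record must cover at least 2 cycles")
  rows <- lapply(seq_len(n_cycles), function(cyc) {
    x <- as.numeric(record$counts[((cyc - 1) * P + 1):(cyc * P)])
    if (all(x == 0))
      return(data.frame(cycle = cyc, onset_h = NA_real_,
                        offset_h = NA_real_, cog_h = NA_real_))
    thr <- threshold_fraction * mean(x)
    sm <- .circ_ma(x, smoothing_window)
    run <- .longest_circular_run(sm > thr)
    if (is.null(run)) {
      onset <- offset <- NA_real_
    } else {
      idx <- run   # circular index sequence, 1-based
      above <- x[idx] > thr
      if (!any(above)) {
        onset <- offset <- NA_real_
      } else {
        onset <- (idx[which(above)[1]] - 1) * bin_h
        offset <- (idx[rev(which(above))[1]] - 1) * bin_h
      }
    }
    cog <- .circ_mean_h((seq_len(P) - 1) * bin_h, weights = x,
                        period = P * bin_h)
    data.frame(cycle = cyc, onset_h = onset, offset_h = offset, cog_h = cog)
  })
  out <- do.call(rbind, rows)
  attr(out, "reference_period") <- P * bin_h
  class(out) <- c("phase_markers", "data.frame")
  out
}

# centred circular moving average
.circ_ma <- function(x, w) {
  if (w <= 1) return(x)
  k <- rep(1 / w, w)
  as.numeric(filter(c(tail(x, w), x, head(x, w)), k, sides = 2)[(w + 1):(w + length(x))])
}

# indices (1-based, possibly wrapping) of the longest circular run of TRUE
.longest_circular_run <- function(b) {
  n <- length(b)
  if (!any(b)) return(NULL)
  if (all(b)) return(seq_len(n))
  r <- rle(c(b, b))                       # doubling handles the wrap
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  true_runs <- which(r$values)
  len <- pmin(r$lengths[true_runs], n)
  best <- true_runs[which.max(len)]
  s <- starts[best]
  ((s - 1 + seq_len(min(r$lengths[best], n)) - 1) %% n) + 1
}

#' Circular phase dispersion of markers across cycles
#'
#' Circular standard deviation (hours, on the reference-period circle) of
#' each marker type across cycles. Defined only for rhythms classified as
#' entrained, mirroring the convention that phase dispersion is reported
#' only when synchronisation to 24 h was achieved.
#'
#' @param markers a `phase_markers` object with >= 3 complete cycles.
#' @param classification an `entrainment_class` for the same record; must
#'   be `"entrained"`.
#' @return Named numeric vector `c(onset=, offset=, cog=)`, hours.
#' @export
phase_dispersion <- function(markers, classification) {
  stopifnot(inherits(markers, "phase_markers"),
            inherits(classification, "entrainment_class"))
  if (classification$label != "entrained")
    stop("phase dispersion is only defined for entrained records")
  P <- attr(markers, "reference_period")
  ok <- stats::complete.cases(markers[, c("onset_h", "offset_h", "cog_h")])
  if (sum(ok) < 3) stop("need >= 3 cycles with complete markers")
  m <- markers[ok, ]
  c(onset = .circ_sd_h(m$onset_h, P),
    offset = .circ_sd_h(m$offset_h, P),
    cog = .circ_sd_h(m$cog_h, P))
}

#' Per-cycle onsets unwrapped to a continuous drift series
#'
#' Helper for drift estimation in actogram coordinates: takes per-cycle
#' markers folded at `modulo` hours and unwraps successive values to the
#' nearest half-cycle, enabling a linear fit of drift (h/day).
#'
#' @param hours per-cycle marker values, hours in `[0, modulo)`.
#' @param modulo fold period, hours.
#' @return Unwrapped numeric vector.
#' @export
unwrap_phase_series <- function(hours, modulo = 24) {
  out <- hours
  if (length(hours) < 2) return(out)
  for (i in 2:length(hours)) {
    d <- (hours[i] - out[i - 1] + modulo / 2) %% modulo - modulo / 2
    out[i] <- out[i - 1] + d
  }
  out
}
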