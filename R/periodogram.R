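#' Chi-square periodogram (Sokolove-Bushell)
#'
#' Scans trial periods on the bin grid (5-min precision for 5-min bins).
#' For a trial period of `P` bins the first `K = floor(N/P)` complete
#' cycles (`N' = K*P` bins) are folded into a `K x P` array; with column
#' means `M_h` and grand mean `M`, the statistic is
#' \deqn{Q_P = K N' \sum_h (M_h - M)^2 / \sum_i (x_i - M)^2,}
#' referred to the chi-square critical value with `P - 1` degrees of
#' freedom at level `alpha`. Incomplete trailing cycles are discarded
#' (complete-row convention); significance is per trial period, with no
#' multiplicity correction, the standard convention for this statistic.
#'
#' @param record an [activity_record()].
#' @param p_min,p_max period scan range, hours.
#' @param alpha significance level of the chi-square reference line.
#' @return An object of class `chi_sq_periodogram`: data frame with
#'   columns `period_h`, `Qp`, `sig_line`, `significant`, and attributes
#'   `peak_period` (the significant period maximising `Qp - sig_line`, or
#'   `NA` if none is significant), `peak_significant` and `alpha`.
#' @references Sokolove, P.G. & Bushell, W.N. (1978) The chi square
#'   periodogram: its utility for analysis of circadian rhythms.
#'   J. Theor. Biol. 72, 131-160.
#' @export
chi_square_periodogram <- function(record, p_min = 20, p_max = 28,
                                   alpha = 0.05) {
  stopifnot(inherits(record, "activity_record"))
  bin_h <- record$bin_minutes / 60
  x <- as.numeric(record$counts)
  N <- length(x)
  P_bins <- seq.int(ceiling(p_min / bin_h), floor(p_max / bin_h))
  if (N < 2 * max(P_bins))
    stop("insufficient data: record must cover at least two cycles of p_max")
  Qp <- vapply(P_bins, function(P) {
    K <- N %/% P
    N2 <- K * P
    xx <- x[seq_len(N2)]
    M <- mean(xx)
    ss_tot <- sum((xx - M)^2)
    if (ss_tot == 0) return(0)
    Mh <- rowMeans(matrix(xx, nrow = P))
    K * N2 * sum((Mh - M)^2) / ss_tot
  }, numeric(1))
  sig <- qchisq(1 - alpha, df = P_bins - 1)
  out <- data.frame(period_h = P_bins * bin_h, Qp = Qp, sig_line = sig,
                    significant = Qp > sig)
  excess <- Qp - sig
  if (any(out$significant)) {
    peak <- out$period_h[which.max(ifelse(out$significant, excess, -Inf))]
    attr(out, "peak_period") <- peak
    attr(out, "peak_significant") <- TRUE
  } else {
    attr(out, "peak_period") <- NA_real_
    attr(out, "peak_significant") <- FALSE
  }
  attr(out, "alpha") <- alpha
  attr(out, "bin_minutes") <- record$bin_minutes
  class(out) <- c("chi_sq_periodogram", "data.frame")
  out
}

#' @export
print.chi_sq_periodogram <- function(x, ...) {
  cat(sprintf("<chi_sq_periodogram> %d periods in [%.2f, %.2f] h, alpha = %g\n",
              nrow(x), min(x$period_h), max(x$period_h), attr(x, "alpha")))
  if (attr(x, "peak_significant")) {
    cat(sprintf("  peak: %.4g h (significant)\n", attr(x, "peak_period")))
  } else {
    cat("  no significant peak\n")
  }
  invisible(x)
}

#' Period estimate from the trailing days of a record
#'
#' Runs the chi-square periodogram on the last `analysis_days` days only,
#' the convention used for per-regimen period determination.
#'
#' @param record an [activity_record()].
#' @param analysis_days trailing window, days.
#' @inheritParams chi_square_periodogram
#' @return List with `period` (hours, `NA` if no significant peak),
#'   `significant`, and the full `periodogram`.
#' @export
estimate_period <- function(record, analysis_days = 15, p_min = 20,
                            p_max = 28, alpha = 0.05) {
  stopifnot(inherits(record, "activity_record"))
  n_bins <- analysis_days * 24 * 60 / record$bin_minutes
  if (length(record$counts) < n_bins)
    stop("record shorter than analysis_days")
  trail <- activity_record(tail(record$counts, n_bins), record$bin_minutes,
                           record$start_datetime, record$animal_id)
  pg <- chi_square_periodogram(trail, p_min, p_max, alpha)
  list(period = attr(pg, "peak_period"),
       significant = attr(pg, "peak_significant"),
       periodogram = pg)
}

#' Classify a periodogram as entrained, free-running or arrhythmic
#'
#' A rhythm is entrained when its significant peak period lies within
#' 24 h +/- `criterion_min` minutes; free-running when a significant peak
#' lies outside that interval; arrhythmic when no period in the scanned
#' range is significant.
#'
#' @param periodogram a `chi_sq_periodogram`.
#' @param criterion_min half-width of the synchronisation criterion,
#'   minutes (default 10).
#' @return An object of class `entrainment_class`: list with `label`
#'   (`"entrained"`, `"free_running"` or `"arrhythmic"`), `period` (hours
#'   or `NA`) and `criterion_min`.
#' @export
classify_entrainment <- function(periodogram, criterion_min = 10) {
  stopifnot(inherits(periodogram, "chi_sq_periodogram"))
  peak <- attr(periodogram, "peak_period")
  label <- if (!attr(periodogram, "peak_significant")) {
    "arrhythmic"
  } else if (abs(peak - 24) <= criterion_min / 60 + 1e-9) {
    "entrained"
  } else {
    "free_running"
  }
  structure(list(label = label, period = peak, criterion_min = criterion_min),
            class = "entrainment_class")
}

#' @export
print.entrainment_class <- function(x, ...) {
  cat(sprintf("<entrainment_class> %s (period %s h; criterion 24 h +/- %g min)\n",
              x$label, ifelse(is.na(x$period), "-", format(x$period, digits = 5)),
              x$criterion_min))
  invisible(x)
}

#' Detect side-band periods
#'
#' Significant local maxima of `Qp - sig_line` lying farther than
#' `main_peak_exclusion` hours from the main peak, sorted by decreasing
#' excess. Side bands flanking the main peak indicate marginal or lost
#' entrainment near the border of the range of entrainment.
#'
#' @param periodogram a `chi_sq_periodogram`.
#' @param main_peak_exclusion half-width of the exclusion zone around the
#'   main peak, hours.
#' @return Data frame with columns `period_h` and `excess` (possibly
#'   zero rows).
#' @export
detect_side_bands <- function(periodogram, main_peak_exclusion = 1) {
  stopifnot(inherits(periodogram, "chi_sq_periodogram"))
  excess <- periodogram$Qp - periodogram$sig_line
  n <- length(excess)
  if (n < 3 || !any(periodogram$significant))
    return(data.frame(period_h = numeric(0), excess = numeric(0)))
  is_max <- c(FALSE, excess[2:(n - 1)] > excess[1:(n - 2)] &
                     excess[2:(n - 1)] >= excess[3:n], FALSE)
  main <- attr(periodogram, "peak_period")
  keep <- is_max & periodogram$significant &
    (is.na(main) | abs(periodogram$period_h - main) > main_peak_exclusion)
  out <- data.frame(period_h = periodogram$period_h[keep],
                    excess = excess[keep])
  out[order(out$excess, decreasing = TRUE), , drop = FALSE]
}

#' Fold a record into an actogram matrix
#'
#' Rows are consecutive `modulo`-hour spans; values are counts. With
#' `double_plot` each row is concatenated with its successor (the standard
#' double-plotted actogram); the final row's right half is `NA`. An
#' incomplete trailing span is padded with `NA`.
#'
#' @param record an [activity_record()].
#' @param modulo row length, hours (on the bin grid).
#' @param double_plot logical.
#' @return A numeric matrix (days x bins), with attribute `bin_minutes`.
#' @export
build_actogram <- function(record, modulo = 24, double_plot = FALSE) {
  stopifnot(inherits(record, "activity_record"))
  nb <- modulo * 60 / record$bin_minutes
  if (abs(nb - round(nb)) > 1e-9) stop("modulo must lie on the bin grid")
  nb <- round(nb)
  x <- as.numeric(record$counts)
  nd <- ceiling(length(x) / nb)
  length(x) <- nd * nb                     # pad with NA
  m <- matrix(x, nrow = nd, byrow = TRUE)
  if (double_plot) {
    m <- cbind(m, rbind(m[-1, , drop = FALSE], rep(NA_real_, nb)))
  }
  attr(m, "bin_minutes") <- record$bin_minutes
  m
}

#' Plot an actogram
#'
#' Minimal base-graphics rendering: black marks for supra-threshold bins,
#' days stacked top to bottom.
#'
#' @param record an [activity_record()].
#' @param modulo row length, hours.
#' @param double_plot logical.
#' @param ... passed to [graphics::image()].
#' @return Invisibly, the actogram matrix.
#' @export
plot_actogram <- function(record, modulo = 24, double_plot = TRUE, ...) {
  m <- build_actogram(record, modulo, double_plot)
  z <- t(m[rev(seq_len(nrow(m))), , drop = FALSE])
  graphics::image(z = z > 0, col = c("white", "black"), axes = FALSE,
                  xlab = "time of day (h)", ylab = "day", ...)
  invisible(m)
}
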