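# independent brute-force oracles and fixture builders used across tests

# explicit fold-and-variance double loop (complete rows only)
brute_qp <- function(x, P_bins) {
  N <- length(x)
  K <- N %/% P_bins
  N2 <- K * P_bins
  xx <- x[1:N2]
  M <- mean(xx)
  Mh <- numeric(P_bins)
  for (h in 1:P_bins) {
    s <- 0
    for (k in 0:(K - 1)) s <- s + xx[k * P_bins + h]
    Mh[h] <- s / K
  }
  num <- 0
  for (h in 1:P_bins) num <- num + (Mh[h] - M)^2
  den <- 0
  for (i in 1:N2) den <- den + (xx[i] - M)^2
  K * N2 * num / den
}

# explicit circular weighted mean by vector summation (hours on period P)
brute_circ_mean <- function(hours, weights, period) {
  S <- 0
  C <- 0
  for (i in seq_along(hours)) {
    th <- hours[i] * 2 * pi / period
    S <- S + weights[i] * sin(th)
    C <- C + weights[i] * cos(th)
  }
  (atan2(S, C) * period / (2 * pi)) %% period
}

# square-wave activity record: active bins are those whose start time t
# satisfies from <= (t mod period) <= to (both endpoints included)
square_wave_record <- function(from = 12, to = 20, days = 10, period = 24,
                               level = 10, bin_minutes = 5) {
  n <- days * 24 * 60 / bin_minutes
  t <- (seq_len(n) - 1) * bin_minutes / 60
  ph <- t %% period
  counts <- ifelse(ph >= from - 1e-9 & ph <= to + 1e-9, level, 0)
  activity_record(counts, bin_minutes)
}

# unforced trajectory helper
dd_trajectory <- function(params, days) {
  reg <- light_regimen(rep(0, days * 24 * 12), 5, 0)
  simulate_oscillator(params, reg)
}

circ_mean24 <- function(h) {
  (atan2(mean(sin(h * pi / 12)), mean(cos(h * pi / 12))) * 12 / pi) %% 24
}
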