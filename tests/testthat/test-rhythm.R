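test_that("Qp equals the brute-force fold-and-variance oracle", {
  # noisy record, < 2000 bins
  rec <- synthetic_free_run(23.5, noise = 3, n_days = 6, seed = 5)
  expect_lt(length(rec$counts), 2000)
  pg <- chi_square_periodogram(rec, p_min = 20, p_max = 28)
  x <- as.numeric(rec$counts)
  for (P_h in c(20, 23.5, 24, 25.25, 28)) {
    P <- P_h * 12
    expect_equal(pg$Qp[abs(pg$period_h - P_h) < 1e-9], brute_qp(x, P),
                 tolerance = 1e-12)
  }
  # grid is 5-minute
  expect_equal(unique(round(diff(pg$period_h) * 60, 9)), 5)
  # significance line is the chi-square critical value at P - 1 df
  expect_equal(pg$sig_line, qchisq(0.95, pg$period_h * 12 - 1))
})

test_that("periodogram peaks are exact for noiseless periodic records", {
  expect_identical(
    attr(chi_square_periodogram(synthetic_free_run(24, noise = 0, n_days = 20)),
         "peak_period"), 24)
  expect_identical(
    attr(chi_square_periodogram(synthetic_free_run(26, noise = 0, n_days = 20)),
         "peak_period"), 26)
  expect_error(chi_square_periodogram(synthetic_free_run(24, n_days = 2)),
               "insufficient")
})

test_that("the significance line has ~5% type-I error per trial period", {
  n_rep <- 200
  hits <- withr::with_seed(20, {
    sum(vapply(seq_len(n_rep), function(i) {
      rec <- activity_record(rpois(288 * 15, 20))
      pg <- chi_square_periodogram(rec, p_min = 24, p_max = 24, alpha = 0.05)
      pg$significant[1]
    }, logical(1)))
  })
  # binomial 99.9% envelope around p = 0.05 at n = 200: [2, 21]
  expect_gte(hits, 2)
  expect_lte(hits, 21)
})

test_that("period estimation uses only the trailing window", {
  two <- activity_record(c(synthetic_free_run(23.5, noise = 0, n_days = 16)$counts,
                           synthetic_free_run(24, noise = 0, n_days = 16)$counts))
  expect_equal(estimate_period(two, analysis_days = 15)$period, 24)
  # stationary record: estimate within one grid step of truth
  rec <- synthetic_free_run(24.7, noise = 0, n_days = 31)
  expect_lt(abs(estimate_period(rec)$period - 24.7), 5 / 60 + 1e-9)
  # degenerate window equals the full-record periodogram
  full <- chi_square_periodogram(rec)
  expect_equal(estimate_period(rec, analysis_days = 31)$period,
               attr(full, "peak_period"))
  expect_error(estimate_period(rec, analysis_days = 40), "shorter")
})

test_that("entrainment classification follows the 24 h +/- 10 min criterion", {
  lab <- function(tau) {
    rec <- synthetic_free_run(tau, noise = 0, n_days = 31)
    classify_entrainment(estimate_period(rec)$periodogram)$label
  }
  expect_equal(lab(24 + 5 / 60), "entrained")      # 24 h 05
  expect_equal(lab(24 + 10 / 60), "entrained")     # boundary inclusive
  expect_equal(lab(24 + 15 / 60), "free_running")  # 24 h 15
  expect_equal(lab(23.5), "free_running")
  flat <- activity_record(rep(3L, 288 * 31))
  expect_equal(classify_entrainment(estimate_period(flat)$periodogram)$label,
               "arrhythmic")
})

test_that("phase markers are exact on canonical fixtures", {
  rec <- square_wave_record(from = 12, to = 20, days = 10)
  m <- detect_phase_markers(rec, 24)
  expect_equal(nrow(m), 10)
  expect_true(all(m$onset_h == 12))
  expect_true(all(m$offset_h == 20))
  expect_equal(m$cog_h, rep(16, 10))
  # point mass: single nonzero bin at hour 6
  x <- numeric(288 * 2)
  x[6 * 12 + 1] <- 50
  x[288 + 6 * 12 + 1] <- 50
  mp <- detect_phase_markers(activity_record(x), 24)
  expect_equal(mp$cog_h, c(6, 6))
  expect_equal(mp$onset_h, c(6, 6))
  # all-zero cycle is flagged, not fabricated
  y <- c(square_wave_record(12, 20, 1)$counts, numeric(288))
  my <- detect_phase_markers(activity_record(y), 24)
  expect_true(is.na(my$onset_h[2]) && is.na(my$cog_h[2]))
})

test_that("CoG equals the brute-force circular mean on asymmetric cycles", {
  withr::with_seed(31, {
    x <- numeric(288)
    x[30:60] <- rpois(31, 20)          # morning bout
    x[200:215] <- rpois(16, 35)        # second, unequal bout
    rec <- activity_record(rep(x, 2))
    m <- detect_phase_markers(rec, 24)
    expect_equal(m$cog_h[1],
                 brute_circ_mean((seq_len(288) - 1) / 12, x, 24),
                 tolerance = 1e-12)
  })
})

test_that("phase dispersion is circular and defined only when entrained", {
  rec <- square_wave_record(12, 20, days = 31)
  cls <- classify_entrainment(estimate_period(rec)$periodogram)
  m <- detect_phase_markers(rec, 24)
  d <- phase_dispersion(m, cls)
  expect_equal(unname(d), c(0, 0, 0))
  # alternating markers 11 / 13 h: circular SD ~ 1 h
  m2 <- m
  m2$onset_h <- rep(c(11, 13), length.out = nrow(m2))
  m2$offset_h <- rep(c(19, 21), length.out = nrow(m2))
  m2$cog_h <- rep(c(15, 17), length.out = nrow(m2))
  d2 <- phase_dispersion(m2, cls)
  expect_equal(unname(d2["onset"]), 1, tolerance = 0.01)
  # rotation invariance
  m3 <- m2
  for (col in c("onset_h", "offset_h", "cog_h")) m3[[col]] <- (m3[[col]] + 7.3) %% 24
  expect_equal(phase_dispersion(m3, cls), d2, tolerance = 1e-9)
  # refuses non-entrained input
  fr <- synthetic_free_run(23.5, noise = 0, n_days = 31)
  cls_fr <- classify_entrainment(estimate_period(fr)$periodogram)
  expect_error(phase_dispersion(detect_phase_markers(fr, 23.5), cls_fr),
               "entrained")
})

test_that("side-band detection flags secondary periodicities only", {
  pure <- synthetic_free_run(24, noise = 0, n_days = 40)
  pg <- chi_square_periodogram(pure)
  expect_equal(nrow(detect_side_bands(pg)), 0)
  # two-tone record: 24 h + 25 h components
  two <- activity_record(synthetic_free_run(24, noise = 0, n_days = 50)$counts +
                         synthetic_free_run(25, noise = 0, n_days = 50)$counts)
  pg2 <- chi_square_periodogram(two)
  sb <- detect_side_bands(pg2, main_peak_exclusion = 0.5)
  expect_gt(nrow(sb), 0)
  main <- attr(pg2, "peak_period")
  second <- setdiff(c(24, 25), main)[1]
  expect_true(any(abs(sb$period_h - second) <= 0.25))
  # exclusion window spanning the whole grid
  expect_equal(nrow(detect_side_bands(pg2, main_peak_exclusion = 8)), 0)
})

test_that("actogram folding is structural and conservative", {
  rec <- activity_record(seq_len(288 * 2))
  m <- build_actogram(rec, 24, double_plot = TRUE)
  expect_equal(dim(m), c(2, 2 * 288))
  expect_equal(m[1, 289:576], m[2, 1:288])
  expect_true(all(is.na(m[2, 289:576])))
  ms <- build_actogram(rec, 24, double_plot = FALSE)
  expect_equal(sum(ms), sum(rec$counts))
  expect_error(build_actogram(rec, modulo = 24.01), "grid")
})
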