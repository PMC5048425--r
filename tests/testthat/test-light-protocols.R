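test_that("random pulse schedules stay inside the window and are reproducible", {
  s <- random_pulse_schedule(6, I = 8, pulse_duration = 1, n_days = 30, seed = 1)
  expect_equal(nrow(s), 30)
  expect_true(all(s$pulse_start >= 6 & s$pulse_start <= 13))
  # 5-min grid
  expect_true(all(abs(s$pulse_start * 12 - round(s$pulse_start * 12)) < 1e-9))
  # bitwise determinism for a fixed seed; global RNG untouched
  withr::with_seed(99, {
    before <- runif(1)
  })
  s2 <- random_pulse_schedule(6, 8, 1, 30, seed = 1)
  expect_identical(s$pulse_start, s2$pulse_start)
  expect_false(identical(
    random_pulse_schedule(6, 8, 1, 30, seed = 2)$pulse_start, s$pulse_start))
  # degenerate window: every start at window_start
  d <- random_pulse_schedule(0, I = 1, pulse_duration = 1, n_days = 10, seed = 5)
  expect_true(all(d$pulse_start == 0))
  expect_error(random_pulse_schedule(6, I = 0.5, pulse_duration = 1, n_days = 5),
               "invalid window")
  expect_error(random_pulse_schedule(6, 8, 1, n_days = 0), "n_days")
})

test_that("pulse start times are uniform over the window", {
  s <- random_pulse_schedule(2, I = 20, pulse_duration = 1, n_days = 10000,
                             seed = 7)
  expect_true(all(s$pulse_start >= 2 & s$pulse_start <= 21))
  slots <- (21 - 2) * 12 + 1
  idx <- round((s$pulse_start - 2) * 12)
  tab <- tabulate(idx + 1, nbins = slots)
  gof <- suppressWarnings(chisq.test(tab))
  expect_gt(gof$p.value, 0.01)
  # Kolmogorov-Smirnov distance against the uniform law is small
  ks <- max(abs(ecdf(s$pulse_start)(seq(2, 21, 0.05)) -
                punif(seq(2, 21, 0.05), 2, 21)))
  expect_lt(ks, 0.02)
})

test_that("fixed schedules equal degenerate random windows and shifts round-trip", {
  f <- fixed_pulse_schedule(12, 1, 29)
  expect_equal(nrow(f), 29)
  expect_true(all(f$pulse_start == 12))
  r <- random_pulse_schedule(12, I = 1, pulse_duration = 1, n_days = 29,
                             seed = 3)
  expect_equal(f$pulse_start, r$pulse_start)
  expect_equal(f$day, r$day)
  expect_equal(attr(f, "pulse_duration"), attr(r, "pulse_duration"))

  s <- random_pulse_schedule(6, 8, 1, 20, seed = 4)
  sh <- shift_schedule(s, 6)
  expect_equal(attr(sh, "window_start"), 12)
  expect_equal(sh$pulse_start, (s$pulse_start + 6) %% 24)
  back <- shift_schedule(sh, -6)
  expect_equal(back$pulse_start, s$pulse_start)
  expect_equal(attr(back, "window_start"), attr(s, "window_start"))
  expect_equal(shift_schedule(s, 0)$pulse_start, s$pulse_start)
  # wrap modulo 24
  late <- shift_schedule(fixed_pulse_schedule(23, 1, 2), 3)
  expect_equal(late$pulse_start, c(2, 2))
})

test_that("rendering a schedule conserves the daily light dose", {
  reg <- schedule_to_regimen(fixed_pulse_schedule(12, 1, 3), L = 1000,
                             background = 0, resolution_min = 5)
  expect_equal(length(reg$lux), 3 * 288)
  day1 <- reg$lux[1:288]
  expect_equal(sum(day1 == 1000), 12)
  expect_true(all(diff(which(day1 == 1000)) == 1))  # consecutive samples
  expect_equal(which(day1 == 1000)[1], 12 * 12 + 1) # starts at 12:00

  s <- random_pulse_schedule(6, 8, 1, 25, seed = 11)
  reg2 <- schedule_to_regimen(s, L = 500, background = 2)
  m <- matrix(reg2$lux, nrow = 288)
  dose <- colSums(m - 2) * 5 / 60
  expect_equal(dose, rep((500 - 2) * 1, 25))

  dd <- schedule_to_regimen(dd_schedule(5), L = 1000)
  expect_true(all(dd$lux == 0))
  expect_equal(regimen_duration(dd), 120)

  expect_error(schedule_to_regimen(fixed_pulse_schedule(12, 1, 3), L = 1000,
                                   resolution_min = 7), "resolution")
  expect_error(schedule_to_regimen(fixed_pulse_schedule(12, 1, 3), L = 0),
               "exceed")
})

test_that("schedule and regimen CSV round-trips preserve content", {
  tmp <- withr::local_tempdir()
  s <- random_pulse_schedule(6, 8, 1, 10, seed = 2)
  write_schedule_csv(s, file.path(tmp, "sched.csv"))
  df <- read.csv(file.path(tmp, "sched.csv"))
  expect_equal(df$pulse_start_hours, s$pulse_start)
  expect_equal(unique(df$duration_hours), 1)

  rec <- synthetic_free_run(24, n_days = 2)
  write_activity_csv(rec, file.path(tmp, "act.csv"))
  back <- read_activity_csv(file.path(tmp, "act.csv"))
  expect_equal(back$counts, rec$counts)

  log <- synthetic_light_log(4, seed = 1)
  write_light_log_csv(log, file.path(tmp, "log.csv"))
  back2 <- read_light_log_csv(file.path(tmp, "log.csv"))
  expect_equal(back2$lux, log$lux)
  expect_equal(back2$range_max, log$range_max)
})
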