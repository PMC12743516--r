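make_constant_rec <- function(x, y, z, minutes = 10, rate = 10) {
  n <- minutes * 60 * rate
  ts <- (seq_len(n) - 1) / rate
  accel_recording(ts, rep(x, n), rep(y, n), rep(z, n), sample_rate_hz = rate)
}

test_that("recording constructor enforces its invariants", {
  expect_error(accel_recording(numeric(0), numeric(0), numeric(0),
                               numeric(0)), "empty")
  expect_error(accel_recording(c(0, 0.01, 0.01), rep(0, 3), rep(0, 3),
                               rep(1000, 3)), "strictly increasing")
  expect_error(accel_recording(0:1, c(0, 9000), c(0, 0), c(1000, 1000)),
               "8 g")
})

test_that("planted offsets are recovered by calibration", {
  prof <- data.frame(duration_min = rep(5, 12),
                     class = rep(c("nonwear", "sedentary"), 6),
                     orientation = rep(1:6, each = 2))
  rec <- simulate_recording(prof, seed = 2, mode = "raw", sample_rate_hz = 50)
  rec$x <- rec$x + 30; rec$y <- rec$y - 20; rec$z <- rec$z + 10
  cal <- calibrate_to_gravity(rec)
  cc <- attr(cal, "calibration")
  expect_true(cc$calibrated)
  # the estimated correction must undo the planted offsets
  expect_equal(unname(cc$offset), c(-30, 20, -10), tolerance = 3 / 10)
  expect_equal(unname(cc$gain), c(1, 1, 1), tolerance = 5e-3)
  expect_lt(abs(cc$stationary_error_mg), 5)
})

test_that("an already-calibrated signal is left (almost) unchanged", {
  prof <- data.frame(duration_min = rep(5, 12),
                     class = rep(c("nonwear", "sedentary"), 6),
                     orientation = rep(1:6, each = 2))
  rec <- simulate_recording(prof, seed = 3, mode = "raw", sample_rate_hz = 50)
  cc <- attr(calibrate_to_gravity(rec), "calibration")
  expect_equal(unname(cc$offset), c(0, 0, 0), tolerance = 1)
  expect_equal(unname(cc$gain), c(1, 1, 1), tolerance = 2e-3)
  # idempotence on epoch values
  once <- calibrate_to_gravity(rec)
  twice <- calibrate_to_gravity(once)
  e1 <- epoch_vector_magnitude(once)$mean_vm_mg
  e2 <- epoch_vector_magnitude(twice)$mean_vm_mg
  expect_lt(max(abs(e1 - e2)), 1)
})

test_that("all-moving signals take the uncalibrated-with-warning path", {
  prof <- data.frame(duration_min = 30, class = "mvpa")
  rec <- simulate_recording(prof, seed = 4, mode = "raw", sample_rate_hz = 25)
  expect_warning(out <- calibrate_to_gravity(rec), "uncalibrated")
  cc <- attr(out, "calibration")
  expect_false(cc$calibrated)
  expect_identical(out$x, rec$x)
})

test_that("epoch ENMO matches closed forms on constant signals", {
  rec0 <- make_constant_rec(0, 0, 1000, minutes = 2)
  expect_true(all(epoch_vector_magnitude(rec0)$mean_vm_mg == 0))
  rec200 <- make_constant_rec(0, 0, 1200, minutes = 2)
  expect_true(all(abs(epoch_vector_magnitude(rec200)$mean_vm_mg - 200) < 1e-9))
  expect_error(epoch_vector_magnitude(rec0[0, ]), "empty")
})

test_that("epoch ENMO equals a brute-force per-epoch recomputation", {
  set.seed(8)
  n <- 10 * 60 * 10  # 10 min at 10 Hz
  ts <- (seq_len(n) - 1) / 10
  rec <- accel_recording(ts, rnorm(n, 0, 40), rnorm(n, 0, 40),
                         rnorm(n, 1000, 40), sample_rate_hz = 10)
  ep <- epoch_vector_magnitude(rec, epoch_length_s = 5)
  enmo <- pmax(0, sqrt(rec$x^2 + rec$y^2 + rec$z^2) - 1000)
  for (i in seq_len(nrow(ep))) {
    sel <- ts >= ep$epoch_start_s[i] & ts < ep$epoch_start_s[i] + 5
    expect_equal(ep$mean_vm_mg[i], mean(enmo[sel]), tolerance = 1e-12)
  }
})

test_that("a trailing partial epoch is dropped", {
  rec <- make_constant_rec(0, 0, 1100, minutes = 2)
  rec2 <- rec[seq_len(nrow(rec) - 7), ]  # chop mid-epoch
  attr(rec2, "sample_rate_hz") <- 10
  ep <- epoch_vector_magnitude(rec2)
  expect_equal(nrow(ep), 2 * 60 / 5 - 1)
})

test_that("fully stationary and fully active recordings bound the detector", {
  quiet <- simulate_recording(data.frame(duration_min = 24 * 60,
                                         class = "nonwear"),
                              seed = 1, mode = "epoch")
  res <- detect_nonwear(quiet)
  expect_equal(nrow(res$intervals), 1L)
  expect_lte(res$intervals$start_s[1], 1)
  expect_gte(res$intervals$end_s[1], 24 * 3600 - 3600)

  active <- simulate_recording(data.frame(duration_min = 24 * 60,
                                          class = "sedentary"),
                               seed = 2, mode = "epoch")  # SD ~18 mg > 13
  expect_equal(nrow(detect_nonwear(active)$intervals), 0L)

  short <- simulate_recording(data.frame(duration_min = 30,
                                         class = "nonwear"),
                              seed = 3, mode = "epoch")
  expect_warning(res3 <- detect_nonwear(short), "shorter")
  expect_equal(nrow(res3$intervals), 0L)
})

test_that("a planted stationary block is located within one window step", {
  prof <- data.frame(duration_min = c(300, 90, 300),
                     class = c("sedentary", "nonwear", "sedentary"))
  rec <- simulate_recording(prof, seed = 11, mode = "epoch",
                            rotate_orientation = FALSE)
  res <- detect_nonwear(rec)
  expect_equal(nrow(res$intervals), 1L)
  step_s <- 15 * 60
  expect_lte(abs(res$intervals$start_s[1] - 300 * 60), step_s)
  expect_lte(abs(res$intervals$end_s[1] - 390 * 60), step_s)
})

test_that("lowering the SD threshold never increases non-wear time", {
  prof <- data.frame(duration_min = c(200, 70, 150, 120, 180),
                     class = c("sedentary", "nonwear", "light", "nonwear",
                               "sedentary"))
  rec <- simulate_recording(prof, seed = 21, mode = "epoch")
  total_nonwear <- function(thr) {
    iv <- detect_nonwear(rec, nonwear_params(sd_threshold_mg = thr))$intervals
    sum(iv$end_s - iv$start_s)
  }
  tots <- vapply(c(25, 20, 13, 8, 4, 1), total_nonwear, numeric(1))
  expect_true(all(diff(tots) <= 0))
})

test_that("intensity classification respects the strict 100 mg rule", {
  ep <- data.frame(epoch_start_s = seq(0, 45, by = 5),
                   mean_vm_mg = c(0, 15, 29.999, 30, 75, 100, 100.0001, 150,
                                  250, 1000),
                   wear = c(rep(TRUE, 9), FALSE))
  attr(ep, "epoch_length_s") <- 5
  class(ep) <- c("epoch_series", "data.frame")
  cl <- classify_intensity(ep)$class
  expect_equal(as.character(cl),
               c("sedentary", "sedentary", "sedentary", "light", "light",
                 "light",  # exactly 100.0 mg is NOT mvpa
                 "mvpa", "mvpa", "mvpa", "nonwear"))
})

test_that("class counts equal an independent recount on random epochs", {
  set.seed(99)
  ep <- data.frame(epoch_start_s = seq(0, by = 5, length.out = 500),
                   mean_vm_mg = runif(500, 0, 200),
                   wear = runif(500) > 0.1)
  attr(ep, "epoch_length_s") <- 5
  class(ep) <- c("epoch_series", "data.frame")
  cl <- classify_intensity(ep)$class
  v <- ep$mean_vm_mg
  expect_equal(sum(cl == "nonwear"), sum(!ep$wear))
  expect_equal(sum(cl == "mvpa"), sum(ep$wear & v > 100))
  expect_equal(sum(cl == "light"), sum(ep$wear & v >= 30 & v <= 100))
  expect_equal(sum(cl == "sedentary"), sum(ep$wear & v < 30))
})

make_classified <- function(n_mvpa, n_light, n_sed, n_nonwear = 0) {
  n <- n_mvpa + n_light + n_sed + n_nonwear
  ep <- data.frame(epoch_start_s = seq(0, by = 5, length.out = n),
                   mean_vm_mg = c(rep(150, n_mvpa), rep(50, n_light),
                                  rep(5, n_sed), rep(0, n_nonwear)),
                   wear = c(rep(TRUE, n_mvpa + n_light + n_sed),
                            rep(FALSE, n_nonwear)))
  attr(ep, "epoch_length_s") <- 5
  class(ep) <- c("epoch_series", "data.frame")
  classify_intensity(ep)
}

test_that("weekly summaries match hand computations", {
  # 1440 mvpa epochs over exactly 7 full wear days -> 1440*5/60 = 120 min
  week_epochs <- 7 * 86400 / 5
  s <- summarise_week(make_classified(1440, 0, week_epochs - 1440))
  expect_equal(s$mvpa_min_week, 120)
  expect_equal(s$valid_wear_days, 7)
  expect_true(s$qc_pass)

  # 60 mvpa epochs over 3.5 wear days -> 60*5/60 * (7/3.5) = 10 min/week
  half_week <- 3.5 * 86400 / 5
  s2 <- summarise_week(make_classified(60, 0, half_week - 60))
  expect_equal(s2$mvpa_min_week, 10)
  # per-day variant reports the daily average
  s2d <- summarise_week(make_classified(60, 0, half_week - 60),
                        scale = "per_day")
  expect_equal(s2d$mvpa_min_week, 60 * 5 / 60 / 3.5)

  # 2 wear days -> QC fail, minutes unusable
  two_days <- 2 * 86400 / 5
  s3 <- summarise_week(make_classified(100, 0, two_days - 100))
  expect_false(s3$qc_pass)
  expect_true(is.na(s3$mvpa_min_week))
})

test_that("class minutes are conserved against wear time", {
  prof <- data.frame(duration_min = c(1000, 45, 2000, 120, 500, 30,
                                      7 * 1440 - 3695),
                     class = c("sedentary", "mvpa", "light", "nonwear",
                               "sedentary", "mvpa", "sedentary"))
  rec <- simulate_recording(prof, seed = 31, mode = "epoch")
  ep <- epoch_vector_magnitude(rec)
  ep <- detect_nonwear(rec, epochs = ep)$epochs
  ep <- classify_intensity(ep)
  len <- attr(ep, "epoch_length_s")
  wear_min <- sum(ep$wear) * len / 60
  class_min <- sum(ep$class %in% c("sedentary", "light", "mvpa") & ep$wear) *
    len / 60
  expect_lte(abs(wear_min - class_min), len / 60)
})

test_that("recording CSV round-trips", {
  prof <- data.frame(duration_min = 5, class = "sedentary")
  rec <- simulate_recording(prof, seed = 6, mode = "epoch")
  path <- withr::local_tempfile(fileext = ".csv")
  write_recording_csv(rec, path)
  back <- read_recording_csv(path)
  expect_equal(back$x, rec$x, tolerance = 1e-9)
  expect_equal(attr(back, "sample_rate_hz"), 0.2)
})
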