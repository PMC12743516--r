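#' @title Accelerometry: raw signal to weekly activity minutes
#' @description Processing chain for wrist-worn tri-axial acceleration:
#'   gravity calibration, 5-s ENMO epochs, SD-based non-wear detection,
#'   intensity classification at the 100 mg MVPA cut, and weekly summaries
#'   with a minimum-wear quality gate.
#' @name accelerometry
NULL

DEVICE_RANGE_MG <- 8000  # +/- 8 g dynamic range
GRAVITY_MG <- 1000

#' Construct an acceleration recording
#'
#' @param timestamp_s numeric, seconds since recording start, strictly
#'   increasing.
#' @param x,y,z per-axis acceleration in milligravity (mg).
#' @param sample_rate_hz nominal sampling rate; 100 Hz for raw device output,
#'   0.2 Hz for pre-aggregated 5-s epoch mode.
#' @return data.frame of class `accel_recording`.
#' @export
accel_recording <- function(timestamp_s, x, y, z, sample_rate_hz = 100) {
  n <- length(timestamp_s)
  if (n == 0L) stop("empty recording")
  if (!(length(x) == n && length(y) == n && length(z) == n))
    stop("axis vectors must match timestamp length")
  if (is.unsorted(timestamp_s, strictly = TRUE))
    stop("timestamps must be strictly increasing")
  if (max(abs(c(x, y, z))) > DEVICE_RANGE_MG)
    stop("acceleration outside the +/-8 g device range")
  rec <- data.frame(timestamp_s = timestamp_s, x = x, y = y, z = z)
  attr(rec, "sample_rate_hz") <- sample_rate_hz
  class(rec) <- c("accel_recording", "data.frame")
  rec
}

#' Non-wear detection parameters
#'
#' Defaults encode the standard rule: an episode is non-wear when all three
#' axes have standard deviation below 13 mg over a stationary stretch of at
#' least 60 minutes. The sliding-window mechanics (60-min window advanced in
#' 15-min steps, overlapping stationary windows merged) are configurable.
#'
#' @param sd_threshold_mg per-axis SD threshold (mg).
#' @param min_episode_min minimum merged episode length (min).
#' @param window_min window length (min).
#' @param window_step_min step between window starts (min).
#' @export
nonwear_params <- function(sd_threshold_mg = 13, min_episode_min = 60,
                           window_min = 60, window_step_min = 15) {
  stopifnot(sd_threshold_mg > 0, min_episode_min > 0, window_min > 0,
            window_step_min > 0, window_step_min <= window_min)
  structure(list(sd_threshold_mg = sd_threshold_mg,
                 min_episode_min = min_episode_min,
                 window_min = window_min,
                 window_step_min = window_step_min),
            class = "nonwear_params")
}

#' Intensity classification thresholds
#'
#' MVPA requires epoch ENMO strictly above `mvpa_mg` (100 mg). The
#' sedentary/light boundary is not part of the published rule set; 30 mg is
#' the conventional companion cut and is configurable.
#'
#' @param mvpa_mg MVPA cut (mg), strict inequality.
#' @param light_lower_mg lower bound of the light band (mg).
#' @export
intensity_thresholds <- function(mvpa_mg = 100, light_lower_mg = 30) {
  stopifnot(light_lower_mg > 0, light_lower_mg < mvpa_mg)
  structure(list(mvpa_mg = mvpa_mg, light_lower_mg = light_lower_mg),
            class = "intensity_thresholds")
}

# Split sample indices into consecutive fixed-duration windows and return
# per-window, per-axis means and SDs. Used by calibration.
stationary_windows <- function(rec, window_s = 10, sd_threshold_mg = 13) {
  idx <- floor(rec$timestamp_s / window_s)
  grp <- match(idx, unique(idx))
  n <- tabulate(grp)
  keep <- n >= 2L
  ax <- as.matrix(rec[, c("x", "y", "z")])
  mu <- rowsum(ax, grp) / n
  m2 <- rowsum(ax^2, grp)
  v <- (m2 - n * mu^2) / pmax(1, n - 1)
  v[v < 0] <- 0
  sds <- sqrt(v)
  stat <- keep & sds[, 1] < sd_threshold_mg & sds[, 2] < sd_threshold_mg &
    sds[, 3] < sd_threshold_mg
  list(means = mu[stat, , drop = FALSE], n_windows = sum(stat))
}

#' Calibrate a recording to gravity
#'
#' Estimates per-axis offset and gain from stationary windows so that
#' stationary vector magnitudes sit at 1 g (1000 mg), then applies the
#' correction. The fit iterates between projecting stationary window means
#' onto the unit sphere and regressing each axis on its raw values; an axis
#' whose stationary means show too little spread to identify a gain gets an
#' offset-only update. With fewer than `min_windows` stationary windows the
#' recording is returned unchanged with `calibrated = FALSE` so QC can record
#' the failure.
#'
#' @param rec an [accel_recording()].
#' @param sd_threshold_mg stationarity SD cut for calibration windows (mg).
#' @param window_s calibration window length (s).
#' @param min_windows minimum stationary windows required.
#' @param max_iter,tol iteration controls.
#' @return the corrected recording; attribute `"calibration"` holds offsets,
#'   gains, the stationary-magnitude error and the `calibrated` flag.
#' @export
calibrate_to_gravity <- function(rec, sd_threshold_mg = 13, window_s = 10,
                                 min_windows = 10, max_iter = 50,
                                 tol = 1e-6) {
  sw <- stationary_windows(rec, window_s, sd_threshold_mg)
  if (sw$n_windows < min_windows) {
    warning(sprintf("only %d stationary windows (< %d): returning uncalibrated",
                    sw$n_windows, min_windows))
    attr(rec, "calibration") <- list(offset = c(x = 0, y = 0, z = 0),
                                     gain = c(x = 1, y = 1, z = 1),
                                     n_stationary = sw$n_windows,
                                     calibrated = FALSE)
    return(rec)
  }
  M <- sw$means
  offset <- c(0, 0, 0)
  gain <- c(1, 1, 1)
  # gains are only identifiable when an axis takes visibly different values
  # across stationary orientations
  spread_ok <- apply(M, 2, stats::sd) > 100
  for (it in seq_len(max_iter)) {
    C <- sweep(sweep(M, 2, gain, "*"), 2, offset, "+")
    r <- sqrt(rowSums(C^2))
    target <- C * (GRAVITY_MG / r)
    new_off <- offset
    new_gain <- gain
    for (j in 1:3) {
      if (spread_ok[j]) {
        fit <- stats::lm.fit(cbind(1, M[, j]), target[, j])
        new_off[j] <- fit$coefficients[1L]
        new_gain[j] <- fit$coefficients[2L]
      } else {
        new_off[j] <- mean(target[, j] - M[, j] * gain[j])
      }
    }
    delta <- max(abs(new_off - offset)) + max(abs(new_gain - gain)) * GRAVITY_MG
    offset <- new_off
    gain <- new_gain
    if (delta < tol) break
  }
  C <- sweep(sweep(M, 2, gain, "*"), 2, offset, "+")
  err <- mean(sqrt(rowSums(C^2))) - GRAVITY_MG
  out <- rec
  out$x <- rec$x * gain[1] + offset[1]
  out$y <- rec$y * gain[2] + offset[2]
  out$z <- rec$z * gain[3] + offset[3]
  attr(out, "sample_rate_hz") <- attr(rec, "sample_rate_hz")
  attr(out, "calibration") <- list(offset = stats::setNames(offset, c("x", "y", "z")),
                                   gain = stats::setNames(gain, c("x", "y", "z")),
                                   stationary_error_mg = err,
                                   n_stationary = sw$n_windows,
                                   calibrated = abs(err) <= 5)
  class(out) <- class(rec)
  out
}

#' Aggregate a recording into 5-s ENMO epochs
#'
#' Per sample the Euclidean norm minus one gravity, truncated at zero
#' (ENMO, mg); per epoch the mean over its samples. A trailing epoch with
#' fewer samples than the full complement is dropped.
#'
#' @param rec calibrated [accel_recording()].
#' @param epoch_length_s epoch length in seconds (default 5).
#' @return data.frame of class `epoch_series` with columns `epoch_start_s`,
#'   `mean_vm_mg` and `wear` (initialised `TRUE`).
#' @export
epoch_vector_magnitude <- function(rec, epoch_length_s = 5) {
  if (nrow(rec) == 0L) stop("empty recording")
  enmo <- pmax(0, sqrt(rec$x^2 + rec$y^2 + rec$z^2) - GRAVITY_MG)
  epoch <- floor(rec$timestamp_s / epoch_length_s)
  ue <- unique(epoch)
  grp <- match(epoch, ue)
  cnt <- tabulate(grp)
  vm <- as.vector(rowsum(enmo, grp)) / cnt
  # drop incomplete trailing epoch (fewer samples than the modal complement)
  full <- max(cnt)
  k <- length(ue)
  if (k > 1L && cnt[k] < full) {
    ue <- ue[-k]; vm <- vm[-k]
  }
  out <- data.frame(epoch_start_s = ue * epoch_length_s, mean_vm_mg = vm,
                    wear = TRUE)
  attr(out, "epoch_length_s") <- epoch_length_s
  class(out) <- c("epoch_series", "data.frame")
  out
}

# per-axis SDs over sliding windows, via prefix sums on the sample grid
sliding_axis_sd <- function(v, ts, starts, window_s) {
  s1 <- c(0, cumsum(v)); s2 <- c(0, cumsum(v^2))
  lo <- findInterval(starts, ts, left.open = TRUE) + 1L       # first idx >= start
  hi <- findInterval(starts + window_s, ts, left.open = TRUE) # last idx < end
  n <- hi - lo + 1L
  sum1 <- s1[hi + 1L] - s1[lo]
  sum2 <- s2[hi + 1L] - s2[lo]
  ok <- n >= 2L
  sd <- rep(Inf, length(starts))
  sd[ok] <- sqrt(pmax(0, (sum2[ok] - sum1[ok]^2 / n[ok]) / (n[ok] - 1L)))
  sd
}

#' Detect non-wear intervals
#'
#' Slides a window of `window_min` minutes over the raw signal in
#' `window_step_min` steps; a window is stationary when all three axis SDs
#' are below `sd_threshold_mg`. Overlapping stationary windows are merged and
#' merged spans of at least `min_episode_min` minutes become non-wear
#' intervals. If an epoch series is supplied, epochs whose midpoints fall
#' inside an interval get `wear = FALSE`.
#'
#' @param rec raw or epoch-mode [accel_recording()] (SDs are computed on the
#'   per-sample axis values, not on epoch summaries).
#' @param params [nonwear_params()].
#' @param epochs optional `epoch_series` to flag.
#' @return list with `intervals` (data.frame `start_s`, `end_s`) and, when
#'   `epochs` was given, the flagged `epochs`.
#' @export
detect_nonwear <- function(rec, params = nonwear_params(), epochs = NULL) {
  window_s <- params$window_min * 60
  span <- max(rec$timestamp_s) - min(rec$timestamp_s)
  if (span < window_s) {
    warning("recording shorter than one non-wear window; no non-wear detected")
    intervals <- data.frame(start_s = numeric(0), end_s = numeric(0))
  } else {
    t0 <- min(rec$timestamp_s)
    starts <- seq(t0, t0 + span - window_s, by = params$window_step_min * 60)
    sdx <- sliding_axis_sd(rec$x, rec$timestamp_s, starts, window_s)
    sdy <- sliding_axis_sd(rec$y, rec$timestamp_s, starts, window_s)
    sdz <- sliding_axis_sd(rec$z, rec$timestamp_s, starts, window_s)
    thr <- params$sd_threshold_mg
    stat <- sdx < thr & sdy < thr & sdz < thr
    intervals <- merge_windows(starts[stat], window_s,
                               params$min_episode_min * 60)
  }
  out <- list(intervals = intervals)
  if (!is.null(epochs)) {
    len <- attr(epochs, "epoch_length_s")
    mid <- epochs$epoch_start_s + len / 2
    inside <- rep(FALSE, nrow(epochs))
    for (i in seq_len(nrow(intervals)))
      inside <- inside | (mid >= intervals$start_s[i] &
                            mid <= intervals$end_s[i])
    epochs$wear <- epochs$wear & !inside
    out$epochs <- epochs
  }
  out
}

merge_windows <- function(starts, window_s, min_span_s) {
  if (length(starts) == 0L)
    return(data.frame(start_s = numeric(0), end_s = numeric(0)))
  starts <- sort(starts)
  ends <- starts + window_s
  ivl_start <- starts[1L]
  ivl_end <- ends[1L]
  res <- list()
  for (i in seq_along(starts)[-1L]) {
    if (starts[i] <= ivl_end) {
      ivl_end <- max(ivl_end, ends[i])
    } else {
      res[[length(res) + 1L]] <- c(ivl_start, ivl_end)
      ivl_start <- starts[i]; ivl_end <- ends[i]
    }
  }
  res[[length(res) + 1L]] <- c(ivl_start, ivl_end)
  m <- do.call(rbind, res)
  keep <- (m[, 2] - m[, 1]) >= min_span_s
  data.frame(start_s = m[keep, 1], end_s = m[keep, 2])
}

#' Classify epochs by intensity
#'
#' Non-wear epochs are labelled `nonwear`; otherwise `mvpa` requires epoch
#' ENMO strictly above the 100 mg cut (an epoch at exactly 100.0 mg is not
#' MVPA), `light` covers `[light_lower_mg, mvpa_mg]`, and everything below is
#' `sedentary` — ties resolve toward the lower intensity.
#'
#' @param epochs `epoch_series` with wear flags set.
#' @param thresholds [intensity_thresholds()].
#' @return the epoch series with a `class` factor column added.
#' @export
classify_intensity <- function(epochs, thresholds = intensity_thresholds()) {
  cls <- ifelse(!epochs$wear, "nonwear",
                ifelse(epochs$mean_vm_mg > thresholds$mvpa_mg, "mvpa",
                       ifelse(epochs$mean_vm_mg >= thresholds$light_lower_mg,
                              "light", "sedentary")))
  epochs$class <- factor(cls, levels = c("sedentary", "light", "mvpa",
                                         "nonwear"))
  epochs
}

#' Summarise classified epochs into weekly activity minutes
#'
#' Wear time determines `valid_wear_days` (wear seconds / 86400); the QC gate
#' requires at least `min_days` valid days. Class minutes are counted on wear
#' epochs and either scaled to a 7-day week by `7 / valid_wear_days`
#' (`scale = "week"`, default, units min/week) or averaged per valid wear day
#' (`scale = "per_day"`, units min/day); the source convention is unstated so
#' both are exposed. A failed QC gate yields `NA` minutes.
#'
#' @param epochs classified `epoch_series`.
#' @param min_days minimum valid wear days (default 3).
#' @param scale `"week"` or `"per_day"`.
#' @return list of class `activity_summary`: `mvpa_min_week`, `lpa_min_week`,
#'   `sedentary_min_week`, `valid_wear_days`, `qc_pass`.
#' @export
summarise_week <- function(epochs, min_days = 3, scale = c("week", "per_day")) {
  scale <- match.arg(scale)
  if (is.null(epochs$class)) stop("epochs must be classified first")
  len <- attr(epochs, "epoch_length_s")
  wear_s <- sum(epochs$wear) * len
  valid_days <- wear_s / 86400
  qc <- valid_days >= min_days
  counts <- table(epochs$class[epochs$wear])
  mins <- as.numeric(counts[c("mvpa", "light", "sedentary")]) * len / 60
  if (!qc || wear_s == 0) {
    mins <- rep(NA_real_, 3)
    qc <- FALSE
  } else {
    f <- if (scale == "week") 7 / valid_days else 1 / valid_days
    mins <- mins * f
  }
  structure(list(mvpa_min_week = mins[1L], lpa_min_week = mins[2L],
                 sedentary_min_week = mins[3L], valid_wear_days = valid_days,
                 qc_pass = qc),
            class = "activity_summary")
}

#' Process a recording end to end
#'
#' Calibration, epoching, non-wear detection, classification and weekly
#' summary in one call.
#'
#' @inheritParams calibrate_to_gravity
#' @param nonwear [nonwear_params()]; `thresholds` [intensity_thresholds()].
#' @param min_days QC gate; `scale` weekly scaling rule.
#' @param calibrate set `FALSE` for signals already in calibrated units.
#' @return [summarise_week()] result with the classified epochs attached as
#'   attribute `"epochs"` and calibration QC as `"calibration"`.
#' @export
summarise_recording <- function(rec, nonwear = nonwear_params(),
                                thresholds = intensity_thresholds(),
                                min_days = 3, scale = "week",
                                calibrate = TRUE) {
  cal <- NULL
  rate <- attr(rec, "sample_rate_hz")
  # pre-aggregated epoch-mode series (< 1 Hz) are already in calibrated
  # units; sphere calibration needs raw within-window variation
  if (calibrate && !is.null(rate) && rate >= 1) {
    rec <- calibrate_to_gravity(rec)
    cal <- attr(rec, "calibration")
  }
  ep <- epoch_vector_magnitude(rec)
  nw <- detect_nonwear(rec, nonwear, epochs = ep)
  ep <- classify_intensity(nw$epochs, thresholds)
  s <- summarise_week(ep, min_days = min_days, scale = scale)
  attr(s, "epochs") <- ep
  attr(s, "calibration") <- cal
  s
}

#' Read / write recordings and epoch series as CSV
#'
#' Plain-text interchange: recordings as `timestamp_s,x_mg,y_mg,z_mg` with a
#' `# sample_rate_hz:` header line, epochs as
#' `epoch_start_s,mean_vm_mg,wear[,class]`.
#'
#' @param path file path; `rec`/`epochs` objects to write.
#' @export
write_recording_csv <- function(rec, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# sample_rate_hz: %g", attr(rec, "sample_rate_hz")), con)
  df <- data.frame(timestamp_s = rec$timestamp_s, x_mg = rec$x, y_mg = rec$y,
                   z_mg = rec$z)
  utils::write.csv(df, con, row.names = FALSE)
  invisible(path)
}

#' @rdname write_recording_csv
#' @export
read_recording_csv <- function(path) {
  hdr <- readLines(path, n = 1L)
  rate <- 100
  skip <- 0L
  if (startsWith(hdr, "#")) {
    rate <- as.numeric(sub(".*sample_rate_hz:\\s*", "", hdr))
    skip <- 1L
  }
  df <- utils::read.csv(path, skip = skip)
  accel_recording(df$timestamp_s, df$x_mg, df$y_mg, df$z_mg,
                  sample_rate_hz = rate)
}

#' @rdname write_recording_csv
#' @export
write_epochs_csv <- function(epochs, path) {
  utils::write.csv(as.data.frame(epochs), path, row.names = FALSE)
  invisible(path)
}
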