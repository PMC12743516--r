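#' @title Synthetic cohort, survival and signal generators
#' @description Generates every input the analysis pipeline needs — a
#'   clinical table with two latent comorbidity phenotypes across 31
#'   indicators, right-skewed weekly MVPA, proportional-hazards event times
#'   whose hazard depends on phenotype and on a smooth spline function of
#'   MVPA, and raw or epoch-mode tri-axial recordings with planted activity
#'   bouts and non-wear — together with the ground truth needed for recovery
#'   tests.
#' @name synthetic_data
NULL

#' The 31 phenotype indicator names
#'
#' Order matches the clustering feature matrix: six indicators derived from
#' continuous measurements (age, sex, BMI, eGFR, liver function, anaemia) and
#' 25 directly binary comorbidity/treatment flags.
#' @export
phenotype_variables <- function() {
  c("age_ge60", "female_sex", "bmi_ge25", "white_background", "alcohol_daily",
    "current_smoker", "egfr_lt90", "abnormal_liver", "cardioversion",
    "catheter_ablation", "lbbb", "lvh", "copd", "ckd", "heart_failure",
    "sleep_apnoea", "malignancy", "pad", "dementia", "stroke",
    "heart_disease", "t2d", "hypertension", "pci", "cabg", "pacemaker",
    "gi_bleeding", "rrt_transplant", "hypothyroidism", "hyperthyroidism",
    "anaemia")
}

#' Default per-variable indicator prevalences for the two latent phenotypes
#'
#' Chosen qualitatively from the published quartile tables (low-risk vs
#' high-risk cluster); order follows [phenotype_variables()].
#' @export
default_prevalence_low <- function() {
  c(age_ge60 = 0.50, female_sex = 0.34, bmi_ge25 = 0.65,
    white_background = 0.98, alcohol_daily = 0.37, current_smoker = 0.07,
    egfr_lt90 = 0.20, abnormal_liver = 0.45, cardioversion = 0.24,
    catheter_ablation = 0.20, lbbb = 0.02, lvh = 0.02, copd = 0.03,
    ckd = 0.03, heart_failure = 0.025, sleep_apnoea = 0.05,
    malignancy = 0.23, pad = 0.002, dementia = 0.006, stroke = 0.04,
    heart_disease = 0.12, t2d = 0.04, hypertension = 0.35, pci = 0.004,
    cabg = 0.006, pacemaker = 0.001, gi_bleeding = 0.04,
    rrt_transplant = 0.001, hypothyroidism = 0.04, hyperthyroidism = 0.02,
    anaemia = 0.05)
}

#' @rdname default_prevalence_low
#' @export
default_prevalence_high <- function() {
  c(age_ge60 = 0.78, female_sex = 0.39, bmi_ge25 = 0.75,
    white_background = 0.98, alcohol_daily = 0.13, current_smoker = 0.05,
    egfr_lt90 = 0.35, abnormal_liver = 0.40, cardioversion = 0.14,
    catheter_ablation = 0.09, lbbb = 0.06, lvh = 0.06, copd = 0.12,
    ckd = 0.18, heart_failure = 0.115, sleep_apnoea = 0.04,
    malignancy = 0.19, pad = 0.07, dementia = 0.025, stroke = 0.22,
    heart_disease = 0.44, t2d = 0.12, hypertension = 0.60, pci = 0.03,
    cabg = 0.10, pacemaker = 0.008, gi_bleeding = 0.07,
    rrt_transplant = 0.007, hypothyroidism = 0.14, hyperthyroidism = 0.025,
    anaemia = 0.12)
}

#' Simulation configuration
#'
#' Defaults encode the study-scale world: a cohort of 4858 with roughly 53%
#' in the high-risk phenotype, log-normal weekly MVPA with median near
#' 100 min/week, a low-risk baseline hazard giving ~7% six-year cumulative
#' incidence, a 3.81 hazard ratio for the high-risk phenotype, a protective
#' steep-then-flat MVPA dose effect, light independent dropout and
#' administrative censoring at 6 years.
#'
#' @param n_individuals cohort size (>= 8).
#' @param seed integer RNG seed.
#' @param phenotype_prevalence probability of high-risk membership.
#' @param prevalence_low,prevalence_high length-31 per-variable Bernoulli
#'   probabilities for the two phenotypes.
#' @param mvpa_log_mean,mvpa_log_sd log-normal parameters of weekly MVPA
#'   (min/week) in the low-risk phenotype.
#' @param mvpa_log_shift_high additive shift of `mvpa_log_mean` in the
#'   high-risk phenotype (negative: less active).
#' @param baseline_hazard events per person-year at the reference covariate
#'   pattern.
#' @param log_hr_cluster log hazard ratio, high- vs low-risk phenotype.
#' @param dose_effect length-2 coefficients of the true log-hazard MVPA
#'   effect on the shared spline basis ([rcs_basis()]).
#' @param dose_knots the 3 knots of that basis (min/week).
#' @param dropout_rate exponential censoring rate per year.
#' @param admin_censor_years administrative censoring horizon (6).
#' @param rhythm_control_prob probability of procedure exposure.
#' @param missing_rate per-cell missingness rate injected into the clinical
#'   table.
#' @param prob_event_on_diagnosis_day probability that an individual carries
#'   a (excludable) event dated on the AF diagnosis day.
#' @return validated list of class `simulation_config`.
#' @export
simulation_config <- function(n_individuals = 4858,
                              seed = 1L,
                              phenotype_prevalence = 0.53,
                              prevalence_low = default_prevalence_low(),
                              prevalence_high = default_prevalence_high(),
                              mvpa_log_mean = log(105),
                              mvpa_log_sd = 0.55,
                              mvpa_log_shift_high = -0.25,
                              baseline_hazard = 0.022,
                              log_hr_cluster = log(3.81),
                              dose_effect = c(-0.0155, 0.0134333),
                              dose_knots = c(25, 100, 220),
                              dropout_rate = 0.02,
                              admin_censor_years = 6,
                              rhythm_control_prob = 0.28,
                              missing_rate = 0.009,
                              prob_event_on_diagnosis_day = 0.005) {
  cfg <- list(n_individuals = as.integer(n_individuals), seed = as.integer(seed),
              phenotype_prevalence = phenotype_prevalence,
              prevalence_low = prevalence_low,
              prevalence_high = prevalence_high,
              mvpa_log_mean = mvpa_log_mean, mvpa_log_sd = mvpa_log_sd,
              mvpa_log_shift_high = mvpa_log_shift_high,
              baseline_hazard = baseline_hazard,
              log_hr_cluster = log_hr_cluster,
              dose_effect = dose_effect, dose_knots = dose_knots,
              dropout_rate = dropout_rate,
              admin_censor_years = admin_censor_years,
              rhythm_control_prob = rhythm_control_prob,
              missing_rate = missing_rate,
              prob_event_on_diagnosis_day = prob_event_on_diagnosis_day)
  validate_simulation_config(cfg)
  class(cfg) <- "simulation_config"
  cfg
}

validate_simulation_config <- function(cfg) {
  probs <- c(cfg$phenotype_prevalence, cfg$rhythm_control_prob,
             cfg$missing_rate, cfg$prob_event_on_diagnosis_day)
  if (any(probs < 0 | probs > 1)) stop("probabilities must lie in [0, 1]")
  for (nm in c("prevalence_low", "prevalence_high")) {
    p <- cfg[[nm]]
    if (length(p) != 31L)
      stop(sprintf("%s must have length 31, got %d", nm, length(p)))
    if (any(p < 0 | p > 1))
      stop(sprintf("%s entries must lie in [0, 1]", nm))
  }
  if (cfg$mvpa_log_sd <= 0) stop("mvpa_log_sd must be positive")
  if (cfg$baseline_hazard <= 0) stop("baseline_hazard must be positive")
  if (cfg$n_individuals < 8L) stop("n_individuals must be at least 8")
  if (length(cfg$dose_effect) != 2L) stop("dose_effect must have length 2")
  invisible(cfg)
}

# Gaussian parameters used to realise the continuous clinical measurements;
# only the threshold-crossing probability matters downstream, so the mean is
# back-solved by probit inversion for the configured prevalence.
continuous_spec <- function() {
  list(age = list(sd = 8, cut = 60, abnormal = "ge"),
       bmi = list(sd = 4.5, cut = 25, abnormal = "ge"),
       egfr = list(sd = 9, cut = 90, abnormal = "lt"),
       ggt = list(sd = 22, cut = 40, abnormal = "gt"),
       haematocrit = list(sd = 3.2, cut = NA, abnormal = "lt"))
}

draw_continuous <- function(n, prev, sd, cut, abnormal) {
  # mean such that P(abnormal side) = prev
  mu <- switch(abnormal,
               ge = cut - sd * stats::qnorm(1 - prev),
               gt = cut - sd * stats::qnorm(1 - prev),
               lt = cut - sd * stats::qnorm(prev))
  stats::rnorm(n, mu, sd)
}

#' Simulate a clinical cohort with latent phenotype structure
#'
#' One row per individual: continuous measurements (age, BMI, eGFR,
#' haematocrit, gamma-glutamyl transferase) drawn per phenotype so their
#' dichotomized versions hit the configured prevalences; 25 directly binary
#' flags; AF diagnosis and accelerometry dates (days since an arbitrary
#' epoch, accelerometry within 5 years after diagnosis); rhythm-control
#' exposure and date; weekly MVPA and sedentary time; accelerometer wear
#' days; survival outcome dates from [simulate_survival()]. Missingness is
#' injected at `missing_rate` into the clustering source columns (sex and
#' dates stay complete).
#'
#' @param config a [simulation_config()].
#' @return list with `clinical` (data.frame) and `truth` (data.frame:
#'   `true_label`, `true_mvpa`, `true_event_time`, `true_censor_time` in
#'   years from the accelerometry date).
#' @export
simulate_cohort <- function(config = simulation_config()) {
  validate_simulation_config(config)
  set.seed(config$seed)
  n <- config$n_individuals
  vars <- phenotype_variables()
  pl <- stats::setNames(as.numeric(config$prevalence_low), vars)
  ph <- stats::setNames(as.numeric(config$prevalence_high), vars)

  high <- stats::rbinom(n, 1L, config$phenotype_prevalence)
  prev_of <- function(v) ifelse(high == 1L, ph[[v]], pl[[v]])

  sex <- ifelse(stats::rbinom(n, 1L, prev_of("female_sex")) == 1L,
                "female", "male")
  cs <- continuous_spec()
  age <- draw_continuous(n, prev_of("age_ge60"), cs$age$sd, cs$age$cut, "ge")
  bmi <- draw_continuous(n, prev_of("bmi_ge25"), cs$bmi$sd, cs$bmi$cut, "ge")
  egfr <- draw_continuous(n, prev_of("egfr_lt90"), cs$egfr$sd, cs$egfr$cut, "lt")
  ggt <- pmax(5, draw_continuous(n, prev_of("abnormal_liver"),
                                 cs$ggt$sd, cs$ggt$cut, "gt"))
  hct_cut <- ifelse(sex == "female", 37, 40)
  p_an <- prev_of("anaemia")
  hct <- hct_cut - cs$haematocrit$sd * stats::qnorm(p_an) +
    stats::rnorm(n, 0, cs$haematocrit$sd)

  binary_vars <- setdiff(vars, c("age_ge60", "female_sex", "bmi_ge25",
                                 "egfr_lt90", "abnormal_liver", "anaemia"))
  flags <- sapply(binary_vars, function(v) stats::rbinom(n, 1L, prev_of(v)))

  mvpa <- stats::rlnorm(n, config$mvpa_log_mean +
                          config$mvpa_log_shift_high * high,
                        config$mvpa_log_sd)
  sedentary <- pmax(300, stats::rnorm(n, 1400 - 2.8 * pmin(mvpa, 300), 90))
  wear_days <- pmin(7, stats::rnorm(n, 6.85, 0.55))

  af_day <- round(stats::runif(n, 0, 5 * 365.25))
  accel_day <- af_day + round(stats::runif(n, 1, 5 * 365.25))
  rhythm_control <- as.integer(flags[, "cardioversion"] == 1L |
                                 flags[, "catheter_ablation"] == 1L)
  # exposure probability is governed by rhythm_control_prob via thinning
  p_any <- mean(rhythm_control)
  if (p_any > 0 && config$rhythm_control_prob < p_any) {
    keep <- stats::rbinom(n, 1L, config$rhythm_control_prob / p_any)
    rhythm_control <- rhythm_control * keep
  }
  procedure_day <- ifelse(rhythm_control == 1L,
                          af_day + round(stats::runif(n) *
                                           pmax(1, accel_day - af_day)),
                          NA_real_)

  clinical <- data.frame(
    id = seq_len(n), sex = sex, age = age, bmi = bmi, egfr = egfr,
    haematocrit = hct, ggt = ggt, flags,
    af_diagnosis_day = af_day, accel_day = accel_day,
    rhythm_control = rhythm_control, procedure_day = procedure_day,
    mvpa_min_week = mvpa, sedentary_min_week = sedentary,
    wear_days = wear_days, check.names = FALSE)

  surv <- simulate_survival(clinical, mvpa, config, high = high)
  clinical$first_mace_day <- ifelse(
    is.finite(surv$event_time),
    accel_day + round(surv$event_time * 365.25), NA_real_)
  clinical$dropout_day <- ifelse(
    is.finite(surv$censor_time),
    accel_day + round(surv$censor_time * 365.25), NA_real_)
  # a small fraction of individuals carry an (excludable) event dated on the
  # AF diagnosis day itself
  on_dx <- stats::rbinom(n, 1L, config$prob_event_on_diagnosis_day) == 1L
  clinical$first_mace_day[on_dx] <- clinical$af_diagnosis_day[on_dx]

  miss_cols <- c("age", "bmi", "egfr", "haematocrit", "ggt", binary_vars)
  if (config$missing_rate > 0) {
    for (cl in miss_cols) {
      gap <- stats::rbinom(n, 1L, config$missing_rate) == 1L
      clinical[[cl]][gap] <- NA
    }
  }

  truth <- data.frame(id = seq_len(n),
                      true_label = ifelse(high == 1L, "high", "low"),
                      true_mvpa = mvpa,
                      true_event_time = surv$event_time,
                      true_censor_time = surv$censor_time)
  list(clinical = clinical, truth = truth)
}

#' Simulate proportional-hazards event and censoring times
#'
#' Event times are exponential with individual rate
#' `baseline_hazard * exp(log_hr_cluster * I[high] + f(MVPA))` where `f` is
#' the configured dose effect on the shared spline basis, centred at its
#' value at 0 min/week so the baseline hazard refers to a fully inactive
#' low-risk individual. Dropout is exponential and independent;
#' administrative censoring caps follow-up at `admin_censor_years`.
#'
#' @param clinical clinical table (needs `high_risk` column or is matched via
#'   `high` argument); here the latent label is taken from the caller.
#' @param true_mvpa weekly MVPA (min/week).
#' @param config [simulation_config()].
#' @param high optional 0/1 latent phenotype vector; defaults to the labels
#'   implied by `clinical$latent_high` if present, else all zero.
#' @return data.frame `event_time`, `censor_time`, `observed_time`, `event`
#'   (times in years from index).
#' @export
simulate_survival <- function(clinical, true_mvpa, config, high = NULL) {
  if (config$baseline_hazard <= 0 || config$dropout_rate < 0)
    stop("hazard parameters must be positive")
  n <- nrow(clinical)
  if (is.null(high)) {
    high <- clinical$latent_high
    if (is.null(high)) high <- rep(0L, n)
  }
  f <- rcs_effect(true_mvpa, config$dose_effect, config$dose_knots) -
    rcs_effect(0, config$dose_effect, config$dose_knots)
  rate <- config$baseline_hazard * exp(config$log_hr_cluster * high + f)
  event_time <- stats::rexp(n, rate)
  censor_time <- if (config$dropout_rate > 0)
    stats::rexp(n, config$dropout_rate) else rep(Inf, n)
  obs <- pmin(event_time, censor_time, config$admin_censor_years)
  data.frame(event_time = event_time, censor_time = censor_time,
             observed_time = obs,
             event = as.integer(event_time <= pmin(censor_time,
                                                   config$admin_censor_years)))
}

# signal-model parameters per intensity class: deterministic ENMO level (mg)
# along the gravity axis plus per-axis Gaussian noise. Noise SDs sit above
# the 13 mg stationarity cut for worn classes and well below it for nonwear.
intensity_classes <- function() {
  # worn classes carry enough per-axis noise that a 60-min window mixing
  # even a quarter of worn signal into a non-wear stretch fails the 13 mg
  # stationarity cut, keeping detected non-wear boundaries within one
  # window step of the truth; MVPA noise stays moderate so single-epoch
  # misclassification across the 100 mg cut is negligible
  list(sedentary = list(level = 5, sd = 26),
       light     = list(level = 65, sd = 26),
       mvpa      = list(level = 150, sd = 18),
       nonwear   = list(level = 0, sd = 2))
}

#' Simulate a tri-axial recording from an activity profile
#'
#' The profile is a data.frame with columns `duration_min` and `class`
#' (sedentary / light / mvpa / nonwear). Each segment gets a gravity vector
#' of 1000 mg along a per-segment axis-aligned orientation plus a class-level
#' acceleration along that axis and per-axis Gaussian noise, so epoch ENMO
#' lands in the class's band (MVPA ~150 mg, light ~65 mg, sedentary <=20 mg)
#' and nonwear segments are stationary (<5 mg per-axis SD). `mode = "epoch"`
#' emits one sample per 5 s (a decimated signal useful for fast week-long
#' tests); `mode = "raw"` samples at `sample_rate_hz`.
#'
#' @param profile data.frame (`duration_min`, `class`).
#' @param nonwear_intervals optional data.frame (`start_min`, `end_min`)
#'   forcing stretches to the nonwear signal model.
#' @param seed RNG seed.
#' @param mode `"raw"` or `"epoch"`.
#' @param sample_rate_hz raw-mode sampling rate (default 100).
#' @param rotate_orientation when `TRUE` (default) each segment gets a fresh
#'   random axis-aligned orientation, giving calibration enough spread; an
#'   optional integer `orientation` column (1-6: +z, -z, +x, -x, +y, -y) in
#'   the profile pins orientations explicitly.
#' @return an [accel_recording()].
#' @export
simulate_recording <- function(profile, nonwear_intervals = NULL, seed = 1L,
                               mode = c("epoch", "raw"), sample_rate_hz = 100,
                               rotate_orientation = TRUE) {
  mode <- match.arg(mode)
  if (is.null(profile) || nrow(profile) == 0L) stop("empty profile")
  classes <- intensity_classes()
  if (!all(profile$class %in% names(classes)))
    stop("intensity classes must be sedentary/light/mvpa/nonwear")
  if (any(profile$duration_min <= 0)) stop("durations must be positive")
  set.seed(seed)
  dt <- if (mode == "epoch") 5 else 1 / sample_rate_hz
  rate <- if (mode == "epoch") 0.2 else sample_rate_hz

  orientations <- rbind(c(0, 0, 1), c(0, 0, -1), c(1, 0, 0),
                        c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0))
  seg_class <- character(0)
  seg_n <- integer(0)
  for (i in seq_len(nrow(profile))) {
    seg_class <- c(seg_class, profile$class[i])
    seg_n <- c(seg_n, round(profile$duration_min[i] * 60 / dt))
  }
  total <- sum(seg_n)
  ts <- (seq_len(total) - 1L) * dt
  cls <- rep(seg_class, seg_n)
  seg_id <- rep(seq_along(seg_n), seg_n)

  if (!is.null(nonwear_intervals)) {
    for (i in seq_len(nrow(nonwear_intervals))) {
      sel <- ts >= nonwear_intervals$start_min[i] * 60 &
        ts < nonwear_intervals$end_min[i] * 60
      cls[sel] <- "nonwear"
    }
  }

  xyz <- matrix(0, total, 3)
  for (s in unique(seg_id)) {
    sel <- seg_id == s
    ori <- if (!is.null(profile$orientation))
      orientations[(profile$orientation[s] - 1L) %% 6L + 1L, ]
    else if (rotate_orientation)
      orientations[sample.int(nrow(orientations), 1L), ]
    else c(0, 0, 1)
    for (cname in unique(cls[sel])) {
      ssel <- sel & cls == cname
      p <- classes[[cname]]
      m <- sum(ssel)
      base <- matrix(rep((GRAVITY_MG + p$level) * ori, each = m), m, 3)
      xyz[ssel, ] <- base + matrix(stats::rnorm(3 * m, 0, p$sd), m, 3)
    }
  }
  rec <- accel_recording(ts, xyz[, 1], xyz[, 2], xyz[, 3],
                         sample_rate_hz = rate)
  attr(rec, "planted_class") <- cls
  rec
}
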