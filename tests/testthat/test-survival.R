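test_that("quartile sizes match the published group splits", {
  q1 <- assign_quartiles(seq_len(2275))
  expect_equal(attr(q1, "sizes"), c(569L, 569L, 569L, 568L))
  q2 <- assign_quartiles(seq_len(1354))
  expect_equal(attr(q2, "sizes"), c(339L, 339L, 338L, 338L))
  expect_equal(sum(attr(q1, "sizes")), 2275L)
})

test_that("quartile assignment is rank-based, stable and validated", {
  q <- assign_quartiles(c(10, 40, 20, 30))
  expect_equal(q, c(1L, 4L, 2L, 3L), ignore_attr = TRUE)
  expect_error(assign_quartiles(c(1, 2, 3)), "at least 4")
  expect_error(assign_quartiles(c(1, 2, NA, 4)), "non-missing")
  # ties broken by stable input order
  qt <- assign_quartiles(c(5, 5, 5, 5))
  expect_equal(qt, 1:4, ignore_attr = TRUE)
  # property: sizes differ by at most 1 and sum to n, labels monotone in rank
  for (n in c(5, 11, 100, 1001)) {
    set.seed(n)
    v <- rlnorm(n)
    q <- assign_quartiles(v)
    expect_equal(sum(attr(q, "sizes")), n)
    expect_lte(diff(range(attr(q, "sizes"))), 1L)
    expect_true(all(diff(q[order(v)]) >= 0))
  }
})

policy_fixture <- function() {
  data.frame(id = 1:6,
             af_diagnosis_day = rep(0, 6),
             accel_day = rep(100, 6),
             first_mace_day = c(100 + 7 * 365.25,  # beyond the 6-year cap
                                0,                 # on AF diagnosis day
                                50,                # before index
                                500, NA, 400),
             dropout_day = c(NA, NA, NA, NA, 900, 350),
             procedure_day = rep(60, 6))
}

test_that("censoring policy caps, drops and excludes as specified", {
  recs <- build_survival_records(policy_fixture())
  excl <- attr(recs, "exclusions")
  # id 1: event 7 years post-index -> censored at 2191 days, no event
  r1 <- recs[recs$id == 1, ]
  expect_equal(r1$time, 2191)
  expect_equal(r1$event, 0L)
  # id 2: event on AF diagnosis day -> outcome dropped, individual censored
  expect_equal(excl[["event_on_diagnosis_day"]], 1L)
  expect_true(2 %in% recs$id)
  expect_equal(recs$event[recs$id == 2], 0L)
  # id 3: event before index -> individual excluded
  expect_equal(excl[["event_before_index"]], 1L)
  expect_false(3 %in% recs$id)
  # id 4: ordinary event at day 500 -> time 400 from index, event
  expect_equal(recs$time[recs$id == 4], 400)
  expect_equal(recs$event[recs$id == 4], 1L)
  # id 6: dropout (350) precedes event (400) -> censored at 250
  expect_equal(recs$time[recs$id == 6], 250)
  expect_equal(recs$event[recs$id == 6], 0L)
})

test_that("procedure-rule indexing starts follow-up at the later date", {
  df <- policy_fixture()
  df$procedure_day <- c(60, 60, 60, 200, 60, 60)
  recs <- build_survival_records(df, censoring_policy(index_rule = "procedure"))
  # index = max(procedure, accel): id 4 -> index 200, event at 500 -> 300
  expect_equal(recs$time[recs$id == 4], 300)
  df$procedure_day[1] <- NA
  expect_error(build_survival_records(
    df, censoring_policy(index_rule = "procedure")), "procedure_day")
})

test_that("records agree with a direct recomputation from ground truth", {
  cfg <- simulation_config(n_individuals = 400, seed = 21, missing_rate = 0,
                           prob_event_on_diagnosis_day = 0)
  co <- simulate_cohort(cfg)
  recs <- build_survival_records(co$clinical)
  # oracle: times in years from the accelerometry date (= index here)
  tr <- co$truth[match(recs$id, co$truth$id), ]
  oracle_time <- round(pmin(tr$true_event_time, tr$true_censor_time,
                            Inf) * 365.25)
  oracle_time <- pmin(oracle_time, 2191)
  oracle_event <- as.integer(round(tr$true_event_time * 365.25) <=
                               pmin(round(tr$true_censor_time * 365.25),
                                    2191))
  expect_equal(recs$time, oracle_time)
  expect_equal(recs$event, oracle_event)
})

test_that("Kaplan-Meier covers the degenerate cases", {
  km0 <- kaplan_meier(c(1, 2, 3), c(0, 0, 0))
  expect_true(all(km0$survival == 1))
  # all events, distinct times, no censoring: S(t) = P(time > t)
  t <- c(5, 1, 3, 2, 4)
  km <- kaplan_meier(t, rep(1, 5))
  expect_equal(km$survival, vapply(km$time, function(u) mean(t > u),
                                   numeric(1)))
  expect_false(is.unsorted(rev(km$survival)))
})

test_that("Kaplan-Meier matches a hand-worked product-limit table", {
  # records: 1 (event), 2 (censored), 3 (event), 4 (event), 5 (censored),
  # 6 (event); classic textbook layout
  time <- c(1, 2, 3, 4, 5, 6)
  event <- c(1, 0, 1, 1, 0, 1)
  km <- kaplan_meier(time, event)
  # t=1: 6 at risk, 1 event -> 5/6
  # t=3: 4 at risk -> 5/6 * 3/4 = 5/8
  # t=4: 3 at risk -> 5/8 * 2/3 = 5/12
  # t=6: 1 at risk -> 0
  expect_equal(km$survival[km$time %in% c(1, 3, 4, 6)],
               c(5 / 6, 5 / 8, 5 / 12, 0))
  expect_equal(km$survival[km$time == 2], 5 / 6)  # censoring leaves S flat
})

test_that("null two-group data give a hazard ratio near 1", {
  set.seed(500)
  n <- 20000
  g <- rbinom(n, 1, 0.5)
  t <- rexp(n, 0.1)
  cc <- pmin(rexp(n, 0.05), 6)
  f <- fit_cox(pmin(t, cc), as.integer(t <= cc), cbind(g = g))
  expect_gt(f$summary$hr, 0.9)
  expect_lt(f$summary$hr, 1.1)
})

test_that("6-record coefficient matches the brute-force likelihood oracle", {
  time <- c(2, 4, 4, 7, 9, 12)
  event <- c(1, 1, 1, 0, 1, 1)
  x <- c(0.5, -1, 0.3, 1.2, -0.7, 0.9)
  f <- fit_cox(time, event, cbind(x = x))
  oracle <- cox_oracle_coef(time, event, x)
  expect_equal(unname(f$coef), oracle, tolerance = 1e-4)
  expect_lt(f$score_max, 1e-8)
})

test_that("fit agrees with the survival package across random datasets", {
  skip_if_not_installed("survival")
  for (seed in 1:5) {
    set.seed(seed)
    n <- 400
    X <- cbind(a = rnorm(n), b = rbinom(n, 1, 0.3), c = runif(n))
    t <- ceiling(rexp(n, 0.1 * exp(0.4 * X[, 1] - 0.6 * X[, 2])) * 50)
    cc <- ceiling(pmin(rexp(n, 0.05) * 50, 300))
    time <- pmin(t, cc); ev <- as.integer(t <= cc)
    f <- fit_cox(time, ev, X)
    g <- survival::coxph(survival::Surv(time, ev) ~ X, ties = "efron")
    expect_equal(unname(f$coef), unname(coef(g)), tolerance = 1e-7)
    expect_equal(unname(f$se), unname(sqrt(diag(vcov(g)))), tolerance = 1e-7)
  }
})

test_that("Cox validation rejects unusable inputs", {
  expect_error(fit_cox(1:5, rep(0, 5), cbind(x = rnorm(5))), "no events")
  expect_error(fit_cox(1:5, c(1, 0, 1, 0, 1), cbind(x = rep(2, 5))),
               "constant covariate")
})

test_that("quartile design keeps Q1 as the implicit unit-HR reference", {
  q <- c(1L, 2L, 3L, 4L, 1L, 2L)
  X <- quartile_design(q)
  expect_equal(colnames(X), c("Q2", "Q3", "Q4"))
  # the reference individual's linear predictor is zero => HR(Q1) = 1
  expect_true(all(X[q == 1L, ] == 0))
  X2 <- quartile_design(q, covariates = cbind(age = 60:65))
  expect_equal(ncol(X2), 4L)
})

test_that("cluster HR recovery brackets the designed 3.81 contrast", {
  cfg <- separated_sim_config(20000, seed = 31,
                              log_hr_cluster = log(3.81),
                              dose_effect = c(0, 0))
  co <- simulate_cohort(cfg)
  recs <- build_survival_records(co$clinical)
  truth <- co$truth$true_label[match(recs$id, co$truth$id)]
  f <- fit_cox(recs$time, recs$event,
               cbind(high = as.numeric(truth == "high")))
  expect_gt(f$summary$hr, 3.4)
  expect_lt(f$summary$hr, 4.3)
})

test_that("confidence-interval overlap reports match the worked cases", {
  fake_fit <- function(lo, hi) {
    structure(list(summary = data.frame(term = "x", hr = (lo + hi) / 2,
                                        hr_lo = lo, hr_hi = hi)),
              class = "cox_fit")
  }
  expect_true(compare_clusters(fake_fit(0.2, 0.6),
                               fake_fit(0.2, 0.6))$overlap)
  r <- compare_clusters(fake_fit(0.2, 0.4), fake_fit(0.5, 0.9))
  expect_false(r$overlap)
  expect_equal(r$gap, 0.1)
  expect_true(compare_clusters(fake_fit(0.2, 0.6),
                               fake_fit(0.5, 0.9))$overlap)
  bad <- fake_fit(0.2, 0.6); bad$summary$term <- "y"
  expect_error(compare_clusters(fake_fit(0.2, 0.6), bad), "mismatch")
})
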