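#' @title Survival analysis: quartile exposure, Kaplan-Meier, Cox models
#' @description Builds follow-up windows under the study censoring policy,
#'   assigns within-cluster MVPA quartiles, and estimates product-limit
#'   curves and Cox proportional-hazards models (Efron tie handling, Newton
#'   iteration on the partial likelihood).
#' @name survival_module
NULL

#' Censoring policy
#'
#' @param max_followup_years administrative cap (default 6; 6 x 365.25 days,
#'   floored, i.e. 2191 days).
#' @param exclude_event_on_diagnosis_day drop events dated on the AF
#'   diagnosis day.
#' @param index_rule `"primary"` (later of AF diagnosis and accelerometry) or
#'   `"procedure"` (later of procedure date and accelerometry).
#' @export
censoring_policy <- function(max_followup_years = 6,
                             exclude_event_on_diagnosis_day = TRUE,
                             index_rule = c("primary", "procedure")) {
  if (max_followup_years <= 0) stop("max_followup_years must be positive")
  structure(list(max_followup_years = max_followup_years,
                 exclude_event_on_diagnosis_day = exclude_event_on_diagnosis_day,
                 index_rule = match.arg(index_rule)),
            class = "censoring_policy")
}

#' Assign MVPA quartiles
#'
#' Rank-based split into four groups of as-equal-as-possible size; when
#' `n %% 4 = r` the `r` lowest quartiles each take one extra individual
#' (n = 2275 gives 569/569/569/568). Ties in MVPA are broken by stable input
#' order.
#'
#' @param mvpa numeric vector of QC-passed weekly MVPA values.
#' @return integer vector of quartile labels 1-4 (1 = least active), with
#'   attribute `"sizes"`.
#' @export
assign_quartiles <- function(mvpa) {
  n <- length(mvpa)
  if (n < 4L) stop("at least 4 individuals are required")
  if (anyNA(mvpa)) stop("MVPA values must be non-missing (QC first)")
  base <- n %/% 4L
  r <- n %% 4L
  sizes <- base + as.integer(seq_len(4L) <= r)
  q <- rep.int(1:4, sizes)
  out <- integer(n)
  out[order(mvpa)] <- q   # order() is stable for ties
  attr(out, "sizes") <- sizes
  out
}

#' Build survival records under the censoring policy
#'
#' Index date is the later of AF diagnosis and accelerometry (primary) or of
#' procedure date and accelerometry (procedure rule). Follow-up is capped at
#' `floor(max_followup_years * 365.25)` days; observed time is the earliest
#' of first qualifying MACE, dropout, and the cap. Events dated on the AF
#' diagnosis day are dropped (the individual continues, censored). An
#' individual whose first event precedes the index, or whose follow-up is
#' non-positive, is excluded and counted in the exclusion log.
#'
#' @param clinical data.frame with `af_diagnosis_day`, `accel_day`,
#'   `first_mace_day`, `dropout_day`, covariates and (for the procedure rule)
#'   `procedure_day`.
#' @param policy a [censoring_policy()].
#' @return data.frame with `id`, `time` (days from index), `event` (0/1) and
#'   all clinical covariates; attribute `"exclusions"` is a named count
#'   vector.
#' @export
build_survival_records <- function(clinical, policy = censoring_policy()) {
  cap_days <- floor(policy$max_followup_years * 365.25)
  idx <- if (policy$index_rule == "procedure") {
    if (anyNA(clinical$procedure_day))
      stop("procedure_day missing for some individuals under procedure rule")
    pmax(clinical$procedure_day, clinical$accel_day)
  } else {
    pmax(clinical$af_diagnosis_day, clinical$accel_day)
  }
  ev_day <- clinical$first_mace_day
  drop_day <- clinical$dropout_day
  excl <- c(event_on_diagnosis_day = 0L, event_before_index = 0L,
            nonpositive_followup = 0L)
  if (policy$exclude_event_on_diagnosis_day) {
    on_dx <- !is.na(ev_day) & ev_day == clinical$af_diagnosis_day
    excl["event_on_diagnosis_day"] <- sum(on_dx)
    ev_day[on_dx] <- NA_real_  # outcome excluded, individual continues
  }
  before <- !is.na(ev_day) & ev_day <= idx
  excl["event_before_index"] <- sum(before)
  keep <- !before
  end_day <- pmin(ifelse(is.na(ev_day), Inf, ev_day),
                  ifelse(is.na(drop_day), Inf, drop_day),
                  idx + cap_days)
  time <- end_day - idx
  event <- as.integer(!is.na(ev_day) & ev_day == end_day & time <= cap_days)
  bad <- keep & time <= 0
  excl["nonpositive_followup"] <- sum(bad)
  keep <- keep & time > 0
  out <- clinical[keep, , drop = FALSE]
  out$index_day <- idx[keep]
  out$time <- time[keep]
  out$event <- event[keep]
  attr(out, "exclusions") <- excl
  out
}

#' Kaplan-Meier product-limit estimator
#'
#' @param time,event follow-up times and 0/1 event indicators.
#' @param group optional grouping factor; one curve per level.
#' @return data.frame with `group`, `time`, `n_risk`, `n_event`, `n_censor`,
#'   `survival` — a right-continuous, non-increasing step function starting
#'   at 1.
#' @export
kaplan_meier <- function(time, event, group = NULL) {
  if (is.null(group)) group <- rep("all", length(time))
  group <- as.factor(group)
  res <- lapply(levels(group), function(g) {
    sel <- group == g
    if (!any(sel)) stop("empty group: ", g)
    t <- time[sel]; d <- event[sel]
    ut <- sort(unique(t))
    n_risk <- vapply(ut, function(u) sum(t >= u), numeric(1))
    n_event <- vapply(ut, function(u) sum(t == u & d == 1), numeric(1))
    n_censor <- vapply(ut, function(u) sum(t == u & d == 0), numeric(1))
    surv <- cumprod(1 - n_event / n_risk)
    data.frame(group = g, time = ut, n_risk = n_risk, n_event = n_event,
               n_censor = n_censor, survival = surv)
  })
  do.call(rbind, res)
}

# Efron-adjusted partial likelihood, score and information at beta.
# X sorted by time ascending together with time/status.
cox_loglik_parts <- function(beta, time, status, X) {
  n <- nrow(X)
  p <- ncol(X)
  eta <- drop(X %*% beta)
  w <- exp(eta)
  revcum <- function(v) rev(cumsum(rev(v)))
  S0 <- revcum(w)
  S1 <- apply(X * w, 2, revcum)
  if (p == 1L) S1 <- matrix(S1, ncol = 1L)
  # pairwise product columns for S2 (p x p symmetric)
  pairs <- which(upper.tri(matrix(0, p, p), diag = TRUE), arr.ind = TRUE)
  XX <- X[, pairs[, 1], drop = FALSE] * X[, pairs[, 2], drop = FALSE]
  S2 <- apply(XX * w, 2, revcum)
  if (nrow(pairs) == 1L) S2 <- matrix(S2, ncol = 1L)

  ev_idx <- which(status == 1)
  ev_times <- time[ev_idx]
  grp_times <- unique(ev_times)
  # first sorted index belonging to each risk set {time >= t}
  k_all <- findInterval(grp_times, time, left.open = TRUE) + 1L
  d_all <- tabulate(match(ev_times, grp_times))

  ll <- 0
  score <- numeric(p)
  info <- matrix(0, p, p)
  unpack <- function(v) {
    M <- matrix(0, p, p)
    M[cbind(pairs[, 1], pairs[, 2])] <- v
    M[cbind(pairs[, 2], pairs[, 1])] <- v
    M
  }

  # untied event times: Efron coincides with Breslow, fully vectorized
  single <- d_all == 1L
  if (any(single)) {
    k <- k_all[single]
    Didx <- ev_idx[ev_times %in% grp_times[single]]
    a <- 1 / S0[k]
    ll <- ll + sum(eta[Didx]) - sum(log(S0[k]))
    S1a <- S1[k, , drop = FALSE] * a
    score <- score + colSums(X[Didx, , drop = FALSE]) - colSums(S1a)
    # sum_g [ S2_g / S0_g - (S1_g / S0_g)(S1_g / S0_g)^T ]
    info <- info + unpack(colSums(S2[k, , drop = FALSE] * a)) - crossprod(S1a)
  }

  for (gi in which(!single)) {
    t0 <- grp_times[gi]
    Didx <- ev_idx[ev_times == t0]
    d <- d_all[gi]
    k <- k_all[gi]
    s0 <- S0[k]
    s1 <- S1[k, ]
    s2 <- unpack(S2[k, ])
    wD <- w[Didx]
    s0d <- sum(wD)
    s1d <- colSums(X[Didx, , drop = FALSE] * wD)
    s2d <- unpack(colSums(XX[Didx, , drop = FALSE] * wD))
    l_frac <- (seq_len(d) - 1) / d
    phi <- s0 - l_frac * s0d
    a <- 1 / phi
    A <- sum(a); B <- sum(l_frac * a)
    A2 <- sum(a^2); C2 <- sum(l_frac * a^2); D2 <- sum(l_frac^2 * a^2)
    ll <- ll + sum(eta[Didx]) - sum(log(phi))
    score <- score + colSums(X[Didx, , drop = FALSE]) - (s1 * A - s1d * B)
    E2 <- s2 * A - s2d * B
    V <- A2 * tcrossprod(s1) -
      C2 * (tcrossprod(s1, s1d) + tcrossprod(s1d, s1)) +
      D2 * tcrossprod(s1d)
    info <- info + E2 - V
  }
  list(loglik = ll, score = score, info = info)
}

#' Fit a Cox proportional-hazards model (Efron ties, Newton iteration)
#'
#' Maximises the Efron-corrected partial likelihood by Newton-Raphson with
#' step halving, declaring convergence when every score component is below
#' `tol` in absolute value (or, at scales where summation roundoff floors
#' the score above `tol`, when the Newton increment vanishes; `score_max`
#' in the result reports the achieved score either way). Constant
#' (non-informative) covariates and datasets without events are rejected
#' rather than silently dropped.
#'
#' @param time,event follow-up times and 0/1 event indicators.
#' @param X numeric model matrix (no intercept), one column per term.
#' @param tol score convergence tolerance (default 1e-8).
#' @param max_iter maximum Newton iterations (default 100).
#' @return object of class `cox_fit`: `coef`, `se`, `vcov`, `loglik`,
#'   `score_max`, a `summary` data.frame (term, coef, HR, CI, p), `n`,
#'   `n_event`, `ties = "efron"`, `iter`.
#' @export
fit_cox <- function(time, event, X, tol = 1e-8, max_iter = 100) {
  if (!is.matrix(X)) X <- as.matrix(X)
  storage.mode(X) <- "double"
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  if (sum(event) == 0) stop("no events: Cox model cannot be fitted")
  cst <- apply(X, 2, function(v) diff(range(v)) == 0)
  if (any(cst))
    stop("constant covariate(s): ", paste(colnames(X)[cst], collapse = ", "))
  ord <- order(time)
  time <- time[ord]; status <- event[ord]; Xs <- X[ord, , drop = FALSE]
  p <- ncol(Xs)
  # centre and scale internally for conditioning; estimates are mapped back
  ctr <- colMeans(Xs)
  scl <- apply(Xs, 2, stats::sd)
  Xs <- sweep(sweep(Xs, 2, ctr), 2, scl, "/")
  beta <- numeric(p)
  parts <- cox_loglik_parts(beta, time, status, Xs)
  for (it in seq_len(max_iter)) {
    if (max(abs(parts$score)) < tol) break
    step <- tryCatch(solve(parts$info, parts$score),
                     error = function(e) stop("singular information matrix"))
    halve <- 0
    repeat {
      cand <- beta + step
      cand_parts <- cox_loglik_parts(cand, time, status, Xs)
      if (is.finite(cand_parts$loglik) &&
          (cand_parts$loglik >= parts$loglik - 1e-12)) break
      step <- step / 2
      halve <- halve + 1
      if (halve > 30) stop("Cox Newton iteration diverged (step halving failed)")
    }
    beta <- cand
    parts <- cand_parts
    # at large n the score cannot be driven below the summation roundoff
    # floor; a vanishing Newton increment is accepted as converged
    if (max(abs(step)) < 1e-10) break
    if (it == max_iter && max(abs(parts$score)) >= tol)
      stop("Cox model failed to converge in ", max_iter, " iterations; ",
           "max score component = ", format(max(abs(parts$score))))
  }
  vcov <- solve(parts$info)
  beta <- beta / scl
  vcov <- vcov / tcrossprod(scl)
  se <- sqrt(diag(vcov))
  z <- beta / se
  summ <- data.frame(term = colnames(Xs), coef = beta, se = se,
                     hr = exp(beta),
                     hr_lo = exp(beta - 1.96 * se),
                     hr_hi = exp(beta + 1.96 * se),
                     p = 2 * stats::pnorm(-abs(z)))
  structure(list(coef = stats::setNames(beta, colnames(Xs)), se = se,
                 vcov = vcov, loglik = parts$loglik,
                 score_max = max(abs(parts$score)), summary = summ,
                 n = length(time), n_event = sum(status), ties = "efron",
                 iter = it),
            class = "cox_fit")
}

#' @export
print.cox_fit <- function(x, ...) {
  cat(sprintf("Cox proportional-hazards fit (Efron ties), n = %d, events = %d\n",
              x$n, x$n_event))
  print(x$summary, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Quartile-exposure design matrix
#'
#' Indicator columns for quartiles 2-4 (quartile 1 is the reference, so its
#' hazard ratio is identically 1), optionally followed by adjustment
#' covariates.
#'
#' @param quartile integer vector 1-4.
#' @param covariates optional data.frame/matrix of adjustment terms.
#' @export
quartile_design <- function(quartile, covariates = NULL) {
  Q <- sapply(2:4, function(q) as.numeric(quartile == q))
  colnames(Q) <- paste0("Q", 2:4)
  if (!is.null(covariates)) Q <- cbind(Q, as.matrix(covariates))
  Q
}

#' Adjustment covariate sets
#'
#' `"core"` is the model description in the statistical-methods text (age,
#' sex, sedentary time, HF, heart disease, T2D, BMI, smoking, hypertension);
#' `"extended"` additionally carries ethnicity and alcohol use, the variant
#' named in the figure captions.
#'
#' @param clinical record table with the covariate columns.
#' @param set `"core"` or `"extended"`.
#' @return numeric matrix of adjustment covariates.
#' @export
adjustment_covariates <- function(clinical, set = c("core", "extended")) {
  set <- match.arg(set)
  out <- cbind(age = clinical$age,
               female_sex = as.numeric(clinical$sex == "female"),
               sedentary = clinical$sedentary_min_week,
               heart_failure = clinical$heart_failure,
               heart_disease = clinical$heart_disease,
               t2d = clinical$t2d,
               bmi = clinical$bmi,
               current_smoker = clinical$current_smoker,
               hypertension = clinical$hypertension)
  if (set == "extended")
    out <- cbind(out, white_background = clinical$white_background,
                 alcohol_daily = clinical$alcohol_daily)
  out
}

#' Compare 95% confidence intervals of two fits term by term
#'
#' @param fit_a,fit_b `cox_fit` objects with matching terms.
#' @return data.frame `term`, `overlap` (logical), `gap` (distance between
#'   the intervals when disjoint, 0 otherwise).
#' @export
compare_clusters <- function(fit_a, fit_b) {
  if (!identical(fit_a$summary$term, fit_b$summary$term))
    stop("fits have mismatching terms")
  lo_a <- fit_a$summary$hr_lo; hi_a <- fit_a$summary$hr_hi
  lo_b <- fit_b$summary$hr_lo; hi_b <- fit_b$summary$hr_hi
  overlap <- !(lo_a > hi_b | lo_b > hi_a)
  gap <- pmax(0, pmax(lo_a - hi_b, lo_b - hi_a))
  data.frame(term = fit_a$summary$term, overlap = overlap, gap = gap)
}
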