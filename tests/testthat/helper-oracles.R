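# Independent oracle implementations used by unit and acceptance tests.
# These deliberately avoid the package's own code paths: naive O(n^3)
# agglomeration recomputing SSE from scratch, a hand-written Efron partial
# likelihood maximised by grid/golden-section search, and brute-force loops
# over curve grids.

# --- Ward agglomeration, recomputed from raw points at every step ----------
ward_oracle <- function(m) {
  n <- nrow(m)
  sse <- function(rows) {
    if (length(rows) == 1L) return(0)
    sub <- m[rows, , drop = FALSE]
    sum(sweep(sub, 2, colMeans(sub))^2)
  }
  clusters <- lapply(seq_len(n), identity)   # member rows
  ids <- seq_len(n)                          # creation-order ids
  refs <- -seq_len(n)                        # hclust-style merge references
  merge <- matrix(0L, n - 1L, 2L)
  height <- numeric(n - 1L)
  for (step in seq_len(n - 1L)) {
    k <- length(clusters)
    best <- NULL
    for (i in seq_len(k - 1L)) {
      for (j in (i + 1L):k) {
        d <- sse(c(clusters[[i]], clusters[[j]])) -
          sse(clusters[[i]]) - sse(clusters[[j]])
        id_pair <- sort(c(ids[i], ids[j]))
        cand <- list(d = d, i = i, j = j, id = id_pair)
        if (is.null(best) || d < best$d - 1e-12 ||
            (abs(d - best$d) <= 1e-12 &&
             (id_pair[1] < best$id[1] ||
              (id_pair[1] == best$id[1] && id_pair[2] < best$id[2]))))
          best <- cand
      }
    }
    height[step] <- best$d
    merge[step, ] <- sort(c(refs[best$i], refs[best$j]))
    clusters[[best$i]] <- c(clusters[[best$i]], clusters[[best$j]])
    ids[best$i] <- n + step
    refs[best$i] <- step
    clusters[[best$j]] <- NULL
    ids <- ids[-best$j]
    refs <- refs[-best$j]
  }
  list(merge = merge, height = height)
}

# --- Efron partial log-likelihood written out directly ---------------------
efron_loglik_manual <- function(beta, time, status, x) {
  eta <- x * beta
  w <- exp(eta)
  ll <- 0
  for (t0 in sort(unique(time[status == 1]))) {
    D <- which(time == t0 & status == 1)
    R <- which(time >= t0)
    d <- length(D)
    for (l in seq_len(d) - 1L) {
      ll <- ll - log(sum(w[R]) - (l / d) * sum(w[D]))
    }
    ll <- ll + sum(eta[D])
  }
  ll
}

# maximise over a bracket by golden-section search
cox_oracle_coef <- function(time, status, x, lower = -5, upper = 5,
                            tol = 1e-9) {
  stats::optimize(function(b) efron_loglik_manual(b, time, status, x),
                  c(lower, upper), maximum = TRUE, tol = tol)$maximum
}

# --- Poisson log-likelihood Newton, written from the formula ---------------
poisson_newton_oracle <- function(y, X, offset, max_iter = 200) {
  beta <- rep(0, ncol(X))
  beta[1] <- log(sum(y) / sum(exp(offset)))
  for (i in seq_len(max_iter)) {
    mu <- exp(drop(X %*% beta) + offset)
    grad <- drop(crossprod(X, y - mu))
    hess <- crossprod(X * mu, X)
    step <- solve(hess, grad)
    beta <- beta + step
    if (max(abs(grad)) < 1e-10) break
  }
  beta
}

# --- exhaustive threshold scan --------------------------------------------
threshold_scan_oracle <- function(fit, spec, rule, reference_dose) {
  grid <- seq(spec$dose_range[1], spec$dose_range[2], by = spec$grid_step)
  minimal <- NA_real_
  for (d in grid) {
    if (d <= reference_dose) next
    cc <- afmvpa:::irr_contrast(fit, d, reference_dose, rule$alpha)
    if (cc$lo > 1 || cc$hi < 1) { minimal <- d; break }
  }
  optimal <- NA_real_
  for (d in grid) {
    if (d < reference_dose + rule$comparison_step) next
    cc <- afmvpa:::irr_contrast(fit, d, d - rule$comparison_step, rule$alpha)
    if (cc$lo <= 1 && cc$hi >= 1) { optimal <- d; break }
  }
  list(minimal = minimal, optimal = optimal)
}

# --- fixture builders ------------------------------------------------------
# a 7-day epoch-mode profile carrying a given number of MVPA minutes
week_profile <- function(mvpa_min, nonwear_min = 0) {
  rest <- 7 * 1440 - mvpa_min - nonwear_min
  segs <- data.frame(duration_min = c(rest / 2, mvpa_min, rest / 2),
                     class = c("sedentary", "mvpa", "sedentary"))
  if (nonwear_min > 0)
    segs <- rbind(segs,
                  data.frame(duration_min = nonwear_min, class = "nonwear"))
  segs
}

# separated two-phenotype world used by clustering recovery tests: ten
# informative indicators at prevalence 0.05 vs 0.60; every other variable
# carries the same realistic prevalence in both groups so the phenotype
# signal lives only in the informative ten (and model covariates such as
# hypertension stay well populated)
separated_sim_config <- function(n, seed, ...) {
  pl <- default_prevalence_low()
  ph <- pl
  informative <- c("copd", "ckd", "heart_failure", "stroke", "heart_disease",
                   "t2d", "pad", "gi_bleeding", "hypothyroidism", "cabg")
  pl[informative] <- 0.05
  ph[informative] <- 0.60
  simulation_config(n_individuals = n, seed = seed, prevalence_low = pl,
                    prevalence_high = ph, missing_rate = 0, ...)
}
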