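#' @title Study pipeline: cluster, stratify, fit, report
#' @description Orchestrates the full design: activity QC, dichotomization
#'   and imputation, two-cluster Ward phenotyping, within-cluster MVPA
#'   quartile survival models, the cluster-contrast Cox model, the pooled
#'   Poisson spline dose-response with threshold extraction, characteristics
#'   tables and a flow log of every exclusion.
#' @name pipeline
NULL

#' Run configuration
#'
#' @param sim a [simulation_config()] used when no clinical table is
#'   supplied.
#' @param policy a [censoring_policy()].
#' @param rules a [dichotomization_rules()].
#' @param spec a [spline_spec()]; `threshold` a [threshold_rule()].
#' @param adjustment `"core"` or `"extended"` covariate set.
#' @param subgroup `"primary"`, `"rhythm_control"` (procedure-indexed
#'   subgroup) or `"sensitivity_no_procedure"`.
#' @param k number of phenotype clusters (2).
#' @param min_wear_days activity QC gate.
#' @param seed RNG seed for the synthetic cohort.
#' @export
run_config <- function(sim = simulation_config(), policy = censoring_policy(),
                       rules = dichotomization_rules(), spec = spline_spec(),
                       threshold = threshold_rule(),
                       adjustment = c("core", "extended"),
                       subgroup = c("primary", "rhythm_control",
                                    "sensitivity_no_procedure"),
                       k = 2L, min_wear_days = 3, seed = NULL) {
  if (!is.null(seed)) sim$seed <- as.integer(seed)
  structure(list(sim = sim, policy = policy, rules = rules, spec = spec,
                 threshold = threshold, adjustment = match.arg(adjustment),
                 subgroup = match.arg(subgroup), k = as.integer(k),
                 min_wear_days = min_wear_days),
            class = "run_config")
}

cox_quartile_fits <- function(records, adjustment) {
  q <- assign_quartiles(records$mvpa_min_week)
  records$quartile <- q
  unadj <- fit_cox(records$time, records$event, quartile_design(q))
  adj <- fit_cox(records$time, records$event,
                 quartile_design(q, adjustment_covariates(records, adjustment)))
  km <- kaplan_meier(records$time, records$event, group = q)
  list(quartile = q, sizes = attr(q, "sizes"), unadjusted = unadj,
       adjusted = adj, km = km,
       mvpa_median = tapply(records$mvpa_min_week, q, stats::median))
}

#' Run the full study on a clinical table (or a fresh synthetic cohort)
#'
#' Stages: activity QC (wear-day gate) -> dichotomize -> impute -> Ward
#' cluster (k = 2) -> survival-record construction under the censoring
#' policy -> per-cluster quartile Kaplan-Meier and Cox models (unadjusted
#' and adjusted) -> cluster-contrast Cox -> pooled Poisson spline
#' dose-response with threshold extraction -> characteristics tables and
#' flow log. Deterministic given the configuration (and its seed, when the
#' cohort is simulated).
#'
#' @param config a [run_config()].
#' @param clinical optional clinical table; when `NULL` a synthetic cohort
#'   is generated from `config$sim`.
#' @return list of class `study_report`.
#' @export
run_study <- function(config = run_config(), clinical = NULL) {
  truth <- NULL
  if (is.null(clinical)) {
    cohort <- simulate_cohort(config$sim)
    clinical <- cohort$clinical
    truth <- cohort$truth
  }
  n_input <- nrow(clinical)
  flow <- c(input = n_input)

  # activity QC
  qc_fail <- is.na(clinical$wear_days) | clinical$wear_days < config$min_wear_days
  flow["qc_fail"] <- sum(qc_fail)
  clinical <- clinical[!qc_fail, , drop = FALSE]

  # model covariates must be complete (clustering variables are imputed,
  # model covariates are not)
  cov_cols <- c("age", "bmi", "sedentary_min_week", "heart_failure",
                "heart_disease", "t2d", "current_smoker", "hypertension")
  if (config$adjustment == "extended")
    cov_cols <- c(cov_cols, "white_background", "alcohol_daily")
  incomplete <- rowSums(is.na(clinical[, cov_cols, drop = FALSE])) > 0
  flow["missing_covariates"] <- sum(incomplete)
  clinical <- clinical[!incomplete, , drop = FALSE]

  # subgroup restriction
  if (config$subgroup == "rhythm_control") {
    drop_n <- sum(clinical$rhythm_control != 1L)
    clinical <- clinical[clinical$rhythm_control == 1L, , drop = FALSE]
    flow["not_in_subgroup"] <- drop_n
    policy <- censoring_policy(config$policy$max_followup_years,
                               config$policy$exclude_event_on_diagnosis_day,
                               index_rule = "procedure")
  } else {
    policy <- config$policy
    if (config$subgroup == "sensitivity_no_procedure") {
      drop_n <- sum(clinical$rhythm_control == 1L)
      clinical <- clinical[clinical$rhythm_control != 1L, , drop = FALSE]
      flow["not_in_subgroup"] <- drop_n
    }
  }

  # phenotype matrix: individuals with un-imputable rows are kept (mode
  # imputation never drops rows); column checks happen inside
  pheno_raw <- dichotomize(clinical, config$rules)
  pheno <- impute_missing(pheno_raw)
  flow["imputed_cells"] <- attr(pheno, "n_imputed")

  tree <- ward_linkage(pheno)
  labels <- cut_clusters(tree, config$k, m = pheno)
  risk <- attr(labels, "risk")
  if (is.null(risk)) risk <- as.character(labels)
  clinical$cluster <- risk

  records <- build_survival_records(clinical, policy)
  excl <- attr(records, "exclusions")
  flow["event_on_diagnosis_day"] <- excl["event_on_diagnosis_day"]
  flow["event_before_index"] <- excl["event_before_index"]
  flow["nonpositive_followup"] <- excl["nonpositive_followup"]
  flow["analysed"] <- nrow(records)

  per_cluster <- lapply(split(records, records$cluster), function(rc)
    cox_quartile_fits(rc, config$adjustment))

  contrast <- NULL
  if (length(unique(records$cluster)) == 2L) {
    Xc <- cbind(high_risk = as.numeric(records$cluster == "high"))
    contrast <- fit_cox(records$time, records$event, Xc)
  }

  # pooled dose-response: per-individual first-event count with person-time
  # offset, doses truncated to the curve range
  doses <- pmin(records$mvpa_min_week, config$spec$dose_range[2])
  pt <- records$time / 365.25
  dr_fit <- fit_poisson_rcs(records$event, doses, person_time = pt,
                            spec = config$spec)
  linearity <- wald_linearity_test(dr_fit)
  curve <- irr_curve(dr_fit, spec = config$spec)
  thresholds <- find_thresholds(dr_fit, config$threshold, config$spec)

  tables <- lapply(split(records, records$cluster), function(rc) {
    q <- assign_quartiles(rc$mvpa_min_week)
    characteristics_table(rc, q)
  })

  structure(list(config = config, flow = flow,
                 cluster_sizes = table(records$cluster),
                 per_cluster = per_cluster, contrast = contrast,
                 dose_response = dr_fit, linearity = linearity,
                 irr_curve = curve, thresholds = thresholds,
                 tables = tables, records = records, truth = truth),
            class = "study_report")
}

#' @export
print.study_report <- function(x, ...) {
  cat("Study report\n============\n")
  cat("Flow log:\n")
  print(x$flow)
  cat("\nCluster sizes:\n")
  print(x$cluster_sizes)
  if (!is.null(x$contrast)) {
    s <- x$contrast$summary
    cat(sprintf("\nCluster contrast (high vs low risk): HR %.2f (95%% CI %.2f-%.2f, p %s)\n",
                s$hr, s$hr_lo, s$hr_hi, format.pval(s$p, digits = 3)))
  }
  for (cl in names(x$per_cluster)) {
    cat(sprintf("\n'%s risk' cluster, adjusted quartile HRs (Q1 reference):\n", cl))
    print(x$per_cluster[[cl]]$adjusted$summary[1:3, ], row.names = FALSE,
          digits = 3)
  }
  cat(sprintf("\nLinearity Wald test: chi2(1) = %.2f, p = %s\n",
              x$linearity$statistic, format.pval(x$linearity$p_value, 3)))
  print(x$thresholds)
  invisible(x)
}

#' Characteristics table with group-comparison tests
#'
#' Continuous rows: per-group `median [IQR]` plus a one-way ANOVA p-value;
#' binary rows: `n (%)` plus a chi-square p-value (the published tables use
#' only t/ANOVA language, which cannot apply to count rows — chi-square is a
#' documented deviation). When the overall test is significant at 0.05,
#' pairwise Welch t-tests flag which groups differ from which. Constant
#' columns get `NA` p-values.
#'
#' @param data record table; `group` grouping vector (>= 2 levels).
#' @param continuous,binary character vectors of column names; sensible
#'   defaults are picked from the standard record layout.
#' @return data.frame with one row per variable: formatted per-group cells,
#'   `p_value`, and `pairwise` flags (comma-separated `i>j` pairs).
#' @export
characteristics_table <- function(data, group,
                                  continuous = intersect(
                                    c("age", "bmi", "egfr", "haematocrit",
                                      "ggt", "mvpa_min_week",
                                      "sedentary_min_week"), names(data)),
                                  binary = intersect(
                                    c("event", phenotype_variables()),
                                    names(data))) {
  group <- as.factor(group)
  if (nlevels(group) < 2L) stop("at least 2 groups are required")
  levs <- levels(group)
  rows <- list()
  fmt_row <- function(var, cells, p, pw) {
    df <- as.data.frame(as.list(stats::setNames(cells, paste0("group_", levs))))
    df$variable <- var; df$p_value <- p; df$pairwise <- pw
    df[, c("variable", paste0("group_", levs), "p_value", "pairwise")]
  }
  pairwise_flags <- function(x, g) {
    combs <- utils::combn(levs, 2)
    hits <- character(0)
    for (c_i in seq_len(ncol(combs))) {
      a <- x[g == combs[1, c_i]]; b <- x[g == combs[2, c_i]]
      if (!isTRUE(stats::sd(c(a, b), na.rm = TRUE) > 0)) next
      p <- tryCatch(stats::t.test(a, b)$p.value, error = function(e) NA)
      if (!is.na(p) && p < 0.05)
        hits <- c(hits, paste0(combs[1, c_i], ">", combs[2, c_i]))
    }
    paste(hits, collapse = ",")
  }
  for (v in continuous) {
    x <- data[[v]]
    cells <- vapply(levs, function(l) {
      q <- stats::quantile(x[group == l], c(0.5, 0.25, 0.75), na.rm = TRUE)
      sprintf("%.1f [%.1f, %.1f]", q[1], q[2], q[3])
    }, character(1))
    p <- if (!isTRUE(stats::sd(x, na.rm = TRUE) > 0)) NA_real_ else
      tryCatch(summary(stats::aov(x ~ group))[[1]][["Pr(>F)"]][1],
               error = function(e) NA_real_)
    pw <- if (!is.na(p) && p < 0.05) pairwise_flags(x, group) else ""
    rows[[v]] <- fmt_row(v, cells, p, pw)
  }
  for (v in binary) {
    x <- data[[v]]
    cells <- vapply(levs, function(l) {
      xs <- x[group == l]
      sprintf("%d (%d)", sum(xs == 1, na.rm = TRUE),
              percentage_summary(sum(xs == 1, na.rm = TRUE),
                                 max(1L, sum(!is.na(xs)))))
    }, character(1))
    p <- if (length(unique(stats::na.omit(x))) < 2L) NA_real_ else
      tryCatch(suppressWarnings(
        stats::chisq.test(table(group, x))$p.value), error = function(e) NA_real_)
    rows[[v]] <- fmt_row(v, cells, p, "")
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Integer percentage, half rounded away from zero
#'
#' `round()` in R rounds half to even; published tables round half away from
#' zero, so 0.5% prints as 1%.
#'
#' @param count numerator; `denominator` must be positive.
#' @return integer percent.
#' @export
#' @examples
#' percentage_summary(156, 2275)  # 7
#' percentage_summary(608, 2583)  # 24
percentage_summary <- function(count, denominator) {
  if (any(denominator <= 0)) stop("denominator must be positive")
  x <- 100 * count / denominator
  as.integer(sign(x) * floor(abs(x) + 0.5))
}

#' Serialize a study report to JSON
#'
#' Writes coefficients, hazard-ratio tables, the IRR curve, thresholds and
#' the flow log; full numeric precision is kept (rendered tables round, the
#' JSON does not).
#'
#' @param report a `study_report`; `path` output file.
#' @export
write_report_json <- function(report, path) {
  cox_obj <- function(f) list(coef = as.list(f$coef), se = f$se,
                              summary = f$summary, n = f$n,
                              n_event = f$n_event)
  obj <- list(
    flow = as.list(report$flow),
    cluster_sizes = as.list(report$cluster_sizes),
    contrast = if (!is.null(report$contrast)) cox_obj(report$contrast),
    per_cluster = lapply(report$per_cluster, function(pc)
      list(sizes = pc$sizes, mvpa_median = as.list(pc$mvpa_median),
           unadjusted = cox_obj(pc$unadjusted),
           adjusted = cox_obj(pc$adjusted))),
    linearity = report$linearity,
    thresholds = unclass(report$thresholds),
    irr_curve = as.data.frame(report$irr_curve))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
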