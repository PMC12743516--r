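#' @title Phenotyping: dichotomization, imputation, Ward clustering
#' @description Turns the clinical table into the 31-column binary phenotype
#'   matrix, imputes gaps by column mode, and builds the two-cluster risk
#'   phenotype by Ward minimum-variance agglomeration on squared Euclidean
#'   distances.
#' @name phenotyping
NULL

#' Clinical dichotomization cut-points
#'
#' Boundary conventions follow the normal/abnormal phrasing of usual
#' clinical practice: age 60 and BMI 25 fall on the abnormal side
#' (>= cut is 1), eGFR 90 is normal (< 90 is abnormal), GGT 40 is normal
#' (<= 40 U/L normal), haematocrit exactly at the sex-specific cut is not
#' anaemic.
#'
#' @param age_cut,bmi_cut,egfr_cut,ggt_cut numeric cut-points.
#' @param haematocrit_cut_female,haematocrit_cut_male anaemia thresholds (%).
#' @export
dichotomization_rules <- function(age_cut = 60, bmi_cut = 25, egfr_cut = 90,
                                  haematocrit_cut_female = 37,
                                  haematocrit_cut_male = 40, ggt_cut = 40) {
  r <- list(age_cut = age_cut, bmi_cut = bmi_cut, egfr_cut = egfr_cut,
            haematocrit_cut_female = haematocrit_cut_female,
            haematocrit_cut_male = haematocrit_cut_male, ggt_cut = ggt_cut)
  if (any(unlist(r) <= 0)) stop("all cut-points must be positive")
  structure(r, class = "dichotomization_rules")
}

#' Dichotomize the clinical table into the 31-column phenotype matrix
#'
#' Missing entries are preserved (imputation is a separate step). An
#' individual with haematocrit present but unknown sex gets a missing
#' anaemia entry, since the cut is sex-specific.
#'
#' @param clinical data.frame with the continuous measurements, `sex`, and
#'   the 25 binary flags named as in [phenotype_variables()].
#' @param rules a [dichotomization_rules()].
#' @return numeric matrix (n x 31, entries 0/1/NA), columns in
#'   [phenotype_variables()] order, with `id` rownames when available.
#' @export
dichotomize <- function(clinical, rules = dichotomization_rules()) {
  vars <- phenotype_variables()
  binary_vars <- setdiff(vars, c("age_ge60", "female_sex", "bmi_ge25",
                                 "egfr_lt90", "abnormal_liver", "anaemia"))
  need <- c("sex", "age", "bmi", "egfr", "haematocrit", "ggt", binary_vars)
  missing_cols <- setdiff(need, names(clinical))
  if (length(missing_cols))
    stop("clinical table lacks columns: ", paste(missing_cols, collapse = ", "))
  n <- nrow(clinical)
  m <- matrix(NA_real_, n, 31, dimnames = list(clinical$id, vars))
  m[, "age_ge60"] <- as.numeric(clinical$age >= rules$age_cut)
  m[, "female_sex"] <- as.numeric(clinical$sex == "female")
  m[, "bmi_ge25"] <- as.numeric(clinical$bmi >= rules$bmi_cut)
  m[, "egfr_lt90"] <- as.numeric(clinical$egfr < rules$egfr_cut)
  m[, "abnormal_liver"] <- as.numeric(clinical$ggt > rules$ggt_cut)
  hct_cut <- ifelse(clinical$sex == "female", rules$haematocrit_cut_female,
                    ifelse(clinical$sex == "male",
                           rules$haematocrit_cut_male, NA_real_))
  m[, "anaemia"] <- as.numeric(clinical$haematocrit < hct_cut)
  for (v in binary_vars) {
    col <- clinical[[v]]
    if (!all(col %in% c(0, 1, NA)))
      stop(sprintf("column '%s' is not binary", v))
    m[, v] <- as.numeric(col)
  }
  m
}

#' Impute missing phenotype entries by column mode
#'
#' Each missing cell is replaced by its column's most frequent value among
#' observed entries; exact ties go to 0. Refuses columns that are entirely
#' missing (naming them) or more than half missing.
#'
#' @param m phenotype matrix with possible `NA` entries.
#' @return completed matrix; attribute `"n_imputed"` counts replaced cells.
#' @export
impute_missing <- function(m) {
  frac_na <- colMeans(is.na(m))
  if (any(frac_na == 1))
    stop("column(s) entirely missing: ",
         paste(colnames(m)[frac_na == 1], collapse = ", "))
  if (any(frac_na > 0.5))
    stop("column(s) with > 50% missingness: ",
         paste(colnames(m)[frac_na > 0.5], collapse = ", "))
  n_imp <- 0L
  for (j in seq_len(ncol(m))) {
    na <- is.na(m[, j])
    if (any(na)) {
      mode_val <- if (mean(m[!na, j]) > 0.5) 1 else 0  # tie -> 0
      m[na, j] <- mode_val
      n_imp <- n_imp + sum(na)
    }
  }
  attr(m, "n_imputed") <- n_imp
  m
}

#' Ward minimum-variance agglomeration on squared Euclidean distances
#'
#' Starts from singletons and at each step merges the pair of clusters whose
#' fusion minimally increases the within-cluster sum of squares
#' (\eqn{\Delta SSE = n_i n_j / (n_i + n_j) \, \lVert c_i - c_j \rVert^2}),
#' maintained by the Lance–Williams update. Exact ties are broken toward the
#' lexicographically lowest pair of cluster indices, where clusters are
#' indexed by creation order (leaves `1..n`, then `n+1, ...` per merge), so
#' the tree is fully deterministic.
#'
#' @param m numeric matrix with binary (0/1) entries, one row per
#'   individual.
#' @return object of class `ward_linkage`: `merge` ((n-1) x 2, `hclust`
#'   convention: negative entries are leaves), `height` (the SSE increase of
#'   each merge), `size` (merged cluster sizes), `n`.
#' @export
ward_linkage <- function(m) {
  if (!is.matrix(m)) m <- as.matrix(m)
  n <- nrow(m)
  if (n < 2L) stop("at least 2 rows are required")
  if (anyNA(m) || !all(m %in% c(0, 1)))
    stop("matrix entries must be binary 0/1 (impute first)")
  # D[i, j] = current Ward merge cost between active clusters i and j,
  # i.e. the SSE increase; for singletons ||x_i - x_j||^2 / 2
  sq <- rowSums(m^2)
  D <- outer(sq, sq, "+") - 2 * tcrossprod(m)
  D <- pmax(D, 0) / 2
  diag(D) <- Inf
  size <- rep(1, n)
  cl_id <- seq_len(n)            # creation-order id of each active slot
  merge_ref <- -seq_len(n)       # hclust-style reference for each slot
  active <- rep(TRUE, n)
  merge <- matrix(0L, n - 1L, 2L)
  height <- numeric(n - 1L)
  sizes <- numeric(n - 1L)
  for (step in seq_len(n - 1L)) {
    dmin <- min(D)
    cand <- which(D == dmin, arr.ind = TRUE)
    cand <- cand[cand[, 1] < cand[, 2], , drop = FALSE]
    # lexicographically lowest pair of creation-order ids
    ids <- cbind(pmin(cl_id[cand[, 1]], cl_id[cand[, 2]]),
                 pmax(cl_id[cand[, 1]], cl_id[cand[, 2]]))
    pick <- order(ids[, 1], ids[, 2])[1L]
    i <- cand[pick, 1L]; j <- cand[pick, 2L]
    if (cl_id[i] > cl_id[j]) { tmp <- i; i <- j; j <- tmp }
    height[step] <- dmin
    merge[step, ] <- sort(c(merge_ref[i], merge_ref[j]))
    ni <- size[i]; nj <- size[j]
    sizes[step] <- ni + nj
    # Lance-Williams Ward update against every other active cluster k
    others <- which(active); others <- others[others != i & others != j]
    if (length(others)) {
      nk <- size[others]
      dnew <- ((ni + nk) * D[i, others] + (nj + nk) * D[j, others] -
                 nk * dmin) / (ni + nj + nk)
      D[i, others] <- dnew
      D[others, i] <- dnew
    }
    active[j] <- FALSE
    D[j, ] <- Inf
    D[, j] <- Inf
    size[i] <- ni + nj
    cl_id[i] <- n + step
    merge_ref[i] <- step
  }
  structure(list(merge = merge, height = height, size = sizes, n = n),
            class = "ward_linkage")
}

#' @export
as.hclust.ward_linkage <- function(x, ...) {
  # order leaves by recursive traversal for plotting
  ord <- integer(0)
  walk <- function(k) {
    for (v in x$merge[k, ]) {
      if (v < 0) ord <<- c(ord, -v) else walk(v)
    }
  }
  walk(x$n - 1L)
  structure(list(merge = x$merge, height = x$height, order = ord,
                 labels = NULL, method = "ward", call = match.call(),
                 dist.method = "squared euclidean"),
            class = "hclust")
}

#' Cut a Ward tree into k clusters
#'
#' Removes the `k - 1` highest (final) merges. For `k = 2` the cluster with
#' the higher mean comorbidity burden (mean row sum of the phenotype matrix)
#' is named `"high"`, the other `"low"`.
#'
#' @param tree a [ward_linkage()].
#' @param k number of clusters, `1 <= k <= n`.
#' @param m optional phenotype matrix, needed for the risk naming.
#' @return integer labels `1..k` (in order of first appearance); when
#'   `k == 2` and `m` is given, attribute `"risk"` holds a character vector
#'   `"low"`/`"high"` per individual.
#' @export
cut_clusters <- function(tree, k, m = NULL) {
  n <- tree$n
  if (k < 1 || k > n) stop("k out of range")
  groups <- vector("list", n - 1L)
  for (s in seq_len(max(0L, n - k))) {
    groups[[s]] <- unlist(lapply(tree$merge[s, ], function(v)
      if (v < 0) -v else groups[[v]]))
  }
  assigned <- rep(NA_integer_, n)
  top <- seq_len(n - k)
  roots <- list()
  # roots: merges in 1..(n-k) not referenced by another merge in that range,
  # plus leaves never merged in that range
  referenced <- rep(FALSE, n - 1L)
  leaf_used <- rep(FALSE, n)
  for (s in top) {
    for (v in tree$merge[s, ]) {
      if (v > 0) referenced[v] <- TRUE else leaf_used[-v] <- TRUE
    }
  }
  for (s in top) if (!referenced[s]) roots[[length(roots) + 1L]] <- groups[[s]]
  for (leaf in which(!leaf_used)) roots[[length(roots) + 1L]] <- leaf
  # label clusters by smallest member for determinism
  ord <- order(vapply(roots, min, numeric(1)))
  for (idx in seq_along(ord)) assigned[roots[[ord[idx]]]] <- idx
  if (k == 2L && !is.null(m)) {
    burden <- tapply(rowSums(m), assigned, mean)
    hi <- as.integer(names(which.max(burden)))
    attr(assigned, "risk") <- ifelse(assigned == hi, "high", "low")
  }
  assigned
}

#' Cluster-count diagnostics
#'
#' Reports the tail of the merge-height profile and the mean silhouette
#' width (squared Euclidean distance) for each candidate `k` in `2..6`.
#' Datasets whose rows are all identical have zero distances everywhere and
#' an undefined silhouette, reported as `NA`.
#'
#' @param tree a [ward_linkage()]; `m` the phenotype matrix.
#' @return list with `heights` (last merges, descending) and `silhouette`
#'   (named numeric over k).
#' @export
cluster_diagnostics <- function(tree, m) {
  if (!is.matrix(m)) m <- as.matrix(m)
  n <- tree$n
  sq <- rowSums(m^2)
  D <- pmax(outer(sq, sq, "+") - 2 * tcrossprod(m), 0)
  ks <- 2:min(6L, n)
  sil <- stats::setNames(rep(NA_real_, length(ks)), ks)
  for (k in ks) {
    lab <- cut_clusters(tree, k)
    s_i <- numeric(n)
    for (i in seq_len(n)) {
      own <- lab == lab[i]
      a <- if (sum(own) > 1L) mean(D[i, own & seq_len(n) != i]) else 0
      b <- min(vapply(setdiff(unique(lab), lab[i]),
                      function(g) mean(D[i, lab == g]), numeric(1)))
      s_i[i] <- if (max(a, b) > 0) (b - a) / max(a, b) else NA_real_
    }
    sil[as.character(k)] <- mean(s_i)
  }
  hts <- rev(tree$height)[seq_len(min(10L, n - 1L))]
  list(heights = hts, silhouette = sil)
}
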