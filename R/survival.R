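#' Two-means patient stratification
#'
#' Splits patients into two groups by k-means (k = 2) on the expression of a
#' module's selected mRNAs, taking the best of `n_restarts` seeded starts by
#' within-cluster sum of squares. Label 0 is the cluster with the lower mean
#' expression over the supplied genes, making the labeling deterministic.
#'
#' @param expr Numeric matrix, patients x selected mRNAs, with patient ids as
#'   rownames.
#' @param seed Seed for the k-means starts.
#' @param n_restarts Number of random starts (default 20).
#' @return Named integer vector of 0/1 labels.
#' @export
cluster_patients <- function(expr, seed = 1L, n_restarts = 20L) {
  if (!is.matrix(expr)) expr <- as.matrix(expr)
  if (nrow(expr) < 4L) stop("need at least 4 patients to cluster", call. = FALSE)
  if (ncol(expr) < 1L) stop("need at least one selected mRNA", call. = FALSE)
  if (all(apply(expr, 2L, function(col) length(unique(col))) == 1L) ||
      nrow(unique(expr)) == 1L) {
    stop("all patients have identical expression; no partition exists", call. = FALSE)
  }
  km <- with_seed(seed, stats::kmeans(expr, centers = 2L, nstart = n_restarts))
  means <- tapply(rowMeans(expr), km$cluster, mean)
  low <- as.integer(names(means)[which.min(means)])
  labels <- as.integer(km$cluster != low)
  stats::setNames(labels, rownames(expr))
}

#' Two-group log-rank test
#'
#' Standard log-rank comparison of the survival distributions of two patient
#' groups (chi-square statistic with 1 degree of freedom, upper-tail
#' p-value). Patients are matched to clinical rows by identifier.
#'
#' @param labels Named 0/1 vector from [cluster_patients()].
#' @param clinical Tibble with `patient_id`, `time_days`, `event`.
#' @return List with `statistic` and `p_value`.
#' @export
logrank_test <- function(labels, clinical) {
  if (is.null(names(labels))) stop("`labels` must be named by patient id", call. = FALSE)
  orphans <- setdiff(names(labels), clinical$patient_id)
  if (length(orphans)) {
    stop("patients missing from the clinical table: ",
         paste(utils::head(orphans, 10L), collapse = ", "), call. = FALSE)
  }
  if (length(unique(labels)) < 2L) {
    stop("both groups must be non-empty", call. = FALSE)
  }
  idx <- match(names(labels), clinical$patient_id)
  df <- data.frame(time = clinical$time_days[idx], event = clinical$event[idx],
                   group = unname(labels))
  sd <- survival::survdiff(survival::Surv(time, event) ~ group, data = df)
  stat <- sd$chisq
  list(statistic = unname(stat),
       p_value = stats::pchisq(unname(stat), df = 1L, lower.tail = FALSE))
}

#' Survival-based module filtering
#'
#' For every module with at least one selected mRNA, patients of the relevant
#' cohort(s) are stratified by [cluster_patients()] on the (re-standardized)
#' expression of the module's selected mRNAs and the two groups are compared
#' with the log-rank test. A cohort-scope module is tested in its own cohort
#' only; a tissue-scope module is tested in every cohort separately and
#' counts as significant only when p < `alpha` in all of them.
#'
#' @param modules An `mtfr_modules` tibble from [extract_modules()].
#' @param dataset The `multitask_dataset` the model was fitted on.
#' @param clinical Named list (by cohort name) of clinical tibbles.
#' @param alpha Significance level (default 0.05, no multiplicity
#'   correction, matching common practice for module screening).
#' @param p_adjust Optional multiplicity correction applied per test column
#'   (a `stats::p.adjust` method; default `"none"`).
#' @param seed,n_restarts Passed to [cluster_patients()].
#' @return A tibble, one row per (module, cohort) test: `scope`,
#'   `rank_index`, `cohort`, `n_patients`, `statistic`, `p_value`,
#'   `significant` (this cohort) and `module_significant` (the module-level
#'   verdict: conjunction over cohorts for tissue modules).
#' @export
survival_filter <- function(modules, dataset, clinical, alpha = 0.05,
                            p_adjust = "none", seed = 1L, n_restarts = 20L) {
  rows <- list()
  for (i in seq_len(nrow(modules))) {
    scope <- modules$scope[i]
    sel <- modules$selected_mrnas[[i]]
    if (length(sel) == 0L) {
      warning(sprintf("module %s/%d has no selected mRNAs; skipped",
                      scope, modules$rank_index[i]), call. = FALSE)
      next
    }
    cohorts <- if (scope == "tissue") dataset$cohort_names else scope
    for (co in cohorts) {
      k <- match(co, dataset$cohort_names)
      expr <- dataset$Y[[k]][, sel, drop = FALSE]
      sds <- apply(expr, 2L, stats::sd)
      sds[sds == 0] <- 1
      expr <- sweep(sweep(expr, 2L, colMeans(expr)), 2L, sds, `/`)
      labels <- cluster_patients(expr,
                                 seed = derive_seed(seed, paste(scope, modules$rank_index[i], co)),
                                 n_restarts = n_restarts)
      lr <- logrank_test(labels, clinical[[co]])
      rows[[length(rows) + 1L]] <- tibble::tibble(
        scope = scope, rank_index = modules$rank_index[i], cohort = co,
        n_patients = length(labels), statistic = lr$statistic,
        p_value = lr$p_value
      )
    }
  }
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0L) return(out)
  out$p_value_adj <- stats::p.adjust(out$p_value, method = p_adjust)
  out$significant <- out$p_value_adj < alpha
  out <- dplyr::group_by(out, .data$scope, .data$rank_index)
  out <- dplyr::mutate(out, module_significant = all(.data$significant))
  dplyr::ungroup(out)
}
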