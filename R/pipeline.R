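#' Serialize a fit to a directory
#'
#' Writes each parameter block as TSV, the objective trace as CSV, and a
#' JSON manifest (ranks, penalty weights, configuration echo, convergence).
#'
#' @param fit An `mtfr_fit` object.
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
write_mtfr_fit <- function(fit, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  wm <- function(m, rn, cn, path) {
    if (nrow(m)) rownames(m) <- rn
    if (ncol(m)) colnames(m) <- cn
    df <- data.frame(id = rownames(m) %||% character(0L), m, check.names = FALSE)
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  p <- fit$params
  Rs <- fit$ranks$Rs
  wm(p$WXS, fit$mirna_ids, paste0("s", seq_len(Rs)), file.path(dir, "WXS.tsv"))
  wm(t(p$WYS), fit$mrna_ids, paste0("s", seq_len(Rs)), file.path(dir, "WYS_t.tsv"))
  for (k in seq_along(p$WXk)) {
    nm <- fit$cohort_names[k]
    rk <- fit$ranks$Rk[k]
    wm(p$WXk[[k]], fit$mirna_ids, paste0("c", seq_len(rk)),
       file.path(dir, paste0("WX_", nm, ".tsv")))
    wm(t(p$WYk[[k]]), fit$mrna_ids, paste0("c", seq_len(rk)),
       file.path(dir, paste0("WY_", nm, "_t.tsv")))
  }
  utils::write.table(fit$objective_trace, file.path(dir, "objective_trace.csv"),
                     sep = ",", quote = FALSE, row.names = FALSE)
  manifest <- list(
    ranks = list(Rs = fit$ranks$Rs, Rk = as.list(fit$ranks$Rk)),
    lambda = as.list(fit$lambda),
    config = unclass(fit$config),
    converged = fit$converged,
    n_outer_restarts = fit$n_outer_restarts,
    cohort_names = fit$cohort_names
  )
  jsonlite::write_json(manifest, file.path(dir, "fit_manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' Read a fit written by [write_mtfr_fit()]
#'
#' @param dir Directory containing the fit files.
#' @return An `mtfr_fit` object (objective trace restored from CSV).
#' @export
read_mtfr_fit <- function(dir) {
  manifest <- jsonlite::read_json(file.path(dir, "fit_manifest.json"),
                                  simplifyVector = TRUE)
  rm_ <- function(path) {
    df <- utils::read.table(path, header = TRUE, sep = "\t", check.names = FALSE,
                            stringsAsFactors = FALSE)
    m <- as.matrix(df[, -1L, drop = FALSE])
    ids <- df[[1L]]
    dimnames(m) <- NULL   # fitted blocks carry no dimnames; ids live in the fit
    attr(m, "ids") <- ids
    m
  }
  strip <- function(m) { ids <- attr(m, "ids"); attr(m, "ids") <- NULL; list(m = m, ids = ids) }
  wxs <- strip(rm_(file.path(dir, "WXS.tsv")))
  wys <- strip(rm_(file.path(dir, "WYS_t.tsv")))
  WXS <- wxs$m
  WYS <- t(wys$m)
  mirna_ids <- wxs$ids
  mrna_ids <- wys$ids
  cohort_names <- manifest$cohort_names
  WXk <- lapply(cohort_names, function(nm) {
    s <- strip(rm_(file.path(dir, paste0("WX_", nm, ".tsv"))))
    s$m
  })
  WYk <- lapply(cohort_names, function(nm) {
    s <- strip(rm_(file.path(dir, paste0("WY_", nm, "_t.tsv"))))
    t(s$m)
  })
  trace <- tibble::as_tibble(utils::read.csv(file.path(dir, "objective_trace.csv")))
  cfg <- manifest$config
  structure(
    list(params = mtfr_params(WXS, WXk, WYS, WYk),
         ranks = list(Rs = manifest$ranks$Rs, Rk = unlist(manifest$ranks$Rk)),
         objective_trace = trace, converged = manifest$converged,
         n_outer_restarts = manifest$n_outer_restarts,
         lambda = penalty_weights(manifest$lambda$lambda1, manifest$lambda$lambda2,
                                  manifest$lambda$lambda3, manifest$lambda$lambda4),
         config = do.call(fit_config, cfg[setdiff(names(cfg), character(0L))]),
         cohort_names = cohort_names,
         mirna_ids = mirna_ids, mrna_ids = mrna_ids),
    class = "mtfr_fit"
  )
}

run_manifest <- function(out_dir, command, seed, extra = list()) {
  manifest <- c(list(command = command,
                     package_version = as.character(utils::packageVersion("mtfr")),
                     seed = seed), extra)
  jsonlite::write_json(manifest, file.path(out_dir, "run_manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
}

#' Generate and write a synthetic dataset directory
#'
#' Runs [simulate_multitask()] and serializes the standardized dataset plus
#' the planted ground truth (JSON) and a run manifest.
#'
#' @param out_dir Output directory.
#' @param seed Global seed.
#' @param ... Passed to [simulate_multitask()].
#' @return `out_dir`, invisibly.
#' @export
run_simulate <- function(out_dir, seed = 1L, ...) {
  sim <- simulate_multitask(seed = derive_seed(seed, "simulate"), ...)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  write_multitask_dataset(sim$dataset, file.path(out_dir, "dataset"))
  tr <- sim$truth
  truth_json <- list(
    sigma = tr$sigma, sparsity = tr$sparsity, signal_scale = tr$signal_scale,
    seed = tr$seed, cohort_names = tr$cohort_names,
    WXS = tr$params$WXS, WYS = tr$params$WYS,
    WXk = tr$params$WXk, WYk = tr$params$WYk,
    mirna_ids = tr$mirna_ids, mrna_ids = tr$mrna_ids
  )
  jsonlite::write_json(truth_json, file.path(out_dir, "ground_truth.json"),
                       digits = NA, auto_unbox = FALSE, matrix = "rowmajor")
  run_manifest(out_dir, "simulate", seed)
  invisible(out_dir)
}

#' Fit the model on a dataset directory and write all outputs
#'
#' Reads a standardized dataset written by [run_simulate()] (or
#' [write_multitask_dataset()]), optionally selects penalty weights by
#' cross-validation, fits with rank estimation, extracts modules, and writes
#' the fit, module tables and a run manifest. Exactly one of `lambda` and
#' `grid` must be supplied.
#'
#' @param data_dir Dataset directory.
#' @param out_dir Output directory.
#' @param lambda Fixed penalty weights, or `NULL` to cross-validate.
#' @param grid An [cv_grid()] used when `lambda` is `NULL`.
#' @param config An [fit_config()]; its seed is re-derived from `seed`.
#' @param seed Global seed.
#' @param rank_search_cv Passed to [cross_validate()] as `rank_search`.
#' @return The `mtfr_fit`, invisibly.
#' @export
run_fit <- function(data_dir, out_dir, lambda = NULL, grid = NULL,
                    config = fit_config(), seed = 1L, rank_search_cv = TRUE) {
  if (is.null(lambda) == is.null(grid)) {
    stop("supply exactly one of `lambda` (fixed weights) or `grid` (CV)", call. = FALSE)
  }
  data <- read_multitask_dataset(file.path(data_dir, "dataset"))
  config$seed <- derive_seed(seed, "fit-init")
  cv <- NULL
  if (is.null(lambda)) {
    grid$seed <- derive_seed(seed, "cv-folds")
    cv <- cross_validate(data, grid, config, rank_search = rank_search_cv)
    lambda <- cv_best_lambda(cv)
  }
  fit <- mtfr_fit(data, lambda, config)
  modules <- extract_modules(fit)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  write_mtfr_fit(fit, file.path(out_dir, "fit"))
  write_modules(modules, file.path(out_dir, "modules"))
  if (!is.null(cv)) {
    utils::write.table(tidy(cv), file.path(out_dir, "cv_table.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  run_manifest(out_dir, "fit", seed,
               list(lambda = as.list(lambda),
                    ranks = list(Rs = fit$ranks$Rs, Rk = as.list(fit$ranks$Rk)),
                    converged = fit$converged))
  invisible(fit)
}

#' Survival-filter the modules of a written fit
#'
#' @param data_dir Dataset directory (as in [run_fit()]).
#' @param fit_dir Output directory of a previous [run_fit()] call.
#' @param clinical_paths Named character vector (by cohort) of clinical TSV
#'   paths.
#' @param out_dir Output directory for the filter report.
#' @param alpha Significance level.
#' @param seed Global seed.
#' @return The filter tibble, invisibly.
#' @export
run_survival <- function(data_dir, fit_dir, clinical_paths, out_dir,
                         alpha = 0.05, seed = 1L) {
  data <- read_multitask_dataset(file.path(data_dir, "dataset"))
  fit <- read_mtfr_fit(file.path(fit_dir, "fit"))
  modules <- extract_modules(fit)
  clinical <- lapply(clinical_paths, read_clinical_table)
  names(clinical) <- names(clinical_paths)
  res <- survival_filter(modules, data, clinical, alpha = alpha,
                         seed = derive_seed(seed, "survival"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.table(res, file.path(out_dir, "survival_filter.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  run_manifest(out_dir, "survival", seed, list(alpha = alpha))
  invisible(res)
}

#' TF permutation test on the first module of every scope
#'
#' @param fit_dir Output directory of a previous [run_fit()] call.
#' @param tf_path Path to a one-gene-per-line TF list.
#' @param out_dir Output directory.
#' @param n_perm Number of permutations.
#' @param seed Global seed.
#' @return The `mtfr_tf_test`, invisibly.
#' @export
run_tf_test <- function(fit_dir, tf_path, out_dir, n_perm = 10000L, seed = 1L) {
  fit <- read_mtfr_fit(file.path(fit_dir, "fit"))
  modules <- extract_modules(fit)
  first <- modules[modules$rank_index == 1L & lengths(modules$selected_mrnas) > 0L, ]
  if (nrow(first) == 0L) stop("no module with selected mRNAs to test", call. = FALSE)
  tf_list <- read_tf_list(tf_path)
  res <- tf_permutation_test(first$selected_mrnas, universe = fit$mrna_ids,
                             tf_list = tf_list, n_perm = n_perm,
                             seed = derive_seed(seed, "tf-test"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  out_tbl <- dplyr::mutate(tidy(res), scope = first$scope, .before = 1L)
  utils::write.table(out_tbl, file.path(out_dir, "tf_test.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(
    list(mannwhitney_p = res$mannwhitney_p, n_perm = n_perm),
    file.path(out_dir, "tf_test.json"), auto_unbox = TRUE, digits = NA)
  run_manifest(out_dir, "tf-test", seed)
  invisible(res)
}
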