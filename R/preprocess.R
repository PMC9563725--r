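#' Expression matrix container
#'
#' A light container for a samples-by-features expression matrix together with
#' its processing stage. Values start as non-negative raw abundances (counts or
#' FPKM-like), become log2 intensities after [log2_transform()], and unitless
#' z-scores after [standardize_columns()].
#'
#' @param values Numeric matrix, rows = samples, columns = features, with
#'   rownames (sample ids) and colnames (feature ids).
#' @param stage One of `"raw"`, `"log2"`, `"standardized"`.
#' @return An object of class `expression_matrix`.
#' @export
expression_matrix <- function(values, stage = c("raw", "log2", "standardized")) {
  stage <- match.arg(stage)
  if (!is.matrix(values) || !is.numeric(values)) {
    stop("`values` must be a numeric matrix", call. = FALSE)
  }
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    stop("`values` must carry sample ids (rownames) and feature ids (colnames)",
         call. = FALSE)
  }
  if (anyDuplicated(rownames(values))) {
    stop("duplicate sample ids: ",
         paste(unique(rownames(values)[duplicated(rownames(values))]), collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(colnames(values))) {
    stop("duplicate feature ids: ",
         paste(unique(colnames(values)[duplicated(colnames(values))]), collapse = ", "),
         call. = FALSE)
  }
  if (anyNA(values)) stop("expression values must not contain NA", call. = FALSE)
  if (stage == "raw" && any(values < 0)) {
    stop("raw expression values must be non-negative", call. = FALSE)
  }
  structure(list(values = values, stage = stage), class = "expression_matrix")
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat(sprintf("<expression_matrix> %d samples x %d features, stage = %s\n",
              nrow(x$values), ncol(x$values), x$stage))
  invisible(x)
}

#' @export
dim.expression_matrix <- function(x) dim(x$values)

#' Read an expression matrix from delimited text
#'
#' Reads a TSV or CSV (by file extension) with one header row and one leading
#' identifier column. Orientation is normalized so that samples are rows.
#'
#' @param path Path to a delimited text file.
#' @param orientation `"samples_in_rows"` (default) if rows are samples, or
#'   `"features_in_rows"` if the file stores features as rows.
#' @return An `expression_matrix` at stage `"raw"`.
#' @export
read_expression_matrix <- function(path,
                                   orientation = c("samples_in_rows", "features_in_rows")) {
  orientation <- match.arg(orientation)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  df <- utils::read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                          colClasses = "character", quote = "\"",
                          comment.char = "", stringsAsFactors = FALSE)
  if (ncol(df) < 2L) stop("expected an identifier column plus data columns", call. = FALSE)
  ids <- df[[1L]]
  cells <- as.matrix(df[, -1L, drop = FALSE])
  colnames(cells) <- names(df)[-1L]  # undo make.unique applied by `[.data.frame`
  num <- suppressWarnings(matrix(as.numeric(cells), nrow = nrow(cells),
                                 dimnames = dimnames(cells)))
  if (anyNA(num)) {
    bad <- which(is.na(num), arr.ind = TRUE)[1L, ]
    stop(sprintf("non-numeric value %s at row %d (id '%s'), column '%s' in %s",
                 dQuote(cells[bad[1L], bad[2L]]), bad[1L], ids[bad[1L]],
                 colnames(cells)[bad[2L]], path), call. = FALSE)
  }
  if (any(num < 0)) {
    bad <- which(num < 0, arr.ind = TRUE)[1L, ]
    stop(sprintf("negative raw expression value at row '%s', column '%s' in %s",
                 ids[bad[1L]], colnames(cells)[bad[2L]], path), call. = FALSE)
  }
  rownames(num) <- ids
  if (orientation == "features_in_rows") num <- t(num)
  expression_matrix(num, stage = "raw")
}

#' Drop features expressed in too few samples
#'
#' A feature counts as expressed in a sample when its raw value is strictly
#' positive; features present in less than `min_fraction` of samples are
#' discarded (features at exactly the threshold are kept).
#'
#' @param m An `expression_matrix` at stage `"raw"`.
#' @param min_fraction Minimum fraction of samples with positive expression.
#' @return The filtered `expression_matrix`, feature order preserved.
#' @export
filter_low_expression <- function(m, min_fraction = 0.5) {
  stopifnot(inherits(m, "expression_matrix"))
  if (m$stage != "raw") {
    stop("expression filtering is defined on raw values (stage = 'raw')", call. = FALSE)
  }
  frac <- colMeans(m$values > 0)
  keep <- frac >= min_fraction
  if (!any(keep)) stop("no feature passes the expression filter", call. = FALSE)
  expression_matrix(m$values[, keep, drop = FALSE], stage = "raw")
}

#' Log2-transform raw expression values
#'
#' @param m An `expression_matrix` at stage `"raw"`.
#' @param pseudocount Added before taking log2 so that zeros map to finite
#'   values; the default `1` maps 0 to 0.
#' @return An `expression_matrix` at stage `"log2"`.
#' @export
log2_transform <- function(m, pseudocount = 1) {
  stopifnot(inherits(m, "expression_matrix"))
  if (m$stage != "raw") stop("log2 transform expects stage 'raw'", call. = FALSE)
  if (pseudocount <= 0 && any(m$values == 0)) {
    stop("pseudocount must be positive when zeros are present", call. = FALSE)
  }
  expression_matrix(log2(m$values + pseudocount), stage = "log2")
}

#' Center and scale each feature column
#'
#' Columns are centered to zero mean and scaled to unit sample standard
#' deviation, the scale the regression model assumes. Columns with zero
#' variance cannot be scaled and are removed with a warning.
#'
#' @param m An `expression_matrix` at stage `"log2"` or `"standardized"`
#'   (re-standardizing is a no-op up to floating point).
#' @return An `expression_matrix` at stage `"standardized"`.
#' @export
standardize_columns <- function(m) {
  stopifnot(inherits(m, "expression_matrix"))
  if (m$stage == "raw") {
    stop("standardize after log2 transformation, not on raw values", call. = FALSE)
  }
  v <- m$values
  sds <- apply(v, 2L, stats::sd)
  zero <- sds == 0 | !is.finite(sds)
  if (any(zero)) {
    warning(sprintf("removed %d zero-variance column(s): %s", sum(zero),
                    paste(utils::head(colnames(v)[zero], 5L), collapse = ", ")),
            call. = FALSE)
    v <- v[, !zero, drop = FALSE]
    sds <- sds[!zero]
  }
  if (ncol(v) == 0L) stop("no columns left after removing zero-variance features", call. = FALSE)
  v <- scale(v, center = TRUE, scale = sds)
  attr(v, "scaled:center") <- NULL
  attr(v, "scaled:scale") <- NULL
  expression_matrix(v, stage = "standardized")
}

#' Multitask dataset of matched cohorts
#'
#' Bundles K cohorts of standardized miRNA (predictor) and mRNA (response)
#' matrices. Within a cohort the two matrices cover the same samples in the
#' same order; miRNA feature lists are identical across cohorts, likewise mRNA.
#'
#' @param cohort_names Character vector of K cohort labels.
#' @param X List of K standardized miRNA `expression_matrix` objects.
#' @param Y List of K standardized mRNA `expression_matrix` objects.
#' @return An object of class `multitask_dataset` with elements
#'   `cohort_names`, `X`, `Y` (plain numeric matrices), `mirna_ids`,
#'   `mrna_ids`, `n_samples`.
#' @export
multitask_dataset <- function(cohort_names, X, Y) {
  K <- length(cohort_names)
  stopifnot(K >= 1L, length(X) == K, length(Y) == K, !anyDuplicated(cohort_names))
  getv <- function(m) if (inherits(m, "expression_matrix")) m$values else m
  X <- lapply(X, getv)
  Y <- lapply(Y, getv)
  for (k in seq_len(K)) {
    if (!identical(rownames(X[[k]]), rownames(Y[[k]]))) {
      stop(sprintf("cohort '%s': miRNA and mRNA matrices must cover identical samples in identical order",
                   cohort_names[k]), call. = FALSE)
    }
    if (!identical(colnames(X[[k]]), colnames(X[[1L]])) ||
        !identical(colnames(Y[[k]]), colnames(Y[[1L]]))) {
      stop("feature lists must be identical (and identically ordered) across cohorts",
           call. = FALSE)
    }
  }
  structure(
    list(cohort_names = cohort_names, X = X, Y = Y,
         mirna_ids = colnames(X[[1L]]), mrna_ids = colnames(Y[[1L]]),
         n_samples = vapply(X, nrow, integer(1L))),
    class = "multitask_dataset"
  )
}

#' @export
print.multitask_dataset <- function(x, ...) {
  cat(sprintf("<multitask_dataset> K = %d cohorts, D = %d miRNAs, T = %d mRNAs\n",
              length(x$cohort_names), length(x$mirna_ids), length(x$mrna_ids)))
  for (k in seq_along(x$cohort_names)) {
    cat(sprintf("  %s: N = %d samples\n", x$cohort_names[k], x$n_samples[k]))
  }
  invisible(x)
}

#' Align cohorts into a multitask dataset
#'
#' Restricts each cohort to the samples present in both its miRNA and mRNA
#' matrices, restricts features to those shared by every cohort (separately
#' for miRNA and mRNA, in the first cohort's order), and re-standardizes each
#' matrix after restriction so the model's zero-mean/unit-sd assumption holds
#' on exactly the data being fitted.
#'
#' @param miRNA,mRNA Lists of `expression_matrix` objects at stage `"log2"`
#'   (or `"standardized"`), one per cohort.
#' @param names Cohort labels.
#' @return A `multitask_dataset`.
#' @export
align_cohorts <- function(miRNA, mRNA, names) {
  K <- length(names)
  stopifnot(length(miRNA) == K, length(mRNA) == K, K >= 1L)
  mir_feats <- Reduce(intersect, lapply(miRNA, function(m) colnames(m$values)))
  mrna_feats <- Reduce(intersect, lapply(mRNA, function(m) colnames(m$values)))
  if (length(mir_feats) == 0L || length(mrna_feats) == 0L) {
    stop("empty feature intersection across cohorts", call. = FALSE)
  }
  X <- vector("list", K)
  Y <- vector("list", K)
  for (k in seq_len(K)) {
    samples <- intersect(rownames(miRNA[[k]]$values), rownames(mRNA[[k]]$values))
    if (length(samples) == 0L) {
      stop(sprintf("cohort '%s': no sample has both expression profiles", names[k]),
           call. = FALSE)
    }
    xk <- expression_matrix(miRNA[[k]]$values[samples, mir_feats, drop = FALSE],
                            stage = miRNA[[k]]$stage)
    yk <- expression_matrix(mRNA[[k]]$values[samples, mrna_feats, drop = FALSE],
                            stage = mRNA[[k]]$stage)
    X[[k]] <- standardize_columns(xk)
    Y[[k]] <- standardize_columns(yk)
  }
  # a zero-variance drop in one cohort must propagate to all, so intersect again
  mir_keep <- Reduce(intersect, lapply(X, function(m) colnames(m$values)))
  mrna_keep <- Reduce(intersect, lapply(Y, function(m) colnames(m$values)))
  if (length(mir_keep) == 0L || length(mrna_keep) == 0L) {
    stop("empty feature intersection after removing zero-variance columns", call. = FALSE)
  }
  for (k in seq_len(K)) {
    xv <- X[[k]]$values[, mir_keep, drop = FALSE]
    yv <- Y[[k]]$values[, mrna_keep, drop = FALSE]
    X[[k]] <- standardize_columns(expression_matrix(xv, stage = "log2"))
    Y[[k]] <- standardize_columns(expression_matrix(yv, stage = "log2"))
  }
  multitask_dataset(names, X, Y)
}

#' Preprocess raw cohorts end to end
#'
#' Convenience wrapper running the full pipeline: expression filter on raw
#' values, log2 transform, cross-cohort alignment, per-cohort standardization.
#'
#' @inheritParams align_cohorts
#' @param min_fraction Passed to [filter_low_expression()].
#' @param pseudocount Passed to [log2_transform()].
#' @return A `multitask_dataset`.
#' @export
preprocess_cohorts <- function(miRNA, mRNA, names, min_fraction = 0.5, pseudocount = 1) {
  step <- function(m) log2_transform(filter_low_expression(m, min_fraction), pseudocount)
  align_cohorts(lapply(miRNA, step), lapply(mRNA, step), names)
}

#' Read a clinical table
#'
#' @param path TSV with mandatory columns `patient_id`, `time_days` (positive
#'   days to death or last follow-up) and `event` (1 = death observed,
#'   0 = censored).
#' @return A tibble with those three columns, validated.
#' @export
read_clinical_table <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t", check.names = FALSE,
                          stringsAsFactors = FALSE)
  need <- c("patient_id", "time_days", "event")
  if (!all(need %in% names(df))) {
    stop("clinical table must have columns: ", paste(need, collapse = ", "), call. = FALSE)
  }
  out <- tibble::as_tibble(df[need])
  if (anyDuplicated(out$patient_id)) stop("duplicate patient ids in clinical table", call. = FALSE)
  if (any(out$time_days <= 0)) stop("time_days must be positive", call. = FALSE)
  if (!all(out$event %in% c(0, 1))) stop("event must be 0 or 1", call. = FALSE)
  out
}

#' Read a transcription-factor gene list
#'
#' @param path Text file, one gene identifier per line.
#' @return Character vector of unique identifiers.
#' @export
read_tf_list <- function(path) {
  x <- readLines(path, warn = FALSE)
  x <- trimws(x)
  unique(x[nzchar(x)])
}

#' Serialize a multitask dataset to a directory
#'
#' Writes one TSV per cohort and matrix plus a JSON manifest (cohort names,
#' dimensions, stage, content hash).
#'
#' @param dataset A `multitask_dataset`.
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_multitask_dataset <- function(dataset, dir) {
  stopifnot(inherits(dataset, "multitask_dataset"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_one <- function(m, path) {
    df <- data.frame(sample_id = rownames(m), m, check.names = FALSE)
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  for (k in seq_along(dataset$cohort_names)) {
    nm <- dataset$cohort_names[k]
    write_one(dataset$X[[k]], file.path(dir, paste0(nm, "_mirna.tsv")))
    write_one(dataset$Y[[k]], file.path(dir, paste0(nm, "_mrna.tsv")))
  }
  manifest <- list(
    cohort_names = dataset$cohort_names,
    n_samples = unname(dataset$n_samples),
    n_mirna = length(dataset$mirna_ids),
    n_mrna = length(dataset$mrna_ids),
    stage = "standardized",
    content_hash = rlang::hash(list(dataset$X, dataset$Y))
  )
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' Read a multitask dataset written by [write_multitask_dataset()]
#'
#' @param dir Directory containing the TSV matrices and `manifest.json`.
#' @return A `multitask_dataset`.
#' @export
read_multitask_dataset <- function(dir) {
  manifest_path <- file.path(dir, "manifest.json")
  if (!file.exists(manifest_path)) {
    stop("not a dataset directory (no manifest.json): ", dir, call. = FALSE)
  }
  manifest <- jsonlite::read_json(manifest_path, simplifyVector = TRUE)
  read_one <- function(path) {
    df <- utils::read.table(path, header = TRUE, sep = "\t", check.names = FALSE,
                            stringsAsFactors = FALSE)
    m <- as.matrix(df[, -1L, drop = FALSE])
    rownames(m) <- df[[1L]]
    m
  }
  X <- lapply(manifest$cohort_names, function(nm) read_one(file.path(dir, paste0(nm, "_mirna.tsv"))))
  Y <- lapply(manifest$cohort_names, function(nm) read_one(file.path(dir, paste0(nm, "_mrna.tsv"))))
  multitask_dataset(manifest$cohort_names, X, Y)
}
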