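#' Predict mRNA expression for one cohort
#'
#' The linear prediction `X %*% [WXS WXk] %*% rbind(WYS, WYk)` for cohort
#' `k`: project the miRNA profiles into the factor space, then regress into
#' mRNA space.
#'
#' @param object An `mtfr_fit` (or [mtfr_params()]) object.
#' @param X Standardized miRNA matrix, N x D.
#' @param cohort Cohort index (or name, when `object` is an `mtfr_fit`).
#' @param ... Unused.
#' @return Predicted mRNA matrix, N x T.
#' @export
predict.mtfr_fit <- function(object, X, cohort = 1L, ...) {
  if (is.character(cohort)) cohort <- match(cohort, object$cohort_names)
  predict_cohort(object$params, X, cohort)
}

#' @rdname predict.mtfr_fit
#' @param params An [mtfr_params()] object.
#' @export
predict_cohort <- function(params, X, cohort = 1L) {
  if (ncol(X) != nrow(params$WXS)) {
    stop("X has ", ncol(X), " columns but the model expects ", nrow(params$WXS),
         call. = FALSE)
  }
  X %*% (stack_x(params, cohort) %*% stack_y(params, cohort))
}

#' Root mean squared error over all matrix entries
#'
#' @param Y Observed matrix.
#' @param Yhat Predicted matrix of the same shape.
#' @return Non-negative scalar.
#' @export
rmse <- function(Y, Yhat) {
  stopifnot(identical(dim(Y), dim(Yhat)))
  sqrt(mean((Y - Yhat)^2))
}

#' Normalized RMSE, averaged over responses
#'
#' Each mRNA's RMSE is normalized by the spread of its observed values and
#' the normalized errors are averaged over mRNAs. With the default `"sd"`
#' normalization, predicting every column by its mean scores exactly 1, so
#' values below 1 measure variance explained beyond the trivial predictor.
#'
#' @inheritParams rmse
#' @param normalization `"sd"` (observed sample standard deviation, default)
#'   or `"range"` (observed max minus min).
#' @return Non-negative scalar.
#' @export
nrmse <- function(Y, Yhat, normalization = c("sd", "range")) {
  normalization <- match.arg(normalization)
  stopifnot(identical(dim(Y), dim(Yhat)))
  col_rmse <- sqrt(colMeans((Y - Yhat)^2))
  denom <- switch(normalization,
    sd = apply(Y, 2L, function(col) {
      # population-style sd with the same 1/N as the column RMSE, so that the
      # column-mean predictor scores exactly 1
      sqrt(mean((col - mean(col))^2))
    }),
    range = apply(Y, 2L, function(col) diff(range(col)))
  )
  if (any(denom == 0)) stop("every response must have positive spread", call. = FALSE)
  mean(col_rmse / denom)
}

#' Cross-validation grid
#'
#' @param lambda1_values,lambda2_values,lambda3_values,lambda4_values
#'   Candidate penalty weights (positive reals).
#' @param n_folds Number of folds (default 4).
#' @param seed Seed fixing the fold assignment.
#' @return A list of class `mtfr_cv_grid`.
#' @export
cv_grid <- function(lambda1_values, lambda2_values, lambda3_values,
                    lambda4_values, n_folds = 4L, seed = 1L) {
  stopifnot(length(lambda1_values) >= 1L, length(lambda2_values) >= 1L,
            length(lambda3_values) >= 1L, length(lambda4_values) >= 1L,
            n_folds >= 2L)
  structure(list(lambda1_values = lambda1_values, lambda2_values = lambda2_values,
                 lambda3_values = lambda3_values, lambda4_values = lambda4_values,
                 n_folds = as.integer(n_folds), seed = as.integer(seed)),
            class = "mtfr_cv_grid")
}

#' Penalty grids used for the cancer-cohort experiments
#'
#' Named presets for the l1 weights (`lambda1`, `lambda3`) and ridge weights
#' (`lambda2`, `lambda4`) scaled to cohort size: `"blood"` uses
#' `{60, 80, 100, 125, 150}` for the l1 weights, `"kidney"` and `"lung"` use
#' `{150, 200, 250, 300, 350}`; all use `{10, 15, 20, 25, 30}` for the ridge
#' weights.
#'
#' @param preset One of `"blood"`, `"kidney"`, `"lung"`.
#' @inheritParams cv_grid
#' @return An `mtfr_cv_grid`.
#' @export
cv_grid_preset <- function(preset = c("blood", "kidney", "lung"),
                           n_folds = 4L, seed = 1L) {
  preset <- match.arg(preset)
  l1 <- switch(preset, blood = c(60, 80, 100, 125, 150),
               kidney = , lung = c(150, 200, 250, 300, 350))
  ridge <- c(10, 15, 20, 25, 30)
  cv_grid(l1, ridge, l1, ridge, n_folds = n_folds, seed = seed)
}

# seeded fold labels stratified by cohort: balanced counts, random assignment
cv_fold_assignment <- function(data, n_folds, seed) {
  with_seed(seed, {
    lapply(seq_along(data$X), function(k) {
      n <- nrow(data$X[[k]])
      if (n < n_folds) stop("every cohort needs at least n_folds samples", call. = FALSE)
      sample(rep_len(seq_len(n_folds), n))
    })
  })
}

# center/scale columns by training-fold statistics (zero-sd columns are
# centered only); returns the transformed matrix
apply_fold_standardization <- function(train, test) {
  mu <- colMeans(train)
  sd <- apply(train, 2L, stats::sd)
  sd[sd == 0] <- 1
  list(train = sweep(sweep(train, 2L, mu), 2L, sd, `/`),
       test = sweep(sweep(test, 2L, mu), 2L, sd, `/`))
}

#' Cross-validated selection of the penalty weights
#'
#' Four-fold (by default) cross-validation over every combination of the
#' grid's candidate weights. Fold membership is assigned once per cohort
#' (seeded, balanced) and reused for every combination. For each combination
#' and fold, the model is fitted on the training folds — re-standardized with
#' training-fold statistics, which are also applied to the held-out fold —
#' and scored by RMSE between predicted and held-out mRNA values pooled over
#' cohorts. The combination minimizing the mean RMSE across folds wins; ties
#' break toward the smallest `(lambda1, lambda3, lambda2, lambda4)`.
#'
#' @param data A `multitask_dataset`.
#' @param grid An [cv_grid()] object.
#' @param config An [fit_config()]; `config$seed` seeds the per-fit
#'   initialization.
#' @param rank_search Run the full rank-estimation loop inside each fold
#'   (default) or fit once at `RU` (`FALSE`, faster).
#' @return A list of class `mtfr_cv` with `table` (tibble: lambda1..lambda4,
#'   `mean_rmse`, per-fold RMSEs in `fold_rmse` list-column) and `best`
#'   (one-row tibble).
#' @export
cross_validate <- function(data, grid, config = fit_config(), rank_search = TRUE) {
  stopifnot(inherits(grid, "mtfr_cv_grid"))
  folds <- cv_fold_assignment(data, grid$n_folds, grid$seed)
  combos <- expand.grid(lambda1 = grid$lambda1_values, lambda2 = grid$lambda2_values,
                        lambda3 = grid$lambda3_values, lambda4 = grid$lambda4_values,
                        KEEP.OUT.ATTRS = FALSE)
  K <- length(data$X)
  fold_data <- lapply(seq_len(grid$n_folds), function(f) {
    Xtr <- Ytr <- Xte <- Yte <- vector("list", K)
    for (k in seq_len(K)) {
      te <- folds[[k]] == f
      if (sum(te) < 2L || sum(!te) < 2L) {
        stop("a fold has fewer than 2 samples in some cohort", call. = FALSE)
      }
      sx <- apply_fold_standardization(data$X[[k]][!te, , drop = FALSE],
                                       data$X[[k]][te, , drop = FALSE])
      sy <- apply_fold_standardization(data$Y[[k]][!te, , drop = FALSE],
                                       data$Y[[k]][te, , drop = FALSE])
      Xtr[[k]] <- sx$train; Xte[[k]] <- sx$test
      Ytr[[k]] <- sy$train; Yte[[k]] <- sy$test
    }
    list(train = list(cohort_names = data$cohort_names, X = Xtr, Y = Ytr),
         test_X = Xte, test_Y = Yte)
  })
  score_combo <- function(lam) {
    vapply(fold_data, function(fd) {
      fit_params <- if (rank_search) {
        mtfr_fit(fd$train, lam, config)$params
      } else {
        mtfr_fit_fixed_ranks(fd$train, lam,
                             list(Rs = config$RU, Rk = rep(config$RU, K)),
                             config)$params
      }
      se <- 0
      n <- 0
      for (k in seq_len(K)) {
        pred <- predict_cohort(fit_params, fd$test_X[[k]], k)
        se <- se + sum((fd$test_Y[[k]] - pred)^2)
        n <- n + length(pred)
      }
      sqrt(se / n)
    }, numeric(1L))
  }
  fold_rmse <- lapply(seq_len(nrow(combos)), function(i) {
    score_combo(penalty_weights(combos$lambda1[i], combos$lambda2[i],
                                combos$lambda3[i], combos$lambda4[i]))
  })
  table <- tibble::as_tibble(combos)
  table$fold_rmse <- fold_rmse
  table$mean_rmse <- vapply(fold_rmse, mean, numeric(1L))
  ord <- order(table$mean_rmse, table$lambda1, table$lambda3,
               table$lambda2, table$lambda4)
  best <- table[ord[1L], ]
  structure(list(table = table, best = best, grid = grid), class = "mtfr_cv")
}

#' @export
print.mtfr_cv <- function(x, ...) {
  cat(sprintf("<mtfr_cv> %d combinations x %d folds\n", nrow(x$table), x$grid$n_folds))
  cat(sprintf("  best: lambda = (%g, %g, %g, %g), mean RMSE = %.4f\n",
              x$best$lambda1, x$best$lambda2, x$best$lambda3, x$best$lambda4,
              x$best$mean_rmse))
  invisible(x)
}

#' Best penalty weights from a CV result
#'
#' `rule = "min"` returns the combination with the minimum mean held-out
#' RMSE. `rule = "1se"` applies the one-standard-error rule: among all
#' combinations whose mean RMSE is within one standard error (across folds,
#' at the minimizer) of the minimum, it returns the most parsimonious one —
#' largest `lambda1 + lambda3`, then largest `lambda2 + lambda4`. Prediction
#' error is typically flat near its minimum while heavier l1 weights prune
#' spurious factors, so the 1se rule is the right choice when the goal is
#' structure (rank and module) recovery rather than raw prediction.
#'
#' @param cv An `mtfr_cv` object.
#' @param rule `"min"` (default) or `"1se"`.
#' @return A [penalty_weights()] vector.
#' @export
cv_best_lambda <- function(cv, rule = c("min", "1se")) {
  rule <- match.arg(rule)
  if (rule == "min") {
    return(penalty_weights(cv$best$lambda1, cv$best$lambda2,
                           cv$best$lambda3, cv$best$lambda4))
  }
  tb <- cv$table
  i_min <- which(tb$lambda1 == cv$best$lambda1 & tb$lambda2 == cv$best$lambda2 &
                   tb$lambda3 == cv$best$lambda3 & tb$lambda4 == cv$best$lambda4)[1L]
  folds <- tb$fold_rmse[[i_min]]
  band <- cv$best$mean_rmse + stats::sd(folds) / sqrt(length(folds))
  cand <- tb[tb$mean_rmse <= band, , drop = FALSE]
  ord <- order(-(cand$lambda1 + cand$lambda3), -(cand$lambda2 + cand$lambda4),
               -cand$lambda1, -cand$lambda2)
  sel <- cand[ord[1L], ]
  penalty_weights(sel$lambda1, sel$lambda2, sel$lambda3, sel$lambda4)
}
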