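#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a fitted multitask factor regression
#'
#' One row per extracted regulatory module with its scope, rank, importance
#' and selected-feature counts.
#'
#' @param x An `mtfr_fit` object.
#' @param ... Unused.
#' @return A tibble.
#' @method tidy mtfr_fit
#' @export
tidy.mtfr_fit <- function(x, ...) {
  m <- extract_modules(x)
  tibble::as_tibble(m[, c("scope", "rank_index", "importance", "n_mirnas", "n_mrnas")])
}

#' One-row summary of a fitted multitask factor regression
#'
#' @param x An `mtfr_fit` object.
#' @param ... Unused.
#' @return A tibble with the estimated ranks, final objective, iteration
#'   counts and convergence flag.
#' @method glance mtfr_fit
#' @export
glance.mtfr_fit <- function(x, ...) {
  tibble::tibble(
    rank_shared = x$ranks$Rs,
    rank_cohort_total = sum(x$ranks$Rk),
    rank_total = x$ranks$Rs + sum(x$ranks$Rk),
    objective = utils::tail(x$objective_trace$objective, 1L),
    n_iterations = nrow(x$objective_trace),
    n_outer_restarts = x$n_outer_restarts,
    converged = x$converged
  )
}

#' Tidy a cross-validation result
#'
#' @param x An `mtfr_cv` object.
#' @param ... Unused.
#' @return The CV table as a tibble (without the list column of per-fold
#'   scores), sorted by mean RMSE.
#' @method tidy mtfr_cv
#' @export
tidy.mtfr_cv <- function(x, ...) {
  out <- x$table[, c("lambda1", "lambda2", "lambda3", "lambda4", "mean_rmse")]
  dplyr::arrange(out, .data$mean_rmse)
}

#' @method glance mtfr_cv
#' @export
glance.mtfr_cv <- function(x, ...) {
  dplyr::mutate(x$best[, c("lambda1", "lambda2", "lambda3", "lambda4", "mean_rmse")],
                n_combinations = nrow(x$table))
}

#' Tidy a TF permutation test
#'
#' @param x An `mtfr_tf_test` object.
#' @param ... Unused.
#' @return A tibble, one row per tested module.
#' @method tidy mtfr_tf_test
#' @export
tidy.mtfr_tf_test <- function(x, ...) {
  tibble::tibble(
    module = seq_along(x$observed_tf_count),
    observed_tf_count = x$observed_tf_count,
    observed_tf_percent = x$observed_tf_percent,
    null_mean_percent = vapply(x$null_percents, mean, numeric(1L)),
    empirical_p = x$empirical_p
  )
}

#' Plot the optimization trace of a fit
#'
#' Objective value per inner iteration, faceted by outer restart of the
#' rank-reduction loop.
#'
#' @param object An `mtfr_fit` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot mtfr_fit
#' @export
autoplot.mtfr_fit <- function(object, ...) {
  ggplot2::ggplot(object$objective_trace,
                  ggplot2::aes(x = .data$iteration, y = .data$objective)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~restart, scales = "free", labeller = ggplot2::label_both) +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "iteration", y = "penalized objective (log scale)",
                  title = "Prox-linear descent across rank restarts") +
    ggplot2::theme_minimal()
}

#' Plot module importance weights
#'
#' @param object An `mtfr_modules` tibble.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot mtfr_modules
#' @export
autoplot.mtfr_modules <- function(object, ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(x = factor(.data$rank_index), y = .data$importance)) +
    ggplot2::geom_col() +
    ggplot2::facet_wrap(~scope, scales = "free_x") +
    ggplot2::labs(x = "module rank within scope", y = "importance (dx * dy)",
                  title = "Regulatory module importance") +
    ggplot2::theme_minimal()
}

#' Plot the cross-validation surface
#'
#' Mean held-out RMSE over the l1 weights, faceted by the ridge weights.
#'
#' @param object An `mtfr_cv` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot mtfr_cv
#' @export
autoplot.mtfr_cv <- function(object, ...) {
  ggplot2::ggplot(object$table,
                  ggplot2::aes(x = factor(.data$lambda1), y = factor(.data$lambda3),
                               fill = .data$mean_rmse)) +
    ggplot2::geom_tile() +
    ggplot2::facet_grid(lambda2 ~ lambda4, labeller = ggplot2::label_both) +
    ggplot2::labs(x = "lambda1 (miRNA-side l1)", y = "lambda3 (mRNA-side l1)",
                  fill = "mean RMSE", title = "Cross-validation grid") +
    ggplot2::theme_minimal()
}

#' Plot the TF permutation null against observed values
#'
#' @param object An `mtfr_tf_test` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot mtfr_tf_test
#' @export
autoplot.mtfr_tf_test <- function(object, ...) {
  null_df <- tibble::tibble(percent = unlist(object$null_percents))
  obs_df <- tibble::tibble(percent = object$observed_tf_percent)
  ggplot2::ggplot(null_df, ggplot2::aes(x = .data$percent)) +
    ggplot2::geom_histogram(bins = 50, fill = "grey70") +
    ggplot2::geom_vline(data = obs_df,
                        ggplot2::aes(xintercept = .data$percent),
                        colour = "red", linetype = 2) +
    ggplot2::labs(x = "TF percent in random gene sets",
                  title = "Permutation null vs observed TF content") +
    ggplot2::theme_minimal()
}
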