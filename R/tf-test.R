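#' Transcription-factor enrichment by permutation
#'
#' Asks whether a module's selected mRNAs contain more transcription factors
#' than random gene sets of the same size. The null distribution is built by
#' drawing `n_perm` uniform random subsets (without replacement) of the gene
#' universe, each of the observed selection's size, and recording the percent
#' of TFs in each draw. The empirical p-value uses the add-one estimator
#' `(1 + #{null >= observed}) / (n_perm + 1)`, so it is never exactly zero.
#' When several modules' selections are supplied, their observed TF percents
#' are additionally compared against the pooled null with a one-sided
#' Mann-Whitney test (alternative: observed greater).
#'
#' @param selected_mrnas Character vector of selected gene ids, or a list of
#'   such vectors (one per module).
#' @param universe Character vector of all candidate gene ids.
#' @param tf_list Character vector of transcription-factor gene ids.
#' @param n_perm Number of permutation draws (default 10000).
#' @param seed Seed for the draws.
#' @return A list of class `mtfr_tf_test`: `observed_tf_count`,
#'   `observed_tf_percent` (vectors, one entry per module), `null_percents`
#'   (per module, list of length-`n_perm` vectors), `empirical_p` (per
#'   module), and `mannwhitney_p` (NA with a single module).
#' @export
tf_permutation_test <- function(selected_mrnas, universe, tf_list,
                                n_perm = 10000L, seed = 1L) {
  if (!is.list(selected_mrnas)) selected_mrnas <- list(selected_mrnas)
  stopifnot(length(universe) >= 1L, n_perm >= 1L)
  sizes <- lengths(selected_mrnas)
  if (any(sizes < 1L)) stop("each selection needs at least one gene", call. = FALSE)
  if (any(sizes > length(universe))) {
    stop("a selection is larger than the gene universe", call. = FALSE)
  }
  is_tf <- universe %in% tf_list
  observed_count <- vapply(selected_mrnas, function(s) sum(s %in% tf_list), integer(1L))
  observed_percent <- 100 * observed_count / sizes
  null_percents <- with_seed(seed, {
    lapply(sizes, function(m) {
      vapply(seq_len(n_perm), function(i) {
        100 * sum(is_tf[sample.int(length(universe), m)]) / m
      }, numeric(1L))
    })
  })
  empirical_p <- vapply(seq_along(sizes), function(j) {
    (1 + sum(null_percents[[j]] >= observed_percent[j])) / (n_perm + 1)
  }, numeric(1L))
  mw <- if (length(sizes) > 1L) {
    stats::wilcox.test(observed_percent, unlist(null_percents),
                       alternative = "greater", exact = FALSE)$p.value
  } else {
    NA_real_
  }
  structure(list(observed_tf_count = observed_count,
                 observed_tf_percent = observed_percent,
                 null_percents = null_percents,
                 empirical_p = empirical_p,
                 mannwhitney_p = mw,
                 n_perm = as.integer(n_perm)),
            class = "mtfr_tf_test")
}

#' @export
print.mtfr_tf_test <- function(x, ...) {
  cat(sprintf("<mtfr_tf_test> %d module(s), %d permutations\n",
              length(x$observed_tf_count), x$n_perm))
  for (j in seq_along(x$observed_tf_count)) {
    cat(sprintf("  module %d: %d TFs (%.2f%%), null mean %.2f%%, empirical p = %.4g\n",
                j, x$observed_tf_count[j], x$observed_tf_percent[j],
                mean(x$null_percents[[j]]), x$empirical_p[j]))
  }
  if (!is.na(x$mannwhitney_p)) {
    cat(sprintf("  one-sided Mann-Whitney (observed > null): p = %.4g\n", x$mannwhitney_p))
  }
  invisible(x)
}
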