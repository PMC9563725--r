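#' Fitting configuration
#'
#' @param RU Upper bound on every block rank; the rank search starts all
#'   blocks here.
#' @param epsilon Relative-objective stopping tolerance of the inner loop:
#'   stop when `|f(t+1) - f(t)| / f(t) < epsilon`.
#' @param max_iter Maximum inner iterations per rank configuration.
#' @param seed Seed for the random initialization.
#' @param init_scale Standard deviation of the Gaussian initialization.
#' @param rank_tolerance Relative singular-value cutoff for the numeric rank
#'   check between restarts. The default 0.15 measures *effective* rank: the
#'   elastic net shrinks spurious components hard but rarely to exact zero,
#'   so a component counts only when its singular value reaches 15% of the
#'   block's largest.
#' @param warm_start After a rank reduction, include the previous solution
#'   with the lowest-importance component of each reduced block dropped as a
#'   candidate start (`TRUE`, default) alongside the random starts.
#' @param n_starts Number of random starts raced per rank configuration; the
#'   problem is non-convex, so each start runs `burn_in` rounds and the one
#'   with the lowest objective continues to convergence.
#' @param burn_in Rounds each candidate start runs before selection.
#' @param multiplier_form Passed to [step_multipliers()].
#' @return A list of class `mtfr_config`.
#' @export
fit_config <- function(RU = 10L, epsilon = 1e-4, max_iter = 1000L, seed = 1L,
                       init_scale = 0.3, rank_tolerance = 0.15,
                       warm_start = TRUE, n_starts = 10L, burn_in = 200L,
                       multiplier_form = c("lipschitz", "printed")) {
  stopifnot(RU >= 1L, epsilon > 0, max_iter >= 1L, init_scale >= 0,
            rank_tolerance > 0, n_starts >= 1L, burn_in >= 1L)
  structure(list(RU = as.integer(RU), epsilon = epsilon,
                 max_iter = as.integer(max_iter), seed = as.integer(seed),
                 init_scale = init_scale, rank_tolerance = rank_tolerance,
                 warm_start = isTRUE(warm_start), n_starts = as.integer(n_starts),
                 burn_in = as.integer(burn_in),
                 multiplier_form = match.arg(multiplier_form)),
            class = "mtfr_config")
}

#' Random initialization of the parameter blocks
#'
#' Every block entry is drawn iid from `N(0, init_scale^2)` using the
#' configured seed, so identical seeds give identical starts.
#'
#' @param data A `multitask_dataset`.
#' @param ranks List with `Rs` (integer) and `Rk` (integer vector, length K).
#' @param config An [fit_config()] object.
#' @return An [mtfr_params()] object.
#' @export
mtfr_init <- function(data, ranks, config = fit_config()) {
  D <- ncol(data$X[[1L]])
  Tn <- ncol(data$Y[[1L]])
  K <- length(data$X)
  stopifnot(ranks$Rs >= 0L, all(ranks$Rk >= 0L), length(ranks$Rk) == K)
  with_seed(config$seed, {
    draw <- function(nr, nc) matrix(stats::rnorm(nr * nc, sd = config$init_scale), nr, nc)
    WXS <- draw(D, ranks$Rs)
    WXk <- lapply(ranks$Rk, function(r) draw(D, r))
    WYS <- draw(ranks$Rs, Tn)
    WYk <- lapply(ranks$Rk, function(r) draw(r, Tn))
    mtfr_params(WXS, WXk, WYS, WYk)
  })
}

# one full prox-linear round over all blocks, Y-side first (the X-side
# multipliers reference the freshly updated Y blocks); gradients are
# recomputed before every block update so each step majorizes the objective
prox_round <- function(params, gram, lam, form) {
  K <- gram$K
  l1x <- lam[["lambda1"]]
  l1y <- lam[["lambda3"]]
  if (nrow(params$WYS) > 0L) {
    mult <- step_multipliers_gram(params, gram, lam, form)
    params$WYS <- prox_update_block(params$WYS, grad_g_shared_gram(params, gram, lam),
                                    mult$beta_s, l1y)
  }
  for (k in seq_len(K)) {
    if (nrow(params$WYk[[k]]) == 0L) next
    mult <- step_multipliers_gram(params, gram, lam, form)
    params$WYk[[k]] <- prox_update_block(params$WYk[[k]],
                                         grad_g_cohort_gram(k, params, gram, lam),
                                         mult$beta_k[k], l1y)
  }
  if (ncol(params$WXS) > 0L) {
    mult <- step_multipliers_gram(params, gram, lam, form)
    params$WXS <- prox_update_block(params$WXS, grad_h_shared_gram(params, gram, lam),
                                    mult$alpha_s, l1x)
  }
  for (k in seq_len(K)) {
    if (ncol(params$WXk[[k]]) == 0L) next
    mult <- step_multipliers_gram(params, gram, lam, form)
    params$WXk[[k]] <- prox_update_block(params$WXk[[k]],
                                         grad_h_cohort_gram(k, params, gram, lam),
                                         mult$alpha_k[k], l1x)
  }
  params
}

# run prox-linear rounds from `params` for at most `max_iter` rounds
inner_descend <- function(params, gram, lam, config, max_iter) {
  f <- objective_gram(params, gram, lam)
  trace <- numeric(max_iter + 1L)
  trace[1L] <- f
  converged <- FALSE
  it <- 0L
  while (it < max_iter) {
    it <- it + 1L
    params <- prox_round(params, gram, lam, config$multiplier_form)
    f_new <- objective_gram(params, gram, lam)
    if (!is.finite(f_new)) {
      stop(sprintf("objective became non-finite at iteration %d (f = %g before)",
                   it, f), call. = FALSE)
    }
    trace[it + 1L] <- f_new
    if (abs(f_new - f) / max(f, .Machine$double.eps) < config$epsilon) {
      converged <- TRUE
      f <- f_new
      break
    }
    f <- f_new
  }
  list(params = params, objective_trace = trace[seq_len(it + 1L)], converged = converged)
}

#' Solve the penalized problem at fixed ranks
#'
#' Runs prox-linear rounds (all blocks, Y-side first) until the relative
#' change of the objective drops below `config$epsilon` or `config$max_iter`
#' is reached. Because the problem is non-convex, `config$n_starts` seeded
#' random starts (plus `params0`, when given) are raced for
#' `config$burn_in` rounds and the one with the lowest objective continues
#' to convergence; with `n_starts = 1` and no `params0` this is a single
#' seeded run.
#'
#' @inheritParams mtfr_init
#' @param lambda Penalty weights from [penalty_weights()].
#' @param params0 Optional additional starting parameters (e.g. a truncated
#'   previous solution).
#' @return List with `params`, `objective_trace` (f at start plus after every
#'   round, for the selected start) and `converged`.
#' @export
mtfr_fit_fixed_ranks <- function(data, lambda, ranks, config = fit_config(),
                                 params0 = NULL) {
  lam <- as_penalty(lambda)
  gram <- precompute_gram(data)
  starts <- if (config$n_starts == 1L) {
    list(mtfr_init(data, ranks, config))
  } else {
    lapply(seq_len(config$n_starts), function(i) {
      cfg <- config
      cfg$seed <- derive_seed(config$seed, paste0("start", i))
      mtfr_init(data, ranks, cfg)
    })
  }
  if (!is.null(params0)) starts <- c(list(params0), starts)
  if (length(starts) == 1L) {
    return(inner_descend(starts[[1L]], gram, lam, config, config$max_iter))
  }
  burn <- min(config$burn_in, config$max_iter)
  burns <- lapply(starts, inner_descend, gram = gram, lam = lam,
                  config = config, max_iter = burn)
  best <- which.min(vapply(burns, function(b) utils::tail(b$objective_trace, 1L),
                           numeric(1L)))
  run <- burns[[best]]
  if (!run$converged && config$max_iter > burn) {
    cont <- inner_descend(run$params, gram, lam, config, config$max_iter - burn)
    run <- list(params = cont$params,
                objective_trace = c(run$objective_trace,
                                    cont$objective_trace[-1L]),
                converged = cont$converged)
  }
  run
}

#' Numeric rank of a parameter block
#'
#' Counts singular values above `rank_tolerance` times the largest singular
#' value; an all-zero (or empty) block has rank 0.
#'
#' @param block Numeric matrix.
#' @param rank_tolerance Relative cutoff.
#' @return Integer rank estimate.
#' @export
numeric_rank <- function(block, rank_tolerance = 1e-4) {
  if (length(block) == 0L) return(0L)
  if (all(block == 0)) return(0L)
  d <- svd(block, nu = 0L, nv = 0L)$d
  sum(d > rank_tolerance * d[1L])
}

# importance of each rank-one component of a (WX, WY) block pair
component_importance <- function(WX, WY) {
  if (ncol(WX) == 0L) return(numeric(0L))
  sqrt(colSums(WX^2)) * sqrt(rowSums(WY^2))
}

# drop the n lowest-importance components of a block pair
truncate_block <- function(WX, WY, new_rank) {
  imp <- component_importance(WX, WY)
  keep <- order(imp, decreasing = TRUE)[seq_len(new_rank)]
  keep <- sort(keep)
  list(WX = WX[, keep, drop = FALSE], WY = WY[keep, , drop = FALSE])
}

#' Fit the multitask sparse factor regression with rank estimation
#'
#' Starts every block at rank `RU`, solves the penalized problem, then checks
#' each block pair's numeric rank. Any pair whose rank falls short of its
#' current dimension has that dimension reduced by one (all deficient blocks
#' in the same restart; a block may reach 0 and drop out of the model) and
#' the problem is re-solved, by default warm-started from the previous
#' solution with the weakest component of each reduced block removed. The
#' loop stops when every surviving block is full rank, which bounds the
#' number of restarts by the total starting rank.
#'
#' @inheritParams mtfr_fit_fixed_ranks
#' @return An object of class `mtfr_fit` with elements `params`, `ranks`
#'   (list `Rs`, `Rk`), `objective_trace` (tibble: restart, iteration,
#'   objective), `converged`, `n_outer_restarts`, `lambda`, `config`,
#'   `cohort_names`, `mirna_ids`, `mrna_ids`.
#' @export
mtfr_fit <- function(data, lambda, config = fit_config()) {
  lam <- as_penalty(lambda)
  K <- length(data$X)
  D <- ncol(data$X[[1L]])
  Tn <- ncol(data$Y[[1L]])
  if (config$RU > min(D, Tn)) {
    stop("RU must not exceed min(D, T)", call. = FALSE)
  }
  ranks <- list(Rs = config$RU, Rk = rep(config$RU, K))
  params0 <- NULL
  traces <- list()
  restart <- 0L
  max_restarts <- config$RU * (K + 1L)
  repeat {
    if (restart > max_restarts) {
      stop("rank-reduction loop exceeded its restart bound", call. = FALSE)
    }
    run <- mtfr_fit_fixed_ranks(data, lam, ranks, config, params0 = params0)
    traces[[restart + 1L]] <- tibble::tibble(
      restart = restart,
      iteration = seq_along(run$objective_trace) - 1L,
      objective = run$objective_trace
    )
    p <- run$params
    block_rank <- function(WX, WY) min(numeric_rank(WX, config$rank_tolerance),
                                       numeric_rank(WY, config$rank_tolerance))
    r_s <- block_rank(p$WXS, p$WYS)
    r_k <- vapply(seq_len(K), function(k) block_rank(p$WXk[[k]], p$WYk[[k]]), integer(1L))
    deficient_s <- r_s < ranks$Rs
    deficient_k <- r_k < ranks$Rk
    if (!deficient_s && !any(deficient_k)) {
      return(structure(
        list(params = p, ranks = ranks,
             objective_trace = dplyr::bind_rows(traces),
             converged = run$converged, n_outer_restarts = restart,
             lambda = lam, config = config,
             cohort_names = data$cohort_names %||% paste0("cohort", seq_len(K)),
             mirna_ids = colnames(data$X[[1L]]) %||% paste0("x", seq_len(D)),
             mrna_ids = colnames(data$Y[[1L]]) %||% paste0("y", seq_len(Tn))),
        class = "mtfr_fit"
      ))
    }
    new_ranks <- list(Rs = ranks$Rs - deficient_s,
                      Rk = ranks$Rk - as.integer(deficient_k))
    if (config$warm_start) {
      ts <- truncate_block(p$WXS, p$WYS, new_ranks$Rs)
      tk <- lapply(seq_len(K), function(k) truncate_block(p$WXk[[k]], p$WYk[[k]], new_ranks$Rk[k]))
      params0 <- mtfr_params(ts$WX, lapply(tk, `[[`, "WX"), ts$WY, lapply(tk, `[[`, "WY"))
    } else {
      params0 <- NULL
    }
    ranks <- new_ranks
    restart <- restart + 1L
  }
}

#' @export
print.mtfr_fit <- function(x, ...) {
  cat(sprintf("<mtfr_fit> Rs = %d, Rk = (%s), converged = %s, restarts = %d\n",
              x$ranks$Rs, paste(x$ranks$Rk, collapse = ", "),
              x$converged, x$n_outer_restarts))
  cat(sprintf("  final objective: %.6g\n", utils::tail(x$objective_trace$objective, 1L)))
  invisible(x)
}
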