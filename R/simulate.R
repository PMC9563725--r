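#' Simulate a multitask dataset with planted module structure
#'
#' Generates K cohorts under the model's own generative assumption: miRNA
#' profiles are iid standard normal, sparse rank-one factor blocks are
#' planted (a shared pair and one private pair per cohort), and mRNA
#' profiles are the noiseless linear map plus iid Gaussian noise,
#' `Yk = Xk [WXS WXk] rbind(WYS, WYk) + E`, `E ~ N(0, sigma^2)`. Each
#' planted module-vector entry is zero with probability `sparsity` and
#' `N(0, signal_scale^2)` otherwise (vectors are redrawn if they come out
#' all-zero, so planted ranks are exact). The returned dataset is
#' column-standardized, the state every downstream function expects; the
#' ground truth keeps the pre-standardization blocks, since standardization
#' rescales coefficients but preserves module directions.
#'
#' @param K Number of cohorts.
#' @param D,T Number of miRNAs and mRNAs.
#' @param N Samples per cohort (scalar or length-K vector).
#' @param Rs,Rk Planted shared and per-cohort ranks (`Rk` recycled to K).
#' @param sparsity Probability a planted weight is exactly zero.
#' @param signal_scale Standard deviation of the nonzero planted weights.
#' @param sigma Noise standard deviation; when `NULL`, chosen so that the
#'   pooled signal-to-noise ratio `||Y_noiseless||_F / (sigma * sqrt(#entries))`
#'   equals `snr`.
#' @param snr Target signal-to-noise ratio used when `sigma` is `NULL`
#'   (default 2, a regime where module structure is visible but far from
#'   noiseless).
#' @param seed Seed for all draws.
#' @return List with `dataset` (a `multitask_dataset`) and `truth` (class
#'   `mtfr_truth`: `params`, `sigma`, `sparsity`, `signal_scale`, `seed`,
#'   and the noiseless responses `Y0`).
#' @export
simulate_multitask <- function(K = 2L, D = 60L, T = 120L, N = 150L,
                               Rs = 2L, Rk = 1L, sparsity = 0.9,
                               signal_scale = 1, sigma = NULL, snr = 2,
                               seed = 1L) {
  stopifnot(K >= 1L, D >= 1L, T >= 1L, Rs >= 0L, all(Rk >= 0L),
            sparsity >= 0, sparsity < 1, signal_scale > 0)
  N <- rep_len(N, K)
  Rk <- rep_len(as.integer(Rk), K)
  if (Rs + max(Rk) > min(D, T)) stop("Rs + max(Rk) must not exceed min(D, T)", call. = FALSE)
  with_seed(seed, {
    sparse_mat <- function(nr, nc, by_col = TRUE) {
      m <- matrix(0, nr, nc)
      n_vec <- if (by_col) nc else nr
      for (j in seq_len(n_vec)) {
        repeat {
          len <- if (by_col) nr else nc
          v <- stats::rnorm(len, sd = signal_scale) *
            (stats::runif(len) >= sparsity)
          if (any(v != 0)) break
        }
        if (by_col) m[, j] <- v else m[j, ] <- v
      }
      m
    }
    WXS <- sparse_mat(D, Rs, by_col = TRUE)
    WYS <- sparse_mat(Rs, T, by_col = FALSE)
    WXk <- lapply(Rk, function(r) sparse_mat(D, r, by_col = TRUE))
    WYk <- lapply(Rk, function(r) sparse_mat(r, T, by_col = FALSE))
    truth_params <- mtfr_params(WXS, WXk, WYS, WYk)
    X <- lapply(seq_len(K), function(k) matrix(stats::rnorm(N[k] * D), N[k], D))
    Y0 <- lapply(seq_len(K), function(k) {
      X[[k]] %*% (stack_x(truth_params, k) %*% stack_y(truth_params, k))
    })
    if (is.null(sigma)) {
      total_entries <- sum(vapply(Y0, length, numeric(1L)))
      signal_f <- sqrt(sum(vapply(Y0, function(y) sum(y^2), numeric(1L))))
      sigma <- signal_f / (snr * sqrt(total_entries))
    }
    Y <- lapply(seq_len(K), function(k) {
      Y0[[k]] + matrix(stats::rnorm(length(Y0[[k]]), sd = sigma),
                       nrow(Y0[[k]]), ncol(Y0[[k]]))
    })
    mirna_ids <- sprintf("mir%03d", seq_len(D))
    mrna_ids <- sprintf("gene%04d", seq_len(T))
    cohort_names <- sprintf("cohort%d", seq_len(K))
    # center/scale columns but keep zero-variance columns (possible for
    # untouched mRNAs when sigma = 0) as zeros, so cohorts stay aligned
    std_keep <- function(m) {
      sds <- apply(m, 2L, stats::sd)
      sds[sds == 0] <- 1
      sweep(sweep(m, 2L, colMeans(m)), 2L, sds, `/`)
    }
    Xs <- Ys <- vector("list", K)
    for (k in seq_len(K)) {
      sample_ids <- sprintf("%s_s%03d", cohort_names[k], seq_len(N[k]))
      dimnames(X[[k]]) <- list(sample_ids, mirna_ids)
      dimnames(Y[[k]]) <- list(sample_ids, mrna_ids)
      Xs[[k]] <- std_keep(X[[k]])
      Ys[[k]] <- std_keep(Y[[k]])
    }
    dataset <- multitask_dataset(cohort_names, Xs, Ys)
    truth <- structure(list(params = truth_params, sigma = sigma,
                            sparsity = sparsity, signal_scale = signal_scale,
                            seed = seed, Y0 = Y0,
                            mirna_ids = mirna_ids, mrna_ids = mrna_ids,
                            cohort_names = cohort_names),
                       class = "mtfr_truth")
    list(dataset = dataset, truth = truth)
  })
}

#' Simulate survival outcomes driven by a module score
#'
#' Event times are exponential with per-patient log-hazard proportional to
#' the standardized module score; censoring times are independent
#' exponentials with rate tuned (by root finding) so the expected fraction
#' of censored patients matches `censoring_rate`.
#'
#' @param module_score Named numeric vector, one score per patient.
#' @param effect Log-hazard ratio per standard deviation of module score
#'   (0 = no survival signal).
#' @param censoring_rate Target expected fraction of censored patients.
#' @param baseline_hazard Baseline event rate per day (default 1/365).
#' @param seed Seed.
#' @return A clinical tibble (`patient_id`, `time_days`, `event`).
#' @export
simulate_survival <- function(module_score, effect = 1.5, censoring_rate = 0.3,
                              baseline_hazard = 1 / 365, seed = 1L) {
  stopifnot(censoring_rate >= 0, censoring_rate < 1)
  n <- length(module_score)
  z <- if (stats::sd(module_score) > 0) {
    (module_score - mean(module_score)) / stats::sd(module_score)
  } else {
    rep(0, n)
  }
  rates <- baseline_hazard * exp(effect * z)
  with_seed(seed, {
    t_event <- stats::rexp(n, rate = rates)
    if (censoring_rate == 0) {
      time <- t_event
      event <- rep(1L, n)
    } else {
      # P(censored | rate_i) = hc / (hc + rate_i); average over patients
      f <- function(hc) mean(hc / (hc + rates)) - censoring_rate
      hc <- stats::uniroot(f, lower = 1e-12, upper = 1e6 * baseline_hazard,
                           tol = 1e-12)$root
      t_cens <- stats::rexp(n, rate = hc)
      time <- pmin(t_event, t_cens)
      event <- as.integer(t_event <= t_cens)
    }
    tibble::tibble(patient_id = names(module_score) %||% sprintf("p%04d", seq_len(n)),
                   time_days = time, event = event)
  })
}

cosine_sim <- function(a, b) {
  na <- sqrt(sum(a^2))
  nb <- sqrt(sum(b^2))
  if (na == 0 || nb == 0) return(0)
  sum(a * b) / (na * nb)
}

# best one-to-one assignment maximizing the total score matrix `s`
# (rows = estimated, cols = true); exact enumeration for small problems,
# greedy otherwise
best_assignment <- function(s) {
  nr <- nrow(s)
  nc <- ncol(s)
  m <- min(nr, nc)
  if (m == 0L) return(cbind(est = integer(0L), true = integer(0L)))
  if (max(nr, nc) <= 7L) {
    small_rows <- nr <= nc
    k_small <- if (small_rows) nr else nc
    k_big <- max(nr, nc)
    best <- NULL
    best_val <- -Inf
    idx <- utils::combn(k_big, k_small, simplify = FALSE)
    perms <- function(v) {
      if (length(v) <= 1L) return(list(v))
      unlist(lapply(seq_along(v), function(i) {
        lapply(perms(v[-i]), function(p) c(v[i], p))
      }), recursive = FALSE)
    }
    for (sub in idx) {
      for (p in perms(sub)) {
        val <- sum(vapply(seq_len(k_small), function(i) {
          if (small_rows) s[i, p[i]] else s[p[i], i]
        }, numeric(1L)))
        if (val > best_val) {
          best_val <- val
          best <- if (small_rows) cbind(est = seq_len(k_small), true = p)
                  else cbind(est = p, true = seq_len(k_small))
        }
      }
    }
    best
  } else {
    pairs <- matrix(integer(0L), 0L, 2L, dimnames = list(NULL, c("est", "true")))
    s_work <- s
    for (i in seq_len(m)) {
      w <- which(s_work == max(s_work), arr.ind = TRUE)[1L, , drop = FALSE]
      pairs <- rbind(pairs, cbind(est = w[1L], true = w[2L]))
      s_work[w[1L], ] <- -Inf
      s_work[, w[2L]] <- -Inf
    }
    pairs
  }
}

#' Match estimated modules to planted ground truth
#'
#' Within each scope, finds the one-to-one assignment between estimated and
#' planted modules that maximizes the summed absolute cosine similarity of
#' their miRNA weight vectors, and reports per-pair similarity on both sides
#' plus selection precision/recall against the planted supports (the
#' nonzero entries of the planted vectors).
#'
#' @param modules An `mtfr_modules` tibble from [extract_modules()].
#' @param truth An `mtfr_truth` object from [simulate_multitask()].
#' @return A tibble, one row per matched pair: `scope`, `rank_index`,
#'   `true_component`, `cosine_mirna`, `cosine_mrna`, `precision_mirna`,
#'   `recall_mirna`, `precision_mrna`, `recall_mrna`.
#' @export
match_modules <- function(modules, truth) {
  scopes <- c("tissue", truth$cohort_names)
  true_blocks <- c(list(list(WX = truth$params$WXS, WY = truth$params$WYS)),
                   lapply(seq_along(truth$params$WXk), function(k) {
                     list(WX = truth$params$WXk[[k]], WY = truth$params$WYk[[k]])
                   }))
  rows <- list()
  for (si in seq_along(scopes)) {
    sc <- scopes[si]
    est <- modules[modules$scope == sc, , drop = FALSE]
    tb <- true_blocks[[si]]
    n_true <- ncol(tb$WX)
    if (nrow(est) == 0L || n_true == 0L) next
    s <- matrix(0, nrow(est), n_true)
    for (i in seq_len(nrow(est))) {
      for (j in seq_len(n_true)) {
        s[i, j] <- abs(cosine_sim(est$mirna_weights[[i]], tb$WX[, j]))
      }
    }
    pairs <- best_assignment(s)
    for (p in seq_len(nrow(pairs))) {
      i <- pairs[p, "est"]
      j <- pairs[p, "true"]
      sel_mir <- est$selected_mirnas[[i]]
      sel_mrna <- est$selected_mrnas[[i]]
      sup_mir <- truth$mirna_ids[tb$WX[, j] != 0]
      sup_mrna <- truth$mrna_ids[tb$WY[j, ] != 0]
      pr <- function(sel, sup) {
        c(precision = if (length(sel)) length(intersect(sel, sup)) / length(sel) else NA_real_,
          recall = if (length(sup)) length(intersect(sel, sup)) / length(sup) else NA_real_)
      }
      pm <- pr(sel_mir, sup_mir)
      pg <- pr(sel_mrna, sup_mrna)
      rows[[length(rows) + 1L]] <- tibble::tibble(
        scope = sc, rank_index = est$rank_index[i], true_component = j,
        cosine_mirna = abs(cosine_sim(est$mirna_weights[[i]], tb$WX[, j])),
        cosine_mrna = abs(cosine_sim(est$mrna_weights[[i]], tb$WY[j, ])),
        precision_mirna = pm[["precision"]], recall_mirna = pm[["recall"]],
        precision_mrna = pg[["precision"]], recall_mrna = pg[["recall"]]
      )
    }
  }
  dplyr::bind_rows(rows)
}
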