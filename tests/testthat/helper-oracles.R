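# Independent oracles and fixture builders shared across test files.
# Everything here deliberately avoids the package's own computation paths:
# objectives are expanded with explicit loops, gradients come from central
# finite differences, the log-rank statistic from a hand-built risk table.

# random problem instance: plain list with X/Y lists plus random parameters
random_instance <- function(K = 2L, D = 6L, T = 8L, N = 10L, Rs = 2L,
                            Rk = 2L, seed = 1L, scale = 0.5) {
  set.seed(seed)
  Rk <- rep_len(Rk, K)
  X <- lapply(seq_len(K), function(k) matrix(rnorm(N * D), N, D))
  Y <- lapply(seq_len(K), function(k) matrix(rnorm(N * T), N, T))
  params <- mtfr_params(
    WXS = matrix(rnorm(D * Rs, sd = scale), D, Rs),
    WXk = lapply(Rk, function(r) matrix(rnorm(D * r, sd = scale), D, r)),
    WYS = matrix(rnorm(Rs * T, sd = scale), Rs, T),
    WYk = lapply(Rk, function(r) matrix(rnorm(r * T, sd = scale), r, T))
  )
  list(data = list(cohort_names = paste0("c", seq_len(K)), X = X, Y = Y),
       params = params, K = K, D = D, T = T, N = N)
}

# literal term-by-term expansion of the penalized objective, scalar loops only
oracle_objective <- function(params, data, lambda) {
  K <- length(data$X)
  total <- 0
  for (k in seq_len(K)) {
    WXSk <- cbind(params$WXS, params$WXk[[k]])
    WYSk <- rbind(params$WYS, params$WYk[[k]])
    W <- matrix(0, nrow(WXSk), ncol(WYSk))
    for (i in seq_len(nrow(WXSk))) {
      for (j in seq_len(ncol(WYSk))) {
        W[i, j] <- sum(WXSk[i, ] * WYSk[, j])
      }
    }
    R <- data$Y[[k]] - data$X[[k]] %*% W
    total <- total + 0.5 * sum(R * R)
  }
  l1 <- function(m) sum(abs(m))
  f2 <- function(m) sum(m * m)
  total +
    lambda[[1L]] * (l1(params$WXS) + sum(sapply(params$WXk, l1))) +
    lambda[[2L]] * (f2(params$WXS) + sum(sapply(params$WXk, f2))) +
    lambda[[3L]] * (l1(params$WYS) + sum(sapply(params$WYk, l1))) +
    lambda[[4L]] * (f2(params$WYS) + sum(sapply(params$WYk, f2)))
}

# smooth part of the objective (l1 weights zeroed) for finite differencing
smooth_objective <- function(params, data, lambda) {
  lam <- lambda
  lam[[1L]] <- 0
  lam[[3L]] <- 0
  mtfr_objective(params, data, lam)
}

# central finite differences of the smooth objective wrt one block
fd_gradient <- function(params, data, lambda, block, k = NULL, h = 1e-6) {
  get_block <- function(p) if (is.null(k)) p[[block]] else p[[block]][[k]]
  set_block <- function(p, m) {
    if (is.null(k)) p[[block]] <- m else p[[block]][[k]] <- m
    p
  }
  base <- get_block(params)
  g <- matrix(0, nrow(base), ncol(base))
  for (i in seq_len(nrow(base))) {
    for (j in seq_len(ncol(base))) {
      up <- base; up[i, j] <- up[i, j] + h
      dn <- base; dn[i, j] <- dn[i, j] - h
      g[i, j] <- (smooth_objective(set_block(params, up), data, lambda) -
                    smooth_objective(set_block(params, dn), data, lambda)) / (2 * h)
    }
  }
  g
}

# log-rank chi-square from an explicit risk table over distinct event times
oracle_logrank <- function(time, event, group) {
  stopifnot(all(group %in% c(0, 1)))
  event_times <- sort(unique(time[event == 1]))
  O1 <- E1 <- V <- 0
  for (t in event_times) {
    at_risk <- time >= t
    n <- sum(at_risk)
    n1 <- sum(at_risk & group == 1)
    d <- sum(event == 1 & time == t)
    d1 <- sum(event == 1 & time == t & group == 1)
    O1 <- O1 + d1
    E1 <- E1 + d * n1 / n
    if (n > 1) V <- V + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  chisq <- (O1 - E1)^2 / V
  list(statistic = chisq, p_value = pchisq(chisq, df = 1, lower.tail = FALSE))
}

# minimal standalone single-task sparse factor regression (one cohort, no
# shared block): mirrors the update schedule with its own algebra
singletask_fit <- function(X, Y, R, lambda, seed, init_scale = 0.1,
                           epsilon = 1e-4, max_iter = 200L) {
  D <- ncol(X); Tn <- ncol(Y)
  set.seed(seed)
  WX <- matrix(rnorm(D * R, sd = init_scale), D, R)
  WY <- matrix(rnorm(R * Tn, sd = init_scale), R, Tn)
  XtX <- unname(crossprod(X))
  XtY <- unname(crossprod(X, Y))
  nx <- svd(XtX, nu = 0, nv = 0)$d[1]
  st <- function(v, tau) sign(v) * pmax(abs(v) - tau, 0)
  f_of <- function(WX, WY) {
    0.5 * sum((Y - X %*% WX %*% WY)^2) +
      lambda[[1L]] * sum(abs(WX)) + lambda[[2L]] * sum(WX^2) +
      lambda[[3L]] * sum(abs(WY)) + lambda[[4L]] * sum(WY^2)
  }
  f <- f_of(WX, WY)
  trace <- f
  for (it in seq_len(max_iter)) {
    beta <- max(svd(crossprod(WX, XtX %*% WX), nu = 0, nv = 0)$d[1], 0) +
      2 * lambda[[4L]]
    beta <- max(beta, 1e-8)
    gY <- crossprod(WX, XtX %*% (WX %*% WY)) - crossprod(WX, XtY) +
      2 * lambda[[4L]] * WY
    WY <- st(WY - gY / beta, lambda[[3L]] / beta)
    alpha <- nx * max(svd(WY, nu = 0, nv = 0)$d[1], 0)^2 + 2 * lambda[[2L]]
    alpha <- max(alpha, 1e-8)
    gX <- XtX %*% (WX %*% (WY %*% t(WY))) - XtY %*% t(WY) + 2 * lambda[[2L]] * WX
    WX <- st(WX - gX / alpha, lambda[[1L]] / alpha)
    f_new <- f_of(WX, WY)
    trace <- c(trace, f_new)
    if (abs(f_new - f) / max(f, .Machine$double.eps) < epsilon) break
    f <- f_new
  }
  list(WX = WX, WY = WY, trace = trace)
}

# memoized headline recovery study shared by the rank- and module-recovery
# acceptance checks (one CV on an independent realization, then 10 seeded
# fits at the study conditions)
.study_cache <- new.env(parent = emptyenv())

headline_study <- function() {
  if (!is.null(.study_cache$result)) return(.study_cache$result)
  cv_sim <- simulate_multitask(seed = 101L)
  cv <- cross_validate(cv_sim$dataset,
                       cv_grid(c(15, 25), c(5, 15), c(15, 25), c(5, 15), seed = 42L),
                       fit_config(RU = 4L, seed = 7L))
  lam <- cv_best_lambda(cv)
  runs <- lapply(1:10, function(seed) {
    sim <- simulate_multitask(seed = seed)
    fit <- mtfr_fit(sim$dataset, lam, fit_config(RU = 4L, seed = seed + 1000L))
    mm <- match_modules(extract_modules(fit), sim$truth)
    list(ranks = fit$ranks, match = mm)
  })
  .study_cache$result <- list(lambda = lam, runs = runs)
  .study_cache$result
}
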