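#' Elastic-net penalty weights
#'
#' The model penalizes the miRNA-side factor blocks with
#' `lambda1 * l1 + lambda2 * Frobenius^2` and the mRNA-side blocks with
#' `lambda3 * l1 + lambda4 * Frobenius^2`. The l1 terms induce sparsity (few
#' miRNAs/mRNAs per module); the squared-Frobenius terms group correlated
#' features and keep the factorization well scaled.
#'
#' @param lambda1,lambda2,lambda3,lambda4 Non-negative reals.
#' @return A named numeric vector of length 4.
#' @export
penalty_weights <- function(lambda1, lambda2, lambda3, lambda4) {
  lam <- c(lambda1 = lambda1, lambda2 = lambda2, lambda3 = lambda3, lambda4 = lambda4)
  if (any(!is.finite(lam)) || any(lam < 0)) {
    stop("penalty weights must be finite and non-negative", call. = FALSE)
  }
  lam
}

as_penalty <- function(lambda) {
  if (length(lambda) != 4L) stop("`lambda` must have 4 entries", call. = FALSE)
  penalty_weights(lambda[[1L]], lambda[[2L]], lambda[[3L]], lambda[[4L]])
}

#' Model parameter blocks
#'
#' Holds the four factor blocks of the multitask model: a shared (tissue)
#' pair `WXS` (D x Rs), `WYS` (Rs x T) and per-cohort pairs `WXk` (D x Rk),
#' `WYk` (Rk x T). The implied coefficient matrix of cohort k is
#' `[WXS WXk] %*% rbind(WYS, WYk)`. A rank of zero (zero-column/zero-row
#' block) represents an eliminated block.
#'
#' @param WXS Numeric matrix D x Rs.
#' @param WXk List of K numeric matrices D x Rk.
#' @param WYS Numeric matrix Rs x T.
#' @param WYk List of K numeric matrices Rk x T.
#' @return An object of class `mtfr_params`.
#' @export
mtfr_params <- function(WXS, WXk, WYS, WYk) {
  stopifnot(is.matrix(WXS), is.matrix(WYS), is.list(WXk), is.list(WYk),
            length(WXk) == length(WYk))
  if (ncol(WXS) != nrow(WYS)) stop("shared ranks disagree: ncol(WXS) != nrow(WYS)", call. = FALSE)
  for (k in seq_along(WXk)) {
    if (ncol(WXk[[k]]) != nrow(WYk[[k]])) {
      stop(sprintf("cohort %d ranks disagree: ncol(WXk) != nrow(WYk)", k), call. = FALSE)
    }
    if (nrow(WXk[[k]]) != nrow(WXS) || ncol(WYk[[k]]) != ncol(WYS)) {
      stop(sprintf("cohort %d block dimensions disagree with shared block", k), call. = FALSE)
    }
  }
  structure(list(WXS = WXS, WXk = WXk, WYS = WYS, WYk = WYk), class = "mtfr_params")
}

#' @export
print.mtfr_params <- function(x, ...) {
  cat(sprintf("<mtfr_params> D = %d, T = %d, Rs = %d, Rk = (%s)\n",
              nrow(x$WXS), ncol(x$WYS), ncol(x$WXS),
              paste(vapply(x$WXk, ncol, integer(1L)), collapse = ", ")))
  invisible(x)
}

param_ranks <- function(params) {
  list(Rs = ncol(params$WXS), Rk = vapply(params$WXk, ncol, integer(1L)))
}

# stacked blocks for cohort k: [WXS WXk] and rbind(WYS, WYk)
stack_x <- function(params, k) cbind(params$WXS, params$WXk[[k]])
stack_y <- function(params, k) rbind(params$WYS, params$WYk[[k]])

#' Soft-thresholding operator
#'
#' Elementwise shrinkage `sign(v) * pmax(|v| - tau, 0)`, the proximal operator
#' of the l1 norm.
#'
#' @param v Numeric vector or matrix.
#' @param tau Non-negative threshold.
#' @return Same shape as `v`.
#' @export
soft_threshold <- function(v, tau) {
  if (length(tau) != 1L || !is.finite(tau) || tau < 0) {
    stop("`tau` must be a single non-negative number", call. = FALSE)
  }
  sign(v) * pmax(abs(v) - tau, 0)
}

# per-cohort Gram matrices reused across iterations
precompute_gram <- function(data) {
  K <- length(data$X)
  XtX <- lapply(seq_len(K), function(k) unname(crossprod(data$X[[k]])))
  XtY <- lapply(seq_len(K), function(k) unname(crossprod(data$X[[k]], data$Y[[k]])))
  XtX_sum <- Reduce(`+`, XtX)
  list(
    K = K, XtX = XtX, XtY = XtY, XtX_sum = XtX_sum,
    XtX_norm = vapply(XtX, spectral_norm, numeric(1L)),
    XtX_sum_norm = spectral_norm(XtX_sum),
    y_ss = sum(vapply(data$Y, function(y) sum(y^2), numeric(1L)))
  )
}

#' Penalized multitask objective
#'
#' The least-squares data fit summed over cohorts plus the elastic-net
#' penalties on every factor block:
#' `1/2 * sum_k ||Yk - Xk [WXS WXk] rbind(WYS, WYk)||_F^2`
#' `+ lambda1 * (l1 of X-side blocks) + lambda2 * (Frobenius^2 of X-side)`
#' `+ lambda3 * (l1 of Y-side blocks) + lambda4 * (Frobenius^2 of Y-side)`.
#'
#' @param params An [mtfr_params()] object.
#' @param data A `multitask_dataset` (or any list with matrices `X`, `Y`).
#' @param lambda Penalty weights from [penalty_weights()].
#' @return A single non-negative number.
#' @export
mtfr_objective <- function(params, data, lambda) {
  lam <- as_penalty(lambda)
  K <- length(data$X)
  stopifnot(length(params$WXk) == K)
  fit <- 0
  for (k in seq_len(K)) {
    resid <- data$Y[[k]] - data$X[[k]] %*% (stack_x(params, k) %*% stack_y(params, k))
    fit <- fit + 0.5 * sum(resid^2)
  }
  xs_l1 <- sum(abs(params$WXS)) + sum(vapply(params$WXk, function(m) sum(abs(m)), numeric(1L)))
  xs_f2 <- sum(params$WXS^2) + sum(vapply(params$WXk, function(m) sum(m^2), numeric(1L)))
  ys_l1 <- sum(abs(params$WYS)) + sum(vapply(params$WYk, function(m) sum(abs(m)), numeric(1L)))
  ys_f2 <- sum(params$WYS^2) + sum(vapply(params$WYk, function(m) sum(m^2), numeric(1L)))
  fit + lam[["lambda1"]] * xs_l1 + lam[["lambda2"]] * xs_f2 +
    lam[["lambda3"]] * ys_l1 + lam[["lambda4"]] * ys_f2
}

# objective from precomputed gram matrices (avoids N x T residuals in the
# inner loop): 1/2||Yk||^2 - tr(Wk' XtYk) + 1/2 tr(Wk' XtXk Wk) + penalties
objective_gram <- function(params, gram, lam) {
  fit <- 0.5 * gram$y_ss
  for (k in seq_len(gram$K)) {
    Wk <- stack_x(params, k) %*% stack_y(params, k)
    fit <- fit - sum(Wk * gram$XtY[[k]]) + 0.5 * sum(Wk * (gram$XtX[[k]] %*% Wk))
  }
  xs_l1 <- sum(abs(params$WXS)) + sum(vapply(params$WXk, function(m) sum(abs(m)), numeric(1L)))
  xs_f2 <- sum(params$WXS^2) + sum(vapply(params$WXk, function(m) sum(m^2), numeric(1L)))
  ys_l1 <- sum(abs(params$WYS)) + sum(vapply(params$WYk, function(m) sum(abs(m)), numeric(1L)))
  ys_f2 <- sum(params$WYS^2) + sum(vapply(params$WYk, function(m) sum(m^2), numeric(1L)))
  fit + lam[["lambda1"]] * xs_l1 + lam[["lambda2"]] * xs_f2 +
    lam[["lambda3"]] * ys_l1 + lam[["lambda4"]] * ys_f2
}

## ---- gradients of the smooth part (objective without the l1 terms) -------

grad_h_shared_gram <- function(params, gram, lam) {
  if (ncol(params$WXS) == 0L) stop("shared block is eliminated (Rs = 0)", call. = FALSE)
  acc <- matrix(0, nrow(params$WXS), ncol(params$WXS))
  for (k in seq_len(gram$K)) {
    WXSk <- stack_x(params, k)
    WYSk <- stack_y(params, k)
    M <- tcrossprod(WYSk, params$WYS)                       # (Rs+Rk) x Rs
    acc <- acc + gram$XtX[[k]] %*% (WXSk %*% M) - gram$XtY[[k]] %*% t(params$WYS)
  }
  acc + 2 * lam[["lambda2"]] * params$WXS
}

grad_h_cohort_gram <- function(k, params, gram, lam) {
  if (ncol(params$WXk[[k]]) == 0L) stop("cohort block is eliminated (Rk = 0)", call. = FALSE)
  WXSk <- stack_x(params, k)
  WYSk <- stack_y(params, k)
  M <- tcrossprod(WYSk, params$WYk[[k]])                    # (Rs+Rk) x Rk
  gram$XtX[[k]] %*% (WXSk %*% M) - gram$XtY[[k]] %*% t(params$WYk[[k]]) +
    2 * lam[["lambda2"]] * params$WXk[[k]]
}

grad_g_shared_gram <- function(params, gram, lam) {
  if (nrow(params$WYS) == 0L) stop("shared block is eliminated (Rs = 0)", call. = FALSE)
  acc <- matrix(0, nrow(params$WYS), ncol(params$WYS))
  for (k in seq_len(gram$K)) {
    WXSk <- stack_x(params, k)
    WYSk <- stack_y(params, k)
    acc <- acc + crossprod(params$WXS, gram$XtX[[k]] %*% (WXSk %*% WYSk)) -
      crossprod(params$WXS, gram$XtY[[k]])
  }
  acc + 2 * lam[["lambda4"]] * params$WYS
}

grad_g_cohort_gram <- function(k, params, gram, lam) {
  if (nrow(params$WYk[[k]]) == 0L) stop("cohort block is eliminated (Rk = 0)", call. = FALSE)
  WXSk <- stack_x(params, k)
  WYSk <- stack_y(params, k)
  crossprod(params$WXk[[k]], gram$XtX[[k]] %*% (WXSk %*% WYSk)) -
    crossprod(params$WXk[[k]], gram$XtY[[k]]) +
    2 * lam[["lambda4"]] * params$WYk[[k]]
}

#' Partial gradients of the smooth objective
#'
#' Gradients of the objective without its l1 terms with respect to the shared
#' and cohort blocks; these drive the prox-linear updates.
#'
#' @inheritParams mtfr_objective
#' @param k Cohort index.
#' @return A matrix shaped like the corresponding block.
#' @name mtfr_gradients
NULL

#' @rdname mtfr_gradients
#' @export
grad_h_shared <- function(params, data, lambda) {
  grad_h_shared_gram(params, precompute_gram(data), as_penalty(lambda))
}

#' @rdname mtfr_gradients
#' @export
grad_h_cohort <- function(k, params, data, lambda) {
  grad_h_cohort_gram(k, params, precompute_gram(data), as_penalty(lambda))
}

#' @rdname mtfr_gradients
#' @export
grad_g_shared <- function(params, data, lambda) {
  grad_g_shared_gram(params, precompute_gram(data), as_penalty(lambda))
}

#' @rdname mtfr_gradients
#' @export
grad_g_cohort <- function(k, params, data, lambda) {
  grad_g_cohort_gram(k, params, precompute_gram(data), as_penalty(lambda))
}

## ---- step-size multipliers ------------------------------------------------

MULTIPLIER_FLOOR <- 1e-8

step_multipliers_gram <- function(params, gram, lam,
                                  form = c("lipschitz", "printed")) {
  form <- match.arg(form)
  l2 <- lam[["lambda2"]]
  l4 <- lam[["lambda4"]]
  K <- gram$K
  if (form == "lipschitz") {
    # exact Lipschitz constants of each block-partial gradient (others fixed):
    # the WXS-dependent part of grad_h_shared is (sum_k Xk'Xk) WXS (WYS WYS'),
    # a linear map with operator norm ||sum_k Xk'Xk||_2 * ||WYS||_2^2, etc.
    alpha_s <- gram$XtX_sum_norm * spectral_norm(params$WYS)^2 + 2 * l2
    alpha_k <- vapply(seq_len(K), function(k) {
      gram$XtX_norm[k] * spectral_norm(params$WYk[[k]])^2 + 2 * l2
    }, numeric(1L))
    beta_s <- if (ncol(params$WXS) > 0L) {
      spectral_norm(crossprod(params$WXS, gram$XtX_sum %*% params$WXS)) + 2 * l4
    } else {
      2 * l4
    }
    beta_k <- vapply(seq_len(K), function(k) {
      if (ncol(params$WXk[[k]]) == 0L) return(2 * l4)
      spectral_norm(crossprod(params$WXk[[k]], gram$XtX[[k]] %*% params$WXk[[k]])) + 2 * l4
    }, numeric(1L))
  } else {
    # closest dimensionally valid reading of the published multiplier
    # formulas; offers no descent guarantee and is kept for comparison only
    alpha_s <- sum(vapply(seq_len(K), function(k) {
      frob(gram$XtX[[k]] %*% params$WXk[[k]]) *
        frob(tcrossprod(stack_y(params, k), params$WYS))
    }, numeric(1L))) + 2 * l2
    alpha_k <- vapply(seq_len(K), function(k) {
      frob(gram$XtX[[k]] %*% params$WXS) *
        frob(tcrossprod(stack_y(params, k), params$WYk[[k]])) + 2 * l2
    }, numeric(1L))
    beta_s <- sum(vapply(seq_len(K), function(k) {
      frob(crossprod(params$WXS, gram$XtX[[k]] %*% (stack_x(params, k) %*% stack_y(params, k))))
    }, numeric(1L))) + 2 * l4
    beta_k <- vapply(seq_len(K), function(k) {
      frob(crossprod(params$WXk[[k]], gram$XtX[[k]] %*% (stack_x(params, k) %*% stack_y(params, k)))) + 2 * l4
    }, numeric(1L))
  }
  list(alpha_s = max(alpha_s, MULTIPLIER_FLOOR),
       alpha_k = pmax(alpha_k, MULTIPLIER_FLOOR),
       beta_s = max(beta_s, MULTIPLIER_FLOOR),
       beta_k = pmax(beta_k, MULTIPLIER_FLOOR))
}

#' Step-size multipliers for the prox-linear updates
#'
#' Returns one multiplier per parameter block, each at least the Lipschitz
#' constant of that block's partial gradient (with the other blocks held
#' fixed), so a prox step of size `1/multiplier` cannot increase the
#' objective. A floor of `1e-8` guards the all-zero cold-start case.
#'
#' @inheritParams mtfr_objective
#' @param form `"lipschitz"` (default) uses exact spectral-norm constants;
#'   `"printed"` uses Frobenius-product surrogates retained for comparison.
#' @return List with `alpha_s`, `alpha_k` (length K), `beta_s`, `beta_k`.
#' @export
step_multipliers <- function(params, data, lambda, form = c("lipschitz", "printed")) {
  step_multipliers_gram(params, precompute_gram(data), as_penalty(lambda), form)
}

#' One prox-linear block update
#'
#' `S_{l1/multiplier}(block - grad/multiplier)`: a gradient step on the smooth
#' part followed by soft-thresholding, the proximal map of the l1 penalty at
#' step size `1/multiplier`. With `l1 = 0` it reduces to a plain gradient
#' step.
#'
#' @param block Current block value (matrix).
#' @param grad Gradient of the smooth objective at `block` (same shape).
#' @param multiplier Positive step-size multiplier.
#' @param l1 Non-negative l1 penalty weight on this block.
#' @return Updated block.
#' @export
prox_update_block <- function(block, grad, multiplier, l1) {
  if (!is.finite(multiplier) || multiplier <= 0) {
    stop("`multiplier` must be positive", call. = FALSE)
  }
  if (l1 < 0) stop("`l1` must be non-negative", call. = FALSE)
  stopifnot(identical(dim(block), dim(grad)))
  soft_threshold(block - grad / multiplier, l1 / multiplier)
}
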