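test_that("soft thresholding shrinks toward zero and rejects negative thresholds", {
  expect_equal(soft_threshold(5, 2), 3)
  expect_equal(soft_threshold(-1, 2), 0)
  expect_equal(soft_threshold(-5, 2), -3)
  v <- matrix(c(-3, 0.5, 0, 2), 2)
  expect_equal(soft_threshold(v, 0), v)
  expect_equal(soft_threshold(v, 1), matrix(c(-2, 0, 0, 1), 2))
  expect_error(soft_threshold(1, -0.1), "non-negative")
})

test_that("the objective matches hand-computable cases", {
  # all-zero parameters: only the residual term survives
  inst <- random_instance(seed = 4)
  zero <- mtfr_params(
    WXS = matrix(0, inst$D, 2), WXk = list(matrix(0, inst$D, 2), matrix(0, inst$D, 2)),
    WYS = matrix(0, 2, inst$T), WYk = list(matrix(0, 2, inst$T), matrix(0, 2, inst$T))
  )
  expect_equal(mtfr_objective(zero, inst$data, penalty_weights(3, 4, 5, 6)),
               0.5 * sum(sapply(inst$data$Y, function(y) sum(y^2))))

  # K=1 identity case with a single unit residual entry
  data1 <- list(X = list(diag(2)), Y = list(diag(2)))
  p1 <- mtfr_params(WXS = matrix(0, 2, 0), WXk = list(matrix(c(1, 0), 2, 1)),
                    WYS = matrix(0, 0, 2), WYk = list(matrix(c(1, 0), 1, 2)))
  expect_equal(mtfr_objective(p1, data1, c(0, 0, 0, 0)), 0.5)
})

test_that("the objective agrees with an independent literal expansion", {
  for (seed in 1:5) {
    inst <- random_instance(K = 2, D = 6, T = 8, N = 10, Rs = 2, Rk = 2, seed = seed)
    lam <- penalty_weights(0.3 * seed, 0.11, 0.25, 0.07)
    expect_equal(mtfr_objective(inst$params, inst$data, lam),
                 oracle_objective(inst$params, inst$data, lam),
                 tolerance = 1e-10)
  }
})

test_that("gradients vanish at zero parameters and at exact-fit parameters", {
  inst <- random_instance(seed = 11)
  lam <- penalty_weights(0, 0.7, 0, 0.9)
  zero <- mtfr_params(
    WXS = matrix(0, inst$D, 2), WXk = list(matrix(0, inst$D, 2), matrix(0, inst$D, 2)),
    WYS = matrix(0, 2, inst$T), WYk = list(matrix(0, 2, inst$T), matrix(0, 2, inst$T))
  )
  expect_equal(grad_h_shared(zero, inst$data, lam), matrix(0, inst$D, 2))
  expect_equal(grad_g_cohort(1, zero, inst$data, lam), matrix(0, 2, inst$T))

  # data generated exactly by the parameters, no ridge: all gradients zero
  p <- inst$params
  exact <- inst$data
  exact$Y <- lapply(1:2, function(k) {
    exact$X[[k]] %*% (cbind(p$WXS, p$WXk[[k]]) %*% rbind(p$WYS, p$WYk[[k]]))
  })
  lam0 <- penalty_weights(0, 0, 0, 0)
  expect_equal(grad_h_shared(p, exact, lam0), matrix(0, inst$D, 2), tolerance = 1e-10)
  expect_equal(grad_h_cohort(2, p, exact, lam0), matrix(0, inst$D, 2), tolerance = 1e-10)
  expect_equal(grad_g_shared(p, exact, lam0), matrix(0, 2, inst$T), tolerance = 1e-10)
  expect_equal(grad_g_cohort(1, p, exact, lam0), matrix(0, 2, inst$T), tolerance = 1e-10)
})

test_that("gradients are rejected for eliminated blocks and bad dimensions", {
  inst <- random_instance(seed = 2)
  gone <- mtfr_params(WXS = matrix(0, inst$D, 0),
                      WXk = inst$params$WXk,
                      WYS = matrix(0, 0, inst$T),
                      WYk = inst$params$WYk)
  expect_error(grad_h_shared(gone, inst$data, c(1, 1, 1, 1)), "eliminated")
})

rel_err <- function(a, b) {
  max(abs(a - b)) / max(max(abs(b)), 1e-8)
}

test_that("every partial gradient matches central finite differences", {
  for (seed in 1:20) {
    inst <- random_instance(K = 2, D = sample(3:8, 1), T = sample(4:10, 1),
                            N = 12, Rs = 2, Rk = c(1, 2), seed = seed)
    lam <- penalty_weights(runif(1), runif(1), runif(1), runif(1))
    expect_lt(rel_err(grad_h_shared(inst$params, inst$data, lam),
                      fd_gradient(inst$params, inst$data, lam, "WXS")), 1e-5)
    expect_lt(rel_err(grad_h_cohort(1, inst$params, inst$data, lam),
                      fd_gradient(inst$params, inst$data, lam, "WXk", 1)), 1e-5)
    expect_lt(rel_err(grad_g_shared(inst$params, inst$data, lam),
                      fd_gradient(inst$params, inst$data, lam, "WYS")), 1e-5)
    expect_lt(rel_err(grad_g_cohort(2, inst$params, inst$data, lam),
                      fd_gradient(inst$params, inst$data, lam, "WYk", 2)), 1e-5)
  }
})

test_that("step multipliers reduce to the ridge terms at zero parameters", {
  inst <- random_instance(seed = 3)
  zero <- mtfr_params(
    WXS = matrix(0, inst$D, 2), WXk = list(matrix(0, inst$D, 2), matrix(0, inst$D, 2)),
    WYS = matrix(0, 2, inst$T), WYk = list(matrix(0, 2, inst$T), matrix(0, 2, inst$T))
  )
  m1 <- step_multipliers(zero, inst$data, penalty_weights(1, 5, 1, 0.1))
  expect_equal(m1$alpha_k, c(10, 10))
  expect_equal(m1$alpha_s, 10)
  m2 <- step_multipliers(zero, inst$data, penalty_weights(1, 0.1, 1, 3))
  expect_equal(m2$beta_s, 6)
  expect_equal(m2$beta_k, c(6, 6))
  # all-zero lambda hits the positivity floor instead of zero
  m3 <- step_multipliers(zero, inst$data, penalty_weights(0, 0, 0, 0))
  expect_gt(m3$alpha_s, 0)
  expect_gt(min(m3$beta_k), 0)
})

test_that("multipliers dominate an empirically estimated local Lipschitz constant", {
  for (seed in 1:10) {
    inst <- random_instance(K = 2, D = 5, T = 6, N = 10, Rs = 2, Rk = 1, seed = seed)
    lam <- penalty_weights(0.2, 0.3, 0.2, 0.4)
    mult <- step_multipliers(inst$params, inst$data, lam)
    # perturb WXS randomly and compare gradient change to parameter change
    set.seed(seed + 500)
    for (rep in 1:5) {
      delta <- matrix(rnorm(inst$D * 2, sd = 0.1), inst$D, 2)
      p2 <- inst$params
      p2$WXS <- p2$WXS + delta
      g1 <- grad_h_shared(inst$params, inst$data, lam)
      g2 <- grad_h_shared(p2, inst$data, lam)
      expect_lte(sqrt(sum((g2 - g1)^2)), mult$alpha_s * sqrt(sum(delta^2)) * (1 + 1e-8))
    }
  }
})

test_that("one prox-linear round never increases the objective, a halved step can", {
  any_violation_halved <- FALSE
  for (seed in 1:20) {
    inst <- random_instance(K = 2, D = 6, T = 8, N = 12, Rs = 2, Rk = 2,
                            seed = seed, scale = 1)
    lam <- penalty_weights(0.5, 0.2, 0.5, 0.2)
    f0 <- mtfr_objective(inst$params, inst$data, lam)
    mult <- step_multipliers(inst$params, inst$data, lam)
    # descent step on the shared X block with the returned multiplier
    g <- grad_h_shared(inst$params, inst$data, lam)
    p_ok <- inst$params
    p_ok$WXS <- prox_update_block(p_ok$WXS, g, mult$alpha_s, lam[["lambda1"]])
    expect_lte(mtfr_objective(p_ok, inst$data, lam), f0 + 1e-10 * (1 + f0))
    # the same step with the multiplier cut far below the Lipschitz bound
    p_bad <- inst$params
    p_bad$WXS <- prox_update_block(p_bad$WXS, g, mult$alpha_s / 50, lam[["lambda1"]])
    if (mtfr_objective(p_bad, inst$data, lam) > f0 + 1e-10 * (1 + f0)) {
      any_violation_halved <- TRUE
    }
  }
  expect_true(any_violation_halved)
})

test_that("prox updates solve the scalar prox problem and handle edge cases", {
  expect_equal(prox_update_block(matrix(1), matrix(0.5), 1, 0.2), matrix(0.3))
  b <- matrix(c(1, -2, 0.5, 3), 2)
  g <- matrix(c(0.2, 0.1, -0.3, 0), 2)
  expect_equal(prox_update_block(b, g, 2, 0), b - g / 2)
  expect_error(prox_update_block(b, g, 0, 1), "positive")

  # brute-force 1-D oracle: argmin over a dense grid of the prox objective
  set.seed(99)
  grid <- seq(-6, 6, by = 1e-4)
  for (i in 1:100) {
    w0 <- runif(1, -2, 2)
    gr <- runif(1, -2, 2)
    mult <- runif(1, 0.5, 3)
    l1 <- runif(1, 0, 1.5)
    got <- prox_update_block(matrix(w0), matrix(gr), mult, l1)[1, 1]
    z <- w0 - gr / mult
    vals <- l1 * abs(grid) + mult / 2 * (grid - z)^2
    expect_lt(abs(got - grid[which.min(vals)]), 1e-4 + 1e-8)
  }
})
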