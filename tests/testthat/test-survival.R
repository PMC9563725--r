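test_that("2-means separates clear groups and labels deterministically", {
  # two Gaussian blobs 10 sd apart: membership must be recovered exactly
  for (seed in 1:20) {
    set.seed(seed)
    n <- 30
    expr <- rbind(matrix(rnorm(n * 3, mean = 0), n, 3),
                  matrix(rnorm(n * 3, mean = 10), n, 3))
    rownames(expr) <- paste0("p", seq_len(2 * n))
    labels <- cluster_patients(expr, seed = seed)
    expect_equal(unname(labels), rep(c(0L, 1L), each = n))
  }

  # 4 points in two obvious pairs
  expr4 <- matrix(c(-1, 0, -1.1, 0, 1, 0, 1.1, 0), 4, 2, byrow = TRUE,
                  dimnames = list(paste0("p", 1:4), NULL))
  lab4 <- cluster_patients(expr4, seed = 1)
  expect_equal(unname(lab4), c(0L, 0L, 1L, 1L))

  expect_identical(cluster_patients(expr4, seed = 9), cluster_patients(expr4, seed = 9))
  expect_error(cluster_patients(expr4[1:3, ], seed = 1), "4 patients")
  same <- matrix(1, 5, 2, dimnames = list(paste0("p", 1:5), NULL))
  expect_error(cluster_patients(same, seed = 1), "identical")
})

test_that("the log-rank statistic matches a hand-built risk-table computation", {
  set.seed(42)
  n <- 20
  time <- round(rexp(n, 1 / 200)) + 1
  event <- rbinom(n, 1, 0.7)
  group <- rep(c(0L, 1L), each = n / 2)
  clinical <- tibble::tibble(patient_id = paste0("p", 1:n), time_days = time,
                             event = event)
  labels <- setNames(group, clinical$patient_id)
  got <- logrank_test(labels, clinical)
  want <- oracle_logrank(time, event, group)
  expect_equal(got$statistic, want$statistic, tolerance = 1e-8)
  expect_equal(got$p_value, want$p_value, tolerance = 1e-8)
})

test_that("log-rank inputs are validated", {
  clinical <- tibble::tibble(patient_id = c("p1", "p2", "p3", "p4"),
                             time_days = c(10, 20, 30, 40), event = c(1, 0, 1, 1))
  labels <- setNames(c(0L, 1L, 0L, 1L), c("p1", "p2", "px", "p4"))
  expect_error(logrank_test(labels, clinical), "px")
  one_group <- setNames(c(0L, 0L), c("p1", "p2"))
  expect_error(logrank_test(one_group, clinical), "non-empty")
})

simulated_filter_setup <- function(effect_cohorts, seed = 1) {
  # two cohorts; one tissue module whose selected mRNAs carry a survival
  # signal in the cohorts listed in effect_cohorts
  sim <- simulate_multitask(K = 2, D = 10, T = 14, N = 120, Rs = 1, Rk = 1,
                            snr = 3, seed = seed)
  fit <- structure(list(params = sim$truth$params,
                        ranks = list(Rs = 1L, Rk = c(1L, 1L)),
                        cohort_names = sim$dataset$cohort_names,
                        mirna_ids = sim$dataset$mirna_ids,
                        mrna_ids = sim$dataset$mrna_ids), class = "mtfr_fit")
  modules <- extract_modules(fit)
  tissue <- modules[modules$scope == "tissue", ]
  sel <- tissue$selected_mrnas[[1]]
  clinical <- lapply(1:2, function(k) {
    score <- rowMeans(sim$dataset$Y[[k]][, sel, drop = FALSE])
    eff <- if (k %in% effect_cohorts) 2.5 else 0
    simulate_survival(setNames(score, rownames(sim$dataset$Y[[k]])),
                      effect = eff, censoring_rate = 0.2, seed = seed + k)
  })
  names(clinical) <- sim$dataset$cohort_names
  list(modules = modules, dataset = sim$dataset, clinical = clinical)
}

test_that("tissue modules need significance in every cohort, cohort modules in their own", {
  both <- simulated_filter_setup(effect_cohorts = c(1, 2), seed = 3)
  res_both <- suppressWarnings(
    survival_filter(both$modules, both$dataset, both$clinical, seed = 5))
  tissue_rows <- res_both[res_both$scope == "tissue", ]
  expect_equal(nrow(tissue_rows), 2)  # tested in each cohort
  expect_true(all(tissue_rows$module_significant))

  one <- simulated_filter_setup(effect_cohorts = 1, seed = 3)
  res_one <- suppressWarnings(
    survival_filter(one$modules, one$dataset, one$clinical, seed = 5))
  t1 <- res_one[res_one$scope == "tissue", ]
  # the conjunction rule: module verdict is the AND of per-cohort verdicts
  expect_equal(unique(t1$module_significant), all(t1$significant))
  expect_false(unique(t1$module_significant))

  # alpha = 1 makes every testable module significant
  res_all <- suppressWarnings(
    survival_filter(both$modules, both$dataset, both$clinical, alpha = 1, seed = 5))
  expect_true(all(res_all$significant))
})

test_that("modules without selected mRNAs are skipped with a warning", {
  s <- simulated_filter_setup(effect_cohorts = c(1, 2), seed = 4)
  m <- s$modules
  m$selected_mrnas[[1]] <- character(0)
  expect_warning(survival_filter(m, s$dataset, s$clinical, seed = 2),
                 "no selected mRNAs")
})

test_that("simulated survival respects censoring settings and effect direction", {
  score <- setNames(rnorm(300), paste0("p", 1:300))
  cl0 <- simulate_survival(score, effect = 0, censoring_rate = 0, seed = 8)
  expect_true(all(cl0$event == 1))
  cl3 <- simulate_survival(score, effect = 0, censoring_rate = 0.4, seed = 8)
  expect_gt(mean(cl3$event == 0), 0.25)
  expect_lt(mean(cl3$event == 0), 0.55)
  # strong positive effect: high scores die sooner
  cl <- simulate_survival(score, effect = 1.5, censoring_rate = 0.1, seed = 9)
  hi <- cl$time_days[score > 1]
  lo <- cl$time_days[score < -1]
  expect_lt(median(hi), median(lo))
})
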