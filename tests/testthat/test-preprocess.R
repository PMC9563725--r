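write_tsv_fixture <- function(df, ext = "tsv") {
  path <- withr::local_tempfile(fileext = paste0(".", ext),
                                .local_envir = parent.frame())
  utils::write.table(df, path, sep = if (ext == "csv") "," else "\t",
                     quote = FALSE, row.names = FALSE)
  path
}

test_that("expression matrices parse from TSV and CSV with either orientation", {
  df <- data.frame(sample = c("s1", "s2", "s3"), f1 = c(0, 2, 4), f2 = c(1, 3, 5))
  m <- read_expression_matrix(write_tsv_fixture(df))
  expect_s3_class(m, "expression_matrix")
  expect_equal(dim(m), c(3L, 2L))
  expect_equal(m$stage, "raw")
  expect_equal(m$values["s2", "f2"], 3)

  mc <- read_expression_matrix(write_tsv_fixture(df, "csv"))
  expect_equal(mc$values, m$values)

  tdf <- data.frame(feature = c("f1", "f2"), s1 = c(0, 1), s2 = c(2, 3), s3 = c(4, 5))
  mt <- read_expression_matrix(write_tsv_fixture(tdf), orientation = "features_in_rows")
  expect_equal(mt$values, m$values)
})

test_that("malformed expression files are rejected with located errors", {
  dup <- data.frame(sample = c("s1", "s1"), f1 = c(1, 2))
  expect_error(read_expression_matrix(write_tsv_fixture(dup)), "duplicate sample")

  dupf <- data.frame(sample = c("s1", "s2"), f1 = c(1, 2), f1 = c(3, 4),
                     check.names = FALSE)
  expect_error(read_expression_matrix(write_tsv_fixture(dupf)), "duplicate feature")

  bad <- data.frame(sample = c("s1", "s2"), f1 = c("1", "oops"), f2 = c(1, 2))
  expect_error(read_expression_matrix(write_tsv_fixture(bad)), "non-numeric.*oops|oops.*non-numeric")

  neg <- data.frame(sample = c("s1", "s2"), f1 = c(1, -3))
  expect_error(read_expression_matrix(write_tsv_fixture(neg)), "negative")

  expect_error(read_expression_matrix("/nonexistent/file.tsv"), "not found")
})

raw_em <- function(values) {
  if (is.null(rownames(values))) rownames(values) <- paste0("s", seq_len(nrow(values)))
  if (is.null(colnames(values))) colnames(values) <- paste0("f", seq_len(ncol(values)))
  expression_matrix(values, stage = "raw")
}

test_that("expression filter keeps features present in at least half the samples", {
  v <- cbind(a = c(1, 2, 0, 0, 0),   # 2/5 expressed -> dropped
             b = c(1, 2, 3, 0, 0),   # 3/5 -> kept
             c = c(1, 1, 1, 1, 0))   # 4/5 -> kept
  out <- filter_low_expression(raw_em(v))
  expect_equal(colnames(out$values), c("b", "c"))

  # exactly at the threshold is kept ("less than" is the discard rule)
  v2 <- cbind(a = c(1, 2, 0, 0), b = c(1, 1, 1, 1))
  out2 <- filter_low_expression(raw_em(v2))
  expect_equal(colnames(out2$values), c("a", "b"))

  # idempotence
  expect_equal(filter_low_expression(out)$values, out$values)

  expect_error(filter_low_expression(raw_em(cbind(a = c(0, 0, 1)))), "no feature")
})

test_that("log2 transform maps counts as expected and guards bad pseudocounts", {
  m <- raw_em(cbind(a = c(0, 3, 15)))
  out <- log2_transform(m)
  expect_equal(unname(out$values[, 1]), c(0, 2, 4))
  expect_equal(out$stage, "log2")
  expect_error(log2_transform(m, pseudocount = 0), "pseudocount")
  expect_error(log2_transform(out), "raw")
})

test_that("column standardization centers, scales, drops constants, and is idempotent", {
  v <- cbind(a = c(1, 2, 3), b = c(5, 5, 5), c = c(2, 4, 9))
  rownames(v) <- paste0("s", 1:3)
  m <- expression_matrix(v, stage = "log2")
  expect_warning(out <- standardize_columns(m), "zero-variance")
  expect_equal(colnames(out$values), c("a", "c"))
  expect_equal(unname(out$values[, "a"]), c(-1, 0, 1))
  expect_true(all(abs(colMeans(out$values)) < 1e-8))
  expect_true(all(abs(apply(out$values, 2, sd) - 1) < 1e-8))

  again <- standardize_columns(out)
  expect_equal(again$values, out$values, tolerance = 1e-12)

  expect_error(standardize_columns(raw_em(cbind(a = 1:3))), "raw")
})

make_cohort <- function(samples, mirnas, mrnas, seed) {
  set.seed(seed)
  x <- matrix(rpois(length(samples) * length(mirnas), 40) + 1,
              length(samples), length(mirnas),
              dimnames = list(samples, mirnas))
  y <- matrix(rpois(length(samples) * length(mrnas), 40) + 1,
              length(samples), length(mrnas),
              dimnames = list(samples, mrnas))
  list(x = log2_transform(expression_matrix(x, "raw")),
       y = log2_transform(expression_matrix(y, "raw")))
}

test_that("cohort alignment intersects samples within and features across cohorts", {
  a <- make_cohort(paste0("a", 1:8), c("m1", "m2", "m3"), c("g1", "g2", "g3"), 1)
  b <- make_cohort(paste0("b", 1:9), c("m2", "m3", "m4"), c("g2", "g3", "g4"), 2)
  ds <- align_cohorts(list(a$x, b$x), list(a$y, b$y), c("A", "B"))
  expect_equal(ds$mirna_ids, c("m2", "m3"))
  expect_equal(ds$mrna_ids, c("g2", "g3"))
  expect_equal(unname(ds$n_samples), c(8L, 9L))

  # mismatched samples between the two matrices of one cohort
  set.seed(3)
  cx <- expression_matrix(matrix(rpois(12, 30) + 1, 4, 3,
        dimnames = list(c("s1", "s2", "s3", "s4"), c("m1", "m2", "m3"))), "raw")
  cy <- expression_matrix(matrix(rpois(12, 30) + 1, 4, 3,
        dimnames = list(c("s2", "s3", "s4", "s5"), c("g1", "g2", "g3"))), "raw")
  ds2 <- align_cohorts(list(log2_transform(cx)), list(log2_transform(cy)), "C")
  expect_equal(rownames(ds2$X[[1]]), c("s2", "s3", "s4"))
  expect_identical(rownames(ds2$X[[1]]), rownames(ds2$Y[[1]]))

  disj <- make_cohort(paste0("d", 1:5), c("zz1", "zz2"), c("g1"), 4)
  expect_error(align_cohorts(list(a$x, disj$x), list(a$y, disj$y), c("A", "D")),
               "empty feature intersection")
})

test_that("the full preprocessing pipeline yields standardized, aligned cohorts", {
  a <- make_cohort(paste0("a", 1:10), paste0("m", 1:6), paste0("g", 1:8), 5)
  b <- make_cohort(paste0("b", 1:12), paste0("m", 1:6), paste0("g", 1:8), 6)
  raw_a <- expression_matrix(2^a$x$values - 1, "raw")
  raw_b <- expression_matrix(2^b$x$values - 1, "raw")
  raw_ya <- expression_matrix(2^a$y$values - 1, "raw")
  raw_yb <- expression_matrix(2^b$y$values - 1, "raw")
  ds <- preprocess_cohorts(list(raw_a, raw_b), list(raw_ya, raw_yb), c("A", "B"))
  for (k in 1:2) {
    for (mat in list(ds$X[[k]], ds$Y[[k]])) {
      expect_true(all(abs(colMeans(mat)) < 1e-8))
      expect_true(all(abs(apply(mat, 2, sd) - 1) < 1e-8))
    }
  }
  expect_identical(colnames(ds$X[[1]]), colnames(ds$X[[2]]))
  expect_identical(colnames(ds$Y[[1]]), colnames(ds$Y[[2]]))
})

test_that("dataset serialization round-trips through TSV plus manifest", {
  sim <- simulate_multitask(K = 2, D = 6, T = 8, N = 12, Rs = 1, Rk = 1, seed = 9)
  dir <- withr::local_tempdir()
  write_multitask_dataset(sim$dataset, dir)
  expect_true(file.exists(file.path(dir, "manifest.json")))
  back <- read_multitask_dataset(dir)
  expect_equal(back$cohort_names, sim$dataset$cohort_names)
  expect_equal(back$X[[1]], sim$dataset$X[[1]], tolerance = 1e-12)
  expect_equal(back$Y[[2]], sim$dataset$Y[[2]], tolerance = 1e-12)
})

test_that("clinical tables and TF lists are read and validated", {
  cl <- data.frame(patient_id = c("p1", "p2"), time_days = c(10, 20), event = c(0, 1))
  path <- write_tsv_fixture(cl)
  out <- read_clinical_table(path)
  expect_equal(out$time_days, c(10, 20))

  bad <- data.frame(patient_id = c("p1", "p2"), time_days = c(-1, 20), event = c(0, 1))
  expect_error(read_clinical_table(write_tsv_fixture(bad)), "positive")

  tfp <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("TP53", "  ", "MYC", "TP53"), tfp)
  expect_equal(read_tf_list(tfp), c("TP53", "MYC"))
})
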