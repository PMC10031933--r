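make_stratum <- function(case, control, genes = sprintf("g%d", seq_len(nrow(case)))) {
  rownames(case) <- genes
  rownames(control) <- genes
  expression_stratum(case, control)
}

test_that("t-test stage handles identity, separation and degenerate arms", {
  set.seed(1)
  x <- matrix(rnorm(40), 8, 5)
  same <- make_stratum(x, x)
  expect_equal(unname(gene_pvalues(same)), rep(1, 8), tolerance = 1e-12)
  # perfect separation drives p toward 0
  sep <- make_stratum(
    rbind(c(10, 10, 10.001), matrix(rnorm(9), 3)),
    rbind(c(0, 0, 0.001), matrix(rnorm(9), 3))
  )
  expect_lt(gene_pvalues(sep)[1], 1e-6)
  # zero variance both arms, equal means -> p = 1 with warning
  flat <- make_stratum(matrix(5, 2, 3), matrix(5, 2, 3))
  expect_warning(pf <- gene_pvalues(flat), "zero variance")
  expect_equal(unname(pf), c(1, 1))
  # < 2 samples in an arm rejects the stratum at construction
  expect_error(
    make_stratum(matrix(1:2, 2, 1), matrix(rnorm(6), 2, 3)),
    ">= 2 samples"
  )
})

test_that("welch matches t.test and pooled matches var.equal = TRUE", {
  set.seed(42)
  case <- matrix(rnorm(60, mean = 0.4), 10, 6)
  control <- matrix(rnorm(50), 10, 5)
  st <- make_stratum(case, control)
  for (g in 1:10) {
    expect_equal(
      unname(gene_pvalues(st)[g]),
      t.test(case[g, ], control[g, ])$p.value,
      tolerance = 1e-12
    )
    expect_equal(
      unname(gene_pvalues(st, var_equal = TRUE)[g]),
      t.test(case[g, ], control[g, ], var.equal = TRUE)$p.value,
      tolerance = 1e-12
    )
  }
})

test_that("type-I error is calibrated under the null", {
  set.seed(2024)
  st <- make_stratum(matrix(rnorm(10000), 2000, 5), matrix(rnorm(10000), 2000, 5))
  p <- gene_pvalues(st)
  expect_lt(abs(mean(p < 0.05) - 0.05), 0.02)
})

test_that("Fisher combination follows the chi-square upper tail", {
  # single stratum: identity (chi-square with 2 df round-trip)
  p <- c(0.01, 0.2, 0.5, 0.99)
  expect_equal(unname(fisher_combine(matrix(p, 4, 1))), p, tolerance = 1e-12)
  # printed example: p = (0.5, 0.5) -> S = 2.7726, df 4
  S <- -2 * (log(0.5) + log(0.5))
  combined <- fisher_combine(matrix(c(0.5, 0.5), 1, 2))
  expect_equal(unname(combined), oracle_chisq4_surv(S), tolerance = 1e-10)
  # p = 1 contributes nothing to the statistic
  with1 <- fisher_combine(matrix(c(0.3, 1, 0.3, 0.999999999999), 2, 2, byrow = TRUE))
  expect_equal(with1[1], with1[2], tolerance = 1e-9)
  # missing strata reduce the degrees of freedom; all-missing gives NA
  pm <- matrix(c(0.1, NA, NA, NA), 2, 2)
  out <- fisher_combine(pm)
  expect_equal(unname(out[1]), 0.1, tolerance = 1e-12)
  expect_true(is.na(out[2]))
  # clipping keeps extreme p-values finite
  expect_true(is.finite(fisher_combine(matrix(c(0, 1e-320), 1, 2))))
})

test_that("Z transform is the upper-tail quantile and strictly monotone", {
  expect_equal(unname(p_to_z(0.5)), 0)
  expect_equal(unname(p_to_z(0.05)), oracle_upper_quantile(0.05), tolerance = 1e-8)
  expect_equal(unname(p_to_z(0.9)), oracle_upper_quantile(0.9), tolerance = 1e-8)
  set.seed(7)
  p <- sort(runif(100, 1e-12, 1 - 1e-12))
  z <- p_to_z(p)
  expect_true(all(diff(z) < 0)) # smaller p => larger Z
  expect_true(all(is.finite(p_to_z(c(0, 1)))))
})

test_that("pipeline is deterministic and null Z-scores are standard normal", {
  set.seed(99)
  strata <- lapply(1:3, function(i) {
    make_stratum(matrix(rnorm(10000), 2000, 5), matrix(rnorm(10000), 2000, 5))
  })
  z1 <- compute_initial_scores(strata)
  z2 <- compute_initial_scores(strata)
  expect_identical(z1, z2)
  # calibration on a single stratum: Welch's conservativeness compounds
  # under Fisher combination, so the near-normality claim is per stratum
  znull <- compute_initial_scores(strata[[1]])
  expect_lt(abs(mean(znull)), 0.05)
  expect_gt(sd(znull), 0.9)
  expect_lt(sd(znull), 1.1)
  # no-combine mode emits a per-stratum Z matrix
  zm <- compute_initial_scores(strata, combine = FALSE)
  expect_equal(dim(zm), c(2000L, 3L))
  expect_equal(zm[, 1], p_to_z(gene_pvalues(strata[[1]])))
})

test_that("expression strata read from TSV files", {
  genes <- c("tp53", "kras", "egfr")
  expr <- matrix(rnorm(18), 3, 6,
    dimnames = list(genes, sprintf("s%d", 1:6))
  )
  expr_path <- withr::local_tempfile()
  write.table(data.frame(gene = genes, expr, check.names = FALSE),
    expr_path,
    sep = "\t", quote = FALSE, row.names = FALSE
  )
  meta_path <- withr::local_tempfile(lines = c(
    "sample\tarm",
    paste0("s", 1:3, "\tcase"),
    paste0("s", 4:6, "\tcontrol")
  ))
  st <- read_expression_stratum(expr_path, meta_path, label = "toy")
  expect_equal(dim(st$case), c(3L, 3L))
  expect_equal(unname(st$control[, 1]), unname(expr[, 4]))
  expect_equal(rownames(st$case), genes)
})
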