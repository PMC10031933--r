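test_that("ground-truth splits respect the ratio, determinism and network filter", {
  net <- rand_network(20, 0.2, 1)
  truth10 <- network_nodes(net)[1:10]
  splits <- split_ground_truth(truth10, net, train_fraction = 0.2, n_trials = 5, seed = 3)
  for (sp in splits) {
    expect_length(sp$train, 2L)
    expect_length(sp$test, 8L)
    expect_length(intersect(sp$train, sp$test), 0L)
    expect_setequal(c(sp$train, sp$test), truth10)
  }
  again <- split_ground_truth(truth10, net, 0.2, 5, seed = 3)
  expect_identical(splits, again)
  # genes not in the network are removed first
  expect_message(
    sp2 <- split_ground_truth(c(truth10, "ghost"), net, 0.2, 1, seed = 1),
    "not available"
  )
  expect_false("ghost" %in% c(sp2[[1]]$train, sp2[[1]]$test))
  expect_error(split_ground_truth("ghost", net, 0.2, 1, 1), "disjoint")
  # round-half-to-even: 0.5 * 5 -> train 2, test 3
  sp5 <- split_ground_truth(truth10[1:5], net, 0.5, 1, seed = 1)[[1]]
  expect_length(sp5$train, 2L)
  expect_length(sp5$test, 3L)
})

test_that("rankings sort by score with lexicographic tie-break and exclusion", {
  expect_equal(rank_genes(c(a = 2, b = 1, c = 3)), c("c", "a", "b"))
  expect_equal(rank_genes(c(a = 2, b = 1, c = 3), exclude = "c"), c("a", "b"))
  expect_equal(rank_genes(c(b = 1, a = 1)), c("a", "b"))
  # invariance to positive affine transforms of the scores
  set.seed(4)
  s <- setNames(rnorm(50), sprintf("g%02d", 1:50))
  expect_identical(rank_genes(s), rank_genes(3 * s + 10))
})

test_that("average precision and precision at k match hand values and the oracle", {
  expect_equal(average_precision(c("a", "x", "b", "y"), c("a", "b")), 5 / 6)
  expect_equal(average_precision(c("a", "b", "x"), c("a", "b")), 1)
  expect_equal(average_precision(letters[1:5], c("zz", "a")), 1 / 2)
  expect_equal(precision_at_k(c("a", "x", "b", "y"), c("a", "b"), 1), 1)
  expect_equal(precision_at_k(c("a", "x", "b", "y"), c("a", "b"), 4), 0.5)
  expect_equal(precision_at_k(letters[1:5], "zz", 5), 0)
  expect_error(precision_at_k(letters[1:3], "a", 4), "3 items")
  expect_error(average_precision(letters, character()), "empty")
  expect_error(average_precision(c("a", "a"), "a"), "duplicates")
  set.seed(11)
  for (i in 1:200) {
    universe <- sprintf("g%03d", 1:60)
    ranking <- sample(universe, sample(20:60, 1))
    relevant <- sample(universe, sample(1:15, 1))
    expect_equal(average_precision(ranking, relevant),
      oracle_avep(ranking, relevant),
      tolerance = 1e-12
    )
    k <- sample(seq_along(ranking), 1)
    expect_equal(precision_at_k(ranking, relevant, k),
      oracle_prec_k(ranking, relevant, k),
      tolerance = 1e-12
    )
  }
})

test_that("AveP is 1 exactly when all relevant items lead the ranking", {
  set.seed(5)
  for (i in 1:20) {
    universe <- sprintf("g%02d", 1:30)
    relevant <- sample(universe, 5)
    perfect <- c(sample(relevant), sample(setdiff(universe, relevant)))
    expect_equal(average_precision(perfect, relevant), 1)
    imperfect <- c(perfect[-1], perfect[1])
    expect_lt(average_precision(imperfect, relevant), 1)
  }
})

fake_report <- function(base, delta, n = 20, metric = "AveP") {
  rbind(
    data.frame(trial = 1:n, method = "rwr", metric = metric, value = base),
    data.frame(trial = 1:n, method = "pwn", metric = metric, value = base + delta)
  )
}

test_that("paired comparisons guard ties, detect shifts and match the t oracle", {
  set.seed(8)
  base <- runif(20, 0.1, 0.3)
  tie <- compare_methods(fake_report(base, 0), "rwr", "pwn")
  expect_equal(tie$p, 1)
  shift <- compare_methods(fake_report(base, 0.01), "rwr", "pwn")
  expect_lt(shift$p, 1e-4)
  # independent t CDF (numerical integration) on noisy differences
  d <- rnorm(20, 0.02, 0.05)
  rep2 <- fake_report(base, d)
  got <- compare_methods(rep2, "rwr", "pwn")$p
  tstat <- mean(d) / (sd(d) / sqrt(length(d)))
  expect_equal(got, oracle_t_upper(tstat, length(d) - 1), tolerance = 1e-10)
  # BH adjustment across the metric family
  rep3 <- rbind(fake_report(base, 0.01), fake_report(base, 0, metric = "Prec@10"))
  out <- compare_methods(rep3, "rwr", "pwn")
  expect_equal(out$p_adjusted, p.adjust(out$p, method = "BH"))
  # mismatched trials error out
  broken <- fake_report(base, 0.01)
  broken <- broken[!(broken$method == "pwn" & broken$trial == 20), ]
  expect_error(compare_methods(broken, "rwr", "pwn"), "trial sets differ")
})

test_that("benchmark harness produces a consistent metric report", {
  inst <- planted_module_network(synthetic_spec(
    background_nodes = 80, n_modules = 3,
    clique_size = 5, n_hubs = 2, hub_degree = 8, n_truth = 15, seed = 5
  ))
  report <- suppressWarnings(suppressMessages(run_benchmark(
    inst$network, inst$truth, inst$scores,
    methods = c("pwn", "rwr"), n_trials = 3, seed = 10, ks = c(10)
  )))
  expect_s3_class(report, "metric_report")
  expect_setequal(unique(report$metric), c("AveP", "Prec@10"))
  expect_equal(nrow(report), 3 * 2 * 2)
  expect_true(all(report$value >= 0 & report$value <= 1))
  agg <- summarize_report(report)
  expect_setequal(names(agg), c("method", "metric", "mean", "sd"))
  cmp <- compare_methods(report, "rwr", "pwn")
  expect_true(all(cmp$p >= 0 & cmp$p <= 1))
  tsv <- withr::local_tempfile()
  json <- withr::local_tempfile()
  write_metric_report(report, tsv, json)
  expect_equal(nrow(read.delim(tsv)), nrow(report))
  expect_true(jsonlite::validate(paste(readLines(json), collapse = "")))
})
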