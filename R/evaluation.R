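# Benchmark harness: repeated random train/test splits of a ground-truth
# gene set, ranking metrics (average precision, precision at k), and paired
# one-sided significance tests with Benjamini-Hochberg adjustment across
# method comparisons.

#' Repeated train/test splits of a ground-truth gene set
#'
#' Removes truth genes absent from the network, then draws `n_trials`
#' independent uniform splits: the train part plays the role of prior
#' knowledge, the test part the relevant genes to be uncovered. Train size is
#' `round(train_fraction * m)` (round half to even, as base R rounds). Fully
#' reproducible from `seed`.
#'
#' @param truth Character vector of ground-truth gene ids.
#' @param net A `ppi_network`.
#' @param train_fraction Fraction of the truth used as prior knowledge
#'   (default 0.2, i.e. a 2:8 split).
#' @param n_trials Number of repeated splits (default 30).
#' @param seed Integer seed.
#' @return List of `trial_split` objects with elements `train`, `test`,
#'   `trial`, `seed`.
#' @export
split_ground_truth <- function(truth, net, train_fraction = 0.2,
                               n_trials = 30, seed = 1) {
  stopifnot(train_fraction > 0, train_fraction < 1, n_trials >= 1)
  truth <- unique(as.character(truth))
  dropped <- setdiff(truth, net$nodes)
  if (length(dropped) > 0L) {
    message(
      "split_ground_truth: removing ", length(dropped),
      " truth gene(s) not available in the network"
    )
  }
  truth <- intersect(truth, net$nodes)
  if (length(truth) == 0L) {
    stop("ground truth disjoint from network", call. = FALSE)
  }
  m <- length(truth)
  n_train <- round(train_fraction * m)
  n_train <- max(1L, min(m - 1L, as.integer(n_train)))
  old <- .Random.seed_guard(seed)
  on.exit(old(), add = TRUE)
  lapply(seq_len(n_trials), function(t) {
    train <- sample(truth, n_train)
    structure(
      list(
        train = sort(train),
        test = sort(setdiff(truth, train)),
        trial = t,
        seed = seed
      ),
      class = "trial_split"
    )
  })
}

# Seed scoping helper: sets the seed and returns a restorer for the caller's
# RNG state, so library functions do not clobber user randomness.
.Random.seed_guard <- function(seed) {
  prev <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  set.seed(seed)
  function() {
    if (is.null(prev)) {
      rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", prev, envir = globalenv())
    }
  }
}

#' Rank genes by score
#'
#' Sorts genes by score descending, removing `exclude` (typically the train
#' priors) beforehand. Ties are broken by lexicographic gene id, so rankings
#' are deterministic.
#'
#' @param scores Named numeric vector of gene scores.
#' @param exclude Character vector of gene ids to drop before ranking.
#' @return Character vector of gene ids, best first.
#' @export
rank_genes <- function(scores, exclude = character()) {
  keep <- !(names(scores) %in% exclude)
  s <- scores[keep]
  names(s)[order(-s, names(s))]
}

#' Average precision of a ranking
#'
#' `AveP = sum_k Prec@k * [k-th item relevant] / (total # relevant)`. The
#' denominator counts all relevant items, including any never ranked, so an
#' incomplete ranking is penalized.
#'
#' @param ranking Character vector of ranked gene ids (duplicate-free).
#' @param relevant Non-empty character vector of relevant gene ids.
#' @return AveP in `[0, 1]`.
#' @export
average_precision <- function(ranking, relevant) {
  relevant <- unique(as.character(relevant))
  if (length(relevant) == 0L) {
    stop("average_precision: empty relevant set", call. = FALSE)
  }
  if (anyDuplicated(ranking)) {
    stop("average_precision: ranking contains duplicates", call. = FALSE)
  }
  hit <- ranking %in% relevant
  if (!any(hit)) {
    return(0)
  }
  prec_at_hits <- cumsum(hit)[hit] / seq_along(ranking)[hit]
  sum(prec_at_hits) / length(relevant)
}

#' Precision at k
#'
#' Fraction of the top-`k` ranked items that are relevant.
#'
#' @param ranking Character vector of ranked gene ids, length at least `k`.
#' @param relevant Character vector of relevant gene ids.
#' @param k Positive cutoff.
#' @return Prec@k in `[0, 1]`.
#' @export
precision_at_k <- function(ranking, relevant, k) {
  stopifnot(k >= 1)
  if (length(ranking) < k) {
    stop(sprintf(
      "precision_at_k: ranking has %d items but k = %d", length(ranking), as.integer(k)
    ), call. = FALSE)
  }
  sum(ranking[seq_len(k)] %in% relevant) / k
}

#' Run a multi-method benchmark over repeated splits
#'
#' For each trial split, every method receives the identical prior set (the
#' train genes) and identical initial scores, and is measured against the
#' identical test set; train genes are excluded from the ranking before
#' metric computation (set `exclude_train = FALSE` for the strict-literal
#' mode that keeps them in).
#'
#' @param net A `ppi_network`.
#' @param truth Ground-truth gene ids.
#' @param scores Named numeric vector of initial gene scores `v0`.
#' @param methods Character vector of method ids among `"pwn"`,
#'   `"pwn_no_curvature"`, `"rwr"`, `"rwr_curvature"`.
#' @param beta,gamma,q Hyperparameters (defaults 0.5, 0.5, 0.3).
#' @param train_fraction,n_trials,seed Passed to [split_ground_truth()].
#' @param ks Precision cutoffs; cutoffs exceeding the ranking length are
#'   skipped.
#' @param exclude_train Drop train genes from rankings before scoring.
#' @return A `metric_report` data frame with columns `trial`, `method`,
#'   `metric`, `value`.
#' @export
run_benchmark <- function(net, truth, scores,
                          methods = c("pwn", "rwr"),
                          beta = 0.5, gamma = 0.5, q = 0.3,
                          train_fraction = 0.2, n_trials = 30, seed = 1,
                          ks = c(100, 200), exclude_train = TRUE) {
  splits <- split_ground_truth(truth, net,
    train_fraction = train_fraction,
    n_trials = n_trials, seed = seed
  )
  rows <- list()
  for (sp in splits) {
    for (method in methods) {
      v <- prioritize(net, scores,
        method = method,
        priors = sp$train, beta = beta, gamma = gamma, q = q
      )
      ranking <- rank_genes(v, exclude = if (exclude_train) sp$train else character())
      vals <- c(AveP = average_precision(ranking, sp$test))
      for (k in ks) {
        if (length(ranking) >= k) {
          vals[[sprintf("Prec@%d", k)]] <- precision_at_k(ranking, sp$test, k)
        }
      }
      rows[[length(rows) + 1L]] <- data.frame(
        trial = sp$trial, method = method,
        metric = names(vals), value = as.numeric(vals),
        stringsAsFactors = FALSE
      )
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("metric_report", "data.frame")
  out
}

#' Aggregate a metric report
#' @param report A `metric_report` from [run_benchmark()].
#' @return Data frame of per-method, per-metric mean and sd.
#' @export
summarize_report <- function(report) {
  agg <- stats::aggregate(value ~ method + metric, report,
    FUN = function(v) c(mean = mean(v), sd = stats::sd(v))
  )
  data.frame(
    method = agg$method, metric = agg$metric,
    mean = agg$value[, "mean"], sd = agg$value[, "sd"],
    stringsAsFactors = FALSE
  )
}

#' Paired one-sided comparison of two methods
#'
#' For each metric, tests whether `alternative` outperforms `baseline` with a
#' one-sided paired t-test over trials (alternative hypothesis: mean
#' difference > 0), then adjusts the family of per-metric p-values with
#' Benjamini-Hochberg. Identical per-trial values (zero-variance differences)
#' are guarded to p = 1.
#'
#' @param report A `metric_report` covering both methods on the same trials.
#' @param baseline,alternative Method ids present in `report`.
#' @return Data frame with columns `metric`, `p`, `p_adjusted`.
#' @export
compare_methods <- function(report, baseline, alternative) {
  metrics <- unique(report$metric)
  ps <- vapply(metrics, function(m) {
    b <- report[report$method == baseline & report$metric == m, ]
    a <- report[report$method == alternative & report$metric == m, ]
    b <- b[order(b$trial), ]
    a <- a[order(a$trial), ]
    if (!identical(a$trial, b$trial)) {
      stop(sprintf(
        "compare_methods: trial sets differ between '%s' and '%s' for metric %s",
        baseline, alternative, m
      ), call. = FALSE)
    }
    d <- a$value - b$value
    # near-constant differences (relative to their scale) break the t-test
    if (length(d) < 2L ||
      stats::sd(d) <= 1e-10 * max(abs(mean(d)), .Machine$double.eps)) {
      # degenerate paired differences: a constant shift is conclusive
      return(if (mean(d) > 0) 0 else 1)
    }
    stats::t.test(d, alternative = "greater")$p.value
  }, numeric(1))
  data.frame(
    metric = metrics,
    p = as.numeric(ps),
    p_adjusted = stats::p.adjust(ps, method = "BH"),
    stringsAsFactors = FALSE
  )
}

#' Write a metric report as TSV plus a JSON aggregate
#' @param report A `metric_report`.
#' @param tsv_path,json_path Output paths (either may be `NULL` to skip).
#' @return `report`, invisibly.
#' @export
write_metric_report <- function(report, tsv_path = NULL, json_path = NULL) {
  if (!is.null(tsv_path)) {
    utils::write.table(report, tsv_path,
      sep = "\t", quote = FALSE, row.names = FALSE
    )
  }
  if (!is.null(json_path)) {
    jsonlite::write_json(summarize_report(report), json_path,
      auto_unbox = TRUE, digits = NA
    )
  }
  invisible(report)
}
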