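# Initial gene scores from case/control expression matrices: per-gene
# t-tests within each stratum (e.g. cancer type), Fisher combination of the
# per-stratum p-values, and conversion to upper-tail Z-scores
# Z = qnorm(1 - p). High Z marks genes differentially expressed across
# strata; the Z vector is the diffusion input v0.

#' Bundle case/control expression matrices for one stratum
#'
#' @param case,control Numeric matrices, genes x samples, with matching row
#'   names (gene ids) and at least two samples each.
#' @param label Stratum name (e.g. a cancer type).
#' @return An `expression_stratum` object.
#' @export
expression_stratum <- function(case, control, label = "stratum") {
  case <- as.matrix(case)
  control <- as.matrix(control)
  if (is.null(rownames(case)) || is.null(rownames(control))) {
    stop("expression matrices need gene ids as row names", call. = FALSE)
  }
  if (!identical(rownames(case), rownames(control))) {
    stop("case and control matrices must share the same gene list", call. = FALSE)
  }
  if (ncol(case) < 2L || ncol(control) < 2L) {
    stop(sprintf(
      "stratum '%s' rejected: need >= 2 samples per arm (got %d case, %d control)",
      label, ncol(case), ncol(control)
    ), call. = FALSE)
  }
  structure(list(case = case, control = control, label = label),
    class = "expression_stratum"
  )
}

row_vars <- function(x) {
  m <- rowMeans(x)
  rowSums((x - m)^2) / (ncol(x) - 1L)
}

#' Per-gene two-sided t-test p-values for one stratum
#'
#' Welch's unequal-variance t-test by default; set `var_equal = TRUE` for the
#' pooled Student variant. Genes with zero variance in both arms get p = 1
#' (with a warning) when the means are equal, and p = 0 when they differ
#' (perfect separation; downstream clipping keeps logs finite).
#'
#' @param stratum An [expression_stratum()].
#' @param alternative Only `"two_sided"` is supported.
#' @param var_equal Use the pooled-variance Student t-test instead of Welch.
#' @return Named numeric vector of p-values in `[0, 1]`.
#' @export
gene_pvalues <- function(stratum, alternative = "two_sided", var_equal = FALSE) {
  alternative <- match.arg(alternative, "two_sided")
  x <- stratum$case
  y <- stratum$control
  n1 <- ncol(x)
  n2 <- ncol(y)
  m1 <- rowMeans(x)
  m2 <- rowMeans(y)
  v1 <- row_vars(x)
  v2 <- row_vars(y)
  if (var_equal) {
    df <- rep(n1 + n2 - 2, length(m1))
    sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / df
    se2 <- sp2 * (1 / n1 + 1 / n2)
  } else {
    se2 <- v1 / n1 + v2 / n2
    df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  }
  p <- stats::setNames(numeric(length(m1)), rownames(x))
  degenerate <- se2 == 0
  if (any(degenerate)) {
    flat <- degenerate & (m1 == m2)
    if (any(flat)) {
      warning(sprintf(
        "gene_pvalues(%s): %d gene(s) with zero variance and equal means; p set to 1",
        stratum$label, sum(flat)
      ))
    }
    p[degenerate] <- ifelse(m1[degenerate] == m2[degenerate], 1, 0)
  }
  ok <- !degenerate
  tstat <- (m1[ok] - m2[ok]) / sqrt(se2[ok])
  p[ok] <- 2 * stats::pt(abs(tstat), df[ok], lower.tail = FALSE)
  p
}

#' Combine per-stratum p-values with Fisher's method
#'
#' For each gene, `S = -2 sum(log p_s)` over the strata where a p-value is
#' available (p clipped to `[1e-300, 1]` before the log) and the combined
#' p-value is the upper tail of a chi-square with `2 * (#strata used)`
#' degrees of freedom. Genes with no available p-value get `NA`.
#'
#' @param pvals Numeric matrix, genes x strata (a vector is treated as a
#'   single-column matrix); `NA` marks a missing stratum.
#' @return Named numeric vector of combined p-values.
#' @export
fisher_combine <- function(pvals) {
  pvals <- as.matrix(pvals)
  clipped <- pmin(pmax(pvals, 1e-300), 1)
  used <- rowSums(!is.na(pvals))
  S <- rowSums(-2 * log(clipped), na.rm = TRUE)
  out <- stats::pchisq(S, df = 2 * used, lower.tail = FALSE)
  out[used == 0L] <- NA_real_
  stats::setNames(out, rownames(pvals))
}

#' Convert p-values to upper-tail Z-scores
#'
#' `Z = qnorm(1 - p) = -qnorm(p)`: small p-values map to large positive
#' Z-scores. p is clipped to `[1e-15, 1 - 1e-15]` so Z stays finite.
#'
#' @param p Numeric vector of p-values.
#' @return Named numeric vector of Z-scores.
#' @export
p_to_z <- function(p) {
  clipped <- pmin(pmax(p, 1e-15), 1 - 1e-15)
  stats::setNames(stats::qnorm(clipped, lower.tail = FALSE), names(p))
}

#' Initial gene scores from expression strata
#'
#' Runs the scoring pipeline: per-stratum t-tests, Fisher combination across
#' strata, Z transform. With `combine = FALSE` (the multidimensional
#' passthrough mode) the per-stratum Z matrix is returned instead.
#'
#' @param strata List of [expression_stratum()] objects sharing a gene list.
#' @param combine Combine strata with Fisher's method (default) or return a
#'   per-stratum Z matrix.
#' @param var_equal Passed to [gene_pvalues()].
#' @return Named numeric vector of Z-scores (or genes x strata Z matrix).
#' @export
compute_initial_scores <- function(strata, combine = TRUE, var_equal = FALSE) {
  if (inherits(strata, "expression_stratum")) {
    strata <- list(strata)
  }
  genes <- rownames(strata[[1L]]$case)
  pmat <- vapply(
    strata,
    function(s) {
      if (!identical(rownames(s$case), genes)) {
        stop("all strata must share the same gene list", call. = FALSE)
      }
      gene_pvalues(s, var_equal = var_equal)
    },
    numeric(length(genes))
  )
  pmat <- matrix(pmat,
    nrow = length(genes),
    dimnames = list(genes, vapply(strata, `[[`, character(1), "label"))
  )
  if (!combine) {
    z <- apply(pmat, 2L, p_to_z)
    rownames(z) <- genes
    return(z)
  }
  p_to_z(fisher_combine(pmat))
}

#' Read one expression stratum from TSV files
#'
#' @param expr_path Genes x samples TSV with a header of sample ids and gene
#'   ids in the first column.
#' @param meta_path Samples-metadata TSV with columns `sample` and `arm`
#'   (values `case` / `control`).
#' @param label Stratum name.
#' @return An [expression_stratum()].
#' @export
read_expression_stratum <- function(expr_path, meta_path, label = basename(expr_path)) {
  expr <- utils::read.table(expr_path,
    header = TRUE, sep = "\t", quote = "",
    row.names = 1L, check.names = FALSE
  )
  meta <- utils::read.table(meta_path,
    header = TRUE, sep = "\t", quote = "",
    stringsAsFactors = FALSE
  )
  if (!all(c("sample", "arm") %in% names(meta))) {
    stop("sample metadata needs columns 'sample' and 'arm'", call. = FALSE)
  }
  missing <- setdiff(meta$sample, colnames(expr))
  if (length(missing) > 0L) {
    stop(
      "samples in metadata absent from expression matrix: ",
      paste(missing, collapse = ", "),
      call. = FALSE
    )
  }
  expr <- as.matrix(expr)
  expression_stratum(
    case = expr[, meta$sample[meta$arm == "case"], drop = FALSE],
    control = expr[, meta$sample[meta$arm == "control"], drop = FALSE],
    label = label
  )
}
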