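# Final score propagation: random walk with restart of the initial gene
# scores v0 over the warped (or unwarped) network,
#
#   v^{m+1} = (1 - q) A* D*^{-1} v^m + q v0,
#
# where D* holds the column sums of the supplied matrix, so A* D*^{-1} is
# column-stochastic wherever columns are nonzero. The fixed point has the
# closed form v* = q (I - (1-q) A* D*^{-1})^{-1} v0.

#' Diffuse gene scores over a (warped) network
#'
#' Runs a random walk with restart of `v0` over `adj` and returns the fixed
#' point `v*`. `adj` may be a `warped_adjacency` (the full pipeline), a
#' `warped_weights` matrix (curvature-only variant), a `ppi_network`
#' (classical unweighted RWR) or any nonnegative matrix. Columns that sum to
#' zero are left all-zero after normalization — score entering such a node
#' leaks back to the restart term only — and are reported via a message.
#'
#' @param adj Network or matrix to diffuse over (column sums define `D*`).
#' @param v0 Initial scores: numeric vector of length n, aligned to the
#'   node/column order (a named vector is reordered to match when the matrix
#'   has dimnames).
#' @param q Restart probability in `[0, 1]`. `q = 1` returns `v0`; `q = 0`
#'   is allowed with a warning (the fixed point may not be unique).
#' @param tol L1 tolerance for power iteration.
#' @param max_iter Iteration cap for power iteration.
#' @param method `"auto"` (sparse linear solve when `q >= 0.05`, else power
#'   iteration), `"linear"` or `"power"`.
#' @return Named numeric vector `v*`.
#' @export
diffuse <- function(adj, v0, q, tol = 1e-12, max_iter = 1e5,
                    method = c("auto", "linear", "power")) {
  method <- match.arg(method)
  M <- weight_matrix(adj)
  n <- nrow(M)
  nodes <- rownames(M)
  if (!is.null(names(v0)) && !is.null(nodes)) {
    if (!setequal(names(v0), nodes)) {
      stop("diffuse: names(v0) do not match the network's nodes", call. = FALSE)
    }
    v0 <- v0[nodes]
  }
  stopifnot(length(v0) == n, q >= 0, q <= 1)
  if (q == 1) {
    return(stats::setNames(as.numeric(v0), nodes))
  }
  if (q == 0) {
    warning("diffuse: q = 0 has no restart; the fixed point may not be unique")
  }
  s <- Matrix::colSums(M)
  zero_cols <- which(s == 0)
  if (length(zero_cols) > 0L) {
    message(
      "diffuse: ", length(zero_cols),
      " zero-sum column(s) left unnormalized (restart-only leakage)"
    )
  }
  S <- M %*% Matrix::Diagonal(n, ifelse(s > 0, 1 / s, 0))
  if (method == "auto") {
    method <- if (q >= 0.05) "linear" else "power"
  }
  if (method == "linear") {
    v <- as.numeric(Matrix::solve(Matrix::Diagonal(n) - (1 - q) * S, q * as.numeric(v0)))
  } else {
    v <- as.numeric(v0)
    converged <- FALSE
    res <- NA_real_
    for (it in seq_len(max_iter)) {
      v_new <- as.numeric((1 - q) * (S %*% v)) + q * as.numeric(v0)
      res <- sum(abs(v_new - v))
      v <- v_new
      if (res <= tol) {
        converged <- TRUE
        break
      }
    }
    if (!converged) {
      stop(sprintf(
        "diffuse: power iteration did not converge in %d iterations (last residual %.3e)",
        as.integer(max_iter), res
      ), call. = FALSE)
    }
  }
  stats::setNames(v, nodes)
}

#' Read a two-column gene/score table
#' @param path TSV path with columns gene id and score (no header required;
#'   a header line whose second field is non-numeric is skipped).
#' @return Named numeric vector of scores.
#' @export
read_score_table <- function(path) {
  tab <- utils::read.table(path,
    header = FALSE, sep = "", quote = "",
    comment.char = "#", stringsAsFactors = FALSE
  )
  if (ncol(tab) < 2L) {
    stop("score table must have two columns (gene, score): ", path, call. = FALSE)
  }
  if (is.na(suppressWarnings(as.numeric(tab[1L, 2L])))) {
    tab <- tab[-1L, , drop = FALSE]
  }
  stats::setNames(as.numeric(tab[[2L]]), as.character(tab[[1L]]))
}

#' Write scores (with ranks) as TSV
#' @param scores Named numeric vector.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_score_table <- function(scores, path) {
  ord <- order(-scores, names(scores))
  out <- data.frame(
    gene = names(scores)[ord],
    score = as.numeric(scores)[ord],
    rank = seq_along(scores)
  )
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
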