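# Augmented Forman-Ricci edge curvature and the curvature-warped weight
# matrix K (the internal, topology-derived feature).
#
# On an unweighted graph the augmented Forman-Ricci curvature of an edge
# e = (u, v) reduces to
#
#   kappa_e = 4 - deg(u) - deg(v) + 3 * |N_u intersect N_v|,
#
# an integer: large and positive inside cliques (protein complexes), strongly
# negative on the spokes of hubs.

#' Augmented Forman-Ricci curvature of every edge
#'
#' Computes `kappa_e = 4 - |N_u| - |N_v| + 3 |N_u & N_v|` for each undirected
#' edge, plus the sample mean and sample standard deviation (n-1 denominator)
#' over the unordered edge set. Curvature is symmetric, so orientation is
#' irrelevant.
#'
#' @param net A `ppi_network` with at least one edge.
#' @return An `edge_curvatures` data frame with columns `from`, `to`, `kappa`
#'   and attributes `mean`, `sd` and `edge_idx`.
#' @export
forman_ricci <- function(net) {
  e <- net$edges
  if (nrow(e) == 0L) {
    stop("forman_ricci: network has no edges (curvature sd undefined)",
      call. = FALSE
    )
  }
  A <- net$adjacency
  deg <- Matrix::colSums(A)
  # (A %*% A)[i, j] counts common neighbors of i and j.
  common <- as.numeric((A %*% A)[e])
  kappa <- 4 - deg[e[, 1L]] - deg[e[, 2L]] + 3 * common
  out <- data.frame(
    from = net$nodes[e[, 1L]],
    to = net$nodes[e[, 2L]],
    kappa = as.numeric(kappa),
    stringsAsFactors = FALSE
  )
  attr(out, "mean") <- mean(out$kappa)
  attr(out, "sd") <- stats::sd(out$kappa)
  attr(out, "edge_idx") <- e
  class(out) <- c("edge_curvatures", "data.frame")
  out
}

#' Per-node average curvature
#'
#' Maps each node to the mean curvature of its incident edges. Isolated
#' nodes (degree zero) are absent from the result.
#'
#' @param net A `ppi_network`.
#' @param curv Curvatures from [forman_ricci()] computed on `net`.
#' @return Named numeric vector over the nodes with degree >= 1.
#' @export
node_average_curvature <- function(net, curv = forman_ricci(net)) {
  e <- attr(curv, "edge_idx")
  idx <- c(e[, 1L], e[, 2L])
  vals <- c(curv$kappa, curv$kappa)
  sums <- tapply(vals, idx, sum)
  counts <- tapply(vals, idx, length)
  avg <- as.numeric(sums / counts)
  names(avg) <- net$nodes[as.integer(names(sums))]
  avg
}

#' Warp a network with curvature into the weight matrix K
#'
#' Normalizes curvatures to z-scores and maps them through a sigmoid,
#' `K_ji = 1 / (1 + exp(-beta * (kappa_ij - mean(kappa)) / sd(kappa)))` on
#' edges and 0 elsewhere. `beta = 0` gives every edge weight 1/2, which is
#' the original unweighted network up to column normalization. If all
#' curvatures are equal (sd = 0, e.g. a single edge or one clique) the warp
#' falls back to uniform weight 1/2 with a warning rather than dividing by
#' zero.
#'
#' @param net A `ppi_network`.
#' @param beta Real hyperparameter controlling the strength (and sign) of the
#'   curvature effect.
#' @param curv Optional precomputed [forman_ricci()] result.
#' @return A `warped_weights` object wrapping the sparse symmetric matrix `K`
#'   (retrieve it with [weight_matrix()]) and the `beta` used.
#' @export
warp_with_curvature <- function(net, beta = 0.5, curv = forman_ricci(net)) {
  e <- attr(curv, "edge_idx")
  s <- attr(curv, "sd")
  if (is.na(s) || s == 0) {
    if (nrow(e) > 0L && beta != 0) {
      warning(
        "warp_with_curvature: curvature sd is 0; using uniform edge weight 1/2 (beta = 0 semantics)"
      )
    }
    w <- rep(0.5, nrow(e))
  } else {
    w <- stats::plogis(beta * (curv$kappa - attr(curv, "mean")) / s)
  }
  n <- length(net$nodes)
  K <- Matrix::sparseMatrix(
    i = c(e[, 1L], e[, 2L]),
    j = c(e[, 2L], e[, 1L]),
    x = c(w, w),
    dims = c(n, n),
    dimnames = list(net$nodes, net$nodes)
  )
  structure(
    list(K = K, beta = beta, nodes = net$nodes),
    class = "warped_weights"
  )
}

#' @export
print.warped_weights <- function(x, ...) {
  cat(sprintf(
    "<warped_weights> %d nodes, beta = %g\n", length(x$nodes), x$beta
  ))
  invisible(x)
}

#' Extract the underlying weight matrix
#'
#' @param x A `warped_weights`, `warped_adjacency`, `ppi_network` or plain
#'   matrix.
#' @return The sparse (or supplied) matrix.
#' @export
weight_matrix <- function(x) {
  if (inherits(x, "warped_weights")) {
    return(x$K)
  }
  if (inherits(x, "warped_adjacency")) {
    return(x$a_star)
  }
  if (inherits(x, "ppi_network")) {
    return(x$adjacency)
  }
  x
}

#' Export curvatures and warped weights as a table
#'
#' @param net A `ppi_network`.
#' @param beta Sigmoid scale passed to [warp_with_curvature()].
#' @param path Optional TSV output path; when given the table is also written.
#' @return Data frame with columns `from`, `to`, `kappa`, `weight`.
#' @export
curvature_table <- function(net, beta = 0.5, path = NULL) {
  curv <- forman_ricci(net)
  K <- weight_matrix(warp_with_curvature(net, beta, curv))
  e <- attr(curv, "edge_idx")
  out <- data.frame(
    from = curv$from, to = curv$to, kappa = curv$kappa,
    weight = as.numeric(K[e]),
    stringsAsFactors = FALSE
  )
  if (!is.null(path)) {
    utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  out
}
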