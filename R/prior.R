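# External-feature warping: spread a prior-knowledge gene set over the
# curvature-warped weights K with a restart Markov kernel, take its
# stationary distribution pi as "smoothed prior knowledge", and scale the
# rows of K by pi to obtain the final (implicitly directed) adjacency A*.

#' Uniform prior vector over a gene set
#'
#' Builds `phi` with mass `1/|P|` on each prior node present in the network
#' and 0 elsewhere. Prior genes absent from the network are dropped with a
#' warning naming them.
#'
#' @param net A `ppi_network`.
#' @param priors Character vector of prior gene ids (non-empty after
#'   intersection with the network).
#' @return Named numeric vector `phi` over the network's nodes, summing to 1.
#' @export
make_prior_vector <- function(net, priors) {
  priors <- unique(as.character(priors))
  missing <- setdiff(priors, net$nodes)
  if (length(missing) > 0L) {
    warning(
      "make_prior_vector: dropping prior genes absent from the network: ",
      paste(missing, collapse = ", ")
    )
  }
  kept <- intersect(priors, net$nodes)
  if (length(kept) == 0L) {
    stop("prior set disjoint from network", call. = FALSE)
  }
  phi <- stats::setNames(numeric(length(net$nodes)), net$nodes)
  phi[kept] <- 1 / length(kept)
  phi
}

#' Restart Markov kernel over the warped weights
#'
#' Assembles the column-stochastic kernel
#' `P_ji = (1 - gamma) K_ji / sum_k K_ki + gamma phi_j`. The rank-one restart
#' term is kept implicit (the kernel object stores the column-normalized
#' weights `W`, `phi` and `gamma`); use [as.matrix()] to materialize it for
#' small networks. A zero-degree node's column is replaced by `phi` (pure
#' restart) with a message; with `gamma = 0` as well this is an error.
#'
#' @param K A `warped_weights` matrix (or any nonnegative matrix whose support
#'   is the edge set).
#' @param phi Prior vector from [make_prior_vector()].
#' @param gamma Restart probability in `[0, 1]`.
#' @return A `prior_kernel` object.
#' @export
make_prior_kernel <- function(K, phi, gamma) {
  stopifnot(gamma >= 0, gamma <= 1)
  K <- weight_matrix(K)
  n <- nrow(K)
  stopifnot(length(phi) == n)
  s <- Matrix::colSums(K)
  dangling <- which(s == 0)
  if (length(dangling) > 0L) {
    if (gamma == 0) {
      stop("dangling node with no restart: zero-degree column(s) ",
        paste(rownames(K)[dangling], collapse = ", "),
        " and gamma = 0",
        call. = FALSE
      )
    }
    message(
      "make_prior_kernel: ", length(dangling),
      " zero-degree column(s) replaced by pure restart"
    )
  }
  inv <- ifelse(s > 0, 1 / s, 0)
  W <- K %*% Matrix::Diagonal(n, inv)
  if (length(dangling) > 0L) {
    W[, dangling] <- phi
  }
  # Renormalize columns to machine precision.
  cs <- Matrix::colSums(W)
  W <- W %*% Matrix::Diagonal(n, 1 / cs)
  dimnames(W) <- dimnames(K)
  structure(
    list(W = W, phi = phi, gamma = gamma, nodes = rownames(K)),
    class = "prior_kernel"
  )
}

#' @export
print.prior_kernel <- function(x, ...) {
  cat(sprintf(
    "<prior_kernel> %d nodes, gamma = %g, %d prior nodes\n",
    length(x$nodes), x$gamma, sum(x$phi > 0)
  ))
  invisible(x)
}

#' Materialize a restart kernel as a dense matrix
#' @param x A `prior_kernel`.
#' @param ... Unused.
#' @return Dense column-stochastic matrix `(1-gamma) W + gamma phi 1^T`.
#' @export
as.matrix.prior_kernel <- function(x, ...) {
  n <- length(x$nodes)
  (1 - x$gamma) * as.matrix(x$W) +
    x$gamma * matrix(x$phi, n, n, dimnames = list(x$nodes, x$nodes))
}

kernel_matvec <- function(kernel, v) {
  as.numeric((1 - kernel$gamma) * (kernel$W %*% v)) +
    kernel$gamma * kernel$phi * sum(v)
}

check_irreducible_aperiodic <- function(W) {
  # For gamma = 0 the chain is just column-normalized K; a unique, convergent
  # stationary distribution needs a connected, non-bipartite support graph.
  n <- nrow(W)
  supp <- methods::as(Matrix::drop0(W + Matrix::t(W)), "nMatrix")
  color <- integer(n) # 0 unvisited, 1/2 two-coloring
  color[1L] <- 1L
  queue <- 1L
  bipartite <- TRUE
  while (length(queue) > 0L) {
    v <- queue[[1L]]
    queue <- queue[-1L]
    nb <- which(supp[, v])
    for (w in nb) {
      if (color[w] == 0L) {
        color[w] <- 3L - color[v]
        queue <- c(queue, w)
      } else if (color[w] == color[v]) {
        bipartite <- FALSE
      }
    }
  }
  if (any(color == 0L)) {
    stop(
      "stationary_distribution: gamma = 0 on a disconnected network has no unique stationary distribution",
      call. = FALSE
    )
  }
  if (bipartite) {
    stop(
      "stationary_distribution: gamma = 0 on a bipartite network does not converge (period 2)",
      call. = FALSE
    )
  }
  invisible(TRUE)
}

#' Stationary distribution of the restart kernel (smoothed prior)
#'
#' Solves `P pi = pi` for the column-stochastic restart kernel. For
#' `gamma > 0` the default is the closed-form sparse linear solve
#' `pi = gamma (I - (1-gamma) W)^{-1} phi`; power iteration is available as
#' an alternative and is the only route for `gamma = 0` (which additionally
#' requires a connected, non-bipartite network).
#'
#' @param kernel A `prior_kernel`.
#' @param tol L1 convergence tolerance for power iteration.
#' @param max_iter Iteration cap for power iteration.
#' @param method `"auto"` (linear solve when `gamma > 0`), `"linear"` or
#'   `"power"`.
#' @return A named `smoothed_prior` vector `pi` (nonnegative, summing to 1)
#'   with attribute `residual`.
#' @export
stationary_distribution <- function(kernel, tol = 1e-12, max_iter = 1e5,
                                    method = c("auto", "linear", "power")) {
  method <- match.arg(method)
  gamma <- kernel$gamma
  n <- length(kernel$nodes)
  if (gamma == 1) {
    pi <- kernel$phi
    return(structure(pi, residual = 0, class = "smoothed_prior"))
  }
  if (method == "auto") {
    method <- if (gamma > 0) "linear" else "power"
  }
  if (method == "linear") {
    if (gamma == 0) {
      stop("stationary_distribution: the closed form requires gamma > 0; use method = 'power'",
        call. = FALSE
      )
    }
    lhs <- Matrix::Diagonal(n) - (1 - gamma) * kernel$W
    pi <- as.numeric(Matrix::solve(lhs, gamma * kernel$phi))
    pi <- pmax(pi, 0)
    pi <- pi / sum(pi)
  } else {
    if (gamma == 0) {
      check_irreducible_aperiodic(kernel$W)
      v <- rep(1 / n, n)
    } else {
      v <- kernel$phi
    }
    converged <- FALSE
    res <- NA_real_
    for (it in seq_len(max_iter)) {
      v_new <- kernel_matvec(kernel, v)
      v_new <- v_new / sum(v_new)
      res <- sum(abs(v_new - v))
      v <- v_new
      if (res <= tol) {
        converged <- TRUE
        break
      }
    }
    if (!converged) {
      stop(sprintf(
        "stationary_distribution: power iteration did not converge in %d iterations (last residual %.3e)",
        as.integer(max_iter), res
      ), call. = FALSE)
    }
    pi <- v
  }
  names(pi) <- kernel$nodes
  residual <- sum(abs(kernel_matvec(kernel, pi) - pi))
  structure(pi, residual = residual, class = "smoothed_prior")
}

#' Final warped adjacency A*
#'
#' Scales the rows of K by the smoothed prior: `A*_ji = K_ji pi_j` on edges,
#' 0 elsewhere. A* is generally asymmetric (the same undirected edge carries
#' different weights in its two directions), which makes the network
#' implicitly directed; whenever `pi` is strictly positive the support stays
#' symmetric and `A*_ji / A*_ij = pi_j / pi_i` on every edge. Rows of nodes
#' with `pi_j = 0` are all zero.
#'
#' @param K A `warped_weights` matrix.
#' @param pi A `smoothed_prior` vector on the same node ordering.
#' @return A `warped_adjacency` object wrapping the sparse matrix `A*` and
#'   the `pi` used (retrieve the matrix with [weight_matrix()]).
#' @export
warp_with_prior <- function(K, pi) {
  Kmat <- weight_matrix(K)
  stopifnot(length(pi) == nrow(Kmat))
  a_star <- Matrix::Diagonal(nrow(Kmat), as.numeric(pi)) %*% Kmat
  a_star <- methods::as(a_star, "CsparseMatrix")
  dimnames(a_star) <- dimnames(Kmat)
  structure(
    list(a_star = a_star, pi = as.numeric(pi), nodes = rownames(Kmat)),
    class = "warped_adjacency"
  )
}

#' @export
print.warped_adjacency <- function(x, ...) {
  cat(sprintf(
    "<warped_adjacency> %d nodes, %d positive-pi nodes\n",
    length(x$nodes), sum(x$pi > 0)
  ))
  invisible(x)
}

#' Read a prior gene set file
#'
#' One gene id per line; `#` comments and blank lines ignored.
#'
#' @param path File path.
#' @return Character vector of gene ids.
#' @export
read_gene_set <- function(path) {
  lines <- trimws(sub("#.*$", "", readLines(path, warn = FALSE)))
  lines[nzchar(lines)]
}
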