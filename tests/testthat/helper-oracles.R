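# Independent oracles used to cross-check the package implementation.
# Everything here is deliberately naive (dense algebra, literal loops,
# numerical integration) and shares no code path with the package.

# Brute-force augmented Forman-Ricci curvature from a raw edge data frame.
oracle_forman <- function(edges) {
  nodes <- sort(unique(c(edges$from, edges$to)))
  nb <- lapply(stats::setNames(nodes, nodes), function(v) {
    unique(c(edges$to[edges$from == v], edges$from[edges$to == v]))
  })
  vapply(seq_len(nrow(edges)), function(r) {
    u <- edges$from[r]
    v <- edges$to[r]
    4 - length(nb[[u]]) - length(nb[[v]]) + 3 * length(intersect(nb[[u]], nb[[v]]))
  }, numeric(1))
}

# Seeded Erdos-Renyi network, connected-by-construction via a random
# spanning path, sampled independently of the package generator.
rand_network <- function(n, p, seed) {
  set.seed(seed)
  ids <- sprintf("n%02d", seq_len(n))
  perm <- sample(ids)
  from <- perm[-n]
  to <- perm[-1L]
  pairs <- t(utils::combn(ids, 2L))
  extra <- stats::runif(nrow(pairs)) < p
  network_from_edges(c(from, pairs[extra, 1L]), c(to, pairs[extra, 2L]))
}

# Dense stationary distribution of (1-g) W + g phi 1^T via direct solve.
oracle_stationary <- function(W, phi, gamma) {
  n <- nrow(W)
  pi <- as.numeric(solve(diag(n) - (1 - gamma) * unname(as.matrix(W)), gamma * phi))
  pi / sum(pi)
}

# Dense RWR fixed point with column normalization.
oracle_diffuse <- function(M, v0, q) {
  M <- unname(as.matrix(M))
  s <- colSums(M)
  S <- sweep(M, 2L, ifelse(s > 0, s, 1), "/")
  S[, s == 0] <- 0
  as.numeric(q * solve(diag(nrow(M)) - (1 - q) * S, v0))
}

# Literal-transcription average precision.
oracle_avep <- function(ranking, relevant) {
  hits <- 0
  total <- 0
  for (k in seq_along(ranking)) {
    if (ranking[k] %in% relevant) {
      hits <- hits + 1
      total <- total + hits / k
    }
  }
  total / length(relevant)
}

oracle_prec_k <- function(ranking, relevant, k) {
  mean(ranking[seq_len(k)] %in% relevant)
}

# Upper-tail standard normal quantile by root-finding on the CDF.
oracle_upper_quantile <- function(p) {
  stats::uniroot(function(x) stats::pnorm(x, lower.tail = FALSE) - p,
    interval = c(-40, 40), tol = 1e-12
  )$root
}

# Chi-square survival at 4 degrees of freedom in closed form:
# P(X > S) = exp(-S/2) * (1 + S/2).
oracle_chisq4_surv <- function(S) exp(-S / 2) * (1 + S / 2)

# Student-t upper tail by numerical integration of the density.
oracle_t_upper <- function(t, df) {
  dens <- function(x) {
    gamma((df + 1) / 2) / (sqrt(df * pi) * gamma(df / 2)) *
      (1 + x^2 / df)^(-(df + 1) / 2)
  }
  stats::integrate(dens, t, Inf, rel.tol = 1e-12)$value
}

make_fig2_edges <- function() {
  left <- paste0("l", 1:5)
  lp <- t(utils::combn(left, 2L))
  data.frame(
    from = c(rep("center", 10L), lp[, 1L]),
    to = c(left, paste0("r", 1:5), lp[, 2L]),
    stringsAsFactors = FALSE
  )
}
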