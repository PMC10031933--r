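# Synthetic fixtures: an 11-node toy graph contrasting a clique side with a
# star side, and planted-module benchmark networks (Erdos-Renyi background +
# planted cliques emulating protein complexes + star hubs) with a ground
# truth concentrated near the planted structure and noisy initial scores.

#' The 11-node clique-versus-star toy graph
#'
#' One central node `center` adjacent to ten others: `l1`..`l5` are pairwise
#' interconnected (the clique side, curvature +1 on the spokes, +6 inside the
#' clique) and `r1`..`r5` have no other edges (the star side, curvature -7).
#' An unweighted one-step walk from the center enters either side with
#' probability 5/10; curvature warping breaks that tie.
#'
#' @return A `ppi_network` with 11 nodes and 20 edges.
#' @export
fig2_graph <- function() {
  left <- paste0("l", 1:5)
  right <- paste0("r", 1:5)
  from <- c(rep("center", 10L), t(utils::combn(left, 2L))[, 1L])
  to <- c(left, right, t(utils::combn(left, 2L))[, 2L])
  network_from_edges(from, to)
}

#' Specification for a planted-module synthetic benchmark
#'
#' @param n_modules Number of planted cliques ("protein complexes").
#' @param clique_size Nodes per planted clique.
#' @param n_hubs Number of star hubs.
#' @param hub_degree Spokes per hub (drawn from the background).
#' @param background_nodes Size of the Erdos-Renyi background.
#' @param background_edge_prob Background edge probability.
#' @param n_truth Number of ground-truth genes.
#' @param truth_fraction_in_modules Fraction of the truth placed inside
#'   planted cliques (the rest is background).
#' @param prior_fraction Fraction of the truth used as prior knowledge in
#'   end-to-end benchmarks (the 2:8 convention).
#' @param score_signal Mean Z-shift added to truth genes and their neighbors
#'   on top of the baseline (the weak causal signal).
#' @param score_baseline Mean Z carried by every gene, emulating the
#'   predominantly positive upper-tail Z-scores of a pervasively perturbed
#'   case/control transcriptome (causes and consequences alike score high).
#' @param score_noise_sd Standard deviation of the Gaussian score noise.
#' @param seed Integer seed; all generator randomness flows from it.
#' @return A `synthetic_spec` list.
#' @export
synthetic_spec <- function(n_modules = 6, clique_size = 8, n_hubs = 6,
                           hub_degree = 15, background_nodes = 300,
                           background_edge_prob = 0.01, n_truth = 40,
                           truth_fraction_in_modules = 0.8,
                           prior_fraction = 0.2,
                           score_signal = 0.5, score_baseline = 3,
                           score_noise_sd = 1,
                           seed = 1) {
  spec <- list(
    n_modules = as.integer(n_modules), clique_size = as.integer(clique_size),
    n_hubs = as.integer(n_hubs), hub_degree = as.integer(hub_degree),
    background_nodes = as.integer(background_nodes),
    background_edge_prob = background_edge_prob,
    n_truth = as.integer(n_truth),
    truth_fraction_in_modules = truth_fraction_in_modules,
    prior_fraction = prior_fraction,
    score_signal = score_signal, score_baseline = score_baseline,
    score_noise_sd = score_noise_sd,
    seed = as.integer(seed)
  )
  counts <- c(
    spec$n_modules, spec$clique_size, spec$n_hubs, spec$hub_degree,
    spec$background_nodes, spec$n_truth
  )
  if (any(counts <= 0L)) {
    stop("synthetic_spec: all counts must be positive", call. = FALSE)
  }
  fracs <- c(
    spec$background_edge_prob, spec$truth_fraction_in_modules,
    spec$prior_fraction
  )
  if (any(fracs < 0 | fracs > 1)) {
    stop("synthetic_spec: probabilities/fractions must lie in [0, 1]", call. = FALSE)
  }
  if (spec$clique_size < 2L) {
    stop("synthetic_spec: clique_size must be >= 2", call. = FALSE)
  }
  if (spec$hub_degree > spec$background_nodes) {
    stop("synthetic_spec: hub_degree exceeds background_nodes", call. = FALSE)
  }
  if (spec$n_truth > spec$background_nodes + spec$n_modules * spec$clique_size) {
    stop("synthetic_spec: n_truth exceeds the available nodes", call. = FALSE)
  }
  class(spec) <- "synthetic_spec"
  spec
}

#' Generate a planted-module benchmark instance
#'
#' Builds an Erdos-Renyi background, plants `n_modules` cliques (each
#' bridged to a random background node) and `n_hubs` star hubs, then patches
#' connectivity by bridging every smaller component to the largest one
#' (bridges are recorded in the `bridges` attribute of the network). The
#' ground truth is sampled with `truth_fraction_in_modules` of its mass
#' inside planted cliques; initial scores are `score_baseline` everywhere
#' (the pervasive-perturbation burden of real case/control omics) plus
#' `score_signal` on truth genes and their network neighbors, plus Gaussian
#' noise.
#'
#' @param spec A [synthetic_spec()].
#' @return List with elements `network` (`ppi_network`), `truth` (character
#'   vector) and `scores` (named numeric vector).
#' @export
planted_module_network <- function(spec = synthetic_spec()) {
  stopifnot(inherits(spec, "synthetic_spec"))
  restore <- .Random.seed_guard(spec$seed)
  on.exit(restore(), add = TRUE)

  bg <- sprintf("g%03d", seq_len(spec$background_nodes))
  pairs <- t(utils::combn(bg, 2L))
  keep <- stats::runif(nrow(pairs)) < spec$background_edge_prob
  from <- pairs[keep, 1L]
  to <- pairs[keep, 2L]

  clique_nodes <- character(0)
  for (m in seq_len(spec$n_modules)) {
    members <- sprintf("m%dc%d", m, seq_len(spec$clique_size))
    clique_nodes <- c(clique_nodes, members)
    cp <- t(utils::combn(members, 2L))
    from <- c(from, cp[, 1L], members[1L])
    to <- c(to, cp[, 2L], sample(bg, 1L))
  }

  hub_nodes <- sprintf("h%d", seq_len(spec$n_hubs))
  for (h in seq_len(spec$n_hubs)) {
    spokes <- sample(bg, spec$hub_degree)
    from <- c(from, rep(hub_nodes[h], spec$hub_degree))
    to <- c(to, spokes)
  }

  # Isolated background nodes must still enter the node universe.
  all_nodes <- c(bg, clique_nodes, hub_nodes)
  net <- network_from_edges(c(from, all_nodes), c(to, all_nodes))
  # network_from_edges drops the padding self-loops; re-add isolated nodes.
  net <- add_isolated_nodes(net, all_nodes)

  # Connectivity patch-up: bridge each smaller component to the largest.
  comp <- graph_components(net)
  sizes <- tabulate(comp)
  main <- which.max(sizes)
  bridges <- NULL
  for (cc in setdiff(seq_along(sizes), main)) {
    a <- sample(net$nodes[comp == cc], 1L)
    b <- sample(net$nodes[comp == main], 1L)
    from <- c(from, a)
    to <- c(to, b)
    bridges <- rbind(bridges, c(a, b))
  }
  if (!is.null(bridges)) {
    net <- network_from_edges(c(from, all_nodes), c(to, all_nodes))
    net <- add_isolated_nodes(net, all_nodes)
    attr(net, "bridges") <- bridges
  }

  n_in <- round(spec$truth_fraction_in_modules * spec$n_truth)
  n_in <- min(n_in, length(clique_nodes))
  n_out <- spec$n_truth - n_in
  truth <- c(sample(clique_nodes, n_in), sample(bg, n_out))

  n <- length(net$nodes)
  scores <- stats::setNames(
    spec$score_baseline + stats::rnorm(n, 0, spec$score_noise_sd), net$nodes
  )
  truth_idx <- match(truth, net$nodes)
  nb_mask <- Matrix::rowSums(net$adjacency[, truth_idx, drop = FALSE]) > 0
  boosted <- unique(c(truth, net$nodes[nb_mask]))
  scores[boosted] <- scores[boosted] + spec$score_signal

  list(network = net, truth = sort(truth), scores = scores)
}

add_isolated_nodes <- function(net, all_nodes) {
  if (setequal(net$nodes, all_nodes)) {
    return(net)
  }
  node_ids <- sort(unique(all_nodes))
  remap <- match(net$nodes, node_ids)
  edge_idx <- cbind(remap[net$edges[, 1L]], remap[net$edges[, 2L]])
  dimnames(edge_idx) <- NULL
  new_network(node_ids, edge_idx)
}

#' Write a synthetic benchmark instance to a directory
#'
#' Emits `network.tsv` (plain edge list), `truth.txt`, `priors.txt` (a
#' `prior_fraction` subsample of the truth) and `scores.tsv`.
#'
#' @param spec A [synthetic_spec()].
#' @param dir Output directory (created if needed).
#' @return The instance list from [planted_module_network()], invisibly.
#' @export
write_synthetic_instance <- function(spec = synthetic_spec(), dir) {
  inst <- planted_module_network(spec)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_edge_list(inst$network, file.path(dir, "network.tsv"))
  writeLines(inst$truth, file.path(dir, "truth.txt"))
  restore <- .Random.seed_guard(spec$seed + 1L)
  on.exit(restore(), add = TRUE)
  n_prior <- max(1L, round(spec$prior_fraction * length(inst$truth)))
  writeLines(sort(sample(inst$truth, n_prior)), file.path(dir, "priors.txt"))
  write_score_table(inst$scores, file.path(dir, "scores.tsv"))
  invisible(inst)
}
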