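# Undirected, unweighted interaction networks.
#
# A `ppi_network` stores an ordered node vector, a deduplicated edge index
# matrix (each undirected edge once, low index first) and a symmetric sparse
# 0/1 adjacency matrix. Node identifiers are opaque strings; any identifier
# mapping must happen upstream.

new_network <- function(node_ids, edge_idx) {
  n <- length(node_ids)
  storage.mode(edge_idx) <- "integer"
  adjacency <- Matrix::sparseMatrix(
    i = c(edge_idx[, 1L], edge_idx[, 2L]),
    j = c(edge_idx[, 2L], edge_idx[, 1L]),
    x = 1,
    dims = c(n, n),
    dimnames = list(node_ids, node_ids)
  )
  structure(
    list(nodes = node_ids, edges = edge_idx, adjacency = adjacency),
    class = "ppi_network"
  )
}

#' Build a network from endpoint vectors
#'
#' Constructs an undirected, unweighted network from parallel `from`/`to`
#' identifier vectors. Self-loops are dropped, duplicate edges (in either
#' orientation) are merged, and every identifier mentioned becomes a node.
#'
#' @param from,to Character vectors of equal length giving edge endpoints.
#' @return A `ppi_network` object.
#' @export
network_from_edges <- function(from, to) {
  stopifnot(length(from) == length(to))
  from <- as.character(from)
  to <- as.character(to)
  node_ids <- sort(unique(c(from, to)))
  i <- match(from, node_ids)
  j <- match(to, node_ids)
  keep <- i != j
  lo <- pmin(i[keep], j[keep])
  hi <- pmax(i[keep], j[keep])
  edge_idx <- unique(cbind(lo, hi))
  if (nrow(edge_idx) > 1L) {
    ord <- order(edge_idx[, 1L], edge_idx[, 2L])
    edge_idx <- edge_idx[ord, , drop = FALSE]
  }
  dimnames(edge_idx) <- NULL
  new_network(node_ids, edge_idx)
}

#' @export
print.ppi_network <- function(x, ...) {
  cat(sprintf(
    "<ppi_network> %d nodes, %d edges\n",
    length(x$nodes), nrow(x$edges)
  ))
  invisible(x)
}

#' Node identifiers of a network
#' @param net A `ppi_network`.
#' @return Character vector of node ids in index order.
#' @export
network_nodes <- function(net) net$nodes

#' Edge table of a network
#' @param net A `ppi_network`.
#' @return A data frame with columns `from`, `to`, one row per undirected edge.
#' @export
network_edges <- function(net) {
  data.frame(
    from = net$nodes[net$edges[, 1L]],
    to = net$nodes[net$edges[, 2L]],
    stringsAsFactors = FALSE
  )
}

#' Node degrees
#' @param net A `ppi_network`.
#' @return Named integer vector of degrees, one entry per node.
#' @export
network_degree <- function(net) {
  d <- Matrix::colSums(net$adjacency)
  names(d) <- net$nodes
  d
}

#' Neighbor sets
#' @param net A `ppi_network`.
#' @return Named list; element i holds the integer indices adjacent to node i.
#' @export
neighbor_sets <- function(net) {
  adj <- net$adjacency
  n <- length(net$nodes)
  ptr <- adj@p
  out <- vector("list", n)
  for (i in seq_len(n)) {
    out[[i]] <- adj@i[seq.int(ptr[i] + 1L, length.out = ptr[i + 1L] - ptr[i])] + 1L
  }
  names(out) <- net$nodes
  out
}

#' Read an interaction network from an edge-list file
#'
#' Supports three dialects: `plain` (two whitespace-separated identifier
#' columns, `#` comments ignored), `string_db` (headered table with a
#' per-channel experimental-evidence column and a combined confidence score,
#' auto-rescaled from the 0-1000 integer scale when present) and `biogrid`
#' (TAB3-style TSV using the two official-symbol columns). Duplicate edges
#' are collapsed, self-loops dropped.
#'
#' @param path Path to the edge-list file.
#' @param dialect One of `"plain"`, `"string_db"`, `"biogrid"`.
#' @param min_confidence For `string_db`: keep only rows whose combined
#'   confidence is strictly greater than this threshold (on the 0-1 scale).
#'   `NULL` disables the filter.
#' @param require_experimental For `string_db`: keep only rows with a nonzero
#'   experimental-evidence channel.
#' @param columns Optional named list overriding `string_db` column names;
#'   recognised entries are `id1`, `id2`, `experimental`, `combined`.
#' @return A `ppi_network`.
#' @export
read_edge_list <- function(path,
                           dialect = c("plain", "string_db", "biogrid"),
                           min_confidence = NULL,
                           require_experimental = FALSE,
                           columns = list()) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) {
    stop("edge-list file not found: ", path, call. = FALSE)
  }
  ends <- switch(dialect,
    plain = read_plain_edges(path),
    string_db = read_string_edges(path, min_confidence, require_experimental, columns),
    biogrid = read_biogrid_edges(path)
  )
  if (length(ends$from) == 0L) {
    stop("empty network: no edges remain after parsing/filtering ", path,
      call. = FALSE
    )
  }
  net <- network_from_edges(ends$from, ends$to)
  if (nrow(net$edges) == 0L) {
    stop("empty network: all rows were self-loops in ", path, call. = FALSE)
  }
  net
}

read_plain_edges <- function(path) {
  lines <- readLines(path, warn = FALSE)
  stripped <- trimws(sub("#.*$", "", lines))
  keep <- nzchar(stripped)
  tokens <- strsplit(stripped[keep], "[ \t]+")
  nl <- lengths(tokens)
  if (any(nl < 2L)) {
    bad <- which(keep)[which(nl < 2L)[1L]]
    stop(sprintf(
      "malformed edge row at line %d of %s: expected two columns", bad, path
    ), call. = FALSE)
  }
  list(
    from = vapply(tokens, `[[`, character(1), 1L),
    to = vapply(tokens, `[[`, character(1), 2L)
  )
}

read_string_edges <- function(path, min_confidence, require_experimental, columns) {
  cols <- utils::modifyList(
    list(
      id1 = "protein1", id2 = "protein2",
      experimental = "experimental", combined = "combined_score"
    ),
    columns
  )
  tab <- utils::read.table(path,
    header = TRUE, sep = "", quote = "",
    comment.char = "#", stringsAsFactors = FALSE, check.names = FALSE
  )
  pick <- function(role) {
    nm <- cols[[role]]
    if (nm %in% names(tab)) {
      return(nm)
    }
    hit <- grep(nm, names(tab), ignore.case = TRUE, value = TRUE)
    if (length(hit) >= 1L) {
      return(hit[1L])
    }
    stop(sprintf(
      "string_db dialect: required column '%s' (%s) not found in %s",
      nm, role, path
    ), call. = FALSE)
  }
  id1 <- tab[[pick("id1")]]
  id2 <- tab[[pick("id2")]]
  combined <- as.numeric(tab[[pick("combined")]])
  # STRING ships confidences either as 0-1000 integers or 0-1 reals.
  if (length(combined) > 0L && max(combined, na.rm = TRUE) > 1) {
    combined <- combined / 1000
  }
  keep <- rep(TRUE, length(id1))
  if (!is.null(min_confidence)) {
    keep <- keep & combined > min_confidence
  }
  if (isTRUE(require_experimental)) {
    expch <- as.numeric(tab[[pick("experimental")]])
    keep <- keep & expch > 0
  }
  list(from = as.character(id1[keep]), to = as.character(id2[keep]))
}

read_biogrid_edges <- function(path) {
  tab <- utils::read.delim(path,
    header = TRUE, sep = "\t", quote = "",
    comment.char = "", stringsAsFactors = FALSE, check.names = FALSE
  )
  find_col <- function(letter) {
    exact <- sprintf("Official Symbol Interactor %s", letter)
    if (exact %in% names(tab)) {
      return(exact)
    }
    hit <- grep(sprintf("official.?symbol.*%s$", letter), names(tab),
      ignore.case = TRUE, value = TRUE
    )
    if (length(hit) >= 1L) {
      return(hit[1L])
    }
    stop(sprintf(
      "biogrid dialect: official-symbol column for interactor %s not found in %s",
      letter, path
    ), call. = FALSE)
  }
  list(
    from = as.character(tab[[find_col("A")]]),
    to = as.character(tab[[find_col("B")]])
  )
}

#' Write a network as a plain two-column edge list
#' @param net A `ppi_network`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_edge_list <- function(net, path) {
  e <- network_edges(net)
  utils::write.table(e, path,
    sep = "\t", quote = FALSE,
    row.names = FALSE, col.names = FALSE
  )
  invisible(path)
}

#' Induced subgraph on a set of nodes
#'
#' Keeps the nodes in `keep` (intersected with the network's nodes) and the
#' edges among them; degrees and adjacency are recomputed. An empty result is
#' allowed and flagged with a warning.
#'
#' @param net A `ppi_network`.
#' @param keep Character vector of node ids to retain.
#' @return The induced `ppi_network`.
#' @export
restrict_to_nodes <- function(net, keep) {
  keep_ids <- intersect(net$nodes, unique(as.character(keep)))
  if (length(keep_ids) == 0L) {
    warning("restrict_to_nodes: no requested node is present; returning an empty network")
  }
  in_keep <- net$nodes %in% keep_ids
  e <- net$edges
  e <- e[in_keep[e[, 1L]] & in_keep[e[, 2L]], , drop = FALSE]
  node_ids <- net$nodes[in_keep]
  remap <- match(net$nodes, node_ids)
  edge_idx <- cbind(remap[e[, 1L]], remap[e[, 2L]])
  dimnames(edge_idx) <- NULL
  new_network(node_ids, edge_idx)
}

graph_components <- function(net) {
  n <- length(net$nodes)
  nb <- neighbor_sets(net)
  comp <- integer(n)
  cur <- 0L
  for (start in seq_len(n)) {
    if (comp[start] != 0L) next
    cur <- cur + 1L
    queue <- start
    comp[start] <- cur
    while (length(queue) > 0L) {
      v <- queue[[1L]]
      queue <- queue[-1L]
      for (w in nb[[v]]) {
        if (comp[w] == 0L) {
          comp[w] <- cur
          queue <- c(queue, w)
        }
      }
    }
  }
  comp
}

#' Largest connected component
#'
#' Returns the induced subgraph on the largest undirected component. Ties in
#' size are broken by the component whose lexicographically smallest node id
#' is smallest.
#'
#' @param net A non-empty `ppi_network`.
#' @return A `ppi_network`.
#' @export
largest_connected_component <- function(net) {
  if (length(net$nodes) == 0L) {
    stop("largest_connected_component: empty network", call. = FALSE)
  }
  comp <- graph_components(net)
  sizes <- tabulate(comp)
  best <- which(sizes == max(sizes))
  if (length(best) > 1L) {
    min_ids <- vapply(
      best,
      function(cc) min(net$nodes[comp == cc]),
      character(1)
    )
    best <- best[order(min_ids)][1L]
  }
  restrict_to_nodes(net, net$nodes[comp == best])
}
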