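# Pipeline front end: method variants as configuration, file-based runs and
# a command-line interface.
#
# Methods:
#   pwn              curvature warp (beta) -> prior smoothing (gamma) -> RWR (q)
#   pwn_no_curvature same with the unweighted adjacency (beta forced to 0)
#   rwr              classical RWR on the unweighted adjacency (no priors)
#   rwr_curvature    RWR on the curvature-warped weights K (no priors)

PWN_METHODS <- c("pwn", "pwn_no_curvature", "rwr", "rwr_curvature")

#' Prioritize genes with a chosen method variant
#'
#' Runs the in-memory stage chain for one method: curvature warping, prior
#' smoothing and score diffusion as applicable. Scores for network genes
#' missing from `scores` are set to 0 with a warning.
#'
#' @param net A `ppi_network`.
#' @param scores Named numeric vector of initial gene scores.
#' @param method One of `"pwn"`, `"pwn_no_curvature"`, `"rwr"`,
#'   `"rwr_curvature"`.
#' @param priors Character vector of prior genes (required for the pwn
#'   variants, ignored with a warning by the rwr variants).
#' @param beta,gamma,q Hyperparameters (defaults 0.5, 0.5, 0.3).
#' @param tol,max_iter Solver controls passed to [stationary_distribution()]
#'   and [diffuse()].
#' @return Named numeric vector of final scores `v*` over the network nodes.
#' @export
prioritize <- function(net, scores, method = "pwn", priors = NULL,
                       beta = 0.5, gamma = 0.5, q = 0.3,
                       tol = 1e-12, max_iter = 1e5) {
  method <- match.arg(method, PWN_METHODS)
  v0 <- stats::setNames(numeric(length(net$nodes)), net$nodes)
  known <- intersect(names(scores), net$nodes)
  if (length(known) < length(net$nodes)) {
    warning(sprintf(
      "prioritize: %d network gene(s) have no initial score; using 0",
      length(net$nodes) - length(known)
    ))
  }
  v0[known] <- scores[known]

  if (method %in% c("rwr", "rwr_curvature")) {
    if (!is.null(priors) && length(priors) > 0L) {
      warning(sprintf("prioritize: method '%s' ignores the prior set", method))
    }
    adj <- if (method == "rwr") net else warp_with_curvature(net, beta)
    return(diffuse(adj, v0, q, tol = tol, max_iter = max_iter))
  }

  if (is.null(priors) || length(priors) == 0L) {
    stop(sprintf("prioritize: method '%s' requires a prior gene set", method),
      call. = FALSE
    )
  }
  if (method == "pwn_no_curvature") {
    beta <- 0
  }
  K <- warp_with_curvature(net, beta)
  phi <- make_prior_vector(net, priors)
  kernel <- make_prior_kernel(K, phi, gamma)
  pi <- stationary_distribution(kernel, tol = tol, max_iter = max_iter)
  a_star <- warp_with_prior(K, pi)
  diffuse(a_star, v0, q, tol = tol, max_iter = max_iter)
}

#' Assemble and validate a run configuration
#'
#' Defaults follow the method's standard hyperparameters: `beta = 0.5`,
#' `gamma = 0.5`, `q = 0.3`. `pwn` and `pwn_no_curvature` require a priors
#' path; the rwr variants ignore one (with a warning at run time);
#' `pwn_no_curvature` forces `beta = 0`.
#'
#' @param method Method id.
#' @param network_path,scores_path,priors_path,output_path Input/output files.
#' @param beta,gamma,q Hyperparameters.
#' @param dialect,min_confidence,require_experimental Passed to
#'   [read_edge_list()].
#' @param lcc Restrict the network to its largest connected component.
#' @param tol,max_iter Solver controls.
#' @param seed Integer seed recorded in the manifest.
#' @return A validated `run_config` list.
#' @export
run_config <- function(method = c("pwn", "pwn_no_curvature", "rwr", "rwr_curvature"),
                       network_path = NULL, scores_path = NULL,
                       priors_path = NULL, output_path = NULL,
                       beta = 0.5, gamma = 0.5, q = 0.3,
                       dialect = "plain", min_confidence = NULL,
                       require_experimental = FALSE, lcc = FALSE,
                       tol = 1e-12, max_iter = 1e5, seed = 1) {
  method <- match.arg(method)
  if (is.null(network_path) || is.null(scores_path)) {
    stop("run_config: network_path and scores_path are required", call. = FALSE)
  }
  if (method %in% c("pwn", "pwn_no_curvature") && is.null(priors_path)) {
    stop(sprintf("run_config: method '%s' requires priors_path", method),
      call. = FALSE
    )
  }
  if (!(gamma >= 0 && gamma <= 1)) stop("run_config: gamma must be in [0, 1]", call. = FALSE)
  if (!(q >= 0 && q <= 1)) stop("run_config: q must be in [0, 1]", call. = FALSE)
  if (method == "pwn_no_curvature" && beta != 0) {
    message("run_config: pwn_no_curvature forces beta = 0")
    beta <- 0
  }
  structure(
    list(
      method = method, network_path = network_path,
      scores_path = scores_path, priors_path = priors_path,
      output_path = output_path, beta = beta, gamma = gamma, q = q,
      dialect = dialect, min_confidence = min_confidence,
      require_experimental = require_experimental, lcc = lcc,
      tol = tol, max_iter = max_iter, seed = as.integer(seed)
    ),
    class = "run_config"
  )
}

#' Execute a configured run
#'
#' Reads the inputs, executes the stage chain for the configured method and
#' returns the ranked score table plus a manifest (parameters, input hashes,
#' package version). When `config$output_path` is set, the ranked table is
#' written there as TSV and the manifest alongside it as
#' `<output_path>.manifest.json`.
#'
#' @param config A [run_config()].
#' @return List with elements `ranking` (data frame gene/score/rank),
#'   `scores` (named vector `v*`) and `manifest` (list).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  message("stage: read_network [", config$network_path, "]")
  net <- read_edge_list(config$network_path,
    dialect = config$dialect,
    min_confidence = config$min_confidence,
    require_experimental = config$require_experimental
  )
  if (isTRUE(config$lcc)) {
    message("stage: largest_connected_component")
    net <- largest_connected_component(net)
  }
  message("stage: read_scores [", config$scores_path, "]")
  scores <- read_score_table(config$scores_path)
  priors <- NULL
  if (config$method %in% c("pwn", "pwn_no_curvature")) {
    message("stage: read_priors [", config$priors_path, "]")
    priors <- read_gene_set(config$priors_path)
  }
  message("stage: prioritize [", config$method, "]")
  v <- prioritize(net, scores,
    method = config$method, priors = priors,
    beta = config$beta, gamma = config$gamma, q = config$q,
    tol = config$tol, max_iter = config$max_iter
  )
  ord <- order(-v, names(v))
  ranking <- data.frame(
    gene = names(v)[ord], score = as.numeric(v)[ord],
    rank = seq_along(v), stringsAsFactors = FALSE
  )
  manifest <- list(
    method = config$method,
    parameters = list(
      beta = config$beta, gamma = config$gamma, q = config$q,
      tol = config$tol, max_iter = config$max_iter
    ),
    inputs = {
      paths <- c(
        network = config$network_path, scores = config$scores_path,
        priors = if (!is.null(priors)) config$priors_path
      )
      lapply(as.list(paths), function(p) {
        list(path = p, md5 = unname(tools::md5sum(p)))
      })
    },
    network = list(nodes = length(net$nodes), edges = nrow(net$edges)),
    seed = config$seed,
    package_version = as.character(utils::packageVersion("warpnet")),
    r_version = as.character(getRversion())
  )
  if (!is.null(config$output_path)) {
    utils::write.table(ranking, config$output_path,
      sep = "\t", quote = FALSE, row.names = FALSE
    )
    jsonlite::write_json(manifest,
      paste0(config$output_path, ".manifest.json"),
      auto_unbox = TRUE, digits = NA, pretty = TRUE
    )
  }
  list(ranking = ranking, scores = v, manifest = manifest)
}

#' Command-line interface
#'
#' Subcommands: `run` (full pipeline), `curvature` (edge curvature/weight
#' table), `generate` (synthetic benchmark instance) and `evaluate` (metrics
#' for a ranking file against a relevant-genes file). Returns an exit code:
#' 0 ok, 1 input error, 2 numerical failure. A thin wrapper script suitable
#' for `Rscript` ships in `inst/cli/warpnet.R`.
#'
#' @param args Character vector of arguments (defaults to the command line).
#' @return Integer exit code, invisibly.
#' @export
warpnet_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  if (length(args) == 0L || args[1L] %in% c("-h", "--help")) {
    cat("usage: warpnet <run|curvature|generate|evaluate> [options]\n")
    return(invisible(0L))
  }
  sub <- args[1L]
  rest <- args[-1L]
  handler <- switch(sub,
    run = cli_run,
    curvature = cli_curvature,
    generate = cli_generate,
    evaluate = cli_evaluate,
    NULL
  )
  if (is.null(handler)) {
    message("unknown subcommand: ", sub)
    return(invisible(1L))
  }
  code <- tryCatch(
    {
      handler(rest)
      0L
    },
    numerical_error = function(e) {
      message("numerical failure: ", conditionMessage(e))
      2L
    },
    error = function(e) {
      msg <- conditionMessage(e)
      message("error: ", msg)
      if (grepl("converge|singular|residual", msg)) 2L else 1L
    }
  )
  invisible(code)
}

cli_run <- function(args) {
  parser <- optparse::OptionParser(
    usage = "warpnet run [options]",
    option_list = list(
      optparse::make_option("--method", default = "pwn"),
      optparse::make_option("--network", type = "character"),
      optparse::make_option("--scores", type = "character"),
      optparse::make_option("--priors", type = "character", default = NULL),
      optparse::make_option("--output", type = "character", default = NULL),
      optparse::make_option("--dialect", default = "plain"),
      optparse::make_option("--min-confidence", type = "double", default = NULL, dest = "min_confidence"),
      optparse::make_option("--require-experimental",
        action = "store_true",
        default = FALSE, dest = "require_experimental"
      ),
      optparse::make_option("--lcc", action = "store_true", default = FALSE),
      optparse::make_option("--beta", type = "double", default = 0.5),
      optparse::make_option("--gamma", type = "double", default = 0.5),
      optparse::make_option("--q", type = "double", default = 0.3),
      optparse::make_option("--tol", type = "double", default = 1e-12),
      optparse::make_option("--seed", type = "integer", default = 1L)
    )
  )
  opt <- optparse::parse_args(parser, args = args)
  config <- run_config(
    method = opt$method, network_path = opt$network,
    scores_path = opt$scores, priors_path = opt$priors,
    output_path = opt$output, beta = opt$beta, gamma = opt$gamma, q = opt$q,
    dialect = opt$dialect, min_confidence = opt$min_confidence,
    require_experimental = opt$require_experimental, lcc = opt$lcc,
    tol = opt$tol, seed = opt$seed
  )
  res <- run_pipeline(config)
  if (is.null(config$output_path)) {
    utils::write.table(res$ranking, stdout(),
      sep = "\t", quote = FALSE, row.names = FALSE
    )
  }
  invisible(res)
}

cli_curvature <- function(args) {
  parser <- optparse::OptionParser(
    usage = "warpnet curvature [options]",
    option_list = list(
      optparse::make_option("--network", type = "character"),
      optparse::make_option("--dialect", default = "plain"),
      optparse::make_option("--beta", type = "double", default = 0.5),
      optparse::make_option("--output", type = "character", default = NULL)
    )
  )
  opt <- optparse::parse_args(parser, args = args)
  net <- read_edge_list(opt$network, dialect = opt$dialect)
  tab <- curvature_table(net, beta = opt$beta, path = opt$output)
  if (is.null(opt$output)) {
    utils::write.table(tab, stdout(), sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(tab)
}

cli_generate <- function(args) {
  parser <- optparse::OptionParser(
    usage = "warpnet generate [options]",
    option_list = list(
      optparse::make_option("--out-dir", type = "character", dest = "out_dir"),
      optparse::make_option("--seed", type = "integer", default = 1L),
      optparse::make_option("--n-truth", type = "integer", default = 40L, dest = "n_truth"),
      optparse::make_option("--background-nodes",
        type = "integer", default = 300L,
        dest = "background_nodes"
      )
    )
  )
  opt <- optparse::parse_args(parser, args = args)
  if (is.null(opt$out_dir)) stop("generate: --out-dir is required", call. = FALSE)
  spec <- synthetic_spec(
    seed = opt$seed, n_truth = opt$n_truth,
    background_nodes = opt$background_nodes
  )
  write_synthetic_instance(spec, opt$out_dir)
  invisible(NULL)
}

cli_evaluate <- function(args) {
  parser <- optparse::OptionParser(
    usage = "warpnet evaluate [options]",
    option_list = list(
      optparse::make_option("--ranking", type = "character"),
      optparse::make_option("--relevant", type = "character"),
      optparse::make_option("--ks", type = "character", default = "100,200")
    )
  )
  opt <- optparse::parse_args(parser, args = args)
  ranking <- utils::read.table(opt$ranking,
    header = TRUE, sep = "\t",
    stringsAsFactors = FALSE
  )$gene
  if (is.null(ranking)) {
    stop("evaluate: ranking file needs a 'gene' column", call. = FALSE)
  }
  relevant <- read_gene_set(opt$relevant)
  ks <- as.integer(strsplit(opt$ks, ",")[[1L]])
  vals <- c(AveP = average_precision(ranking, relevant))
  for (k in ks) {
    if (length(ranking) >= k) {
      vals[[sprintf("Prec@%d", k)]] <- precision_at_k(ranking, relevant, k)
    }
  }
  cat(jsonlite::toJSON(as.list(vals), auto_unbox = TRUE, digits = NA), "\n")
  invisible(vals)
}
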