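test_that("prior vector puts uniform mass on surviving priors", {
  net <- network_from_edges(c("a", "b", "c"), c("b", "c", "d"))
  phi <- make_prior_vector(net, c("a", "b"))
  expect_equal(unname(phi[c("a", "b", "c", "d")]), c(0.5, 0.5, 0, 0))
  expect_equal(sum(phi), 1)
  expect_warning(phi2 <- make_prior_vector(net, c("a", "x")), "x")
  expect_equal(unname(phi2["a"]), 1)
  expect_error(make_prior_vector(net, character()), "disjoint")
  suppressWarnings(expect_error(make_prior_vector(net, c("x", "y")), "disjoint"))
})

test_that("restart kernel matches its formula limits and the hand-built path example", {
  net <- network_from_edges(c("a", "b"), c("b", "c"))
  K <- warp_with_curvature(net, beta = 0)
  phi <- make_prior_vector(net, "a")
  # gamma = 1: every column equals phi
  k1 <- as.matrix(make_prior_kernel(K, phi, 1))
  expect_equal(unname(k1), matrix(rep(c(1, 0, 0), 3), 3), tolerance = 1e-15)
  # gamma = 0: column-normalized K
  k0 <- as.matrix(make_prior_kernel(K, phi, 0))
  expect_equal(unname(k0[, 2]), c(0.5, 0, 0.5))
  # gamma = 0.5: column b = (0.75, 0, 0.25), assembled by hand
  kh <- as.matrix(make_prior_kernel(K, phi, 0.5))
  expect_equal(unname(kh[, "b"]), c(0.75, 0, 0.25), tolerance = 1e-15)
})

test_that("kernel columns sum to one and dangling nodes restart", {
  for (seed in 1:5) {
    net <- rand_network(14, 0.25, seed)
    K <- warp_with_curvature(net, beta = 0.8)
    phi <- make_prior_vector(net, network_nodes(net)[1:3])
    kern <- make_prior_kernel(K, phi, 0.5)
    expect_equal(colSums(as.matrix(kern)), setNames(rep(1, 14), network_nodes(net)),
      tolerance = 1e-14
    )
  }
  # dangling column: zero-degree node under a K with an all-zero column
  Kz <- Matrix::sparseMatrix(
    i = c(1, 2), j = c(2, 1), x = c(0.5, 0.5), dims = c(3, 3),
    dimnames = rep(list(c("a", "b", "c")), 2)
  )
  phi <- c(a = 1, b = 0, c = 0)
  expect_message(kd <- make_prior_kernel(Kz, phi, 0.5), "restart")
  expect_equal(unname(as.matrix(kd)[, "c"]), c(1, 0, 0))
  expect_error(make_prior_kernel(Kz, phi, 0), "dangling")
})

test_that("stationary solves agree with each other and the dense oracle", {
  # restart-only chain returns phi exactly
  net <- fig2_graph()
  K <- warp_with_curvature(net, 0.5)
  phi <- make_prior_vector(net, c("l1", "r2"))
  expect_equal(as.numeric(stationary_distribution(make_prior_kernel(K, phi, 1))),
    unname(phi),
    tolerance = 1e-15
  )
  # two-node single edge, gamma = 0.5: direct 2x2 solve vs power iteration
  two <- network_from_edges("a", "b")
  K2 <- suppressWarnings(warp_with_curvature(two, 0.5))
  phi2 <- make_prior_vector(two, "a")
  kern2 <- make_prior_kernel(K2, phi2, 0.5)
  direct <- oracle_stationary(as.matrix(kern2$W), unname(phi2), 0.5)
  powered <- stationary_distribution(kern2, method = "power", tol = 1e-14)
  expect_equal(as.numeric(powered), direct, tolerance = 1e-10)
  expect_equal(as.numeric(stationary_distribution(kern2)), direct, tolerance = 1e-12)
  # random graphs: linear vs power vs dense oracle
  for (seed in 1:8) {
    net <- rand_network(16, 0.2, seed)
    K <- warp_with_curvature(net, 0.7)
    phi <- make_prior_vector(net, network_nodes(net)[1:2])
    kern <- make_prior_kernel(K, phi, 0.4)
    lin <- stationary_distribution(kern, method = "linear")
    pow <- stationary_distribution(kern, method = "power", tol = 1e-13)
    ora <- oracle_stationary(as.matrix(kern$W), unname(phi), 0.4)
    expect_equal(as.numeric(lin), ora, tolerance = 1e-10)
    expect_equal(as.numeric(pow), ora, tolerance = 1e-10)
    expect_lt(attr(lin, "residual"), 1e-10)
    expect_true(all(lin > 0)) # irreducible restart chain
    expect_equal(sum(lin), 1)
  }
})

test_that("gamma = 0 uses the dominant eigenvector and refuses degenerate chains", {
  net <- rand_network(10, 0.35, 3) # connected, contains triangles
  K <- warp_with_curvature(net, 0.5)
  phi <- make_prior_vector(net, network_nodes(net)[1])
  kern <- make_prior_kernel(K, phi, 0)
  pow <- stationary_distribution(kern, method = "power", tol = 1e-13)
  eig <- eigen(as.matrix(kern$W))
  lead <- Re(eig$vectors[, which.max(Re(eig$values))])
  lead <- lead / sum(lead)
  expect_equal(as.numeric(pow), lead, tolerance = 1e-8)
  # disconnected: two separate edges
  disc <- network_from_edges(c("a", "c"), c("b", "d"))
  Kd <- suppressWarnings(warp_with_curvature(disc, 0))
  phid <- make_prior_vector(disc, "a")
  expect_error(
    stationary_distribution(make_prior_kernel(Kd, phid, 0), method = "power"),
    "disconnected"
  )
  # bipartite: a path graph
  path <- network_from_edges(c("a", "b"), c("b", "c"))
  Kp <- warp_with_curvature(path, 0)
  expect_error(
    stationary_distribution(
      make_prior_kernel(Kp, make_prior_vector(path, "a"), 0),
      method = "power"
    ),
    "bipartite"
  )
})

test_that("A* follows the ratio law and support rules", {
  net <- rand_network(8, 0.35, 11)
  K <- warp_with_curvature(net, 0.6)
  phi <- make_prior_vector(net, network_nodes(net)[1:2])
  pi <- stationary_distribution(make_prior_kernel(K, phi, 0.5))
  a_star <- warp_with_prior(K, pi)
  A <- weight_matrix(a_star)
  e <- net$edges
  for (r in seq_len(nrow(e))) {
    i <- e[r, 1L]
    j <- e[r, 2L]
    expect_equal(A[j, i] / A[i, j], as.numeric(pi[j] / pi[i]), tolerance = 1e-12)
    expect_equal(A[j, i], as.numeric(weight_matrix(K)[j, i] * pi[j]), tolerance = 1e-15)
  }
  expect_true(all((A > 0) == (Matrix::t(A) > 0)))
  # uniform pi scales K; indicator pi keeps a single nonzero row
  n <- length(network_nodes(net))
  unif <- warp_with_prior(K, rep(1 / n, n))
  expect_equal(
    as.matrix(weight_matrix(unif)),
    as.matrix(weight_matrix(K)) / n,
    tolerance = 1e-15
  )
  ind <- rep(0, n)
  ind[3] <- 1
  rows <- Matrix::rowSums(weight_matrix(warp_with_prior(K, ind)) != 0)
  expect_true(all(rows[-3] == 0))
})
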