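# small named builders
path_graph <- function(weights) {
  n <- length(weights) + 1
  w <- matrix(0, n, n)
  for (i in seq_along(weights)) w[i, i + 1] <- w[i + 1, i] <- weights[i]
  connectivity_matrix(w, state = "thresholded")
}
binary_graph <- function(edges, n) {
  w <- matrix(0, n, n)
  for (e in edges) w[e[1], e[2]] <- w[e[2], e[1]] <- 1
  connectivity_matrix(w, state = "binarized")
}

test_that("shortest paths invert weights and flag unreachable pairs", {
  m <- path_graph(c(1, 1))  # unit A-B-C
  d <- shortest_path_lengths(m)
  expect_equal(d[1, 3], 2)

  tri <- connectivity_matrix(
    matrix(c(0, 1, .5, 1, 0, .5, .5, .5, 0), 3), state = "thresholded")
  d <- shortest_path_lengths(tri)
  # direct edges beat any 2-hop detour: lengths 1, 2, 2
  expect_equal(sort(d[upper.tri(d)]), c(1, 2, 2))

  dyads <- binary_graph(list(c(1, 2), c(3, 4)), 4)
  d <- shortest_path_lengths(dyads)
  expect_true(is.infinite(d[1, 3]))
  expect_equal(d[1, 2], 1)

  neg <- connectivity_matrix(matrix(c(0, -.5, -.5, 0), 2), state = "raw")
  neg$state <- "thresholded"
  expect_error(shortest_path_lengths(neg), "negative")
})

test_that("distance metrics omit diagonal and infinite entries", {
  d <- shortest_path_lengths(path_graph(c(1, 1)))
  dm <- distance_metrics(d)
  expect_equal(dm$cpl, 4 / 3)                       # mean{1,1,2}
  expect_equal(dm$global_efficiency, 5 / 6)         # mean{1,1,1/2}
  expect_equal(dm$radius, 1)
  expect_equal(dm$diameter, 2)

  dm2 <- distance_metrics(shortest_path_lengths(binary_graph(
    list(c(1, 2), c(3, 4)), 4)))
  expect_equal(dm2$cpl, 1)        # finite pairs only
  expect_equal(dm2$diameter, 1)

  k4 <- binary_graph(utils::combn(4, 2, simplify = FALSE), 4)
  dm3 <- distance_metrics(shortest_path_lengths(k4))
  expect_equal(dm3$cpl, 1)
  expect_equal(dm3$global_efficiency, 1)
  expect_equal(dm3$radius, 1)
  expect_equal(dm3$diameter, 1)

  none <- distance_metrics(shortest_path_lengths(
    connectivity_matrix(matrix(0, 3, 3), state = "thresholded")))
  expect_true(is.na(none$cpl))
})

test_that("largest cluster counts isolated nodes as singletons", {
  expect_equal(largest_cluster_size(binary_graph(
    list(c(1, 2), c(2, 3), c(3, 4), c(4, 5)), 5)), 5)
  # components 4 + 3 + 2
  comps <- binary_graph(list(c(1, 2), c(2, 3), c(3, 4), c(1, 4),
                             c(5, 6), c(6, 7), c(8, 9)), 9)
  expect_equal(largest_cluster_size(comps), 4)
  expect_equal(oracle_largest_component(comps$weights), 4)
  expect_equal(largest_cluster_size(
    connectivity_matrix(matrix(0, 90, 90), state = "thresholded")), 1)
})

test_that("nodal metrics match closed forms on stars and triangles", {
  star <- binary_graph(list(c(1, 2), c(1, 3), c(1, 4), c(1, 5)), 5)
  nm <- nodal_metrics(star)
  expect_equal(nm$degree, c(4, 1, 1, 1, 1))
  expect_equal(nm$betweenness[1], 6)  # C(4,2) leaf pairs
  expect_equal(nm$betweenness[-1], rep(0, 4))
  expect_equal(nm$clustering, rep(0, 5))

  tri <- binary_graph(list(c(1, 2), c(2, 3), c(1, 3)), 3)
  nmt <- nodal_metrics(tri)
  expect_equal(nmt$clustering, rep(1, 3))
  expect_equal(nmt$local_efficiency, rep(1, 3))
  expect_equal(nmt$eigenvector, rep(1 / sqrt(3), 3))

  w <- matrix(0, 3, 3)
  w[1, 2] <- w[2, 1] <- 0.2
  w[1, 3] <- w[3, 1] <- 0.3
  m <- connectivity_matrix(w, state = "thresholded")
  expect_equal(nodal_metrics(m)$strength[1], 0.5)
})

test_that("weighted nodal metrics agree with brute-force oracles on small graphs", {
  for (s in 1:30) {
    m <- random_conn(sample(4:7, 1), p = 0.6, seed = s)
    nm <- nodal_metrics(m)
    expect_equal(nm$betweenness, oracle_betweenness(m$weights), tolerance = 1e-8)
    d <- shortest_path_lengths(m)
    expect_equal(d, oracle_distances(m$weights), ignore_attr = TRUE)
    mb <- binarize(m)
    expect_equal(nodal_metrics(mb)$clustering,
                 oracle_clustering_binary(mb$weights))
  }
})

test_that("on binarized input the weighted formulas reduce to binary ones", {
  for (s in 1:5) {
    mb <- binarize(random_conn(12, p = 0.35, seed = s + 100))
    nm <- nodal_metrics(mb)
    g <- igraph::graph_from_adjacency_matrix(mb$weights, mode = "undirected")
    expect_equal(nm$degree, as.numeric(igraph::degree(g)))
    expect_equal(nm$strength, as.numeric(igraph::degree(g)))
    ig_cc <- unname(igraph::transitivity(g, type = "local", isolates = "zero"))
    ig_cc[igraph::degree(g) < 2] <- 0
    expect_equal(nm$clustering, ig_cc)
  }
})

test_that("Louvain communities recover planted cliques with Q = 0.5", {
  two_k4 <- binary_graph(c(utils::combn(4, 2, simplify = FALSE),
                           lapply(utils::combn(4, 2, simplify = FALSE),
                                  function(e) e + 4)), 8)
  cm <- community_metrics(two_k4, seed = 7, restarts = 10)
  expect_equal(cm$Q, 0.5)
  expect_equal(length(unique(cm$partition)), 2)
  expect_true(all(cm$participation == 0))  # all edges within-module

  # strength split equally across two modules -> p = 0.5
  w <- matrix(0, 5, 5)
  w[1, 2] <- w[2, 1] <- 1; w[1, 3] <- w[3, 1] <- 1
  part <- c(1, 1, 2, 1, 2)
  pc <- participation_coefficient(w, part)
  expect_equal(pc[1], 0.5)
  expect_equal(pc[4], 0)  # isolated node

  edgeless <- connectivity_matrix(matrix(0, 4, 4), state = "thresholded")
  expect_true(is.na(community_metrics(edgeless)$Q))
})

test_that("returned Louvain partition never scores below the trivial one", {
  for (s in 1:5) {
    m <- random_conn(15, p = 0.3, seed = s + 40)
    cm <- community_metrics(m, seed = s, restarts = 5)
    expect_gte(cm$Q, 0)
  }
})

test_that("transitivity and assortativity match closed forms", {
  tri <- binary_graph(list(c(1, 2), c(2, 3), c(1, 3)), 3)
  expect_equal(network_metrics(tri)$transitivity, 1)

  star <- binary_graph(list(c(1, 2), c(1, 3), c(1, 4), c(1, 5)), 5)
  nm <- network_metrics(star)
  expect_equal(nm$transitivity, 0)
  expect_equal(nm$assortativity, -1)

  cyc <- binary_graph(list(c(1, 2), c(2, 3), c(3, 4), c(1, 4)), 4)
  expect_equal(network_metrics(cyc)$transitivity, 0)

  dyad <- binary_graph(list(c(1, 2)), 3)
  expect_true(is.na(network_metrics(dyad)$transitivity))

  # binary assortativity agrees with igraph's
  for (s in 1:5) {
    mb <- binarize(random_conn(12, p = 0.4, seed = s + 60))
    g <- igraph::graph_from_adjacency_matrix(mb$weights, mode = "undirected")
    expect_equal(network_metrics(mb)$assortativity,
                 igraph::assortativity_degree(g), tolerance = 1e-10)
  }
})

test_that("sigma is 1 when a network is its own null", {
  m <- binarize(random_conn(20, p = 0.3, seed = 8))
  C <- mean(clustering_onnela(m$weights))
  L <- distance_metrics(shortest_path_lengths(m))$cpl
  expect_equal((C / C) / (L / L), 1)
  sw <- small_worldness(m, n_null = 5, seed = 3)
  expect_true(is.finite(sw$sigma))
  expect_equal(sw$C, C)
  expect_equal(sw$L, L)
})

test_that("tail fraction flags hubs of heavy-tailed degree distributions", {
  reg <- binary_graph(list(c(1, 2), c(2, 3), c(3, 4), c(1, 4)), 4)
  expect_equal(degree_distribution_summary(reg)$tail_fraction, 0)

  star9 <- binary_graph(lapply(2:10, function(j) c(1, j)), 10)
  expect_equal(degree_distribution_summary(star9)$tail_fraction, 0.1)

  empty <- connectivity_matrix(matrix(0, 5, 5), state = "thresholded")
  expect_equal(degree_distribution_summary(empty)$tail_fraction, 0)
})

test_that("global quantifier sets are internally consistent", {
  m <- random_conn(20, p = 0.25, seed = 12)
  gq <- global_quantifiers(m, which = "all", seed = 1,
                           louvain_restarts = 5, n_null = 3)
  expect_equal(gq$avg_degree, 2 * n_edges(m) / 20)
  expect_equal(gq$density, n_edges(m) / 190)
  expect_gte(gq$radius, 0)
  expect_lte(gq$radius, gq$diameter)
  expect_gte(gq$global_efficiency, 0)
  expect_lte(gq$largest_cluster, 20)
  expect_error(global_quantifiers(m, which = "bogus"), "unknown quantifier")
})
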