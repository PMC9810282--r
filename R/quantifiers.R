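#' All-pairs shortest path lengths
#'
#' Edge lengths are the reciprocal of edge weights for weighted input (strong
#' correlations = short functional distance) and 1 for binarized input.
#' Unreachable pairs get `Inf`.
#'
#' @param m a thresholded or binarized `connectivity_matrix`.
#' @return n x n symmetric matrix of shortest-path lengths with zero diagonal.
#' @export
shortest_path_lengths <- function(m) {
  if (!m$state %in% c("thresholded", "binarized")) {
    stop("shortest paths expect a thresholded or binarized matrix")
  }
  if (any(m$weights < 0)) stop("negative weights are not allowed")
  g <- as_igraph(m, weighted = TRUE)
  wts <- igraph::E(g)$weight
  d <- igraph::distances(g, weights = if (length(wts)) 1 / wts else NULL)
  dimnames(d) <- list(m$labels, m$labels)
  d
}

#' Integration metrics from a distance matrix
#'
#' Characteristic path length, global efficiency, radius and diameter.
#' Diagonal and infinite distances are omitted throughout, so fragmented
#' networks still yield finite values: CPL is the mean finite off-diagonal
#' distance, efficiency the mean reciprocal over the same pairs, and
#' eccentricities use each node's maximum finite distance (nodes with no
#' finite partner are excluded from radius/diameter).
#'
#' @param d distance matrix from [shortest_path_lengths()].
#' @return list with `cpl`, `global_efficiency`, `radius`, `diameter`; all
#'   `NA` if no finite off-diagonal entry exists.
#' @export
distance_metrics <- function(d) {
  off <- d[row(d) != col(d)]
  fin <- off[is.finite(off)]
  if (!length(fin)) {
    return(list(cpl = NA_real_, global_efficiency = NA_real_,
                radius = NA_real_, diameter = NA_real_))
  }
  dd <- d
  diag(dd) <- NA
  dd[!is.finite(dd)] <- NA
  ecc <- apply(dd, 1, function(r) if (all(is.na(r))) NA_real_ else max(r, na.rm = TRUE))
  list(cpl = mean(fin),
       global_efficiency = mean(1 / fin),
       radius = min(ecc, na.rm = TRUE),
       diameter = max(ecc, na.rm = TRUE))
}

#' Size of the largest connected component
#'
#' Any nonzero weight counts as an edge; isolated nodes are components of
#' size 1, so a nonempty edgeless network returns 1.
#'
#' @param m a `connectivity_matrix`.
#' @return integer node count.
#' @export
largest_cluster_size <- function(m) {
  n <- n_regions(m)
  if (n == 0) return(0L)
  comp <- igraph::components(as_igraph(m, weighted = FALSE))
  as.integer(max(comp$csize))
}

# internal: membership vector of largest component, ties -> component holding
# the lowest node index among tied sizes is NOT used; see disconnected_after
component_membership <- function(m) {
  igraph::components(as_igraph(m, weighted = FALSE))
}

#' Nodal quantifier table
#'
#' Per-region metrics of the weighted network:
#' \itemize{
#'  \item `degree`: count of nonzero neighbors;
#'  \item `strength`: sum of incident edge weights;
#'  \item `betweenness`: weighted shortest-path betweenness (lengths = 1/w),
#'    endpoints excluded, unnormalized path counts;
#'  \item `eigenvector`: absolute leading eigenvector of the weight matrix,
#'    unit Euclidean norm;
#'  \item `clustering`: weighted clustering coefficient (geometric mean of
#'    triangle weights, normalized by the maximum weight);
#'  \item `local_efficiency`: efficiency of each node's neighborhood subgraph
#'    in the weighted formulation (cube-root weighted path contributions).
#' }
#'
#' @param m a thresholded or binarized `connectivity_matrix`.
#' @return data frame with one row per region.
#' @export
nodal_metrics <- function(m) {
  if (!m$state %in% c("thresholded", "binarized")) {
    stop("nodal metrics expect a thresholded or binarized matrix")
  }
  w <- m$weights
  a <- (w != 0) * 1
  deg <- rowSums(a)
  g <- as_igraph(m, weighted = TRUE)
  wts <- igraph::E(g)$weight
  btw <- igraph::betweenness(g, weights = if (length(wts)) 1 / wts else NULL,
                             normalized = FALSE)
  data.frame(label = m$labels,
             degree = as.integer(deg),
             strength = rowSums(w),
             betweenness = as.numeric(btw),
             eigenvector = eigenvector_centrality(w),
             clustering = clustering_onnela(w),
             local_efficiency = local_efficiency_weighted(w),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Eigenvector centrality
#'
#' Absolute value of the leading eigenvector of the (nonnegative) weight
#' matrix, scaled to unit Euclidean norm. On disconnected networks the mass
#' concentrates on the dominant component.
#'
#' @param w square symmetric nonnegative weight matrix.
#' @return numeric vector of centralities.
#' @export
eigenvector_centrality <- function(w) {
  n <- nrow(w)
  if (n == 0) return(numeric(0))
  if (all(w == 0)) return(rep(1 / sqrt(n), n))
  v <- abs(eigen(w, symmetric = TRUE)$vectors[, 1])
  v / sqrt(sum(v^2))
}

#' Weighted clustering coefficient (geometric-mean triangle weights)
#'
#' For each node i, the mean geometric triangle intensity
#' \eqn{C_i = \sum_{jh} (\hat w_{ij}\hat w_{ih}\hat w_{jh})^{1/3} / (k_i(k_i-1))}
#' with weights normalized by the matrix maximum; reduces to the binary
#' clustering coefficient on 0/1 input. Nodes of degree < 2 get 0.
#'
#' @param w square symmetric nonnegative weight matrix.
#' @return numeric vector of clustering coefficients in \[0, 1\].
#' @export
clustering_onnela <- function(w) {
  n <- nrow(w)
  if (n == 0) return(numeric(0))
  mx <- max(w)
  if (mx == 0) return(rep(0, n))
  cw <- (w / mx)^(1 / 3)
  k <- rowSums(w != 0)
  cyc <- diag(cw %*% cw %*% cw)
  out <- rep(0, n)
  ok <- k >= 2
  out[ok] <- cyc[ok] / (k[ok] * (k[ok] - 1))
  out
}

#' Weighted local efficiency
#'
#' Efficiency of information transfer around each node when the node itself
#' is removed: paths between its neighbors are scored on the cube-root
#' weighted subgraph restricted to the neighborhood, and each pair's inverse
#' path length is weighted by the cube-root connection weights to the center
#' (the standard weighted formulation used with proportionally thresholded
#' correlation networks). Nodes of degree < 2 get 0.
#'
#' @param w square symmetric nonnegative weight matrix.
#' @return numeric vector of local efficiencies.
#' @export
local_efficiency_weighted <- function(w) {
  n <- nrow(w)
  out <- rep(0, n)
  if (n == 0) return(out)
  mx <- max(w)
  if (mx == 0) return(out)
  wn <- w / mx
  cw <- wn^(1 / 3)
  a <- (w != 0) * 1
  for (i in seq_len(n)) {
    nb <- which(a[i, ] != 0)
    k <- length(nb)
    if (k < 2) next
    sub <- cw[nb, nb, drop = FALSE]
    g <- igraph::graph_from_adjacency_matrix(sub, mode = "undirected",
                                             weighted = TRUE, diag = FALSE)
    ws <- igraph::E(g)$weight
    dsub <- igraph::distances(g, weights = if (length(ws)) 1 / ws else NULL)
    e <- 1 / dsub
    diag(e) <- 0
    e[!is.finite(e)] <- 0
    sw <- cw[i, nb]
    num <- sum((sw %o% sw) * e)
    out[i] <- num / (k * (k - 1))
  }
  out
}

#' Louvain communities, modularity and participation coefficients
#'
#' Runs Louvain community detection `restarts` times under seeded random node
#' orders and keeps the partition with the highest weighted modularity Q
#' (resolution 1). The participation coefficient of node i is
#' \eqn{p_i = 1 - \sum_c (s_{i,c}/s_i)^2} over the chosen partition; isolated
#' nodes get 0.
#'
#' @param m a thresholded or binarized `connectivity_matrix`.
#' @param seed integer RNG seed for the restarts.
#' @param restarts number of random-order restarts (default 100).
#' @return list with `Q`, `partition` (integer module ids) and
#'   `participation` (numeric vector). On an edgeless network `Q` is `NA`.
#' @export
community_metrics <- function(m, seed = 1L, restarts = 100L) {
  if (!m$state %in% c("thresholded", "binarized")) {
    stop("community metrics expect a thresholded or binarized matrix")
  }
  n <- n_regions(m)
  if (n_edges(m) == 0) {
    return(list(Q = NA_real_, partition = rep(1L, n), participation = rep(0, n)))
  }
  g <- as_igraph(m, weighted = TRUE)
  best_q <- -Inf
  best_part <- NULL
  with_seed(seed, {
    for (r in seq_len(restarts)) {
      perm <- sample.int(n)
      gp <- igraph::permute(g, perm)
      cl <- igraph::cluster_louvain(gp, weights = igraph::E(gp)$weight)
      # permute() sends old vertex i to new index perm[i]
      memb <- as.integer(igraph::membership(cl))[perm]
      q <- igraph::modularity(g, memb, weights = igraph::E(g)$weight)
      if (q > best_q) {
        best_q <- q
        best_part <- memb
      }
    }
  })
  list(Q = best_q, partition = as.integer(best_part),
       participation = participation_coefficient(m$weights, best_part))
}

#' Participation coefficient
#'
#' @param w square symmetric nonnegative weight matrix.
#' @param partition integer module assignment per node.
#' @return numeric vector; 1 minus the sum of squared within-module strength
#'   fractions. Isolated nodes get 0.
#' @export
participation_coefficient <- function(w, partition) {
  n <- nrow(w)
  s <- rowSums(w)
  out <- rep(0, n)
  for (i in seq_len(n)) {
    if (s[i] == 0) next
    sc <- tapply(w[i, ], partition, sum)
    out[i] <- 1 - sum((sc / s[i])^2)
  }
  out
}

#' Transitivity and degree assortativity
#'
#' Weighted transitivity is the ratio of the total geometric-mean triangle
#' intensity to the total number of connected triples,
#' \eqn{T = \sum_i \mathrm{cyc}_i / \sum_i k_i(k_i-1)} with max-normalized
#' weights; it reduces to the closed-triple ratio on binary graphs.
#' Assortativity is the Pearson correlation of endpoint degrees over edges.
#'
#' @param m a thresholded or binarized `connectivity_matrix`.
#' @return list with `transitivity` and `assortativity`; each `NA` when
#'   undefined (no connected triples / fewer than 2 edges or constant degree).
#' @export
network_metrics <- function(m) {
  if (!m$state %in% c("thresholded", "binarized")) {
    stop("network metrics expect a thresholded or binarized matrix")
  }
  w <- m$weights
  a <- (w != 0) * 1
  k <- rowSums(a)
  denom <- sum(k * (k - 1))
  if (denom == 0) {
    trans <- NA_real_
  } else {
    mx <- max(w)
    cw <- (w / mx)^(1 / 3)
    trans <- sum(diag(cw %*% cw %*% cw)) / denom
  }
  idx <- which(upper.tri(a) & a != 0, arr.ind = TRUE)
  if (nrow(idx) < 2) {
    assort <- NA_real_
  } else {
    di <- c(k[idx[, 1]], k[idx[, 2]])
    dj <- c(k[idx[, 2]], k[idx[, 1]])
    assort <- suppressWarnings(stats::cor(di, dj))
    if (is.na(assort)) assort <- NA_real_
  }
  list(transitivity = trans, assortativity = assort)
}

#' Small-worldness sigma
#'
#' \eqn{\sigma = (C/C_{rand}) / (L/L_{rand})} where C is the mean clustering
#' coefficient, L the characteristic path length over finite pairs, and the
#' null values are means over `n_null` degree-preserving rewired versions of
#' the network (10 swap attempts per edge). For weighted networks the edge
#' weights are randomly reassigned to the rewired edges, preserving the
#' weight distribution. Sigma > 1 indicates small-world topology.
#'
#' @param m a thresholded or binarized `connectivity_matrix`.
#' @param n_null number of null networks (default 20).
#' @param seed RNG seed.
#' @return list with `sigma`, `C`, `L`, `C_rand`, `L_rand`; `sigma` is `NA`
#'   when the null ensemble is degenerate (no clustering or no finite paths).
#' @export
small_worldness <- function(m, n_null = 20L, seed = 1L) {
  if (!m$state %in% c("thresholded", "binarized")) {
    stop("small-worldness expects a thresholded or binarized matrix")
  }
  C <- mean(clustering_onnela(m$weights))
  L <- distance_metrics(shortest_path_lengths(m))$cpl
  g <- as_igraph(m, weighted = TRUE)
  ne <- igraph::ecount(g)
  if (ne == 0) return(list(sigma = NA_real_, C = C, L = L,
                           C_rand = NA_real_, L_rand = NA_real_))
  wts <- igraph::E(g)$weight
  cs <- numeric(n_null)
  ls <- numeric(n_null)
  with_seed(seed, {
    for (b in seq_len(n_null)) {
      gr <- igraph::rewire(g, igraph::keeping_degseq(niter = 10 * ne))
      wr <- matrix(0, n_regions(m), n_regions(m))
      el <- igraph::as_edgelist(gr, names = FALSE)
      perm_w <- sample(wts)
      wr[el] <- perm_w
      wr <- wr + t(wr)
      cs[b] <- mean(clustering_onnela(wr))
      mr <- m
      mr$weights <- wr
      dimnames(mr$weights) <- dimnames(m$weights)
      ls[b] <- distance_metrics(shortest_path_lengths(mr))$cpl
    }
  })
  C_rand <- mean(cs)
  L_rand <- mean(ls, na.rm = TRUE)
  sigma <- if (is.na(C_rand) || C_rand == 0 || is.na(L_rand) || L_rand == 0 ||
               is.na(L) || is.na(C)) NA_real_ else (C / C_rand) / (L / L_rand)
  list(sigma = sigma, C = C, L = L, C_rand = C_rand, L_rand = L_rand)
}

#' Degree distribution summary
#'
#' Degree histogram plus a descriptive tail statistic: the fraction of nodes
#' whose degree exceeds twice the mean degree (hubs of a heavy-tailed
#' distribution).
#'
#' @param m a `connectivity_matrix`.
#' @return list with `histogram` (table of degree counts) and `tail_fraction`.
#' @export
degree_distribution_summary <- function(m) {
  deg <- rowSums(m$weights != 0)
  mean_deg <- mean(deg)
  tail_fraction <- if (length(deg) == 0 || mean_deg == 0) 0 else
    mean(deg > 2 * mean_deg)
  list(histogram = table(factor(deg, levels = 0:max(deg, 0))),
       tail_fraction = tail_fraction)
}

# The full set of global quantifier names global_quantifiers() understands.
CHEAP_GLOBALS <- c("largest_cluster", "n_edges", "density", "avg_degree",
                   "avg_strength", "cpl", "global_efficiency", "radius",
                   "diameter", "avg_betweenness", "avg_clustering",
                   "avg_eigenvector", "avg_local_efficiency")
ALL_GLOBALS <- c(CHEAP_GLOBALS, "modularity", "avg_participation",
                 "transitivity", "assortativity", "small_worldness")

#' Global quantifier set
#'
#' Computes a named set of global network quantifiers. The default set covers
#' the cheap metrics tracked along attack trajectories; the full battery adds
#' modularity, participation, transitivity, assortativity and small-world
#' sigma (the expensive ones, intended for the unattacked networks).
#'
#' @param m a thresholded or binarized `connectivity_matrix`.
#' @param which character vector of quantifier names (see
#'   `percnet:::ALL_GLOBALS`), or `"all"`.
#' @param seed RNG seed for modularity restarts / small-world nulls.
#' @param louvain_restarts restarts for Louvain (default 100).
#' @param n_null null networks for sigma (default 20).
#' @return named list of numeric values.
#' @export
global_quantifiers <- function(m, which = CHEAP_GLOBALS, seed = 1L,
                               louvain_restarts = 100L, n_null = 20L) {
  if (identical(which, "all")) which <- ALL_GLOBALS
  bad <- setdiff(which, ALL_GLOBALS)
  if (length(bad)) stop("unknown quantifier(s): ", paste(bad, collapse = ", "))
  out <- list()
  n <- n_regions(m)
  need_dist <- any(c("cpl", "global_efficiency", "radius", "diameter") %in% which)
  dm <- if (need_dist) distance_metrics(shortest_path_lengths(m)) else NULL
  avg_btw <- if ("avg_betweenness" %in% which) {
    g <- as_igraph(m, weighted = TRUE)
    wts <- igraph::E(g)$weight
    mean(igraph::betweenness(g, weights = if (length(wts)) 1 / wts else NULL,
                             normalized = FALSE))
  }
  comm <- if (any(c("modularity", "avg_participation") %in% which))
    community_metrics(m, seed = seed, restarts = louvain_restarts) else NULL
  net <- if (any(c("transitivity", "assortativity") %in% which))
    network_metrics(m) else NULL
  for (q in which) {
    out[[q]] <- switch(q,
      largest_cluster = as.numeric(largest_cluster_size(m)),
      n_edges = as.numeric(n_edges(m)),
      density = graph_density(m),
      avg_degree = 2 * n_edges(m) / n,
      avg_strength = mean(rowSums(m$weights)),
      cpl = dm$cpl,
      global_efficiency = dm$global_efficiency,
      radius = dm$radius,
      diameter = dm$diameter,
      avg_betweenness = avg_btw,
      avg_clustering = mean(clustering_onnela(m$weights)),
      avg_eigenvector = mean(eigenvector_centrality(m$weights)),
      avg_local_efficiency = mean(local_efficiency_weighted(m$weights)),
      modularity = comm$Q,
      avg_participation = mean(comm$participation),
      transitivity = net$transitivity,
      assortativity = net$assortativity,
      small_worldness = small_worldness(m, n_null = n_null, seed = seed)$sigma
    )
  }
  out
}
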