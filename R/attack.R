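#' Remove a node from a connectivity matrix
#'
#' Node removal by zeroing: the node's row and column are set to zero while
#' the matrix dimension is unchanged, so node indexing stays stable across
#' attack snapshots and the removed node persists as an isolate.
#'
#' @param m a `connectivity_matrix`.
#' @param node node index (1-based) or label.
#' @return the attacked `connectivity_matrix`.
#' @export
remove_node <- function(m, node) {
  i <- resolve_node(m, node)
  m$weights[i, ] <- 0
  m$weights[, i] <- 0
  m
}

# internal: label or index -> index, with range check
resolve_node <- function(m, node) {
  if (is.character(node)) {
    i <- match(node, m$labels)
    if (is.na(i)) stop("unknown node label: ", node)
  } else {
    i <- as.integer(node)
    if (is.na(i) || i < 1 || i > n_regions(m)) stop("node index out of range: ", node)
  }
  i
}

# nodal quantifiers available as attack criteria
ATTACK_QUANTIFIERS <- c("degree", "strength", "betweenness", "eigenvector",
                        "clustering", "local_efficiency", "participation", "ci")

# internal: vector of the chosen nodal quantifier on the current matrix
nodal_quantifier_vector <- function(m, quantifier, seed = 1L,
                                    louvain_restarts = 20L, ci_ell = 2L) {
  switch(quantifier,
    degree = rowSums(m$weights != 0),
    strength = rowSums(m$weights),
    betweenness = {
      g <- as_igraph(m, weighted = TRUE)
      wts <- igraph::E(g)$weight
      as.numeric(igraph::betweenness(g, weights = if (length(wts)) 1 / wts else NULL,
                                     normalized = FALSE))
    },
    eigenvector = eigenvector_centrality(m$weights),
    clustering = clustering_onnela(m$weights),
    local_efficiency = local_efficiency_weighted(m$weights),
    participation = {
      if (n_edges(m) == 0) rep(0, n_regions(m))
      else community_metrics(m, seed = seed, restarts = louvain_restarts)$participation
    },
    ci = collective_influence_scores(m, ell = ci_ell),
    stop("unknown attack quantifier: ", quantifier)
  )
}

#' Basis attack order
#'
#' Nodes ranked by a nodal quantifier computed once on the unaltered network,
#' descending; ties broken by ascending node index. This is the removal order
#' of a basis attack (and of the collective-influence attack, which is basis
#' only).
#'
#' @param m a thresholded or binarized `connectivity_matrix`.
#' @param quantifier one of `degree`, `strength`, `betweenness`,
#'   `eigenvector`, `clustering`, `local_efficiency`, `participation`, `ci`.
#' @param seed RNG seed (participation's Louvain restarts).
#' @param ci_ell ball radius for `ci`.
#' @return integer vector: a permutation of `1:n`.
#' @export
basis_attack_order <- function(m, quantifier, seed = 1L, ci_ell = 2L) {
  quantifier <- match.arg(quantifier, ATTACK_QUANTIFIERS)
  v <- nodal_quantifier_vector(m, quantifier, seed = seed, ci_ell = ci_ell)
  order(-v, seq_along(v))
}

#' Run a targeted attack
#'
#' Removes all n nodes one at a time and snapshots global quantifiers after
#' every removal. `scheme = "basis"` follows the precomputed ranking of the
#' intact network (it may therefore "remove" nodes that are already
#' disconnected — a known property of basis attacks, reproduced rather than
#' patched); `scheme = "iterative"` recomputes the quantifier on the current
#' network before each removal and takes the maximum (ties to the lowest
#' index).
#'
#' @param m a thresholded or binarized `connectivity_matrix`.
#' @param scheme `"basis"` or `"iterative"`.
#' @param quantifier nodal quantifier driving the attack (see
#'   [basis_attack_order()]).
#' @param seed RNG seed.
#' @param track character vector of global quantifiers to snapshot (default
#'   the cheap set; see [global_quantifiers()]).
#' @param ci_ell ball radius when `quantifier = "ci"`.
#' @return an `attack_trajectory`: list with `scheme`, `quantifier`,
#'   `removal_order` (indices), `removal_labels`, `snapshots` (data frame,
#'   n+1 rows; row t+1 = after t removals, column `step` = removals so far),
#'   `n_reps = 1`, `seed`.
#' @export
run_targeted_attack <- function(m, scheme = c("basis", "iterative"),
                                quantifier = "degree", seed = 1L,
                                track = c("largest_cluster", "n_edges",
                                          "avg_degree", "avg_strength",
                                          "cpl", "global_efficiency",
                                          "avg_betweenness", "avg_clustering"),
                                ci_ell = 2L) {
  scheme <- match.arg(scheme)
  quantifier <- match.arg(quantifier, ATTACK_QUANTIFIERS)
  if (scheme == "iterative" && quantifier == "ci") {
    stop("collective influence is available as a basis attack only")
  }
  n <- n_regions(m)
  snaps <- vector("list", n + 1)
  snaps[[1]] <- global_quantifiers(m, which = track, seed = seed)
  removal <- integer(n)
  cur <- m
  if (scheme == "basis") {
    removal <- basis_attack_order(m, quantifier, seed = seed, ci_ell = ci_ell)
    for (t in seq_len(n)) {
      cur <- remove_node(cur, removal[t])
      snaps[[t + 1]] <- global_quantifiers(cur, which = track, seed = seed)
    }
  } else {
    alive <- rep(TRUE, n)
    for (t in seq_len(n)) {
      v <- nodal_quantifier_vector(cur, quantifier, seed = seed, ci_ell = ci_ell)
      v[!alive] <- -Inf
      pick <- which.max(v)  # which.max takes the first (lowest index) on ties
      removal[t] <- pick
      alive[pick] <- FALSE
      cur <- remove_node(cur, pick)
      snaps[[t + 1]] <- global_quantifiers(cur, which = track, seed = seed)
    }
  }
  new_attack_trajectory(scheme, quantifier, removal, m$labels, snaps,
                        n_reps = 1L, seed = seed)
}

#' Random attack ensemble
#'
#' Runs `n_reps` independent uniformly random removal permutations and
#' averages each tracked global quantifier across repetitions at every step.
#' The stored `removal_order` is that of the first repetition.
#'
#' @param m a thresholded or binarized `connectivity_matrix`.
#' @param n_reps number of random permutations (default 100).
#' @param seed RNG seed; rep r uses a seed derived from it.
#' @param track global quantifiers to snapshot.
#' @return an `attack_trajectory` with `scheme = "random"` and
#'   `n_reps = n_reps`; snapshots are per-step ensemble means.
#' @export
random_attack_ensemble <- function(m, n_reps = 100L, seed = 1L,
                                   track = c("largest_cluster", "n_edges",
                                             "avg_degree", "avg_strength")) {
  if (n_reps < 1) stop("n_reps must be >= 1")
  n <- n_regions(m)
  acc <- matrix(0, n + 1, length(track), dimnames = list(NULL, track))
  first_order <- NULL
  for (r in seq_len(n_reps)) {
    perm <- with_seed(seed + r - 1L, sample.int(n))
    if (r == 1) first_order <- perm
    cur <- m
    acc[1, ] <- acc[1, ] + unlist(global_quantifiers(cur, which = track, seed = seed))
    for (t in seq_len(n)) {
      cur <- remove_node(cur, perm[t])
      acc[t + 1, ] <- acc[t + 1, ] +
        unlist(global_quantifiers(cur, which = track, seed = seed))
    }
  }
  snaps <- lapply(seq_len(n + 1), function(t) as.list(acc[t, ] / n_reps))
  new_attack_trajectory("random", "random", first_order, m$labels, snaps,
                        n_reps = as.integer(n_reps), seed = seed)
}

# internal constructor; snapshots: list of named lists, length n+1
new_attack_trajectory <- function(scheme, quantifier, removal, labels, snaps,
                                  n_reps, seed) {
  sdf <- do.call(rbind, lapply(snaps, function(s) as.data.frame(s)))
  sdf <- cbind(step = seq_along(snaps) - 1L, sdf)
  rownames(sdf) <- NULL
  structure(
    list(scheme = scheme, quantifier = quantifier,
         removal_order = as.integer(removal),
         removal_labels = labels[removal],
         snapshots = sdf, n_reps = n_reps, seed = seed),
    class = "attack_trajectory"
  )
}

#' @export
print.attack_trajectory <- function(x, ...) {
  cat(sprintf("<attack_trajectory> scheme=%s quantifier=%s, %d removals, %d snapshots%s\n",
              x$scheme, x$quantifier, length(x$removal_order),
              nrow(x$snapshots),
              if (x$n_reps > 1) sprintf(" (mean of %d reps)", x$n_reps) else ""))
  invisible(x)
}

#' Area under the normalized largest-cluster curve
#'
#' Trapezoidal area under largest-cluster-size vs removals, with both axes
#' normalized to \[0, 1\]. Smaller areas mean faster network degradation, so
#' this is the scalar used to compare attack schemes.
#'
#' @param traj an `attack_trajectory` whose snapshots include
#'   `largest_cluster`.
#' @return numeric area in \[0, 1\].
#' @export
attack_auc <- function(traj) {
  lc <- traj$snapshots$largest_cluster
  if (is.null(lc)) stop("trajectory does not track largest_cluster")
  y <- lc / lc[1]
  x <- seq(0, 1, length.out = length(y))
  sum(diff(x) * (head(y, -1) + tail(y, -1)) / 2)
}
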