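#' Collective influence scores
#'
#' Ranks nodes for optimal percolation: the collective influence of node i at
#' ball radius `ell` is
#' \deqn{CI_\ell(i) = (k_i - 1) \sum_{j \in \partial B(i,\ell)} (k_j - 1)}
#' where \eqn{\partial B(i,\ell)} is the frontier of the ball — the nodes at
#' unweighted shortest-path (hop) distance exactly `ell` from i. High-CI nodes
#' sit at the junctions that hold the giant component together; removing them
#' fragments the network fastest. CI is defined on the binary topology, so
#' edge weights are ignored.
#'
#' @param m a thresholded or binarized `connectivity_matrix`.
#' @param ell ball radius (hop distance), integer >= 1; default 2.
#' @return numeric vector of nonnegative CI values, one per region. Nodes of
#'   degree <= 1 score 0.
#' @export
collective_influence_scores <- function(m, ell = 2L) {
  if (!m$state %in% c("thresholded", "binarized")) {
    stop("collective influence expects a thresholded or binarized matrix")
  }
  if (!is.numeric(ell) || length(ell) != 1 || ell < 1 || ell != floor(ell)) {
    stop("ell must be an integer >= 1")
  }
  a <- m$weights != 0
  n <- nrow(a)
  k <- rowSums(a)
  adj <- apply(a, 1, which, simplify = FALSE)
  ci <- numeric(n)
  for (i in seq_len(n)) {
    if (k[i] <= 1) next
    # BFS to hop distance ell; frontier at exactly ell
    visited <- logical(n)
    visited[i] <- TRUE
    frontier <- adj[[i]]
    visited[frontier] <- TRUE
    depth <- 1L
    while (depth < ell && length(frontier)) {
      nxt <- unique(unlist(adj[frontier], use.names = FALSE))
      nxt <- nxt[!visited[nxt]]
      visited[nxt] <- TRUE
      frontier <- nxt
      depth <- depth + 1L
    }
    if (depth == ell && length(frontier)) {
      ci[i] <- (k[i] - 1) * sum(k[frontier] - 1)
    }
  }
  ci
}
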