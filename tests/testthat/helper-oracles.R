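# Independent brute-force oracles used to cross-check the package's graph
# machinery on small networks. These deliberately share no code with the
# implementation: paths are enumerated explicitly, components found by
# union-find, balls grown by matrix powers.

# random symmetric weighted matrix in "thresholded" state
random_conn <- function(n, p = 0.5, seed = 1, weighted = TRUE, group = "control") {
  set.seed(seed)
  w <- matrix(0, n, n)
  ut <- which(upper.tri(w))
  on <- ut[stats::runif(length(ut)) < p]
  w[on] <- if (weighted) stats::runif(length(on), 0.1, 1) else 1
  w <- w + t(w)
  connectivity_matrix(w, state = if (weighted) "thresholded" else "binarized",
                      group = group)
}

# all simple paths from s to t; returns list of vectors of node indices
enumerate_paths <- function(adj, s, t) {
  out <- list()
  walk <- function(path) {
    last <- path[length(path)]
    if (last == t) {
      out[[length(out) + 1]] <<- path
      return(invisible())
    }
    for (nb in which(adj[last, ] != 0)) {
      if (!nb %in% path) walk(c(path, nb))
    }
  }
  walk(s)
  out
}

# shortest-path matrix by exhaustive path enumeration; lengths = 1/weight
oracle_distances <- function(w) {
  n <- nrow(w)
  len <- ifelse(w != 0, 1 / w, 0)
  d <- matrix(Inf, n, n)
  diag(d) <- 0
  for (s in seq_len(n)) for (t in seq_len(n)) {
    if (s >= t) next
    paths <- enumerate_paths(w, s, t)
    if (length(paths)) {
      plens <- vapply(paths, function(p) {
        sum(len[cbind(p[-length(p)], p[-1])])
      }, numeric(1))
      d[s, t] <- d[t, s] <- min(plens)
    }
  }
  d
}

# betweenness by geodesic enumeration: endpoints excluded, unnormalized
oracle_betweenness <- function(w) {
  n <- nrow(w)
  len <- ifelse(w != 0, 1 / w, 0)
  b <- numeric(n)
  for (s in seq_len(n)) for (t in seq_len(n)) {
    if (s >= t) next
    paths <- enumerate_paths(w, s, t)
    if (!length(paths)) next
    plens <- vapply(paths, function(p) {
      sum(len[cbind(p[-length(p)], p[-1])])
    }, numeric(1))
    geo <- paths[abs(plens - min(plens)) < 1e-9]
    for (p in geo) {
      inner <- setdiff(p, c(s, t))
      # each ordered pair counted once; undirected so one s<t pass suffices
      b[inner] <- b[inner] + 1 / length(geo)
    }
  }
  b
}

# binary clustering coefficient by triple counting
oracle_clustering_binary <- function(a) {
  n <- nrow(a)
  out <- numeric(n)
  for (i in seq_len(n)) {
    nb <- which(a[i, ] != 0)
    k <- length(nb)
    if (k < 2) next
    links <- 0
    for (x in nb) for (y in nb) if (x < y && a[x, y] != 0) links <- links + 1
    out[i] <- 2 * links / (k * (k - 1))
  }
  out
}

# largest component via union-find
oracle_largest_component <- function(a) {
  n <- nrow(a)
  if (n == 0) return(0L)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i < j && a[i, j] != 0) {
      ri <- find(i); rj <- find(j)
      if (ri != rj) parent[ri] <- rj
    }
  }
  roots <- vapply(seq_len(n), find, integer(1))
  max(table(roots))
}

# collective influence via hop distances from boolean matrix powers
oracle_ci <- function(a, ell) {
  n <- nrow(a)
  k <- rowSums(a != 0)
  reach <- (a != 0)
  hops <- matrix(Inf, n, n)
  diag(hops) <- 0
  cur <- reach
  for (h in seq_len(ell)) {
    newly <- cur & !is.finite(hops)
    hops[newly] <- h
    cur <- (cur %*% (a != 0)) > 0
  }
  ci <- numeric(n)
  for (i in seq_len(n)) {
    frontier <- which(hops[i, ] == ell)
    ci[i] <- max(k[i] - 1, 0) * sum(pmax(k[frontier] - 1, 0))
  }
  ci[k <= 1] <- 0
  ci
}

# exact two-sided rank-sum p by full enumeration of group assignments
oracle_ranksum_exact_p <- function(a, b) {
  n1 <- length(a); n <- n1 + length(b)
  pooled <- c(a, b)
  r <- rank(pooled)
  obs <- sum(r[seq_len(n1)])
  combs <- utils::combn(n, n1)
  sums <- apply(combs, 2, function(idx) sum(r[idx]))
  mu <- mean(sums)
  mean(abs(sums - mu) >= abs(obs - mu) - 1e-9)
}
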