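#' Construct a connectivity matrix object
#'
#' The central container of the package: a symmetric weighted region-by-region
#' network with processing-state metadata. Weights are pairwise association
#' values (typically Pearson correlations of regional time series); the
#' diagonal is always zero.
#'
#' @param weights square numeric matrix of edge weights.
#' @param labels character vector of region labels; defaults to the matrix
#'   dimnames or `"R<i>"`.
#' @param subject_id subject identifier string.
#' @param group `"control"` or `"disease"`.
#' @param state processing state: `"raw"` (signed correlations in \[-1, 1\]),
#'   `"normalized"` (\[0, 1\], max 1), `"thresholded"` (\[0, 1\], sparse) or
#'   `"binarized"` (0/1).
#' @param symmetrize if `TRUE` (default), asymmetric input is symmetrized by
#'   averaging `(W + t(W)) / 2`; asymmetry beyond `1e-6` triggers a message.
#'
#' @return an object of class `connectivity_matrix` with elements `weights`,
#'   `labels`, `subject_id`, `group`, `state`.
#' @export
connectivity_matrix <- function(weights, labels = NULL, subject_id = "",
                                group = c("control", "disease"),
                                state = c("raw", "normalized", "thresholded", "binarized"),
                                symmetrize = TRUE) {
  state <- match.arg(state)
  group <- match.arg(group)
  weights <- as.matrix(weights)
  if (nrow(weights) != ncol(weights)) {
    stop("weights must be a square matrix, got ", nrow(weights), "x", ncol(weights))
  }
  if (!is.numeric(weights)) stop("weights must be numeric")
  if (is.null(labels)) {
    labels <- rownames(weights)
    if (is.null(labels)) labels <- paste0("R", seq_len(nrow(weights)))
  }
  if (length(labels) != nrow(weights)) stop("labels length must match matrix dimension")
  if (anyDuplicated(labels)) stop("region labels must be unique")

  if (symmetrize) {
    asym <- max(abs(weights - t(weights)))
    if (asym > 1e-6) {
      message(sprintf("asymmetry of %.3g symmetrized by averaging", asym))
    }
    weights <- (weights + t(weights)) / 2
  }
  diag(weights) <- 0
  dimnames(weights) <- list(labels, labels)

  m <- structure(
    list(weights = weights, labels = labels, subject_id = subject_id,
         group = group, state = state),
    class = "connectivity_matrix"
  )
  validate_connectivity_matrix(m)
  m
}

#' Validate the connectivity-matrix invariants
#'
#' Checks symmetry (to 1e-9), a zero diagonal, and the weight range implied by
#' the processing state.
#'
#' @param m a `connectivity_matrix`.
#' @return `m`, invisibly; errors on violation.
#' @export
validate_connectivity_matrix <- function(m) {
  w <- m$weights
  if (max(abs(w - t(w))) > 1e-9) stop("connectivity matrix is not symmetric")
  if (any(diag(w) != 0)) stop("diagonal must be exactly zero")
  rng <- range(w)
  ok <- switch(m$state,
    raw         = rng[1] >= -1 - 1e-12 && rng[2] <= 1 + 1e-12,
    normalized  = rng[1] >= 0 && rng[2] <= 1 + 1e-12,
    thresholded = rng[1] >= 0 && rng[2] <= 1 + 1e-12,
    binarized   = all(w %in% c(0, 1))
  )
  if (!ok) stop("weights out of range for state '", m$state, "'")
  invisible(m)
}

#' @export
print.connectivity_matrix <- function(x, ...) {
  n <- length(x$labels)
  e <- n_edges(x)
  cat(sprintf("<connectivity_matrix> %d regions, %d edges, state=%s, group=%s%s\n",
              n, e, x$state, x$group,
              if (nzchar(x$subject_id)) paste0(", subject=", x$subject_id) else ""))
  invisible(x)
}

#' Number of regions in a connectivity matrix
#' @param m a `connectivity_matrix`.
#' @return integer node count.
#' @export
n_regions <- function(m) length(m$labels)

#' Number of edges (nonzero upper-triangle entries)
#' @param m a `connectivity_matrix`.
#' @return integer edge count.
#' @export
n_edges <- function(m) {
  w <- m$weights
  sum(w[upper.tri(w)] != 0)
}

#' Graph density E / (n(n-1)/2)
#' @param m a `connectivity_matrix`.
#' @return density in \[0, 1\].
#' @export
graph_density <- function(m) {
  n <- n_regions(m)
  if (n < 2) return(0)
  n_edges(m) / (n * (n - 1) / 2)
}

# internal: connectivity_matrix -> igraph, weighted unless binary topology asked
as_igraph <- function(m, weighted = TRUE) {
  w <- m$weights
  if (!weighted) w <- (w != 0) * 1
  igraph::graph_from_adjacency_matrix(w, mode = "undirected",
                                      weighted = if (weighted) TRUE else NULL,
                                      diag = FALSE)
}

# internal: run expr with a temporary RNG seed, restoring global state after
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}
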