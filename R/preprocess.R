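#' Average raw connectivity matrices within a group
#'
#' Element-wise arithmetic mean of raw (signed) matrices. Averaging happens
#' before normalization and thresholding, so weak-but-consistent connections
#' survive while idiosyncratic ones cancel.
#'
#' @param ms list of `connectivity_matrix` objects with identical labels and
#'   `state = "raw"`.
#' @return a raw `connectivity_matrix`; `group` propagated from the inputs,
#'   `subject_id` set to `"group-average"`.
#' @export
group_average <- function(ms) {
  stopifnot(length(ms) >= 1)
  labels <- ms[[1]]$labels
  for (m in ms) {
    if (m$state != "raw") stop("group_average expects raw matrices")
    if (!identical(m$labels, labels)) stop("label mismatch across matrices")
  }
  w <- Reduce(`+`, lapply(ms, `[[`, "weights")) / length(ms)
  connectivity_matrix(w, labels = labels, subject_id = "group-average",
                      group = ms[[1]]$group, state = "raw")
}

#' Normalize a raw matrix to \[0, 1\]
#'
#' Negative entries (anticorrelations) are set to zero and the remainder is
#' divided by the maximum entry so the strongest connection has weight 1. An
#' all-zero (or all-nonpositive) matrix is returned unchanged. Any strictly
#' monotone rescaling gives the same thresholded topology downstream; this
#' max-scaling is the package's fixed convention.
#'
#' @param m a raw `connectivity_matrix`.
#' @return a `connectivity_matrix` with `state = "normalized"`.
#' @export
normalize_matrix <- function(m) {
  if (m$state != "raw") stop("normalize expects a raw matrix")
  w <- m$weights
  w[w < 0] <- 0
  mx <- max(w)
  if (mx > 0) w <- w / mx
  out <- m
  out$weights <- w
  out$state <- "normalized"
  validate_connectivity_matrix(out)
  out
}

#' Threshold a matrix at a proportional graph density
#'
#' Retains the `E = round(density * n(n-1)/2)` largest-weight edges (rounding
#' half away from zero) and zeroes the rest, so that every network analyzed
#' shares the same graph density. With n = 90 and density 0.10 this keeps
#' E = 401 edges, i.e. density 0.1001 and average degree 8.911. Ties at the
#' cut weight are broken by ascending (row, column) index for determinism.
#'
#' @param m a normalized `connectivity_matrix`.
#' @param density target density in (0, 1\].
#' @return a `connectivity_matrix` with `state = "thresholded"`.
#' @export
threshold_proportional <- function(m, density = 0.10) {
  if (m$state != "normalized") stop("threshold expects a normalized matrix")
  if (!is.numeric(density) || density <= 0 || density > 1) {
    stop("density must be in (0, 1]")
  }
  n <- n_regions(m)
  n_pairs <- n * (n - 1) / 2
  e_keep <- round_half_away(density * n_pairs)
  w <- m$weights
  ut <- which(upper.tri(w))
  pos <- ut[w[ut] > 0]
  # order: weight descending, then (i, j) ascending; column-major index order
  # of the upper triangle is exactly ascending (j, i) -> use (i, j) sort keys
  ij <- arrayInd(pos, dim(w))
  ord <- order(-w[pos], ij[, 1], ij[, 2])
  keep <- pos[ord][seq_len(min(e_keep, length(pos)))]
  w2 <- matrix(0, n, n, dimnames = dimnames(w))
  w2[keep] <- w[keep]
  w2 <- w2 + t(w2)
  out <- m
  out$weights <- w2
  out$state <- "thresholded"
  validate_connectivity_matrix(out)
  out
}

# round half away from zero (round() would go half-to-even: 400.5 -> 400)
round_half_away <- function(x) sign(x) * floor(abs(x) + 0.5)

#' Binarize a thresholded matrix
#'
#' Every surviving edge gets weight 1.
#'
#' @param m a thresholded `connectivity_matrix`.
#' @return a `connectivity_matrix` with `state = "binarized"`.
#' @export
binarize <- function(m) {
  if (m$state != "thresholded") stop("binarize expects a thresholded matrix")
  out <- m
  out$weights <- (m$weights != 0) * 1
  dimnames(out$weights) <- dimnames(m$weights)
  out$state <- "binarized"
  out
}

#' Subtract two binarized matrices
#'
#' Edge-set comparison of two binary networks: `+1` marks edges only in `a`,
#' `-1` edges only in `b`, `0` edges shared or absent in both. Used to build
#' the BrainNet Viewer difference display between group-average networks.
#'
#' @param a,b binarized `connectivity_matrix` objects with identical labels.
#' @return list with `difference` (signed matrix in \{-1, 0, 1\}), `shared`
#'   (elementwise product: the common edge mask) and `counts` (named vector
#'   `only_a`, `only_b`, `shared` of upper-triangle edge counts).
#' @export
binary_subtract <- function(a, b) {
  if (a$state != "binarized" || b$state != "binarized") {
    stop("both matrices must be binarized")
  }
  if (!identical(a$labels, b$labels)) stop("label mismatch")
  d <- a$weights - b$weights
  shared <- a$weights * b$weights
  ut <- upper.tri(d)
  list(difference = d, shared = shared,
       counts = c(only_a = sum(d[ut] == 1), only_b = sum(d[ut] == -1),
                  shared = sum(shared[ut] == 1)))
}
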