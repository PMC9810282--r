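#' Difference-to-diseased-baseline curve
#'
#' The progression model asks how many targeted attacks on the healthy
#' network are needed before a quantifier reaches the value it has in the
#' intact diseased network. The curve is
#' \eqn{\Delta_t = q_{disease}(0) - q_{control}(t)} for t = 0..n removals; a
#' sign change marks the attack at which the control network has degraded to
#' the diseased baseline.
#'
#' @param traj an `attack_trajectory` of the (healthy) network.
#' @param baseline named list/vector of global quantifiers of the intact
#'   diseased network (e.g. from [global_quantifiers()]).
#' @param quantifier name of the quantifier to compare.
#' @return numeric vector `Delta_t`, length n+1.
#' @export
baseline_difference_curve <- function(traj, baseline, quantifier) {
  if (!quantifier %in% names(traj$snapshots)) {
    stop("quantifier '", quantifier, "' not tracked in trajectory")
  }
  if (!quantifier %in% names(baseline)) {
    stop("quantifier '", quantifier, "' missing from baseline")
  }
  as.numeric(baseline[[quantifier]]) - traj$snapshots[[quantifier]]
}

#' Attacks needed to reach the diseased baseline
#'
#' First index at which the difference curve changes sign (or hits zero)
#' relative to its initial sign, reported fractionally by linear
#' interpolation between the two bracketing steps; an exact zero at step t
#' returns t; a curve that never crosses returns `Inf`. A curve starting at
#' exactly zero returns 0.
#'
#' @param diff_curve numeric vector from [baseline_difference_curve()]
#'   (element 1 = step 0).
#' @return nonnegative real crossing step, possibly `Inf`.
#' @export
attacks_to_reach_baseline <- function(diff_curve) {
  stopifnot(length(diff_curve) >= 1)
  d0 <- diff_curve[1]
  if (d0 == 0) return(0)
  s0 <- sign(d0)
  for (t in seq_along(diff_curve)[-1]) {
    dt <- diff_curve[t]
    if (dt == 0) return(t - 1)
    if (sign(dt) != s0) {
      prev <- diff_curve[t - 1]
      return((t - 2) + abs(prev) / (abs(prev) + abs(dt)))
    }
  }
  Inf
}

#' Nodes shared among the first k attacks of two schemes
#'
#' @param orderA,orderB removal orders (vectors of node ids or labels).
#' @param k number of leading attacks to compare.
#' @return the intersection of the first `k` entries of each order, as a
#'   vector (set semantics; symmetric in its arguments).
#' @export
shared_early_attacks <- function(orderA, orderB, k) {
  if (k < 0 || k > length(orderA) || k > length(orderB)) {
    stop("k out of range")
  }
  intersect(orderA[seq_len(k)], orderB[seq_len(k)])
}

#' Nodes disconnected from the main network after removals
#'
#' Applies [remove_node()] for each listed node, then returns the surviving
#' nodes that are not in the largest connected component — the regions an
#' attack has cut off from the core network. The removed nodes themselves are
#' excluded. When several components tie for largest, the one containing the
#' lowest node index is kept as "largest".
#'
#' @param m a `connectivity_matrix`.
#' @param removed vector of node ids or labels to remove (may be empty).
#' @return character vector of disconnected surviving region labels.
#' @export
disconnected_after <- function(m, removed) {
  idx <- vapply(removed, function(x) resolve_node(m, x), integer(1))
  cur <- m
  for (i in idx) cur <- remove_node(cur, i)
  comp <- igraph::components(as_igraph(cur, weighted = FALSE))
  surviving <- setdiff(seq_len(n_regions(m)), idx)
  if (!length(surviving)) return(character(0))
  sizes <- comp$csize
  # components reached by surviving nodes only (removed nodes are isolates)
  surv_comp <- comp$membership[surviving]
  max_size <- max(sizes[unique(surv_comp)])
  tied <- which(sizes == max_size)
  tied <- tied[tied %in% surv_comp]
  # tie-break: component containing the lowest surviving node index
  first_comp <- surv_comp[which(surv_comp %in% tied)[1]]
  out <- surviving[comp$membership[surviving] != first_comp]
  m$labels[out]
}

#' Full progression analysis of one trajectory
#'
#' Convenience wrapper: difference curves and crossing steps for every
#' quantifier tracked by the trajectory.
#'
#' @param traj an `attack_trajectory` of the healthy network.
#' @param baseline global quantifiers of the intact diseased network.
#' @return a `progression_result`: list with `scheme`, `quantifier` (attack
#'   criterion), `curves` (data frame: step + one Delta column per tracked
#'   quantifier) and `crossings` (named vector of crossing steps).
#' @export
progression_analysis <- function(traj, baseline) {
  qs <- intersect(setdiff(names(traj$snapshots), "step"), names(baseline))
  qs <- qs[!vapply(qs, function(q) any(is.na(traj$snapshots[[q]])) ||
                     is.na(baseline[[q]]), logical(1))]
  curves <- data.frame(step = traj$snapshots$step)
  crossings <- stats::setNames(numeric(length(qs)), qs)
  for (q in qs) {
    dc <- baseline_difference_curve(traj, baseline, q)
    curves[[q]] <- dc
    crossings[q] <- attacks_to_reach_baseline(dc)
  }
  structure(list(scheme = traj$scheme, quantifier = traj$quantifier,
                 curves = curves, crossings = crossings),
            class = "progression_result")
}

#' @export
print.progression_result <- function(x, ...) {
  cat(sprintf("<progression_result> attack=%s/%s\n", x$scheme, x$quantifier))
  for (q in names(x$crossings)) {
    cat(sprintf("  %-22s crossing at %s\n", q,
                if (is.infinite(x$crossings[q])) "never"
                else sprintf("%.2f attacks", x$crossings[q])))
  }
  invisible(x)
}
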