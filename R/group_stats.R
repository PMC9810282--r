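#' Wilcoxon rank-sum test (normal approximation)
#'
#' Two-sided rank-sum test with midranks for ties, tie-corrected variance and
#' a continuity correction. The statistic is the Mann-Whitney count
#' \eqn{U = R_b - n_b(n_b+1)/2} (rank sum of sample `b`), so z is positive
#' when `b` tends to exceed `a`.
#'
#' @param a,b numeric samples (nonempty).
#' @return list with signed `z` and two-sided `p`. Degenerate data (all
#'   values identical) returns `z = 0`, `p = 1`.
#' @export
rank_sum_test <- function(a, b) {
  stopifnot(length(a) >= 1, length(b) >= 1)
  n1 <- length(a); n2 <- length(b); n <- n1 + n2
  r <- rank(c(a, b))
  u <- sum(r[(n1 + 1):n]) - n2 * (n2 + 1) / 2
  mu <- n1 * n2 / 2
  ties <- table(r)
  tie_term <- sum(ties^3 - ties)
  v <- n1 * n2 / 12 * ((n + 1) - tie_term / (n * (n - 1)))
  if (v <= 0) return(list(z = 0, p = 1))
  cc <- sign(u - mu) * 0.5
  z <- (u - mu - cc) / sqrt(v)
  list(z = z, p = min(1, 2 * stats::pnorm(-abs(z))))
}

#' Effect size r for a rank-sum test
#'
#' \eqn{r = |z| / \sqrt{n}} with n the total number of samples across both
#' groups.
#'
#' @param z rank-sum z statistic.
#' @param n_total total sample count (both groups), >= 2.
#' @return effect size in \[0, 1\] for |z| <= sqrt(n); capped at the formula
#'   value otherwise (not truncated).
#' @export
effect_size_r <- function(z, n_total) {
  stopifnot(n_total >= 2)
  abs(z) / sqrt(n_total)
}

#' Compare quantifier tables across two groups
#'
#' For every metric column present in both groups, reports mean, standard
#' error (SD/sqrt(n)) and SD per group, the rank-sum z and two-sided p, and
#' the effect size r. P-values are deliberately uncorrected: each quantifier
#' is reported as its own comparison, mirroring standard practice for these
#' exploratory network batteries (interpret the many nodal rows accordingly).
#'
#' @param groupA,groupB data frames: one row per subject, one numeric column
#'   per metric (a `metric` id column layout also works via
#'   [quantifier_long_to_wide()]). Column sets must match.
#' @param nameA,nameB group display names.
#' @return data frame with one row per metric: `metric`, `mean_a`, `se_a`,
#'   `sd_a`, `mean_b`, `se_b`, `sd_b`, `z`, `p`, `r`, sorted by `p`.
#' @export
compare_quantifiers <- function(groupA, groupB, nameA = "control", nameB = "disease") {
  metrics <- intersect(names(groupA), names(groupB))
  metrics <- metrics[vapply(metrics, function(m) is.numeric(groupA[[m]]), logical(1))]
  if (!length(metrics)) stop("no shared numeric metric columns")
  if (!setequal(names(groupA)[sapply(groupA, is.numeric)],
                names(groupB)[sapply(groupB, is.numeric)])) {
    stop("metric columns are misaligned between groups")
  }
  if (nrow(groupA) < 2 || nrow(groupB) < 2) stop("need >= 2 subjects per group")
  rows <- lapply(metrics, function(mt) {
    va <- groupA[[mt]]; vb <- groupB[[mt]]
    ok <- is.finite(va) & !is.na(va)
    okb <- is.finite(vb) & !is.na(vb)
    va <- va[ok]; vb <- vb[okb]
    if (length(va) < 2 || length(vb) < 2) return(NULL)
    ts <- rank_sum_test(va, vb)
    data.frame(metric = mt,
               mean_a = mean(va), se_a = stats::sd(va) / sqrt(length(va)),
               sd_a = stats::sd(va),
               mean_b = mean(vb), se_b = stats::sd(vb) / sqrt(length(vb)),
               sd_b = stats::sd(vb),
               z = ts$z, p = ts$p,
               r = effect_size_r(ts$z, length(va) + length(vb)),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "groups") <- c(a = nameA, b = nameB)
  out[order(out$p), , drop = FALSE]
}

#' Reshape a long quantifier table to subject-by-metric
#'
#' @param long data frame with columns `subject_id`, `metric`, `value`.
#' @return wide data frame, one row per subject, one column per metric.
#' @export
quantifier_long_to_wide <- function(long) {
  stopifnot(all(c("subject_id", "metric", "value") %in% names(long)))
  wide <- stats::reshape(long[, c("subject_id", "metric", "value")],
                         idvar = "subject_id", timevar = "metric",
                         direction = "wide")
  names(wide) <- sub("^value\\.", "", names(wide))
  rownames(wide) <- NULL
  wide
}
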