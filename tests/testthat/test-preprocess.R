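test_that("group averaging is the element-wise mean of raw matrices", {
  m1 <- random_conn(6, seed = 1); m1$state <- "raw"
  expect_equal(group_average(list(m1))$weights, m1$weights)

  w2 <- matrix(c(0, .4, .4, 0), 2)
  w1 <- matrix(c(0, .2, .2, 0), 2)
  a <- connectivity_matrix(w1); b <- connectivity_matrix(w2)
  expect_equal(group_average(list(a, b))$weights[1, 2], 0.3)

  # 17 synthetic matrices against an independent mean
  cfg <- cohort_config(n_regions = 20, n_per_group = 17, seed = 11)
  co <- generate_cohort(cfg)
  avg <- group_average(co$control)
  manual <- Reduce(`+`, lapply(co$control, `[[`, "weights")) / 17
  expect_equal(avg$weights, manual)

  b$labels <- c("x", "y")
  dimnames(b$weights) <- list(b$labels, b$labels)
  expect_error(group_average(list(a, b)), "label mismatch")
})

test_that("normalization clips negatives and scales the maximum to 1", {
  w <- matrix(0, 3, 3)
  w[1, 2] <- w[2, 1] <- 0.8
  w[1, 3] <- w[3, 1] <- 0.4
  w[2, 3] <- w[3, 2] <- -0.2
  m <- normalize_matrix(connectivity_matrix(w))
  expect_equal(m$weights[1, 2], 1.0)
  expect_equal(m$weights[1, 3], 0.5)
  expect_equal(m$weights[2, 3], 0.0)
  expect_identical(m$state, "normalized")

  z <- normalize_matrix(connectivity_matrix(matrix(0, 3, 3)))
  expect_true(all(z$weights == 0))

  for (s in 1:20) {
    set.seed(s)
    w <- matrix(stats::runif(49, -1, 1), 7)
    w <- (w + t(w)) / 2; diag(w) <- 0
    nm <- normalize_matrix(connectivity_matrix(w))
    expect_equal(max(nm$weights), 1)
    expect_gte(min(nm$weights), 0)
  }
})

test_that("proportional thresholding reproduces the printed 90-node arithmetic", {
  atlas <- generate_atlas(90, seed = 1)
  m <- generate_subject_matrix(atlas, cohort_config(), seed = 3)
  mt <- threshold_proportional(normalize_matrix(m), 0.10)
  expect_identical(n_edges(mt), 401L)
  expect_equal(round(graph_density(mt), 4), 0.1001)
  expect_equal(round(2 * n_edges(mt) / 90, 3), 8.911)
})

test_that("thresholding keeps exactly the top-E edges (sort oracle)", {
  # n=5, density 0.3 -> round(0.3 * 10) = 3 edges
  set.seed(42)
  w <- matrix(0, 5, 5)
  w[upper.tri(w)] <- sample(seq(0.1, 1, length.out = 10))
  w <- w + t(w)
  m <- connectivity_matrix(w, state = "raw")
  mt <- threshold_proportional(normalize_matrix(m), 0.3)
  expect_equal(n_edges(mt), 3)
  kept <- which(upper.tri(w) & mt$weights != 0)
  top3 <- order(w[upper.tri(w)], decreasing = TRUE)[1:3]
  expect_setequal(kept, which(upper.tri(w))[top3])

  # density 1 on strictly positive weights keeps everything
  m1 <- normalize_matrix(m)
  full <- threshold_proportional(m1, 1.0)
  expect_equal(full$weights, m1$weights)

  expect_error(threshold_proportional(m1, 0), "density")
  expect_error(threshold_proportional(m1, 1.2), "density")
})

test_that("thresholding never increases weights, keeps symmetry, nests by density", {
  for (s in 1:10) {
    m <- random_conn(8, p = 1, seed = s)
    m$state <- "raw"
    mn <- normalize_matrix(m)
    t1 <- threshold_proportional(mn, 0.2)
    t2 <- threshold_proportional(mn, 0.6)
    expect_true(all(t1$weights <= mn$weights))
    expect_equal(t1$weights, t(t1$weights))
    expect_true(all(diag(t1$weights) == 0))
    # monotone nesting of edge sets for distinct weights
    expect_true(all(which(t1$weights != 0) %in% which(t2$weights != 0)))
  }
})

test_that("tie-broken thresholding is deterministic", {
  w <- matrix(0, 4, 4)
  w[upper.tri(w)] <- 0.5  # all six edges tie
  w <- w + t(w)
  m <- normalize_matrix(connectivity_matrix(w))
  t1 <- threshold_proportional(m, 0.5)  # keep 3 of 6
  t2 <- threshold_proportional(m, 0.5)
  expect_identical(t1$weights, t2$weights)
  expect_equal(n_edges(t1), 3)
  # lexicographic (i, j): (1,2), (1,3), (1,4) kept
  expect_true(all(t1$weights[1, 2:4] > 0))
})

test_that("binarize maps every surviving edge to 1", {
  m <- random_conn(6, p = 0.5, seed = 2)
  mb <- binarize(m)
  expect_identical(mb$state, "binarized")
  expect_true(all(mb$weights %in% c(0, 1)))
  expect_equal(mb$weights != 0, m$weights != 0)

  atlas <- generate_atlas(90, seed = 1)
  m90 <- generate_subject_matrix(atlas, cohort_config(), seed = 3)
  mb90 <- binarize(threshold_proportional(normalize_matrix(m90), 0.10))
  expect_equal(sum(mb90$weights[upper.tri(mb90$weights)]), 401)
})

test_that("binary subtraction obeys edge-set algebra", {
  a <- binarize(random_conn(10, p = 0.4, seed = 5))
  b <- binarize(random_conn(10, p = 0.4, seed = 6))
  d <- binary_subtract(a, b)
  expect_true(all(d$difference %in% c(-1, 0, 1)))
  ut <- upper.tri(d$difference)
  union_size <- sum((a$weights + b$weights)[ut] > 0)
  expect_equal(sum(d$counts), union_size)

  same <- binary_subtract(a, a)
  expect_true(all(same$difference == 0))
  expect_equal(same$shared, a$weights)

  expect_error(binary_subtract(a, random_conn(10, seed = 6)), "binarized")
})
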