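star5 <- function() {
  w <- matrix(0, 5, 5)
  w[1, 2:5] <- w[2:5, 1] <- 1
  connectivity_matrix(w, state = "binarized")
}

# two triangles joined through a bridge node 7: 3+3 barbell
barbell <- function() {
  w <- matrix(0, 7, 7)
  for (e in list(c(1, 2), c(2, 3), c(1, 3), c(4, 5), c(5, 6), c(4, 6),
                 c(3, 7), c(7, 4))) {
    w[e[1], e[2]] <- w[e[2], e[1]] <- 1
  }
  connectivity_matrix(w, state = "binarized")
}

test_that("node removal zeroes rows/columns and keeps dimension", {
  s <- star5()
  out <- remove_node(s, 1)
  expect_equal(n_regions(out), 5)
  expect_equal(largest_cluster_size(out), 1)
  expect_true(all(out$weights == 0))

  # removing an isolated node is a no-op
  iso <- remove_node(out, 2)
  expect_identical(iso$weights, out$weights)

  bb <- remove_node(barbell(), 7)
  expect_equal(largest_cluster_size(bb), 3)

  expect_error(remove_node(s, 9), "out of range")
  expect_error(remove_node(s, "nope"), "unknown node label")
})

test_that("basis order sorts by the intact network's quantifier, ties by index", {
  expect_equal(basis_attack_order(star5(), "degree")[1], 1)
  edgeless <- connectivity_matrix(matrix(0, 4, 4), state = "thresholded")
  expect_equal(basis_attack_order(edgeless, "degree"), 1:4)

  m <- random_conn(12, p = 0.5, seed = 31)
  st <- rowSums(m$weights)
  expect_equal(basis_attack_order(m, "strength"), order(-st, seq_along(st)))
  expect_error(basis_attack_order(m, "bogus"))
})

test_that("targeted attacks remove every node and snapshot each step", {
  atlas <- generate_atlas(90, seed = 3)
  m <- threshold_proportional(normalize_matrix(
    generate_subject_matrix(atlas, cohort_config(), seed = 4)), 0.10)
  tr <- run_targeted_attack(m, "basis", "degree", track = "largest_cluster")
  expect_equal(length(tr$removal_order), 90)
  expect_equal(nrow(tr$snapshots), 91)
  expect_setequal(tr$removal_order, 1:90)
  expect_true(all(diff(tr$snapshots$largest_cluster) <= 0))
  # removed nodes persist as isolates: the empty graph's largest "cluster" is 1
  expect_equal(tr$snapshots$largest_cluster[91], 1)
})

test_that("iterative betweenness finds the barbell bridge first", {
  tr <- run_targeted_attack(barbell(), "iterative", "betweenness",
                            track = "largest_cluster")
  expect_equal(tr$removal_order[1], 7)
  expect_equal(tr$snapshots$largest_cluster[2], 3)
})

test_that("basis attacks on an edgeless graph are deterministic and inert", {
  edgeless <- connectivity_matrix(matrix(0, 5, 5), state = "thresholded")
  tr <- run_targeted_attack(edgeless, "basis", "degree",
                            track = c("largest_cluster", "n_edges"))
  expect_equal(tr$removal_order, 1:5)
  expect_true(all(tr$snapshots$n_edges == 0))

  expect_error(run_targeted_attack(barbell(), "iterative", "ci"), "basis")
})

test_that("basis and iterative degree attacks coincide on stars", {
  b <- run_targeted_attack(star5(), "basis", "degree", track = "largest_cluster")
  i <- run_targeted_attack(star5(), "iterative", "degree", track = "largest_cluster")
  expect_equal(b$removal_order, i$removal_order)
  expect_equal(b$snapshots, i$snapshots)
})

test_that("random ensembles are seeded, monotone and exact on complete graphs", {
  m <- binarize(random_conn(12, p = 0.5, seed = 77))
  r1 <- random_attack_ensemble(m, n_reps = 1, seed = 5, track = "largest_cluster")
  r2 <- random_attack_ensemble(m, n_reps = 1, seed = 5, track = "largest_cluster")
  expect_identical(r1$removal_order, r2$removal_order)
  expect_identical(r1$snapshots, r2$snapshots)

  r50 <- random_attack_ensemble(m, n_reps = 50, seed = 9, track = "largest_cluster")
  expect_true(all(diff(r50$snapshots$largest_cluster) <= 1e-12))

  k10 <- connectivity_matrix(matrix(1, 10, 10) - diag(10), state = "binarized")
  rk <- random_attack_ensemble(k10, n_reps = 3, seed = 2, track = "largest_cluster")
  expect_equal(rk$snapshots$largest_cluster, c(10:1, 1))
  expect_error(random_attack_ensemble(m, n_reps = 0), "n_reps")
})

test_that("largest cluster never grows along any scheme's trajectory", {
  atlas <- generate_atlas(30, seed = 5)
  m <- threshold_proportional(normalize_matrix(
    generate_subject_matrix(atlas, cohort_config(n_regions = 30), seed = 6)), 0.10)
  for (spec in list(c("basis", "degree"), c("iterative", "strength"),
                    c("basis", "ci"))) {
    tr <- run_targeted_attack(m, spec[1], spec[2], track = "largest_cluster")
    expect_true(all(diff(tr$snapshots$largest_cluster) <= 0))
  }
})

test_that("attack AUC integrates the normalized largest-cluster curve", {
  k10 <- connectivity_matrix(matrix(1, 10, 10) - diag(10), state = "binarized")
  tr <- random_attack_ensemble(k10, n_reps = 1, seed = 1, track = "largest_cluster")
  # curve 10,9,...,1,1 normalized: trapezoid area known in closed form
  y <- c(10:1, 1) / 10
  expected <- sum(diff(seq(0, 1, length.out = 11)) * (head(y, -1) + tail(y, -1)) / 2)
  expect_equal(attack_auc(tr), expected)
})
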