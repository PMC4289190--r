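test_that("split score equals the normalized information gain definition", {
  # perfect split is the node's maximum, proportional split scores 0
  s_perfect <- split_score(c("A", "A"), c("B", "B"))
  s_none <- split_score(c("A", "B"), c("A", "B"))
  expect_equal(s_none, 0)
  expect_gt(s_perfect, 0)
  expect_equal(s_perfect, 1) # 2I/(Hc+Hs) = 1 when I = Hc = Hs

  # {A,A,B} | {B}: hand entropy arithmetic
  expect_equal(split_score(c("A", "A", "B"), "B"),
               oracle_split_score(c("A", "A", "B"), "B"), tolerance = 1e-12)

  # random label partitions agree with the from-scratch oracle
  set.seed(10)
  for (i in 1:25) {
    y <- sample(c("A", "B", "C"), 12, replace = TRUE)
    k <- sample(1:11, 1)
    expect_equal(split_score(y[1:k], y[-(1:k)]),
                 oracle_split_score(y[1:k], y[-(1:k)]), tolerance = 1e-12)
  }

  expect_error(split_score(character(0), "A"), class = "zs_invalid_split")
})

test_that("random test draws are valid, uniform, and detect degenerate nodes", {
  # only attribute 5 varies: every draw must test it, threshold inside its
  # node-local range
  X <- matrix(1, 10, 768)
  X[, 5] <- seq(-1, 1, length.out = 10)
  for (s in 1:20) {
    t <- draw_random_test(X, "SIMPLETHRES", seed = s)
    expect_true(t$valid)
    expect_equal(t$attr, 5)
    expect_true(t$threshold > -1 && t$threshold < 1)
  }

  # all-identical samples: no valid test exists
  expect_false(draw_random_test(matrix(3, 5, 768), "SIMPLETHRES",
                                seed = 1)$valid)

  # attribute choice is uniform: two varying attributes drawn ~ 50/50
  # within 3-sigma binomial bounds over 10^4 draws
  X2 <- matrix(0, 6, 768)
  X2[, 10] <- rnorm(6)
  X2[, 500] <- rnorm(6)
  picks <- vapply(1:10000, function(s) {
    draw_random_test(X2, "SIMPLETHRES", seed = s)$attr
  }, numeric(1))
  expect_setequal(unique(picks), c(10, 500))
  p10 <- mean(picks == 10)
  expect_lt(abs(p10 - 0.5), 3 * sqrt(0.25 / 10000))

  # DIFFNEIGHBOR neighbors are 8-adjacent within the same channel plane
  set.seed(5)
  X3 <- matrix(rnorm(20 * 768), 20, 768)
  for (s in 1:200) {
    t <- draw_random_test(X3, "DIFFNEIGHBOR", seed = s)
    expect_true(t$valid)
    a <- t$attr - 1
    b <- t$attr2 - 1
    expect_equal(a %/% 256, b %/% 256) # same channel plane
    ra <- (a %% 256) %/% 16
    ca <- (a %% 256) %% 16
    rb <- (b %% 256) %/% 16
    cb <- (b %% 256) %% 16
    expect_true(max(abs(ra - rb), abs(ca - cb)) == 1)
  }
})

test_that("tree building stops on purity, size, and degenerate nodes", {
  X <- random_patch_matrix(20, seed = 1)

  # all one class: a single leaf holding every sample
  e1 <- ert_ensemble(X, rep("A", 20), n_trees = 1, seed = 1)
  expect_equal(e1$trees[[1]]$n_nodes, 1L)
  expect_equal(sum(e1$trees[[1]]$counts), 20)

  # n_min above the sample count: single leaf with the full class counts
  e2 <- ert_ensemble(X, rep(c("A", "B"), 10), n_trees = 1, n_min = 100,
                     seed = 1)
  expect_equal(e2$trees[[1]]$n_nodes, 1L)
  expect_equal(as.numeric(e2$trees[[1]]$counts), c(10, 10))

  # four linearly separable samples: all leaves pure, training accuracy 1
  X4 <- matrix(0, 4, 768)
  X4[, 1] <- c(-2, -1, 1, 2)
  y4 <- c("A", "A", "B", "B")
  e4 <- ert_ensemble(X4, y4, n_trees = 5, seed = 3)
  pred <- predict(e4, X4, type = "response")
  expect_equal(as.character(pred), y4)
  for (tr in e4$trees) {
    leaf_counts <- tr$counts[!is.na(tr$leaf_id), , drop = FALSE]
    expect_true(all(rowSums(leaf_counts > 0) == 1))
  }
})

test_that("with n_min = 1 on non-degenerate data all leaves are pure and
           every sample reaches a leaf of its own class", {
  X <- random_patch_matrix(60, seed = 2)
  y <- sample(c("A", "B", "C"), 60, replace = TRUE)
  ens <- ert_ensemble(X, y, n_trees = 10, seed = 4)
  for (tr in ens$trees) {
    leaves <- !is.na(tr$leaf_id)
    expect_true(all(rowSums(tr$counts[leaves, , drop = FALSE] > 0) == 1))
  }
  # propagating each training sample reaches a leaf counting its class
  P <- predict(ens, X, type = "prob")
  expect_true(all(P[cbind(1:60, match(y, ens$classes))] > 0))
  # with pure leaves, training predictions are exact
  expect_equal(as.character(predict(ens, X, type = "response")), y)
})

test_that("ensembles are deterministic and number leaves contiguously", {
  X <- random_patch_matrix(40, seed = 6)
  y <- rep(c("A", "B"), 20)
  e1 <- ert_ensemble(X, y, n_trees = 4, seed = 11)
  e2 <- ert_ensemble(X, y, n_trees = 4, seed = 11)
  expect_identical(ert_serialize(e1), ert_serialize(e2))
  e3 <- ert_ensemble(X, y, n_trees = 4, seed = 12)
  expect_false(identical(ert_serialize(e1), ert_serialize(e3)))

  ids <- sort(unlist(lapply(e1$trees, function(t) t$leaf_id[!is.na(t$leaf_id)])))
  expect_equal(ids, seq_len(e1$n_leaves))

  # every leaf is reachable: the training set touches all of them
  leaves <- ert_propagate(e1, X)
  expect_setequal(as.integer(leaves), seq_len(e1$n_leaves))
})

test_that("propagation follows the test semantics and a path-replay oracle", {
  # single-leaf tree: same leaf for any input
  ens <- make_manual_ensemble(list(make_leaf_tree(c(3, 1), 1L)), c("A", "B"))
  expect_true(all(ert_propagate(ens, random_patch_matrix(5, 1)) == 1L))

  # depth-1 stump on attribute 1, threshold 0.5
  stump <- make_manual_ensemble(list(make_stump_tree(1L, 0.5, c(4, 0), c(0, 4), 1L)),
                                c("A", "B"))
  v_lo <- c(0.2, rep(0, 767))
  v_hi <- c(0.9, rep(0, 767))
  expect_equal(as.integer(ert_propagate(stump, rbind(v_lo, v_hi))), c(1L, 2L))

  # random trees + random vectors: agreement with the path-replay oracle
  X <- random_patch_matrix(50, seed = 7)
  y <- sample(c("A", "B"), 50, replace = TRUE)
  ens <- ert_ensemble(X, y, n_trees = 3, test_kind = "DIFFNEIGHBOR", seed = 9)
  V <- random_patch_matrix(20, seed = 8)
  leaves <- ert_propagate(ens, V)
  for (t in seq_along(ens$trees)) {
    tr <- ens$trees[[t]]
    for (i in 1:20) {
      expect_equal(leaves[i, t], tr$leaf_id[oracle_propagate(tr, V[i, ])])
    }
  }
})

test_that("DIFFNEIGHBOR is invariant to per-channel shifts of the raw patch", {
  set.seed(12)
  raw <- array(runif(768, 0, 200), c(16, 16, 3))
  shifted <- raw
  for (ch in 1:3) shifted[, , ch] <- raw[, , ch] + c(30, -20, 10)[ch]
  # the shift is removed by TRGB, so the encoded vectors already coincide;
  # propagation through DIFFNEIGHBOR trees is therefore identical
  v1 <- trgb_normalize(raw)
  v2 <- trgb_normalize(shifted)
  expect_equal(v1, v2, tolerance = 1e-9)
  X <- random_patch_matrix(30, seed = 13)
  ens <- ert_ensemble(X, rep(c("A", "B"), 15), n_trees = 3,
                      test_kind = "DIFFNEIGHBOR", seed = 2)
  expect_identical(ert_propagate(ens, rbind(v1)), ert_propagate(ens, rbind(v2)))
})

test_that("JSON serialization round-trips a model exactly", {
  X <- random_patch_matrix(30, seed = 14)
  y <- rep(c("A", "B", "C"), 10)
  ens <- ert_ensemble(X, y, n_trees = 3, seed = 21)
  path <- tempfile(fileext = ".json")
  ert_write(ens, path)
  back <- ert_read(path)
  expect_equal(back$classes, ens$classes)
  expect_identical(ert_serialize(back), ert_serialize(ens))
  V <- random_patch_matrix(10, seed = 15)
  expect_identical(predict(back, V, type = "prob"),
                   predict(ens, V, type = "prob"))
  unlink(path)
})
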