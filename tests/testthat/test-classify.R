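test_that("C-mode prediction averages leaf distributions over subwindows and trees", {
  # constant model: ensemble of single-leaf trees with counts (3, 1)
  ens <- make_manual_ensemble(list(make_leaf_tree(c(3, 1), 1L),
                                   make_leaf_tree(c(3, 1), 2L)),
                              c("A", "B"))
  set.seed(20)
  img <- array(runif(64 * 64 * 3, 0, 255), c(64, 64, 3))
  r <- predict_C(img, ens, sampler_params(n_subwindows = 7), seed = 1)
  expect_equal(unname(r$prob), c(0.75, 0.25), tolerance = 1e-12)
  expect_equal(r$label, "A")

  # argmax ties break by class order
  tie <- make_manual_ensemble(list(make_leaf_tree(c(2, 2), 1L)), c("A", "B"))
  expect_equal(predict_C(img, tie, sampler_params(n_subwindows = 3),
                         seed = 1)$label, "A")
})

test_that("C-mode probabilities equal the exhaustive (subwindow, tree) average", {
  # hand-built 2-tree ensemble with informative stumps, 2 subwindows
  t1 <- make_stump_tree(1L, 0.25, c(3, 1), c(1, 4), 1L)
  t2 <- make_stump_tree(300L, -0.5, c(2, 2), c(0, 5), 3L)
  ens <- make_manual_ensemble(list(t1, t2), c("A", "B"))
  set.seed(21)
  img <- array(runif(48 * 48 * 3, 0, 255), c(48, 48, 3))
  smp <- sampler_params(n_subwindows = 2, min_frac = 0.4, max_frac = 0.9)

  got <- predict_C(img, ens, smp, seed = 33)

  # oracle: re-extract the same subwindows, replay every tree path, and
  # enumerate the 4-term average of leaf class frequencies
  specs <- sample_subwindows(img, smp, seed = 33)
  X <- patchify(img, specs, smp$patch_px)
  acc <- c(0, 0)
  for (i in 1:2) {
    for (tr in ens$trees) {
      node <- oracle_propagate(tr, X[i, ])
      cnt <- tr$counts[node, ]
      acc <- acc + cnt / sum(cnt)
    }
  }
  expect_equal(unname(got$prob), acc / 4, tolerance = 1e-12)
})

test_that("subwindow order does not change C probabilities or BAGS descriptors", {
  X <- random_patch_matrix(40, seed = 22)
  ens <- ert_ensemble(X, rep(c("A", "B"), 20), n_trees = 3, n_min = 10,
                      seed = 5)
  set.seed(23)
  img <- array(runif(64 * 64 * 3, 0, 255), c(64, 64, 3))
  smp <- sampler_params(n_subwindows = 50)
  specs <- sample_subwindows(img, smp, seed = 3)
  perm <- sample(nrow(specs))
  P1 <- predict(ens, patchify(img, specs), type = "prob")
  P2 <- predict(ens, patchify(img, specs[perm, ]), type = "prob")
  expect_equal(colMeans(P1), colMeans(P2), tolerance = 1e-12)
  d1 <- tabulate(ert_propagate(ens, patchify(img, specs)), ens$n_leaves)
  d2 <- tabulate(ert_propagate(ens, patchify(img, specs[perm, ])), ens$n_leaves)
  expect_identical(d1, d2)
})

test_that("BAGS descriptors put one unit of mass per tree", {
  # single-leaf single-tree ensemble: descriptor [1]
  ens1 <- make_manual_ensemble(list(make_leaf_tree(c(1, 1), 1L)), c("A", "B"))
  set.seed(24)
  img <- array(runif(64 * 64 * 3, 0, 255), c(64, 64, 3))
  d <- bags_descriptor(img, ens1, sampler_params(n_subwindows = 9), seed = 1)
  expect_equal(as.numeric(d), 1)
  expect_equal(attr(d, "n_subwindows_used"), 9)

  # per-tree block sums are 1 for a real multi-leaf ensemble
  X <- random_patch_matrix(200, seed = 25)
  ens <- ert_ensemble(X, rep(c("A", "B"), 100), n_trees = 4, n_min = 25,
                      seed = 6)
  blocks <- rep(seq_along(ens$trees),
                vapply(ens$trees, function(t) t$n_leaves, integer(1)))
  for (i in 1:5) {
    im <- array(runif(48 * 48 * 3, 0, 255), c(48, 48, 3))
    d <- bags_descriptor(im, ens, sampler_params(n_subwindows = 100), seed = i)
    expect_equal(as.numeric(tapply(d, blocks, sum)), rep(1, 4), tolerance = 1e-9)
  }
})

test_that("a leaf split on brightness recovers the dark/bright subwindow fraction", {
  # stump on the central pixel of the unnormalized patch (row 8, col 8 of
  # the R plane -> attribute 8*16 + 8 + 1): raw intensities
  stump <- make_manual_ensemble(list(make_stump_tree(137L, 128, c(1, 0), c(0, 1), 1L)),
                                c("dark", "bright"))
  # left half dark (30), right half bright (220): window centers fall
  # uniformly, so the central patch pixel is dark for half the subwindows
  img <- array(220, c(64, 64, 3))
  img[, 1:32, ] <- 30
  smp <- sampler_params(n_subwindows = 1000, min_frac = 0.2, max_frac = 0.45)
  specs <- sample_subwindows(img, smp, seed = 4)
  X <- patchify(img, specs, normalize = FALSE)
  counts <- tabulate(ert_propagate(stump, X), 2)
  expect_lt(abs(counts[1] / 1000 - 0.5), 3 * sqrt(0.25 / 1000) + 0.05)
})

test_that("the BAGS linear SVM separates descriptor clusters and enforces contracts", {
  D <- rbind(matrix(rep(c(1, 0, 0, 0), 10), 10, 4, byrow = TRUE),
             matrix(rep(c(0, 1, 0, 0), 10), 10, 4, byrow = TRUE))
  y <- rep(c("A", "B"), each = 10)
  svm <- train_bags_svm(D, y)
  expect_equal(as.character(predict(svm, D)), y)

  expect_error(train_bags_svm(D, rep("A", 20)), class = "zs_training_error")
  expect_error(predict(svm, matrix(0, 2, 7)), class = "zs_model_error")

  # three-class one-vs-rest
  D3 <- rbind(D, matrix(rep(c(0, 0, 1, 0), 10), 10, 4, byrow = TRUE)) +
    matrix(rnorm(120, 0, 0.01), 30, 4)
  y3 <- rep(c("A", "B", "C"), each = 10)
  svm3 <- train_bags_svm(D3, y3)
  expect_equal(as.character(predict(svm3, D3)), y3)
})

test_that("BAGS image prediction is deterministic and validates model pairing", {
  X <- random_patch_matrix(300, seed = 26)
  ens <- ert_ensemble(X, rep(c("A", "B"), 150), n_trees = 3, n_min = 50,
                      seed = 7)
  set.seed(27)
  imgs <- lapply(1:6, function(i) array(runif(64 * 64 * 3, 0, 255),
                                        c(64, 64, 3)))
  smp <- sampler_params(n_subwindows = 80)
  D <- t(vapply(seq_along(imgs), function(i) {
    as.numeric(bags_descriptor(imgs[[i]], ens, smp, seed = i))
  }, numeric(ens$n_leaves)))
  svm <- train_bags_svm(D, rep(c("A", "B"), 3))
  p1 <- predict_BAGS(imgs[[1]], ens, svm, smp, seed = 1)
  p2 <- predict_BAGS(imgs[[1]], ens, svm, smp, seed = 1)
  expect_identical(as.character(p1), as.character(p2))
  # an image identical to a training image under the same seed reproduces
  # its training descriptor, hence its training-time decision
  expect_equal(as.numeric(bags_descriptor(imgs[[1]], ens, smp, seed = 1)),
               D[1, ], tolerance = 1e-15)

  # mismatched ensemble/SVM pair
  ens2 <- ert_ensemble(X, rep(c("A", "B"), 150), n_trees = 2, n_min = 20,
                       seed = 8)
  expect_error(predict_BAGS(imgs[[1]], ens2, svm, smp, seed = 1),
               class = "zs_model_error")
})

test_that("the image classifier learns well-separated synthetic classes end to end", {
  gs <- generate_classification_set(12, classes = c("Normal", "Dead", "Chorion"),
                                    seed = 5)
  cls <- vapply(parse_labels(gs$manifest$labels), `[`, character(1), 1)
  idx <- stats::ave(seq_along(cls), cls, FUN = seq_along)
  tr <- which(idx <= 8)
  te <- which(idx > 8)
  smp <- sampler_params(n_subwindows = 80)
  for (mode in c("C", "BAGS")) {
    fit <- larva_classifier(gs$images[tr], cls[tr], mode = mode,
                            sampler = smp, seed = 2)
    acc_tr <- mean(as.character(predict(fit, gs$images[tr])) == cls[tr])
    acc_te <- mean(as.character(predict(fit, gs$images[te])) == cls[te])
    expect_gte(acc_tr, 0.95)
    expect_gte(acc_te, 0.9)
  }
})
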