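# Image-level prediction.
#
# C mode: every subwindow is propagated through every tree and the leaf
# class-frequency vectors are averaged over (subwindow, tree) pairs; the
# image takes the most probable class.
#
# BAGS mode: the image is described by the frequency with which its
# subwindows land in each leaf of each tree (per-tree blocks normalized by
# the subwindow count, so descriptors are image-size independent) and that
# descriptor is classified by a linear SVM.

#' Classify one image by direct subwindow voting (C mode)
#'
#' @param img `H x W x 3` image array.
#' @param ensemble an [ert_ensemble()] (trained with the C-mode `n_min`).
#' @param sampler a [sampler_params()]; test-time subwindows are extracted
#'   with the same parameters used for training.
#' @param seed integer seed for the subwindow draw.
#' @return A list with `prob` (named class-probability vector, sums to 1),
#'   and `label` (argmax, ties broken by class order).
#' @export
predict_C <- function(img, ensemble, sampler = sampler_params(), seed = 1L) {
  if (!inherits(ensemble, "ert_ensemble")) {
    zs_stop("ensemble is not a trained ert_ensemble", "zs_model_error")
  }
  specs <- sample_subwindows(img, sampler, seed = seed)
  x <- patchify(img, specs, sampler$patch_px)
  P <- predict(ensemble, x, type = "prob")
  p <- colMeans(P)
  list(prob = p, label = ensemble$classes[which.max(p)])
}

#' Bag-of-leaf-frequencies descriptor of an image
#'
#' Counts the arrivals of the image's subwindows in every leaf of every
#' tree, normalized per tree by the subwindow count (each per-tree block of
#' the descriptor sums to 1).
#'
#' @inheritParams predict_C
#' @return A numeric vector of length `ensemble$n_leaves` with attribute
#'   `n_subwindows_used`.
#' @export
bags_descriptor <- function(img, ensemble, sampler = sampler_params(),
                            seed = 1L) {
  if (!inherits(ensemble, "ert_ensemble")) {
    zs_stop("ensemble is not a trained ert_ensemble", "zs_model_error")
  }
  specs <- sample_subwindows(img, sampler, seed = seed)
  x <- patchify(img, specs, sampler$patch_px)
  leaves <- ert_propagate(ensemble, x)
  d <- tabulate(as.integer(leaves), nbins = ensemble$n_leaves) /
    nrow(specs)
  attr(d, "n_subwindows_used") <- nrow(specs)
  d
}

#' Train a linear SVM on bag-of-leaf-frequency descriptors
#'
#' A maximum-margin linear classifier (libsvm via e1071, cost `C`); for
#' more than two classes a one-vs-rest wrapper takes the class with the
#' largest decision value.
#'
#' @param descriptors numeric matrix, one image descriptor per row.
#' @param labels class labels (>= 2 classes present).
#' @param cost SVM regularization constant.
#' @return An object of class `bags_svm`.
#' @export
train_bags_svm <- function(descriptors, labels, cost = 1) {
  d <- as.matrix(descriptors)
  y <- factor(labels)
  if (nlevels(y) < 2) {
    zs_stop("training labels contain fewer than 2 classes", "zs_training_error")
  }
  if (nlevels(y) == 2) {
    models <- list(e1071::svm(d, y, kernel = "linear", cost = cost,
                              scale = FALSE))
  } else {
    models <- lapply(levels(y), function(cl) {
      yy <- factor(ifelse(y == cl, "pos", "rest"), levels = c("pos", "rest"))
      e1071::svm(d, yy, kernel = "linear", cost = cost, scale = FALSE)
    })
  }
  structure(list(models = models, classes = levels(y), dim = ncol(d),
                 cost = cost),
            class = "bags_svm")
}

#' @export
predict.bags_svm <- function(object, newdata, ...) {
  d <- if (is.matrix(newdata)) newdata else matrix(newdata, nrow = 1)
  if (ncol(d) != object$dim) {
    zs_stop("descriptor length does not match the trained SVM", "zs_model_error")
  }
  if (length(object$models) == 1) {
    pr <- predict(object$models[[1]], d, decision.values = TRUE)
    dec <- attr(pr, "decision.values")
    out <- factor(as.character(pr), levels = object$classes)
    attr(out, "decision") <- dec
    return(out)
  }
  dec <- vapply(object$models, function(m) {
    v <- attr(predict(m, d, decision.values = TRUE), "decision.values")
    # orient so positive always means the "pos" (one-vs-rest target) side
    if (colnames(v)[1] == "pos/rest") as.numeric(v) else -as.numeric(v)
  }, numeric(nrow(d)))
  dec <- matrix(dec, nrow = nrow(d))
  colnames(dec) <- object$classes
  out <- factor(object$classes[max.col(dec, ties.method = "first")],
                levels = object$classes)
  attr(out, "decision") <- dec
  out
}

#' Classify one image in BAGS mode
#'
#' [bags_descriptor()] followed by the linear SVM decision; deterministic
#' for a fixed seed.
#'
#' @inheritParams predict_C
#' @param svm a [train_bags_svm()] model fitted on descriptors from the
#'   same ensemble.
#' @return The predicted label (factor of length 1) with attribute
#'   `decision` (SVM decision values).
#' @export
predict_BAGS <- function(img, ensemble, svm, sampler = sampler_params(),
                         seed = 1L) {
  d <- bags_descriptor(img, ensemble, sampler, seed)
  if (length(d) != svm$dim) {
    zs_stop("ensemble and SVM descriptor dimensions do not match",
            "zs_model_error")
  }
  predict(svm, matrix(d, nrow = 1))
}

#' Train an image classifier (C or BAGS mode)
#'
#' The main fitting function: extracts `n_subwindows` TRGB-normalized
#' patches from every training image (each image in its own reproducible
#' random stream, so results do not depend on processing order), grows an
#' ensemble of extremely randomized trees on the pooled patches labeled by
#' their source image, and — in BAGS mode — fits a linear SVM on the
#' per-image leaf-frequency descriptors.
#'
#' @param images list of `H x W x 3` arrays (names, when present, identify
#'   the per-image random streams; otherwise positions are used).
#' @param labels one class label per image.
#' @param mode `"C"` (direct subwindow voting; `n_min = 1`) or `"BAGS"`
#'   (leaf-frequency descriptors + linear SVM; `n_min = 1000`).
#' @param sampler a [sampler_params()].
#' @param n_trees,n_tests number of trees and candidate tests per node.
#' @param test_kind node-test family, `"SIMPLETHRES"` or `"DIFFNEIGHBOR"`.
#' @param n_min minimal node size to split; defaults to the recommended
#'   value for the chosen mode.
#' @param svm_cost linear SVM regularization (BAGS mode).
#' @param seed integer seed governing every random draw.
#' @return An object of class `larva_classifier` with `predict`, `print`
#'   and `summary` methods.
#' @export
larva_classifier <- function(images, labels, mode = c("C", "BAGS"),
                             sampler = sampler_params(), n_trees = 10,
                             n_tests = 28,
                             test_kind = c("SIMPLETHRES", "DIFFNEIGHBOR"),
                             n_min = NULL, svm_cost = 1, seed = 1L) {
  mode <- match.arg(mode)
  test_kind <- match.arg(test_kind)
  if (is.null(n_min)) n_min <- if (mode == "C") 1L else 1000L
  n_img <- length(images)
  if (n_img < 2) zs_stop("need at least two training images", "zs_parameter_error")
  if (length(labels) != n_img) {
    zs_stop("one label per training image required", "zs_parameter_error")
  }
  y <- factor(labels)
  ids <- names(images) %||% as.character(seq_len(n_img))
  n_sw <- sampler$n_subwindows
  nattr <- 3L * sampler$patch_px^2

  X <- matrix(0, n_img * n_sw, nattr)
  for (i in seq_len(n_img)) {
    specs <- sample_subwindows(images[[i]], sampler,
                               seed = derive_seed(seed, ids[i]))
    X[(i - 1L) * n_sw + seq_len(n_sw), ] <-
      patchify(images[[i]], specs, sampler$patch_px)
  }
  ensemble <- ert_ensemble(X, rep(y, each = n_sw), n_trees = n_trees,
                           n_tests = n_tests, n_min = n_min,
                           test_kind = test_kind,
                           patch_px = sampler$patch_px,
                           seed = derive_seed(seed, "ensemble"))
  svm <- NULL
  if (mode == "BAGS") {
    leaves <- ert_propagate(ensemble, X)
    D <- matrix(0, n_img, ensemble$n_leaves)
    for (i in seq_len(n_img)) {
      rows <- (i - 1L) * n_sw + seq_len(n_sw)
      D[i, ] <- tabulate(as.integer(leaves[rows, ]),
                         nbins = ensemble$n_leaves) / n_sw
    }
    svm <- train_bags_svm(D, y, cost = svm_cost)
  }
  structure(list(mode = mode, ensemble = ensemble, svm = svm,
                 sampler = sampler, classes = levels(y), seed = seed,
                 n_train = n_img),
            class = "larva_classifier")
}

#' Predict phenotype classes for images
#'
#' @param object a [larva_classifier()].
#' @param images list of `H x W x 3` arrays; names, when present, identify
#'   the per-image random streams (an image predicted under the same name
#'   and seed always yields the same subwindows, hence the same result).
#' @param seed base seed for the test-time subwindow draws (defaults to the
#'   training seed).
#' @param ... unused.
#' @return A factor of predicted labels; in C mode with attribute `prob`
#'   (per-image class-probability matrix), in BAGS mode with attribute
#'   `decision`.
#' @export
predict.larva_classifier <- function(object, images, seed = NULL, ...) {
  if (!is.list(images)) images <- list(images)
  seed <- seed %||% object$seed
  ids <- names(images) %||% as.character(seq_along(images))
  n <- length(images)
  labels <- character(n)
  if (object$mode == "C") {
    prob <- matrix(0, n, length(object$classes),
                   dimnames = list(ids, object$classes))
    for (i in seq_len(n)) {
      r <- predict_C(images[[i]], object$ensemble, object$sampler,
                     seed = derive_seed(seed, ids[i]))
      prob[i, ] <- r$prob
      labels[i] <- r$label
    }
    out <- factor(labels, levels = object$classes)
    attr(out, "prob") <- prob
  } else {
    dec <- NULL
    for (i in seq_len(n)) {
      r <- predict_BAGS(images[[i]], object$ensemble, object$svm,
                        object$sampler, seed = derive_seed(seed, ids[i]))
      labels[i] <- as.character(r)
      d <- attr(r, "decision")
      if (is.null(dec)) {
        dec <- matrix(0, n, length(d), dimnames = list(ids, colnames(d)))
      }
      dec[i, ] <- d
    }
    out <- factor(labels, levels = object$classes)
    attr(out, "decision") <- dec
  }
  names(out) <- ids
  out
}

#' @export
print.larva_classifier <- function(x, ...) {
  cat(sprintf("larva_classifier (%s mode)\n", x$mode))
  cat(sprintf("  classes: %s\n", paste(x$classes, collapse = ", ")))
  cat(sprintf("  trained on %d images, %d subwindows each (sides %.0f%%-%.0f%% of min dim)\n",
              x$n_train, x$sampler$n_subwindows, 100 * x$sampler$min_frac,
              100 * x$sampler$max_frac))
  print(x$ensemble)
  invisible(x)
}

#' @export
summary.larva_classifier <- function(object, ...) {
  print(object)
  if (!is.null(object$svm)) {
    cat(sprintf("  linear SVM on %d-dimensional BAGS descriptors (C = %g)\n",
                object$svm$dim, object$svm$cost))
  }
  invisible(object)
}
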