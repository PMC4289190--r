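# Extremely randomized trees over patch attribute vectors.
#
# Both the tested attribute and its threshold are drawn at random at every
# node; of K such candidate tests the one with the best normalized Shannon
# information gain is kept. Two node-test families are supported:
# SIMPLETHRES thresholds a single (TRGB) pixel value, DIFFNEIGHBOR the
# difference between a pixel and one of its 8 spatial neighbors in the same
# channel plane. Leaves store raw class counts; leaf identifiers are unique
# and contiguous across the whole ensemble, which makes them usable as
# bag-of-visual-words coordinates (BAGS mode).

ERT_TEST_KINDS <- c("SIMPLETHRES", "DIFFNEIGHBOR")

#' Fit an ensemble of extremely randomized trees
#'
#' @param x numeric matrix of training attribute vectors (one subwindow per
#'   row, `3 * patch_px^2` columns in channel-planar layout).
#' @param y class labels (factor or character), one per row of `x`.
#' @param n_trees number of trees `T` (10 is the minimal recommended value).
#' @param n_tests number of candidate tests `K` evaluated per node (28 is
#'   the usual default for 768-attribute color patches, roughly `sqrt(M)`).
#' @param n_min minimal node size to attempt a split: 1 for direct
#'   subwindow classification (C mode), 1000 for BAGS descriptors.
#' @param test_kind `"SIMPLETHRES"` or `"DIFFNEIGHBOR"`.
#' @param patch_px patch edge; defines the neighbor grid for DIFFNEIGHBOR.
#' @param seed integer seed; trees use independent substreams, so the same
#'   seed always reproduces the identical ensemble.
#' @return An object of class `ert_ensemble`.
#' @export
ert_ensemble <- function(x, y, n_trees = 10, n_tests = 28, n_min = 1,
                         test_kind = c("SIMPLETHRES", "DIFFNEIGHBOR"),
                         patch_px = 16, seed = 1L) {
  test_kind <- match.arg(test_kind)
  if (n_trees < 1 || n_tests < 1 || n_min < 1) {
    zs_stop("n_trees, n_tests and n_min must all be >= 1", "zs_parameter_error")
  }
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  if (nrow(x) < 1) zs_stop("need at least one training sample", "zs_parameter_error")
  if (ncol(x) != 3L * patch_px^2) {
    zs_stop(sprintf("expected %d attributes for patch_px = %d", 3 * patch_px^2,
                    patch_px), "zs_parameter_error")
  }
  y <- factor(y)
  if (length(y) != nrow(x)) zs_stop("length(y) != nrow(x)", "zs_parameter_error")
  classes <- levels(y)
  trees <- cpp_build_ensemble(x, as.integer(y) - 1L, length(classes),
                              as.integer(n_trees), as.integer(n_tests),
                              as.integer(n_min),
                              match(test_kind, ERT_TEST_KINDS) - 1L,
                              as.integer(patch_px), as.double(seed))
  structure(list(
    trees = trees,
    classes = classes,
    n_leaves = sum(vapply(trees, function(t) t$n_leaves, integer(1))),
    params = list(n_trees = as.integer(n_trees), n_tests = as.integer(n_tests),
                  n_min = as.integer(n_min), test_kind = test_kind,
                  patch_px = as.integer(patch_px), seed = as.integer(seed)),
    n_train = nrow(x)
  ), class = "ert_ensemble")
}

#' @export
print.ert_ensemble <- function(x, ...) {
  p <- x$params
  cat("Extremely randomized trees ensemble\n")
  cat(sprintf("  %d trees, K = %d, N_min = %d, %s tests\n",
              p$n_trees, p$n_tests, p$n_min, p$test_kind))
  cat(sprintf("  classes: %s\n", paste(x$classes, collapse = ", ")))
  cat(sprintf("  %d leaves over %d training vectors\n", x$n_leaves, x$n_train))
  invisible(x)
}

#' Propagate attribute vectors through an ensemble
#'
#' Deterministic descent: at each internal node the tested quantity (pixel
#' value, or pixel difference) goes left iff it is strictly below the node
#' threshold.
#'
#' @param ensemble an [ert_ensemble()].
#' @param x numeric matrix of attribute vectors.
#' @return An integer matrix (`nrow(x)` x `n_trees`) of ensemble-unique
#'   leaf identifiers.
#' @export
ert_propagate <- function(ensemble, x) {
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  out <- matrix(0L, nrow(x), length(ensemble$trees))
  for (t in seq_along(ensemble$trees)) {
    tr <- ensemble$trees[[t]]
    nodes <- cpp_propagate(x, tr$attr, tr$attr2, tr$threshold, tr$left,
                           tr$right)
    out[, t] <- tr$leaf_id[nodes]
  }
  out
}

#' Predict from an ensemble of extremely randomized trees
#'
#' @param object an [ert_ensemble()].
#' @param newdata numeric matrix of attribute vectors.
#' @param type `"prob"` for class-probability vectors (leaf class
#'   frequencies averaged over trees), `"response"` for the most probable
#'   class (ties broken by class order), `"leaf"` for leaf identifiers.
#' @param ... unused.
#' @export
predict.ert_ensemble <- function(object, newdata,
                                 type = c("prob", "response", "leaf"), ...) {
  type <- match.arg(type)
  x <- as.matrix(newdata)
  storage.mode(x) <- "double"
  if (ncol(x) != 3L * object$params$patch_px^2) {
    zs_stop("attribute count does not match the trained ensemble",
            "zs_model_error")
  }
  if (type == "leaf") {
    return(ert_propagate(object, x))
  }
  P <- matrix(0, nrow(x), length(object$classes))
  for (tr in object$trees) {
    nodes <- cpp_propagate(x, tr$attr, tr$attr2, tr$threshold, tr$left,
                           tr$right)
    cnt <- tr$counts[nodes, , drop = FALSE]
    P <- P + cnt / rowSums(cnt)
  }
  P <- P / length(object$trees)
  colnames(P) <- object$classes
  if (type == "prob") {
    return(P)
  }
  factor(object$classes[max.col(P, ties.method = "first")],
         levels = object$classes)
}

#' Draw one random node test (exposed for diagnostics)
#'
#' Draws a candidate node test exactly as tree induction does: attribute
#' (and, for DIFFNEIGHBOR, one of its in-grid 8-neighbors) uniform at
#' random, threshold uniform in the open interval between the node-local
#' minimum and maximum of the tested quantity, so the split is never
#' degenerate. Returns `valid = FALSE` when no non-constant quantity exists.
#'
#' @param x numeric matrix of the attribute vectors at the node (>= 2 rows).
#' @param test_kind `"SIMPLETHRES"` or `"DIFFNEIGHBOR"`.
#' @param patch_px patch edge defining the neighbor grid.
#' @param seed integer seed for the draw.
#' @return A list with `kind`, `attr`, `attr2`, `threshold`, `valid`.
#' @export
draw_random_test <- function(x, test_kind = c("SIMPLETHRES", "DIFFNEIGHBOR"),
                             patch_px = 16, seed = 1L) {
  test_kind <- match.arg(test_kind)
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  if (nrow(x) < 2) zs_stop("node needs >= 2 samples", "zs_parameter_error")
  out <- cpp_draw_random_test(x, match(test_kind, ERT_TEST_KINDS) - 1L,
                              as.integer(patch_px), as.double(seed))
  out$kind <- test_kind
  out
}

#' Normalized information-gain score of a candidate split
#'
#' `2 * I(split; class) / (H_class + H_split)` with Shannon entropies; 0 for
#' an uninformative split, maximal when both sides are pure.
#'
#' @param left_labels,right_labels class labels on the two sides (both
#'   non-empty; coerced to a common factor).
#' @return A non-negative scalar.
#' @export
split_score <- function(left_labels, right_labels) {
  if (length(left_labels) == 0 || length(right_labels) == 0) {
    zs_stop("both sides of a split must be non-empty", "zs_invalid_split")
  }
  all_y <- factor(c(as.character(left_labels), as.character(right_labels)))
  nl <- length(left_labels)
  yl <- as.integer(all_y[seq_len(nl)]) - 1L
  yr <- as.integer(all_y[-seq_len(nl)]) - 1L
  cpp_split_score(yl, yr, nlevels(all_y))
}

#' Serialize an ensemble to versioned JSON
#'
#' The JSON carries a header (format version, parameters, class names, leaf
#' count) and the full tree array with thresholds as decimal floats, so
#' models are portable and diff-able; identical seeds give byte-identical
#' files.
#'
#' @param ensemble an [ert_ensemble()].
#' @return A JSON string (class `json`).
#' @export
ert_serialize <- function(ensemble) {
  payload <- list(
    version = 1L,
    params = ensemble$params,
    n_classes = length(ensemble$classes),
    class_names = ensemble$classes,
    n_leaves = ensemble$n_leaves,
    n_train = ensemble$n_train,
    trees = lapply(ensemble$trees, function(tr) {
      list(attr = tr$attr, attr2 = tr$attr2, threshold = tr$threshold,
           left = tr$left, right = tr$right, leaf_id = tr$leaf_id,
           counts = tr$counts, n_nodes = tr$n_nodes, n_leaves = tr$n_leaves)
    })
  )
  jsonlite::toJSON(payload, digits = NA, auto_unbox = TRUE, na = "null")
}

#' Write / read an ensemble as a JSON model file
#'
#' @param ensemble an [ert_ensemble()].
#' @param path file path.
#' @return `ert_write` returns `path` invisibly; `ert_read` the restored
#'   `ert_ensemble`.
#' @export
ert_write <- function(ensemble, path) {
  writeLines(ert_serialize(ensemble), path)
  invisible(path)
}

#' @rdname ert_write
#' @export
ert_read <- function(path) {
  p <- jsonlite::fromJSON(path, simplifyDataFrame = FALSE,
                          simplifyMatrix = TRUE)
  if (is.null(p$version) || p$version != 1L) {
    zs_stop("unsupported model file version", "zs_model_error")
  }
  trees <- lapply(p$trees, function(tr) {
    list(attr = as.integer(tr$attr), attr2 = as.integer(tr$attr2),
         threshold = as.numeric(tr$threshold), left = as.integer(tr$left),
         right = as.integer(tr$right), leaf_id = as.integer(tr$leaf_id),
         counts = matrix(as.numeric(tr$counts), ncol = p$n_classes),
         n_nodes = as.integer(tr$n_nodes), n_leaves = as.integer(tr$n_leaves))
  })
  structure(list(trees = trees, classes = p$class_names,
                 n_leaves = p$n_leaves,
                 params = list(n_trees = p$params$n_trees,
                               n_tests = p$params$n_tests,
                               n_min = p$params$n_min,
                               test_kind = p$params$test_kind,
                               patch_px = p$params$patch_px,
                               seed = p$params$seed),
                 n_train = p$n_train),
            class = "ert_ensemble")
}
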