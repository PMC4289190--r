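# Independent brute-force oracles used to pin down expected values.
# These deliberately re-derive each quantity from its definition with plain
# loops, independently of the package's implementation paths.

# population variance of the (2r+1)^2 window at each fully interior pixel;
# border ring of width r left at 0
oracle_variance_filter <- function(g, radius) {
  H <- nrow(g)
  W <- ncol(g)
  out <- matrix(0, H, W)
  for (r in (radius + 1):(H - radius)) {
    for (c in (radius + 1):(W - radius)) {
      win <- g[(r - radius):(r + radius), (c - radius):(c + radius)]
      out[r, c] <- mean((win - mean(win))^2)
    }
  }
  out
}

# exhaustive Otsu scan: the threshold (bin edge over 256 levels of the
# rescaled image) maximizing between-class variance
oracle_otsu_threshold <- function(g) {
  x <- (g - min(g)) / (max(g) - min(g))
  best <- -Inf
  best_t <- 0
  for (t in (1:255) / 256) {
    lo <- x[x <= t]
    hi <- x[x > t]
    if (!length(lo) || !length(hi)) next
    w <- length(lo) / length(x)
    v <- w * (1 - w) * (mean(lo) - mean(hi))^2
    if (v > best) {
      best <- v
      best_t <- t
    }
  }
  best_t
}

# one binary dilation by repeated neighborhood max
oracle_dilate_once <- function(mask) {
  H <- nrow(mask)
  W <- ncol(mask)
  out <- matrix(FALSE, H, W)
  for (r in 1:H) {
    for (c in 1:W) {
      rr <- max(1, r - 1):min(H, r + 1)
      cc <- max(1, c - 1):min(W, c + 1)
      out[r, c] <- any(mask[rr, cc])
    }
  }
  out
}

# 8-connected labeling by explicit flood fill (stack-based)
oracle_flood_fill <- function(mask) {
  H <- nrow(mask)
  W <- ncol(mask)
  lab <- matrix(0L, H, W)
  nxt <- 0L
  for (start in which(mask)) {
    if (lab[start] != 0L) next
    nxt <- nxt + 1L
    stack <- start
    lab[start] <- nxt
    while (length(stack)) {
      p <- stack[length(stack)]
      stack <- stack[-length(stack)]
      pr <- (p - 1L) %% H + 1L
      pc <- (p - 1L) %/% H + 1L
      for (dr in -1:1) {
        for (dc in -1:1) {
          r <- pr + dr
          c <- pc + dc
          if (r < 1 || r > H || c < 1 || c > W) next
          q <- r + (c - 1L) * H
          if (mask[q] && lab[q] == 0L) {
            lab[q] <- nxt
            stack <- c(stack, q)
          }
        }
      }
    }
  }
  lab
}

# area and bbox of the largest 8-connected component under the same
# tie-break rule (smallest bbox origin)
oracle_largest_component <- function(mask) {
  lab <- oracle_flood_fill(mask)
  areas <- tabulate(lab[lab > 0])
  best <- NULL
  for (id in which(areas == max(areas))) {
    idx <- which(lab == id, arr.ind = TRUE)
    bbox <- c(min(idx[, 1]), min(idx[, 2]), max(idx[, 1]), max(idx[, 2]))
    if (is.null(best) || bbox[1] < best$bbox[1] ||
        (bbox[1] == best$bbox[1] && bbox[2] < best$bbox[2])) {
      best <- list(bbox = unname(bbox), area = max(areas))
    }
  }
  best
}

# bilinear resample of a single-channel matrix to oh x ow (half-pixel
# centers, clamped), re-derived from the interpolation definition
oracle_bilinear <- function(m, oh, ow) {
  H <- nrow(m)
  W <- ncol(m)
  out <- matrix(0, oh, ow)
  for (i in 1:oh) {
    sy <- min(max((i - 0.5) * H / oh - 0.5, 0), H - 1)
    y0 <- floor(sy)
    fy <- sy - y0
    y1 <- min(y0 + 1, H - 1)
    for (j in 1:ow) {
      sx <- min(max((j - 0.5) * W / ow - 0.5, 0), W - 1)
      x0 <- floor(sx)
      fx <- sx - x0
      x1 <- min(x0 + 1, W - 1)
      out[i, j] <- (1 - fy) * ((1 - fx) * m[y0 + 1, x0 + 1] + fx * m[y0 + 1, x1 + 1]) +
        fy * ((1 - fx) * m[y1 + 1, x0 + 1] + fx * m[y1 + 1, x1 + 1])
    }
  }
  out
}

# re-evaluate every node test along the path of a tree (path replay)
oracle_propagate <- function(tree, vec) {
  node <- 1L
  while (!is.na(tree$left[node])) {
    q <- vec[tree$attr[node]]
    if (!is.na(tree$attr2[node])) q <- q - vec[tree$attr2[node]]
    node <- if (q < tree$threshold[node]) tree$left[node] else tree$right[node]
  }
  node
}

# normalized information gain from first principles (natural-log entropies)
oracle_split_score <- function(left, right) {
  ent <- function(y) {
    p <- table(y) / length(y)
    -sum(ifelse(p > 0, p * log(p), 0))
  }
  y <- c(left, right)
  n <- length(y)
  pl <- length(left) / n
  pr <- length(right) / n
  hc <- ent(y)
  hs <- -(pl * log(pl) + pr * log(pr))
  gain <- hc - pl * ent(left) - pr * ent(right)
  2 * gain / (hc + hs)
}

# hand-buildable ensembles for constant/oracle prediction tests ------------

make_leaf_tree <- function(counts, leaf_id) {
  list(attr = NA_integer_, attr2 = NA_integer_, threshold = NA_real_,
       left = NA_integer_, right = NA_integer_, leaf_id = leaf_id,
       counts = matrix(counts, nrow = 1), n_nodes = 1L, n_leaves = 1L)
}

make_stump_tree <- function(attr, threshold, counts_left, counts_right,
                            first_leaf_id) {
  list(attr = c(attr, NA, NA), attr2 = rep(NA_integer_, 3),
       threshold = c(threshold, NA, NA), left = c(2L, NA, NA),
       right = c(3L, NA, NA),
       leaf_id = c(NA, first_leaf_id, first_leaf_id + 1L),
       counts = rbind(0, counts_left, counts_right),
       n_nodes = 3L, n_leaves = 2L)
}

make_manual_ensemble <- function(trees, classes, patch_px = 16) {
  structure(list(
    trees = trees, classes = classes,
    n_leaves = sum(vapply(trees, function(t) t$n_leaves, integer(1))),
    params = list(n_trees = length(trees), n_tests = 1L, n_min = 1L,
                  test_kind = "SIMPLETHRES", patch_px = as.integer(patch_px),
                  seed = 0L),
    n_train = 0L
  ), class = "ert_ensemble")
}

# a larva_classifier whose ensemble is a single constant leaf, so it always
# predicts `label`: used to exercise two-tier routing deterministically
make_constant_classifier <- function(classes, label, patch_px = 16) {
  counts <- ifelse(classes == label, 3, 1)
  ens <- make_manual_ensemble(list(make_leaf_tree(counts, 1L)), classes,
                              patch_px)
  structure(list(mode = "C", ensemble = ens, svm = NULL,
                 sampler = sampler_params(n_subwindows = 2),
                 classes = classes, seed = 1L, n_train = 0L),
            class = "larva_classifier")
}

# small random labeled attribute matrices for tree tests
random_patch_matrix <- function(n, seed, nattr = 768) {
  set.seed(seed)
  matrix(rnorm(n * nattr), n, nattr)
}
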