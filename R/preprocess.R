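# Larva localization and square cropping.
#
# The localization chain mirrors the classical morphological recipe for
# finding a single dark object on a bright background: an edge-enhancing
# neighborhood-variance filter, automatic global thresholding, two
# dilatations to close the outline, connected-component labeling keeping the
# largest object, and a square crop centered on it (with a tight bounding
# square for near-circular objects such as unhatched chorions, and a clipped
# rectangle when the square would leave the image).

#' Neighborhood variance filter
#'
#' Replaces each pixel with the population variance of the intensities in
#' its `(2*radius+1)^2` square neighborhood, highlighting object edges.
#' The border ring of width `radius`, where the window would leave the
#' image, is set to 0.
#'
#' @param img grayscale matrix, or an `H x W x 3` array (converted to
#'   grayscale by the unweighted channel mean).
#' @param radius neighborhood radius in pixels (window side `2*radius+1`).
#' @return A numeric matrix of the same size as the input.
#' @export
variance_filter <- function(img, radius = 2) {
  if (!is.numeric(radius) || length(radius) != 1 || radius < 1) {
    zs_stop("radius must be a single integer >= 1", "zs_parameter_error")
  }
  radius <- as.integer(radius)
  g <- to_gray(img)
  g <- g - mean(g) # shift-invariant; improves conditioning of E[x^2]-E[x]^2
  H <- nrow(g)
  W <- ncol(g)
  k <- 2L * radius + 1L
  out <- matrix(0, H, W)
  if (H < k || W < k) {
    return(out)
  }
  n <- as.numeric(k)^2
  s1 <- window_sums(g, k)
  s2 <- window_sums(g * g, k)
  v <- s2 / n - (s1 / n)^2
  out[(radius + 1L):(H - radius), (radius + 1L):(W - radius)] <- pmax(v, 0)
  out
}

# full-window sums of k x k neighborhoods via a padded integral image;
# returns an (H-k+1) x (W-k+1) matrix of sums for all fully interior windows
window_sums <- function(m, k) {
  H <- nrow(m)
  W <- ncol(m)
  P <- matrix(0, H + 1L, W + 1L)
  P[-1L, -1L] <- apply(apply(m, 2L, cumsum), 1L, cumsum) |> t()
  r1 <- (k + 1L):(H + 1L)
  r0 <- 1L:(H + 1L - k)
  c1 <- (k + 1L):(W + 1L)
  c0 <- 1L:(W + 1L - k)
  P[r1, c1, drop = FALSE] - P[r0, c1, drop = FALSE] -
    P[r1, c0, drop = FALSE] + P[r0, c0, drop = FALSE]
}

#' Binarize a grayscale image with an automatic global threshold
#'
#' Thresholds at the Otsu optimum (maximal between-class variance over a
#' 256-level histogram of the rescaled intensities). Pixels strictly above
#' the threshold are `TRUE`; for a non-constant input the global maximum is
#' always `TRUE`. A constant image is not separable: it yields an all-`FALSE`
#' mask with a warning.
#'
#' @param img grayscale matrix (any real range), or an `H x W x 3` array.
#' @return A logical matrix of the same size.
#' @export
binarize <- function(img) {
  g <- to_gray(img)
  if (length(g) == 0) zs_stop("empty image", "zs_parameter_error")
  rng <- range(g)
  if (rng[1] == rng[2]) {
    warning("constant image: no object separable; returning empty mask")
    return(matrix(FALSE, nrow(g), ncol(g)))
  }
  x <- (g - rng[1]) / (rng[2] - rng[1])
  th <- EBImage::otsu(x, range = c(0, 1), levels = 256L)
  x > th
}

#' Dilate a binary mask with a 3x3 square structuring element
#'
#' @param mask logical matrix.
#' @param iterations number of dilatations (`0` is the identity).
#' @return A logical matrix; always a superset of the input.
#' @export
dilate_mask <- function(mask, iterations = 1) {
  if (iterations < 0) zs_stop("iterations must be >= 0", "zs_parameter_error")
  if (iterations == 0) {
    return(mask)
  }
  m <- mask * 1
  brush <- matrix(1, 3, 3)
  for (i in seq_len(iterations)) m <- EBImage::dilate(m, brush)
  m > 0.5
}

#' Largest 8-connected component of a binary mask
#'
#' Labels the mask with 8-connectivity and returns the component with the
#' maximal pixel count; ties are broken by the lexicographically smallest
#' bounding-box origin `(row_min, col_min)` so the result is deterministic.
#'
#' @param mask logical matrix with at least one `TRUE` pixel.
#' @return A list with `bbox = c(row_min, col_min, row_max, col_max)`
#'   (1-based, inclusive), `area` (pixel count) and
#'   `aspect_ratio = max(h, w) / min(h, w)`.
#' @export
largest_component <- function(mask) {
  if (!any(mask)) zs_stop("mask contains no object", "zs_no_object")
  lab <- cpp_label8(mask)
  areas <- tabulate(lab[lab > 0L])
  amax <- max(areas)
  best <- NULL
  for (id in which(areas == amax)) {
    idx <- which(lab == id, arr.ind = TRUE)
    bbox <- c(min(idx[, 1]), min(idx[, 2]), max(idx[, 1]), max(idx[, 2]))
    if (is.null(best) || bbox[1] < best$bbox[1] ||
      (bbox[1] == best$bbox[1] && bbox[2] < best$bbox[2])) {
      best <- list(bbox = unname(bbox), area = amax)
    }
  }
  h <- best$bbox[3] - best$bbox[1] + 1
  w <- best$bbox[4] - best$bbox[2] + 1
  best$aspect_ratio <- max(h, w) / min(h, w)
  best
}

#' Square crop around a located region
#'
#' Near-circular regions (`aspect_ratio <= circular_ratio_max`, e.g.
#' unhatched chorions) are cropped by the tight bounding square anchored at
#' the region origin; elongated regions by a square of side `max(h, w)`
#' centered on the bounding-box center. A square that would exceed the image
#' is clipped to a rectangle (the near-border fallback); the crop always
#' contains the full bounding box.
#'
#' @param img `H x W x 3` image array.
#' @param region result of [largest_component()].
#' @param circular_ratio_max aspect-ratio cutoff for the circular case.
#' @return The cropped image, with attributes `crop_bbox` (its position in
#'   the original image, `c(row_min, col_min, row_max, col_max)`) and
#'   `fallback_used` (`TRUE` when clipping occurred).
#' @export
square_crop <- function(img, region, circular_ratio_max = 1.2) {
  d <- dim(img)
  H <- d[1]
  W <- d[2]
  bb <- region$bbox
  if (bb[1] < 1 || bb[2] < 1 || bb[3] > H || bb[4] > W) {
    zs_stop("region lies outside the image", "zs_parameter_error")
  }
  h <- bb[3] - bb[1] + 1
  w <- bb[4] - bb[2] + 1
  s <- max(h, w)
  if (region$aspect_ratio <= circular_ratio_max) {
    r0 <- bb[1]
    c0 <- bb[2]
  } else {
    r0 <- floor((bb[1] + bb[3]) / 2 - (s - 1) / 2)
    c0 <- floor((bb[2] + bb[4]) / 2 - (s - 1) / 2)
  }
  r1 <- r0 + s - 1
  c1 <- c0 + s - 1
  rr0 <- max(1, r0)
  cc0 <- max(1, c0)
  rr1 <- min(H, r1)
  cc1 <- min(W, c1)
  fallback <- (rr0 != r0) || (cc0 != c0) || (rr1 != r1) || (cc1 != c1)
  out <- img[rr0:rr1, cc0:cc1, , drop = FALSE]
  attr(out, "crop_bbox") <- c(rr0, cc0, rr1, cc1)
  attr(out, "fallback_used") <- fallback
  out
}

#' Locate the larva in a brightfield image and crop it
#'
#' Composition of [variance_filter()], [binarize()], two (by default)
#' [dilate_mask()] passes, [largest_component()] and [square_crop()].
#' Deterministic for fixed input and parameters.
#'
#' @inheritParams square_crop
#' @param radius variance-filter radius in pixels.
#' @param dilations number of 3x3 dilatations applied to the binarized edge
#'   mask before labeling.
#' @return The cropped image with attributes `crop_bbox`, `fallback_used`
#'   and `region` (the located component).
#' @export
locate_and_crop <- function(img, radius = 2, dilations = 2,
                            circular_ratio_max = 1.2) {
  assert_rgb_image(img)
  v <- variance_filter(img, radius)
  m <- suppressWarnings(binarize(v))
  if (!any(m)) zs_stop("no object found in image", "zs_no_object")
  m <- dilate_mask(m, dilations)
  reg <- largest_component(m)
  out <- square_crop(img, reg, circular_ratio_max)
  attr(out, "region") <- reg
  out
}
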