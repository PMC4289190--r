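# Random-subwindow extraction and TRGB encoding.
#
# An image is described by square subwindows drawn at random positions and
# sizes, each resized to a fixed patch grid and standardized per RGB channel
# (TRGB: subtract the mean, divide by the population standard deviation,
# within the subwindow and channel). A patch of edge `patch_px` yields
# 3 * patch_px^2 attributes in channel-planar order (all R, all G, all B;
# row-major inside each plane), the fixed layout the neighbor-difference
# node tests index into.

#' Subwindow sampler parameters
#'
#' @param n_subwindows number of subwindows extracted per image.
#' @param min_frac,max_frac subwindow side range as a fraction of the
#'   image's smaller dimension; sides are drawn uniformly on the integer
#'   interval `[ceil(min_frac * min(H, W)), floor(max_frac * min(H, W))]`.
#' @param patch_px edge of the fixed patch grid each subwindow is resized
#'   to; the default 16 gives the 768-attribute description.
#' @return A list of class `sampler_params`.
#' @export
sampler_params <- function(n_subwindows = 1000, min_frac = 0.5,
                           max_frac = 0.9, patch_px = 16) {
  if (!(min_frac >= 0 && min_frac <= max_frac && max_frac <= 1)) {
    zs_stop("need 0 <= min_frac <= max_frac <= 1", "zs_parameter_error")
  }
  if (n_subwindows < 1) zs_stop("n_subwindows must be >= 1", "zs_parameter_error")
  structure(list(n_subwindows = as.integer(n_subwindows),
                 min_frac = min_frac, max_frac = max_frac,
                 patch_px = as.integer(patch_px)),
            class = "sampler_params")
}

#' Sample random square subwindows
#'
#' Draws `n_subwindows` square subwindows: sides uniform on the allowed
#' integer interval, positions uniform among placements fully inside the
#' image.
#'
#' @param img `H x W x 3` image array (or matrix).
#' @param params a [sampler_params()] object.
#' @param seed optional integer; when given, sampling runs in its own
#'   reproducible stream and the caller's RNG state is untouched.
#' @return An integer matrix with columns `row`, `col`, `side` (1-based).
#' @export
sample_subwindows <- function(img, params = sampler_params(), seed = NULL) {
  d <- dim(img)
  H <- d[1]
  W <- d[2]
  mside <- min(H, W)
  lo <- max(2L, as.integer(ceiling(params$min_frac * mside)))
  hi <- as.integer(floor(params$max_frac * mside))
  if (params$min_frac == params$max_frac) hi <- lo # degenerate fixed-size range
  if (hi < lo || lo > mside) {
    zs_stop("image too small for the requested subwindow size range",
            "zs_parameter_error")
  }
  n <- params$n_subwindows
  draw <- function() {
    side <- lo + floor(runif(n) * (hi - lo + 1L))
    side <- pmin(as.integer(side), hi)
    row <- 1L + as.integer(floor(runif(n) * (H - side + 1L)))
    col <- 1L + as.integer(floor(runif(n) * (W - side + 1L)))
    cbind(row = row, col = col, side = side)
  }
  if (is.null(seed)) draw() else with_seed(seed, draw())
}

#' Extract one subwindow as a resized patch
#'
#' Crops the square subwindow and resizes it per channel to
#' `patch_px x patch_px` by bilinear interpolation; a source window already
#' at the patch size is returned unchanged.
#'
#' @param img `H x W x 3` image array.
#' @param spec integer vector `c(row, col, side)` (1-based, fully inside
#'   the image).
#' @param patch_px patch edge in pixels.
#' @return A `patch_px x patch_px x 3` numeric array (raw intensities).
#' @export
extract_patch <- function(img, spec, patch_px = 16) {
  storage.mode(img) <- "double"
  v <- cpp_extract_patches(img, matrix(as.integer(spec[1:3]), 1L), patch_px,
                           FALSE)
  aperm(array(as.numeric(v), c(patch_px, patch_px, 3L)), c(2L, 1L, 3L))
}

#' TRGB-normalize a patch into an attribute vector
#'
#' Standardizes each channel of the patch independently — subtract the
#' channel mean, divide by the channel's population standard deviation — and
#' flattens channel-planar. A constant channel (zero standard deviation)
#' maps to all zeros.
#'
#' @param patch `edge x edge x 3` numeric array.
#' @return A numeric vector of length `3 * edge^2`.
#' @export
trgb_normalize <- function(patch) {
  edge <- dim(patch)[1]
  storage.mode(patch) <- "double"
  as.numeric(cpp_extract_patches(patch, matrix(c(1L, 1L, edge), 1L), edge,
                                 TRUE))
}

#' Batch-encode subwindows of an image as TRGB attribute vectors
#'
#' Equivalent to [extract_patch()] + [trgb_normalize()] for every row of
#' `specs`, in one compiled pass.
#'
#' @param img `H x W x 3` image array.
#' @param specs integer matrix from [sample_subwindows()].
#' @param patch_px patch edge in pixels.
#' @param normalize apply TRGB standardization (default) or keep raw
#'   intensities.
#' @return A numeric matrix with one row per subwindow and
#'   `3 * patch_px^2` columns.
#' @export
patchify <- function(img, specs, patch_px = 16, normalize = TRUE) {
  storage.mode(img) <- "double"
  specs <- matrix(as.integer(specs), ncol = 3L,
                  dimnames = list(NULL, c("row", "col", "side")))
  cpp_extract_patches(img, specs, patch_px, normalize)
}
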