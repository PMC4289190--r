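test_that("variance filter matches the windowed-variance definition", {
  # constant image: variance of constants is 0
  expect_equal(variance_filter(matrix(128, 9, 9), radius = 1),
               matrix(0, 9, 9))

  # single bright pixel: every interior value equals the brute-force
  # population variance of its 3x3 window
  g <- matrix(0, 5, 5)
  g[3, 3] <- 10
  expect_equal(variance_filter(g, radius = 1), oracle_variance_filter(g, 1),
               tolerance = 1e-10)

  # vertical step edge: maximal response in the two columns adjacent to the
  # edge, and agreement with the oracle everywhere
  g <- cbind(matrix(0, 8, 4), matrix(255, 8, 4))
  v <- variance_filter(g, radius = 1)
  expect_equal(v, oracle_variance_filter(g, 1), tolerance = 1e-8)
  interior <- v[2:7, 2:7]
  peak_cols <- which(colSums(interior) == max(colSums(interior))) + 1
  expect_setequal(peak_cols, c(4, 5))

  # border ring of width `radius` is excluded (zero)
  g2 <- matrix(runif(100, 0, 255), 10, 10)
  v2 <- variance_filter(g2, radius = 2)
  expect_true(all(v2[c(1, 2, 9, 10), ] == 0) && all(v2[, c(1, 2, 9, 10)] == 0))
  expect_equal(v2, oracle_variance_filter(g2, 2), tolerance = 1e-8)

  expect_error(variance_filter(g2, radius = 0), class = "zs_parameter_error")
})

test_that("binarization uses the Otsu optimum and handles degenerate input", {
  # bimodal extremes: mask is exactly the 255 pixels
  g <- matrix(c(rep(0, 40), rep(255, 24)), 8, 8)
  expect_identical(binarize(g), g == 255)

  # constant image: all-false mask plus a warning
  expect_warning(m <- binarize(matrix(7, 8, 8)), "constant")
  expect_false(any(m))

  # two well-separated Gaussian intensity modes: threshold between the
  # modes, agreeing with an exhaustive scan of the Otsu criterion
  set.seed(1)
  g <- matrix(c(rnorm(300, 60, 8), rnorm(212, 200, 8)), 32, 16)
  m <- binarize(g)
  th_oracle <- oracle_otsu_threshold(g)
  x <- (g - min(g)) / (max(g) - min(g))
  expect_identical(m, x > th_oracle)
  # the implied threshold separates the modes
  expect_true(all(m[g > 150]) && !any(m[g < 100]))
  # global maximum is always on
  expect_true(m[which.max(g)])
})

test_that("dilation applies a 3x3 square element and is monotone", {
  m <- matrix(FALSE, 7, 7)
  m[4, 4] <- TRUE
  d1 <- dilate_mask(m, 1)
  expect_identical(d1, {
    e <- matrix(FALSE, 7, 7)
    e[3:5, 3:5] <- TRUE
    e
  })
  expect_identical(dilate_mask(m, 0), m)

  # two pixels three apart merge after two dilatations; agreement with the
  # brute-force repeated neighborhood-max oracle
  m2 <- matrix(FALSE, 9, 9)
  m2[5, 3] <- m2[5, 6] <- TRUE
  d2 <- dilate_mask(m2, 2)
  expect_identical(d2, oracle_dilate_once(oracle_dilate_once(m2)))
  expect_equal(max(oracle_flood_fill(d2)), 1)

  # supersets: dilate(m, k) >= dilate(m, j) for k >= j on random masks
  set.seed(42)
  for (i in 1:5) {
    m3 <- matrix(runif(144) < 0.2, 12, 12)
    dj <- dilate_mask(m3, 1)
    dk <- dilate_mask(m3, 2)
    expect_true(all(m3 <= dj) && all(dj <= dk))
  }
})

test_that("largest_component picks the maximal-area 8-connected object", {
  # two rectangles of areas 20 and 80
  m <- matrix(FALSE, 30, 30)
  m[2:5, 2:6] <- TRUE # 20 px
  m[10:17, 12:21] <- TRUE # 80 px
  r <- largest_component(m)
  expect_equal(r$area, 80)
  expect_equal(r$bbox, c(10, 12, 17, 21))
  expect_equal(r$aspect_ratio, 10 / 8)

  expect_error(largest_component(matrix(FALSE, 4, 4)), class = "zs_no_object")

  # agreement with the recursive flood-fill oracle on seeded random masks
  set.seed(7)
  for (i in 1:100) {
    m <- matrix(runif(24 * 24) < 0.35, 24, 24)
    if (!any(m)) next
    got <- largest_component(m)
    want <- oracle_largest_component(m)
    expect_equal(got$area, want$area)
    expect_equal(got$bbox, want$bbox)
  }
})

test_that("square_crop follows the circular / centered-square / clip rules", {
  img <- array(runif(1000 * 1000 * 3, 0, 255), c(1000, 1000, 3))

  # already-square bbox with ratio 1: crop equals the bbox
  reg <- list(bbox = c(101, 201, 200, 300), area = 100 * 100,
              aspect_ratio = 1)
  cr <- square_crop(img, reg)
  expect_equal(attr(cr, "crop_bbox"), c(101, 201, 200, 300))
  expect_identical(unclass(cr)[, , ], img[101:200, 201:300, ])
  expect_false(attr(cr, "fallback_used"))

  # elongated 200x50 bbox centered at (500, 500): 200x200 crop, centered
  reg2 <- list(bbox = c(401, 476, 600, 525), area = 200 * 50,
               aspect_ratio = 4)
  cr2 <- square_crop(img, reg2)
  bb2 <- attr(cr2, "crop_bbox")
  expect_equal(bb2[3] - bb2[1] + 1, 200)
  expect_equal(bb2[4] - bb2[2] + 1, 200)
  expect_true(bb2[1] <= 401 && bb2[3] >= 600 && bb2[2] <= 476 && bb2[4] >= 525)

  # near the left edge: clipped rectangle narrower than 200, still
  # containing the bbox
  reg3 <- list(bbox = c(401, 16, 600, 65), area = 200 * 50, aspect_ratio = 4)
  cr3 <- square_crop(img, reg3)
  bb3 <- attr(cr3, "crop_bbox")
  expect_true(attr(cr3, "fallback_used"))
  expect_lt(bb3[4] - bb3[2] + 1, 200)
  expect_true(bb3[2] <= 16 && bb3[4] >= 65)
})

test_that("locate_and_crop finds the larva, ignores debris, flags blanks", {
  # one dark ellipse on a bright background
  img <- array(225, c(128, 128, 3))
  rr <- row(matrix(0, 128, 128))
  cc <- col(matrix(0, 128, 128))
  ell <- ((rr - 60) / 30)^2 + ((cc - 70) / 14)^2 <= 1
  for (ch in 1:3) {
    plane <- img[, , ch]
    plane[ell] <- 60
    img[, , ch] <- plane
  }
  cr <- locate_and_crop(img)
  bb <- attr(cr, "crop_bbox")
  pix <- which(ell, arr.ind = TRUE)
  inside <- pix[, 1] >= bb[1] & pix[, 1] <= bb[3] &
    pix[, 2] >= bb[2] & pix[, 2] <= bb[4]
  expect_gte(mean(inside), 0.99)

  # small debris dot must not divert the crop
  img2 <- img
  for (ch in 1:3) {
    plane <- img2[, , ch]
    plane[10:13, 110:113] <- 40
    img2[, , ch] <- plane
  }
  cr2 <- locate_and_crop(img2)
  bb2 <- attr(cr2, "crop_bbox")
  inside2 <- pix[, 1] >= bb2[1] & pix[, 1] <= bb2[3] &
    pix[, 2] >= bb2[2] & pix[, 2] <= bb2[4]
  expect_gte(mean(inside2), 0.99)

  # blank background: no object to find
  expect_error(locate_and_crop(array(225, c(64, 64, 3))),
               class = "zs_no_object")
})

test_that("locate_and_crop is idempotent in position", {
  r <- render_fish("Normal", seed = 31)
  cr1 <- locate_and_crop(r$image)
  bb1 <- attr(cr1, "crop_bbox")
  mask1 <- r$mask[bb1[1]:bb1[3], bb1[2]:bb1[4]]
  cr2 <- locate_and_crop(unclass(cr1))
  bb2 <- attr(cr2, "crop_bbox")
  pix <- which(mask1, arr.ind = TRUE)
  inside <- pix[, 1] >= bb2[1] & pix[, 1] <= bb2[3] &
    pix[, 2] >= bb2[2] & pix[, 2] <= bb2[4]
  expect_gte(mean(inside), 0.99)
})
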