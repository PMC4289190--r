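# Synthetic larva-image generator.
#
# Parametric-geometric renderer: a bright noisy background with a mild
# illumination gradient, and a single dark object whose geometry encodes
# the phenotype class — a curved-spine larva (dense discs along a
# parametric spine with a tapering width profile, yolk sac, eye) with
# class-specific modifications (tail/body curvature, shortened tail, pale
# edema sac, darkened necrotic yolk, red hemostasis spot), a dark irregular
# necrosed mass for "Dead", or a circular chorion ring enclosing a curled
# embryo for "Chorion". Ground-truth labels and object masks are exact by
# construction, which is what makes every downstream stage (cropping,
# training, two-tier evaluation, dose-response) testable without real data.

# classes the renderer can draw ("Up Curved Tail/Fish" is a derived union
# term, never rendered on its own)
renderable_classes <- function() {
  setdiff(phenotype_vocabulary(), "Up Curved Tail/Fish")
}

# label set implied by a rendered class (fills the union term)
class_label_set <- function(class) {
  switch(class,
    "Up Curved Tail" = c("Up Curved Tail", "Up Curved Tail/Fish"),
    "Up Curved Fish" = c("Up Curved Fish", "Up Curved Tail/Fish"),
    class
  )
}

# -- low-level painters on an integer region-code matrix ---------------------

paint_disc <- function(lab, cy, cx, r, code) {
  H <- nrow(lab)
  W <- ncol(lab)
  r0 <- max(1L, floor(cy - r))
  r1 <- min(H, ceiling(cy + r))
  c0 <- max(1L, floor(cx - r))
  c1 <- min(W, ceiling(cx + r))
  if (r0 > r1 || c0 > c1) return(lab)
  d2 <- outer((r0:r1 - cy)^2, (c0:c1 - cx)^2, "+")
  sub <- lab[r0:r1, c0:c1]
  sub[d2 <= r^2] <- code
  lab[r0:r1, c0:c1] <- sub
  lab
}

paint_ellipse <- function(lab, cy, cx, ry, rx, code) {
  H <- nrow(lab)
  W <- ncol(lab)
  r0 <- max(1L, floor(cy - ry))
  r1 <- min(H, ceiling(cy + ry))
  c0 <- max(1L, floor(cx - rx))
  c1 <- min(W, ceiling(cx + rx))
  d2 <- outer(((r0:r1 - cy) / ry)^2, ((c0:c1 - cx) / rx)^2, "+")
  sub <- lab[r0:r1, c0:c1]
  sub[d2 <= 1] <- code
  lab[r0:r1, c0:c1] <- sub
  lab
}

paint_ring <- function(lab, cy, cx, r_in, r_out, code) {
  H <- nrow(lab)
  W <- ncol(lab)
  r0 <- max(1L, floor(cy - r_out))
  r1 <- min(H, ceiling(cy + r_out))
  c0 <- max(1L, floor(cx - r_out))
  c1 <- min(W, ceiling(cx + r_out))
  d2 <- outer((r0:r1 - cy)^2, (c0:c1 - cx)^2, "+")
  sub <- lab[r0:r1, c0:c1]
  sub[d2 <= r_out^2 & d2 >= r_in^2] <- code
  lab[r0:r1, c0:c1] <- sub
  lab
}

# region codes -> mean RGB color and texture noise sd
ZS_REGION_STYLES <- list(
  body      = list(code = 1L, rgb = c(100, 92, 84), sd = 6),
  yolk      = list(code = 2L, rgb = c(82, 75, 68), sd = 5),
  eye       = list(code = 3L, rgb = c(30, 30, 32), sd = 2),
  edema     = list(code = 4L, rgb = c(206, 206, 210), sd = 3),
  blood     = list(code = 5L, rgb = c(158, 38, 38), sd = 6),
  ring      = list(code = 6L, rgb = c(108, 102, 96), sd = 4),
  inner_bg  = list(code = 7L, rgb = c(212, 210, 205), sd = 3),
  embryo    = list(code = 8L, rgb = c(95, 88, 80), sd = 6),
  debris    = list(code = 9L, rgb = c(70, 65, 60), sd = 4),
  dead_mass = list(code = 10L, rgb = c(52, 46, 40), sd = 13),
  necrosed  = list(code = 11L, rgb = c(36, 32, 28), sd = 11),
  edema_rim = list(code = 12L, rgb = c(138, 138, 142), sd = 4)
)

# codes belonging to the larva/chorion object (ground-truth mask);
# the inner chorion background and debris are not object pixels
ZS_OBJECT_CODES <- c(1L, 2L, 3L, 4L, 5L, 6L, 8L, 10L, 11L, 12L)

#' Render one synthetic larva image with ground truth
#'
#' @param class one of the renderable phenotype classes (all vocabulary
#'   terms except the derived "Up Curved Tail/Fish").
#' @param canvas square canvas edge in pixels (>= 128; geometry scales with
#'   it).
#' @param noise_sd Gaussian background/texture noise standard deviation in
#'   intensity units.
#' @param seed integer seed; identical seeds give identical images.
#' @param offset optional `c(row, col)` displacement of the object from the
#'   canvas center (default: a small random jitter), e.g. to construct
#'   near-border cases.
#' @param distractor also draw a small dark debris dot (not part of the
#'   ground-truth object)?
#' @return A list with `image` (`canvas x canvas x 3`, intensities 0-255),
#'   `labels` (ground-truth label set), `mask` (logical matrix of
#'   ground-truth object pixels) and `class`.
#' @export
render_fish <- function(class = "Normal", canvas = 256, noise_sd = 8,
                        seed = 1L, offset = NULL, distractor = FALSE) {
  if (canvas < 128) zs_stop("canvas must be >= 128 pixels", "zs_parameter_error")
  if (!class %in% renderable_classes()) {
    zs_stop(paste0("not a renderable class: ", class), "zs_parameter_error")
  }
  s <- canvas / 256
  with_seed(seed, {
    lab <- matrix(0L, canvas, canvas)
    if (is.null(offset)) {
      offset <- round(runif(2, -16, 16) * s)
    }
    oy <- offset[1]
    ox <- offset[2]

    if (class == "Dead") {
      cy <- canvas / 2 + oy
      cx <- canvas / 2 + ox
      for (i in seq_len(10)) {
        lab <- paint_disc(lab, cy + rnorm(1, 0, 14 * s),
                          cx + rnorm(1, 0, 14 * s),
                          runif(1, 12, 24) * s, 10L)
      }
    } else if (class == "Chorion") {
      cy <- canvas / 2 + oy
      cx <- canvas / 2 + ox
      R <- 62 * s
      lab <- paint_disc(lab, cy, cx, R - 5 * s, 7L)
      lab <- paint_ring(lab, cy, cx, R - 5 * s, R, 6L)
      theta <- seq(0.2 * pi, 2.1 * pi, length.out = 90)
      rad <- seq(34, 8, length.out = 90) * s
      wd <- seq(7, 3.5, length.out = 90) * s
      for (i in seq_along(theta)) {
        lab <- paint_disc(lab, cy + rad[i] * sin(theta[i]),
                          cx + rad[i] * cos(theta[i]), wd[i], 8L)
      }
    } else {
      L <- (if (class == "Short Tail") 88 else 150) * s
      hx <- 78 * s + ox
      hy <- 128 * s + oy
      t <- seq(0, 1, length.out = 160)
      dy <- switch(class,
        "Down Curved Tail" = 65 * pmax(0, (t - 0.55) / 0.45)^2,
        "Up Curved Tail" = -65 * pmax(0, (t - 0.55) / 0.45)^2,
        "Up Curved Fish" = 42 * sin(pi * t),
        6 * sin(pi * t)
      ) * s
      xs <- hx + t * L
      ys <- hy + dy
      wt <- (13 * (1 - t)^0.85 + 2.5) * s

      if (class == "Edema") {
        ey <- ys[round(0.18 * 159) + 1] + 20 * s
        ex <- xs[round(0.18 * 159) + 1] + 2 * s
        lab <- paint_ellipse(lab, ey, ex, 15 * s + 3 * s, 21 * s + 3 * s, 12L)
        lab <- paint_ellipse(lab, ey, ex, 15 * s, 21 * s, 4L)
      }
      for (i in seq_along(t)) {
        lab <- paint_disc(lab, ys[i], xs[i], wt[i], 1L)
      }
      yolk_code <- if (class == "Necrosed Yolk Sac") 11L else 2L
      yolk_scale <- if (class == "Necrosed Yolk Sac") 1.2 else 1
      i0 <- round(0.16 * 159) + 1
      lab <- paint_ellipse(lab, ys[i0] + 9 * s, xs[i0],
                           10 * s * yolk_scale, 13 * s * yolk_scale,
                           yolk_code)
      if (class == "Hemostasis") {
        # blood accumulations can sit anywhere along the embryo (mainly the
        # head/pericardial area): one pericardial spot plus 1-3 more along
        # the body
        i1 <- round(0.22 * 159) + 1
        lab <- paint_disc(lab, ys[i1] + 6 * s, xs[i1] + 6 * s, 10 * s, 5L)
        for (k in seq_len(sample(1:3, 1))) {
          ik <- sample(10:120, 1)
          lab <- paint_disc(lab, ys[ik] + runif(1, -4, 4) * s, xs[ik],
                            runif(1, 6, 9) * s, 5L)
        }
      }
      lab <- paint_disc(lab, ys[4] - 5 * s, xs[4] + 2 * s, 3.2 * s, 3L)
    }

    if (distractor) {
      lab <- paint_disc(lab, runif(1, 0.05, 0.2) * canvas,
                        runif(1, 0.7, 0.95) * canvas, 4 * s, 9L)
    }

    # assemble intensities: warm bright background + illumination gradient,
    # then region colors with their texture, then global noise
    img <- array(0, c(canvas, canvas, 3))
    base <- c(228, 226, 220)
    grad <- outer(seq(-4, 4, length.out = canvas),
                  seq(-6, 6, length.out = canvas), "+")
    for (ch in 1:3) img[, , ch] <- base[ch] + grad
    for (style in ZS_REGION_STYLES) {
      idx <- which(lab == style$code)
      if (!length(idx)) next
      for (ch in 1:3) {
        plane <- img[, , ch]
        plane[idx] <- style$rgb[ch] + rnorm(length(idx), 0, style$sd)
        img[, , ch] <- plane
      }
    }
    if (noise_sd > 0) {
      img <- img + rnorm(length(img), 0, noise_sd)
    }
    img <- round(pmin(pmax(img, 0), 255))

    list(image = img, labels = class_label_set(class),
         mask = matrix(lab %in% ZS_OBJECT_CODES, canvas, canvas),
         class = class)
  })
}

#' Generate a labeled synthetic classification dataset
#'
#' Renders `n_per_class` images per class and assembles the manifest
#' (honoring the vocabulary invariants: Dead/Chorion exclusivity, the
#' "Up Curved Tail/Fish" union filled in automatically). With `dir` given,
#' PNG files and a `manifest.csv` are written; the images and manifest are
#' returned either way.
#'
#' @param n_per_class images per class.
#' @param classes classes to render (default all renderable classes).
#' @param canvas,noise_sd renderer settings, see [render_fish()].
#' @param seed integer base seed; each image derives its own stream, so the
#'   output (including the manifest) is byte-identical across runs.
#' @param dir optional output directory.
#' @return Invisibly, a list with `images` (named list of arrays) and
#'   `manifest` (data frame: `filename`, `labels`, `session`, `split`).
#' @export
generate_classification_set <- function(n_per_class, classes = renderable_classes(),
                                        canvas = 256, noise_sd = 8, seed = 1L,
                                        dir = NULL) {
  if (n_per_class < 1) zs_stop("n_per_class must be >= 1", "zs_parameter_error")
  bad <- setdiff(classes, renderable_classes())
  if (length(bad)) {
    zs_stop(paste0("unknown or non-renderable class: ", paste(bad, collapse = ", ")),
            "zs_parameter_error")
  }
  images <- list()
  rows <- list()
  for (class in classes) {
    slug <- gsub("[ /]", "_", tolower(class))
    for (j in seq_len(n_per_class)) {
      r <- render_fish(class, canvas = canvas, noise_sd = noise_sd,
                       seed = derive_seed(seed, paste0(class, "#", j)))
      fn <- sprintf("%s_%03d.png", slug, j)
      images[[fn]] <- r$image
      rows[[fn]] <- data.frame(filename = fn,
                               labels = paste(r$labels, collapse = ";"),
                               session = ((j - 1L) %% 5L) + 1L,
                               split = "LS", stringsAsFactors = FALSE)
    }
  }
  manifest <- do.call(rbind, rows)
  rownames(manifest) <- NULL
  assert_label_sets(parse_labels(manifest$labels))
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    for (fn in names(images)) write_rgb_image(images[[fn]], file.path(dir, fn))
    write_manifest(manifest, file.path(dir, "manifest.csv"))
  }
  invisible(list(images = images, manifest = manifest))
}

#' Specification of a synthetic toxicology plate
#'
#' The generating curves are log-logistic in dose: mortality with midpoint
#' `10^log10_lc50` and Hill slope `hill_survival`; probability of any
#' defect among survivors with midpoint `10^log10_ec50` and slope
#' `hill_terato`. Defaults emulate a caffeine-like compound (LC50 6.6 mM,
#' EC50 0.13 mM) screened at 25 embryos per condition over log-spaced doses
#' bracketing both midpoints.
#'
#' @param compound compound name (bookkeeping only).
#' @param concentrations dose levels (>= 4, including the untreated 0).
#' @param n_per_conc embryos per concentration (>= 5).
#' @param log10_lc50,log10_ec50 generating midpoints (log10 concentration).
#' @param hill_survival,hill_terato generating Hill slopes.
#' @param seed integer seed.
#' @return A list of class `plate_spec`.
#' @export
plate_spec <- function(compound = "caffeine-like",
                       concentrations = c(0, 0.04, 0.2, 1, 5, 25),
                       n_per_conc = 25,
                       log10_lc50 = log10(6.6), log10_ec50 = log10(0.13),
                       hill_survival = 2, hill_terato = 1.5, seed = 1L) {
  if (length(concentrations) < 4 || !any(concentrations == 0)) {
    zs_stop("need >= 4 concentrations including an untreated control (0)",
            "zs_parameter_error")
  }
  if (n_per_conc < 5) zs_stop("n_per_conc must be >= 5", "zs_parameter_error")
  structure(list(compound = compound,
                 concentrations = sort(unique(concentrations)),
                 n_per_conc = as.integer(n_per_conc),
                 log10_lc50 = log10_lc50, log10_ec50 = log10_ec50,
                 hill_survival = hill_survival, hill_terato = hill_terato,
                 seed = as.integer(seed)),
            class = "plate_spec")
}

# log-logistic event probability at dose d (0 at the untreated control)
loglogistic_prob <- function(d, log10_mid, hill) {
  ifelse(d > 0, 1 / (1 + 10^(hill * (log10_mid - log10(d)))), 0)
}

#' Simulate the true phenotype outcomes of a plate
#'
#' Each embryo dies with the mortality-curve probability at its dose;
#' survivors are abnormal with the teratogenicity-curve probability, the
#' defect drawn uniformly from the non-lethal classes, and Normal
#' otherwise.
#'
#' @param spec a [plate_spec()].
#' @return A data frame with one embryo per row: `embryo`, `concentration`,
#'   `class`, `labels`; the generating spec is attached as attribute
#'   `truth`.
#' @export
simulate_plate_labels <- function(spec) {
  stopifnot(inherits(spec, "plate_spec"))
  defects <- setdiff(renderable_classes(), c("Normal", "Dead"))
  with_seed(spec$seed, {
    rows <- list()
    k <- 0L
    for (d in spec$concentrations) {
      p_dead <- loglogistic_prob(d, spec$log10_lc50, spec$hill_survival)
      p_ab <- loglogistic_prob(d, spec$log10_ec50, spec$hill_terato)
      for (i in seq_len(spec$n_per_conc)) {
        k <- k + 1L
        class <- if (runif(1) < p_dead) {
          "Dead"
        } else if (runif(1) < p_ab) {
          sample(defects, 1)
        } else {
          "Normal"
        }
        rows[[k]] <- data.frame(
          embryo = k, concentration = d, class = class,
          labels = paste(class_label_set(class), collapse = ";"),
          stringsAsFactors = FALSE
        )
      }
    }
    out <- do.call(rbind, rows)
    attr(out, "truth") <- spec
    out
  })
}

#' Generate a full synthetic plate: images plus truth manifest
#'
#' Simulates the per-embryo outcomes with [simulate_plate_labels()] and
#' renders one image per embryo. With `dir` given, PNGs and a
#' `manifest.csv` (with `compound` and `concentration` columns) are
#' written.
#'
#' @param spec a [plate_spec()].
#' @param canvas,noise_sd renderer settings.
#' @param dir optional output directory.
#' @return Invisibly, a list with `images`, `manifest` and `truth`
#'   (the spec).
#' @export
generate_plate <- function(spec, canvas = 256, noise_sd = 8, dir = NULL) {
  labs <- simulate_plate_labels(spec)
  images <- list()
  fns <- sprintf("embryo_%04d.png", labs$embryo)
  for (i in seq_len(nrow(labs))) {
    r <- render_fish(labs$class[i], canvas = canvas, noise_sd = noise_sd,
                     seed = derive_seed(spec$seed, paste0("img", labs$embryo[i])))
    images[[fns[i]]] <- r$image
  }
  manifest <- data.frame(filename = fns, labels = labs$labels,
                         session = 1L, split = "TS",
                         compound = spec$compound,
                         concentration = labs$concentration,
                         stringsAsFactors = FALSE)
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    for (fn in names(images)) write_rgb_image(images[[fn]], file.path(dir, fn))
    write_manifest(manifest, file.path(dir, "manifest.csv"))
  }
  invisible(list(images = images, manifest = manifest, truth = spec))
}
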