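# Seeded generator of sperm-like microscope images.
#
# Two labeling schemes mirror the public benchmark layouts:
#   smids3  — abnormal_sperm / non_sperm / normal_sperm
#   hushem4 — amorphous / normal / pyriform / tapered (head-shape classes)
# Class names are kept in lexicographic order so that a folder round-trip
# through read_image_folder() reproduces label ids exactly.
#
# Every image is one bright head(+tail) object on a noisy, mildly
# illumination-graded background, rendered grayscale and replicated to three
# channels (stained micrographs are effectively monochrome in structure).

SCHEME_CLASSES <- list(
  smids3  = c("abnormal_sperm", "non_sperm", "normal_sperm"),
  hushem4 = c("amorphous", "normal", "pyriform", "tapered")
)

#' Specification of a synthetic labeled image set
#'
#' @param scheme `"smids3"` (3 classes) or `"hushem4"` (4 head-shape classes).
#' @param n_per_class images per class (>= 1).
#' @param image_size square side in pixels (>= 32). Default 128.
#' @param noise_sd background noise standard deviation in intensity units
#'   (dynamic range is 1). Default 0.05.
#' @param deform_strength strength of class-specific head deformation in
#'   `[0, 1]`. Default 0.5.
#' @param seed integer seed; identical specs yield bit-identical datasets.
#' @return an object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(scheme = c("smids3", "hushem4"), n_per_class,
                           image_size = 128, noise_sd = 0.05,
                           deform_strength = 0.5, seed = 1) {
  scheme <- match.arg(scheme)
  stopifnot(n_per_class >= 1, image_size >= 32, noise_sd >= 0,
            deform_strength >= 0, deform_strength <= 1)
  structure(list(scheme = scheme, n_per_class = as.integer(n_per_class),
                 image_size = as.integer(image_size), noise_sd = noise_sd,
                 deform_strength = deform_strength, seed = as.integer(seed)),
            class = "synthetic_spec")
}

# ---- drawing primitives (all vectorized over the pixel grid) ----

# soft-edged filled ellipse; returns an H x W coverage mask in [0, 1]
soft_ellipse <- function(xx, yy, cx, cy, a, b, phi, edge_px, size) {
  xr <- (xx - cx) * cos(phi) + (yy - cy) * sin(phi)
  yr <- -(xx - cx) * sin(phi) + (yy - cy) * cos(phi)
  r <- sqrt((xr / a)^2 + (yr / b)^2)
  edge <- edge_px / (size * min(a, b))
  1 / (1 + exp((r - 1) / edge))
}

# blob bounded by a periodic random-walk radius r(theta); pear/debris shapes
soft_blob <- function(xx, yy, cx, cy, r0, amp, n_knots, edge_px, size) {
  steps <- stats::rnorm(n_knots)
  walk <- cumsum(steps)
  walk <- walk - seq(walk[1], walk[n_knots], length.out = n_knots)  # periodic
  walk <- walk / max(abs(walk), 1e-8)
  th_k <- seq(0, 2 * pi, length.out = n_knots)
  theta <- atan2(yy - cy, xx - cx) + pi
  rad <- stats::approx(th_k, r0 * (1 + amp * walk), xout = theta,
                       rule = 2)$y
  rad <- matrix(rad, nrow = nrow(xx))
  d <- sqrt((xx - cx)^2 + (yy - cy)^2)
  edge <- edge_px / size
  1 / (1 + exp((d - rad) / edge))
}

# quadratic Bezier tail stroke with tapering width
soft_tail <- function(xx, yy, p0, p1, p2, w0, edge_px, size, n = 60) {
  dmin <- matrix(Inf, nrow(xx), ncol(xx))
  for (t in seq(0, 1, length.out = n)) {
    px <- (1 - t)^2 * p0[1] + 2 * (1 - t) * t * p1[1] + t^2 * p2[1]
    py <- (1 - t)^2 * p0[2] + 2 * (1 - t) * t * p1[2] + t^2 * p2[2]
    w <- w0 * (1 - 0.7 * t)
    d <- sqrt((xx - px)^2 + (yy - py)^2) - w
    dmin <- pmin(dmin, d)
  }
  edge <- edge_px / size
  1 / (1 + exp(dmin / edge))
}

# ---- per-class rendering ----

#' Render one synthetic cell image
#'
#' Draws one bright object (head, optionally with tail) on a noisy
#' background. Head geometry is class-specific: ovals for normal heads,
#' elongated ellipses for tapered, fused unequal ellipses for pyriform,
#' random-walk polygons for amorphous, offset doubled ellipses for
#' abnormal sperm, and tail-less blobs for non-sperm debris.
#'
#' @param class_id 1-based class index within the scheme.
#' @param scheme `"smids3"` or `"hushem4"`.
#' @param size square image side in pixels.
#' @param deform_strength deformation strength in `[0, 1]`.
#' @param seed integer seed (bit-identical output for identical calls).
#' @param noise_sd background noise sd (default 0.05).
#' @return an `size x size x 3` array in `[0, 1]`.
#' @export
render_cell <- function(class_id, scheme = c("smids3", "hushem4"), size = 128,
                        deform_strength = 0.5, seed = 1, noise_sd = 0.05) {
  scheme <- match.arg(scheme)
  classes <- SCHEME_CLASSES[[scheme]]
  if (!(class_id %in% seq_along(classes))) {
    stop(sprintf("unknown class_id %s for scheme '%s'; valid classes: %s",
                 class_id, scheme,
                 paste(sprintf("%d=%s", seq_along(classes), classes),
                       collapse = ", ")), call. = FALSE)
  }
  cls <- classes[class_id]
  with_seed(seed, render_cell_impl(cls, size, deform_strength, noise_sd))
}

render_cell_impl <- function(cls, size, ds, noise_sd) {
  xx <- matrix(rep(seq(0, 1, length.out = size), each = size), size, size)
  yy <- matrix(rep(seq(0, 1, length.out = size), times = size), size, size)

  # background: low-intensity Gaussian noise plus a mild illumination ramp
  psi <- stats::runif(1, 0, 2 * pi)
  bg <- 0.12 + matrix(stats::rnorm(size^2, 0, noise_sd), size, size) +
    0.06 * ((xx - 0.5) * cos(psi) + (yy - 0.5) * sin(psi))

  cx <- 0.5 + stats::runif(1, -0.06, 0.06)
  cy <- 0.5 + stats::runif(1, -0.06, 0.06)
  # bounded orientation jitter around a canonical axis: the emulated
  # benchmark crops are orientation-normalized (heads aligned), so the
  # generator reproduces aligned heads with moderate residual rotation
  phi <- pi / 2 + stats::runif(1, -0.45, 0.45)
  a0 <- 0.16 * stats::runif(1, 0.9, 1.1)   # base head semi-major axis
  edge <- 1.0                               # edge softness in pixels

  mask <- matrix(0, size, size)
  add <- function(m) mask <<- pmax(mask, m)

  tail_from <- function(ax) {
    # tail leaves the head rear (along -major axis) as a curved stroke
    rear <- c(cx - ax * cos(phi), cy - ax * sin(phi))
    len <- stats::runif(1, 0.28, 0.38)
    bend <- stats::runif(1, -0.12, 0.12)
    mid <- c(rear[1] - 0.5 * len * cos(phi) - bend * sin(phi),
             rear[2] - 0.5 * len * sin(phi) + bend * cos(phi))
    end <- c(rear[1] - len * cos(phi), rear[2] - len * sin(phi))
    soft_tail(xx, yy, rear, mid, end, w0 = 0.012, edge_px = edge, size = size)
  }

  if (cls == "normal" || cls == "normal_sperm") {
    b0 <- a0 / 1.5
    add(soft_ellipse(xx, yy, cx, cy, a0, b0, phi, edge, size))
    add(0.85 * tail_from(0.8 * a0))
  } else if (cls == "tapered") {
    ratio <- 2.5 + 1.2 * ds
    b0 <- a0 / ratio
    add(soft_ellipse(xx, yy, cx, cy, a0 * 1.1, b0, phi, edge, size))
    add(0.85 * tail_from(0.9 * a0))
  } else if (cls == "pyriform") {
    # pear: large ellipse fused with a smaller circle at the head tip
    b0 <- a0 / 1.6
    add(soft_ellipse(xx, yy, cx, cy, a0, b0, phi, edge, size))
    tip <- c(cx + (0.85 + 0.4 * ds) * a0 * cos(phi),
             cy + (0.85 + 0.4 * ds) * a0 * sin(phi))
    r_small <- b0 * (0.55 - 0.2 * ds)
    add(soft_ellipse(xx, yy, tip[1], tip[2], r_small, r_small, 0, edge, size))
    add(0.85 * tail_from(0.8 * a0))
  } else if (cls == "amorphous") {
    add(soft_blob(xx, yy, cx, cy, r0 = 0.8 * a0, amp = 0.25 + 0.5 * ds,
                  n_knots = 14, edge_px = edge, size = size))
    add(0.85 * tail_from(0.7 * a0))
  } else if (cls == "abnormal_sperm") {
    # eccentric doubled head: distorted main ellipse + offset ghost ellipse
    ratio <- 1.5 + 1.2 * ds * sample(c(-0.6, 1), 1)
    ratio <- max(1.05, ratio)
    b0 <- a0 / ratio
    add(soft_ellipse(xx, yy, cx, cy, a0, b0, phi, edge, size))
    off <- (0.35 + 0.45 * ds) * a0
    ang <- phi + stats::runif(1, -0.9, 0.9)
    # the secondary lobe is part of the same uniformly stained head
    add(soft_ellipse(xx, yy, cx + off * cos(ang), cy + off * sin(ang),
                     0.7 * a0, 0.7 * b0, phi, edge, size))
    add(0.85 * tail_from(0.8 * a0))
  } else if (cls == "non_sperm") {
    # tail-less debris blob, occasionally with a detached speck
    add(soft_blob(xx, yy, cx, cy, r0 = 0.9 * a0, amp = 0.15 + 0.35 * ds,
                  n_knots = 10, edge_px = edge, size = size))
    if (stats::runif(1) < 0.5) {
      sx <- cx + stats::runif(1, -0.25, 0.25)
      sy <- cy + stats::runif(1, -0.25, 0.25)
      add(0.7 * soft_ellipse(xx, yy, sx, sy, 0.03, 0.03, 0, edge, size))
    }
  } else {
    stop("unhandled class: ", cls)
  }

  fg <- stats::runif(1, 0.8, 0.92)
  img <- bg * (1 - mask) + fg * mask
  img <- pmin(pmax(img, 0), 1)
  array(img, dim = c(size, size, 3))
}

#' Generate a labeled synthetic dataset
#'
#' Renders `n_per_class` images per class and shuffles them with the spec
#' seed. The result is balanced exactly and bit-identical for identical
#' specs.
#'
#' @param spec a [synthetic_spec()].
#' @return a `labeled_image_set`: list with `images` (list of H x W x 3
#'   arrays), `labels` (1-based integer vector), `class_names`.
#' @export
generate_dataset <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  classes <- SCHEME_CLASSES[[spec$scheme]]
  images <- list()
  labels <- integer(0)
  for (ci in seq_along(classes)) {
    for (i in seq_len(spec$n_per_class)) {
      s <- derive_seed(spec$seed, "render", ci, i)
      images[[length(images) + 1L]] <-
        render_cell(ci, spec$scheme, spec$image_size, spec$deform_strength,
                    seed = s, noise_sd = spec$noise_sd)
      labels <- c(labels, ci)
    }
  }
  ord <- with_seed(derive_seed(spec$seed, "shuffle"), sample(length(images)))
  structure(list(images = images[ord], labels = labels[ord],
                 class_names = classes),
            class = "labeled_image_set")
}

#' @export
print.labeled_image_set <- function(x, ...) {
  cat(sprintf("labeled_image_set: %d images, %d classes (%s)\n",
              length(x$images), length(x$class_names),
              paste(x$class_names, collapse = ", ")))
  print(table(factor(x$labels, levels = seq_along(x$class_names),
                     labels = x$class_names)))
  invisible(x)
}

#' Write a labeled image set as a folder-per-class PNG tree
#'
#' Layout is `path/<class_name>/<class>_<i>.png` with a `manifest.json`
#' at the root listing file, class and label for every image. An empty set
#' produces an empty manifest and no class directories.
#'
#' @param set a `labeled_image_set`.
#' @param path output directory (created if needed).
#' @return the manifest as a data.frame, invisibly.
#' @export
write_image_folder <- function(set, path) {
  stopifnot(inherits(set, "labeled_image_set"))
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(path)) stop("cannot create directory: ", path, call. = FALSE)
  n <- length(set$images)
  files <- character(n); cls <- character(n)
  counter <- integer(length(set$class_names))
  for (i in seq_len(n)) {
    lab <- set$labels[i]
    cname <- set$class_names[lab]
    counter[lab] <- counter[lab] + 1L
    dir.create(file.path(path, cname), showWarnings = FALSE)
    f <- file.path(cname, sprintf("%s_%04d.png", cname, counter[lab]))
    png::writePNG(set$images[[i]], file.path(path, f))
    files[i] <- f; cls[i] <- cname
  }
  manifest <- data.frame(file = files, class = cls, label = set$labels,
                         stringsAsFactors = FALSE)
  jsonlite::write_json(list(class_names = set$class_names, files = manifest),
                       file.path(path, "manifest.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(manifest)
}
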