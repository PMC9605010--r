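# Synthetic scalp microscopy simulator.
#
# Generates 640x480 trichoscopy-like images: a mottled skin-tone
# background, one darkened soft-edged disk per hair follicle, and dark
# anti-aliased hair strokes (slightly curved quadratic arcs) emanating from
# each follicle center. Every image ships with exact ground truth, so the
# detector, the feature extractor and the severity pipeline are all
# testable without clinical data.
#
# Class bands (radius px / hair count / thickness px):
#   severe  r in [4, 10],  count 1,      thickness in [1, 3]
#   normal  r in (10, 20), count 1,      thickness in (3, 6)
#   healthy r in (20, 32], count 2 or 3, thickness in (6, 10]

.sim_bands <- list(
  severe = list(r = c(4, 10), count = 1L, thickness = c(1, 3)),
  normal = list(r = c(10, 20), count = 1L, thickness = c(3, 6)),
  healthy = list(r = c(20, 32), count = c(2L, 3L), thickness = c(6, 10))
)

# Interior margin (px) kept from band edges shared with the adjacent class
# under strict sampling, so that the generating class is recoverable from
# measurements with sub-pixel error.
.band_margin <- 0.3

#' Simulator configuration
#'
#' Defaults emulate the study regime: 640 x 480 px images, 10–45 follicles
#' per image, class mixture proportional to the labeled-dataset totals
#' (severe 3836 : normal 11,262 : healthy 8914).
#'
#' @param image_size `(width, height)` in pixels.
#' @param follicles_per_image inclusive integer range for the per-image
#'   follicle count.
#' @param class_mixture probabilities for severe, normal, healthy (any
#'   positive weights; normalized to sum to 1).
#' @param skin_tone background RGB in `[0, 1]`.
#' @param mottle_amp low-frequency multiplicative mottle amplitude
#'   (fraction of tone).
#' @param mottle_scale mottle correlation length in pixels.
#' @param strict_bands if TRUE, follicle attributes are sampled strictly
#'   inside their class band, keeping a small interior margin from edges
#'   shared with the neighboring class.
#' @param overlap_factor minimum center distance between two follicles as a
#'   multiple of the larger of their radii; the default 2.5 yields
#'   non-overlapping follicles with well-separated hair strands.
#' @param seed base RNG seed for dataset generation.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(image_size = c(640, 480),
                       follicles_per_image = c(10, 45),
                       class_mixture = c(severe = 3836, normal = 11262,
                                         healthy = 8914),
                       skin_tone = c(210, 180, 160) / 255,
                       mottle_amp = 0.10,
                       mottle_scale = 40,
                       strict_bands = TRUE,
                       overlap_factor = 2.5,
                       seed = 1L) {
  mix <- as.numeric(class_mixture)
  if (length(mix) != 3 || any(mix < 0) || sum(mix) <= 0) {
    stop("class_mixture needs three non-negative weights")
  }
  names(mix) <- c("severe", "normal", "healthy")
  if (follicles_per_image[1] > follicles_per_image[2] || follicles_per_image[1] < 0) {
    stop("follicles_per_image must be a non-degenerate non-negative range")
  }
  structure(
    list(
      image_size = as.integer(image_size),
      follicles_per_image = as.integer(follicles_per_image),
      class_mixture = mix / sum(mix),
      skin_tone = skin_tone,
      mottle_amp = mottle_amp,
      mottle_scale = mottle_scale,
      strict_bands = isTRUE(strict_bands),
      overlap_factor = overlap_factor,
      seed = as.integer(seed)
    ),
    class = "sim_config"
  )
}

# Sampling range for one attribute: under strict bands, pull in by the
# interior margin at edges shared with the adjacent class.
.band_range <- function(label, what, strict) {
  b <- .sim_bands[[label]][[what]]
  if (!strict) return(b)
  m <- .band_margin
  switch(paste(label, what),
    "severe r" = c(b[1], b[2] - m),
    "normal r" = c(b[1] + m, b[2] - m),
    "healthy r" = c(b[1] + m, b[2]),
    "severe thickness" = c(b[1], b[2] - m),
    "normal thickness" = c(b[1] + m, b[2] - m),
    "healthy thickness" = c(b[1] + m, b[2]),
    b
  )
}

#' Sample follicle attributes for a class
#'
#' Draws radius, hair count, hair thickness, hair angles (separated by at
#' least 50 degrees), per-hair lengths (1.15–1.4 r, so every strand crosses
#' the follicle boundary) and a small stroke curvature. With strict bands
#' the attributes always satisfy the class's criteria.
#'
#' @param labels character vector of classes to sample (one follicle each).
#' @param config a [sim_config()].
#' @param seed RNG seed.
#' @return tibble with one row per follicle: `label`, `r`, `hair_count`,
#'   `hair_thickness`, and list-columns `angles`, `lengths`, `curvatures`.
#' @export
sample_follicles <- function(labels, config = sim_config(), seed = 1L) {
  stopifnot(all(labels %in% class_levels()))
  with_seed(seed, {
    purrr::map_dfr(labels, function(lab) {
      rr <- .band_range(lab, "r", config$strict_bands)
      tt <- .band_range(lab, "thickness", config$strict_bands)
      cnt <- .sim_bands[[lab]]$count
      count <- if (length(cnt) > 1) sample(cnt[1]:cnt[2], 1) else cnt
      # hair directions separated by >= 50 degrees
      min_sep <- 50 * pi / 180
      ang <- stats::runif(1, 0, 2 * pi)
      while (length(ang) < count) {
        cand <- stats::runif(1, 0, 2 * pi)
        d <- abs(((cand - ang + pi) %% (2 * pi)) - pi)
        if (all(d >= min_sep)) ang <- c(ang, cand)
      }
      r <- stats::runif(1, rr[1], rr[2])
      tibble::tibble(
        label = lab,
        r = r,
        hair_count = as.integer(count),
        hair_thickness = stats::runif(1, tt[1], tt[2]),
        angles = list(ang),
        lengths = list(stats::runif(count, 1.15, 1.4) * r),
        curvatures = list(stats::runif(count, -0.12, 0.12))
      )
    })
  })
}

#' @rdname sample_follicles
#' @param label single class label.
#' @export
sample_follicle <- function(label, config = sim_config(), seed = 1L) {
  sample_follicles(label, config, seed)
}

# Dart-throwing placement, largest follicles first. Returns the follicle
# tibble with cx/cy columns, or NULL if placement failed.
place_follicles <- function(follicles, config, max_tries = 300L) {
  w <- config$image_size[1]; h <- config$image_size[2]
  ord <- order(-follicles$r)
  follicles <- follicles[ord, , drop = FALSE]
  n <- nrow(follicles)
  cx <- numeric(n); cy <- numeric(n)
  for (i in seq_len(n)) {
    r <- follicles$r[i]
    if (2 * (r + 2) >= min(w, h)) return(NULL)
    ok <- FALSE
    for (try in seq_len(max_tries)) {
      x <- stats::runif(1, r + 2, w - r - 2)
      y <- stats::runif(1, r + 2, h - r - 2)
      if (i == 1) { ok <- TRUE } else {
        prev <- seq_len(i - 1)
        mind <- config$overlap_factor * pmax(r, follicles$r[prev])
        ok <- all((x - cx[prev])^2 + (y - cy[prev])^2 >= mind^2)
      }
      if (ok) { cx[i] <- x; cy[i] <- y; break }
    }
    if (!ok) return(NULL)
  }
  follicles$cx <- cx
  follicles$cy <- cy
  follicles
}

# Low-frequency multiplicative mottle field (H x W), mean ~1.
.mottle_field <- function(h, w, amp, scale) {
  gh <- max(2L, ceiling(h / scale) + 1L)
  gw <- max(2L, ceiling(w / scale) + 1L)
  coarse <- matrix(stats::runif(gh * gw, -amp, amp), gh, gw)
  fine <- .from_eb(EBImage::resize(.as_eb(coarse - min(coarse)),
                                   w = w, h = h, filter = "bilinear"))
  1 + (fine + min(coarse))
}

# Composite one anti-aliased stroke (quadratic arc) into an RGB array.
.draw_stroke <- function(img, x0, y0, ang, len, thick, curv, ink) {
  h <- dim(img)[1]; w <- dim(img)[2]
  dx <- cos(ang); dy <- sin(ang)
  p0 <- c(x0, y0)
  p2 <- c(x0 + len * dx, y0 + len * dy)
  p1 <- (p0 + p2) / 2 + curv * len * c(-dy, dx)
  ts <- seq(0, 1, length.out = max(8L, ceiling(len)))
  px <- (1 - ts)^2 * p0[1] + 2 * (1 - ts) * ts * p1[1] + ts^2 * p2[1]
  py <- (1 - ts)^2 * p0[2] + 2 * (1 - ts) * ts * p1[2] + ts^2 * p2[2]

  pad <- thick / 2 + 2
  c0 <- max(1L, floor(min(px) - pad)); c1 <- min(w, ceiling(max(px) + pad))
  r0 <- max(1L, floor(min(py) - pad)); r1 <- min(h, ceiling(max(py) + pad))
  if (c0 > c1 || r0 > r1) return(img)
  # pixel centers at (col - 0.5, row - 0.5) in 0-based continuous coords
  gx <- matrix(seq.int(c0, c1) - 0.5, nrow = r1 - r0 + 1,
               ncol = c1 - c0 + 1, byrow = TRUE)
  gy <- matrix(seq.int(r0, r1) - 0.5, nrow = r1 - r0 + 1, ncol = c1 - c0 + 1)
  d2 <- matrix(Inf, nrow(gx), ncol(gx))
  for (s in seq_len(length(ts) - 1L)) {
    ax <- px[s]; ay <- py[s]
    bx <- px[s + 1L]; by <- py[s + 1L]
    vx <- bx - ax; vy <- by - ay
    vv <- vx * vx + vy * vy
    tt <- if (vv == 0) 0 else pmin(pmax(((gx - ax) * vx + (gy - ay) * vy) / vv, 0), 1)
    dd <- (gx - (ax + tt * vx))^2 + (gy - (ay + tt * vy))^2
    d2 <- pmin(d2, dd)
  }
  alpha <- clamp01(thick / 2 + 0.5 - sqrt(d2))
  for (k in 1:3) {
    img[r0:r1, c0:c1, k] <- img[r0:r1, c0:c1, k] * (1 - alpha) + ink[k] * alpha
  }
  img
}

#' Render a scalp image from placed follicles
#'
#' Composites the mottled background, a darkened soft-edged disk per
#' follicle, and each follicle's hair strokes; returns the raster together
#' with its exact ground-truth annotation set.
#'
#' @param follicles tibble from [sample_follicles()] with placement columns
#'   `cx`, `cy` (see [simulate_scalp_image()] for automatic placement).
#' @param config a [sim_config()].
#' @param seed RNG seed for the background texture.
#' @param image_id id recorded in the annotation set.
#' @return list with `image` (H x W x 3 array in `[0, 1]`) and `set`
#'   (an [annotation_set()]).
#' @export
render_scalp_image <- function(follicles, config = sim_config(), seed = 1L,
                               image_id = "sim_001") {
  w <- config$image_size[1]; h <- config$image_size[2]
  ink <- c(30, 25, 20) / 255
  img <- with_seed(seed, {
    mot <- .mottle_field(h, w, config$mottle_amp, config$mottle_scale)
    a <- array(0, dim = c(h, w, 3))
    for (k in 1:3) a[, , k] <- clamp01(config$skin_tone[k] * mot)
    a
  })

  if (nrow(follicles) > 0) {
    stopifnot(all(c("cx", "cy") %in% names(follicles)))
    gx <- matrix(seq_len(w) - 0.5, nrow = h, ncol = w, byrow = TRUE)
    gy <- matrix(seq_len(h) - 0.5, nrow = h, ncol = w)
    for (i in seq_len(nrow(follicles))) {
      f <- follicles[i, ]
      # darkened disk with a 1.5 px linear soft edge
      win <- ceiling(f$r + 3)
      c0 <- max(1L, floor(f$cx - win)); c1 <- min(w, ceiling(f$cx + win))
      r0 <- max(1L, floor(f$cy - win)); r1 <- min(h, ceiling(f$cy + win))
      d <- sqrt((gx[r0:r1, c0:c1] - f$cx)^2 + (gy[r0:r1, c0:c1] - f$cy)^2)
      cov <- clamp01((f$r + 0.75 - d) / 1.5)
      for (k in 1:3) {
        img[r0:r1, c0:c1, k] <- img[r0:r1, c0:c1, k] * (1 - 0.45 * cov)
      }
      ang <- f$angles[[1]]; lens <- f$lengths[[1]]; curv <- f$curvatures[[1]]
      for (j in seq_len(f$hair_count)) {
        img <- .draw_stroke(img, f$cx, f$cy, ang[j], lens[j],
                            f$hair_thickness, curv[j], ink)
      }
    }
  }

  anns <- if (nrow(follicles) > 0) {
    tibble::tibble(
      image_id = image_id,
      cx = follicles$cx, cy = follicles$cy, r = follicles$r,
      label = follicles$label
    )
  } else {
    tibble::tibble(image_id = character(), cx = numeric(), cy = numeric(),
                   r = numeric(), label = character())
  }
  set <- annotation_set(
    tibble::tibble(image_id = image_id, width = w, height = h),
    anns
  )
  list(image = img, set = set)
}

#' Sample and place the follicles of one image
#'
#' Samples a follicle count (uniform over the configured range unless
#' given), class labels from the mixture, attributes, and dart-throwing
#' placements. If placement fails, the whole follicle list is
#' deterministically re-sampled (up to 20 attempts).
#'
#' @param config a [sim_config()].
#' @param seed RNG seed; drives every random choice for this image.
#' @param n_follicles fixed follicle count (default: sampled from
#'   `config$follicles_per_image`).
#' @param mixture optional class mixture override.
#' @return placed follicle tibble (with `cx`, `cy`), plus attribute
#'   `"render_seed"` used by [simulate_scalp_image()] for the background.
#' @export
sample_scalp_follicles <- function(config = sim_config(), seed = 1L,
                                   n_follicles = NULL, mixture = NULL) {
  mix <- mixture %||% config$class_mixture
  mix <- mix / sum(mix)
  for (attempt in seq_len(20L)) {
    s <- substream_seed(seed, attempt - 1L)
    placed <- with_seed(s, {
      lo <- config$follicles_per_image[1]
      hi <- config$follicles_per_image[2]
      n <- n_follicles %||% (lo + sample.int(hi - lo + 1L, 1) - 1L)
      if (n == 0) {
        tibble::tibble(label = character(), r = numeric(),
                       hair_count = integer(), hair_thickness = numeric(),
                       angles = list(), lengths = list(), curvatures = list(),
                       cx = numeric(), cy = numeric())
      } else {
        labels <- sample(class_levels(), n, replace = TRUE,
                         prob = mix[class_levels()])
        fols <- sample_follicles(labels, config,
                                 seed = substream_seed(s, 7L))
        place_follicles(fols, config)
      }
    })
    if (!is.null(placed)) {
      attr(placed, "render_seed") <- substream_seed(s, 11L)
      return(placed)
    }
  }
  stop("could not place ", n_follicles %||% "the requested", " follicles on a ",
       config$image_size[1], "x", config$image_size[2],
       " canvas under the overlap policy")
}

#' Simulate one scalp image end to end
#'
#' [sample_scalp_follicles()] followed by [render_scalp_image()].
#'
#' @inheritParams sample_scalp_follicles
#' @param image_id id recorded in the annotation set.
#' @return list with `image`, `set` (ground truth) and `follicles`
#'   (placed attribute tibble incl. hair count/thickness).
#' @export
simulate_scalp_image <- function(config = sim_config(), seed = 1L,
                                 n_follicles = NULL, mixture = NULL,
                                 image_id = "sim_001") {
  placed <- sample_scalp_follicles(config, seed, n_follicles, mixture)
  out <- render_scalp_image(placed, config,
                            seed = attr(placed, "render_seed"),
                            image_id = image_id)
  out$follicles <- placed
  out
}

#' Generate a synthetic dataset on disk
#'
#' Writes `n_images` PNG images plus a VIA-dialect ground-truth JSON and a
#' YAML manifest recording the sampling parameters and per-class
#' annotation totals. Fully deterministic under `config$seed`.
#'
#' @param n_images number of images (>= 1).
#' @param config a [sim_config()].
#' @param dir output directory (created if needed); NULL skips writing the
#'   PNG files and returns annotations only.
#' @param prefix image file name prefix.
#' @param render if FALSE, skip rasterization entirely and return ground
#'   truth only (fast annotation-scale datasets, e.g. for split studies).
#' @return list with `set` (ground-truth [annotation_set()]), `follicles`
#'   (attribute tibble for all images), `manifest` (list), and `dir`.
#' @export
generate_dataset <- function(n_images, config = sim_config(), dir = NULL,
                             prefix = "sim", render = TRUE) {
  stopifnot(n_images >= 1)
  if (!is.null(dir) && !dir.exists(dir)) dir.create(dir, recursive = TRUE)
  sets <- vector("list", n_images)
  fols <- vector("list", n_images)
  w <- config$image_size[1]; h <- config$image_size[2]
  for (i in seq_len(n_images)) {
    id <- sprintf("%s_%04d.png", prefix, i)
    seed_i <- substream_seed(config$seed, i)
    if (render) {
      sim <- simulate_scalp_image(config, seed = seed_i, image_id = id)
      placed <- sim$follicles
      sets[[i]] <- sim$set
      if (!is.null(dir)) png::writePNG(sim$image, file.path(dir, id))
    } else {
      placed <- sample_scalp_follicles(config, seed = seed_i)
      anns <- tibble::tibble(image_id = id, cx = placed$cx, cy = placed$cy,
                             r = placed$r, label = placed$label)
      sets[[i]] <- annotation_set(
        tibble::tibble(image_id = id, width = w, height = h), anns
      )
    }
    placed$image_id <- id
    fols[[i]] <- placed
  }
  images <- dplyr::bind_rows(purrr::map(sets, "images"))
  annotations <- dplyr::bind_rows(purrr::map(sets, "annotations"))
  set <- annotation_set(images, annotations)
  follicles <- dplyr::bind_rows(fols)
  manifest <- list(
    n_images = n_images,
    image_size = config$image_size,
    follicles_per_image = config$follicles_per_image,
    class_mixture = as.list(config$class_mixture),
    strict_bands = config$strict_bands,
    overlap_factor = config$overlap_factor,
    seed = config$seed,
    per_class_annotations = as.list(table(annotations$label)),
    total_annotations = nrow(annotations)
  )
  if (!is.null(dir)) {
    write_via_annotations(set, file.path(dir, "ground_truth.json"))
    yaml::write_yaml(manifest, file.path(dir, "manifest.yaml"))
  }
  list(set = set, follicles = follicles, manifest = manifest, dir = dir)
}
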