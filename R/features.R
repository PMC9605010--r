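# Follicle feature measurement and rule-based classification.
#
# The three diagnostic features per follicle are its radius (px), the
# number of hairs crossing its boundary, and the hair thickness (px,
# median medial-axis width of the strands attached to it). Features are
# measured from a dark-strand segmentation: threshold -> connected
# components -> Zhang-Suen skeleton -> distance-transform widths.

# Gray level below which a pixel is considered hair ink. Rendered strokes
# are near-black (~0.1); the darkened follicle disk stays above ~0.36 even
# under the deepest background mottle.
.strand_threshold <- 0.30

#' Zhang–Suen skeletonization of a binary mask
#'
#' Iterative morphological thinning to a 1-pixel-wide, 8-connected
#' skeleton (medial axis approximation).
#'
#' @param mask logical or 0/1 matrix.
#' @param max_iter iteration cap.
#' @return logical matrix of the same size.
#' @export
skeletonize <- function(mask, max_iter = 200L) {
  m <- matrix(FALSE, nrow(mask) + 2L, ncol(mask) + 2L)
  m[2:(nrow(mask) + 1L), 2:(ncol(mask) + 1L)] <- mask > 0
  nr <- nrow(m); nc <- ncol(m)
  up <- function(x) rbind(x[-1, , drop = FALSE], FALSE)
  dn <- function(x) rbind(FALSE, x[-nr, , drop = FALSE])
  lf <- function(x) cbind(x[, -1, drop = FALSE], FALSE)
  rt <- function(x) cbind(FALSE, x[, -nc, drop = FALSE])
  for (iter in seq_len(max_iter)) {
    changed <- FALSE
    for (phase in 1:2) {
      p2 <- dn(m); p3 <- dn(rt(m)); p4 <- rt(m); p5 <- up(rt(m))
      p6 <- up(m); p7 <- up(lf(m)); p8 <- lf(m); p9 <- dn(lf(m))
      b <- p2 + p3 + p4 + p5 + p6 + p7 + p8 + p9
      a <- (!p2 & p3) + (!p3 & p4) + (!p4 & p5) + (!p5 & p6) +
        (!p6 & p7) + (!p7 & p8) + (!p8 & p9) + (!p9 & p2)
      cond <- m & b >= 2 & b <= 6 & a == 1
      if (phase == 1) {
        cond <- cond & !(p2 & p4 & p6) & !(p4 & p6 & p8)
      } else {
        cond <- cond & !(p2 & p4 & p8) & !(p2 & p6 & p8)
      }
      if (any(cond)) {
        m[cond] <- FALSE
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  m[2:(nrow(mask) + 1L), 2:(ncol(mask) + 1L)]
}

# Euclidean distance transform (distance to nearest background pixel).
.distmap <- function(mask) {
  t(EBImage::imageData(EBImage::distmap(EBImage::Image(t(mask * 1)))))
}

# Connected-component labeling (8-connectivity).
.bwlabel <- function(mask) {
  t(EBImage::imageData(EBImage::bwlabel(EBImage::Image(t(mask * 1)))))
}

# Bilinear sample of matrix `m` at continuous (x, y) image coordinates
# (0-based, pixel centers at integer + 0.5); out-of-range returns `fill`.
.bilinear <- function(m, x, y, fill = NA_real_) {
  i <- y - 0.5 + 1  # fractional row index
  j <- x - 0.5 + 1
  i0 <- floor(i); j0 <- floor(j)
  fi <- i - i0; fj <- j - j0
  get <- function(ii, jj) {
    ok <- ii >= 1 & ii <= nrow(m) & jj >= 1 & jj <= ncol(m)
    out <- rep(fill, length(ii))
    out[ok] <- m[cbind(ii[ok], jj[ok])]
    out
  }
  v <- get(i0, j0) * (1 - fi) * (1 - fj) + get(i0 + 1, j0) * fi * (1 - fj) +
    get(i0, j0 + 1) * (1 - fi) * fj + get(i0 + 1, j0 + 1) * fi * fj
  v
}

# Sub-pixel strand width at skeleton pixels: integrate the ink coverage
# along a profile perpendicular to the local skeleton orientation.
# `gray` is the cropped image and `bgmat` a background model of the same
# size (skin tone outside the follicle disk, darkened tone inside, blended
# across the soft edge); a per-profile scale factor absorbs the local
# mottle. `skel_xy` is an n x 2 matrix of 0-based (x, y) skeleton
# coordinates to measure at, `all_xy` the full skeleton point set (for
# orientation), `ink` the assumed hair ink gray level.
.profile_widths <- function(gray, bgmat, skel_xy, all_xy, ink = 0.10,
                            max_half = 8, step = 0.5) {
  offs <- seq(-max_half, max_half, by = step)
  far <- abs(offs) >= max_half - 2.5
  widths <- rep(NA_real_, nrow(skel_xy))
  for (i in seq_len(nrow(skel_xy))) {
    p <- skel_xy[i, ]
    near <- all_xy[abs(all_xy[, 1] - p[1]) <= 3.5 &
                     abs(all_xy[, 2] - p[2]) <= 3.5, , drop = FALSE]
    if (nrow(near) < 3) next
    cc <- sweep(near, 2, colMeans(near))
    ev <- eigen(crossprod(cc) / nrow(near), symmetric = TRUE)$vectors[, 1]
    perp <- c(-ev[2], ev[1])
    xs <- p[1] + offs * perp[1]
    ys <- p[2] + offs * perp[2]
    g <- .bilinear(gray, xs, ys)
    b <- .bilinear(bgmat, xs, ys)
    scale <- median((g / b)[far], na.rm = TRUE)
    if (!is.finite(scale)) next
    b <- b * min(max(scale, 0.7), 1.3)
    alpha <- clamp01((b - g) / pmax(b - ink, 0.15))
    alpha[is.na(alpha)] <- 0
    widths[i] <- sum(alpha) * step
  }
  widths[!is.na(widths)]
}

#' Measure follicle features from an image
#'
#' For one detected (or ground-truth) follicle circle, measures:
#' * `radius` — the circle radius itself;
#' * `hair_count` — distinct dark strands crossing the circle boundary,
#'   counted as connected components of the strand mask restricted to a
#'   narrow annulus at the boundary;
#' * `hair_thickness` — median medial-axis width (2 x distance-transform
#'   value - 1) over skeleton pixels of the attached strands, sampled
#'   between 0.45 r and 1.35 r from the center to stay clear of the strand
#'   merge zone at the follicle center and of the stroke tips.
#'
#' @param img H x W (gray) or H x W x 3 (RGB) array in `[0, 1]`.
#' @param detection one-row data frame with `cx`, `cy`, `r` (detection or
#'   ground-truth circle).
#' @param strand_threshold gray level below which pixels count as hair.
#' @return one-row tibble: `radius`, `hair_count`, `hair_thickness`.
#' @export
extract_features <- function(img, detection,
                             strand_threshold = .strand_threshold) {
  gray <- to_gray(img)
  h <- nrow(gray); w <- ncol(gray)
  cx <- detection$cx; cy <- detection$cy; r <- detection$r
  if (is.na(r) || r <= 0) stop("detection has no usable circle")

  win <- ceiling(1.6 * r + 8)
  c0 <- max(1L, floor(cx - win)); c1 <- min(w, ceiling(cx + win))
  r0 <- max(1L, floor(cy - win)); r1 <- min(h, ceiling(cy + win))
  crop <- gray[r0:r1, c0:c1, drop = FALSE]
  mask <- crop < strand_threshold
  if (!any(mask)) {
    return(tibble::tibble(radius = r, hair_count = 0L, hair_thickness = 0))
  }

  # pixel-center distances from the follicle center, in the crop frame
  gx <- matrix(seq.int(c0, c1) - 0.5, nrow(crop), ncol(crop), byrow = TRUE)
  gy <- matrix(seq.int(r0, r1) - 0.5, nrow(crop), ncol(crop))
  dcen <- sqrt((gx - cx)^2 + (gy - cy)^2)

  # strands crossing the circle boundary: components of the strand mask
  # restricted to a narrow annulus, after a small closing that bridges
  # single-pixel aliasing gaps in very thin strands
  annulus <- mask & dcen >= r - 2 & dcen <= r + 2
  hair_count <- if (any(annulus)) {
    ann_eb <- EBImage::closing(EBImage::Image(t(annulus * 1)),
                               EBImage::makeBrush(3, "box"))
    ann <- t(EBImage::imageData(ann_eb)) > 0 & dcen >= r - 2.5 & dcen <= r + 2.5
    max(.bwlabel(ann))
  } else 0L

  if (hair_count == 0L) {
    return(tibble::tibble(radius = r, hair_count = 0L, hair_thickness = 0))
  }

  # keep only components attached to this follicle (touching the annulus)
  labs <- .bwlabel(mask)
  keep <- unique(labs[annulus & labs > 0])
  strand <- matrix(labs %in% keep, nrow(labs), ncol(labs))

  # sub-pixel thickness: perpendicular coverage profiles at skeleton pixels
  # between 0.45 r and 1.35 r from the center (clear of the central merge
  # zone and of stroke tips)
  skel <- skeletonize(strand)
  sel <- skel & dcen >= 0.45 * r & dcen <= 1.35 * r
  thickness <- 0
  if (any(sel)) {
    pts <- which(skel, arr.ind = TRUE)
    all_xy <- cbind(pts[, 2] - 0.5, pts[, 1] - 0.5)
    sp <- which(sel, arr.ind = TRUE)
    sel_xy <- cbind(sp[, 2] - 0.5, sp[, 1] - 0.5)
    if (nrow(sel_xy) > 60) {
      sel_xy <- sel_xy[seq(1, nrow(sel_xy), length.out = 60), , drop = FALSE]
    }
    # background model: skin tone outside the disk, darkened tone inside,
    # blended linearly across the disk's soft edge
    non_strand <- !strand
    skin_px <- crop[non_strand & dcen > r + 2]
    disk_px <- crop[non_strand & dcen < r - 1]
    skin_tone <- if (length(skin_px) > 20) median(skin_px) else 0.72
    disk_tone <- if (length(disk_px) > 5) median(disk_px) else 0.55 * skin_tone
    wdisk <- clamp01((r + 1 - dcen) / 2)
    bgmat <- skin_tone * (1 - wdisk) + disk_tone * wdisk
    wds <- .profile_widths(crop, bgmat, sel_xy, all_xy)
    if (length(wds) > 0) {
      thickness <- median(wds)
    } else {
      dm <- .distmap(strand)
      thickness <- max(0, 2 * median(dm[sel]) - 1)
    }
  }
  tibble::tibble(radius = r, hair_count = as.integer(hair_count),
                 hair_thickness = thickness)
}

#' Classification rule thresholds
#'
#' Band edges for the three features. Bands are closed on the severe-ward
#' side (a boundary case flags the more severe class): radius <= 10 px
#' severe, (10, 20) normal, >= 20 healthy; thickness <= 3 px severe,
#' (3, 6) normal, >= 6 healthy; hair count <= 1 severe-or-normal,
#' >= 2 healthy.
#'
#' @param severe_r_max,normal_r_max radius band edges (px).
#' @param severe_t_max,normal_t_max thickness band edges (px).
#' @param healthy_count_min minimum hair count for healthy.
#' @return list of class `rule_thresholds`.
#' @export
rule_thresholds <- function(severe_r_max = 10, normal_r_max = 20,
                            severe_t_max = 3, normal_t_max = 6,
                            healthy_count_min = 2) {
  if (!(severe_r_max < normal_r_max)) stop("severe_r_max must be < normal_r_max")
  if (!(severe_t_max < normal_t_max)) stop("severe_t_max must be < normal_t_max")
  structure(
    list(severe_r_max = severe_r_max, normal_r_max = normal_r_max,
         severe_t_max = severe_t_max, normal_t_max = normal_t_max,
         healthy_count_min = healthy_count_min),
    class = "rule_thresholds"
  )
}

#' Rule-based follicle state classification
#'
#' Each feature votes for a class according to its band; radius and
#' thickness cast a full vote for their band's class, while a hair count
#' below `healthy_count_min` splits half a vote between severe and normal
#' (the count criterion of those two classes is identical) and a count of
#' `healthy_count_min` or more votes healthy. The majority wins; ties
#' break toward the more severe class (clinically conservative). In
#' `mode = "strict"` a follicle is labeled only if all three features
#' agree, otherwise `"indeterminate"`.
#'
#' @param features data frame with columns `radius`, `hair_count`,
#'   `hair_thickness` (one row per follicle).
#' @param thresholds a [rule_thresholds()].
#' @param mode `"vote"` (default) or `"strict"`.
#' @return character vector of labels.
#' @examples
#' rule_classify(tibble::tibble(radius = 8, hair_count = 1,
#'                              hair_thickness = 2))      # "severe"
#' rule_classify(tibble::tibble(radius = 25, hair_count = 2,
#'                              hair_thickness = 7))      # "healthy"
#' @export
rule_classify <- function(features, thresholds = rule_thresholds(),
                          mode = c("vote", "strict")) {
  mode <- match.arg(mode)
  th <- thresholds
  stopifnot(all(c("radius", "hair_count", "hair_thickness") %in% names(features)))
  vapply(seq_len(nrow(features)), function(i) {
    r <- features$radius[i]
    n <- features$hair_count[i]
    t <- features$hair_thickness[i]
    votes <- c(severe = 0, normal = 0, healthy = 0)
    r_class <- if (r <= th$severe_r_max) "severe"
      else if (r < th$normal_r_max) "normal" else "healthy"
    t_class <- if (t <= th$severe_t_max) "severe"
      else if (t < th$normal_t_max) "normal" else "healthy"
    votes[r_class] <- votes[r_class] + 1
    votes[t_class] <- votes[t_class] + 1
    if (n >= th$healthy_count_min) {
      votes["healthy"] <- votes["healthy"] + 1
    } else {
      votes["severe"] <- votes["severe"] + 0.5
      votes["normal"] <- votes["normal"] + 0.5
    }
    if (mode == "strict") {
      n_class <- if (n >= th$healthy_count_min) "healthy" else "severe_or_normal"
      agree <- r_class == t_class &&
        ((n_class == "healthy") == (r_class == "healthy"))
      if (!agree) return("indeterminate")
      return(r_class)
    }
    best <- max(votes)
    # tie-break toward the more severe class
    names(votes)[votes == best][1]
  }, character(1))
}

#' Measure and classify every detection in an image
#'
#' Convenience wrapper: runs [extract_features()] on each detection circle
#' and [rule_classify()] on the measurements.
#'
#' @param img image array.
#' @param detections data frame with `cx`, `cy`, `r` (one row per
#'   follicle), e.g. from [detect_follicles_reference()] or ground truth.
#' @param thresholds a [rule_thresholds()].
#' @param mode see [rule_classify()].
#' @return `detections` with added columns `radius`, `hair_count`,
#'   `hair_thickness`, `label`.
#' @export
classify_follicles <- function(img, detections,
                               thresholds = rule_thresholds(),
                               mode = "vote") {
  if (nrow(detections) == 0) {
    detections$radius <- numeric()
    detections$hair_count <- integer()
    detections$hair_thickness <- numeric()
    detections$label <- character()
    return(tibble::as_tibble(detections))
  }
  feats <- purrr::map_dfr(seq_len(nrow(detections)), function(i) {
    extract_features(img, detections[i, ])
  })
  out <- dplyr::bind_cols(
    tibble::as_tibble(detections)[setdiff(names(detections),
                                          c("radius", "hair_count",
                                            "hair_thickness", "label"))],
    feats
  )
  out$label <- rule_classify(feats, thresholds, mode)
  out
}
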