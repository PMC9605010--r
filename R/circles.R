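# Circle geometry. Coordinates are 0-based continuous pixel coordinates,
# x rightward, y downward (the VIA convention); radii in pixels.

#' Construct a circle
#'
#' @param cx,cy center in pixels (x rightward, y downward, 0-based).
#' @param r radius in pixels, strictly positive.
#' @return a one-row tibble with columns `cx`, `cy`, `r`.
#' @examples
#' circle(100, 80, 15)
#' @export
circle <- function(cx, cy, r) {
  stopifnot(is.finite(cx), is.finite(cy), is.finite(r))
  if (any(r <= 0)) stop("circle radius must be strictly positive")
  tibble::tibble(cx = as.numeric(cx), cy = as.numeric(cy), r = as.numeric(r))
}

#' Axis-aligned bounding box of a circle
#'
#' The box spans `[cx - r, cx + r] x [cy - r, cy + r]`, so its width and
#' height both equal `2r` and its area is `4r^2`.
#'
#' @param circles a data frame with columns `cx`, `cy`, `r` (one row per
#'   circle), or a single circle from [circle()].
#' @return a tibble with columns `x1`, `y1`, `x2`, `y2`, `l_width`,
#'   `l_height`, `area`, one row per input circle.
#' @examples
#' bbox_from_circle(circle(100, 100, 10))
#' @export
bbox_from_circle <- function(circles) {
  stopifnot(all(c("cx", "cy", "r") %in% names(circles)))
  if (any(circles$r <= 0)) stop("circle radius must be strictly positive")
  tibble::tibble(
    x1 = circles$cx - circles$r,
    y1 = circles$cy - circles$r,
    x2 = circles$cx + circles$r,
    y2 = circles$cy + circles$r,
    l_width = 2 * circles$r,
    l_height = 2 * circles$r,
    area = 4 * circles$r^2
  )
}

#' Intersection-over-union of two circles
#'
#' `circle_iou()` evaluates the closed-form circular "lens" intersection
#' area; `circle_iou_raster()` estimates the same quantity by rasterizing
#' both disks on a fine grid, which serves as an independent cross-check
#' (the two agree within 0.01 for radii of a few pixels and up).
#'
#' @param a,b circles: one-row data frames (or lists) with `cx`, `cy`, `r`.
#' @param scale raster samples per pixel for the rasterized estimate.
#' @return IoU in `[0, 1]`.
#' @examples
#' circle_iou(circle(0, 0, 1), circle(1, 0, 1))
#' @export
circle_iou <- function(a, b) {
  ra <- a$r; rb <- b$r
  d <- sqrt((a$cx - b$cx)^2 + (a$cy - b$cy)^2)
  if (d >= ra + rb) return(0)
  if (d <= abs(ra - rb)) {
    inter <- pi * min(ra, rb)^2
  } else {
    # lens area: sum of the two circular-segment areas
    da <- (d^2 + ra^2 - rb^2) / (2 * d)
    db <- d - da
    inter <- ra^2 * acos(pmin(pmax(da / ra, -1), 1)) - da * sqrt(pmax(ra^2 - da^2, 0)) +
      rb^2 * acos(pmin(pmax(db / rb, -1), 1)) - db * sqrt(pmax(rb^2 - db^2, 0))
  }
  union <- pi * ra^2 + pi * rb^2 - inter
  max(0, min(1, inter / union))
}

#' @rdname circle_iou
#' @export
circle_iou_raster <- function(a, b, scale = 8) {
  x0 <- floor(min(a$cx - a$r, b$cx - b$r)) - 1
  x1 <- ceiling(max(a$cx + a$r, b$cx + b$r)) + 1
  y0 <- floor(min(a$cy - a$r, b$cy - b$r)) - 1
  y1 <- ceiling(max(a$cy + a$r, b$cy + b$r)) + 1
  xs <- seq(x0, x1, by = 1 / scale)
  ys <- seq(y0, y1, by = 1 / scale)
  gx <- matrix(xs, nrow = length(ys), ncol = length(xs), byrow = TRUE)
  gy <- matrix(ys, nrow = length(ys), ncol = length(xs))
  in_a <- (gx - a$cx)^2 + (gy - a$cy)^2 <= a$r^2
  in_b <- (gx - b$cx)^2 + (gy - b$cy)^2 <= b$r^2
  inter <- sum(in_a & in_b)
  union <- sum(in_a | in_b)
  if (union == 0) return(0)
  inter / union
}
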