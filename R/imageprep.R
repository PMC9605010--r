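# Deterministic image preparation: resizing with annotation rescaling and
# the augmentation set (brightness, contrast, flips, Gaussian blur).

# Mirror-reflection index into 1..n (boundary pixels not repeated).
reflect_idx <- function(i, n) {
  if (n == 1L) return(rep(1L, length(i)))
  p <- (i - 1L) %% (2L * n - 2L)
  ifelse(p < n, p + 1L, 2L * n - p - 1L)
}

#' Gaussian blur with reflective borders
#'
#' Separable convolution with a normalized discrete Gaussian kernel
#' truncated at 3 sigma; borders are mirror-reflected so edges stay
#' artifact-free.
#'
#' @param img numeric image array (H x W or H x W x 3) in `[0, 1]`.
#' @param sigma Gaussian standard deviation in pixels; `sigma <= 0` is the
#'   identity.
#' @return blurred array, same dimensions.
#' @export
gaussian_blur <- function(img, sigma) {
  if (sigma <= 0) return(img)
  if (length(dim(img)) == 3L) {
    for (k in seq_len(dim(img)[3])) img[, , k] <- gaussian_blur(img[, , k], sigma)
    return(img)
  }
  k <- ceiling(3 * sigma)
  kern <- exp(-((-k:k)^2) / (2 * sigma^2))
  kern <- kern / sum(kern)
  conv1 <- function(m) {  # along rows (dimension 1)
    n <- nrow(m)
    pad <- m[reflect_idx(seq.int(1L - k, n + k), n), , drop = FALSE]
    out <- matrix(0, n, ncol(m))
    for (t in seq_along(kern)) {
      out <- out + kern[t] * pad[seq.int(t, t + n - 1L), , drop = FALSE]
    }
    out
  }
  t(conv1(t(conv1(img))))
}

#' Resize an image together with its circle annotations
#'
#' Bilinear resize to the target size (default 640 x 480); annotation
#' centers scale by the per-axis factors and radii by the geometric mean
#' `sqrt(sx * sy)`, since a circle cannot stay a circle under anisotropic
#' scaling. An anisotropic resize is reported with a message.
#'
#' @param img numeric image array (H x W or H x W x 3).
#' @param annotations data frame with columns `cx`, `cy`, `r` (may be
#'   empty), or NULL.
#' @param target `(width, height)` in pixels.
#' @return list with `image` (resized array) and `annotations` (rescaled
#'   tibble, same columns).
#' @export
resize_with_annotations <- function(img, annotations = NULL,
                                    target = c(640, 480)) {
  d <- dim(img)
  if (any(d[1:2] == 0)) stop("cannot resize a zero-dimension image")
  in_w <- d[2]; in_h <- d[1]
  sx <- target[1] / in_w; sy <- target[2] / in_h
  if (abs(sx - sy) > 1e-12) {
    message(sprintf("anisotropic resize (sx = %.4f, sy = %.4f); radii scaled by sqrt(sx*sy)", sx, sy))
  }
  out <- if (in_w == target[1] && in_h == target[2]) {
    img
  } else {
    .from_eb(EBImage::resize(.as_eb(img), w = target[1], h = target[2],
                             filter = "bilinear"))
  }
  anns <- NULL
  if (!is.null(annotations)) {
    anns <- tibble::as_tibble(annotations)
    if (nrow(anns) > 0) {
      anns$cx <- anns$cx * sx
      anns$cy <- anns$cy * sy
      anns$r <- anns$r * sqrt(sx * sy)
    }
  }
  list(image = out, annotations = anns)
}

#' Apply an augmentation pipeline to an image
#'
#' Operations are applied in the listed order, with pixel values clipped to
#' `[0, 1]` after each step. Supported operations:
#' * `brightness(delta)` — add `delta`;
#' * `contrast(gain)` — scale around mid-gray, `(x - 0.5) * gain + 0.5`;
#' * `hflip` / `vflip` — mirror horizontally / vertically;
#' * `gaussian_blur(sigma)` — [gaussian_blur()].
#'
#' @param img numeric image array.
#' @param ops list of operations; each element is either a string
#'   (`"hflip"`, `"vflip"`) or a list with an `op` element and parameters,
#'   e.g. `list(op = "brightness", delta = 0.1)`.
#' @param seed RNG seed scoping any stochastic operation (all current
#'   operations are deterministic; the seed keeps the contract stable).
#' @return augmented array, same dimensions as the input.
#' @examples
#' img <- matrix(0.5, 8, 8)
#' augment_image(img, list(list(op = "brightness", delta = 0.2), "hflip"))
#' @export
augment_image <- function(img, ops, seed = 1L) {
  flip2 <- function(m, which) {
    if (which == "h") m[, rev(seq_len(ncol(m))), drop = FALSE]
    else m[rev(seq_len(nrow(m))), , drop = FALSE]
  }
  flip <- function(a, which) {
    if (length(dim(a)) == 3L) {
      for (k in seq_len(dim(a)[3])) a[, , k] <- flip2(a[, , k], which)
      a
    } else flip2(a, which)
  }
  with_seed(seed, {
    for (op in ops) {
      if (is.character(op)) op <- list(op = op)
      img <- switch(op$op,
        brightness = clamp01(img + op$delta),
        contrast = clamp01((img - 0.5) * op$gain + 0.5),
        hflip = flip(img, "h"),
        vflip = flip(img, "v"),
        gaussian_blur = clamp01(gaussian_blur(img, op$sigma)),
        stop("unknown augmentation op: ", op$op)
      )
    }
  })
  img
}
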