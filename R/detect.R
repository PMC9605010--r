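# Follicle detection. The deep instance-segmentation stage lives behind a
# pluggable contract (detections JSON); a deterministic classical detector
# serves as the reference implementation: background flattening, dark
# thresholding, morphological cleanup, connected components, circle fit.

#' Reference follicle detector
#'
#' Deterministic classical pipeline:
#' 1. grayscale conversion;
#' 2. background flattening — subtract a large-kernel Gaussian smoothing of
#'    the image, removing illumination and skin mottle;
#' 3. thresholding of dark regions, split into hair-ink pixels (near-black)
#'    and follicle-disk pixels;
#' 4. morphological closing + hole filling + light opening of the disk
#'    mask, bridging the slits left where hair strands cross a follicle;
#' 5. connected components, filtered by area and radial circularity;
#' 6. circle fit per component: centroid center, equivalent-area radius.
#'
#' Scores are the component circularity (1 - sd/mean of boundary radii,
#' clipped to `[0, 1]`).
#'
#' @param img H x W or H x W x 3 array in `[0, 1]`.
#' @param image_id id to record on the detections.
#' @param bg_sigma background-flattening Gaussian sigma (px).
#' @param dark_delta how far below the flattened background a pixel must
#'   fall to count as a follicle disk.
#' @param strand_threshold absolute gray level for hair ink.
#' @param min_r,max_r radius acceptance band (px).
#' @param min_circularity minimum accepted circularity score.
#' @return tibble with columns `image_id`, `cx`, `cy`, `r`, `score`,
#'   `label` (NA; filled by [classify_follicles()]); zero rows on a blank
#'   image.
#' @export
detect_follicles_reference <- function(img, image_id = "image",
                                       bg_sigma = 25,
                                       dark_delta = 0.10,
                                       strand_threshold = .strand_threshold,
                                       min_r = 3, max_r = 40,
                                       min_circularity = 0.55) {
  gray <- to_gray(img)
  eb <- EBImage::Image(t(gray))
  bg <- t(EBImage::imageData(EBImage::gblur(eb, sigma = bg_sigma)))
  flat <- gray - bg
  strand <- gray < strand_threshold
  disk <- (flat < -dark_delta) & !strand

  disk_eb <- EBImage::Image(t(disk * 1))
  disk_eb <- EBImage::closing(disk_eb, EBImage::makeBrush(11, "disc"))
  disk_eb <- EBImage::fillHull(disk_eb)
  disk_eb <- EBImage::opening(disk_eb, EBImage::makeBrush(5, "disc"))
  labs <- t(EBImage::imageData(EBImage::bwlabel(disk_eb)))
  n <- max(labs)
  if (n == 0) {
    return(tibble::tibble(image_id = character(), cx = numeric(),
                          cy = numeric(), r = numeric(), score = numeric(),
                          label = character()))
  }

  idx <- which(labs > 0, arr.ind = TRUE)
  lab_of <- labs[labs > 0]
  dets <- purrr::map_dfr(seq_len(n), function(L) {
    px <- idx[lab_of == L, , drop = FALSE]
    area <- nrow(px)
    x <- px[, 2] - 0.5
    y <- px[, 1] - 0.5
    cx <- mean(x); cy <- mean(y)
    r_eq <- sqrt(area / pi)
    if (r_eq < min_r || r_eq > max_r) return(NULL)
    rad <- sqrt((x - cx)^2 + (y - cy)^2)
    # radial circularity: for a perfect disk, sd(rad)/mean(rad) ~ 0.236;
    # normalize so a disk scores ~1
    circ <- clamp01(1 - (stats::sd(rad) / mean(rad) - 0.236) * 2)
    if (circ < min_circularity) return(NULL)
    tibble::tibble(image_id = image_id, cx = cx, cy = cy, r = r_eq,
                   score = circ, label = NA_character_)
  })
  if (is.null(dets) || nrow(dets) == 0) {
    return(tibble::tibble(image_id = character(), cx = numeric(),
                          cy = numeric(), r = numeric(), score = numeric(),
                          label = character()))
  }
  dets
}

#' Average binary cross-entropy mask loss
#'
#' Per-cell binary cross-entropy between a true binary m x m mask and the
#' predicted probability mask for the ground-truth class, averaged over
#' the m^2 cells. Predictions are clipped to `[epsilon, 1 - epsilon]`
#' because the loss is undefined at exactly 0 or 1.
#'
#' @param y_true binary matrix (0/1).
#' @param y_pred probability matrix, same shape, values in `[0, 1]`.
#' @param epsilon clip bound in (0, 0.5).
#' @return non-negative scalar.
#' @examples
#' mask_loss(matrix(c(1, 0, 0, 1), 2), matrix(c(0.9, 0.2, 0.1, 0.8), 2))
#' @export
mask_loss <- function(y_true, y_pred, epsilon = 1e-7) {
  if (!all(dim(y_true) == dim(y_pred))) stop("mask shapes differ")
  if (!(epsilon > 0 && epsilon < 0.5)) stop("epsilon must lie in (0, 0.5)")
  if (any(y_pred < 0 | y_pred > 1)) stop("predicted mask must lie in [0, 1]")
  if (!all(y_true %in% c(0, 1))) stop("true mask must be binary")
  p <- pmin(pmax(y_pred, epsilon), 1 - epsilon)
  -mean(y_true * log(p) + (1 - y_true) * log(1 - p))
}

#' Read and write detections JSON
#'
#' The interchange format for external (deep) detectors: a JSON array of
#' objects `{image_id, cx, cy, r, score, label?}`.
#'
#' @param path JSON file path.
#' @return `read_detections()` returns a tibble with columns `image_id`,
#'   `cx`, `cy`, `r`, `score`, `label`.
#' @export
read_detections <- function(path) {
  df <- jsonlite::fromJSON(path)
  if (length(df) == 0) {
    return(tibble::tibble(image_id = character(), cx = numeric(),
                          cy = numeric(), r = numeric(), score = numeric(),
                          label = character()))
  }
  df <- tibble::as_tibble(df)
  stopifnot(all(c("image_id", "cx", "cy", "r", "score") %in% names(df)))
  if (!"label" %in% names(df)) df$label <- NA_character_
  if (any(df$score < 0 | df$score > 1)) stop("scores must lie in [0, 1]")
  df[, c("image_id", "cx", "cy", "r", "score", "label")]
}

#' @rdname read_detections
#' @param detections detections tibble.
#' @export
write_detections <- function(detections, path) {
  cols <- c("image_id", "cx", "cy", "r", "score", "label")
  stopifnot(all(setdiff(cols, "label") %in% names(detections)))
  if (!"label" %in% names(detections)) detections$label <- NA_character_
  writeLines(
    jsonlite::toJSON(as.data.frame(detections[, cols]), dataframe = "rows",
                     auto_unbox = TRUE, digits = NA, pretty = TRUE, na = "null"),
    path
  )
  invisible(path)
}
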