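# Annotation sets and VIA (VGG Image Annotator) JSON I/O.
#
# The VIA dialect used here is the v2 project/export layout: a JSON object
# keyed by "<filename><size>" with fields {filename, size, regions,
# file_attributes}. Circle regions carry shape_attributes
# {name: "circle", cx, cy, r} and region_attributes {class: "<code>"} with
# the fixed coding 0 = severe, 1 = normal, 2 = healthy. Image width/height
# are stored in file_attributes so a set round-trips losslessly.

#' Build an annotation set
#'
#' An annotation set couples an image table with a follicle annotation table.
#' Circles extending past their image border are kept unclipped but flagged
#' in the `at_border` column, so area computations always use the full
#' circle geometry.
#'
#' @param images data frame with columns `image_id`, `width`, `height`.
#' @param annotations data frame with columns `image_id`, `cx`, `cy`, `r`
#'   and either `label` or `class_code` (the other is derived).
#' @param max_per_image upper bound on annotations per image (the study
#'   regime is 10–45; the default bound of 200 only guards against
#'   malformed input).
#' @return an object of class `annotation_set`: a list with tibbles
#'   `$images` and `$annotations` (the latter gains `at_border`).
#' @examples
#' anns <- tibble::tibble(image_id = "img1", cx = 100, cy = 80, r = 15,
#'                        label = "healthy")
#' imgs <- tibble::tibble(image_id = "img1", width = 640, height = 480)
#' annotation_set(imgs, anns)
#' @export
annotation_set <- function(images, annotations, max_per_image = 200) {
  images <- tibble::as_tibble(images)
  annotations <- tibble::as_tibble(annotations)
  stopifnot(all(c("image_id", "width", "height") %in% names(images)))
  stopifnot(all(c("image_id", "cx", "cy", "r") %in% names(annotations)))
  if (anyDuplicated(images$image_id)) stop("duplicate image_id in images table")

  if (!"label" %in% names(annotations) && !"class_code" %in% names(annotations)) {
    stop("annotations need a 'label' or 'class_code' column")
  }
  if (!"label" %in% names(annotations)) {
    annotations$label <- class_label(annotations$class_code)
  }
  annotations$class_code <- class_code(annotations$label)

  if (nrow(annotations) > 0) {
    if (any(annotations$r <= 0)) stop("annotation radii must be strictly positive")
    orphan <- setdiff(annotations$image_id, images$image_id)
    if (length(orphan) > 0) {
      stop("annotations reference unknown image_id(s): ",
           paste(utils::head(orphan, 5), collapse = ", "))
    }
    counts <- table(annotations$image_id)
    if (any(counts > max_per_image)) {
      stop("image(s) exceed max_per_image = ", max_per_image, ": ",
           paste(names(counts)[counts > max_per_image], collapse = ", "))
    }
    idx <- match(annotations$image_id, images$image_id)
    w <- images$width[idx]; h <- images$height[idx]
    annotations$at_border <-
      (annotations$cx - annotations$r < 0) | (annotations$cy - annotations$r < 0) |
      (annotations$cx + annotations$r > w) | (annotations$cy + annotations$r > h)
  } else {
    annotations <- tibble::tibble(
      image_id = character(), cx = numeric(), cy = numeric(), r = numeric(),
      label = character(), class_code = integer(), at_border = logical()
    )
  }

  structure(
    list(
      images = images[, c("image_id", "width", "height")],
      annotations = annotations[, c("image_id", "cx", "cy", "r",
                                    "label", "class_code", "at_border")]
    ),
    class = "annotation_set"
  )
}

#' @export
print.annotation_set <- function(x, ...) {
  cat("<annotation_set> ", nrow(x$images), " image(s), ",
      nrow(x$annotations), " annotation(s)\n", sep = "")
  if (nrow(x$annotations) > 0) {
    print(table(x$annotations$label))
  }
  invisible(x)
}

#' @export
tidy.annotation_set <- function(x, ...) x$annotations

.via_key <- function(filename) paste0(filename, "-1")

#' Read follicle annotations from a VIA JSON file
#'
#' Parses circle regions from a VIA v2 project or export JSON. Non-circle
#' regions (polygons, ellipses, ...) are skipped with a warning; a class
#' code outside \{0, 1, 2\} is an error naming the offending region.
#'
#' @param path path to a VIA JSON file.
#' @param default_size assumed `(width, height)` for images whose
#'   file_attributes do not record dimensions.
#' @return an [annotation_set()]; attribute `"via_meta"` holds a list with
#'   the counts of parsed and skipped regions.
#' @seealso [write_via_annotations()]
#' @export
read_via_annotations <- function(path, default_size = c(640, 480)) {
  doc <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  if (!is.null(doc[["_via_img_metadata"]])) doc <- doc[["_via_img_metadata"]]
  if (!is.list(doc)) stop("not a VIA project/export JSON: ", path)

  imgs <- list(); anns <- list(); skipped <- 0L
  for (key in names(doc)) {
    entry <- doc[[key]]
    fname <- entry$filename %||% key
    fa <- entry$file_attributes %||% list()
    w <- as.numeric(fa$width %||% default_size[1])
    h <- as.numeric(fa$height %||% default_size[2])
    imgs[[length(imgs) + 1L]] <- tibble::tibble(image_id = fname, width = w, height = h)
    for (ri in seq_along(entry$regions)) {
      reg <- entry$regions[[ri]]
      sa <- reg$shape_attributes
      if (is.null(sa$name) || sa$name != "circle") {
        skipped <- skipped + 1L
        next
      }
      code_raw <- reg$region_attributes$class
      if (is.null(code_raw)) {
        stop("region ", ri, " of image '", fname, "' has no 'class' attribute")
      }
      code <- suppressWarnings(as.integer(as.character(code_raw)))
      if (is.na(code) || !code %in% 0:2) {
        stop("region ", ri, " of image '", fname, "' has class code '",
             as.character(code_raw), "' outside {0, 1, 2}")
      }
      anns[[length(anns) + 1L]] <- tibble::tibble(
        image_id = fname,
        cx = as.numeric(sa$cx), cy = as.numeric(sa$cy), r = as.numeric(sa$r),
        class_code = code
      )
    }
  }
  if (skipped > 0) {
    warning(skipped, " non-circle region(s) skipped while reading ", path)
  }
  images <- if (length(imgs)) dplyr::bind_rows(imgs) else
    tibble::tibble(image_id = character(), width = numeric(), height = numeric())
  annotations <- if (length(anns)) dplyr::bind_rows(anns) else
    tibble::tibble(image_id = character(), cx = numeric(), cy = numeric(),
                   r = numeric(), class_code = integer())
  set <- annotation_set(images, annotations)
  attr(set, "via_meta") <- list(parsed = nrow(annotations), skipped = skipped)
  set
}

#' Write an annotation set as VIA JSON
#'
#' Emits the VIA v2 export dialect readable by [read_via_annotations()] and
#' by the VIA tool itself. Class codes are always written as strings; keys
#' are written in a canonical order so write–read–write is byte-stable.
#'
#' @param set an [annotation_set()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_via_annotations <- function(set, path) {
  stopifnot(inherits(set, "annotation_set"))
  out <- list()
  imgs <- set$images[order(set$images$image_id), ]
  for (i in seq_len(nrow(imgs))) {
    id <- imgs$image_id[i]
    rows <- set$annotations[set$annotations$image_id == id, , drop = FALSE]
    regions <- lapply(seq_len(nrow(rows)), function(j) {
      list(
        shape_attributes = list(
          name = "circle",
          cx = rows$cx[j], cy = rows$cy[j], r = rows$r[j]
        ),
        region_attributes = list(class = as.character(rows$class_code[j]))
      )
    })
    out[[.via_key(id)]] <- list(
      filename = id,
      size = -1L,
      regions = regions,
      file_attributes = list(width = imgs$width[i], height = imgs$height[i])
    )
  }
  json <- jsonlite::toJSON(out, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  writeLines(json, path)
  invisible(path)
}

#' Split an annotation set into training and test images
#'
#' Images are assigned at random (by image, so annotations travel with
#' their image); the training set holds `round(fraction * N)` images,
#' rounding halves up. The same seed always reproduces the same split.
#'
#' @param set an [annotation_set()].
#' @param fraction training fraction in (0, 1); default 0.75 for the
#'   3:1 train:test regime.
#' @param seed integer RNG seed.
#' @return a list of class `dataset_split` with `train_ids`, `test_ids`,
#'   `fraction`, `seed`, and `train`/`test` annotation subsets.
#' @examples
#' imgs <- tibble::tibble(image_id = paste0("im", 1:4), width = 640, height = 480)
#' anns <- tibble::tibble(image_id = "im1", cx = 50, cy = 50, r = 12,
#'                        label = "normal")
#' split_dataset(annotation_set(imgs, anns), fraction = 0.75, seed = 1)
#' @export
split_dataset <- function(set, fraction = 0.75, seed = 1L) {
  stopifnot(inherits(set, "annotation_set"))
  if (!(fraction > 0 && fraction < 1)) stop("fraction must lie strictly in (0, 1)")
  ids <- set$images$image_id
  n <- length(ids)
  if (n < 2) stop("need at least 2 images to split")
  n_train <- as.integer(round_half_up(fraction * n))
  train_ids <- with_seed(seed, sort(sample(ids, n_train)))
  test_ids <- sort(setdiff(ids, train_ids))
  structure(
    list(
      train_ids = train_ids,
      test_ids = test_ids,
      fraction = fraction,
      seed = as.integer(seed),
      train = subset_annotation_set(set, train_ids),
      test = subset_annotation_set(set, test_ids)
    ),
    class = "dataset_split"
  )
}

#' Subset an annotation set to a set of images
#'
#' @param set an [annotation_set()].
#' @param image_ids image ids to keep.
#' @return an [annotation_set()] restricted to `image_ids`.
#' @export
subset_annotation_set <- function(set, image_ids) {
  annotation_set(
    set$images[set$images$image_id %in% image_ids, , drop = FALSE],
    set$annotations[set$annotations$image_id %in% image_ids, , drop = FALSE]
  )
}

#' @export
print.dataset_split <- function(x, ...) {
  cat("<dataset_split> ", length(x$train_ids), " train / ",
      length(x$test_ids), " test (fraction = ", x$fraction,
      ", seed = ", x$seed, ")\n", sep = "")
  invisible(x)
}
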