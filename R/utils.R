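# Internal helpers: class-code mapping, RNG scoping, image array conventions.
#
# Images are numeric arrays in [0, 1], either H x W (grayscale) or H x W x 3
# (RGB), row = y (downward), column = x (rightward) — the png package layout.
# EBImage stores images transposed (x, y); .as_eb()/.from_eb() convert.

# Fixed label <-> class-code bijection: 0 = severe, 1 = normal, 2 = healthy.
.class_levels <- c("severe", "normal", "healthy")
.class_codes <- c(severe = 0L, normal = 1L, healthy = 2L)

#' Follicle class labels and codes
#'
#' The three follicle states use a fixed integer coding: 0 = severe,
#' 1 = normal, 2 = healthy. These helpers convert between the two
#' representations and validate their input.
#'
#' @param label character vector of labels among `"severe"`, `"normal"`,
#'   `"healthy"`.
#' @param code integer (or string) vector of class codes among 0, 1, 2.
#' @return `class_code()` returns an integer vector; `class_label()` a
#'   character vector; `class_levels()` the three labels ordered by code.
#' @examples
#' class_code(c("healthy", "severe"))
#' class_label(c(0, 2))
#' @export
class_code <- function(label) {
  label <- as.character(label)
  bad <- setdiff(unique(label), .class_levels)
  if (length(bad) > 0) {
    stop("unknown follicle class label(s): ", paste(bad, collapse = ", "))
  }
  unname(.class_codes[label])
}

#' @rdname class_code
#' @export
class_label <- function(code) {
  code <- suppressWarnings(as.integer(as.character(code)))
  if (anyNA(code) || !all(code %in% 0:2)) {
    stop("class codes must be integers in {0, 1, 2}")
  }
  .class_levels[code + 1L]
}

#' @rdname class_code
#' @export
class_levels <- function() .class_levels

# Evaluate `expr` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      },
      add = TRUE
    )
  }
  set.seed(as.integer(seed))
  expr
}

# Derive a substream seed from a base seed and an index, staying within
# 32-bit integer range.
substream_seed <- function(seed, index) {
  as.integer((as.numeric(seed) * 48271 + as.numeric(index) * 69621) %% 2147483647)
}

clamp01 <- function(x) pmin(pmax(x, 0), 1)

# ---- image array <-> EBImage conversions -----------------------------------

.as_eb <- function(img) {
  if (length(dim(img)) == 2L) {
    EBImage::Image(t(img), colormode = "Grayscale")
  } else {
    EBImage::Image(aperm(img, c(2L, 1L, 3L)), colormode = "Color")
  }
}

.from_eb <- function(eb) {
  d <- EBImage::imageData(eb)
  if (length(dim(d)) == 2L) t(d) else aperm(d, c(2L, 1L, 3L))
}

# Luminance (Rec. 601) of an RGB or grayscale array.
to_gray <- function(img) {
  if (length(dim(img)) == 2L) return(img)
  0.299 * img[, , 1] + 0.587 * img[, , 2] + 0.114 * img[, , 3]
}

# Half-up rounding (round() in R is banker's rounding).
round_half_up <- function(x) floor(x + 0.5)

`%||%` <- function(a, b) if (is.null(a)) b else a
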