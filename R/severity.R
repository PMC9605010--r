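# Severity scoring: the per-image weighted label score (PLS), the local
# hair-loss severity index P, and the scalp-level average Pavg.
#
# P is oriented so that higher = healthier: a patch of 45 healthy follicles
# scores 1, a bare patch scores 0.

#' Severity scoring parameters
#'
#' @param alpha per-class weights in the order healthy, normal, severe;
#'   default `c(32, 22, 12)`. Must be strictly decreasing from healthy to
#'   severe so that healthier follicles contribute more. The alternative
#'   preset `"squares"` uses `c(9, 4, 1)` (3^2, 2^2, 1^2).
#' @param beta additive per-follicle weight rewarding follicle density
#'   regardless of class; default 0.
#' @param n_max follicle count at which a patch of all-healthy follicles
#'   saturates the index; default 45, the upper end of the per-image
#'   annotation regime.
#' @return list of class `severity_params`.
#' @export
severity_params <- function(alpha = c(healthy = 32, normal = 22, severe = 12),
                            beta = 0, n_max = 45) {
  if (identical(alpha, "squares")) alpha <- c(healthy = 9, normal = 4, severe = 1)
  alpha <- setNames(as.numeric(alpha), c("healthy", "normal", "severe"))
  if (!(alpha["healthy"] > alpha["normal"] && alpha["normal"] > alpha["severe"])) {
    stop("alpha must be strictly decreasing from healthy to severe")
  }
  if (any(alpha < 0) || beta < 0) stop("alpha and beta must be non-negative")
  if (n_max < 1) stop("n_max must be >= 1")
  structure(list(alpha = alpha, beta = beta, n_max = n_max),
            class = "severity_params")
}

#' Per-image weighted label score (PLS)
#'
#' Sums predicted class codes over follicles. In the `"literal"` variant
#' each follicle's bounding-box area multiplies and divides itself, so the
#' score reduces to the plain sum of class codes; the `"area_weighted"`
#' variant (default) weights each code by its follicle's share of the total
#' bounding-box area, giving the area-normalized reading.
#'
#' @param labels per-follicle predicted labels (characters) or class codes
#'   (0 = severe, 1 = normal, 2 = healthy).
#' @param areas per-follicle bounding-box areas in px^2 (strictly positive;
#'   ignored by the literal variant's value but still validated).
#' @param variant `"area_weighted"` or `"literal"`.
#' @return scalar score.
#' @examples
#' pls_score(c(2, 0), areas = c(300, 100))              # 1.5
#' pls_score(c(2, 1, 0), areas = rep(1, 3), variant = "literal")  # 3
#' @export
pls_score <- function(labels, areas, variant = c("area_weighted", "literal")) {
  variant <- match.arg(variant)
  if (length(labels) == 0) stop("pls_score needs at least one follicle")
  codes <- if (is.character(labels) || is.factor(labels)) {
    class_code(as.character(labels))
  } else {
    as.numeric(labels)
  }
  if (!all(codes %in% 0:2)) stop("labels must be class codes in {0, 1, 2}")
  stopifnot(length(areas) == length(labels))
  if (any(areas <= 0)) stop("bounding-box areas must be strictly positive")
  switch(variant,
    literal = sum(codes),
    area_weighted = sum(codes * areas) / sum(areas)
  )
}

#' Local hair-loss severity index P for one scalp patch
#'
#' Computes the weighted count score `S = sum_i n_i * (alpha_i + beta)` over
#' the three classes and normalizes it to `[0, 1]` against the fixed scale
#' `S_max = n_max * (alpha_healthy + beta)` (the score of a patch holding
#' `n_max` healthy follicles), clamping at 1. A fixed scale keeps P
#' comparable across patches and subjects. Higher P = healthier.
#'
#' @param counts named counts for `healthy`, `normal`, `severe` (missing
#'   names count as 0), or a data frame with a `label` column whose rows
#'   are tallied.
#' @param params a [severity_params()].
#' @param k optional region/image index carried into the result.
#' @return one-row tibble with `k`, `n_healthy`, `n_normal`, `n_severe`,
#'   `s` (raw score) and `p` (normalized index).
#' @examples
#' local_severity_index(c(healthy = 5, normal = 3, severe = 2),
#'                      severity_params(n_max = 10))
#' @export
local_severity_index <- function(counts, params = severity_params(), k = NA) {
  stopifnot(inherits(params, "severity_params"))
  if (is.data.frame(counts)) {
    counts <- table(factor(counts$label, levels = class_levels()))
  }
  full <- setNames(numeric(3), c("healthy", "normal", "severe"))
  counts <- unlist(counts)
  if (is.null(names(counts)) && length(counts) == 3) {
    names(counts) <- c("healthy", "normal", "severe")
  }
  bad <- setdiff(names(counts), names(full))
  if (length(bad) > 0) stop("unknown class name(s): ", paste(bad, collapse = ", "))
  full[names(counts)] <- as.numeric(counts)
  if (any(full < 0)) stop("class counts must be non-negative")

  s <- sum(full * (params$alpha[names(full)] + params$beta))
  s_max <- params$n_max * (params$alpha["healthy"] + params$beta)
  p <- min(1, s / s_max)
  tibble::tibble(
    k = k,
    n_healthy = full[["healthy"]], n_normal = full[["normal"]],
    n_severe = full[["severe"]],
    s = s, p = p
  )
}

#' Severity index for every image in a label table
#'
#' Tidy wrapper around [local_severity_index()]: tallies per-image class
#' counts and scores each image.
#'
#' @param labels data frame with columns `image_id` and `label`.
#' @param params a [severity_params()].
#' @return tibble with one row per image (`k` = image_id).
#' @export
severity_by_image <- function(labels, params = severity_params()) {
  stopifnot(all(c("image_id", "label") %in% names(labels)))
  purrr::map_dfr(split(labels, labels$image_id), function(df) {
    local_severity_index(df, params, k = df$image_id[1])
  })
}

#' Scalp-level severity estimate Pavg
#'
#' Arithmetic mean of local severity indices; the scalp protocol uses 12
#' regions, and any other count is accepted with a warning.
#'
#' @param p_values numeric vector of local indices in `[0, 1]`.
#' @param expected_m expected number of regions (default 12).
#' @return scalar mean in `[0, 1]`.
#' @export
average_severity <- function(p_values, expected_m = 12) {
  if (length(p_values) == 0) stop("need at least one local severity index")
  if (any(p_values < 0 | p_values > 1)) stop("P values must lie in [0, 1]")
  if (length(p_values) != expected_m) {
    warning("averaging ", length(p_values), " regions (protocol uses ",
            expected_m, ")")
  }
  mean(p_values)
}
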