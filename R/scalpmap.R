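# Scalp-level assembly: 12 regional severity indices on a top-view scalp
# ellipse, their mean Pavg, and a deterministic rendered heatmap.
#
# The heatmap raster is drawn directly into a numeric RGB array (no
# graphics device), so identical inputs give byte-identical PNGs.

#' The 12-region scalp layout
#'
#' Three columns (left, center, right) by four rows (1 = anterior to
#' 4 = posterior), placed on a top-view unit ellipse at u in
#' \{-0.45, 0, 0.45\} and v in \{-0.6, -0.2, 0.2, 0.6\}.
#'
#' @return tibble with columns `region`, `side`, `row`, `u`, `v`.
#' @export
scalp_layout <- function() {
  grid <- expand.grid(row = 1:4, side = c("left", "center", "right"),
                      stringsAsFactors = FALSE)
  u <- c(left = -0.45, center = 0, right = 0.45)
  v <- c(-0.6, -0.2, 0.2, 0.6)
  tibble::tibble(
    region = paste0(grid$side, "_", grid$row),
    side = grid$side,
    row = grid$row,
    u = unname(u[grid$side]),
    v = v[grid$row]
  )
}

#' Assemble 12 regional severity results into a scalp map
#'
#' @param results data frame with columns `region` and `p` (one row per
#'   region; exactly the 12 regions of [scalp_layout()], each once), or a
#'   named numeric vector of P values keyed by region.
#' @return object of class `scalp_severity_map`: layout tibble joined with
#'   P values, plus `pavg`.
#' @examples
#' res <- tibble::tibble(region = scalp_layout()$region, p = 0.5)
#' assemble_scalp_map(res)
#' @export
assemble_scalp_map <- function(results) {
  if (is.numeric(results) && !is.null(names(results))) {
    results <- tibble::tibble(region = names(results), p = unname(results))
  }
  stopifnot(all(c("region", "p") %in% names(results)))
  layout <- scalp_layout()
  missing <- setdiff(layout$region, results$region)
  if (length(missing) > 0) {
    stop("missing region(s): ", paste(missing, collapse = ", "))
  }
  extra <- setdiff(results$region, layout$region)
  if (length(extra) > 0) {
    stop("unknown region(s): ", paste(extra, collapse = ", "))
  }
  dup <- unique(results$region[duplicated(results$region)])
  if (length(dup) > 0) {
    stop("duplicate region(s): ", paste(dup, collapse = ", "))
  }
  if (any(results$p < 0 | results$p > 1)) stop("P values must lie in [0, 1]")
  regions <- dplyr::left_join(layout, results[, c("region", "p")], by = "region")
  structure(
    list(regions = regions, pavg = average_severity(regions$p)),
    class = "scalp_severity_map"
  )
}

#' @export
print.scalp_severity_map <- function(x, ...) {
  cat("<scalp_severity_map> Pavg =", format(x$pavg, digits = 4), "\n")
  print(x$regions[, c("region", "p")], n = 12)
  invisible(x)
}

#' @export
tidy.scalp_severity_map <- function(x, ...) x$regions

#' @export
glance.scalp_severity_map <- function(x, ...) {
  tibble::tibble(pavg = x$pavg, m = nrow(x$regions),
                 p_min = min(x$regions$p), p_max = max(x$regions$p))
}

# Red-yellow-green severity colormap: P = 0 (bare/severe) -> red,
# P = 1 (healthy) -> green. Returns an n x 3 matrix in [0, 1].
severity_colormap <- function(p) {
  stops <- rbind(c(0.839, 0.157, 0.157),   # red
                 c(0.992, 0.878, 0.545),   # yellow
                 c(0.102, 0.596, 0.314))   # green
  p <- clamp01(p)
  t <- p * 2
  lo <- pmin(floor(t), 1) + 1
  frac <- t - (lo - 1)
  out <- stops[lo, , drop = FALSE] * (1 - frac) +
    stops[pmin(lo + 1, 3), , drop = FALSE] * frac
  out
}

# ---- minimal 3x5 bitmap font for in-raster labels ---------------------------

.glyphs <- list(
  "0" = c("111", "101", "101", "101", "111"),
  "1" = c("010", "110", "010", "010", "111"),
  "2" = c("111", "001", "111", "100", "111"),
  "3" = c("111", "001", "111", "001", "111"),
  "4" = c("101", "101", "111", "001", "001"),
  "5" = c("111", "100", "111", "001", "111"),
  "6" = c("111", "100", "111", "101", "111"),
  "7" = c("111", "001", "001", "010", "010"),
  "8" = c("111", "101", "111", "101", "111"),
  "9" = c("111", "101", "111", "001", "111"),
  "." = c("000", "000", "000", "000", "010"),
  "=" = c("000", "111", "000", "111", "000"),
  "P" = c("111", "101", "111", "100", "100"),
  "a" = c("000", "011", "101", "101", "011"),
  "v" = c("000", "101", "101", "101", "010"),
  "g" = c("011", "101", "011", "001", "110"),
  " " = c("000", "000", "000", "000", "000")
)

# Stamp `text` into the RGB array at (row0, col0), scaled by `scale`.
.stamp_text <- function(img, text, row0, col0, scale = 2, col = c(0.1, 0.1, 0.1)) {
  chars <- strsplit(text, "")[[1]]
  x <- col0
  for (ch in chars) {
    g <- .glyphs[[ch]] %||% .glyphs[[" "]]
    for (gy in 1:5) {
      bits <- strsplit(g[gy], "")[[1]] == "1"
      for (gx in 1:3) {
        if (!bits[gx]) next
        rr <- row0 + (gy - 1) * scale + seq_len(scale) - 1
        cc <- x + (gx - 1) * scale + seq_len(scale) - 1
        rr <- rr[rr >= 1 & rr <= dim(img)[1]]
        cc <- cc[cc >= 1 & cc <= dim(img)[2]]
        for (k in 1:3) img[rr, cc, k] <- col[k]
      }
    }
    x <- x + 4 * scale
  }
  img
}

#' Render a scalp severity heatmap raster
#'
#' Draws the 12-region map on an ellipse-masked top view. In `"rbf"` mode
#' the P field is smoothed between region centers with a Gaussian
#' radial-basis weighted average; `"nearest"` colors each pixel by its
#' nearest region's P (block mode). A vertical color bar and the Pavg value
#' are drawn in the right margin. Rendering is a pure function of its
#' arguments: identical calls give identical rasters.
#'
#' @param map a [assemble_scalp_map()] result.
#' @param width,height raster size in pixels.
#' @param smoothing `"rbf"` or `"nearest"`.
#' @param bandwidth Gaussian RBF bandwidth in normalized ellipse units.
#' @param path optional PNG output path.
#' @return H x W x 3 numeric array in `[0, 1]` (invisibly written to
#'   `path` if given).
#' @export
render_heatmap <- function(map, width = 360, height = 400,
                           smoothing = c("rbf", "nearest"),
                           bandwidth = 0.35, path = NULL) {
  stopifnot(inherits(map, "scalp_severity_map"))
  smoothing <- match.arg(smoothing)
  margin <- 70  # right margin for color bar + label
  img <- array(1, dim = c(height, width + margin, 3))

  # normalized coordinates over the scalp panel
  us <- ((seq_len(width) - 0.5) / width) * 2 - 1
  vs <- ((seq_len(height) - 0.5) / height) * 2 - 1
  gu <- matrix(us, nrow = height, ncol = width, byrow = TRUE)
  gv <- matrix(vs, nrow = height, ncol = width)
  inside <- (gu / 0.85)^2 + (gv / 0.95)^2 <= 1

  cen <- map$regions
  if (smoothing == "rbf") {
    wsum <- matrix(0, height, width)
    vsum <- matrix(0, height, width)
    for (i in seq_len(nrow(cen))) {
      w <- exp(-((gu - cen$u[i])^2 + (gv - cen$v[i])^2) / (2 * bandwidth^2))
      wsum <- wsum + w
      vsum <- vsum + w * cen$p[i]
    }
    field <- vsum / wsum
  } else {
    field <- matrix(0, height, width)
    best <- matrix(Inf, height, width)
    for (i in seq_len(nrow(cen))) {
      d2 <- (gu - cen$u[i])^2 + (gv - cen$v[i])^2
      hit <- d2 < best
      best[hit] <- d2[hit]
      field[hit] <- cen$p[i]
    }
  }

  cols <- severity_colormap(as.vector(field))
  for (k in 1:3) {
    plane <- img[, seq_len(width), k]
    plane[inside] <- matrix(cols[, k], height, width)[inside]
    img[, seq_len(width), k] <- plane
  }
  # ellipse outline
  ring <- abs(sqrt((gu / 0.85)^2 + (gv / 0.95)^2) - 1) < 0.01
  for (k in 1:3) {
    plane <- img[, seq_len(width), k]
    plane[ring] <- 0.2
    img[, seq_len(width), k] <- plane
  }

  # color bar in the margin (top P=1 -> bottom P=0)
  bar_rows <- seq.int(20, height - 60)
  bar_cols <- width + seq.int(20, 40)
  bar_p <- rev((seq_along(bar_rows) - 0.5) / length(bar_rows))
  bar_cols_mat <- severity_colormap(bar_p)
  for (k in 1:3) {
    img[bar_rows, bar_cols, k] <-
      matrix(bar_cols_mat[, k], length(bar_rows), length(bar_cols))
  }
  img <- .stamp_text(img, "1", 14, width + 46, scale = 2)
  img <- .stamp_text(img, "0", height - 66, width + 46, scale = 2)
  img <- .stamp_text(img, sprintf("Pavg=%.3f", map$pavg),
                     height - 40, width + 4, scale = 2)

  if (!is.null(path)) {
    png::writePNG(img, path)
  }
  invisible(img)
}

#' Plot a scalp severity map
#'
#' ggplot2 rendering of the 12-region map: tiles at the region centers on
#' the scalp ellipse, colored by P, annotated with Pavg.
#'
#' @param object a [assemble_scalp_map()] result.
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.scalp_severity_map <- function(object, ...) {
  ell <- tibble::tibble(
    t = seq(0, 2 * pi, length.out = 200),
    u = 0.85 * cos(.data$t), v = 0.95 * sin(.data$t)
  )
  ggplot2::ggplot(object$regions, ggplot2::aes(x = .data$u, y = -.data$v)) +
    ggplot2::geom_path(data = ell, ggplot2::aes(x = .data$u, y = -.data$v),
                       inherit.aes = FALSE, color = "grey40") +
    ggplot2::geom_tile(ggplot2::aes(fill = .data$p), width = 0.42, height = 0.36) +
    ggplot2::geom_text(ggplot2::aes(label = sprintf("%.2f", .data$p)), size = 3) +
    ggplot2::scale_fill_gradientn(
      colors = c("#d62828", "#fde08b", "#1a9850"),
      limits = c(0, 1), name = "P"
    ) +
    ggplot2::coord_equal() +
    ggplot2::labs(
      title = sprintf("Scalp severity map (Pavg = %.3f)", object$pavg),
      x = NULL, y = NULL
    ) +
    ggplot2::theme_void() +
    ggplot2::theme(plot.title = ggplot2::element_text(hjust = 0.5))
}
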