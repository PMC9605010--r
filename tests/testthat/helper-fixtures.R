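# Shared fixtures, all generated in code.

# Small annotation set: n images, k annotations each, deterministic.
make_annotation_set <- function(n_images = 3, per_image = 2, seed = 1) {
  withr::with_seed(seed, {
    images <- tibble::tibble(
      image_id = sprintf("img_%03d.png", seq_len(n_images)),
      width = 640, height = 480
    )
    anns <- do.call(rbind, lapply(images$image_id, function(id) {
      tibble::tibble(
        image_id = id,
        cx = runif(per_image, 40, 600),
        cy = runif(per_image, 40, 440),
        r = runif(per_image, 5, 30),
        label = sample(class_levels(), per_image, replace = TRUE)
      )
    }))
    annotation_set(images, anns)
  })
}

# One hand-built follicle with fully controlled attributes, placed at
# (cx, cy); renderable by render_scalp_image().
make_follicle <- function(label, r, thickness, count = 1,
                          cx = 100, cy = 100,
                          angles = seq(0, by = 2.2, length.out = count),
                          length_factor = 1.3) {
  tibble::tibble(
    label = label, r = r, hair_count = as.integer(count),
    hair_thickness = thickness,
    angles = list(angles),
    lengths = list(rep(length_factor * r, count)),
    curvatures = list(rep(0.05, count)),
    cx = cx, cy = cy
  )
}

small_config <- function(...) {
  sim_config(image_size = c(240, 240), follicles_per_image = c(3, 6), ...)
}

# Independent strand-crossing counter: walk the circle of radius `r0`
# around (cx, cy) at fine angular steps and count circular runs of dark
# pixels. Used as an oracle against the feature extractor.
count_dark_crossings <- function(img, cx, cy, r0, threshold = 0.3) {
  gray <- 0.299 * img[, , 1] + 0.587 * img[, , 2] + 0.114 * img[, , 3]
  th <- seq(0, 2 * pi, length.out = 2000)[-1]
  xs <- pmin(pmax(cx + r0 * cos(th), 0.51), ncol(gray) - 0.51)
  ys <- pmin(pmax(cy + r0 * sin(th), 0.51), nrow(gray) - 0.51)
  dark <- gray[cbind(round(ys + 0.5), round(xs + 0.5))] < threshold
  runs <- sum(dark & !c(dark[length(dark)], dark[-length(dark)]))
  runs
}
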