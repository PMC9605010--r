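test_that("class code <-> label mapping is the fixed bijection", {
  expect_equal(class_code(c("severe", "normal", "healthy")), c(0L, 1L, 2L))
  expect_equal(class_label(0:2), c("severe", "normal", "healthy"))
  expect_equal(class_label(class_code(class_levels())), class_levels())
  expect_error(class_code("bald"), "unknown")
  expect_error(class_label(3), "0, 1, 2")
})

test_that("annotation_set validates geometry and flags border circles", {
  imgs <- tibble::tibble(image_id = "a.png", width = 100, height = 100)
  anns <- tibble::tibble(image_id = "a.png",
                         cx = c(50, 95), cy = c(50, 50), r = c(10, 10),
                         label = c("normal", "severe"))
  set <- annotation_set(imgs, anns)
  expect_equal(set$annotations$at_border, c(FALSE, TRUE))
  expect_equal(set$annotations$r, c(10, 10))  # kept unclipped
  expect_error(
    annotation_set(imgs, transform(anns, image_id = "missing.png")),
    "unknown image_id"
  )
  expect_error(annotation_set(imgs, transform(anns, r = c(10, -1))), "positive")
})

test_that("VIA circle regions map to annotations field by field", {
  via <- list(
    "scalp1.png-1" = list(
      filename = "scalp1.png", size = -1,
      regions = list(
        list(shape_attributes = list(name = "circle", cx = 100, cy = 80, r = 15),
             region_attributes = list(class = "2"))
      ),
      file_attributes = list(width = 640, height = 480)
    )
  )
  path <- withr::local_tempfile(fileext = ".json")
  writeLines(jsonlite::toJSON(via, auto_unbox = TRUE), path)
  set <- read_via_annotations(path)
  ann <- set$annotations
  expect_equal(nrow(ann), 1)
  expect_equal(ann$cx, 100)
  expect_equal(ann$cy, 80)
  expect_equal(ann$r, 15)
  expect_equal(ann$label, "healthy")
  expect_equal(attr(set, "via_meta")$skipped, 0)
})

test_that("non-circle regions are skipped with a warning; bad codes error", {
  via <- list(
    "x.png-1" = list(
      filename = "x.png", size = -1,
      regions = list(
        list(shape_attributes = list(name = "circle", cx = 10, cy = 10, r = 5),
             region_attributes = list(class = 1)),
        list(shape_attributes = list(name = "polygon",
                                     all_points_x = c(1, 2, 3),
                                     all_points_y = c(1, 2, 3)),
             region_attributes = list(class = "0"))
      ),
      file_attributes = list(width = 64, height = 64)
    )
  )
  path <- withr::local_tempfile(fileext = ".json")
  writeLines(jsonlite::toJSON(via, auto_unbox = TRUE), path)
  expect_warning(set <- read_via_annotations(path), "skipped")
  expect_equal(nrow(set$annotations), 1)
  expect_equal(attr(set, "via_meta")$skipped, 1)

  via[["x.png-1"]]$regions[[1]]$region_attributes$class <- "7"
  writeLines(jsonlite::toJSON(via, auto_unbox = TRUE), path)
  expect_error(suppressWarnings(read_via_annotations(path)), "outside \\{0, 1, 2\\}")
})

test_that("VIA round-trip is lossless for circles and class codes", {
  for (seed in 1:5) {
    set <- make_annotation_set(n_images = 4, per_image = 3, seed = seed)
    path <- withr::local_tempfile(fileext = ".json")
    write_via_annotations(set, path)
    back <- read_via_annotations(path)
    ord0 <- order(set$annotations$image_id, set$annotations$cx)
    ord1 <- order(back$annotations$image_id, back$annotations$cx)
    expect_equal(back$annotations[ord1, ], set$annotations[ord0, ],
                 ignore_attr = TRUE)
    expect_equal(back$images[order(back$images$image_id), ],
                 set$images[order(set$images$image_id), ],
                 ignore_attr = TRUE)
  }
})

test_that("write -> read -> write is byte-identical", {
  set <- make_annotation_set(seed = 11)
  p1 <- withr::local_tempfile(fileext = ".json")
  p2 <- withr::local_tempfile(fileext = ".json")
  write_via_annotations(set, p1)
  write_via_annotations(read_via_annotations(p1), p2)
  expect_identical(readLines(p1), readLines(p2))
})

test_that("empty annotation set writes valid JSON with zero regions", {
  set <- annotation_set(
    tibble::tibble(image_id = "e.png", width = 10, height = 10),
    tibble::tibble(image_id = character(), cx = numeric(), cy = numeric(),
                   r = numeric(), label = character())
  )
  path <- withr::local_tempfile(fileext = ".json")
  write_via_annotations(set, path)
  back <- read_via_annotations(path)
  expect_equal(nrow(back$annotations), 0)
})

test_that("dataset split is a seeded partition obeying half-up rounding", {
  set <- make_annotation_set(n_images = 4, per_image = 1, seed = 2)
  sp <- split_dataset(set, 0.75, seed = 7)
  expect_length(sp$train_ids, 3)
  expect_length(sp$test_ids, 1)
  expect_length(intersect(sp$train_ids, sp$test_ids), 0)
  expect_setequal(c(sp$train_ids, sp$test_ids), set$images$image_id)
  # annotations travel with their images
  expect_setequal(unique(sp$train$annotations$image_id), sp$train_ids)

  sp2 <- split_dataset(set, 0.75, seed = 7)
  expect_identical(sp$train_ids, sp2$train_ids)
  sp3 <- split_dataset(set, 0.75, seed = 8)
  expect_false(identical(sp$train_ids, sp3$train_ids) &&
                 identical(sp, sp3))

  expect_error(split_dataset(set, 1.2, seed = 1), "fraction")
  one <- subset_annotation_set(set, set$images$image_id[1])
  expect_error(split_dataset(one, 0.75, seed = 1), "at least 2")
})

test_that("train size equals round(fraction * N) for every N up to 1000", {
  # formula check against an independent rounding oracle, exhaustive in N
  frac <- 0.75
  for (n in 2:1000) {
    ids <- sprintf("i%04d", seq_len(n))
    images <- tibble::tibble(image_id = ids, width = 10, height = 10)
    set <- annotation_set(images, tibble::tibble(
      image_id = character(), cx = numeric(), cy = numeric(),
      r = numeric(), label = character()
    ))
    sp <- split_dataset(set, frac, seed = n)
    expected <- floor(frac * n + 0.5)
    expect_length(sp$train_ids, expected)
    expect_length(sp$test_ids, n - expected)
  }
})
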