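test_that("bounding boxes follow the width/height/area identities", {
  bb <- bbox_from_circle(circle(100, 100, 10))
  expect_equal(unlist(bb), c(x1 = 90, y1 = 90, x2 = 110, y2 = 110,
                             l_width = 20, l_height = 20, area = 400))
  expect_equal(bbox_from_circle(circle(0, 0, 1))$area, 4)
  withr::with_seed(8, {
    cs <- tibble::tibble(cx = runif(50, -100, 100), cy = runif(50, -100, 100),
                         r = runif(50, 0.1, 50))
    bb <- bbox_from_circle(cs)
    expect_equal(bb$area, 4 * cs$r^2)
    expect_equal(bb$x2 - bb$x1, bb$l_width)
    expect_equal(bb$y2 - bb$y1, bb$l_height)
  })
})

test_that("feature triples inside one band classify to that band's class", {
  cases <- tibble::tibble(
    radius = c(8, 15, 25), hair_count = c(1L, 1L, 2L),
    hair_thickness = c(2, 4, 7),
    expected = c("severe", "normal", "healthy")
  )
  expect_equal(rule_classify(cases), cases$expected)

  # exhaustive grid over band interiors
  grids <- list(
    severe = expand.grid(radius = seq(4.1, 9.9, length.out = 7),
                         hair_count = 1L,
                         hair_thickness = seq(1.1, 2.9, length.out = 7)),
    normal = expand.grid(radius = seq(10.1, 19.9, length.out = 7),
                         hair_count = 1L,
                         hair_thickness = seq(3.1, 5.9, length.out = 7)),
    healthy = expand.grid(radius = seq(20.1, 32, length.out = 7),
                          hair_count = 2:3,
                          hair_thickness = seq(6.1, 10, length.out = 7))
  )
  for (lab in names(grids)) {
    expect_true(all(rule_classify(tibble::as_tibble(grids[[lab]])) == lab),
                label = paste("band interior:", lab))
  }
})

test_that("conflicting features resolve by majority with severe-ward ties", {
  # radius healthy + thickness healthy + count split -> healthy
  expect_equal(rule_classify(tibble::tibble(
    radius = 25, hair_count = 1L, hair_thickness = 7)), "healthy")
  # radius severe + thickness normal + count split -> 1.5 vs 1.5 tie -> severe
  expect_equal(rule_classify(tibble::tibble(
    radius = 8, hair_count = 1L, hair_thickness = 4)), "severe")
  # boundary values flag the more severe class
  expect_equal(rule_classify(tibble::tibble(
    radius = 10, hair_count = 1L, hair_thickness = 3)), "severe")
  expect_equal(rule_classify(tibble::tibble(
    radius = 20, hair_count = 2L, hair_thickness = 6)), "healthy")
  # no visible hair is at least as severe as one thin hair
  expect_equal(rule_classify(tibble::tibble(
    radius = 8, hair_count = 0L, hair_thickness = 0)), "severe")
})

test_that("strict mode labels only unanimous cases", {
  f <- tibble::tibble(radius = c(8, 8), hair_count = c(1L, 2L),
                      hair_thickness = c(2, 2))
  expect_equal(rule_classify(f, mode = "strict"),
               c("severe", "indeterminate"))
})

test_that("classification is monotone: larger features never more severe", {
  sev_rank <- c(severe = 0, normal = 1, healthy = 2)
  withr::with_seed(13, {
    for (i in 1:200) {
      f <- tibble::tibble(radius = runif(1, 1, 35),
                          hair_count = sample(0:4, 1),
                          hair_thickness = runif(1, 0, 12))
      base <- sev_rank[rule_classify(f)]
      for (col in names(f)) {
        g <- f
        g[[col]] <- g[[col]] + if (col == "hair_count") 1L else runif(1, 0, 5)
        expect_gte(sev_rank[rule_classify(g)], base)
      }
    }
  })
})

test_that("features measured on rendered follicles match ground truth", {
  cfg <- small_config()
  # severe: r = 8, one strand of width 2
  f <- make_follicle("severe", r = 8, thickness = 2, cx = 120, cy = 120)
  out <- render_scalp_image(f, cfg, seed = 71)
  ft <- extract_features(out$image, tibble::tibble(cx = 120, cy = 120, r = 8))
  expect_equal(ft$radius, 8)
  expect_equal(ft$hair_count, 1L)
  expect_lt(abs(ft$hair_thickness - 2), 1)

  # healthy: two strands of width 7
  f <- make_follicle("healthy", r = 24, thickness = 7, count = 2,
                     cx = 120, cy = 120)
  out <- render_scalp_image(f, cfg, seed = 72)
  ft <- extract_features(out$image, tibble::tibble(cx = 120, cy = 120, r = 24))
  expect_equal(ft$hair_count, 2L)
  expect_lt(abs(ft$hair_thickness - 7), 1)
})

test_that("a follicle disk with no strands measures zero hairs", {
  cfg <- small_config()
  f <- make_follicle("severe", r = 8, thickness = 2, count = 0,
                     cx = 120, cy = 120)
  f$angles <- list(numeric()); f$lengths <- list(numeric())
  f$curvatures <- list(numeric())
  out <- render_scalp_image(f, cfg, seed = 73)
  ft <- extract_features(out$image, tibble::tibble(cx = 120, cy = 120, r = 8))
  expect_equal(ft$hair_count, 0L)
  expect_equal(ft$hair_thickness, 0)
})

test_that("skeletonization thins a thick bar to a one-pixel path", {
  mask <- matrix(FALSE, 20, 40)
  mask[9:13, 5:35] <- TRUE
  sk <- skeletonize(mask)
  expect_true(all(colSums(sk[, 8:32]) <= 2))
  expect_true(sum(sk) >= 25)
  expect_true(all(which(sk, arr.ind = TRUE)[, 1] %in% 9:13))
})

test_that("rule thresholds validate their ordering", {
  expect_error(rule_thresholds(severe_r_max = 25), "severe_r_max")
  expect_error(rule_thresholds(severe_t_max = 8), "severe_t_max")
})
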