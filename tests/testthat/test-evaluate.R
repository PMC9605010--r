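# Independent AP oracle: each true positive at rank i contributes
# (1 / n_truth) times the maximum precision at rank i or later (brute-force
# per-point maxima, no envelope recursion).
ap_oracle <- function(scores, is_tp, n_truth) {
  ord <- order(-scores)
  hit <- is_tp[ord]
  prec <- cumsum(hit) / seq_along(hit)
  contrib <- vapply(which(hit), function(i) max(prec[i:length(prec)]),
                    numeric(1))
  sum(contrib) / n_truth
}

test_that("circle IoU matches the closed-form lens area", {
  expect_equal(circle_iou(circle(5, 5, 3), circle(5, 5, 3)), 1)
  expect_equal(circle_iou(circle(0, 0, 1), circle(3, 0, 1)), 0)
  # two unit circles, centers one radius apart
  expect_equal(circle_iou(circle(0, 0, 1), circle(1, 0, 1)), 0.2430,
               tolerance = 1e-4)
  # concentric containment: ratio of areas
  expect_equal(circle_iou(circle(0, 0, 2), circle(0, 0, 1)), 0.25)
})

test_that("circle IoU is symmetric and scale invariant", {
  withr::with_seed(31, {
    for (i in 1:50) {
      a <- circle(runif(1, 0, 50), runif(1, 0, 50), runif(1, 1, 20))
      b <- circle(runif(1, 0, 50), runif(1, 0, 50), runif(1, 1, 20))
      expect_equal(circle_iou(a, b), circle_iou(b, a), tolerance = 1e-12)
      s <- runif(1, 0.5, 4)
      a2 <- circle(a$cx * s, a$cy * s, a$r * s)
      b2 <- circle(b$cx * s, b$cy * s, b$r * s)
      expect_equal(circle_iou(a, b), circle_iou(a2, b2), tolerance = 1e-9)
    }
  })
})

test_that("closed-form IoU agrees with the raster estimate", {
  withr::with_seed(32, {
    for (i in 1:40) {
      a <- circle(runif(1, 20, 60), runif(1, 20, 60), runif(1, 5, 25))
      b <- circle(a$cx + runif(1, -20, 20), a$cy + runif(1, -20, 20),
                  runif(1, 5, 25))
      expect_equal(circle_iou(a, b), circle_iou_raster(a, b),
                   tolerance = 0.01)
    }
  })
})

test_that("greedy matching follows the score order and the IoU gate", {
  truth <- tibble::tibble(cx = 50, cy = 50, r = 10)
  det <- tibble::tibble(cx = 51, cy = 50, r = 10, score = 0.9)
  m <- match_detections(det, truth, tau = 0.5)
  expect_equal(nrow(m$pairs), 1)
  expect_length(m$fp_index, 0)
  expect_length(m$fn_index, 0)

  m2 <- match_detections(det, truth[0, ], tau = 0.5)
  expect_equal(nrow(m2$pairs), 0)
  expect_equal(m2$fp_index, 1)

  # two detections on one truth: the higher score wins, the other is FP
  dets <- tibble::tibble(cx = c(52, 50), cy = 50, r = 10,
                         score = c(0.7, 0.95))
  m3 <- match_detections(dets, truth, tau = 0.5)
  expect_equal(m3$pairs$det_index, 2)
  expect_equal(m3$fp_index, 1)

  # each truth matched at most once even with many detections
  truths <- tibble::tibble(cx = c(30, 60), cy = 50, r = 8)
  dets <- tibble::tibble(cx = c(30, 31, 60), cy = 50, r = 8,
                         score = c(0.9, 0.8, 0.7))
  m4 <- match_detections(dets, truths, tau = 0.5)
  expect_equal(sort(m4$pairs$truth_index), 1:2)
  expect_equal(m4$fp_index, 2)
})

test_that("AP reproduces hand-traced precision-recall areas", {
  # perfect retrieval
  expect_equal(average_precision(c(0.9, 0.8), c(TRUE, TRUE), 2), 1)
  # no detections at all
  expect_equal(average_precision(numeric(), logical(), 3), 0)
  # TP, FP, TP over two truths -> all-point area 5/6
  expect_equal(average_precision(c(0.9, 0.8, 0.7), c(TRUE, FALSE, TRUE), 2),
               5 / 6, tolerance = 1e-12)
  expect_error(average_precision(0.5, TRUE, 0), "undefined")
})

test_that("AP equals the envelope-integration oracle on all small instances", {
  for (n in 1:6) {
    scores <- seq(0.95, by = -0.1, length.out = n)
    flag_grid <- expand.grid(rep(list(c(FALSE, TRUE)), n))
    for (row in seq_len(nrow(flag_grid))) {
      flags <- unlist(flag_grid[row, ])
      n_truth <- max(1, sum(flags))
      expect_equal(
        average_precision(scores, flags, n_truth),
        ap_oracle(scores, flags, n_truth),
        tolerance = 1e-12
      )
    }
  }
})

test_that("mAP reaches 1 when detections equal the truth", {
  set <- make_annotation_set(n_images = 2, per_image = 4, seed = 51)
  truths <- set$annotations
  dets <- truths
  dets$score <- 0.9
  res <- mean_ap(dets, truths)
  expect_equal(res$mAP50, 1)
  expect_equal(res$mAP75, 1)
  expect_equal(res$mAP, 1)
})

test_that("per-class metrics follow one-vs-rest definitions", {
  cm <- confusion_matrix(rep(class_levels(), each = 2),
                         rep(class_levels(), each = 2))
  met <- classification_metrics(cm)
  expect_true(all(met$per_class$precision == 1))
  expect_true(all(met$per_class$recall == 1))
  expect_equal(met$accuracy, 1)

  # uniform confusion: accuracy 1/3
  lv <- class_levels()
  truth <- rep(lv, each = 3)
  pred <- rep(lv, times = 3)
  expect_equal(classification_metrics(confusion_matrix(truth, pred))$accuracy,
               1 / 3)

  # hand-counted matrix [[8,2,0],[1,7,2],[0,3,7]]
  counts <- matrix(c(8, 2, 0, 1, 7, 2, 0, 3, 7), 3, byrow = TRUE)
  truth <- rep(lv, times = rowSums(counts))
  pred <- unlist(lapply(1:3, function(i) rep(lv, times = counts[i, ])))
  cm <- confusion_matrix(truth, pred)
  expect_equal(cm$counts, matrix(as.integer(counts), 3,
                                 dimnames = list(true = lv, predicted = lv)))
  expect_equal(classification_metrics(cm)$accuracy, 22 / 30)
})

test_that("row-normalized rows sum to one for non-empty classes", {
  cm <- confusion_matrix(c("severe", "severe", "normal"),
                         c("severe", "normal", "normal"))
  sums <- rowSums(cm$row_normalized)
  expect_equal(sums[["severe"]], 1)
  expect_equal(sums[["normal"]], 1)
  expect_equal(cm$support[["healthy"]], 0)
})

test_that("the weighted misclassification rate is the support-weighted mean", {
  expect_equal(weighted_misclassification_rate(c(0, 0, 0), c(5, 5, 5)), 0)
  expect_equal(weighted_misclassification_rate(c(0.5, 0.1), c(10, 30)), 0.2)
  expect_error(weighted_misclassification_rate(c(1.2, 0), c(1, 1)), "\\[0, 1\\]")
  expect_error(weighted_misclassification_rate(c(0.1), c(0)), "positive")
})

test_that("weighted misclassification equals 1 - accuracy on shared data", {
  withr::with_seed(61, {
    for (i in 1:20) {
      n <- 60
      truth <- sample(class_levels(), n, replace = TRUE)
      pred <- ifelse(runif(n) < 0.7, truth,
                     sample(class_levels(), n, replace = TRUE))
      cm <- confusion_matrix(truth, pred)
      present <- cm$support > 0
      err <- (1 - diag(cm$row_normalized))[present]
      rate <- weighted_misclassification_rate(err, cm$support[present])
      expect_equal(rate, 1 - classification_metrics(cm)$accuracy,
                   tolerance = 1e-12)
    }
  })
})

test_that("tidy/glance/autoplot methods summarize a confusion matrix", {
  cm <- confusion_matrix(c("severe", "normal", "healthy", "healthy"),
                         c("severe", "normal", "normal", "healthy"))
  expect_equal(nrow(tidy(cm)), 3)
  g <- glance(cm)
  expect_equal(g$accuracy, 0.75)
  expect_equal(g$n, 4)
  expect_s3_class(autoplot(cm), "ggplot")
})
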