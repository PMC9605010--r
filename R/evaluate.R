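# Detection and classification evaluation: greedy IoU matching, all-point
# interpolated average precision with a COCO-style threshold sweep, 3x3
# confusion matrices, per-class metrics, and the support-weighted
# misclassification rate.

#' Match detections to ground-truth annotations by circle IoU
#'
#' Detections are taken in descending score order; each claims the
#' highest-IoU still-unmatched truth with IoU >= `tau`. Each truth and each
#' detection is matched at most once.
#'
#' @param detections data frame with columns `cx`, `cy`, `r`, `score`
#'   (one image's worth).
#' @param truths data frame with columns `cx`, `cy`, `r`.
#' @param tau IoU threshold (default 0.5).
#' @return a list of class `match_result`: `pairs` (tibble with
#'   `det_index`, `truth_index`, `iou`, `score`), `fp_index`
#'   (unmatched detections), `fn_index` (unmatched truths), and `tau`.
#' @export
match_detections <- function(detections, truths, tau = 0.5) {
  nd <- nrow(detections); nt <- nrow(truths)
  ord <- if (nd > 0) order(-detections$score) else integer()
  taken <- rep(FALSE, nt)
  pairs <- vector("list", nd)
  for (d in ord) {
    if (nt == 0) break
    ious <- vapply(seq_len(nt), function(t) {
      if (taken[t]) return(-1)
      circle_iou(detections[d, ], truths[t, ])
    }, numeric(1))
    best <- which.max(ious)
    if (length(best) == 1 && ious[best] >= tau) {
      taken[best] <- TRUE
      pairs[[d]] <- tibble::tibble(
        det_index = d, truth_index = best,
        iou = ious[best], score = detections$score[d]
      )
    }
  }
  pairs <- dplyr::bind_rows(pairs)
  if (nrow(pairs) == 0) {
    pairs <- tibble::tibble(det_index = integer(), truth_index = integer(),
                            iou = numeric(), score = numeric())
  }
  structure(
    list(
      pairs = pairs,
      fp_index = setdiff(seq_len(nd), pairs$det_index),
      fn_index = setdiff(seq_len(nt), pairs$truth_index),
      tau = tau
    ),
    class = "match_result"
  )
}

#' Average precision from scored true/false positive flags
#'
#' `average_precision()` computes the all-point interpolated area under the
#' precision-recall curve: detections are ranked by score, precision is
#' replaced by its running maximum from the right, and the area is summed
#' over recall increments.
#'
#' @param scores detection confidence scores.
#' @param is_tp logical, whether each detection is a true positive.
#' @param n_truth number of ground-truth instances (must be >= 1; an AP over
#'   zero truths is undefined and raises an error rather than returning 0).
#' @return AP in `[0, 1]`; 0 when there are no detections.
#' @export
average_precision <- function(scores, is_tp, n_truth) {
  stopifnot(length(scores) == length(is_tp))
  if (n_truth < 1) stop("AP is undefined with zero ground-truth instances")
  if (length(scores) == 0) return(0)
  ord <- order(-scores)
  tp <- cumsum(as.integer(is_tp[ord]))
  fp <- cumsum(as.integer(!is_tp[ord]))
  recall <- tp / n_truth
  precision <- tp / (tp + fp)
  # envelope: max precision at any recall >= r
  prec_env <- rev(cummax(rev(precision)))
  r_prev <- c(0, recall[-length(recall)])
  sum((recall - r_prev) * prec_env)
}

#' Per-class AP and mean average precision over an IoU threshold sweep
#'
#' For each class and IoU threshold, detections across all images are
#' matched per image with [match_detections()], pooled, and scored with
#' [average_precision()]. `mAP` averages over the COCO-style sweep
#' tau = 0.50, 0.55, ..., 0.95; `mAP50`/`mAP75` are the single-threshold
#' means.
#'
#' @param detections data frame with `image_id`, `cx`, `cy`, `r`, `score`,
#'   `label`.
#' @param truths data frame with `image_id`, `cx`, `cy`, `r`, `label`.
#' @param taus IoU thresholds to sweep.
#' @return list with `per_class` (tibble: class, tau, ap, n_truth),
#'   `mAP`, `mAP50`, `mAP75`.
#' @export
mean_ap <- function(detections, truths,
                    taus = seq(0.5, 0.95, by = 0.05)) {
  stopifnot(nrow(truths) > 0)
  classes <- intersect(class_levels(), unique(truths$label))
  per <- purrr::map_dfr(classes, function(cl) {
    tr_cl <- truths[truths$label == cl, , drop = FALSE]
    de_cl <- detections[detections$label == cl, , drop = FALSE]
    purrr::map_dfr(taus, function(tau) {
      flags <- purrr::map_dfr(unique(tr_cl$image_id) |> union(unique(de_cl$image_id)),
        function(id) {
          de <- de_cl[de_cl$image_id == id, , drop = FALSE]
          tr <- tr_cl[tr_cl$image_id == id, , drop = FALSE]
          if (nrow(de) == 0) return(tibble::tibble(score = numeric(), is_tp = logical()))
          m <- match_detections(de, tr, tau = tau)
          tibble::tibble(
            score = de$score,
            is_tp = seq_len(nrow(de)) %in% m$pairs$det_index
          )
        })
      ap <- if (nrow(tr_cl) == 0) NA_real_ else
        average_precision(flags$score, flags$is_tp, nrow(tr_cl))
      tibble::tibble(class = cl, tau = tau, ap = ap, n_truth = nrow(tr_cl))
    })
  })
  by_tau <- function(t) mean(per$ap[abs(per$tau - t) < 1e-9], na.rm = TRUE)
  list(
    per_class = per,
    mAP = mean(per$ap, na.rm = TRUE),
    mAP50 = by_tau(0.50),
    mAP75 = by_tau(0.75)
  )
}

#' Three-class confusion matrix
#'
#' Rows are true classes, columns predicted, both in the fixed order
#' severe, normal, healthy.
#'
#' @param truth,predicted character vectors of class labels.
#' @return object of class `follicle_cm`: list with integer `counts`,
#'   `row_normalized` fractions, and per-true-class `support`.
#' @export
confusion_matrix <- function(truth, predicted) {
  stopifnot(length(truth) == length(predicted))
  lv <- class_levels()
  counts <- table(factor(truth, levels = lv), factor(predicted, levels = lv))
  counts <- matrix(as.integer(counts), 3, 3, dimnames = list(true = lv, predicted = lv))
  support <- rowSums(counts)
  rn <- counts / ifelse(support == 0, 1, support)
  structure(
    list(counts = counts, row_normalized = rn, support = support),
    class = "follicle_cm"
  )
}

#' @export
print.follicle_cm <- function(x, ...) {
  cat("<follicle_cm> n =", sum(x$counts), "\n")
  print(x$counts)
  invisible(x)
}

#' Per-class precision, recall, F1 and overall accuracy
#'
#' Standard one-vs-rest definitions on a 3x3 confusion matrix. Cells with a
#' zero denominator yield 0 and are flagged in `degenerate`.
#'
#' @param cm a [confusion_matrix()] result.
#' @return list with `per_class` tibble (class, precision, recall, f1,
#'   support, degenerate) and `accuracy`.
#' @export
classification_metrics <- function(cm) {
  stopifnot(inherits(cm, "follicle_cm"))
  counts <- cm$counts
  total <- sum(counts)
  if (total == 0) stop("empty confusion matrix")
  lv <- rownames(counts)
  per <- purrr::map_dfr(seq_along(lv), function(i) {
    tp <- counts[i, i]
    pred_i <- sum(counts[, i]); true_i <- sum(counts[i, ])
    prec <- if (pred_i == 0) 0 else tp / pred_i
    rec <- if (true_i == 0) 0 else tp / true_i
    f1 <- if (prec + rec == 0) 0 else 2 * prec * rec / (prec + rec)
    tibble::tibble(
      class = lv[i], precision = prec, recall = rec, f1 = f1,
      support = true_i, degenerate = pred_i == 0 || true_i == 0
    )
  })
  list(per_class = per, accuracy = sum(diag(counts)) / total)
}

#' @export
tidy.follicle_cm <- function(x, ...) {
  classification_metrics(x)$per_class
}

#' @export
glance.follicle_cm <- function(x, ...) {
  m <- classification_metrics(x)
  err <- 1 - diag(x$row_normalized)
  tibble::tibble(
    accuracy = m$accuracy,
    misclassification_rate = weighted_misclassification_rate(err, x$support),
    n = sum(x$counts)
  )
}

#' Support-weighted misclassification rate
#'
#' Combines per-true-class error fractions into a single rate weighted by
#' class support: `sum(support * error) / sum(support)`. When the errors
#' come from the row-normalized confusion matrix of the same data, this
#' equals `1 - accuracy`.
#'
#' @param per_class_error per-true-class error fractions in `[0, 1]`
#'   (e.g. the off-diagonal row sums of a row-normalized confusion matrix).
#' @param support per-class ground-truth counts.
#' @return rate in `[0, 1]`.
#' @examples
#' weighted_misclassification_rate(c(0.34, 0.26, 0.26), c(2794, 8059, 6408))
#' @export
weighted_misclassification_rate <- function(per_class_error, support) {
  stopifnot(length(per_class_error) == length(support))
  if (any(per_class_error < 0 | per_class_error > 1)) {
    stop("per-class errors must lie in [0, 1]")
  }
  if (any(support < 0)) stop("supports must be non-negative")
  if (sum(support) <= 0) stop("total support must be positive")
  sum(support * per_class_error) / sum(support)
}

#' Plot a row-normalized confusion matrix
#'
#' @param x a [confusion_matrix()] result.
#' @param ... unused.
#' @return a ggplot object showing row-normalized percentages.
#' @export
autoplot.follicle_cm <- function(x, ...) {
  df <- tibble::as_tibble(as.data.frame.table(x$row_normalized,
                                              responseName = "fraction"))
  names(df)[1:2] <- c("true", "predicted")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$predicted, y = .data$true,
                                   fill = .data$fraction)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(
      label = sprintf("%.1f%%", 100 * .data$fraction))) +
    ggplot2::scale_y_discrete(limits = rev(class_levels())) +
    ggplot2::scale_fill_gradient(low = "white", high = "#3b6fb6",
                                 limits = c(0, 1), name = "fraction") +
    ggplot2::labs(x = "predicted class", y = "true class") +
    ggplot2::theme_minimal()
}
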