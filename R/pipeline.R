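# End-to-end pipeline: a YAML config names the stages to run and their
# parameters; each stage reads and writes the documented plain-text
# formats inside a working directory, so partial pipelines and re-runs are
# possible stage by stage. A thin command-line wrapper lives in
# inst/cli/trichoscan.

#' Run the analysis pipeline from a config
#'
#' Stages (each optional, run in this order when present in the config):
#' * `simulate` — generate a synthetic dataset (`images/`,
#'   `ground_truth.json`, `manifest.yaml`);
#' * `detect` — run the reference detector over `images/` (or import an
#'   external detector's `detections.json`) into `detections.json`;
#' * `classify` — measure features and apply the labeling rules,
#'   writing `follicles.csv`;
#' * `severity` — per-image severity indices into `severity.csv`;
#' * `map` — assemble 12 images into the scalp map: `heatmap.png` +
#'   `scalp_map.json`;
#' * `evaluate` — detections vs ground truth: `metrics.json`.
#'
#' @param config path to a YAML file, or an equivalent named list. Top
#'   level keys: `workdir` (default `"."`), `seed`, and one section per
#'   stage (see the pipeline vignette for the schema).
#' @param seed overrides the config seed when non-NULL.
#' @param verbose print stage timings and record counts.
#' @return named list of per-stage results, invisibly.
#' @export
run_pipeline <- function(config, seed = NULL, verbose = TRUE) {
  cfg <- if (is.character(config)) yaml::read_yaml(config) else config
  workdir <- cfg$workdir %||% "."
  if (!dir.exists(workdir)) dir.create(workdir, recursive = TRUE)
  seed <- as.integer(seed %||% cfg$seed %||% 1L)
  say <- function(...) if (verbose) message(...)
  results <- list()
  tick <- function(stage, expr) {
    t0 <- proc.time()[["elapsed"]]
    out <- expr
    say(sprintf("[%s] done in %.1fs", stage, proc.time()[["elapsed"]] - t0))
    out
  }

  img_dir <- file.path(workdir, "images")
  gt_path <- file.path(workdir, "ground_truth.json")
  det_path <- file.path(workdir, "detections.json")
  fol_path <- file.path(workdir, "follicles.csv")

  if (!is.null(cfg$simulate)) {
    results$simulate <- tick("simulate", {
      sc <- cfg$simulate
      conf <- sim_config(
        image_size = unlist(sc$image_size %||% c(640, 480)),
        follicles_per_image = unlist(sc$follicles_per_image %||% c(10, 45)),
        class_mixture = unlist(sc$class_mixture %||%
                                 c(severe = 3836, normal = 11262, healthy = 8914)),
        strict_bands = sc$strict_bands %||% TRUE,
        seed = seed
      )
      ds <- generate_dataset(sc$n_images %||% 12, conf, dir = img_dir)
      file.copy(file.path(img_dir, "ground_truth.json"), gt_path,
                overwrite = TRUE)
      say("  ", ds$manifest$total_annotations, " annotations over ",
          ds$manifest$n_images, " images")
      ds
    })
  }

  if (!is.null(cfg$detect)) {
    results$detect <- tick("detect", {
      dc <- cfg$detect
      dets <- if (!is.null(dc$import)) {
        read_detections(dc$import)
      } else {
        files <- sort(list.files(img_dir, pattern = "\\.png$", full.names = TRUE))
        purrr::map_dfr(files, function(f) {
          detect_follicles_reference(png::readPNG(f), image_id = basename(f))
        })
      }
      write_detections(dets, det_path)
      say("  ", nrow(dets), " detections")
      dets
    })
  }

  if (!is.null(cfg$classify)) {
    results$classify <- tick("classify", {
      dets <- read_detections(det_path)
      mode <- cfg$classify$mode %||% "vote"
      out <- purrr::map_dfr(unique(dets$image_id), function(id) {
        img <- png::readPNG(file.path(img_dir, id))
        classify_follicles(img, dets[dets$image_id == id, ], mode = mode)
      })
      utils::write.csv(
        out[, c("image_id", "cx", "cy", "r", "hair_count",
                "hair_thickness", "label")],
        fol_path, row.names = FALSE
      )
      say("  ", nrow(out), " follicles classified")
      out
    })
  }

  if (!is.null(cfg$severity)) {
    results$severity <- tick("severity", {
      sv <- cfg$severity
      params <- severity_params(
        alpha = unlist(sv$alpha %||% c(healthy = 32, normal = 22, severe = 12)),
        beta = sv$beta %||% 0,
        n_max = sv$n_max %||% 45
      )
      labels <- utils::read.csv(fol_path, stringsAsFactors = FALSE)
      out <- severity_by_image(labels, params)
      utils::write.csv(out, file.path(workdir, "severity.csv"),
                       row.names = FALSE)
      say("  P computed for ", nrow(out), " image(s)")
      out
    })
  }

  if (!is.null(cfg$map)) {
    results$map <- tick("map", {
      sev <- utils::read.csv(file.path(workdir, "severity.csv"),
                             stringsAsFactors = FALSE)
      regions <- scalp_layout()$region
      assign <- cfg$map$regions %||%
        setNames(as.list(utils::head(sev$k, 12)), utils::head(regions, 12))
      res <- tibble::tibble(
        region = names(assign),
        p = vapply(unlist(assign), function(id) {
          row <- sev[sev$k == id, ]
          if (nrow(row) == 0) stop("no severity record for image '", id, "'")
          row$p[1]
        }, numeric(1))
      )
      m <- assemble_scalp_map(res)
      render_heatmap(m, path = file.path(workdir, "heatmap.png"))
      sidecar <- c(as.list(setNames(m$regions$p, m$regions$region)),
                   list(Pavg = m$pavg))
      writeLines(jsonlite::toJSON(sidecar, auto_unbox = TRUE, digits = NA,
                                  pretty = TRUE),
                 file.path(workdir, "scalp_map.json"))
      say(sprintf("  Pavg = %.3f", m$pavg))
      m
    })
  }

  if (!is.null(cfg$evaluate)) {
    results$evaluate <- tick("evaluate", {
      truth <- read_via_annotations(gt_path)
      dets <- if (file.exists(fol_path)) {
        f <- utils::read.csv(fol_path, stringsAsFactors = FALSE)
        d <- read_detections(det_path)
        d$label <- f$label[match(paste(d$image_id, round(d$cx, 3)),
                                 paste(f$image_id, round(f$cx, 3)))]
        d
      } else {
        read_detections(det_path)
      }
      maps <- mean_ap(dets, truth$annotations)
      # classification metrics over matched pairs at IoU 0.5
      pairs <- purrr::map_dfr(unique(truth$annotations$image_id), function(id) {
        tr <- truth$annotations[truth$annotations$image_id == id, ]
        de <- dets[dets$image_id == id, ]
        if (nrow(de) == 0) return(NULL)
        m <- match_detections(de, tr)
        tibble::tibble(truth = tr$label[m$pairs$truth_index],
                       predicted = de$label[m$pairs$det_index])
      })
      metrics <- list(mAP = maps$mAP, mAP50 = maps$mAP50, mAP75 = maps$mAP75)
      if (nrow(pairs) > 0 && !all(is.na(pairs$predicted))) {
        cm <- confusion_matrix(pairs$truth, pairs$predicted)
        metrics$accuracy <- classification_metrics(cm)$accuracy
        metrics$misclassification_rate <- glance(cm)$misclassification_rate
      }
      writeLines(jsonlite::toJSON(metrics, auto_unbox = TRUE, digits = NA,
                                  pretty = TRUE),
                 file.path(workdir, "metrics.json"))
      say(sprintf("  mAP50 = %.3f", maps$mAP50))
      metrics
    })
  }

  invisible(results)
}
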