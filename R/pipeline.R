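#' Pipeline configuration
#'
#' Nested configuration of every stage. All values are plain lists/atomics so
#' the object round-trips losslessly through YAML/JSON ([read_config()],
#' [write_config()]).
#'
#' @param filters detection filter-bank parameters (see
#'   [build_filter_bank()]).
#' @param postprocess_filters bank for the star/string shape test (20
#'   orientations in the reference pipeline).
#' @param preprocess [preprocess_config()] arguments.
#' @param detection [detect_cells()] arguments (threshold 0.7 and 128 px
#'   windows are the reference values).
#' @param postprocess `min_size` for [keep_central_component()],
#'   `prominence_frac`/`min_separation_deg` for [classify_star_string()], and
#'   `classify_on` (`"mask"`: run the shape test on the segmented mask;
#'   `"patch"`: on the raw intensity patch).
#' @param segmentation `prob_threshold` for [segment_patch()].
#' @param seed global seed recorded in run reports.
#' @return a list of class `pipeline_config`.
#' @export
pipeline_config <- function(filters = list(n_scales = 3, n_orientations = 8,
                                           base_kernel_size = 15,
                                           aspect_ratio = 3),
                            postprocess_filters = list(n_scales = 1,
                                                       n_orientations = 20,
                                                       base_kernel_size = 41,
                                                       aspect_ratio = 3),
                            preprocess = list(denoise_enabled = TRUE,
                                              threshold_multiplier = 3,
                                              normalization = "minmax",
                                              vst = FALSE),
                            detection = list(dr_threshold = 0.7,
                                             min_blob_area = 30,
                                             patch_size = 128,
                                             min_separation = 25),
                            postprocess = list(min_size = 100,
                                               prominence_frac = 0.5,
                                               min_separation_deg = 30,
                                               classify_on = "mask"),
                            segmentation = list(prob_threshold = 0.5),
                            seed = 1L) {
  structure(list(filters = filters,
                 postprocess_filters = postprocess_filters,
                 preprocess = preprocess, detection = detection,
                 postprocess = postprocess, segmentation = segmentation,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Run the full detection-and-segmentation pipeline on one image
#'
#' Stages: denoise, normalize, detect somata via the multiscale Directional
#' Ratio, segment each 128x128 window with the trained network, clean each
#' patch mask (central component), discard string-like objects by the
#' orientation-profile shape test, and reassemble the surviving masks into a
#' full-image labeled segmentation. Runs are deterministic given the config
#' and model.
#'
#' @param image an image path ([read_image()] formats) or a numeric matrix.
#' @param model a trained [build_gesunet()] model, a path to a saved model, or
#'   `NULL` for a detection-only run.
#' @param config a [pipeline_config()].
#' @param out_dir optional output directory; writes `labels.tif`,
#'   `centroids.csv`, `classes.csv`, `report.json` and per-cell mask PNGs.
#' @return an object of class `pipeline_result`: list with `detection`
#'   (a [detect_cells()] result), `segmentation` (a [reassemble()] result or
#'   `NULL`), `classes`, `preprocessed` image and `report` (stage counts and
#'   timings: `detected`, `segmented`, `discarded_as_string`, `final_cells`).
#' @export
run_pipeline <- function(image, model = NULL, config = pipeline_config(),
                         out_dir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  t0 <- proc.time()[["elapsed"]]
  timings <- list()
  tick <- function(stage) {
    t1 <- proc.time()[["elapsed"]]
    timings[[stage]] <<- round(t1 - t0, 3)
    t0 <<- t1
  }
  img <- if (is.character(image)) read_image(image) else image
  assert_image(img)
  if (is.character(model)) model <- load_gesunet(model)
  bank <- do.call(build_filter_bank, config$filters)
  pp <- do.call(preprocess_config, config$preprocess)
  img_dn <- denoise(img, bank, pp)
  img_n <- normalize_intensity(img_dn, pp)
  tick("preprocess")
  det <- do.call(detect_cells,
                 c(list(image = img_n, bank = bank), config$detection))
  tick("detect")
  n_det <- nrow(det$centroids)
  seg <- NULL
  classes <- list()
  n_string <- 0L
  if (!is.null(model) && n_det > 0) {
    if (model$spec$patch_size != det$patch_size)
      stop("model patch size (", model$spec$patch_size,
           ") does not match detection ROI size (", det$patch_size, ")")
    pbank <- do.call(build_filter_bank, config$postprocess_filters)
    patch_masks <- vector("list", n_det)
    for (i in seq_len(n_det)) {
      roi <- det$rois[[i]]
      patch <- extract_patch(img_n, roi)
      mask <- segment_patch(model, patch,
                            config$segmentation$prob_threshold)
      ctr <- c(det$centroids[i, 1] - roi$top + 1,
               det$centroids[i, 2] - roi$left + 1)
      mask <- keep_central_component(mask, ctr, config$postprocess$min_size)
      subject <- if (identical(config$postprocess$classify_on, "patch"))
        patch else mask
      prof <- orientation_profile(subject, pbank)
      classes[[i]] <- classify_star_string(
        prof, config$postprocess$prominence_frac,
        config$postprocess$min_separation_deg)
      patch_masks[[i]] <- list(mask = mask, roi = roi)
    }
    tick("segment")
    n_string <- sum(vapply(classes, function(cl) cl$label == "string",
                           logical(1)))
    seg <- reassemble(patch_masks, dim(img_n), classes)
    tick("postprocess")
  }
  report <- list(
    detected = n_det,
    segmented = if (is.null(seg)) 0L else n_det,
    discarded_as_string = n_string,
    final_cells = if (is.null(seg)) n_det else seg$n_cells,
    detection_only = is.null(model),
    seed = config$seed,
    timings_sec = timings
  )
  res <- structure(list(detection = det, segmentation = seg,
                        classes = classes, preprocessed = img_n,
                        report = report, config = config),
                   class = "pipeline_result")
  if (!is.null(out_dir)) write_pipeline_outputs(res, out_dir)
  res
}

write_pipeline_outputs <- function(res, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  write_centroids_csv(res$detection$centroids,
                      file.path(out_dir, "centroids.csv"))
  write_report(res$report, file.path(out_dir, "report.json"))
  if (!is.null(res$segmentation)) {
    write_labels(res$segmentation$labels, file.path(out_dir, "labels.tif"))
    cls <- res$classes
    utils::write.csv(data.frame(
      id = seq_along(cls),
      class = vapply(cls, `[[`, character(1), "label"),
      n_prominent = vapply(cls, `[[`, integer(1), "n_prominent"),
      peak_angles = vapply(cls, function(cl)
        paste(round(cl$peak_angles, 1), collapse = ";"), character(1))
    ), file.path(out_dir, "classes.csv"), row.names = FALSE)
    masks_dir <- file.path(out_dir, "masks")
    dir.create(masks_dir, showWarnings = FALSE)
    for (i in seq_along(res$segmentation$masks)) {
      m <- res$segmentation$masks[[i]]$mask
      write_image(m * 1, file.path(masks_dir, sprintf("cell_%03d.png", i)),
                  bits = 8L)
    }
  }
  invisible(out_dir)
}

#' @export
print.pipeline_result <- function(x, ...) {
  r <- x$report
  cat("Pipeline run:", r$detected, "detected,", r$discarded_as_string,
      "discarded as string,", r$final_cells, "final cell(s)\n")
  invisible(x)
}
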