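#' Directional Ratio map at one scale
#'
#' Per-pixel ratio of the smallest squared absolute directional response to
#' the largest absolute response over orientations,
#' `min_l |r_jl(p)|^2 / (max_l |r_jl(p)| + eps)`, computed after dividing the
#' whole response stack by its global maximum absolute value. With that
#' normalization the map is dimensionless in \[0, 1\]: close to 1 at the
#' center of a bright isotropic blob commensurate with the filter scale (a
#' soma), close to 0 on thin vessel-like structures (one orientation dominates)
#' and exactly 0 in flat background (all responses vanish; the `eps` guard
#' makes 0/0 read as 0).
#'
#' @param stack an [apply_bank()] response stack.
#' @param scale scale index `j` within the stack.
#' @param eps small positive division guard (default 1e-12).
#' @return an object of class `directional_ratio_map`: list with `values`
#'   (matrix in \[0, 1\]), `scale`, `border_margin` (pixels near the border
#'   where reflective padding makes values unreliable).
#' @export
directional_ratio <- function(stack, scale, eps = 1e-12) {
  stopifnot(inherits(stack, "directional_response_stack"))
  if (eps <= 0) stop("eps must be positive")
  if (scale < 1 || scale > stack$n_scales)
    stop("scale must be within the bank range (1..", stack$n_scales, ")")
  r <- abs(stack$responses)
  gmax <- max(r)
  if (gmax > 0) r <- r / gmax
  rj <- r[, , , scale, drop = FALSE]
  dim(rj) <- dim(rj)[1:3]
  mn <- rj[, , 1]
  mx <- rj[, , 1]
  for (l in seq_len(dim(rj)[3])[-1]) {
    mn <- pmin(mn, rj[, , l])
    mx <- pmax(mx, rj[, , l])
  }
  structure(list(values = mn^2 / (mx + eps), scale = scale,
                 border_margin = stack$border_margin),
            class = "directional_ratio_map")
}

# square ROI (top, left, size) centered on a (row, col) point; top/left may
# run outside the image (extract_patch zero-pads)
roi_around <- function(center, size) {
  half <- (size - 1) %/% 2
  list(top = as.integer(round(center[1])) - half,
       left = as.integer(round(center[2])) - half,
       size = as.integer(size))
}

#' Extract a square window from an image, zero-padding outside the bounds
#' @param image numeric matrix.
#' @param roi list with `top`, `left`, `size` (1-based; `top`/`left` may be
#'   outside the image).
#' @return `size x size` matrix.
#' @export
extract_patch <- function(image, roi) {
  out <- matrix(0, roi$size, roi$size)
  rows <- roi$top + seq_len(roi$size) - 1L
  cols <- roi$left + seq_len(roi$size) - 1L
  rok <- rows >= 1 & rows <= nrow(image)
  cok <- cols >= 1 & cols <= ncol(image)
  out[rok, cok] <- image[rows[rok], cols[cok]]
  out
}

# paste patch values back: returns index matrices for the in-bounds overlap
roi_index <- function(roi, image_shape) {
  rows <- roi$top + seq_len(roi$size) - 1L
  cols <- roi$left + seq_len(roi$size) - 1L
  list(img_rows = rows[rows >= 1 & rows <= image_shape[1]],
       img_cols = cols[cols >= 1 & cols <= image_shape[2]],
       patch_rows = which(rows >= 1 & rows <= image_shape[1]),
       patch_cols = which(cols >= 1 & cols <= image_shape[2]))
}

#' Detect cells via the thresholded multiscale Directional Ratio
#'
#' Computes the Directional Ratio from the bank's directional *smoothing*
#' responses (`apply_bank(type = "smoothing")`; inside a bright soma every
#' orientation averages to the soma intensity, so the ratio approaches 1,
#' while one dominant orientation on a thin process drives it towards 0) at
#' every bank scale, takes the per-pixel
#' maximum over scales, thresholds it, extracts 8-connected components,
#' discards components below `min_blob_area`, merges components whose
#' centroids are closer than `min_separation` (single somata can fragment;
#' merged by area-weighted centroid), and returns one centroid and one
#' `patch_size` square window per surviving component.
#'
#' @param image preprocessed 2D image, values in \[0, 1\].
#' @param bank a [build_filter_bank()] object (detection default:
#'   `build_filter_bank(3, 8, 15)`).
#' @param dr_threshold Directional Ratio threshold (default 0.7).
#' @param min_blob_area discard DR components smaller than this, px.
#' @param patch_size side of the square ROI (default 128).
#' @param min_separation merge components with centroids closer than this, px.
#' @param eps division guard for [directional_ratio()].
#' @return an object of class `detection_result`: list with `centroids`
#'   (matrix, columns `row`/`col`), `rois` (list of `(top, left, size)`),
#'   `source_image_shape`, `dr_map` (the max-over-scales map). Zero detections
#'   yield empty (not an error).
#' @export
detect_cells <- function(image, bank = build_filter_bank(3, 8, 15),
                         dr_threshold = 0.7, min_blob_area = 30,
                         patch_size = 128L, min_separation = 25,
                         eps = 1e-12) {
  assert_image(image)
  if (min(image) < -1e-9 || max(image) > 1 + 1e-9)
    stop("image must be normalized to [0, 1] (see normalize_intensity)")
  stack <- apply_bank(image, bank, type = "smoothing")
  dr <- NULL
  for (j in seq_len(bank$n_scales)) {
    v <- directional_ratio(stack, j, eps)$values
    dr <- if (is.null(dr)) v else pmax(dr, v)
  }
  labels <- label_components(dr >= dr_threshold, 8)
  sizes <- component_sizes(labels)
  cents <- component_centroids(labels)
  keep <- sizes >= min_blob_area
  cents <- cents[keep, , drop = FALSE]
  sizes <- sizes[keep]
  # merge nearby fragments (area-weighted centroid), closest pair first
  while (nrow(cents) > 1) {
    d <- as.matrix(stats::dist(cents))
    diag(d) <- Inf
    if (min(d) >= min_separation) break
    ij <- which(d == min(d), arr.ind = TRUE)[1, ]
    i <- min(ij); k <- max(ij)
    wsum <- sizes[i] + sizes[k]
    cents[i, ] <- (sizes[i] * cents[i, ] + sizes[k] * cents[k, ]) / wsum
    sizes[i] <- wsum
    cents <- cents[-k, , drop = FALSE]
    sizes <- sizes[-k]
  }
  detection_result(cents, patch_size, dim(image), dr)
}

detection_result <- function(centroids, patch_size, image_shape,
                             dr_map = NULL) {
  rois <- apply(centroids, 1, function(ctr) roi_around(ctr, patch_size))
  structure(list(centroids = centroids,
                 rois = rois %||% list(),
                 patch_size = as.integer(patch_size),
                 source_image_shape = as.integer(image_shape),
                 dr_map = dr_map),
            class = "detection_result")
}

#' @export
print.detection_result <- function(x, ...) {
  cat("Detection result:", nrow(x$centroids), "cell(s) in a",
      paste(x$source_image_shape, collapse = "x"), "image (ROI size",
      x$patch_size, ")\n")
  invisible(x)
}
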