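#' Keep only the component of a patch mask that belongs to the central cell
#'
#' Detection windows are centered on the detected cell, so foreground
#' components other than the one containing (or nearest to) the window
#' centroid belong to neighboring cells or debris and are removed; `min_size`
#' is the size below which such satellite components would be discarded even
#' if they belonged to the cell (they are removed here regardless, since the
#' ROI construction guarantees the central component is the cell).
#'
#' @param mask binary patch mask.
#' @param centroid `(row, col)` of the detected cell within the patch;
#'   defaults to the patch center.
#' @param min_size retained for interface compatibility (see above); default
#'   100 px at 1024x1024 / 20x scale.
#' @return binary mask containing only the selected component (empty mask in,
#'   empty mask out).
#' @export
keep_central_component <- function(mask,
                                   centroid = (dim(mask) + 1) / 2,
                                   min_size = 100) {
  m <- mask != 0
  labels <- label_components(m, 8)
  if (max(labels) == 0) return(matrix(FALSE, nrow(m), ncol(m)))
  ri <- min(max(1L, round(centroid[1])), nrow(m))
  ci <- min(max(1L, round(centroid[2])), ncol(m))
  target <- labels[ri, ci]
  if (target == 0) {
    # nearest component by pixel distance to the centroid
    fg <- which(labels > 0, arr.ind = TRUE)
    d2 <- (fg[, 1] - centroid[1])^2 + (fg[, 2] - centroid[2])^2
    target <- labels[fg[which.min(d2), , drop = FALSE]]
  }
  labels == target
}

#' Aggregate directional response per orientation for one object
#'
#' Applies the bank at its coarsest scale and sums the absolute response over
#' the object's pixels for each orientation, normalized to a maximum of 1.
#' An elongated object concentrates its response in one orientation; a
#' star-shaped object spreads it over the directions of its processes.
#'
#' @param object_mask binary patch mask (or a nonnegative image patch; any
#'   positive pixel counts as object support).
#' @param bank a [build_filter_bank()] object; the shape test of the reference
#'   pipeline uses 20 orientations (`build_filter_bank(1, 20, 41)`).
#' @return an object of class `orientation_profile`: list with `values`
#'   (length `n_orientations`, max 1; all zeros for an empty object) and
#'   `angle_step`.
#' @export
orientation_profile <- function(object_mask,
                                bank = build_filter_bank(1, 20, 41)) {
  assert_image(object_mask * 1)
  support <- object_mask > 0
  n <- bank$n_orientations
  if (!any(support))
    return(structure(list(values = numeric(n), angle_step = bank$angle_step),
                     class = "orientation_profile"))
  stack <- apply_bank(object_mask * 1, bank)
  j <- bank$n_scales # coarsest scale
  vals <- vapply(seq_len(n), function(l) {
    sum(abs(stack$responses[, , l, j])[support])
  }, numeric(1))
  if (max(vals) > 0) vals <- vals / max(vals)
  structure(list(values = vals, angle_step = bank$angle_step),
            class = "orientation_profile")
}

#' Star/string classification from an orientation profile
#'
#' Counts prominent peaks of the circular profile: local maxima (plateaus
#' collapsed to their center) with height at least `prominence_frac` of the
#' profile maximum, selected greedily by height under a pairwise circular
#' angular separation of at least `min_separation_deg`. At least 2 prominent
#' peaks mark a star (processes in at least 2 distinct orientations); exactly
#' one marks a string. A completely flat positive profile is isotropic - all
#' orientations tie - and is classified as a star (>= 2 indistinguishable
#' peaks); an all-zero profile is a degenerate empty object and classified as
#' a string.
#'
#' @param profile an [orientation_profile()].
#' @param prominence_frac peak height fraction of the maximum (0 < f < 1,
#'   default 0.5).
#' @param min_separation_deg minimal circular angular separation between
#'   counted peaks (default 30).
#' @return an object of class `shape_class`: list with `label`
#'   (`"star"`/`"string"`), `n_prominent`, `peak_angles` (degrees).
#' @export
classify_star_string <- function(profile, prominence_frac = 0.5,
                                 min_separation_deg = 30) {
  stopifnot(inherits(profile, "orientation_profile"))
  if (prominence_frac <= 0 || prominence_frac >= 1)
    stop("prominence_frac must be in (0, 1)")
  v <- profile$values
  n <- length(v)
  step <- profile$angle_step
  if (max(v) <= 0)
    return(shape_class("string", 0L, numeric(0)))
  if (diff(range(v)) < 1e-12) {
    # isotropic tie: every orientation is an indistinguishable peak
    return(shape_class("star", n, (seq_len(n) - 1) * step))
  }
  # circular local maxima with plateau handling: collapse runs of equal
  # values, then compare each run to its circular neighbors
  runs <- rle(v)
  nv <- length(runs$values)
  run_start <- cumsum(c(1, runs$lengths[-nv]))
  # merge wrap-around run if first and last values equal
  peaks <- integer(0)
  for (i in seq_len(nv)) {
    prev <- runs$values[if (i == 1) nv else i - 1]
    nxt <- runs$values[if (i == nv) 1 else i + 1]
    if (runs$values[i] > prev && runs$values[i] > nxt) {
      center <- run_start[i] + (runs$lengths[i] - 1) / 2
      peaks <- c(peaks, round(center))
    }
  }
  if (length(peaks) == 0) peaks <- which.max(v)
  # greedy selection by height under circular angular separation
  peaks <- peaks[v[peaks] >= prominence_frac * max(v)]
  peaks <- peaks[order(-v[peaks], peaks)]
  sel <- integer(0)
  for (p in peaks) {
    ang_p <- (p - 1) * step
    ok <- all(vapply(sel, function(s) {
      d <- abs(ang_p - (s - 1) * step) %% 180
      min(d, 180 - d) >= min_separation_deg
    }, logical(1)))
    if (ok) sel <- c(sel, p)
  }
  label <- if (length(sel) >= 2) "star" else "string"
  shape_class(label, length(sel), sort((sel - 1) * step))
}

shape_class <- function(label, n_prominent, peak_angles) {
  structure(list(label = label, n_prominent = as.integer(n_prominent),
                 peak_angles = peak_angles), class = "shape_class")
}

#' @export
print.shape_class <- function(x, ...) {
  cat("Shape:", x$label, "(", x$n_prominent, "prominent peak(s) at",
      paste(round(x$peak_angles, 1), collapse = ", "), "deg )\n")
  invisible(x)
}

#' Reassemble per-patch masks into a full-image labeled segmentation
#'
#' String-classified objects are excluded; each surviving cell receives a
#' unique positive label in input order. Pixels claimed by two or more cells
#' (overlapping processes that cannot be reliably attributed to either cell)
#' receive the reserved ambiguous label `-1`. Patches with identical ROIs
#' (duplicate centroids) are merged into one cell with a warning.
#'
#' @param patch_masks list of `list(mask, roi)` where `roi` is
#'   `(top, left, size)` as produced by [detect_cells()].
#' @param image_shape `(rows, cols)` of the output label map.
#' @param classes optional list of [classify_star_string()] results (or a
#'   character vector `"star"`/`"string"`), one per patch; `NULL` keeps all.
#' @return an object of class `labeled_segmentation`: list with `labels`
#'   (integer matrix; 0 background, -1 ambiguous), `n_cells`,
#'   `ambiguous_label = -1`, `kept` (indices of input patches kept) and
#'   `masks` (the kept binary patch masks with their ROIs).
#' @export
reassemble <- function(patch_masks, image_shape, classes = NULL) {
  if (!is.null(classes)) {
    lab <- vapply(classes, function(cl)
      if (inherits(cl, "shape_class")) cl$label else as.character(cl),
      character(1))
    stopifnot(length(lab) == length(patch_masks))
    keep <- lab == "star"
  } else {
    keep <- rep(TRUE, length(patch_masks))
  }
  kept_idx <- which(keep)
  # merge duplicates (identical ROI)
  if (length(kept_idx) > 1) {
    sig <- vapply(patch_masks[kept_idx], function(pm)
      paste(pm$roi$top, pm$roi$left, pm$roi$size), character(1))
    if (anyDuplicated(sig)) {
      warning("duplicate centroids: merging patches with identical ROIs")
      kept_idx <- kept_idx[!duplicated(sig)]
    }
  }
  labels <- matrix(0L, image_shape[1], image_shape[2])
  claimed <- matrix(0L, image_shape[1], image_shape[2])
  for (i in seq_along(kept_idx)) {
    pm <- patch_masks[[kept_idx[i]]]
    ix <- roi_index(pm$roi, image_shape)
    sub <- pm$mask[ix$patch_rows, ix$patch_cols, drop = FALSE] != 0
    cur <- labels[ix$img_rows, ix$img_cols, drop = FALSE]
    cnt <- claimed[ix$img_rows, ix$img_cols, drop = FALSE]
    cur[sub & cnt == 0L] <- i
    cur[sub & cnt > 0L] <- -1L
    cnt[sub] <- cnt[sub] + 1L
    labels[ix$img_rows, ix$img_cols] <- cur
    claimed[ix$img_rows, ix$img_cols] <- cnt
  }
  structure(list(labels = labels, n_cells = length(kept_idx),
                 ambiguous_label = -1L, kept = kept_idx,
                 masks = patch_masks[kept_idx]),
            class = "labeled_segmentation")
}

#' @export
print.labeled_segmentation <- function(x, ...) {
  cat("Labeled segmentation:", x$n_cells, "cell(s);",
      sum(x$labels == x$ambiguous_label), "ambiguous pixel(s)\n")
  invisible(x)
}
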