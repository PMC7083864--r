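#' Configuration for synthetic GFAP-like scenes
#'
#' Describes the world the generator renders: star-shaped cells (a bright,
#' roughly isotropic soma plus several thin curved processes), string-like
#' precursor objects (a smooth curve of near-constant width, no soma), a dim
#' background and photon-counting (Poisson) noise. Defaults emulate
#' GFAP-stained cortex micrographs at 20x / 1024x1024 scale: mean cell area
#' near 1500 px, 10-65 cells per full-size image, soma intensity above process
#' intensity above background.
#'
#' @param image_size `(rows, cols)` of the rendered image.
#' @param n_stars,n_strings object counts.
#' @param soma_radius_range soma disk radius range, px.
#' @param n_processes_range number of processes per star (>= 3).
#' @param process_length_range process length range, px.
#' @param process_width_range initial process width range, px (tapers to 1).
#' @param process_curvature_sd per-step direction jitter of the process random
#'   walk, radians.
#' @param string_length_range,string_width_range string geometry, px.
#' @param string_curvature_sd per-step direction jitter for strings (small, so
#'   strings stay close to one orientation).
#' @param mean_cell_area_target documentation of the calibration target for
#'   the mean star area, px (the defaults above were calibrated once against
#'   it; it is not itself used while rendering).
#' @param min_soma_separation minimal distance between object centers, px.
#' @param soma_intensity,process_intensity,background_intensity intensities in
#'   \[0, 1\], ordered background < process <= soma.
#' @param blur_sigma optics surrogate: Gaussian blur applied before noise, px.
#' @param photon_peak expected photon count of a unit-intensity pixel; the
#'   clean image is scaled by this, Poisson-sampled and rescaled.
#' @param margin minimal distance of object centers from the border, px.
#' @param seed integer seed making the scene fully reproducible.
#' @return a list of class `scene_config`.
#' @export
scene_config <- function(image_size = c(1024L, 1024L),
                         n_stars = 25L, n_strings = 3L,
                         soma_radius_range = c(9, 13),
                         n_processes_range = c(4L, 7L),
                         process_length_range = c(40, 75),
                         process_width_range = c(4, 7),
                         process_curvature_sd = 0.08,
                         string_length_range = c(55, 100),
                         string_width_range = c(2.5, 4),
                         string_curvature_sd = 0.02,
                         mean_cell_area_target = 1500,
                         min_soma_separation = 40,
                         soma_intensity = 0.95,
                         process_intensity = 0.5,
                         background_intensity = 0.08,
                         blur_sigma = 1,
                         photon_peak = 50,
                         margin = 30,
                         seed = 1L) {
  cfg <- list(image_size = as.integer(image_size),
              n_stars = as.integer(n_stars),
              n_strings = as.integer(n_strings),
              soma_radius_range = soma_radius_range,
              n_processes_range = as.integer(n_processes_range),
              process_length_range = process_length_range,
              process_width_range = process_width_range,
              process_curvature_sd = process_curvature_sd,
              string_length_range = string_length_range,
              string_width_range = string_width_range,
              string_curvature_sd = string_curvature_sd,
              mean_cell_area_target = mean_cell_area_target,
              min_soma_separation = min_soma_separation,
              soma_intensity = soma_intensity,
              process_intensity = process_intensity,
              background_intensity = background_intensity,
              blur_sigma = blur_sigma,
              photon_peak = photon_peak,
              margin = margin,
              seed = as.integer(seed))
  validate_scene_config(cfg)
  structure(cfg, class = "scene_config")
}

validate_scene_config <- function(cfg) {
  stopifnot(length(cfg$image_size) == 2, all(cfg$image_size >= 64))
  rng_ok <- function(r) length(r) == 2 && r[1] <= r[2]
  for (f in c("soma_radius_range", "n_processes_range",
              "process_length_range", "process_width_range",
              "string_length_range", "string_width_range"))
    if (!rng_ok(cfg[[f]])) stop(f, " must be a nondecreasing length-2 range")
  if (cfg$soma_radius_range[1] <= 0)
    stop("soma radius must be positive")
  if (cfg$n_processes_range[1] < 3)
    stop("stars need at least 3 processes")
  if (!(cfg$background_intensity < cfg$process_intensity &&
          cfg$process_intensity <= cfg$soma_intensity))
    stop("intensities must satisfy background < process <= soma")
  if (cfg$photon_peak <= 0) stop("photon_peak must be positive")
  invisible(cfg)
}

# evaluate `code` under a temporary RNG seeded with `seed` (NULL = current RNG)
with_seed <- function(seed, code) {
  if (is.null(seed)) return(code)
  if (!exists(".Random.seed", globalenv(), inherits = FALSE)) set.seed(NULL)
  old <- get(".Random.seed", globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  code
}

# stamp a filled disk into a logical matrix, clipped to bounds
stamp_disk <- function(mask, cy, cx, r) {
  H <- nrow(mask); W <- ncol(mask)
  r0 <- max(1L, floor(cy - r)); r1 <- min(H, ceiling(cy + r))
  c0 <- max(1L, floor(cx - r)); c1 <- min(W, ceiling(cx + r))
  if (r0 > r1 || c0 > c1) return(mask)
  ys <- r0:r1; xs <- c0:c1
  sub <- outer((ys - cy)^2, (xs - cx)^2, `+`) <= r^2
  mask[ys, xs] <- mask[ys, xs] | sub
  mask
}

# trace a tapering random-walk curve; returns updated mask
walk_process <- function(mask, start, theta, len, width0, width1, curv_sd) {
  pos <- start
  for (s in seq_len(round(len))) {
    theta <- theta + rnorm(1, 0, curv_sd)
    pos <- pos + c(sin(theta), cos(theta)) # (row, col) step, unit length
    w <- width0 + (width1 - width0) * s / len
    # radius floor sqrt(2)/2 so every stamp covers at least one pixel
    mask <- stamp_disk(mask, pos[1], pos[2], max(w / 2, 0.75))
  }
  mask
}

#' Generate one star-shaped cell mask
#'
#' Soma = filled disk; processes grow from the soma boundary at distinct
#' angles as smooth random-walk curves with linearly tapering width. The mask
#' is a single 8-connected component by construction.
#'
#' @param center `(row, col)` soma center.
#' @param config a [scene_config()].
#' @param seed optional seed; `NULL` uses the current RNG state.
#' @return list with `mask` (logical matrix of `config$image_size`),
#'   `soma_mask`, and `centroid` (`(row, col)` = soma center).
#' @export
generate_star <- function(center, config, seed = NULL) {
  validate_scene_config(config)
  with_seed(seed, {
    H <- config$image_size[1]; W <- config$image_size[2]
    if (center[1] < 2 || center[1] > H - 1 || center[2] < 2 ||
          center[2] > W - 1)
      stop("star center must lie inside the image")
    # build on a small local canvas (object extent only), then paste: avoids
    # copying the full image for every disk stamp of the random walk
    reach <- ceiling(config$soma_radius_range[2] +
                       config$process_length_range[2] +
                       max(config$process_width_range) + 4)
    cside <- 2L * reach + 1L
    cc <- c(reach + 1, reach + 1)
    r <- runif(1, config$soma_radius_range[1], config$soma_radius_range[2])
    soma_c <- stamp_disk(matrix(FALSE, cside, cside), cc[1], cc[2], r)
    canvas <- soma_c
    k <- sample(seq(config$n_processes_range[1], config$n_processes_range[2]),
                1)
    base_angles <- 2 * pi * (seq_len(k) - 1) / k + runif(1, 0, 2 * pi)
    jitter <- runif(k, -0.3, 0.3) * 2 * pi / k
    for (i in seq_len(k)) {
      theta <- base_angles[i] + jitter[i]
      len <- runif(1, config$process_length_range[1],
                   config$process_length_range[2])
      w0 <- runif(1, config$process_width_range[1],
                  config$process_width_range[2])
      start <- cc + (r - 0.5) * c(sin(theta), cos(theta))
      canvas <- walk_process(canvas, start, theta, len, w0, 1,
                             config$process_curvature_sd)
    }
    list(mask = paste_canvas(canvas, center, c(H, W)),
         soma_mask = paste_canvas(soma_c, center, c(H, W)),
         centroid = c(row = center[1], col = center[2]))
  })
}

# paste a logical canvas (odd side, object centered) into a full-size mask at
# `center`, clipping at the borders
paste_canvas <- function(canvas, center, shape) {
  mask <- matrix(FALSE, shape[1], shape[2])
  half <- (nrow(canvas) - 1L) %/% 2L
  top <- round(center[1]) - half; left <- round(center[2]) - half
  rows <- top + seq_len(nrow(canvas)) - 1L
  cols <- left + seq_len(ncol(canvas)) - 1L
  rok <- rows >= 1 & rows <= shape[1]
  cok <- cols >= 1 & cols <= shape[2]
  mask[rows[rok], cols[cok]] <- canvas[rok, cok]
  mask
}

#' Generate one string-like (precursor) object mask
#'
#' A single smooth curve of near-constant width with no soma, length much
#' greater than width, staying close to one orientation.
#'
#' @param config a [scene_config()]; geometry from the `string_*` fields.
#' @param center optional `(row, col)` curve midpoint; random if `NULL`.
#' @param seed optional seed.
#' @return list with `mask` and `centroid` (mask centroid).
#' @export
generate_string <- function(config, center = NULL, seed = NULL) {
  validate_scene_config(config)
  with_seed(seed, {
    H <- config$image_size[1]; W <- config$image_size[2]
    m <- config$margin
    if (is.null(center))
      center <- c(runif(1, m, H - m), runif(1, m, W - m))
    len <- runif(1, config$string_length_range[1],
                 config$string_length_range[2])
    wdt <- runif(1, config$string_width_range[1],
                 config$string_width_range[2])
    theta <- runif(1, 0, pi)
    reach <- ceiling(len / 2 + wdt + 4)
    cside <- 2L * reach + 1L
    cc <- c(reach + 1, reach + 1)
    canvas <- matrix(FALSE, cside, cside)
    # grow both half-curves from the midpoint so `center` is central
    for (dir in c(0, pi))
      canvas <- walk_process(canvas, cc, theta + dir, len / 2, wdt, wdt,
                             config$string_curvature_sd)
    mask <- paste_canvas(canvas, center, c(H, W))
    cen <- component_centroids(label_components(mask))
    list(mask = mask, centroid = c(row = cen[1, 1], col = cen[1, 2]))
  })
}

#' Render a full synthetic scene with exact ground truth
#'
#' Objects are placed by rejection sampling under the minimal center
#' separation, composed into an intensity image by per-pixel maximum
#' (fluorescence is non-subtractive), blurred by a small Gaussian (optics
#' surrogate), scaled to `photon_peak`, Poisson-sampled, and rescaled to
#' \[0, 1\]. Ground truth (label map, centroids, classes) is kept noise-free.
#'
#' @param config a [scene_config()]; `config$seed` makes the scene
#'   bitwise-reproducible.
#' @return an object of class `synthetic_scene`: list with `image` (matrix in
#'   \[0, 1\]), `label_map` (integer matrix, 0 = background, stars first then
#'   strings), `centroids` (matrix with columns `row`, `col`), `classes`
#'   (character, `"star"`/`"string"`), `soma_centers`, and `config`.
#' @export
render_scene <- function(config) {
  validate_scene_config(config)
  with_seed(config$seed, {
    H <- config$image_size[1]; W <- config$image_size[2]
    m <- config$margin
    n_obj <- config$n_stars + config$n_strings
    centers <- matrix(numeric(0), 0, 2)
    attempts <- 0
    while (nrow(centers) < n_obj) {
      cand <- c(runif(1, m, H - m), runif(1, m, W - m))
      if (nrow(centers) == 0 ||
            min(sqrt(colSums((t(centers) - cand)^2))) >=
              config$min_soma_separation) {
        centers <- rbind(centers, cand)
      }
      attempts <- attempts + 1
      if (attempts > 1000 * n_obj)
        stop("placement failure: could not satisfy min_soma_separation = ",
             config$min_soma_separation, " for ", n_obj, " objects in a ",
             H, "x", W, " image")
    }
    label_map <- matrix(0L, H, W)
    clean <- matrix(config$background_intensity, H, W)
    centroids <- matrix(NA_real_, n_obj, 2,
                        dimnames = list(NULL, c("row", "col")))
    classes <- character(n_obj)
    for (i in seq_len(n_obj)) {
      if (i <= config$n_stars) {
        obj <- generate_star(centers[i, ], config)
        classes[i] <- "star"
        intens <- ifelse(obj$soma_mask, config$soma_intensity,
                         config$process_intensity)
      } else {
        obj <- generate_string(config, center = centers[i, ])
        classes[i] <- "string"
        intens <- matrix(config$process_intensity, H, W)
      }
      centroids[i, ] <- obj$centroid
      sel <- obj$mask
      clean[sel] <- pmax(clean[sel], intens[sel])
      label_map[sel & label_map == 0L] <- i
    }
    img <- gaussian_blur(clean, config$blur_sigma)
    counts <- matrix(rpois(length(img), pmax(img, 0) * config$photon_peak),
                     H, W)
    img <- counts / config$photon_peak
    img <- img / max(img)
    structure(list(image = img, label_map = label_map,
                   centroids = centroids, classes = classes,
                   soma_centers = centroids[classes == "star", , drop = FALSE],
                   config = config),
              class = "synthetic_scene")
  })
}

#' @export
print.synthetic_scene <- function(x, ...) {
  cat("Synthetic scene", paste(dim(x$image), collapse = "x"), "px:",
      sum(x$classes == "star"), "star(s),",
      sum(x$classes == "string"), "string(s), seed",
      x$config$seed, "\n")
  invisible(x)
}

#' Extract per-cell training pairs from a synthetic scene
#'
#' One `(image patch, binary mask)` pair per star, the patch centered on the
#' ground-truth soma center and the mask restricted to that cell's label
#' (neighboring cells in the window are background in the mask, as in
#' manually annotated single-cell patches). Patches at the border are
#' zero-padded to full size.
#'
#' @param scene a [render_scene()] result.
#' @param patch_size odd or even window size in px (default 128).
#' @return an object of class `training_set`: list with `patches` (list of
#'   `list(image, mask)`), `patch_size`, `augmentation_factor = 0`.
#' @export
make_training_pairs <- function(scene, patch_size = 128L) {
  stopifnot(inherits(scene, "synthetic_scene"))
  stars <- which(scene$classes == "star")
  pairs <- lapply(stars, function(i) {
    ctr <- scene$centroids[i, ]
    roi <- roi_around(ctr, patch_size)
    list(image = extract_patch(scene$image, roi),
         mask = extract_patch((scene$label_map == i) * 1, roi))
  })
  training_set(pairs, patch_size)
}

training_set <- function(pairs, patch_size, augmentation_factor = 0L) {
  for (p in pairs) {
    stopifnot(identical(dim(p$image), dim(p$mask)),
              all(p$mask %in% c(0, 1)))
  }
  structure(list(patches = pairs, patch_size = as.integer(patch_size),
                 augmentation_factor = as.integer(augmentation_factor)),
            class = "training_set")
}

#' @export
print.training_set <- function(x, ...) {
  cat("Training set:", length(x$patches), "pairs of",
      x$patch_size, "x", x$patch_size,
      "px (augmentation factor", x$augmentation_factor, ")\n")
  invisible(x)
}
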