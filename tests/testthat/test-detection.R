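# hand-constructed response stacks for the Directional Ratio unit cases
fake_stack <- function(responses) {
  structure(list(responses = responses, n_scales = dim(responses)[4],
                 n_orientations = dim(responses)[3], angle_step = 45,
                 type = "smoothing", border_margin = 0L),
            class = "directional_response_stack")
}

test_that("Directional Ratio limits match the definition", {
  # 4 orientations, 1 scale; global max response 1 at pixel (1,1)
  r <- array(0, c(2, 2, 4, 1))
  r[1, 1, , 1] <- 1          # isotropy at full response -> 1
  r[1, 2, , 1] <- 0.6        # isotropy at m -> m^2/m = m
  r[2, 1, , 1] <- c(0, 1, 1, 1) # one vanishing orientation -> 0
  d <- directional_ratio(fake_stack(r), 1)
  expect_equal(d$values[1, 1], 1, tolerance = 1e-9)
  expect_equal(d$values[1, 2], 0.6, tolerance = 1e-9)
  expect_equal(d$values[2, 1], 0, tolerance = 1e-9)
  expect_equal(d$values[2, 2], 0) # flat zero background: eps guard -> 0
  expect_error(directional_ratio(fake_stack(r), 1, eps = 0), "eps")
  expect_error(directional_ratio(fake_stack(r), 2), "within the bank range")
})

test_that("DR separates an isotropic disk from a thin bar", {
  bank <- build_filter_bank(3, 8, 15)
  # disk radius = 2x the finest kernel support: kernel strictly inside the
  # disk sees a locally isotropic region
  img <- phantom_disk(192, center = c(60, 60), radius = 30)
  img[150 + 0:2, 10:180] <- 0.95 # 3 px bar
  img <- normalize_intensity(img)
  stack <- apply_bank(img, bank, type = "smoothing")
  dr <- Reduce(pmax, lapply(1:3, function(j)
    directional_ratio(stack, j)$values))
  expect_gt(dr[60, 60], 0.7)
  expect_lt(max(dr[151, 40:160]), 0.7)
  # oracle agreement (criterion: brute-force convolutions, same formula)
  small <- img[1:64, 1:64]
  sb <- build_filter_bank(1, 4, 9)
  stack_s <- apply_bank(small, sb, type = "smoothing")
  expect_lt(max(abs(directional_ratio(stack_s, 1)$values -
                      brute_dr(small, sb, 1))), 1e-8)
})

test_that("defaults match the reference pipeline values", {
  expect_equal(formals(detect_cells)$dr_threshold, 0.7)
  expect_equal(formals(detect_cells)$patch_size, 128L)
})

test_that("blank images yield an empty detection result", {
  det <- detect_cells(matrix(0, 96, 96), build_filter_bank(1, 4, 9))
  expect_s3_class(det, "detection_result")
  expect_equal(nrow(det$centroids), 0)
  expect_length(det$rois, 0)
})

test_that("detection recovers well-separated synthetic stars", {
  sc <- render_scene(scene_config(image_size = c(512, 512), n_stars = 12,
                                  n_strings = 0, min_soma_separation = 80,
                                  seed = 42))
  img <- normalize_intensity(sc$image, preprocess_config(
    normalization = "percentile", percentile_bounds = c(0.5, 99.5)))
  det <- detect_cells(img)
  expect_equal(nrow(det$centroids), 12)
  m <- match_detections(det$centroids, sc$soma_centers, radius = 10)
  expect_equal(m$counts$TP, 12)
  # each centroid lies inside its ROI; ROI size is the configured patch size
  for (i in seq_len(12)) {
    roi <- det$rois[[i]]
    expect_equal(roi$size, 128L)
    expect_true(det$centroids[i, 1] >= roi$top &&
                  det$centroids[i, 1] < roi$top + roi$size)
    expect_true(det$centroids[i, 2] >= roi$left &&
                  det$centroids[i, 2] < roi$left + roi$size)
  }

  # DR map invariance under rescaling + re-normalization
  det2 <- detect_cells(normalize_intensity(img * 0.43))
  expect_equal(det2$dr_map, det$dr_map, tolerance = 1e-12)

  # count invariance under 90 degree rotation
  img90 <- t(img)[ncol(img):1, ]
  det90 <- detect_cells(img90)
  expect_equal(nrow(det90$centroids), 12)
})

test_that("contiguous cells with separated somata yield two centroids", {
  cfg <- scene_config(image_size = c(256, 256), n_stars = 2, n_strings = 0,
                      process_length_range = c(60, 75),
                      min_soma_separation = 60, margin = 70, seed = 5)
  # two stars ~60 px apart (>= 2 soma diameters), processes overlap
  s1 <- generate_star(c(128, 98), cfg, seed = 101)
  s2 <- generate_star(c(128, 158), cfg, seed = 202)
  expect_gt(sum(s1$mask & s2$mask), 0) # really entangled
  img <- matrix(0.08, 256, 256)
  img[s1$mask] <- 0.5; img[s2$mask] <- pmax(img[s2$mask], 0.5)
  img[s1$soma_mask | s2$soma_mask] <- 0.95
  img <- normalize_intensity(gaussian_blur(img, 1))
  det <- detect_cells(img)
  expect_equal(nrow(det$centroids), 2)
  m <- match_detections(det$centroids, rbind(c(128, 98), c(128, 158)),
                        radius = 15)
  expect_equal(m$counts$TP, 2)
})

test_that("zero-padded ROI extraction is exact at the borders", {
  img <- matrix(seq_len(36) / 36, 6, 6)
  p <- extract_patch(img, list(top = -1L, left = 4L, size = 4L))
  expect_equal(dim(p), c(4, 4))
  expect_equal(p[1:2, ], matrix(0, 2, 4)) # above the image
  expect_equal(p[3, 1], img[1, 4])
  expect_equal(p[4, 3], img[2, 6])
  expect_equal(p[, 4], rep(0, 4)) # right of the image
})
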