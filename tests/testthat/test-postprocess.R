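test_that("central-component cleanup keeps the detected cell only", {
  m <- matrix(FALSE, 64, 64)
  m[20:47, 20:47] <- TRUE                  # ~800 px central blob
  m[2:9, 2:9] <- TRUE                      # 64 px corner blob
  out <- keep_central_component(m, c(32, 32), min_size = 100)
  expect_true(all(out[20:47, 20:47]))
  expect_false(any(out[2:9, 2:9]))

  # single component passes through unchanged
  single <- matrix(FALSE, 32, 32); single[10:20, 10:20] <- TRUE
  expect_equal(keep_central_component(single, c(15, 15)), single)

  # centroid on background: nearest component is kept
  two <- matrix(FALSE, 64, 64)
  two[5:10, 5:10] <- TRUE
  two[40:60, 40:60] <- TRUE
  out <- keep_central_component(two, c(30, 30), min_size = 10)
  expect_true(any(out[40:60, 40:60])) # nearer to (30,30) than the corner blob
  expect_false(any(out[5:10, 5:10]))

  empty <- matrix(FALSE, 16, 16)
  expect_equal(keep_central_component(empty, c(8, 8)), empty)
})

test_that("orientation profiles peak along object orientations", {
  bank20 <- build_filter_bank(1, 20, 41)
  bar <- phantom_bar(96, width = 3, fg = 1, bg = 0)
  pb <- orientation_profile(bar, bank20)
  expect_equal(which.max(pb$values), 1) # horizontal = orientation 0 deg
  expect_equal(max(pb$values), 1)       # normalized to max 1
  expect_lt(sort(pb$values, decreasing = TRUE)[5], 0.8) # single dominant peak

  cross <- bar + t(bar); cross <- pmin(cross, 1)
  pc <- orientation_profile(cross, bank20)
  peaks <- order(pc$values, decreasing = TRUE)[1:2]
  expect_setequal(peaks, c(1, 11)) # 0 and 90 degrees

  expect_equal(orientation_profile(matrix(0, 48, 48), bank20)$values,
               numeric(20))
})

test_that("star/string classification counts prominent peaks", {
  bank20 <- build_filter_bank(1, 20, 41)
  bar <- phantom_bar(96, width = 3, fg = 1, bg = 0)
  cross <- pmin(bar + t(bar), 1)
  cs <- classify_star_string(orientation_profile(cross, bank20))
  expect_equal(cs$label, "star")
  expect_equal(cs$n_prominent, 2L)
  cb <- classify_star_string(orientation_profile(bar, bank20))
  expect_equal(cb$label, "string")
  expect_equal(cb$n_prominent, 1L)

  # a rendered synthetic star has >= 2 prominent peaks
  cfg <- scene_config(image_size = c(128, 128), n_stars = 1,
                      n_processes_range = c(5L, 5L), margin = 60, seed = 9)
  star <- generate_star(c(64, 64), cfg, seed = 9)
  ps <- orientation_profile(star$mask * 1, bank20)
  expect_gte(sum(ps$values >= 0.5), 2)
  expect_equal(classify_star_string(ps)$label, "star")

  # ties: a uniform profile is isotropic -> star by the documented rule
  unif <- structure(list(values = rep(0.8, 20), angle_step = 9),
                    class = "orientation_profile")
  expect_equal(classify_star_string(unif)$label, "star")
  # degenerate: all-zero profile -> string
  zero <- structure(list(values = numeric(20), angle_step = 9),
                    class = "orientation_profile")
  expect_equal(classify_star_string(zero)$label, "string")
  expect_equal(classify_star_string(zero)$n_prominent, 0L)
  expect_error(classify_star_string(unif, prominence_frac = 1.2),
               "prominence_frac")
})

test_that("classification is rotation-equivariant across bank orientations", {
  bank20 <- build_filter_bank(1, 20, 41)
  bar <- phantom_bar(97, width = 3, fg = 1, bg = 0)
  cross <- pmin(bar + t(bar), 1)
  base_bar <- classify_star_string(orientation_profile(bar, bank20))
  base_cross <- classify_star_string(orientation_profile(cross, bank20))
  for (k in seq(0, 19)) {
    ang <- k * bank20$angle_step
    rb <- rotate_image(bar, ang, "nearest")
    cb <- classify_star_string(orientation_profile(rb, bank20))
    expect_equal(cb$label, "string")
    # peak angle tracks the rotation (mod 180, one-step slack for sampling)
    d <- abs(((cb$peak_angles[1] - (base_bar$peak_angles[1] + ang)) %% 180))
    expect_lte(min(d, 180 - d), bank20$angle_step)
    rc <- rotate_image(cross, ang, "nearest")
    expect_equal(
      classify_star_string(orientation_profile(rc, bank20))$label, "star")
  }
})

test_that("reassembly labels cells, marks overlap, drops strings", {
  # two disjoint patches
  m1 <- matrix(FALSE, 16, 16); m1[4:12, 4:12] <- TRUE
  pm <- list(list(mask = m1, roi = list(top = 1L, left = 1L, size = 16L)),
             list(mask = m1, roi = list(top = 30L, left = 30L, size = 16L)))
  seg <- reassemble(pm, c(64, 64))
  expect_equal(sort(unique(as.vector(seg$labels))), c(0L, 1L, 2L))
  expect_equal(sum(seg$labels == 1), sum(m1))
  expect_equal(sum(seg$labels == 2), sum(m1))

  # overlapping foreground becomes the ambiguous label
  pm2 <- list(list(mask = m1, roi = list(top = 1L, left = 1L, size = 16L)),
              list(mask = m1, roi = list(top = 1L, left = 6L, size = 16L)))
  seg2 <- reassemble(pm2, c(32, 32))
  ov <- sum(m1[, 6:12] & m1[, 1:7]) # 9 rows x 4 overlapping columns
  expect_equal(sum(seg2$labels == seg2$ambiguous_label), ov)
  # conservation: every retained patch-foreground pixel is labeled
  expect_equal(sum(seg2$labels != 0), 2 * sum(m1) - ov)

  # strings excluded
  seg3 <- reassemble(pm, c(64, 64), classes = c("star", "string"))
  expect_equal(seg3$n_cells, 1L)
  expect_false(any(seg3$labels == 2))

  # duplicate ROIs merged with a warning
  expect_warning(seg4 <- reassemble(list(pm[[1]], pm[[1]]), c(32, 32)),
                 "duplicate")
  expect_equal(seg4$n_cells, 1L)
})

test_that("scene reassembly keeps stars and removes strings end to end", {
  sc <- render_scene(scene_config(image_size = c(320, 320), n_stars = 3,
                                  n_strings = 2, min_soma_separation = 90,
                                  margin = 60, seed = 13))
  bank20 <- build_filter_bank(1, 20, 41)
  patch_masks <- list(); classes <- list()
  for (i in seq_along(sc$classes)) {
    roi <- astroseg:::roi_around(sc$centroids[i, ], 128L)
    mask <- extract_patch((sc$label_map == i) * 1, roi) > 0
    patch_masks[[i]] <- list(mask = mask, roi = roi)
    classes[[i]] <- classify_star_string(orientation_profile(mask, bank20))
  }
  seg <- reassemble(patch_masks, dim(sc$image), classes)
  expect_equal(seg$n_cells, 3L)
  expect_setequal(seg$kept, which(sc$classes == "star"))
})
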