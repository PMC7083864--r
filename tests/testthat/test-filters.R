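test_that("bank construction enforces arguments and advertised structure", {
  expect_error(build_filter_bank(3, 1, 15), "n_orientations")
  expect_error(build_filter_bank(3, 8, 14), "odd")
  expect_error(build_filter_bank(3, 8, 3), "odd integer >= 5")
  expect_error(build_filter_bank(0, 8, 15), "n_scales")

  bank <- build_filter_bank(3, 20, 15)
  expect_equal(bank$angle_step, 9)
  expect_length(unlist(bank$kernels, recursive = FALSE), 60)
  expect_true(is.matrix(bank$lowpass))
  # support approximately doubles per scale
  ratio <- bank$kernel_size_per_scale[-1] / bank$kernel_size_per_scale[-3]
  expect_true(all(abs(ratio - 2) < 0.1))
})

test_that("directional kernels are zero-mean with bounded response", {
  bank <- build_filter_bank(2, 8, 15)
  ks <- unlist(bank$kernels, recursive = FALSE)
  expect_true(all(abs(vapply(ks, sum, numeric(1))) < 1e-10))
  # max |response| to any [0,1] image is the positive-part mass (zero-mean
  # kernels), and the bank normalization caps it at 1
  posmass <- vapply(ks, function(k) sum(pmax(k, 0)), numeric(1))
  expect_true(all(posmass <= 1 + 1e-12))
  expect_equal(max(posmass), 1, tolerance = 1e-12)
  # equal L2 norm across the bank (unit L2, shared rescaling)
  l2 <- vapply(ks, function(k) sqrt(sum(k^2)), numeric(1))
  expect_lt(diff(range(l2)), 1e-10)
})

test_that("smoothing kernels are nonnegative unit-mass averages", {
  bank <- build_filter_bank(2, 6, 15)
  ss <- unlist(bank$smoothers, recursive = FALSE)
  expect_true(all(vapply(ss, min, numeric(1)) >= 0))
  expect_true(all(abs(vapply(ss, sum, numeric(1)) - 1) < 1e-12))
})

test_that("kernels at orientation l are rotations of the l = 0 kernel", {
  bank <- build_filter_bank(1, 8, 31)
  k0 <- bank$kernels[[1]][[1]]
  for (l in c(2, 4, 7)) {
    kr <- rotate_image(k0, (l - 1) * bank$angle_step, "bilinear")
    rel <- sqrt(sum((bank$kernels[[1]][[l]] - kr)^2) / sum(k0^2))
    expect_lt(rel, 0.12) # bilinear interpolation error
  }
  # exact at 90 degrees (grid-aligned rotation)
  l90 <- 1 + 90 / bank$angle_step
  expect_equal(rotate_image(k0, 90, "bilinear"), bank$kernels[[1]][[l90]],
               tolerance = 1e-10)
})

test_that("two orthogonal kernels respond symmetrically to rotated bars", {
  bank <- build_filter_bank(1, 2, 5)
  expect_length(bank$kernels[[1]], 2)
  bar_h <- phantom_bar(64, width = 3, horizontal = TRUE)
  bar_v <- phantom_bar(64, width = 3, horizontal = FALSE)
  st_h <- apply_bank(bar_h, bank)
  st_v <- apply_bank(bar_v, bank)
  ctr <- 32
  expect_equal(st_h$responses[ctr, ctr, 1, 1], st_v$responses[ctr, ctr, 2, 1],
               tolerance = 1e-8)
})

test_that("apply_bank matches the brute-force convolution oracle to 1e-8", {
  set.seed(11)
  img <- matrix(runif(64 * 64), 64, 64)
  bank <- build_filter_bank(2, 4, 9)
  st <- apply_bank(img, bank)
  st_s <- apply_bank(img, bank, type = "smoothing")
  for (j in 1:2) for (l in 1:4) {
    expect_lt(max(abs(st$responses[, , l, j] -
                        brute_xcorr(img, bank$kernels[[j]][[l]]))), 1e-8)
    expect_lt(max(abs(st_s$responses[, , l, j] -
                        brute_xcorr(img, bank$smoothers[[j]][[l]]))), 1e-8)
  }
})

test_that("apply_bank trivial identities hold", {
  bank <- build_filter_bank(1, 4, 9)
  # constant image: zero-mean kernels respond 0
  st <- apply_bank(matrix(0.7, 32, 32), bank)
  expect_lt(max(abs(st$responses)), 1e-10)
  # delta image reproduces the (point-symmetric = flipped) kernel
  img <- matrix(0, 33, 33); img[17, 17] <- 1
  st <- apply_bank(img, bank)
  got <- st$responses[13:21, 13:21, 2, 1]
  expect_equal(got, bank$kernels[[1]][[2]], tolerance = 1e-10)
  expect_error(apply_bank(matrix(numeric(0), 0, 0), bank), "empty")
  expect_error(apply_bank(matrix(c(1, NA, 1, 1), 2), bank), "finite")
})

test_that("rotating the input cyclically permutes the orientation axis", {
  # smooth anisotropic blob at the center (rotation-fixed point)
  H <- 129
  g <- outer(seq(-64, 64), seq(-64, 64), function(y, x)
    exp(-x^2 / 800 - y^2 / 80))
  bank <- build_filter_bank(1, 8, 21)
  st0 <- apply_bank(g, bank)
  str <- apply_bank(rotate_image(g, bank$angle_step, "bilinear"), bank)
  ctr <- 65
  prof0 <- st0$responses[ctr, ctr, , 1]
  profr <- str$responses[ctr, ctr, , 1]
  # orientation l of the rotated image matches orientation l-1 of the original
  shifted <- c(prof0[bank$n_orientations], prof0[-bank$n_orientations])
  expect_lt(sqrt(sum((profr - shifted)^2) / sum(prof0^2)), 0.05)
})
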