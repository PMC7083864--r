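test_that("spec validation catches inconsistent architectures", {
  expect_error(gesunet_spec(patch_size = 100, depth = 3), "divisible")
  expect_error(gesunet_spec(n_basis = 1), "n_basis")
  expect_error(gesunet_spec(loss = "mse"), "mean-absolute-error")
  expect_error(build_gesunet(gesunet_spec(
    transfer_encoder = "pretrained-image-classifier")), "download")
  sp <- gesunet_spec(preset = "desk")
  expect_equal(sp$patch_size, 64L)
  expect_equal(sp$depth, 3L)
  expect_equal(sp$base_channels, 8L)
})

test_that("constrained convolution equals the explicit basis combination", {
  set.seed(51)
  basis <- array(rnorm(5 * 5 * 4), c(5, 5, 4))
  coef <- array(rnorm(3 * 2 * 4), c(3, 2, 4)) # (out, in, nb)
  x <- array(runif(16 * 16 * 2), c(16, 16, 2))
  got <- constrained_conv_layer(x, coef, basis)
  # oracle: per-basis convolutions by brute-force shift-and-add, combined
  want <- array(0, c(16, 16, 3))
  for (o in 1:3) for (i in 1:2) for (b in 1:4)
    want[, , o] <- want[, , o] +
      coef[o, i, b] * brute_xcorr_zero(x[, , i], basis[, , b])
  expect_lt(max(abs(got - want)), 1e-6)

  # one-hot coefficients reduce to a plain convolution with that kernel
  oh <- array(0, c(1, 1, 4)); oh[1, 1, 3] <- 1
  got1 <- constrained_conv_layer(x[, , 1], oh, basis)
  expect_lt(max(abs(got1 - brute_xcorr_zero(x[, , 1], basis[, , 3]))), 1e-10)

  expect_error(constrained_conv_layer(x, array(0, c(3, 5, 4)), basis),
               "in_channels")
  expect_error(constrained_conv_layer(x, array(0, c(3, 2, 5)), basis),
               "n_basis")
})

test_that("constrained layers make the parameter count size-independent", {
  # out = 16, in = 1, 9 basis filters, 15x15 kernels: 144 coefficients
  # (+ 16 biases) versus 3600 weights for a free convolution
  cp <- astroseg:::conv_param(15, 1, 16, constrained = TRUE, nb = 9)
  expect_equal(length(cp$coef), 144)
  expect_equal(length(cp$b), 16)
  free <- astroseg:::conv_param(15, 1, 16)
  expect_equal(length(free$w), 3600)
  # same count if the basis kernels were 31x31
  expect_equal(length(astroseg:::conv_param(31, 1, 16, constrained = TRUE,
                                            nb = 9)$coef), 144)

  # whole network: constrained first U-net beats its free twin
  con <- astroseg:::unet_params(1, 8, 3, k = 5, constrained_encoder = TRUE,
                                nb = 9)
  fre <- astroseg:::unet_params(1, 8, 3, k = 5)
  expect_lt(astroseg:::tree_count(con), astroseg:::tree_count(fre))
})

test_that("forward passes are shaped, bounded and deterministic", {
  for (ps in c(32L, 64L, 128L)) {
    spec <- gesunet_spec(patch_size = ps, depth = 3L, base_channels = 4L)
    model <- build_gesunet(spec, seed = 2)
    y <- astroseg:::model_fwd(model, astroseg:::as_batch(matrix(0, ps, ps)))$y
    expect_equal(dim(y), c(ps, ps, 1L, 1L))
    expect_true(all(is.finite(y) & y >= 0 & y <= 1))
  }
  spec <- gesunet_spec(patch_size = 32L, depth = 2L, base_channels = 4L)
  m1 <- build_gesunet(spec, seed = 7)
  m2 <- build_gesunet(spec, seed = 7)
  x <- matrix(runif(32 * 32), 32, 32)
  expect_identical(segment_patch(m1, x), segment_patch(m2, x))
  expect_error(segment_patch(m1, matrix(0, 16, 16)), "32")
  # thresholding at 0 keeps every pixel
  expect_true(all(segment_patch(m1, x, prob_threshold = 0)))
})

test_that("augmentation multiplies pairs by k + 1 and preserves masks", {
  blob <- matrix(0, 32, 32); blob[10:20, 12:22] <- 1
  pairs <- replicate(6, list(image = blob * 0.8, mask = blob),
                     simplify = FALSE)
  ts <- astroseg:::training_set(pairs, 32L)
  expect_identical(augment(ts, 0), ts)
  a3 <- augment(ts, 3, seed = 4)
  expect_length(a3$patches, 24)
  expect_equal(a3$augmentation_factor, 3L)
  # deterministic given seed
  b3 <- augment(ts, 3, seed = 4)
  expect_identical(a3, b3)
  expect_false(identical(a3, augment(ts, 3, seed = 5)))
  # masks stay binary under the joint transform
  expect_true(all(vapply(a3$patches, function(p)
    all(p$mask %in% c(0, 1)), logical(1))))
  # exact 90-degree rotations preserve foreground area exactly
  for (ang in c(90, 180, 270))
    expect_equal(sum(rotate_image(blob, ang, "nearest")), sum(blob))
  expect_error(augment(ts, -1), "k")
})

test_that("a small network overfits five pairs (loss decreases, low MAE)", {
  set.seed(61)
  pairs <- lapply(1:5, function(i) {
    m <- matrix(0, 32, 32)
    r0 <- sample(4:12, 1); c0 <- sample(4:12, 1)
    m[r0 + 0:12, c0 + 0:12] <- 1
    img <- pmin(m * 0.75 + 0.1 + matrix(runif(1024, 0, 0.1), 32), 1)
    list(image = img, mask = m)
  })
  ts <- astroseg:::training_set(pairs, 32L)
  model <- build_gesunet(gesunet_spec(patch_size = 32L, depth = 2L,
                                      base_channels = 8L), seed = 1)
  # 200 optimizer steps: 5 pairs in one batch per epoch
  fit <- train_gesunet(model, ts, epochs = 200, validation_fraction = 0,
                       batch_size = 5L, seed = 1)
  expect_equal(nrow(fit$history), 200)
  expect_true(all(is.na(fit$history$val_mae)))
  expect_lt(fit$history$train_mae[200], 0.05)
  expect_lt(fit$history$train_mae[200], fit$history$train_mae[1])
})

test_that("training requires compatible inputs", {
  ts <- astroseg:::training_set(list(), 64L)
  model <- build_gesunet(gesunet_spec(preset = "desk"), seed = 1)
  expect_error(train_gesunet(model, ts), "empty")
  blob <- matrix(0, 32, 32); blob[4:9, 4:9] <- 1
  ts32 <- astroseg:::training_set(list(list(image = blob, mask = blob)), 32L)
  expect_error(train_gesunet(model, ts32), "patch size")
})

test_that("the ablation variants train and report loss histories", {
  set.seed(62)
  pairs <- lapply(1:8, function(i) {
    m <- matrix(0, 32, 32); m[8:24, 8:24] <- 1
    list(image = m * 0.7 + 0.1, mask = m)
  })
  ts <- astroseg:::training_set(pairs, 32L)
  hist <- list()
  for (arch in c("gesu", "unet1", "unet2")) {
    spec <- gesunet_spec(patch_size = 32L, depth = 2L, base_channels = 4L,
                         architecture = arch)
    fit <- train_gesunet(build_gesunet(spec, seed = 1), ts, epochs = 3,
                         validation_fraction = 0.25, seed = 1)
    hist[[arch]] <- fit$history
    expect_equal(nrow(fit$history), 3)
    expect_false(any(is.na(fit$history$val_mae)))
  }
  # losses are finite and reported for qualitative architecture comparison
  expect_true(all(vapply(hist, function(h)
    all(is.finite(h$train_mae)), logical(1))))
})

test_that("models round-trip through serialization", {
  model <- build_gesunet(gesunet_spec(patch_size = 32L, depth = 2L,
                                      base_channels = 4L), seed = 3)
  path <- tempfile(fileext = ".rds")
  save_gesunet(model, path)
  m2 <- load_gesunet(path)
  x <- matrix(runif(1024), 32, 32)
  expect_identical(segment_patch(model, x), segment_patch(m2, x))
  bad <- tempfile(fileext = ".rds"); saveRDS(list(a = 1), bad)
  expect_error(load_gesunet(bad), "not a serialized")
})
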