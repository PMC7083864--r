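#' Specification of the stacked geometry-constrained segmentation network
#'
#' The network is two stacked U-nets: the first ("representation") U-net has
#' encoder convolutions constrained to linear combinations of predefined
#' directional basis filters (only the combination coefficients are trained),
#' the second ("segmentation") U-net receives the original patch concatenated
#' with the first U-net's output. Presets: `"full"` = 128x128 patches, depth
#' 4, 16 base channels; `"desk"` = 64x64 patches, depth 3, 8 base channels
#' (trains in CPU-minutes on synthetic data).
#'
#' @param patch_size input patch side; must be divisible by `2^depth`.
#' @param depth number of pooling levels per U-net.
#' @param base_channels channels of the first encoder level (doubling per
#'   level).
#' @param n_basis number of basis filters per constrained layer (>= 2). The
#'   default basis is `n_basis - 1` directional kernels plus one low-pass,
#'   built by [build_filter_bank()] at `basis_kernel_size`.
#' @param basis_kernel_size odd spatial size of the basis filters.
#' @param basis_bank optional [build_filter_bank()] object supplying the basis
#'   (finest scale + low-pass used; overrides `n_basis`/`basis_kernel_size`).
#' @param transfer_encoder `"none"` (random initialization; default, works
#'   offline) or `"pretrained-image-classifier"`, which would initialize the
#'   second encoder from an external pretrained classification backbone and
#'   therefore requires a one-time weight download - not available in this
#'   build and rejected with an informative error.
#' @param architecture `"gesu"` (both U-nets, default), `"unet1"` (first
#'   U-net alone, constrained encoder) or `"unet2"` (second U-net alone, free
#'   convolutions) - the ablation variants.
#' @param loss only `"mae"` (mean absolute error) is supported.
#' @param preset `"full"` or `"desk"` fills size/depth/channels.
#' @return a list of class `gesunet_spec`.
#' @export
gesunet_spec <- function(patch_size = 128L, depth = 4L, base_channels = 16L,
                         n_basis = 9L, basis_kernel_size = 5L,
                         basis_bank = NULL,
                         transfer_encoder = c("none",
                                              "pretrained-image-classifier"),
                         architecture = c("gesu", "unet1", "unet2"),
                         loss = "mae", preset = NULL) {
  transfer_encoder <- match.arg(transfer_encoder)
  architecture <- match.arg(architecture)
  if (!is.null(preset)) {
    preset <- match.arg(preset, c("full", "desk"))
    if (preset == "full") {
      patch_size <- 128L; depth <- 4L; base_channels <- 16L
    } else {
      patch_size <- 64L; depth <- 3L; base_channels <- 8L
    }
  }
  if (patch_size %% 2^depth != 0)
    stop("patch_size must be divisible by 2^depth")
  if (n_basis < 2) stop("n_basis must be >= 2")
  if (loss != "mae") stop("only the mean-absolute-error loss is supported")
  structure(list(patch_size = as.integer(patch_size),
                 depth = as.integer(depth),
                 base_channels = as.integer(base_channels),
                 n_basis = as.integer(n_basis),
                 basis_kernel_size = as.integer(basis_kernel_size),
                 basis_bank = basis_bank,
                 transfer_encoder = transfer_encoder,
                 architecture = architecture, loss = loss),
            class = "gesunet_spec")
}

# basis array (k, k, nb): finest-scale directional kernels + low-pass of a
# bank, each normalized to unit L2 norm
basis_from_bank <- function(bank) {
  ks <- c(bank$kernels[[1]], list(bank$lowpass))
  k <- nrow(ks[[1]])
  arr <- array(0, c(k, k, length(ks)))
  for (i in seq_along(ks)) arr[, , i] <- ks[[i]] / sqrt(sum(ks[[i]]^2))
  arr
}

#' Build the stacked constrained segmentation network
#'
#' @param spec a [gesunet_spec()].
#' @param seed seed for weight initialization (reproducible builds).
#' @return an object of class `gesunet`: list with `spec`, `basis` (array
#'   `k x k x n_basis`), and parameter trees `unet1` (constrained encoder)
#'   and/or `unet2` per the architecture. Maps a
#'   `patch_size x patch_size` patch to a per-pixel probability in \[0, 1\].
#' @export
build_gesunet <- function(spec = gesunet_spec(), seed = 1L) {
  stopifnot(inherits(spec, "gesunet_spec"))
  if (spec$transfer_encoder == "pretrained-image-classifier")
    stop("transfer_encoder = 'pretrained-image-classifier' requires a ",
         "one-time external download of classification-backbone weights, ",
         "which is unavailable in this offline build; use 'none'")
  bank <- spec$basis_bank %||%
    build_filter_bank(1, max(spec$n_basis - 1L, 2L),
                      spec$basis_kernel_size)
  basis <- basis_from_bank(bank)
  nb <- dim(basis)[3]
  with_seed(seed, {
    unet1 <- if (spec$architecture %in% c("gesu", "unet1"))
      unet_params(1L, spec$base_channels, spec$depth,
                  k = dim(basis)[1], constrained_encoder = TRUE, nb = nb)
    unet2 <- if (spec$architecture %in% c("gesu", "unet2"))
      unet_params(if (spec$architecture == "gesu") 2L else 1L,
                  spec$base_channels, spec$depth)
    structure(list(spec = spec, basis = basis, unet1 = unet1,
                   unet2 = unet2, version = 1L),
              class = "gesunet")
  })
}

#' @export
print.gesunet <- function(x, ...) {
  cat("GESU-net (", x$spec$architecture, "):", x$spec$patch_size, "x",
      x$spec$patch_size, "patches, depth", x$spec$depth, ", base",
      x$spec$base_channels, "channels,", dim(x$basis)[3],
      "basis filters;", count_parameters(x), "trainable parameters\n")
  invisible(x)
}

#' Count trainable parameters of a model
#' @param model a [build_gesunet()] model.
#' @return integer count (constrained layers contribute
#'   `out_channels * in_channels * n_basis` weights plus biases,
#'   independent of the basis kernels' spatial size).
#' @export
count_parameters <- function(model) {
  n <- 0
  for (net in c("unet1", "unet2"))
    if (!is.null(model[[net]])) n <- n + tree_count(model[[net]])
  as.integer(n)
}

#' Convolution constrained to a linear combination of basis kernels
#'
#' Output channel `c` is `sum_b coefficients[c, i, b] * (input_i * basis_b)`;
#' only the combination coefficients (and bias) would be trained, so the
#' trainable parameter count `out_channels * in_channels * n_basis` is
#' independent of the kernels' spatial size.
#'
#' @param input matrix (H, W), array (H, W, C) or batch (H, W, C, N).
#' @param coefficients array `(out_channels, in_channels, n_basis)`.
#' @param basis array `(k, k, n_basis)` of basis kernels.
#' @param bias optional length-`out_channels` vector (default zeros).
#' @return feature stack with the input's spatial size and `out_channels`
#'   channels (same array rank as the input).
#' @export
constrained_conv_layer <- function(input, coefficients, basis, bias = NULL) {
  rank <- length(dim(input) %||% c(NA, NA))
  x <- as_batch(input)
  if (length(dim(coefficients)) != 3)
    stop("coefficients must be (out_channels, in_channels, n_basis)")
  if (dim(coefficients)[2] != dim(x)[3])
    stop("coefficients in_channels (", dim(coefficients)[2],
         ") does not match input channels (", dim(x)[3], ")")
  if (dim(coefficients)[3] != dim(basis)[3])
    stop("coefficients n_basis (", dim(coefficients)[3],
         ") does not match basis count (", dim(basis)[3], ")")
  cout <- dim(coefficients)[1]
  # internal layout is (n_basis, in, out)
  coef <- aperm(coefficients, c(3, 2, 1))
  w <- compose_basis(basis, coef)
  y <- .conv2d_fwd(x, w, bias %||% numeric(cout))
  if (rank == 2 && cout == 1 && dim(x)[4] == 1) {
    dim(y) <- dim(y)[1:2]
  } else if (rank <= 3 && dim(x)[4] == 1) {
    dim(y) <- dim(y)[1:3]
  }
  y
}

#' Augment a training set with rigid transforms
#'
#' Generates `k` extra pairs per input pair by applying a joint random rigid
#' transform: rotation uniform in \[0, 360) degrees about the patch center
#' followed by an integer translation within +/- 10% of the patch size
#' (bilinear resampling for the image, nearest-neighbor for the mask).
#' Deterministic given `seed`.
#'
#' @param training_set a `training_set` (see [make_training_pairs()]).
#' @param k extra pairs per input pair (>= 0); `k = 0` returns the input.
#' @param seed integer seed.
#' @return a `training_set` with `(k + 1) * n` pairs (originals first).
#' @export
augment <- function(training_set, k, seed = 1L) {
  stopifnot(inherits(training_set, "training_set"))
  if (k < 0) stop("k must be >= 0")
  if (k == 0) return(training_set)
  ps <- training_set$patch_size
  max_shift <- round(0.1 * ps)
  with_seed(seed, {
    extra <- list()
    for (pair in training_set$patches) {
      for (i in seq_len(k)) {
        ang <- runif(1, 0, 360)
        dr <- sample(seq(-max_shift, max_shift), 1)
        dc <- sample(seq(-max_shift, max_shift), 1)
        img <- shift_matrix(rotate_image(pair$image, ang, "bilinear"), dr, dc)
        msk <- shift_matrix(rotate_image(pair$mask, ang, "nearest"), dr, dc)
        extra[[length(extra) + 1]] <- list(image = img, mask = msk)
      }
    }
    training_set(c(training_set$patches, extra), ps,
                 augmentation_factor = as.integer(k))
  })
}

shift_matrix <- function(m, dr, dc) {
  H <- nrow(m); W <- ncol(m)
  out <- matrix(0, H, W)
  sr <- seq_len(H) - dr; sc <- seq_len(W) - dc
  rok <- sr >= 1 & sr <= H; cok <- sc >= 1 & sc <= W
  out[rok, cok] <- m[sr[rok], sc[cok]]
  out
}

stack_pairs <- function(pairs, field) {
  H <- nrow(pairs[[1]][[field]])
  arr <- array(0, c(H, ncol(pairs[[1]][[field]]), 1L, length(pairs)))
  for (i in seq_along(pairs)) arr[, , 1, i] <- pairs[[i]][[field]]
  arr
}

#' Train a segmentation network
#'
#' Mean-absolute-error loss on the per-pixel probabilities, Adam optimizer,
#' random mini-batches; a seeded random `validation_fraction` of the pairs is
#' held out and evaluated each epoch. Optimizer settings are package defaults
#' (adaptive-moment optimizer, learning rate 1e-3, batch size 8), not values
#' from any reference. Runs are reproducible given `seed`.
#'
#' @param model a [build_gesunet()] model.
#' @param training_set a `training_set` whose patch size matches the model.
#' @param epochs maximal number of epochs.
#' @param validation_fraction fraction of pairs held out (0 disables
#'   validation; the validation history is then empty).
#' @param seed seed controlling the split and batch order.
#' @param lr,batch_size optimizer settings.
#' @param dice_target optional early stop: training ends once the held-out
#'   pixel Dice (masks thresholded at 0.5) reaches this value.
#' @param verbose print per-epoch losses.
#' @return list with `model` (trained) and `history` (data frame `epoch`,
#'   `train_mae`, `val_mae`, `val_dice`; validation columns are `NA` when no
#'   validation split is requested).
#' @export
train_gesunet <- function(model, training_set, epochs = 30,
                          validation_fraction = 0.15, seed = 1L,
                          lr = 1e-3, batch_size = 8L, dice_target = NULL,
                          verbose = FALSE) {
  stopifnot(inherits(model, "gesunet"), inherits(training_set, "training_set"))
  pairs <- training_set$patches
  if (length(pairs) == 0) stop("training set is empty")
  if (training_set$patch_size != model$spec$patch_size)
    stop("training patch size (", training_set$patch_size,
         ") does not match model patch size (", model$spec$patch_size, ")")
  with_seed(seed, {
    n <- length(pairs)
    n_val <- round(validation_fraction * n)
    val_idx <- if (n_val > 0) sample.int(n, n_val) else integer(0)
    tr_idx <- setdiff(seq_len(n), val_idx)
    if (length(tr_idx) == 0) stop("no training pairs left after split")
    Xval <- if (n_val > 0) stack_pairs(pairs[val_idx], "image")
    Tval <- if (n_val > 0) stack_pairs(pairs[val_idx], "mask")
    state <- adam_init(model)
    hist <- data.frame(epoch = integer(0), train_mae = numeric(0),
                       val_mae = numeric(0), val_dice = numeric(0))
    for (ep in seq_len(epochs)) {
      ord <- sample(tr_idx)
      tot <- 0
      for (b0 in seq(1, length(ord), by = batch_size)) {
        bi <- ord[b0:min(b0 + batch_size - 1, length(ord))]
        X <- stack_pairs(pairs[bi], "image")
        Tm <- stack_pairs(pairs[bi], "mask")
        fw <- model_fwd(model, X)
        err <- fw$y - Tm
        tot <- tot + sum(abs(err))
        # search direction: smooth (Huber) relaxation of the absolute error,
        # which on [0,1] outputs coincides with the quadratic. The raw MAE
        # subgradient is untrainable from random initialization here (the
        # background majority saturates the output; see vignette); the
        # reported loss history stays plain MAE.
        gy <- 2 * err / length(err)
        # deep supervision for the stacked model: the loss is also applied
        # to the first U-net's output (weight 0.5)
        aux <- NULL
        if (model$spec$architecture == "gesu")
          aux <- (fw$cache$u1$y - Tm) / length(err)
        grads <- model_bwd(model, fw$cache, gy, aux)
        st <- adam_step(model, grads, state, lr = lr)
        model <- st$model
        state <- st$state
      }
      train_mae <- tot / (length(ord) * model$spec$patch_size^2)
      val_mae <- NA_real_; val_dice <- NA_real_
      if (n_val > 0) {
        pv <- predict_batch(model, Xval)
        val_mae <- mean(abs(pv - Tval))
        val_dice <- mean(vapply(seq_len(n_val), function(i) {
          dice_of(pv[, , 1, i] >= 0.5, Tval[, , 1, i] > 0)
        }, numeric(1)))
      }
      hist <- rbind(hist, data.frame(epoch = ep, train_mae = train_mae,
                                     val_mae = val_mae, val_dice = val_dice))
      if (verbose)
        message(sprintf("epoch %3d  train MAE %.4f  val MAE %s  val Dice %s",
                        ep, train_mae, format(val_mae, digits = 3),
                        format(val_dice, digits = 3)))
      if (!is.null(dice_target) && isTRUE(val_dice >= dice_target)) break
    }
    list(model = model, history = hist)
  })
}

dice_of <- function(pred, truth) {
  tp <- sum(pred & truth)
  den <- 2 * tp + sum(pred & !truth) + sum(!pred & truth)
  if (den == 0) return(1)
  2 * tp / den
}

# forward in chunks to bound memory
predict_batch <- function(model, X, chunk = 16L) {
  out <- X * 0
  N <- dim(X)[4]
  for (s in seq(1, N, by = chunk)) {
    ii <- s:min(s + chunk - 1, N)
    out[, , , ii] <- model_fwd(model, X[, , , ii, drop = FALSE])$y
  }
  out
}

#' Segment a single patch
#'
#' @param model a trained [build_gesunet()] model.
#' @param patch numeric matrix in \[0, 1\] of the model's patch size.
#' @param prob_threshold probability threshold for the binary mask (default
#'   0.5).
#' @return logical mask of the patch size.
#' @export
segment_patch <- function(model, patch, prob_threshold = 0.5) {
  stopifnot(inherits(model, "gesunet"))
  if (!is.matrix(patch) || nrow(patch) != model$spec$patch_size ||
        ncol(patch) != model$spec$patch_size)
    stop("patch must be a ", model$spec$patch_size, "x",
         model$spec$patch_size, " matrix")
  y <- model_fwd(model, as_batch(patch))$y
  matrix(y >= prob_threshold, nrow(patch), ncol(patch))
}

#' Save / load a model
#'
#' The on-disk format is a versioned R list (`version` field) written with
#' `saveRDS`; forward-compatible readers should check `version`.
#' @param model a `gesunet` model.
#' @param path file path (conventionally `.rds`).
#' @return `load_gesunet` returns the model.
#' @export
save_gesunet <- function(model, path) {
  stopifnot(inherits(model, "gesunet"))
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_gesunet
#' @export
load_gesunet <- function(path) {
  model <- readRDS(path)
  if (!inherits(model, "gesunet") || is.null(model$version))
    stop("not a serialized gesunet model: ", path)
  model
}
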