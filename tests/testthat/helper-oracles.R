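# Independent oracles and fixture builders used across the suite.

# mirror (symmetric) extension of 1..n by p, implemented independently of the
# package's pad_reflect
reflect_index <- function(n, p) {
  idx <- seq.int(1 - p, n + p)
  period <- 2 * n
  idx <- ((idx - 1) %% period + period) %% period
  ifelse(idx < n, idx + 1, 2 * n - idx)
}

# brute-force (shift-and-add) cross-correlation with reflective boundaries;
# the oracle for apply_bank / xcorr2
brute_xcorr <- function(x, k) {
  p <- (nrow(k) - 1) %/% 2
  xp <- x[reflect_index(nrow(x), p), reflect_index(ncol(x), p), drop = FALSE]
  H <- nrow(x); W <- ncol(x)
  out <- matrix(0, H, W)
  for (dy in seq_len(nrow(k))) for (dx in seq_len(ncol(k)))
    out <- out + k[dy, dx] *
      xp[(dy - 1) + seq_len(H), (dx - 1) + seq_len(W)]
  out
}

# brute-force zero-padded cross-correlation (the convention of the network's
# conv layers)
brute_xcorr_zero <- function(x, k) {
  p <- (nrow(k) - 1) %/% 2
  H <- nrow(x); W <- ncol(x)
  out <- matrix(0, H, W)
  for (dy in seq_len(nrow(k))) for (dx in seq_len(ncol(k))) {
    sh <- matrix(0, H, W)
    rr <- seq_len(H) + dy - 1 - p
    cc <- seq_len(W) + dx - 1 - p
    rok <- rr >= 1 & rr <= H
    cok <- cc >= 1 & cc <= W
    sh[rok, cok] <- x[rr[rok], cc[cok]]
    out <- out + k[dy, dx] * sh
  }
  out
}

# brute-force Directional Ratio from explicit per-orientation correlations
brute_dr <- function(image, bank, scale, eps = 1e-12) {
  resp <- lapply(seq_len(bank$n_scales), function(j)
    lapply(bank$smoothers[[j]], function(k) brute_xcorr(image, k)))
  gmax <- max(abs(unlist(resp)))
  rj <- lapply(resp[[scale]], function(r) abs(r) / gmax)
  mn <- Reduce(pmin, rj)
  mx <- Reduce(pmax, rj)
  mn^2 / (mx + eps)
}

# disk / bar phantoms
phantom_disk <- function(size = 128, center = (size + 1) / 2, radius = 30,
                         fg = 0.95, bg = 0.05) {
  img <- matrix(bg, size, size)
  img[(row(img) - center[1])^2 + (col(img) - center[2])^2 <= radius^2] <- fg
  img
}

phantom_bar <- function(size = 128, width = 3, horizontal = TRUE, fg = 0.95,
                        bg = 0.05) {
  img <- matrix(bg, size, size)
  mid <- floor(size / 2)
  sel <- mid + seq_len(width) - (width + 1) %/% 2
  if (horizontal) img[sel, ] <- fg else img[, sel] <- fg
  img
}

# exhaustive optimal bipartite matching: maximal number of (pred, truth)
# pairs within `radius`, then (among maximal) smallest total distance
optimal_match_tp <- function(predicted, truth, radius) {
  np <- nrow(predicted); nt <- nrow(truth)
  if (np == 0 || nt == 0) return(0L)
  d <- sqrt(outer(predicted[, 1], truth[, 1], `-`)^2 +
              outer(predicted[, 2], truth[, 2], `-`)^2)
  best <- 0L
  rec <- function(p, used) {
    if (p > np) {
      best <<- max(best, sum(used))
      return()
    }
    # bound: even matching all remaining predictions cannot beat best
    if (sum(used) + (np - p + 1) <= best) {
      # continue anyway only if could tie-improve count; count is the target
    }
    rec(p + 1, used) # leave prediction p unmatched
    for (t in seq_len(nt)) {
      if (!used[t] && d[p, t] <= radius) {
        used[t] <- TRUE
        rec(p + 1, used)
        used[t] <- FALSE
      }
    }
  }
  rec(1L, logical(nt))
  best
}

# small desk-scale training set: 64x64 patches of full-scale synthetic cells
desk_training_pairs <- function(n_pairs, seed) {
  pairs <- list()
  s <- 0
  while (length(pairs) < n_pairs) {
    s <- s + 1
    sc <- render_scene(scene_config(image_size = c(256, 256), n_stars = 6,
                                    n_strings = 0, min_soma_separation = 56,
                                    margin = 40, seed = seed * 1000 + s))
    pairs <- c(pairs, make_training_pairs(sc, 64L)$patches)
  }
  astroseg:::training_set(pairs[seq_len(n_pairs)], 64L)
}

# memoized desk-scale model shared between acceptance criteria / pipeline
# integration (training is the expensive step)
.model_cache <- new.env(parent = emptyenv())
get_desk_model <- function(seed = 1L) {
  key <- paste0("m", seed)
  if (is.null(.model_cache[[key]])) {
    ts <- desk_training_pairs(100, seed = seed)
    model <- build_gesunet(gesunet_spec(preset = "desk"), seed = seed)
    fit <- train_gesunet(model, ts, epochs = 40, validation_fraction = 0.15,
                         seed = seed, dice_target = 0.76)
    .model_cache[[key]] <- fit$model
  }
  .model_cache[[key]]
}
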