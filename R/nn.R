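# Internal minimal neural-network engine: static U-net graphs with manual
# backpropagation over the Rcpp conv/pool/upsample primitives, MAE loss and
# Adam. Feature maps are arrays dim = c(H, W, C, N).

as_batch <- function(x) {
  # matrix (H,W) or array (H,W,C) -> (H,W,C,N)
  if (is.matrix(x)) dim(x) <- c(dim(x), 1L, 1L)
  else if (length(dim(x)) == 3) dim(x) <- c(dim(x), 1L)
  x
}

cat4 <- function(a, b) {
  da <- dim(a); db <- dim(b)
  stopifnot(da[c(1, 2, 4)] == db[c(1, 2, 4)])
  out <- array(0, c(da[1], da[2], da[3] + db[3], da[4]))
  out[, , seq_len(da[3]), ] <- a
  out[, , da[3] + seq_len(db[3]), ] <- b
  out
}

split4 <- function(g, ca) {
  list(g[, , seq_len(ca), , drop = FALSE],
       g[, , -seq_len(ca), , drop = FALSE])
}

# compose an explicit kernel from basis filters and combination coefficients
# basis: (k, k, nb); coef: (nb, cin, cout) -> w: (k, k, cin, cout)
compose_basis <- function(basis, coef) {
  k <- dim(basis)[1]; nb <- dim(basis)[3]
  cin <- dim(coef)[2]; cout <- dim(coef)[3]
  w <- matrix(basis, k * k, nb) %*% matrix(coef, nb, cin * cout)
  dim(w) <- c(k, k, cin, cout)
  w
}

# gradient wrt coefficients given the gradient wrt the composed kernel
basis_coef_grad <- function(basis, gw) {
  k <- dim(basis)[1]; nb <- dim(basis)[3]
  cin <- dim(gw)[3]; cout <- dim(gw)[4]
  g <- t(matrix(basis, k * k, nb)) %*% matrix(gw, k * k, cin * cout)
  dim(g) <- c(nb, cin, cout)
  g
}

conv_param <- function(k, cin, cout, constrained = FALSE, nb = NULL) {
  p <- if (constrained) {
    list(type = "cconv",
         coef = array(rnorm(nb * cin * cout, 0, sqrt(2 / (nb * cin))),
                      c(nb, cin, cout)),
         b = numeric(cout))
  } else {
    list(type = "conv",
         w = array(rnorm(k * k * cin * cout, 0, sqrt(2 / (k * k * cin))),
                   c(k, k, cin, cout)),
         b = numeric(cout))
  }
  p
}

conv_fwd <- function(x, p, basis) {
  w <- if (p$type == "cconv") compose_basis(basis, p$coef) else p$w
  list(y = .conv2d_fwd(x, w, p$b), x = x, w = w)
}

conv_bwd <- function(p, cache, gy, basis) {
  r <- .conv2d_bwd(cache$x, cache$w, gy)
  grad <- if (p$type == "cconv")
    list(type = "cconv", coef = basis_coef_grad(basis, r$gw), b = r$gb)
  else list(type = "conv", w = r$gw, b = r$gb)
  list(gx = r$gx, grad = grad)
}

# leaky rectifier (slope 0.05 below zero): plain ReLUs die wholesale here -
# with the MAE subgradient the majority background class drives features
# negative early and a dead decoder leaves only the output bias, whose
# MAE-optimal uniform output is all-background
RELU_LEAK <- 0.05
relu_fwd <- function(x) {
  pos <- x > 0
  list(y = pmax(x, 0) + RELU_LEAK * pmin(x, 0), pos = pos)
}
relu_bwd <- function(cache, gy) gy * ifelse(cache$pos, 1, RELU_LEAK)
sigmoid_fwd <- function(x) 1 / (1 + exp(-x))

# conv + leaky relu block used everywhere in the U-nets
block_fwd <- function(x, p, basis) {
  cv <- conv_fwd(x, p, basis)
  rl <- relu_fwd(cv$y)
  list(y = rl$y, conv = cv, relu = rl)
}
block_bwd <- function(p, cache, gy, basis) {
  conv_bwd(p, cache$conv, relu_bwd(cache$relu, gy), basis)
}

# ---- single U-net --------------------------------------------------------

# parameters for one U-net; encoder convs may be constrained to the basis
unet_params <- function(in_ch, base, depth, k = 3,
                        constrained_encoder = FALSE, nb = NULL) {
  ch <- base * 2^(seq_len(depth) - 1)
  enc <- vector("list", depth)
  cin <- in_ch
  for (i in seq_len(depth)) {
    enc[[i]] <- list(
      a = conv_param(k, cin, ch[i], constrained_encoder, nb),
      b = conv_param(k, ch[i], ch[i], constrained_encoder, nb))
    cin <- ch[i]
  }
  cb <- base * 2^depth
  bott <- list(a = conv_param(k, ch[depth], cb),
               b = conv_param(k, cb, cb))
  dec <- vector("list", depth)
  up_in <- cb
  for (i in rev(seq_len(depth))) {
    dec[[i]] <- list(a = conv_param(k, up_in + ch[i], ch[i]),
                     b = conv_param(k, ch[i], ch[i]))
    up_in <- ch[i]
  }
  out <- conv_param(1, ch[1], 1)
  list(enc = enc, bott = bott, dec = dec, out = out,
       depth = depth, in_ch = in_ch)
}

unet_fwd <- function(params, x, basis = NULL) {
  cache <- list(enc = vector("list", params$depth),
                dec = vector("list", params$depth))
  h <- x
  for (i in seq_len(params$depth)) {
    a <- block_fwd(h, params$enc[[i]]$a, basis)
    b <- block_fwd(a$y, params$enc[[i]]$b, basis)
    pl <- .maxpool2_fwd(b$y)
    cache$enc[[i]] <- list(a = a, b = b, pool_idx = pl$idx,
                           pre_pool_dim = dim(b$y))
    h <- pl$y
  }
  ba <- block_fwd(h, params$bott$a, NULL)
  bb <- block_fwd(ba$y, params$bott$b, NULL)
  cache$bott <- list(a = ba, b = bb)
  h <- bb$y
  for (i in rev(seq_len(params$depth))) {
    up <- .upsample2_fwd(h)
    skip <- cache$enc[[i]]$b$y
    hcat <- cat4(up, skip)
    a <- block_fwd(hcat, params$dec[[i]]$a, NULL)
    b <- block_fwd(a$y, params$dec[[i]]$b, NULL)
    cache$dec[[i]] <- list(a = a, b = b, up_ch = dim(up)[3])
    h <- b$y
  }
  oc <- conv_fwd(h, params$out, NULL)
  y <- sigmoid_fwd(oc$y)
  cache$out <- oc
  cache$y <- y
  list(y = y, cache = cache)
}

# Floor on the sigmoid derivative in the backward pass. The mean-absolute
#-error subgradient has constant magnitude, so once the output saturates
# (y ~ 0 on the majority background class) the true derivative y*(1-y)
# vanishes for every pixel and training stalls in the all-background state;
# the floor keeps saturated pixels trainable while leaving the MAE objective
# itself untouched.
SIGMOID_GRAD_FLOOR <- 0.02

unet_bwd <- function(params, cache, gy, basis = NULL) {
  grads <- list(enc = vector("list", params$depth),
                dec = vector("list", params$depth))
  # through output sigmoid + 1x1 conv
  gz <- gy * (cache$y * (1 - cache$y) + SIGMOID_GRAD_FLOOR)
  ob <- conv_bwd(params$out, cache$out, gz, NULL)
  grads$out <- ob$grad
  g <- ob$gx
  skip_g <- vector("list", params$depth)
  for (i in seq_len(params$depth)) { # decoder, shallow to deep
    dc <- cache$dec[[i]]
    b <- block_bwd(params$dec[[i]]$b, dc$b, g, NULL)
    a <- block_bwd(params$dec[[i]]$a, dc$a, b$gx, NULL)
    grads$dec[[i]] <- list(a = a$grad, b = b$grad)
    sp <- split4(a$gx, dc$up_ch)
    skip_g[[i]] <- sp[[2]]
    g <- .upsample2_bwd(sp[[1]])
  }
  bb <- block_bwd(params$bott$b, cache$bott$b, g, NULL)
  ba <- block_bwd(params$bott$a, cache$bott$a, bb$gx, NULL)
  grads$bott <- list(a = ba$grad, b = bb$grad)
  g <- ba$gx
  for (i in rev(seq_len(params$depth))) { # encoder, deep to shallow
    ec <- cache$enc[[i]]
    gpool <- .maxpool2_bwd(ec$pool_idx, g, as.integer(ec$pre_pool_dim))
    gtot <- gpool + skip_g[[i]]
    b <- block_bwd(params$enc[[i]]$b, ec$b, gtot, basis)
    a <- block_bwd(params$enc[[i]]$a, ec$a, b$gx, basis)
    grads$enc[[i]] <- list(a = a$grad, b = b$grad)
    g <- a$gx
  }
  list(gx = g, grads = grads)
}

# ---- whole-model forward/backward ---------------------------------------

model_fwd <- function(model, x) {
  switch(model$spec$architecture,
    gesu = {
      u1 <- unet_fwd(model$unet1, x, model$basis)
      x2 <- cat4(x, u1$y)
      u2 <- unet_fwd(model$unet2, x2)
      list(y = u2$y, cache = list(u1 = u1$cache, u2 = u2$cache))
    },
    unet1 = {
      u1 <- unet_fwd(model$unet1, x, model$basis)
      list(y = u1$y, cache = list(u1 = u1$cache))
    },
    unet2 = {
      u2 <- unet_fwd(model$unet2, x)
      list(y = u2$y, cache = list(u2 = u2$cache))
    })
}

model_bwd <- function(model, cache, gy, aux_gy1 = NULL) {
  switch(model$spec$architecture,
    gesu = {
      b2 <- unet_bwd(model$unet2, cache$u2, gy)
      sp <- split4(b2$gx, 1L)
      gy1 <- sp[[2]]
      # deep supervision: the loss is also applied to the first U-net's
      # output; without this direct signal the second stage saturates into
      # the all-background state before the first learns (see vignette)
      if (!is.null(aux_gy1)) gy1 <- gy1 + aux_gy1
      b1 <- unet_bwd(model$unet1, cache$u1, gy1, model$basis)
      list(unet1 = b1$grads, unet2 = b2$grads)
    },
    unet1 = list(unet1 = unet_bwd(model$unet1, cache$u1, gy,
                                  model$basis)$grads),
    unet2 = list(unet2 = unet_bwd(model$unet2, cache$u2, gy)$grads))
}

# ---- parameter tree utilities -------------------------------------------

is_param_leaf <- function(x) is.list(x) && !is.null(x$type)

# apply f(param_leaf, grad_leaf, state_leaf) over matching tree leaves
tree_map <- function(p, g, f) {
  if (is_param_leaf(p)) return(f(p, g))
  out <- p
  for (nm in names(p)) {
    if (is.list(p[[nm]]) && !is.null(g[[nm]]))
      out[[nm]] <- tree_map(p[[nm]], g[[nm]], f)
  }
  out
}

leaf_fields <- function(p) if (p$type == "cconv") c("coef", "b") else
  c("w", "b")

adam_init <- function(model) {
  zero_like <- function(p, g) {
    st <- list(type = p$type)
    for (f in leaf_fields(p)) {
      st[[paste0("m_", f)]] <- p[[f]] * 0
      st[[paste0("v_", f)]] <- p[[f]] * 0
    }
    st
  }
  list(unet1 = if (!is.null(model$unet1))
         tree_map(model$unet1, model$unet1, zero_like),
       unet2 = if (!is.null(model$unet2))
         tree_map(model$unet2, model$unet2, zero_like),
       t = 0L)
}

# one Adam step over whichever sub-nets the model has; returns updated
# model + state
adam_step <- function(model, grads, state, lr = 1e-3, beta1 = 0.9,
                      beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  t <- state$t
  upd <- function(p, gs) { # gs = list(grad = ..., state = ...)
    g <- gs$grad; st <- gs$state
    for (f in leaf_fields(p)) {
      m <- beta1 * st[[paste0("m_", f)]] + (1 - beta1) * g[[f]]
      v <- beta2 * st[[paste0("v_", f)]] + (1 - beta2) * g[[f]]^2
      st[[paste0("m_", f)]] <- m
      st[[paste0("v_", f)]] <- v
      mhat <- m / (1 - beta1^t)
      vhat <- v / (1 - beta2^t)
      p[[f]] <- p[[f]] - lr * mhat / (sqrt(vhat) + eps)
    }
    list(p = p, st = st)
  }
  for (net in c("unet1", "unet2")) {
    if (is.null(model[[net]]) || is.null(grads[[net]])) next
    res <- tree_zip_update(model[[net]], grads[[net]], state[[net]], upd)
    model[[net]] <- res$p
    state[[net]] <- res$st
  }
  list(model = model, state = state)
}

tree_zip_update <- function(p, g, s, f) {
  if (is_param_leaf(p)) {
    r <- f(p, list(grad = g, state = s))
    return(list(p = r$p, st = r$st))
  }
  for (nm in names(p)) {
    if (is.list(p[[nm]]) && !is.null(g[[nm]])) {
      r <- tree_zip_update(p[[nm]], g[[nm]], s[[nm]], f)
      p[[nm]] <- r$p
      s[[nm]] <- r$st
    }
  }
  list(p = p, st = s)
}

# number of trainable parameters in a parameter tree
tree_count <- function(p) {
  if (is_param_leaf(p))
    return(sum(vapply(leaf_fields(p), function(f) length(p[[f]]),
                      numeric(1))))
  sum(vapply(p[vapply(p, is.list, logical(1))], tree_count, numeric(1)))
}
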