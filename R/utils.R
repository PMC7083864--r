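#' @useDynLib astroseg, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats fft median quantile rnorm runif rpois
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

assert_image <- function(x, name = "image") {
  if (!is.matrix(x) || !is.numeric(x))
    stop(name, " must be a numeric matrix", call. = FALSE)
  if (length(x) == 0) stop(name, " is empty", call. = FALSE)
  if (!all(is.finite(x))) stop(name, " contains non-finite values", call. = FALSE)
  invisible(x)
}

odd_size <- function(x) {
  x <- as.integer(round(x))
  if (x %% 2L == 0L) x + 1L else x
}

#' Pad a matrix by mirror reflection (edge pixel included)
#'
#' Symmetric padding: the first padded row repeats row 1, the next row 2, and
#' so on. Padding widths larger than the image are built by repeated
#' reflection.
#' @param x numeric matrix.
#' @param p non-negative integer padding width applied on all four sides.
#' @return a `(nrow(x) + 2p) x (ncol(x) + 2p)` matrix.
#' @keywords internal
pad_reflect <- function(x, p) {
  if (p == 0) return(x)
  reflect_idx <- function(n, p) {
    # symmetric extension of 1..n by p on each side
    idx <- seq.int(1 - p, n + p)
    period <- 2 * n
    idx <- ((idx - 1) %% period + period) %% period # 0..2n-1
    ifelse(idx < n, idx + 1, 2 * n - idx)
  }
  x[reflect_idx(nrow(x), p), reflect_idx(ncol(x), p), drop = FALSE]
}

# Embed a (2c+1)x(2c+1) kernel into an HxW array with its center wrapped to
# (1,1), for FFT-based correlation.
embed_kernel <- function(kernel, H, W) {
  k <- nrow(kernel)
  c0 <- (k - 1L) %/% 2L
  out <- matrix(0, H, W)
  rows <- ((seq_len(k) - 1L - c0) %% H) + 1L
  cols <- ((seq_len(k) - 1L - c0) %% W) + 1L
  out[rows, cols] <- out[rows, cols] + kernel
  out
}

# FFT plan: reflect-pad the image by `pad`, then zero-extend to a
# 2-3-5-smooth size so base R's mixed-radix FFT stays fast. The interior crop
# [pad+1, pad+H] is unaffected by the circular wrap as long as kernel
# half-size <= pad.
prep_fft <- function(x, pad) {
  H <- nrow(x); W <- ncol(x)
  nh <- stats::nextn(H + 2L * pad, c(2, 3, 5))
  nw <- stats::nextn(W + 2L * pad, c(2, 3, 5))
  big <- matrix(0, nh, nw)
  big[seq_len(H + 2L * pad), seq_len(W + 2L * pad)] <- pad_reflect(x, pad)
  list(fx = fft(big), H = H, W = W, pad = pad, nh = nh, nw = nw)
}

#' Same-size 2D cross-correlation with reflective boundaries
#'
#' Computes `sum_q x(p + q) k(q)` at every pixel p, with the image extended by
#' mirror reflection. Implemented by FFT on the padded image; for the
#' point-symmetric kernels used throughout the package this equals 2D
#' convolution.
#' @param x numeric matrix.
#' @param kernel odd-sized square kernel.
#' @param plan optional precomputed `prep_fft()` plan to reuse across kernels;
#'   its `pad` must be at least half the kernel size.
#' @param pad padding width; defaults to half the kernel size.
#' @return matrix of the same size as `x`.
#' @keywords internal
xcorr2 <- function(x, kernel, pad = (nrow(kernel) - 1L) %/% 2L, plan = NULL) {
  if (nrow(kernel) %% 2L == 0L) stop("kernel size must be odd")
  if (is.null(plan)) plan <- prep_fft(x, pad)
  if ((nrow(kernel) - 1L) %/% 2L > plan$pad)
    stop("fft plan padding too small for kernel")
  ke <- embed_kernel(kernel, plan$nh, plan$nw)
  out <- Re(fft(plan$fx * Conj(fft(ke)), inverse = TRUE)) / length(plan$fx)
  out[plan$pad + seq_len(plan$H), plan$pad + seq_len(plan$W), drop = FALSE]
}

#' Gaussian blur with reflective boundaries
#' @param x numeric matrix.
#' @param sigma standard deviation in pixels.
#' @return blurred matrix, same size.
#' @keywords internal
gaussian_blur <- function(x, sigma) {
  if (sigma <= 0) return(x)
  k <- gaussian_kernel(sigma)
  xcorr2(x, k)
}

gaussian_kernel <- function(sigma, size = odd_size(2 * ceiling(3 * sigma) + 1)) {
  half <- (size - 1L) / 2
  g <- exp(-(seq(-half, half))^2 / (2 * sigma^2))
  k <- outer(g, g)
  k / sum(k)
}

#' Rotate an image about its center
#'
#' Positive angles rotate structure counter-clockwise in the (column, row)
#' frame used by the filter bank, i.e. a horizontal bar rotated by 90 degrees
#' becomes vertical. Pixels sampled from outside the input are 0.
#' @param x numeric matrix.
#' @param angle_deg rotation angle in degrees.
#' @param method `"bilinear"` (images) or `"nearest"` (masks/labels).
#' @return rotated matrix, same size.
#' @export
rotate_image <- function(x, angle_deg, method = c("bilinear", "nearest")) {
  method <- match.arg(method)
  H <- nrow(x); W <- ncol(x)
  a <- angle_deg * pi / 180
  cy <- (H + 1) / 2; cx <- (W + 1) / 2
  dest <- expand.grid(r = seq_len(H), c = seq_len(W))
  dy <- dest$r - cy; dx <- dest$c - cx
  # inverse map: rotate destination offsets by -angle
  sx <- cos(a) * dx + sin(a) * dy + cx
  sy <- -sin(a) * dx + cos(a) * dy + cy
  out <- numeric(H * W)
  if (method == "nearest") {
    ri <- round(sy); ci <- round(sx)
    ok <- ri >= 1 & ri <= H & ci >= 1 & ci <= W
    out[ok] <- x[cbind(ri[ok], ci[ok])]
  } else {
    r0 <- floor(sy); c0 <- floor(sx)
    fr <- sy - r0; fc <- sx - c0
    val <- function(r, c) {
      ok <- r >= 1 & r <= H & c >= 1 & c <= W
      v <- numeric(length(r)); v[ok] <- x[cbind(r[ok], c[ok])]
      v
    }
    out <- (1 - fr) * (1 - fc) * val(r0, c0) +
      (1 - fr) * fc * val(r0, c0 + 1) +
      fr * (1 - fc) * val(r0 + 1, c0) +
      fr * fc * val(r0 + 1, c0 + 1)
  }
  matrix(out, H, W)
}

#' Label connected components of a binary mask
#' @param mask logical or 0/1 numeric matrix.
#' @param connectivity 4 or 8 (default).
#' @return integer matrix; 0 is background, components numbered from 1.
#' @export
label_components <- function(mask, connectivity = 8) {
  if (!connectivity %in% c(4, 8)) stop("connectivity must be 4 or 8")
  m <- if (is.logical(mask)) mask else mask != 0
  storage.mode(m) <- "logical"
  .cc_label(m, as.integer(connectivity))
}

# centroids (row, col) of each positive label in a label map
component_centroids <- function(labels) {
  ids <- sort(unique(labels[labels > 0]))
  if (length(ids) == 0)
    return(matrix(numeric(0), 0, 2, dimnames = list(NULL, c("row", "col"))))
  rows <- row(labels); cols <- col(labels)
  t(vapply(ids, function(i) {
    sel <- labels == i
    c(row = mean(rows[sel]), col = mean(cols[sel]))
  }, numeric(2)))
}

# sizes of each positive label
component_sizes <- function(labels) {
  ids <- sort(unique(labels[labels > 0]))
  vapply(ids, function(i) sum(labels == i), numeric(1))
}
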