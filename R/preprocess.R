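#' Pre-processing configuration
#'
#' @param denoise_enabled apply multiscale directional shrinkage denoising.
#' @param threshold_multiplier soft-threshold aggressiveness `k` in `k * sigma`
#'   (robust noise scale from the finest band's median absolute deviation).
#' @param normalization `"minmax"` or `"percentile"`.
#' @param percentile_bounds lower/upper percentiles (in \[0, 100\],
#'   lower < upper) used when `normalization = "percentile"`.
#' @param vst apply the Anscombe variance-stabilizing transform before
#'   shrinkage and invert it afterwards. Only appropriate when pixel values
#'   are (proportional to) photon counts with unit gain; on images already
#'   rescaled to \[0, 1\] the transform mis-stabilizes and hurts, hence the
#'   default `FALSE` (the MAD-based noise scale adapts to the actual noise
#'   level either way).
#' @return a list of class `preprocess_config`.
#' @export
preprocess_config <- function(denoise_enabled = TRUE,
                              threshold_multiplier = 3,
                              normalization = c("minmax", "percentile"),
                              percentile_bounds = c(1, 99),
                              vst = FALSE) {
  normalization <- match.arg(normalization)
  if (threshold_multiplier <= 0) stop("threshold_multiplier must be positive")
  if (length(percentile_bounds) != 2 ||
        percentile_bounds[1] < 0 || percentile_bounds[2] > 100 ||
        percentile_bounds[1] >= percentile_bounds[2])
    stop("percentile_bounds must satisfy 0 <= lower < upper <= 100")
  structure(list(denoise_enabled = denoise_enabled,
                 threshold_multiplier = threshold_multiplier,
                 normalization = normalization,
                 percentile_bounds = percentile_bounds,
                 vst = vst),
            class = "preprocess_config")
}

#' Multiscale directional shrinkage denoising
#'
#' Decomposes the image over the directional bank plus its low-pass kernel,
#' soft-thresholds the directional band coefficients at
#' `threshold_multiplier * sigma_band`, and reconstructs with the canonical
#' dual frame: writing `K_i` for the transfer functions of the kernels and
#' `S = sum_i |K_i|^2`, the output spectrum is
#' `sum_i K_i * fft(shrunk coefficients_i) / S`, which reproduces the input
#' exactly when no coefficient is shrunk. The robust noise scale is the median
#' absolute deviation of the finest-scale coefficients divided by 0.6745; an
#' Anscombe transform is applied first (and inverted after) when
#' `config$vst` is `TRUE` so Poisson noise becomes approximately Gaussian.
#' Output intensities are clamped to be non-negative.
#'
#' @param image 2D numeric matrix (non-negative intensities).
#' @param bank a [build_filter_bank()] object supplying the directional bands
#'   and the low-pass kernel.
#' @param config a [preprocess_config()].
#' @return denoised matrix, same shape, non-negative.
#' @export
denoise <- function(image, bank = build_filter_bank(3, 8, 15),
                    config = preprocess_config()) {
  assert_image(image)
  stopifnot(inherits(bank, "directional_filter_bank"),
            inherits(config, "preprocess_config"))
  if (!config$denoise_enabled) return(image)
  y <- if (config$vst) 2 * sqrt(pmax(image, 0) + 3 / 8) else image
  H <- nrow(y); W <- ncol(y)
  pad <- (max(bank$kernel_size_per_scale) - 1L) %/% 2L
  plan <- prep_fft(y, pad)
  Y <- plan$fx
  npix <- length(Y)

  # the analysis/synthesis frame uses unit-L2 rescalings of the bank's
  # kernels: the response-bound normalization of the bank proper leaves the
  # directional bands spectrally so weak that the complementary residual band
  # would carry (and pass through) nearly all noise
  kernels <- lapply(c(unlist(bank$kernels, recursive = FALSE),
                      list(bank$lowpass)),
                    function(k) k / sqrt(sum(k^2)))
  Ks <- lapply(kernels, function(k) fft(embed_kernel(k, plan$nh, plan$nw)))
  # complement the frame so the frame function S is exactly flat: a zero-phase
  # residual band with |R|^2 = max(S) - S makes synthesis perfectly
  # conditioned (division by the constant max(S)) and reconstruction exact
  # when nothing is shrunk
  S <- Reduce(`+`, lapply(Ks, function(K) Mod(K)^2))
  smax <- max(S)
  Ks <- c(Ks, list(fft_zero_phase <- sqrt(pmax(smax - S, 0)) + 0i))
  l2 <- vapply(Ks, function(K) sqrt(sum(Mod(K)^2) / npix), numeric(1))

  # analysis coefficients (correlation) per band
  coefs <- lapply(Ks, function(K) Re(fft(Y * Conj(K), inverse = TRUE)) / npix)
  n_band <- length(coefs)
  i_lp <- n_band - 1L # low-pass: never shrunk
  # robust image-domain noise scale from the finest-scale directional bands
  fine <- unlist(coefs[seq_len(bank$n_orientations)])
  sigma <- median(abs(fine - median(fine))) / 0.6745 / l2[1]
  soft <- function(x, t) sign(x) * pmax(abs(x) - t, 0)
  for (i in setdiff(seq_len(n_band), i_lp))
    coefs[[i]] <- soft(coefs[[i]], config$threshold_multiplier * sigma * l2[i])

  num <- Reduce(`+`, Map(function(K, cf) K * fft(cf), Ks, coefs))
  rec <- Re(fft(num / smax, inverse = TRUE)) / npix
  out <- rec[pad + seq_len(H), pad + seq_len(W)]
  if (config$vst) out <- pmax((out / 2)^2 - 3 / 8, 0)
  pmax(out, 0)
}

#' Intensity normalization to \[0, 1\]
#'
#' Min-max scaling, or percentile scaling with clipping at the configured
#' percentile bounds. The transform is monotone. A constant image has no
#' contrast to preserve and maps to all zeros (documented degenerate case).
#'
#' @param image 2D numeric matrix.
#' @param config a [preprocess_config()]; fields `normalization` and
#'   `percentile_bounds` are used.
#' @return matrix of the same shape with values in \[0, 1\].
#' @export
normalize_intensity <- function(image, config = preprocess_config()) {
  assert_image(image)
  if (config$normalization == "minmax") {
    lo <- min(image); hi <- max(image)
  } else {
    qs <- quantile(image, config$percentile_bounds / 100, names = FALSE)
    lo <- qs[1]; hi <- qs[2]
  }
  if (hi <= lo) return(matrix(0, nrow(image), ncol(image)))
  pmin(pmax((image - lo) / (hi - lo), 0), 1)
}
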