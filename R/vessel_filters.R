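#' Binary vessel map
#'
#' Result of binarizing a filtered OCTA image: `TRUE` marks vessel pixels.
#' After ROI restriction, vessel pixels are always a subset of the lesion ROI.
#'
#' @param mask logical matrix, `TRUE` = vessel.
#' @param scale pixels per mm.
#' @return An object of class `vessel_map`.
#' @export
vessel_map <- function(mask, scale) {
  if (!is.matrix(mask) || !is.logical(mask))
    stop("`mask` must be a logical matrix")
  if (!is.numeric(scale) || length(scale) != 1L || scale <= 0)
    stop("`scale` must be a single positive number")
  structure(list(mask = mask, scale = as.numeric(scale)), class = "vessel_map")
}

#' @export
print.vessel_map <- function(x, ...) {
  cat(sprintf("<vessel_map> %d x %d px, %d vessel px, %.6g px/mm\n",
              nrow(x$mask), ncol(x$mask), sum(x$mask), x$scale))
  invisible(x)
}

#' Filtering-stage parameters
#'
#' Collects the tunable parameters of the four filtering stages. Defaults
#' follow the study pipeline: Gaussian sigma 1 px, local-threshold window
#' radius 8 px with offset 0, Mexican-hat neighbourhood radius 13 px.
#' Frangi parameters follow the original vesselness conventions:
#' beta = 0.5, scales 1-3 px, and `frangi_c = NA` meaning half the maximum
#' Hessian Frobenius norm at each scale.
#'
#' @param gaussian_sigma sigma of the denoising Gaussian, pixels.
#' @param threshold_radius local-median window radius, pixels.
#' @param threshold_offset subtracted from the local median before the strict
#'   `>` comparison, intensity units.
#' @param mexican_hat_radius Ricker-wavelet neighbourhood radius, pixels.
#' @param frangi_scales Hessian scales (sigma), pixels; strictly increasing.
#' @param frangi_beta blob-ness sensitivity, dimensionless.
#' @param frangi_c structure-ness sensitivity, intensity units; `NA` = auto.
#' @return A list of class `filter_config`.
#' @export
filter_config <- function(gaussian_sigma = 1,
                          threshold_radius = 8,
                          threshold_offset = 0,
                          mexican_hat_radius = 13,
                          frangi_scales = c(1, 1.5, 2, 2.5, 3),
                          frangi_beta = 0.5,
                          frangi_c = NA_real_) {
  if (gaussian_sigma <= 0) stop("`gaussian_sigma` must be positive")
  if (threshold_radius < 1) stop("`threshold_radius` must be >= 1")
  if (mexican_hat_radius < 1) stop("`mexican_hat_radius` must be >= 1")
  if (length(frangi_scales) == 0 || any(frangi_scales <= 0) ||
      is.unsorted(frangi_scales, strictly = TRUE))
    stop("`frangi_scales` must be non-empty, positive and strictly increasing")
  if (frangi_beta <= 0) stop("`frangi_beta` must be positive")
  structure(list(gaussian_sigma = gaussian_sigma,
                 threshold_radius = threshold_radius,
                 threshold_offset = threshold_offset,
                 mexican_hat_radius = mexican_hat_radius,
                 frangi_scales = frangi_scales,
                 frangi_beta = frangi_beta,
                 frangi_c = frangi_c),
            class = "filter_config")
}

# normalized 2D Gaussian kernel sampled on integer offsets
gaussian_kernel <- function(sigma, radius = max(1L, ceiling(4 * sigma))) {
  x <- -radius:radius
  g <- exp(-outer(x^2, x^2, "+") / (2 * sigma^2))
  g / sum(g)
}

convolve_replicate <- function(px, kernel) {
  EBImage::filter2(px, kernel, boundary = "replicate")
}

#' Gaussian blur (pipeline stage 1A)
#'
#' Convolution with the normalized 2D Gaussian
#' \eqn{G(x,y) = \frac{1}{2\pi\sigma^2} e^{-(x^2+y^2)/(2\sigma^2)}},
#' with image borders handled by edge replication, used to denoise the
#' delineated lesion before vessel enhancement. Single OCTA frames are
#' noticeably noisier than averaged acquisitions, which is why this stage
#' precedes the vesselness filter.
#'
#' @param image a [raster_image()].
#' @param sigma Gaussian sigma in pixels (the pipeline default is 1).
#' @param quantize round the result back to 8-bit integers (default). With
#'   `FALSE` the raw convolution values are returned.
#' @return A [raster_image()].
#' @export
gaussian_blur <- function(image, sigma = 1, quantize = TRUE) {
  if (!is.numeric(sigma) || sigma <= 0) stop("`sigma` must be positive")
  out <- convolve_replicate(image$pixels, gaussian_kernel(sigma))
  if (quantize) out <- pmin(pmax(round(out), 0), 255)
  dim(out) <- dim(image$pixels)
  raster_image(out, image$scale)
}

#' Frangi vesselness filter (pipeline stage 1B)
#'
#' Hessian-based vessel enhancement. At each scale \eqn{\sigma} the image is
#' convolved with scale-normalized Gaussian second-derivative kernels
#' (normalization \eqn{\sigma^2}), the Hessian eigenvalues are ordered by
#' magnitude \eqn{|\lambda_1| \le |\lambda_2|}, and the vesselness is
#' \deqn{V = \exp(-R_B^2 / 2\beta^2)\,(1 - \exp(-S^2 / 2c^2)),}
#' with \eqn{R_B = \lambda_1/\lambda_2} (blob-ness) and
#' \eqn{S = \sqrt{\lambda_1^2+\lambda_2^2}} (structure-ness), set to 0
#' wherever \eqn{\lambda_2 > 0} (bright-vessel convention). The final
#' response is the maximum over scales, rescaled to 8-bit. Adding a constant
#' to the image leaves the response unchanged.
#'
#' @param image a [raster_image()] (usually the stage-1A output).
#' @param scales Hessian scales in pixels.
#' @param beta blob-ness sensitivity.
#' @param c structure-ness sensitivity; `NA` (default) uses half the maximum
#'   Frobenius norm of the Hessian at each scale.
#' @param quantize rescale the response onto `[0, 255]` integers (default).
#' @return A [raster_image()]; zero wherever the image has no ridge-like
#'   bright structure (in particular on constant images and dark ridges).
#' @export
frangi_vesselness <- function(image, scales = c(1, 1.5, 2, 2.5, 3),
                              beta = 0.5, c = NA_real_, quantize = TRUE) {
  if (length(scales) == 0) stop("`scales` must be non-empty")
  if (any(scales <= 0)) stop("all `scales` must be positive")
  px <- image$pixels
  resp <- array(0, dim(px))
  for (s in scales) {
    r <- max(2L, ceiling(4 * s))
    x <- -r:r
    g1 <- exp(-x^2 / (2 * s^2))
    g1 <- g1 / sum(g1)                       # 1D Gaussian, unit sum
    d2 <- ((x^2 - s^2) / s^4) * g1           # second derivative of Gaussian
    d2 <- d2 - mean(d2)                      # exact zero sum despite truncation
    d1 <- (-x / s^2) * g1                    # first derivative (odd: sums to 0)
    kxx <- outer(d2, g1)                     # d2 along rows
    kyy <- outer(g1, d2)                     # d2 along columns
    kxy <- outer(d1, d1)
    hxx <- convolve_replicate(px, kxx) * s^2
    hyy <- convolve_replicate(px, kyy) * s^2
    hxy <- convolve_replicate(px, kxy) * s^2
    root <- sqrt(((hxx - hyy) / 2)^2 + hxy^2)
    m <- (hxx + hyy) / 2
    e1 <- m + root
    e2 <- m - root
    swap <- abs(e1) > abs(e2)                # lam1 = smaller magnitude
    lam1 <- ifelse(swap, e2, e1)
    lam2 <- ifelse(swap, e1, e2)
    S2 <- lam1^2 + lam2^2
    smax <- sqrt(max(S2))
    if (smax < 1e-6) next  # flat at this scale: only FFT roundoff, no structure
    cs <- if (is.na(c)) smax / 2 else c
    v <- array(0, dim(px))
    keep <- lam2 < 0
    if (any(keep) && cs > 0) {
      rb2 <- (lam1[keep] / lam2[keep])^2
      v[keep] <- exp(-rb2 / (2 * beta^2)) * (1 - exp(-S2[keep] / (2 * cs^2)))
    }
    resp <- pmax(resp, v)
  }
  if (quantize) {
    mx <- max(resp)
    resp <- if (mx > 0) round(resp / mx * 255) else array(0, dim(px))
  }
  dim(resp) <- dim(px)
  raster_image(resp, image$scale)
}

#' Local median thresholding (pipeline stage 1C)
#'
#' Adaptive binarization: a pixel is classified as vessel iff its value is
#' strictly greater than the median of the `(2r+1) x (2r+1)` window around
#' it (clipped at the image borders) minus `offset`. Ties go to background,
#' so a constant image yields no vessel pixels. The median is the lower
#' median (the `ceiling(n/2)`-th smallest value), deterministic on the 8-bit
#' integer range. Pixels outside the ROI are always background.
#'
#' @param image a [raster_image()] with values in `[0, 255]` (rounded
#'   internally).
#' @param radius window radius in pixels (pipeline default 8).
#' @param offset subtracted from the local median before comparison.
#' @param roi optional [roi_mask()] restricting the output.
#' @return A [vessel_map()].
#' @export
local_median_threshold <- function(image, radius = 8, offset = 0, roi = NULL) {
  if (radius < 1) stop("`radius` must be >= 1")
  px <- pmin(pmax(round(image$pixels), 0), 255)
  storage.mode(px) <- "integer"
  med <- cpp_local_median(px, as.integer(radius))
  mask <- px > (med - offset)
  if (!is.null(roi)) {
    if (!all(dim(roi$mask) == dim(px))) stop("ROI shape does not match image")
    mask <- mask & roi$mask
  }
  dim(mask) <- dim(px)
  vessel_map(mask, image$scale)
}

#' Mexican-hat (Ricker wavelet) filter (pipeline stage 2A)
#'
#' Convolution with the 2D Ricker wavelet
#' \deqn{\psi(x,y) = \frac{1}{\pi\sigma^4}\Big(1-\frac{x^2+y^2}{2\sigma^2}\Big)
#'   e^{-(x^2+y^2)/(2\sigma^2)},}
#' truncated to the `(2r+1) x (2r+1)` neighbourhood with `sigma = radius/3`
#' and re-centred to exact zero sum, so a constant image produces a constant
#' (zero) response. Enhances blob/ridge structures of width comparable to
#' sigma ahead of skeletonization. Negative responses are clipped at 0 and
#' the result is rescaled to 8-bit.
#'
#' @param image a [raster_image()].
#' @param radius neighbourhood radius in pixels (pipeline default 13).
#' @param sigma wavelet sigma; defaults to `radius/3` so the kernel decays
#'   to near zero at the window edge.
#' @param quantize rescale the clipped response onto `[0, 255]` integers.
#' @return A [raster_image()].
#' @export
mexican_hat <- function(image, radius = 13, sigma = radius / 3,
                        quantize = TRUE) {
  if (radius < 1) stop("`radius` must be >= 1")
  x <- -radius:radius
  rho2 <- outer(x^2, x^2, "+")
  k <- (1 / (pi * sigma^4)) * (1 - rho2 / (2 * sigma^2)) *
    exp(-rho2 / (2 * sigma^2))
  k <- k - mean(k)  # discrete re-centring to zero sum
  out <- convolve_replicate(image$pixels, k)
  out[out < 0] <- 0
  if (quantize) {
    mx <- max(out)
    out <- if (mx > 0) round(out / mx * 255) else array(0, dim(image$pixels))
  }
  dim(out) <- dim(image$pixels)
  raster_image(out, image$scale)
}
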