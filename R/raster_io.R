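#' Grayscale raster image with a physical pixel scale
#'
#' The pipeline's working representation of an en-face OCTA image: a numeric
#' matrix of intensities (rows = image rows, origin at the top-left) plus the
#' pixel scale in pixels per millimetre that turns pixel counts into physical
#' lengths and areas. The study images are 1024x1024 at 170 px/mm, i.e. a
#' physical side of about 6.02 mm.
#'
#' @param pixels numeric matrix of intensities.
#' @param scale pixels per mm; must be a single positive number.
#' @return An object of class `raster_image` with fields `pixels` and `scale`.
#' @export
raster_image <- function(pixels, scale) {
  if (!is.matrix(pixels) || !is.numeric(pixels))
    stop("`pixels` must be a numeric matrix")
  if (!is.numeric(scale) || length(scale) != 1L || !is.finite(scale) || scale <= 0)
    stop("`scale` (pixels per mm) must be a single positive number")
  structure(list(pixels = pixels, scale = as.numeric(scale)),
            class = "raster_image")
}

#' @export
print.raster_image <- function(x, ...) {
  d <- dim(x$pixels)
  cat(sprintf("<raster_image> %d x %d px, %.6g px/mm (%.3g x %.3g mm), range [%g, %g]\n",
              d[1], d[2], x$scale, d[1] / x$scale, d[2] / x$scale,
              min(x$pixels), max(x$pixels)))
  invisible(x)
}

#' @export
dim.raster_image <- function(x) dim(x$pixels)

#' Binary lesion-delineation (ROI) mask
#'
#' Marks the manually delineated mCNV lesion; every biomarker is restricted
#' to this region. A mask either comes from an explicit mask file or is
#' derived from a pre-cropped image in which everything outside the contour
#' was cleared to zero.
#'
#' @param mask logical matrix, `TRUE` inside the lesion.
#' @param provenance how the mask was obtained; one of
#'   `"derived-from-cleared-background"` or `"explicit-mask-file"`.
#' @return An object of class `roi_mask`.
#' @export
roi_mask <- function(mask,
                     provenance = c("derived-from-cleared-background",
                                    "explicit-mask-file")) {
  provenance <- match.arg(provenance)
  if (!is.matrix(mask) || !is.logical(mask))
    stop("`mask` must be a logical matrix")
  if (!any(mask)) stop("empty ROI: the lesion mask contains no pixels")
  structure(list(mask = mask, provenance = provenance), class = "roi_mask")
}

#' @export
print.roi_mask <- function(x, ...) {
  cat(sprintf("<roi_mask> %d x %d px, %d inside (%s)\n",
              nrow(x$mask), ncol(x$mask), sum(x$mask), x$provenance))
  invisible(x)
}

read_raster_file <- function(path) {
  if (!file.exists(path)) stop("cannot read image file: ", path)
  ext <- tolower(tools::file_ext(path))
  arr <- switch(ext,
    tif = , tiff = tiff::readTIFF(path, as.is = TRUE),
    png = {
      a <- png::readPNG(path)
      round(a * 255)  # readPNG returns [0,1]; PNG rasters here are 8-bit
    },
    stop("unsupported image format '", ext, "' for file: ", path))
  if (is.list(arr)) arr <- arr[[1]]
  if (length(dim(arr)) == 3L) {
    # collapse channels by equal-weight mean (OCTA exports are pseudo-gray);
    # drop a trailing alpha channel first when present
    nch <- dim(arr)[3]
    if (nch == 4L) arr <- arr[, , 1:3, drop = FALSE]
    arr <- apply(arr, c(1, 2), mean)
  }
  if (length(dim(arr)) != 2L) stop("not a 2D raster: ", path)
  storage.mode(arr) <- "double"
  arr
}

#' Load a grayscale image as a `raster_image`
#'
#' Reads a TIFF (default format) or PNG raster, collapses multi-channel input
#' to one grayscale channel by the equal-weight channel mean, and attaches the
#' pixel scale.
#'
#' @param path path to a TIFF or PNG file.
#' @param scale pixels per mm (the study's acquisition uses 170).
#' @return A [raster_image()].
#' @export
load_image <- function(path, scale = 170) {
  raster_image(read_raster_file(path), scale)
}

#' Write an 8-bit grayscale image
#'
#' Values are clamped to `[0, 255]` and written as 8-bit TIFF or PNG
#' (chosen from the file extension). A written image read back with
#' [load_image()] reproduces its pixels bit-exactly.
#'
#' @param image a [raster_image()] or numeric matrix.
#' @param path output path ending in `.tif`, `.tiff` or `.png`.
#' @return `path`, invisibly.
#' @export
write_image <- function(image, path) {
  px <- if (inherits(image, "raster_image")) image$pixels else image
  px <- pmin(pmax(round(px), 0), 255) / 255
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    tif = , tiff = tiff::writeTIFF(px, path, bits.per.sample = 8L),
    png = png::writePNG(px, path),
    stop("unsupported output format: ", ext))
  invisible(path)
}

#' Derive the lesion ROI for an image
#'
#' An explicit mask file (same shape, nonzero = inside) takes precedence.
#' Without one, the ROI is the nonzero support of the image, following the
#' delineation convention that everything outside the drawn contour is
#' cleared to 0.
#'
#' @param image a [raster_image()].
#' @param mask_path optional path to a same-shape TIFF/PNG mask.
#' @return A [roi_mask()].
#' @export
derive_roi <- function(image, mask_path = NULL) {
  if (!is.null(mask_path)) {
    m <- read_raster_file(mask_path)
    if (!all(dim(m) == dim(image$pixels)))
      stop("ROI mask shape ", paste(dim(m), collapse = "x"),
           " does not match image shape ",
           paste(dim(image$pixels), collapse = "x"))
    return(roi_mask(m > 0, "explicit-mask-file"))
  }
  inside <- image$pixels != 0
  if (!any(inside))
    stop("empty ROI: image is all zero and no mask file was given")
  roi_mask(inside, "derived-from-cleared-background")
}

#' Convert to 8-bit grayscale
#'
#' Linear min-max rescale of the input range onto `[0, 255]`, rounded to the
#' nearest integer. A constant image maps to all zeros. Full-range 8-bit
#' input (integers spanning 0..255) passes through unchanged, so the
#' operation is idempotent on already-converted images.
#'
#' @param image a [raster_image()].
#' @return A [raster_image()] with integer values in `[0, 255]`.
#' @export
to_8bit <- function(image) {
  px <- image$pixels
  lo <- min(px); hi <- max(px)
  out <- if (hi == lo) array(0, dim(px)) else round((px - lo) / (hi - lo) * 255)
  dim(out) <- dim(px)
  raster_image(out, image$scale)
}

#' Percentile-based contrast stretch
#'
#' Linear brightness/contrast adjustment: the intensities at the
#' `saturation_fraction` and `1 - saturation_fraction` quantiles of the ROI
#' pixels are mapped to 0 and 255 and everything outside is clipped. With the
#' default fraction 0.0035 this reproduces the usual "auto" contrast
#' behaviour of interactive tools. A constant ROI passes through unchanged.
#'
#' @param image a [raster_image()].
#' @param saturation_fraction proportion in `[0, 0.5)` of pixels saturated at
#'   each end.
#' @param roi optional [roi_mask()]; quantiles are taken over ROI pixels only
#'   (the whole image when absent). Pixels outside the ROI are left at 0.
#' @return A [raster_image()] with integer values in `[0, 255]`.
#' @export
adjust_contrast <- function(image, saturation_fraction = 0.0035, roi = NULL) {
  if (saturation_fraction < 0 || saturation_fraction >= 0.5)
    stop("`saturation_fraction` must lie in [0, 0.5)")
  px <- image$pixels
  v <- if (is.null(roi)) as.numeric(px) else px[roi$mask]
  q <- quantile(v, c(saturation_fraction, 1 - saturation_fraction),
                names = FALSE, type = 7)
  if (q[2] <= q[1]) return(image)  # degenerate range: pass through
  out <- round((px - q[1]) / (q[2] - q[1]) * 255)
  out <- pmin(pmax(out, 0), 255)
  dim(out) <- dim(px)
  if (!is.null(roi)) out[!roi$mask] <- 0
  raster_image(out, image$scale)
}
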