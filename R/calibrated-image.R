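#' Calibrated single-slice fluorescence image
#'
#' A `calibrated_image` wraps a 2-D intensity matrix together with its physical
#' pixel size, so that all downstream size filters and distance measurements
#' can be expressed in micrometres. Intensities are arbitrary units (a.u.),
#' finite and non-negative; confocal quantification images are single slices,
#' so only 2-D rasters are supported.
#'
#' @param pixels Numeric matrix of non-negative, finite intensities
#'   (rows = y, columns = x).
#' @param pixel_size Physical edge length of one pixel, in micrometres
#'   (must be > 0).
#' @param channel_label Free-text channel name (e.g. `"GFP-DEPS-1"`).
#'
#' @return An object of class `calibrated_image`: a list with elements
#'   `pixels`, `pixel_size` and `channel_label`.
#' @examples
#' img <- calibrated_image(matrix(0, 32, 32), pixel_size = 0.05)
#' dim(img$pixels)
#' @export
calibrated_image <- function(pixels, pixel_size, channel_label = "") {
  if (!is.matrix(pixels) || length(pixels) == 0L)
    stop("'pixels' must be a non-empty matrix")
  storage.mode(pixels) <- "double"
  if (any(!is.finite(pixels)) || any(pixels < 0))
    stop("intensities must be finite and >= 0")
  if (!is.numeric(pixel_size) || length(pixel_size) != 1L || pixel_size <= 0)
    stop("'pixel_size' must be a single positive number (um per pixel)")
  structure(
    list(pixels = pixels, pixel_size = as.numeric(pixel_size),
         channel_label = as.character(channel_label)),
    class = "calibrated_image"
  )
}

#' @export
print.calibrated_image <- function(x, ...) {
  cat(sprintf("calibrated_image: %d x %d px, %.4g um/px, channel '%s'\n",
              nrow(x$pixels), ncol(x$pixels), x$pixel_size, x$channel_label))
  cat(sprintf("  intensity range [%.4g, %.4g]\n",
              min(x$pixels), max(x$pixels)))
  invisible(x)
}

#' Read a single-slice TIFF as a calibrated image
#'
#' Reads an 8- or 16-bit (or float) single-slice TIFF. Pixel size is supplied
#' by the caller (typically from the run configuration): intensity data are
#' arbitrary units and acquisition metadata does not travel reliably through
#' TIFF files written by different tools.
#'
#' @param path TIFF file path.
#' @param pixel_size Pixel edge length in micrometres.
#' @param channel_label Channel name stored on the returned object.
#' @return A [calibrated_image()].
#' @export
read_calibrated_tiff <- function(path, pixel_size, channel_label = "") {
  px <- tiff::readTIFF(path, as.is = TRUE)
  if (length(dim(px)) == 3L) px <- px[, , 1L]  # first channel of an RGB write
  calibrated_image(as.matrix(px), pixel_size, channel_label)
}

#' Write a calibrated image (or label matrix) as a 16-bit TIFF
#'
#' Intensities are rounded to integers and stored as 16-bit samples; values
#' above 65535 are clipped. Label matrices round-trip exactly for up to 65535
#' labels.
#'
#' @param x A [calibrated_image()] or a numeric matrix.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_calibrated_tiff <- function(x, path) {
  px <- if (inherits(x, "calibrated_image")) x$pixels else as.matrix(x)
  px <- pmin(pmax(round(px), 0), 65535)
  tiff::writeTIFF(px / 65535, path, bits.per.sample = 16L)
  invisible(path)
}

#' Intensity histogram of an image region
#'
#' Builds the intensity histogram that the hierarchical K-means level finder
#' clusters. Integer-valued data get one bin per distinct intensity;
#' non-integer data are binned into `n_bins` equal-width bins over the
#' observed range (bin centres reported). Counts always sum to the number of
#' analysed pixels.
#'
#' @param image A [calibrated_image()].
#' @param mask Optional logical matrix with the image's dimensions; only
#'   `TRUE` pixels are analysed.
#' @param n_bins Number of equal-width bins used for non-integer data
#'   (default 256).
#' @return An object of class `intensity_histogram`: list with `bin_centers`
#'   (strictly increasing), `counts` and `n_pixels`.
#' @examples
#' img <- calibrated_image(matrix(c(0, 0, 100, 100), 2, 2), 0.05)
#' build_histogram(img)
#' @export
build_histogram <- function(image, mask = NULL, n_bins = 256L) {
  stopifnot(inherits(image, "calibrated_image"))
  v <- image$pixels
  if (!is.null(mask)) {
    if (!identical(dim(mask), dim(v)))
      stop("mask dimensions must match the image")
    v <- v[mask]
  }
  v <- as.numeric(v)
  if (length(v) == 0L) stop("no pixels to analyse")
  integerish <- all(v == round(v))
  if (integerish || length(unique(v)) <= n_bins) {
    tab <- table(v)
    centers <- as.numeric(names(tab))
    counts <- as.integer(tab)
  } else {
    rng <- range(v)
    breaks <- seq(rng[1], rng[2], length.out = n_bins + 1L)
    idx <- findInterval(v, breaks, rightmost.closed = TRUE, all.inside = TRUE)
    counts <- tabulate(idx, nbins = n_bins)
    centers <- (breaks[-1] + breaks[-length(breaks)]) / 2
    keep <- counts > 0L
    centers <- centers[keep]
    counts <- counts[keep]
  }
  structure(
    list(bin_centers = centers, counts = counts, n_pixels = length(v)),
    class = "intensity_histogram"
  )
}

#' @export
print.intensity_histogram <- function(x, ...) {
  cat(sprintf("intensity_histogram: %d bins, %d pixels, range [%.4g, %.4g]\n",
              length(x$bin_centers), x$n_pixels,
              min(x$bin_centers), max(x$bin_centers)))
  invisible(x)
}
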