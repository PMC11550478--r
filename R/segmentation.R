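#' Otsu automatic threshold
#'
#' Computes the intensity threshold maximizing the between-class variance of
#' the two classes `{<= t, > t}`, the criterion behind MATLAB's `graythresh`.
#' The histogram spans the `[min, max]` range of the analysed region with
#' `n_bins` equal-width bins (256 by default, mirroring the 8-bit
#' convention); candidate thresholds are the interior bin edges. Class
#' statistics are computed from the actual pixel values (per-bin sums), so
#' the result is exactly the argmax over all candidate edges of
#' `w0 * w1 * (mu0 - mu1)^2`; ties resolve to the lowest threshold.
#'
#' Thresholding is typically applied locally — to a sub-region around the
#' structure of interest, per channel — rather than to the whole frame; pass
#' the cropped region or use `restrict_to` in [binarize()].
#'
#' @param image Numeric vector or matrix of intensities (>= 2 distinct
#'   values; a constant region has no foreground/background split and is an
#'   error, not a silent threshold).
#' @param n_bins Number of histogram bins.
#' @return The threshold, a scalar on the intensity scale of `image`.
#' @examples
#' img <- c(rep(10, 50), rep(200, 50))
#' otsu_threshold(img)  # strictly between 10 and 200
#' @export
otsu_threshold <- function(image, n_bins = 256L) {
  x <- as.numeric(image)
  x <- x[is.finite(x)]
  if (length(x) < 2L) abort("need at least 2 pixels")
  lo <- min(x); hi <- max(x)
  if (hi <= lo) abort("degenerate histogram: image is constant")
  width <- (hi - lo) / n_bins
  bin <- ceiling((x - lo) / width)
  bin[bin < 1L] <- 1L
  bin[bin > n_bins] <- n_bins
  counts <- tabulate(bin, n_bins)
  sums <- numeric(n_bins)
  agg <- rowsum(x, group = bin)
  sums[as.integer(rownames(agg))] <- agg
  cum_n <- cumsum(counts)
  cum_s <- cumsum(sums)
  n <- length(x); s <- cum_s[n_bins]
  k <- seq_len(n_bins - 1L)
  w0 <- cum_n[k]; w1 <- n - w0
  valid <- w0 > 0 & w1 > 0
  mu0 <- cum_s[k] / w0
  mu1 <- (s - cum_s[k]) / w1
  sigma_b <- ifelse(valid, w0 * w1 * (mu0 - mu1)^2, -Inf)
  best <- which.max(sigma_b)
  lo + best * width
}

#' Binarize a frame at a threshold, optionally within an ROI
#'
#' @param image Numeric `Y x X` matrix.
#' @param threshold Intensity threshold; pixels strictly above it are
#'   foreground.
#' @param restrict_to Optional [roi_polygon]; pixels outside it are
#'   background regardless of intensity.
#' @return A logical `Y x X` mask with attribute `threshold_used`.
#' @export
binarize <- function(image, threshold, restrict_to = NULL) {
  mask <- image > threshold
  if (!is.null(restrict_to)) {
    mask <- mask & rasterize_roi(restrict_to, dim(image))
  }
  attr(mask, "threshold_used") <- threshold
  mask
}

#' Partition an ROI into a fixed-width boundary band and apical interior
#'
#' The junctional boundary band is the set of ROI pixels within
#' `band_width_um` (0.5 um by default) of the ROI perimeter; the apical
#' region is everything deeper. The band is carved with the exact Euclidean
#' distance transform of the rasterized ROI rather than pixel-structuring
#' erosion, so the metric width is honoured isotropically and sub-pixel
#' band widths behave sensibly at any pixel size.
#'
#' @param roi An [roi_polygon] delimiting the compartment.
#' @param image_shape `c(Y, X)` of the frame the masks apply to.
#' @param pixel_size_um Pixel size in micrometres.
#' @param band_width_um Band width in micrometres (> 0).
#' @return An object of class `compartment_partition`: list with logical
#'   masks `boundary_band` and `apical` (disjoint, union = rasterized ROI),
#'   plus `roi`, `band_width_um`, `pixel_size_um`.
#' @examples
#' sq <- roi_polygon(c(10, 110, 110, 10), c(10, 10, 110, 110))
#' part <- partition_compartment(sq, c(130, 130), pixel_size_um = 0.1)
#' sum(part$apical)  # inner 90 x 90 region
#' @export
partition_compartment <- function(roi, image_shape, pixel_size_um,
                                  band_width_um = 0.5) {
  if (band_width_um <= 0) abort("`band_width_um` must be > 0")
  if (pixel_size_um <= 0) abort("`pixel_size_um` must be > 0")
  raster <- rasterize_roi(roi, image_shape)
  if (!any(raster)) abort("ROI rasterizes to an empty mask")
  dist_px <- as.matrix(EBImage::distmap(raster + 0))
  # distmap measures center-to-center distance to the nearest outside
  # pixel, which exceeds the distance to the ROI perimeter by half a pixel;
  # the +0.5 keeps the discrete band at the stated metric width
  band_px <- band_width_um / pixel_size_um + 0.5
  boundary <- raster & dist_px <= band_px
  apical <- raster & dist_px > band_px
  if (!any(apical)) abort("ROI too small for band width")
  structure(
    list(boundary_band = boundary, apical = apical, roi = roi,
         band_width_um = band_width_um, pixel_size_um = pixel_size_um),
    class = "compartment_partition")
}

#' @export
print.compartment_partition <- function(x, ...) {
  cat("<compartment_partition> band ", x$band_width_um, " um (",
      sum(x$boundary_band), " px), apical ", sum(x$apical), " px\n", sep = "")
  invisible(x)
}
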