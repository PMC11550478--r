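#' Dice-Sorensen coefficient of two binary masks
#'
#' Twice the joint area of the two thresholded signals divided by the sum of
#' their areas: 1 = complete colocalization, 0 = complete segregation. Used
#' to follow the transition of a junctional marker pair from colocalized
#' contact patches to segregated rings.
#'
#' @param mask_a,mask_b Logical masks of identical shape; at least one must
#'   be non-empty (0/0 is undefined and raises an error rather than quietly
#'   returning 0).
#' @return A scalar in `[0, 1]`.
#' @examples
#' a <- matrix(FALSE, 10, 10); a[1:10, 1:10] <- TRUE
#' dice_coefficient(a, a)  # 1
#' @export
dice_coefficient <- function(mask_a, mask_b) {
  if (!identical(dim(mask_a), dim(mask_b))) abort("masks must share shape")
  na <- sum(mask_a); nb <- sum(mask_b)
  if (na + nb == 0L) abort("both masks are empty: Dice coefficient undefined")
  2 * sum(mask_a & mask_b) / (na + nb)
}

#' Boundary-to-apical (B/A) intensity ratio
#'
#' Mean intensity over the 0.5-um boundary band divided by mean intensity
#' over the apical interior of a [partition_compartment()] result. Ratios
#' near 1 indicate junctional protein spread over the whole compartment;
#' high ratios indicate clean apical clearance with the protein confined to
#' the junctional ring. The ratio is invariant to multiplicative gain but
#' not to additive offsets (no background subtraction is applied here; make
#' any subtraction an explicit upstream step).
#'
#' @param image Numeric `Y x X` frame matching the partition's masks.
#' @param part A `compartment_partition`.
#' @return The B/A ratio, a positive scalar for positive images.
#' @export
boundary_apical_ratio <- function(image, part) {
  stopifnot(inherits(part, "compartment_partition"))
  if (!identical(dim(image), dim(part$boundary_band))) {
    abort("image and partition masks must share shape")
  }
  if (!any(part$boundary_band) || !any(part$apical)) abort("empty mask")
  m_b <- mean(image[part$boundary_band])
  m_a <- mean(image[part$apical])
  if (!is.finite(m_a) || m_a == 0) abort("undefined ratio: apical mean is zero")
  m_b / m_a
}

#' Coefficient of variation of intensities under a mask
#'
#' Sample standard deviation divided by mean — the heterogeneity measure
#' used for apical cargo distribution (smooth apical signal gives low CV,
#' clustered signal high CV). Scale-invariant.
#'
#' @param image Numeric `Y x X` frame.
#' @param mask Logical mask with at least 2 pixels.
#' @return CV, a non-negative scalar.
#' @export
coefficient_of_variation <- function(image, mask) {
  if (!identical(dim(image), dim(mask))) abort("image and mask must share shape")
  v <- image[mask]
  if (length(v) < 2L) abort("mask must cover at least 2 pixels")
  m <- mean(v)
  if (m == 0) abort("zero mean intensity: CV undefined")
  sd(v) / m
}

#' Standardize an image by its whole-cell mean intensity
#'
#' Divides every pixel by the mean intensity over the cell mask, so the
#' normalized image has mean 1 over the cell; per-region means (periphery vs
#' apical) then read directly as fold-of-cell-mean. Ratios of means, such as
#' the B/A ratio, are unchanged by this normalization.
#'
#' @param image Numeric `Y x X` frame.
#' @param cell_mask Logical mask of the whole cell (mean intensity > 0).
#' @return The normalized image, same shape as `image`.
#' @export
normalize_by_cell_mean <- function(image, cell_mask) {
  if (!identical(dim(image), dim(cell_mask))) abort("image and mask must share shape")
  if (!any(cell_mask)) abort("empty cell mask")
  m <- mean(image[cell_mask])
  if (!is.finite(m) || m <= 0) abort("cell mean must be positive")
  image / m
}

bilinear_sample <- function(image, x, y) {
  ny <- nrow(image); nx <- ncol(image)
  x0 <- pmin(pmax(floor(x), 0), nx - 2L)
  y0 <- pmin(pmax(floor(y), 0), ny - 2L)
  fx <- x - x0; fy <- y - y0
  i <- function(yy, xx) image[cbind(yy + 1L, xx + 1L)]
  (1 - fx) * (1 - fy) * i(y0, x0) + fx * (1 - fy) * i(y0, x0 + 1L) +
    (1 - fx) * fy * i(y0 + 1L, x0) + fx * fy * i(y0 + 1L, x0 + 1L)
}

#' Intensity profile along a polyline
#'
#' Samples the image along a polyline at 1-pixel arclength steps with
#' bilinear interpolation, averaging over `width_px` parallel samples taken
#' perpendicular to the local segment direction. This reproduces
#' line-intensity profiles across junctional rings (two peaks at the
#' boundary, a trough over the apical compartment).
#'
#' @param image Numeric `Y x X` frame.
#' @param polyline Two-column matrix (or data frame) of `(x, y)` waypoints in
#'   0-based pixel coordinates; must stay within the image.
#' @param width_px Odd integer averaging width perpendicular to the line.
#' @param pixel_size_um Pixel size used to report arclength in micrometres.
#' @return A tibble with columns `arclength_um`, `intensity`.
#' @export
line_profile <- function(image, polyline, width_px = 1L, pixel_size_um = 1) {
  pts <- as.matrix(polyline)
  if (ncol(pts) != 2L || nrow(pts) < 2L) abort("polyline needs >= 2 (x, y) points")
  if (width_px %% 2L != 1L || width_px < 1L) abort("`width_px` must be odd and >= 1")
  seg <- diff(pts)
  seg_len <- sqrt(rowSums(seg^2))
  if (any(seg_len == 0)) abort("polyline has zero-length segments")
  cum <- c(0, cumsum(seg_len))
  total <- cum[length(cum)]
  s <- seq(0, total, by = 1)
  if (s[length(s)] < total) s <- c(s, total)
  seg_idx <- pmin(findInterval(s, cum, rightmost.closed = TRUE),
                  nrow(pts) - 1L)
  f <- (s - cum[seg_idx]) / seg_len[seg_idx]
  px <- pts[seg_idx, 1L] + f * seg[seg_idx, 1L]
  py <- pts[seg_idx, 2L] + f * seg[seg_idx, 2L]
  tx <- seg[seg_idx, 1L] / seg_len[seg_idx]
  ty <- seg[seg_idx, 2L] / seg_len[seg_idx]
  offsets <- seq_len(width_px) - (width_px + 1L) / 2
  vals <- matrix(0, length(s), width_px)
  for (k in seq_along(offsets)) {
    sx <- px - offsets[k] * ty      # unit normal = (-ty, tx)
    sy <- py + offsets[k] * tx
    if (any(sx < 0 | sx > ncol(image) - 1L | sy < 0 | sy > nrow(image) - 1L)) {
      abort("polyline (with width) leaves image bounds")
    }
    vals[, k] <- bilinear_sample(image, sx, sy)
  }
  tibble(arclength_um = s * pixel_size_um, intensity = rowMeans(vals))
}

#' Photoconversion half-ring recovery curve
#'
#' For a half-ring photoconversion pulse-chase: per frame, the ratio of the
#' mean intensity of one half-ring ROI to the other for a chosen channel.
#' With `numerator = "converted"` on the unconverted-colour channel this is
#' the recovery of new (green) protein into the converted half relative to
#' the unconverted half; with `numerator = "unconverted"` on the converted
#' (magenta) channel it follows the escape of converted protein into the
#' other half. Ratios are of spatial means, so hand-drawn halves of unequal
#' area compare fairly.
#'
#' @param stack An [image_stack].
#' @param converted_roi,unconverted_roi [roi_polygon]s for the two halves.
#' @param channel Channel index or name.
#' @param numerator Which ROI forms the numerator.
#' @param frames Optional frame indices to analyse (default all).
#' @param t_zero_s Time subtracted from the frame times, e.g. the conversion
#'   time, so the curve starts at 0 (default: time of the first analysed
#'   frame).
#' @return A tibble of class `recovery_curve` with columns `frame`, `time_s`,
#'   `ratio`.
#' @export
halfring_recovery <- function(stack, converted_roi, unconverted_roi,
                              channel = 1L,
                              numerator = c("converted", "unconverted"),
                              frames = NULL, t_zero_s = NULL) {
  numerator <- match.arg(numerator)
  shape <- dim(stack$data)
  shape <- shape[(length(shape) - 1L):length(shape)]
  m_conv <- rasterize_roi(converted_roi, shape)
  m_unconv <- rasterize_roi(unconverted_roi, shape)
  if (!any(m_conv) || !any(m_unconv)) abort("half-ring ROI rasterizes empty")
  if (is.null(frames)) frames <- seq_len(n_frames(stack))
  times <- (frames - 1) * stack$frame_interval_s
  if (is.null(t_zero_s)) t_zero_s <- times[1L]
  ratio <- vapply(frames, function(t) {
    img <- stack_frame(stack, t, channel)
    num <- mean(img[if (numerator == "converted") m_conv else m_unconv])
    den <- mean(img[if (numerator == "converted") m_unconv else m_conv])
    if (!is.finite(den) || den <= 0) {
      abort(paste0("denominator mean <= 0 at frame ", t))
    }
    num / den
  }, numeric(1))
  structure(
    tibble(frame = frames, time_s = times - t_zero_s, ratio = ratio),
    numerator = numerator,
    class = c("recovery_curve", class(tibble())))
}

#' First time a recovery curve reaches a fraction of its reference level
#'
#' Linear interpolation between samples; a curve already at or above the
#' level at its first sample returns that first time, and a curve that never
#' reaches it returns `NA` (a reported sentinel, not an error), since
#' never-recovering controls are a legitimate outcome.
#'
#' @param curve A `recovery_curve` (or any tibble with `time_s`, `ratio`).
#' @param fraction Level to reach, in (0, 1).
#' @return Time in seconds on the curve's time axis, or `NA_real_`.
#' @examples
#' tt <- tibble::tibble(time_s = seq(0, 600, 30),
#'                      ratio = 1 - exp(-seq(0, 600, 30) / 100))
#' time_to_fraction(tt, 0.9)  # ~ 100 * log(10) = 230 s
#' @export
time_to_fraction <- function(curve, fraction = 0.9) {
  if (fraction <= 0 || fraction >= 1) abort("`fraction` must be in (0, 1)")
  t <- curve$time_s; r <- curve$ratio
  if (r[1L] >= fraction) return(t[1L])
  hit <- which(r >= fraction)
  if (length(hit) == 0L) return(NA_real_)
  i <- hit[1L]
  t[i - 1L] + (fraction - r[i - 1L]) / (r[i] - r[i - 1L]) * (t[i] - t[i - 1L])
}

#' Area under a recovery curve
#'
#' Trapezoidal integral of the ratio over the curve's time span; the summary
#' statistic compared between groups with [compare_groups()].
#'
#' @param curve A `recovery_curve`.
#' @return AUC in ratio-seconds.
#' @export
recovery_auc <- function(curve) {
  t <- curve$time_s; r <- curve$ratio
  if (length(t) < 2L) abort("curve needs at least 2 points")
  sum(diff(t) * (r[-1L] + r[-length(r)]) / 2)
}

#' Two-sided unpaired two-sample t test
#'
#' Classical pooled-variance (equal-variance) unpaired t test by default,
#' two-sided; Welch's correction is available behind `welch = TRUE`.
#'
#' @param a,b Numeric vectors, at least 2 values each.
#' @param welch Use Welch's unequal-variance form.
#' @return A one-row tibble: `statistic`, `df`, `p_value`, `mean_a`,
#'   `mean_b`, `method`.
#' @examples
#' compare_groups(c(1, 2, 3), c(4, 5, 6))
#' @export
compare_groups <- function(a, b, welch = FALSE) {
  if (length(a) < 2L || length(b) < 2L) abort("need >= 2 samples per group")
  ht <- t.test(a, b, var.equal = !welch)
  tibble(statistic = unname(ht$statistic), df = unname(ht$parameter),
         p_value = ht$p.value, mean_a = mean(a), mean_b = mean(b),
         method = if (welch) "welch" else "pooled")
}

#' @method glance recovery_curve
#' @export
glance.recovery_curve <- function(x, fraction = 0.9, ...) {
  tibble(n_frames = nrow(x),
         t_reach_s = time_to_fraction(x, fraction),
         fraction = fraction,
         auc = recovery_auc(x),
         final_ratio = x$ratio[nrow(x)])
}

#' @method tidy recovery_curve
#' @export
tidy.recovery_curve <- function(x, ...) as_tibble(unclass(x)[c("frame", "time_s", "ratio")])
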