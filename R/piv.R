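#' Particle image velocimetry on one frame pair
#'
#' Estimates a displacement field between two frames by normalized,
#' mean-subtracted cross-correlation within square interrogation windows on
#' a regular (possibly overlapping) grid. The integer correlation peak is
#' refined to sub-pixel precision by a three-point Gaussian (default) or
#' parabolic fit along each axis. A window is marked invalid — its vector
#' reported as `NA`, never fabricated — when its texture variance is ~0,
#' its mean intensity falls below `min_mean_intensity`, its first-to-second
#' correlation peak ratio falls below `min_peak_ratio`, or the displacement
#' leaves the search range (`window_px / 2`).
#'
#' @param frame_a,frame_b Numeric `Y x X` matrices of identical shape.
#' @param window_px Interrogation window size in pixels (>= 8).
#' @param overlap_px Overlap between adjacent windows (`0 <= overlap_px <
#'   window_px`).
#' @param subpixel `"gauss3"`, `"parabolic"`, or `"none"` (integer peak).
#' @param min_peak_ratio Detectability threshold on peak1/peak2 (peak2 taken
#'   outside the 3x3 neighbourhood of peak1).
#' @param min_mean_intensity Windows dimmer than this are invalidated before
#'   correlation to avoid noise-locking.
#' @param pixel_size_um,frame_interval_s Calibration used for the `u_um_s`,
#'   `v_um_s` columns.
#' @return A tibble of class `velocity_field`, one row per window: `x`, `y`
#'   (window-center pixel coordinates), `u`, `v` (px/frame; positive u
#'   rightward, positive v downward), `u_um_s`, `v_um_s`, `peak_ratio`,
#'   `valid`. Grid geometry and calibration are carried as attributes.
#' @export
piv_pair <- function(frame_a, frame_b, window_px = 32L, overlap_px = 16L,
                     subpixel = c("gauss3", "parabolic", "none"),
                     min_peak_ratio = 1.2, min_mean_intensity = 0,
                     pixel_size_um = 1, frame_interval_s = 1) {
  subpixel <- match.arg(subpixel)
  if (!identical(dim(frame_a), dim(frame_b))) abort("frames must share shape")
  if (window_px < 8L) abort("`window_px` must be >= 8")
  if (overlap_px < 0L || overlap_px >= window_px) {
    abort("`overlap_px` must satisfy 0 <= overlap < window")
  }
  ny <- nrow(frame_a); nx <- ncol(frame_a)
  if (window_px > min(ny, nx)) abort("window larger than image")
  step <- window_px - overlap_px
  x0s <- seq(0L, nx - window_px, by = step)
  y0s <- seq(0L, ny - window_px, by = step)
  w <- window_px
  wp <- 2L * w                       # zero-padded linear correlation size
  # padded circular index -> signed lag
  disp_of <- ifelse(seq_len(wp) - 1L < w, seq_len(wp) - 1L, seq_len(wp) - 1L - wp)
  max_disp <- w / 2
  in_search <- abs(disp_of) <= max_disp
  # per-lag overlap area corrects the triangular correlation envelope that
  # otherwise biases peaks toward zero lag
  overlap_1d <- pmax(w - abs(disp_of), 1L)
  overlap <- outer(overlap_1d, overlap_1d)
  grid <- expand.grid(x0 = x0s, y0 = y0s)
  n <- nrow(grid)
  u <- v <- pr <- rep(NA_real_, n)
  valid <- rep(FALSE, n)
  pad_a <- matrix(0, wp, wp)
  pad_b <- matrix(0, wp, wp)
  for (i in seq_len(n)) {
    rows <- grid$y0[i] + seq_len(w)
    cols <- grid$x0[i] + seq_len(w)
    a <- frame_a[rows, cols]; b <- frame_b[rows, cols]
    if (mean(a) < min_mean_intensity || mean(b) < min_mean_intensity) next
    a0 <- a - mean(a); b0 <- b - mean(b)
    sa <- sqrt(sum(a0^2)); sb <- sqrt(sum(b0^2))
    if (sa < 1e-10 || sb < 1e-10) next
    pad_a[] <- 0; pad_b[] <- 0
    pad_a[seq_len(w), seq_len(w)] <- a0 / sa
    pad_b[seq_len(w), seq_len(w)] <- b0 / sb
    cc <- Re(fft(Conj(fft(pad_a)) * fft(pad_b), inverse = TRUE)) / length(pad_a)
    cc <- cc * (w * w) / overlap
    cc[!in_search, ] <- -Inf
    cc[, !in_search] <- -Inf
    pk <- arrayInd(which.max(cc), dim(cc))
    peak1 <- cc[pk]
    if (!is.finite(peak1) || peak1 <= 0) next
    # second peak outside the 5x5 neighbourhood of the first; the margin
    # keeps the shoulder of a finite-width particle peak from masquerading
    # as a competing peak
    nb_r <- ((pk[1L] - 3L):(pk[1L] + 1L)) %% wp + 1L
    nb_c <- ((pk[2L] - 3L):(pk[2L] + 1L)) %% wp + 1L
    cc2 <- cc
    cc2[nb_r, nb_c] <- -Inf
    peak2 <- max(cc2)
    ratio <- if (is.finite(peak2) && peak2 > 0) peak1 / peak2 else Inf
    pr[i] <- ratio
    if (ratio < min_peak_ratio) next
    dv <- disp_of[pk[1L]]; du <- disp_of[pk[2L]]
    if (subpixel != "none") {
      du <- du + subpixel_offset(cc, pk, 2L, subpixel)
      dv <- dv + subpixel_offset(cc, pk, 1L, subpixel)
    }
    if (abs(du) > max_disp || abs(dv) > max_disp) next
    u[i] <- du; v[i] <- dv
    valid[i] <- TRUE
  }
  scale <- pixel_size_um / frame_interval_s
  out <- tibble(
    x = grid$x0 + (w - 1) / 2, y = grid$y0 + (w - 1) / 2,
    u = u, v = v,
    u_um_s = u * scale, v_um_s = v * scale,
    peak_ratio = pr, valid = valid)
  structure(out,
            window_px = window_px, overlap_px = overlap_px,
            pixel_size_um = pixel_size_um, frame_interval_s = frame_interval_s,
            image_shape = c(ny, nx),
            class = c("velocity_field", class(tibble())))
}

# three-point fit along one axis of the (circular) correlation plane
subpixel_offset <- function(cc, pk, axis, method) {
  w <- dim(cc)[axis]
  idx <- function(offset) {
    p <- pk
    p[axis] <- (pk[axis] - 1L + offset) %% w + 1L
    cc[p[1L], p[2L]]
  }
  c0 <- idx(0L); cl <- idx(-1L); cr <- idx(1L)
  if (!is.finite(c0) || !is.finite(cl) || !is.finite(cr)) return(0)
  if (method == "gauss3" && cl > 0 && cr > 0 && c0 > 0) {
    l0 <- log(c0); ll <- log(cl); lr <- log(cr)
    den <- ll - 2 * l0 + lr
    if (den >= 0) return(0)
    return((ll - lr) / (2 * den))
  }
  den <- cl - 2 * c0 + cr
  if (den >= 0) return(0)
  (cl - cr) / (2 * den)
}

#' Decompose a velocity field radially about a compartment center
#'
#' Adds signed radial (positive = outward, away from the center) and
#' tangential velocity components in um/s for every valid window. Windows
#' coinciding with the center have no defined direction and are excluded.
#' For valid windows `radial^2 + tangential^2` reconstructs the speed
#' exactly.
#'
#' @param field A `velocity_field` (or a series tibble from [piv_series()]).
#' @param center `c(x, y)` of the compartment center in pixel coordinates —
#'   conventionally the centroid of the apical mask, see [mask_centroid()].
#' @return The input with added columns `radial_um_s`, `tangential_um_s`.
#' @export
radial_project <- function(field, center) {
  if (!any(field$valid)) abort("no valid windows to project")
  dx <- field$x - center[1L]
  dy <- field$y - center[2L]
  rr <- sqrt(dx^2 + dy^2)
  ok <- field$valid & rr > 1e-9
  rhx <- dx / rr; rhy <- dy / rr
  radial <- ifelse(ok, field$u_um_s * rhx + field$v_um_s * rhy, NA_real_)
  tangential <- ifelse(ok, -field$u_um_s * rhy + field$v_um_s * rhx, NA_real_)
  field$radial_um_s <- radial
  field$tangential_um_s <- tangential
  field
}

#' Centroid of a binary mask
#'
#' @param mask Logical `Y x X` matrix.
#' @return `c(x, y)` in 0-based pixel coordinates.
#' @export
mask_centroid <- function(mask) {
  if (!any(mask)) abort("empty mask")
  idx <- which(mask, arr.ind = TRUE)
  c(x = mean(idx[, 2L]) - 1, y = mean(idx[, 1L]) - 1)
}

#' PIV over consecutive frame pairs of a stack
#'
#' Runs [piv_pair()] on every consecutive pair of the selected frames and
#' (optionally) [radial_project()]s each field about the compartment center,
#' returning one long tibble timestamped by the first frame of each pair.
#'
#' @param stack An [image_stack].
#' @param channel Channel index or name.
#' @param frames Frame indices (default all); pairs are consecutive entries.
#' @param center Optional `c(x, y)` center for radial decomposition.
#' @param ... Passed to [piv_pair()]; calibration is taken from the stack.
#' @return A tibble of class `velocity_field_series`: the `velocity_field`
#'   columns plus `pair` (index) and `time_s` (time of the pair's first
#'   frame).
#' @export
piv_series <- function(stack, channel = 1L, frames = NULL, center = NULL, ...) {
  if (is.null(frames)) frames <- seq_len(n_frames(stack))
  if (length(frames) < 2L) abort("need at least 2 frames")
  fields <- vector("list", length(frames) - 1L)
  for (p in seq_len(length(frames) - 1L)) {
    f <- piv_pair(stack_frame(stack, frames[p], channel),
                  stack_frame(stack, frames[p + 1L], channel),
                  pixel_size_um = stack$pixel_size_um,
                  frame_interval_s = stack$frame_interval_s, ...)
    atts <- attributes(f)
    if (!is.null(center)) f <- radial_project(f, center)
    f$pair <- p
    f$time_s <- (frames[p] - 1) * stack$frame_interval_s
    fields[[p]] <- f
  }
  out <- dplyr::bind_rows(fields)
  structure(out,
            window_px = atts$window_px, overlap_px = atts$overlap_px,
            pixel_size_um = atts$pixel_size_um,
            frame_interval_s = atts$frame_interval_s,
            image_shape = atts$image_shape,
            class = c("velocity_field_series", class(tibble())))
}

#' Accumulate radial displacement over a time span
#'
#' Combines the per-pair radial velocities of a series into the total radial
#' particle displacement per grid position over the span (e.g. ten 36-s
#' pairs -> 360 s), the quantity shown as a diverging-colour heat map.
#' Windows invalid in a pair contribute zero to the sum; the number of valid
#' contributions is reported alongside so an average form (mean radial
#' velocity) is also available.
#'
#' @param series A `velocity_field_series` with radial components (i.e. run
#'   with a `center`).
#' @return A tibble, one row per grid position: `x`, `y`, `total_um` (summed
#'   radial displacement), `mean_um_s` (mean radial velocity over valid
#'   pairs; `NA` where never valid), `n_valid`.
#' @export
heatmap_accumulate <- function(series) {
  if (!"radial_um_s" %in% names(series)) {
    abort("series lacks radial components; run piv_series() with a center")
  }
  dt <- attr(series, "frame_interval_s")
  series |>
    dplyr::group_by(.data$x, .data$y) |>
    dplyr::summarise(
      total_um = sum(ifelse(.data$valid & is.finite(.data$radial_um_s),
                            .data$radial_um_s * dt, 0)),
      n_valid = sum(.data$valid & is.finite(.data$radial_um_s)),
      .groups = "drop") |>
    dplyr::mutate(mean_um_s = ifelse(.data$n_valid > 0,
                                     .data$total_um / (.data$n_valid * dt),
                                     NA_real_))
}

#' Accumulated radial displacement as a grid matrix
#'
#' @param accum Output of [heatmap_accumulate()].
#' @param value Column to spread (`"total_um"` or `"mean_um_s"`).
#' @return A numeric matrix (rows = grid y, cols = grid x) suitable for
#'   [write_heatmap()].
#' @export
heatmap_matrix <- function(accum, value = "total_um") {
  xs <- sort(unique(accum$x)); ys <- sort(unique(accum$y))
  m <- matrix(NA_real_, length(ys), length(xs))
  m[cbind(match(accum$y, ys), match(accum$x, xs))] <- accum[[value]]
  m
}

#' Mean radial velocity in fixed time bins
#'
#' Averages the radial component over all valid windows and pairs within
#' non-overlapping bins of `interval_s` (2 minutes by default), the summary
#' in which sustained outward ring expansion reads as positive bins and
#' pulsatile inward detachment episodes as negative bins.
#'
#' @param series A `velocity_field_series` with radial components.
#' @param interval_s Bin width in seconds (>= one frame interval).
#' @return A tibble: `t_start_s`, `t_mid_s`, `mean_radial_um_s` (`NA` for
#'   bins with no valid window), `n_valid`.
#' @export
mean_radial_series <- function(series, interval_s = 120) {
  if (!"radial_um_s" %in% names(series)) {
    abort("series lacks radial components; run piv_series() with a center")
  }
  dt <- attr(series, "frame_interval_s")
  if (interval_s < dt) abort("`interval_s` must be >= one frame interval")
  bins <- floor(series$time_s / interval_s)
  all_bins <- seq(min(bins), max(bins))
  series$bin <- bins
  out <- series |>
    dplyr::filter(.data$valid, is.finite(.data$radial_um_s)) |>
    dplyr::group_by(.data$bin) |>
    dplyr::summarise(mean_radial_um_s = mean(.data$radial_um_s),
                     n_valid = dplyr::n(), .groups = "drop")
  full <- tibble(bin = all_bins) |>
    dplyr::left_join(out, by = "bin") |>
    dplyr::mutate(n_valid = ifelse(is.na(.data$n_valid), 0L, .data$n_valid),
                  t_start_s = .data$bin * interval_s,
                  t_mid_s = .data$t_start_s + interval_s / 2)
  full[, c("t_start_s", "t_mid_s", "mean_radial_um_s", "n_valid")]
}

#' Detect inward-flow episodes in a binned radial series
#'
#' An episode is a bin whose mean radial velocity is below
#' `-threshold_um_s`.
#'
#' @param binned Output of [mean_radial_series()].
#' @param threshold_um_s Detection threshold (positive number, um/s).
#' @return The episode rows of `binned`.
#' @export
detect_inward_episodes <- function(binned, threshold_um_s = 0.001) {
  binned[!is.na(binned$mean_radial_um_s) &
           binned$mean_radial_um_s < -threshold_um_s, ]
}

#' Arrow-map rendering data for a velocity field
#'
#' Arrows are anchored at window centers with length `display_scale` times
#' the actual displacement (2x by default, for visibility); the underlying
#' data columns are untouched. Colour encodes the radial velocity when
#' present.
#'
#' @param field A `velocity_field`, optionally radially projected.
#' @param display_scale Display magnification of arrow length.
#' @return A tibble of valid windows: `x`, `y`, `xend`, `yend`,
#'   `radial_um_s` (NA when not projected), `display_scale`.
#' @export
arrow_map <- function(field, display_scale = 2) {
  ok <- field$valid
  tibble(
    x = field$x[ok], y = field$y[ok],
    xend = field$x[ok] + display_scale * field$u[ok],
    yend = field$y[ok] + display_scale * field$v[ok],
    radial_um_s = if ("radial_um_s" %in% names(field))
      field$radial_um_s[ok] else NA_real_,
    display_scale = display_scale)
}

#' @method glance velocity_field
#' @export
glance.velocity_field <- function(x, ...) {
  sp <- sqrt(x$u_um_s^2 + x$v_um_s^2)
  tibble(n_windows = nrow(x), n_valid = sum(x$valid),
         frac_valid = mean(x$valid),
         mean_speed_um_s = mean(sp[x$valid]),
         mean_radial_um_s = if ("radial_um_s" %in% names(x))
           mean(x$radial_um_s[x$valid], na.rm = TRUE) else NA_real_)
}

#' @method tidy velocity_field
#' @export
tidy.velocity_field <- function(x, ...) as_tibble(unclass(x))

#' @method glance velocity_field_series
#' @export
glance.velocity_field_series <- glance.velocity_field

#' @method tidy velocity_field_series
#' @export
tidy.velocity_field_series <- tidy.velocity_field
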