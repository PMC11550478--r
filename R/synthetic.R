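#' Parameters for a synthetic two-channel junctional time-lapse
#'
#' Describes a scene emulating the imaging regimes the quantification stages
#' are built for: a bright elliptical junctional band enclosing an apical
#' interior, punctate particles advected by a configurable flow field, an
#' optional photoconversion event with ongoing turnover, Gaussian-PSF
#' rendering and Poisson + Gaussian noise. Every dataset generated from
#' these parameters comes with exact ground truth ([generate_scene()]), so
#' statistics are validated by parameter recovery.
#'
#' @param image_shape `c(Y, X)` in pixels.
#' @param pixel_size_um Pixel size (um; default 0.1, typical of high-zoom
#'   confocal time-lapse of 5-20 um compartments).
#' @param frame_interval_s Frame interval (s; default 36, the cadence used
#'   for velocimetry of junctional particles).
#' @param n_frames Number of frames.
#' @param ring List: `center_px` (`c(x, y)`), `semi_axes_um` (`c(a, b)`),
#'   `band_um` (band thickness used for particle placement).
#' @param n_particles Particles per channel (or in the single shared pool
#'   for photoconversion scenes).
#' @param particle_intensity Integrated intensity per particle (arbitrary
#'   units).
#' @param psf_sigma_um Isotropic Gaussian PSF proxy sigma (um); rendering
#'   integrates the Gaussian over each pixel (erf-based), so sub-pixel
#'   positions are faithfully encoded.
#' @param placement `"ring"` (band/interior split per `channel_allocation`)
#'   or `"uniform"` (whole frame; for velocimetry test patterns).
#' @param channel_allocation Numeric length-2: fraction of each channel's
#'   particles placed in the band (the rest go to the interior).
#' @param ring_background Constant intensity added to band pixels
#'   (structured background under the punctate signal).
#' @param flow List: `mode` one of `"static"`, `"translation"`, `"outward"`,
#'   `"inward_burst"`, `"rotation"`; `speed_um_s` (radial speed, positive =
#'   outward); `translation_px` (`c(dx, dy)` px/frame); `omega_rad_s`;
#'   `burst`: a list of episodes, each a list with `pairs` (frame-pair
#'   indices), `sectors` (list of `c(lo, hi)` angle ranges, radians) and
#'   `speed_um_s` (inward speed during the episode).
#' @param conversion `NULL`, or list(`time_s`, `roi` ([roi_polygon] or
#'   `"left_half"`), `rate_per_s` = turnover/exchange rate).
#' @param noise List: `poisson_gain` (0 disables; variance = gain x mean)
#'   and `gaussian_sd`.
#' @param seed Integer RNG seed; scenes are bit-reproducible given the seed.
#' @return A validated list of class `scene_params`.
#' @export
scene_params <- function(image_shape = c(256L, 256L),
                         pixel_size_um = 0.1,
                         frame_interval_s = 36,
                         n_frames = 11L,
                         ring = list(center_px = c(x = 127.5, y = 127.5),
                                     semi_axes_um = c(8, 8),
                                     band_um = 0.5),
                         n_particles = 600L,
                         particle_intensity = 150,
                         psf_sigma_um = 0.15,
                         placement = c("ring", "uniform"),
                         channel_allocation = c(0.85, 0.85),
                         ring_background = 0,
                         flow = list(mode = "static"),
                         conversion = NULL,
                         noise = list(poisson_gain = 0, gaussian_sd = 0),
                         seed = 1L) {
  placement <- match.arg(placement)
  burst_in <- flow$burst
  flow$burst <- NULL
  flow <- modifyList(list(mode = "static", speed_um_s = 0,
                          translation_px = c(0, 0), omega_rad_s = 0),
                     flow)
  # attached verbatim, not via modifyList, which mangles unnamed lists
  flow$burst <- if (is.null(burst_in)) list() else burst_in
  noise <- modifyList(list(poisson_gain = 0, gaussian_sd = 0), noise)
  ring <- modifyList(list(center_px = c(x = 127.5, y = 127.5),
                          semi_axes_um = c(8, 8), band_um = 0.5), ring)
  p <- list(image_shape = as.integer(image_shape),
            pixel_size_um = pixel_size_um,
            frame_interval_s = frame_interval_s,
            n_frames = as.integer(n_frames),
            ring = ring, n_particles = as.integer(n_particles),
            particle_intensity = particle_intensity,
            psf_sigma_um = psf_sigma_um, placement = placement,
            channel_allocation = channel_allocation,
            ring_background = ring_background,
            flow = flow, conversion = conversion, noise = noise,
            seed = as.integer(seed))
  validate_scene_params(p)
  structure(p, class = "scene_params")
}

validate_scene_params <- function(p) {
  if (any(p$image_shape < 16L)) abort("image_shape too small")
  if (p$pixel_size_um <= 0) abort("pixel_size_um must be positive")
  if (p$n_frames < 1L) abort("n_frames must be >= 1")
  if (p$n_frames > 1L && p$frame_interval_s <= 0) {
    abort("frame_interval_s must be positive")
  }
  if (p$n_particles < 1L) abort("n_particles must be >= 1")
  if (p$particle_intensity <= 0) abort("particle_intensity must be positive")
  if (p$psf_sigma_um <= 0) abort("psf_sigma_um must be positive")
  sigma_px <- p$psf_sigma_um / p$pixel_size_um
  if (8 * sigma_px > min(p$image_shape)) abort("particle kernel wider than image")
  if (any(p$channel_allocation < 0) || any(p$channel_allocation > 1)) {
    abort("channel_allocation fractions must lie in [0, 1]")
  }
  if (any(p$ring$semi_axes_um <= 0) || p$ring$band_um <= 0) {
    abort("ring geometry must be positive")
  }
  if (!p$flow$mode %in% c("static", "translation", "outward", "inward_burst",
                          "rotation")) {
    abort(paste0("unknown flow mode '", p$flow$mode, "'"))
  }
  for (ep in p$flow$burst) {
    if (is.null(ep$pairs) || is.null(ep$sectors) || is.null(ep$speed_um_s)) {
      abort("each burst episode needs pairs, sectors and speed_um_s")
    }
    if (any(ep$pairs < 1L | ep$pairs >= p$n_frames)) {
      abort("burst schedule must lie within [1, n_frames)")
    }
  }
  if (p$noise$poisson_gain < 0 || p$noise$gaussian_sd < 0) {
    abort("noise parameters must be non-negative")
  }
  if (!is.null(p$conversion)) {
    if (p$conversion$rate_per_s < 0) abort("exchange rate must be >= 0")
    if (p$conversion$time_s < 0 ||
        p$conversion$time_s > (p$n_frames - 1) * p$frame_interval_s) {
      abort("conversion time outside the scene")
    }
  }
  invisible(p)
}

# run code under a deterministic RNG stream, restoring global state after
with_scene_rng <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# membership of angles in a possibly wrapping (lo, hi) sector
angle_in_sector <- function(a, sector) {
  lo <- sector[1L]; hi <- sector[2L]
  if (lo <= hi) a >= lo & a <= hi else a >= lo | a <= hi
}

# ground-truth displacement (px) applied between frames `pair` and pair + 1
scene_displacement <- function(params, x, y, pair) {
  f <- params$flow
  dt <- params$frame_interval_s
  px <- params$pixel_size_um
  cx <- params$ring$center_px[["x"]]; cy <- params$ring$center_px[["y"]]
  dx <- x - cx; dy <- y - cy
  r <- sqrt(dx^2 + dy^2)
  rhx <- ifelse(r > 1e-12, dx / r, 0)
  rhy <- ifelse(r > 1e-12, dy / r, 0)
  switch(f$mode,
    static = cbind(dx = rep(0, length(x)), dy = rep(0, length(x))),
    translation = cbind(dx = rep(f$translation_px[1L], length(x)),
                        dy = rep(f$translation_px[2L], length(x))),
    outward = {
      s <- f$speed_um_s * dt / px
      cbind(dx = s * rhx, dy = s * rhy)
    },
    inward_burst = {
      s_base <- f$speed_um_s * dt / px
      d <- cbind(dx = s_base * rhx, dy = s_base * rhy)
      a <- atan2(dy, dx)
      for (ep in f$burst) {
        if (!pair %in% ep$pairs) next
        hit <- Reduce(`|`, lapply(ep$sectors, angle_in_sector, a = a),
                      accumulate = FALSE, init = rep(FALSE, length(x)))
        s_b <- ep$speed_um_s * dt / px
        d[hit, 1L] <- -s_b * rhx[hit]
        d[hit, 2L] <- -s_b * rhy[hit]
      }
      d
    },
    rotation = {
      th <- f$omega_rad_s * dt
      nx <- cx + dx * cos(th) - dy * sin(th)
      ny <- cy + dx * sin(th) + dy * cos(th)
      cbind(dx = nx - x, dy = ny - y)
    })
}

# pixel-integrated Gaussian rendering of point particles
render_particles <- function(shape, x, y, intensity, sigma_px) {
  img <- matrix(0, shape[1L], shape[2L])
  if (length(x) == 0L) return(img)
  rad <- ceiling(4 * sigma_px) + 1L
  nx <- shape[2L]; ny <- shape[1L]
  for (i in seq_along(x)) {
    j0 <- max(floor(x[i]) - rad, 0L); j1 <- min(floor(x[i]) + rad, nx - 1L)
    k0 <- max(floor(y[i]) - rad, 0L); k1 <- min(floor(y[i]) + rad, ny - 1L)
    if (j0 > j1 || k0 > k1) next
    jj <- j0:j1; kk <- k0:k1
    wx <- pnorm((jj + 0.5 - x[i]) / sigma_px) - pnorm((jj - 0.5 - x[i]) / sigma_px)
    wy <- pnorm((kk + 0.5 - y[i]) / sigma_px) - pnorm((kk - 0.5 - y[i]) / sigma_px)
    img[kk + 1L, jj + 1L] <- img[kk + 1L, jj + 1L] +
      intensity * (wy %o% wx)
  }
  img
}

ellipse_roi <- function(center_px, semi_axes_px, n_vertices = 90L,
                        label = "ring") {
  th <- seq(0, 2 * pi, length.out = n_vertices + 1L)[-(n_vertices + 1L)]
  roi_polygon(center_px[["x"]] + semi_axes_px[1L] * cos(th),
              center_px[["y"]] + semi_axes_px[2L] * sin(th), label = label)
}

left_half_roi <- function(params) {
  cx <- params$ring$center_px[["x"]]
  ny <- params$image_shape[1L]
  roi_polygon(c(-0.5, cx, cx, -0.5), c(-0.5, -0.5, ny - 0.5, ny - 0.5),
              label = "converted_half")
}

points_in_roi <- function(roi, x, y) {
  vx <- roi$x; vy <- roi$y
  n <- length(vx)
  j <- c(seq_len(n)[-1L], 1L)
  inside <- rep(FALSE, length(x))
  for (e in seq_len(n)) {
    y1 <- vy[e]; y2 <- vy[j[e]]
    if (y1 == y2) next
    cross <- ((y1 > y) != (y2 > y))
    xint <- vx[e] + (y - y1) * (vx[j[e]] - vx[e]) / (y2 - y1)
    inside <- xor(inside, cross & (x < xint))
  }
  inside
}

#' Photoconversion with memoryless turnover on a particle pool
#'
#' At the conversion time, particles inside the ROI switch label
#' green -> magenta instantly (the optical pulse). Afterwards every
#' converted particle independently reverts to green with probability
#' `1 - exp(-rate * dt)` per frame step, modelling replacement of converted
#' protein by new, unconverted protein at the exchange rate, so the expected
#' green fraction in the converted region follows
#' `1 - exp(-rate * (t - t_convert))`.
#'
#' @param trajectories Tibble with columns `frame`, `id`, `x`, `y` (as in
#'   `SceneTruth$trajectories`).
#' @param roi Conversion [roi_polygon].
#' @param t_convert_s Conversion time (s).
#' @param rate_per_s Exchange (turnover) rate (1/s); 0 makes the converted
#'   pool permanent.
#' @param frame_interval_s Frame interval (s).
#' @return A tibble `frame`, `id`, `channel` (`"green"`/`"magenta"`) with
#'   attribute `conversion_frame`. Draws from the current RNG stream.
#' @export
simulate_photoconversion <- function(trajectories, roi, t_convert_s,
                                     rate_per_s, frame_interval_s) {
  frames <- sort(unique(trajectories$frame))
  ids <- sort(unique(trajectories$id))
  k <- frames[which((frames - 1) * frame_interval_s >= t_convert_s)[1L]]
  if (is.na(k)) abort("conversion time beyond last frame")
  lab <- matrix("green", length(frames), length(ids))
  at_k <- trajectories[trajectories$frame == k, ]
  at_k <- at_k[order(at_k$id), ]
  converted <- points_in_roi(roi, at_k$x, at_k$y)
  if (!any(converted)) warn("conversion ROI contains no particles")
  p_flip <- 1 - exp(-rate_per_s * frame_interval_s)
  state <- converted          # TRUE = currently magenta
  for (fi in seq_along(frames)) {
    if (frames[fi] < k) next
    if (frames[fi] > k) {
      flip <- state & (runif(length(state)) < p_flip)
      state <- state & !flip
    }
    lab[fi, state] <- "magenta"
  }
  out <- tibble(frame = rep(frames, each = length(ids)),
                id = rep(ids, times = length(frames)),
                channel = as.vector(t(lab)))
  attr(out, "conversion_frame") <- k
  out
}

#' Generate a synthetic scene with exact ground truth
#'
#' Renders the scene described by a [scene_params()] object and returns both
#' the image stack and a `scene_truth` object carrying everything needed for
#' parameter recovery: per-particle trajectories (and channel labels),
#' ground-truth masks (ring raster, boundary band, apical interior), the
#' displacement function actually applied, and the parameter echo.
#' Deterministic given `params$seed`: frame-noise substreams are derived
#' from the seed, so the same parameters always produce bit-identical
#' stacks.
#'
#' @param params A [scene_params()] object.
#' @return A list with elements `stack` ([image_stack], channels
#'   `green`/`magenta`) and `truth` (class `scene_truth`).
#' @examples
#' sc <- generate_scene(scene_preset("translation_test"))
#' sc$stack
#' @export
generate_scene <- function(params) {
  stopifnot(inherits(params, "scene_params"))
  validate_scene_params(params)
  shape <- params$image_shape
  px <- params$pixel_size_um
  sigma_px <- params$psf_sigma_um / px
  axes_px <- params$ring$semi_axes_um / px
  ring_roi <- ellipse_roi(params$ring$center_px, axes_px)
  part <- partition_compartment(ring_roi, shape, px, params$ring$band_um)
  masks <- list(ring = rasterize_roi(ring_roi, shape),
                boundary_band = part$boundary_band, apical = part$apical)
  conv <- params$conversion
  if (!is.null(conv) && identical(conv$roi, "left_half")) {
    conv$roi <- left_half_roi(params)
  }

  n_ch <- 2L
  with_scene_rng(params$seed, {
    pools <- if (is.null(conv)) seq_len(n_ch) else 1L
    place <- lapply(pools, function(ch) {
      place_particles(params, masks, ch, stratify = !is.null(conv))
    })

    # advect
    frames <- seq_len(params$n_frames)
    traj <- vector("list", length(pools))
    for (pi in seq_along(pools)) {
      pos <- place[[pi]]
      n <- nrow(pos)
      xs <- matrix(0, params$n_frames, n)
      ys <- matrix(0, params$n_frames, n)
      xs[1L, ] <- pos$x; ys[1L, ] <- pos$y
      if (params$n_frames > 1L) {
        for (t in seq_len(params$n_frames - 1L)) {
          d <- scene_displacement(params, xs[t, ], ys[t, ], t)
          xs[t + 1L, ] <- xs[t, ] + d[, 1L]
          ys[t + 1L, ] <- ys[t, ] + d[, 2L]
        }
      }
      id0 <- if (pi == 1L) 0L else nrow(place[[1L]])
      traj[[pi]] <- tibble(
        frame = rep(frames, each = n),
        id = rep(id0 + seq_len(n), times = params$n_frames),
        x = as.vector(t(xs)), y = as.vector(t(ys)),
        pool = pools[pi])
    }
    trajectories <- dplyr::bind_rows(traj)

    if (is.null(conv)) {
      trajectories$channel <- c("green", "magenta")[trajectories$pool]
      conversion_frame <- NA_integer_
    } else {
      labels <- simulate_photoconversion(trajectories, conv$roi, conv$time_s,
                                         conv$rate_per_s,
                                         params$frame_interval_s)
      trajectories <- dplyr::left_join(trajectories, labels,
                                       by = c("frame", "id"))
      conversion_frame <- attr(labels, "conversion_frame")
    }
    trajectories$pool <- NULL

    data <- array(0, c(params$n_frames, n_ch, shape[1L], shape[2L]))
    ch_name <- c("green", "magenta")
    for (t in frames) {
      at_t <- trajectories[trajectories$frame == t, ]
      for (ch in seq_len(n_ch)) {
        sel <- at_t$channel == ch_name[ch]
        img <- render_particles(shape, at_t$x[sel], at_t$y[sel],
                                params$particle_intensity, sigma_px)
        if (params$ring_background > 0) {
          img <- img + params$ring_background * masks$boundary_band
        }
        data[t, ch, , ] <- img
      }
    }

    # frame/channel noise substreams derived from the scene seed
    if (params$noise$poisson_gain > 0 || params$noise$gaussian_sd > 0) {
      for (t in frames) {
        for (ch in seq_len(n_ch)) {
          set.seed(params$seed %% 100000L + 211L * t + 7L * ch)
          img <- matrix(data[t, ch, , ], shape[1L], shape[2L])
          if (params$noise$poisson_gain > 0) {
            g <- params$noise$poisson_gain
            img <- matrix(rpois(length(img), img / g) * g,
                          shape[1L], shape[2L])
          }
          if (params$noise$gaussian_sd > 0) {
            img <- img + rnorm(length(img), sd = params$noise$gaussian_sd)
          }
          data[t, ch, , ] <- img
        }
      }
    }

    stack <- image_stack(data, px, params$frame_interval_s, ch_name)
    truth <- structure(
      list(trajectories = trajectories,
           masks = masks, ring_roi = ring_roi,
           center_px = params$ring$center_px,
           conversion_frame = conversion_frame,
           conversion_roi = if (is.null(conv)) NULL else conv$roi,
           displacement_fn = function(x, y, pair) {
             scene_displacement(params, x, y, pair)
           },
           params = params),
      class = "scene_truth")
    list(stack = stack, truth = truth)
  })
}

place_particles <- function(params, masks, channel, stratify = FALSE) {
  n <- params$n_particles
  shape <- params$image_shape
  if (params$placement == "uniform") {
    return(tibble(x = runif(n, 0, shape[2L] - 1),
                  y = runif(n, 0, shape[1L] - 1)))
  }
  f_band <- params$channel_allocation[channel]
  n_band <- round(f_band * n)
  n_int <- n - n_band
  sample_mask <- function(mask, k) {
    if (k == 0L) return(tibble(x = numeric(), y = numeric()))
    idx <- which(mask, arr.ind = TRUE)
    pick <- idx[sample.int(nrow(idx), k, replace = TRUE), , drop = FALSE]
    tibble(x = pick[, 2L] - 1 + runif(k, -0.5, 0.5),
           y = pick[, 1L] - 1 + runif(k, -0.5, 0.5))
  }
  if (stratify) {
    # equal counts in the left and right halves: photoconversion scenes
    # compare half-ring means, so the two pools start at equal density
    cx <- params$ring$center_px[["x"]]
    xs <- col(masks$boundary_band) - 1
    left <- masks$boundary_band & xs < cx
    right <- masks$boundary_band & xs >= cx
    band <- dplyr::bind_rows(sample_mask(left, n_band %/% 2L),
                             sample_mask(right, n_band - n_band %/% 2L))
    xs_a <- col(masks$apical) - 1
    left_a <- masks$apical & xs_a < cx
    right_a <- masks$apical & xs_a >= cx
    interior <- dplyr::bind_rows(sample_mask(left_a, n_int %/% 2L),
                                 sample_mask(right_a, n_int - n_int %/% 2L))
    return(dplyr::bind_rows(band, interior))
  }
  dplyr::bind_rows(sample_mask(masks$boundary_band, n_band),
                   sample_mask(masks$apical, n_int))
}

#' @export
print.scene_truth <- function(x, ...) {
  cat("<scene_truth> ", length(unique(x$trajectories$id)), " particles, ",
      max(x$trajectories$frame), " frames, flow '", x$params$flow$mode,
      "'\n", sep = "")
  invisible(x)
}


# band width whose discrete band mask covers half the compartment pixels:
# the median depth of the exact distance transform, minus the half-pixel
# center-to-center offset
equal_area_band_um <- function(center_px, semi_axes_um, pixel_size_um,
                               image_shape) {
  roi <- ellipse_roi(center_px, semi_axes_um / pixel_size_um)
  raster <- rasterize_roi(roi, image_shape)
  d <- as.matrix(EBImage::distmap(raster + 0))
  (stats::median(d[raster]) - 0.5) * pixel_size_um
}

#' Named scene presets
#'
#' Fully specified study conditions used throughout the tests and the
#' acceptance analyses:
#'
#' * `"wildtype_ring"` — slow sustained outward band expansion
#'   (0.005 um/s), the signature of a growing junctional ring; all 2-minute
#'   radial bins are expected non-negative.
#' * `"rasip1_like"` — pulsatile inward bursts (0.015 um/s) confined to two
#'   angular subregions of the ring during scheduled frame pairs (bins 2
#'   and 5 of six), over a weak 0.002 um/s outward baseline — the
#'   detachment-toward-the-center regime.
#' * `"translation_test"` — uniform (3, -2) px/frame drift of an
#'   unstructured particle field, noiseless; integer-displacement oracle.
#' * `"subpixel_test"` — uniform sub-pixel drift (0.3 px/frame) of smooth
#'   blobs, noiseless; sub-pixel refinement oracle.
#' * `"rotation_test"` — rigid rotation about the ring center, noiseless;
#'   zero-radial oracle.
#' * `"conversion_test"` — static ring, half-ring photoconversion at 40 s
#'   with exchange rate `log(10)/200` per s, so 90% green recovery is
#'   expected at 200 s.
#' * `"ba_test"` — single-frame disk compartment whose band width makes
#'   band and interior areas equal (`w = R (1 - 1/sqrt(2))`), with a chosen
#'   fraction of total intensity in the band; B/A recovery oracle.
#'
#' @param name Preset name.
#' @param ... Named [scene_params()] arguments overriding the preset (e.g.
#'   `seed`).
#' @return A [scene_params()] object.
#' @export
scene_preset <- function(name, ...) {
  base <- switch(name,
    wildtype_ring = list(
      n_frames = 21L, n_particles = 700L,
      channel_allocation = c(0.85, 0.85),
      flow = list(mode = "outward", speed_um_s = 0.005),
      noise = list(poisson_gain = 1, gaussian_sd = 2),
      seed = 101L),
    rasip1_like = list(
      n_frames = 21L, n_particles = 1000L,
      channel_allocation = c(0.7, 0.7),
      flow = list(mode = "inward_burst", speed_um_s = 0.002,
                  burst = list(
                    list(pairs = c(5L, 6L, 7L),
                         sectors = list(c(-pi / 4, pi / 4),
                                        c(3 * pi / 4, -3 * pi / 4)),
                         speed_um_s = 0.02),
                    list(pairs = c(15L, 16L, 17L),
                         sectors = list(c(pi / 4, 3 * pi / 4),
                                        c(-3 * pi / 4, -pi / 4)),
                         speed_um_s = 0.02))),
      noise = list(poisson_gain = 1, gaussian_sd = 2),
      seed = 202L),
    translation_test = list(
      n_frames = 2L, n_particles = 1500L, placement = "uniform",
      flow = list(mode = "translation", translation_px = c(3, -2)),
      noise = list(poisson_gain = 0, gaussian_sd = 0),
      seed = 303L),
    subpixel_test = list(
      n_frames = 2L, n_particles = 1500L, placement = "uniform",
      psf_sigma_um = 0.15,
      flow = list(mode = "translation", translation_px = c(0.3, 0)),
      noise = list(poisson_gain = 0, gaussian_sd = 0),
      seed = 707L),
    rotation_test = list(
      n_frames = 3L, n_particles = 1500L, placement = "uniform",
      flow = list(mode = "rotation", omega_rad_s = 0.0375 / 36),
      noise = list(poisson_gain = 0, gaussian_sd = 0),
      seed = 404L),
    conversion_test = list(
      frame_interval_s = 20, n_frames = 33L, n_particles = 4000L,
      psf_sigma_um = 0.1, channel_allocation = c(1, 1),
      flow = list(mode = "static"),
      conversion = list(time_s = 40, roi = "left_half",
                        rate_per_s = log(10) / 200),
      noise = list(poisson_gain = 0, gaussian_sd = 0),
      seed = 505L),
    ba_test = list(
      n_frames = 1L, n_particles = 3000L,
      particle_intensity = 100, psf_sigma_um = 0.05,
      ring = list(center_px = c(x = 127.5, y = 127.5),
                  semi_axes_um = c(6, 6),
                  band_um = equal_area_band_um(
                    c(x = 127.5, y = 127.5), c(6, 6), 0.1, c(256L, 256L))),
      channel_allocation = c(0.5, 0.5),
      noise = list(poisson_gain = 1, gaussian_sd = 2),
      seed = 606L),
    abort(paste0("unknown preset '", name, "'")))
  args <- modifyList(base, list(...))
  do.call(scene_params, args)
}
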