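# Shared fixture builders: everything is generated in code at test time.

make_rect_roi <- function(x0, y0, x1, y1, label = "rect") {
  roi_polygon(c(x0, x1, x1, x0), c(y0, y0, y1, y1), label = label)
}

make_disk_roi <- function(cx, cy, r, n = 72, label = "disk") {
  th <- seq(0, 2 * pi, length.out = n + 1)[-(n + 1)]
  roi_polygon(cx + r * cos(th), cy + r * sin(th), label = label)
}

# small random test image with two intensity populations
make_bimodal_image <- function(ny = 64, nx = 64, seed = 1) {
  set.seed(seed)
  bg <- matrix(rnorm(ny * nx, 20, 5), ny, nx)
  fg <- matrix(rnorm(ny * nx, 120, 15), ny, nx)
  pick <- matrix(runif(ny * nx) < 0.3, ny, nx)
  ifelse(pick, fg, bg)
}

# brute-force Otsu oracle: for every candidate bin edge, split the actual
# pixel values and score the between-class variance directly
otsu_bruteforce <- function(x, n_bins = 256L) {
  x <- as.numeric(x)
  lo <- min(x); hi <- max(x)
  width <- (hi - lo) / n_bins
  # identical bin assignment as the implementation, scored the slow way
  bin_of <- function(v) as.integer(max(1, min(n_bins, ceiling((v - lo) / width))))
  bins <- vapply(x, bin_of, integer(1))
  best_t <- NA_real_; best_s <- -Inf
  for (k in seq_len(n_bins - 1L)) {
    t <- lo + k * width
    g0 <- x[bins <= k]; g1 <- x[bins > k]
    if (length(g0) == 0L || length(g1) == 0L) next
    s <- length(g0) * length(g1) * (mean(g0) - mean(g1))^2
    if (s > best_s) { best_s <- s; best_t <- t }
  }
  best_t
}

# tiny conversion scene, fast enough for unit tests
small_conversion_params <- function(rate_per_s, seed = 11L, n_frames = 24L,
                                    frame_interval_s = 20) {
  scene_preset("conversion_test", n_particles = 1500L,
               image_shape = c(160L, 160L),
               ring = list(center_px = c(x = 79.5, y = 79.5),
                           semi_axes_um = c(5, 5), band_um = 0.5),
               n_frames = n_frames, frame_interval_s = frame_interval_s,
               conversion = list(time_s = 2 * frame_interval_s,
                                 roi = "left_half", rate_per_s = rate_per_s),
               seed = seed)
}

right_half_roi <- function(shape, cx) {
  roi_polygon(c(cx, shape[2] - 0.5, shape[2] - 0.5, cx),
              c(-0.5, -0.5, shape[1] - 0.5, shape[1] - 0.5),
              label = "unconverted_half")
}
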