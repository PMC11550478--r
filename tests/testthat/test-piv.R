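test_that("identical frames give zero displacement everywhere valid", {
  set.seed(21)
  img <- lumenflow:::render_particles(c(128, 128), runif(400, 0, 127),
                                      runif(400, 0, 127), 100, 1.5)
  f <- piv_pair(img, img, min_mean_intensity = 0.01)
  expect_gt(sum(f$valid), 0)
  expect_true(all(abs(f$u[f$valid]) < 1e-9))
  expect_true(all(abs(f$v[f$valid]) < 1e-9))
})

test_that("an integer (3, -2) px shift is recovered exactly on interior windows", {
  sc <- generate_scene(scene_preset("translation_test"))
  f <- piv_pair(stack_frame(sc$stack, 1, 1), stack_frame(sc$stack, 2, 1),
                subpixel = "none", min_mean_intensity = 0.01)
  interior <- f$x >= 32 & f$x <= 223 & f$y >= 32 & f$y <= 223
  ok <- f$valid & interior
  expect_gt(sum(ok), 50)
  expect_true(all(f$u[ok] == 3))
  expect_true(all(f$v[ok] == -2))
})

test_that("sub-pixel shifts are recovered within 0.1 px RMSE by gauss3", {
  for (s in c(0.2, 0.4)) {
    sc <- generate_scene(scene_preset(
      "subpixel_test", flow = list(mode = "translation",
                                   translation_px = c(s, 0))))
    f <- piv_pair(stack_frame(sc$stack, 1, 1), stack_frame(sc$stack, 2, 1),
                  min_mean_intensity = 0.01)
    ok <- f$valid
    expect_lt(sqrt(mean((f$u[ok] - s)^2)), 0.1)
    expect_lt(sqrt(mean(f$v[ok]^2)), 0.1)
  }
})

test_that("pure-noise frame pairs are mostly invalidated by the peak ratio", {
  set.seed(5)
  n1 <- matrix(rnorm(128 * 128), 128)
  n2 <- matrix(rnorm(128 * 128), 128)
  f <- piv_pair(n1, n2)
  expect_gte(mean(!f$valid), 0.8)
})

test_that("degenerate windows are invalid: constant frames, dim frames", {
  f <- piv_pair(matrix(1, 64, 64), matrix(1, 64, 64))
  expect_false(any(f$valid))
  f2 <- piv_pair(matrix(0.01, 64, 64), matrix(0.01, 64, 64),
                 min_mean_intensity = 0.5)
  expect_false(any(f2$valid))
  expect_error(piv_pair(matrix(1, 16, 16), matrix(1, 8, 8)), "shape")
  expect_error(piv_pair(matrix(1, 16, 16), matrix(1, 16, 16),
                        window_px = 32), "larger")
  expect_error(piv_pair(matrix(1, 64, 64), matrix(1, 64, 64),
                        overlap_px = 32), "overlap")
})

test_that("radial decomposition is exact and respects symmetry oracles", {
  # synthetic field: uniform outward 0.05 um/s on a centered grid
  grid <- expand.grid(x = seq(7.5, 247.5, 16), y = seq(7.5, 247.5, 16))
  center <- c(x = 127.5, y = 127.5)
  dx <- grid$x - center[1]; dy <- grid$y - center[2]
  r <- sqrt(dx^2 + dy^2)
  s <- 0.05
  f <- tibble::tibble(x = grid$x, y = grid$y,
                      u = s * dx / r, v = s * dy / r,
                      u_um_s = u, v_um_s = v,
                      peak_ratio = 2, valid = TRUE)
  out <- radial_project(f, center)
  expect_equal(out$radial_um_s, rep(s, nrow(f)), tolerance = 1e-12)
  expect_equal(out$tangential_um_s, rep(0, nrow(f)), tolerance = 1e-12)
  # rigid rotation: radial 0, |tangential| = omega * r
  om <- 0.002
  frot <- tibble::tibble(x = grid$x, y = grid$y,
                         u = -om * dy, v = om * dx,
                         u_um_s = u, v_um_s = v, peak_ratio = 2, valid = TRUE)
  rot <- radial_project(frot, center)
  expect_true(all(abs(rot$radial_um_s) < 1e-12))
  expect_equal(abs(rot$tangential_um_s), om * r, tolerance = 1e-12)
  # uniform translation over a symmetric grid: mean radial cancels
  ftr <- tibble::tibble(x = grid$x, y = grid$y, u = 0.3, v = -0.1,
                        u_um_s = u, v_um_s = v, peak_ratio = 2, valid = TRUE)
  tr <- radial_project(ftr, center)
  expect_lt(abs(mean(tr$radial_um_s)), 1e-12)
  # speed reconstruction for random vectors
  set.seed(77)
  fr <- tibble::tibble(x = grid$x, y = grid$y,
                       u = rnorm(nrow(grid)), v = rnorm(nrow(grid)),
                       u_um_s = u, v_um_s = v, peak_ratio = 2, valid = TRUE)
  pr <- radial_project(fr, center)
  expect_equal(pr$radial_um_s^2 + pr$tangential_um_s^2,
               fr$u_um_s^2 + fr$v_um_s^2, tolerance = 1e-9)
})

test_that("measured rotation and outward scenes match their flow oracles", {
  sc <- generate_scene(scene_preset("rotation_test"))
  ser <- piv_series(sc$stack, center = sc$truth$center_px,
                    min_mean_intensity = 0.5)
  speed_t <- 0.0375 / 36 * 8  # omega * ring radius (um/s)
  expect_lt(abs(mean(ser$radial_um_s[ser$valid], na.rm = TRUE)),
            0.01 * speed_t)
  sw <- generate_scene(scene_preset("wildtype_ring", n_frames = 5L))
  serw <- piv_series(sw$stack, center = sw$truth$center_px,
                     min_mean_intensity = 0.5)
  expect_lt(abs(mean(serw$radial_um_s[serw$valid], na.rm = TRUE) - 0.005) /
              0.005, 0.15)
})

test_that("heatmap accumulation is linear and ignores invalid windows", {
  mk_series <- function(radials, valids) {
    n <- length(radials)
    out <- tibble::tibble(
      x = rep(10, n), y = rep(10, n), u = radials, v = 0,
      u_um_s = radials, v_um_s = 0, peak_ratio = 2,
      valid = valids,
      radial_um_s = ifelse(valids, radials, NaN),  # poisoned when invalid
      tangential_um_s = 0,
      pair = seq_len(n), time_s = (seq_len(n) - 1) * 36)
    structure(out, frame_interval_s = 36,
              class = c("velocity_field_series", class(tibble::tibble())))
  }
  ser <- mk_series(rep(0.05 / 36, 10), rep(TRUE, 10))
  acc <- heatmap_accumulate(ser)
  expect_equal(acc$total_um, 0.5, tolerance = 1e-9)
  alt <- mk_series(rep(c(0.01, -0.01), 5), rep(TRUE, 10))
  expect_equal(heatmap_accumulate(alt)$total_um, 0, tolerance = 1e-12)
  # NaN-poisoned invalid entries never leak into the statistics
  poisoned <- mk_series(rep(0.01, 10), rep(c(TRUE, FALSE), 5))
  accp <- heatmap_accumulate(poisoned)
  expect_true(is.finite(accp$total_um))
  expect_equal(accp$total_um, 5 * 0.01 * 36, tolerance = 1e-9)
  expect_equal(accp$n_valid, 5)
  # concatenation linearity
  first <- mk_series(rep(0.02, 4), rep(TRUE, 4))
  second <- mk_series(rep(-0.01, 6), rep(TRUE, 6))
  both <- mk_series(c(rep(0.02, 4), rep(-0.01, 6)), rep(TRUE, 10))
  expect_equal(heatmap_accumulate(both)$total_um,
               heatmap_accumulate(first)$total_um +
                 heatmap_accumulate(second)$total_um, tolerance = 1e-12)
})

test_that("mean_radial_series bins correctly and flags empty bins", {
  n <- 10
  ser <- tibble::tibble(
    x = 10, y = 10, u = 1, v = 0, u_um_s = 0.01, v_um_s = 0,
    peak_ratio = 2, valid = c(rep(TRUE, 7), rep(FALSE, 3)),
    radial_um_s = c(rep(0.01, 7), rep(NaN, 3)), tangential_um_s = 0,
    pair = 1:n, time_s = (0:(n - 1)) * 36)
  ser <- structure(ser, frame_interval_s = 36,
                   class = c("velocity_field_series", class(tibble::tibble())))
  b <- mean_radial_series(ser, 120)
  expect_equal(nrow(b), 3)
  expect_equal(b$mean_radial_um_s[1:2], c(0.01, 0.01))
  expect_true(is.na(b$mean_radial_um_s[3]))   # only invalid pairs in the bin
  expect_equal(b$n_valid, c(4, 3, 0))
  expect_error(mean_radial_series(ser, 10), "frame interval")
})

test_that("arrow_map scales display length without touching the data", {
  f <- tibble::tibble(x = c(1, 2), y = c(3, 4), u = c(0.5, -1), v = c(0, 2),
                      u_um_s = u, v_um_s = v, peak_ratio = 2,
                      valid = c(TRUE, TRUE))
  am1 <- arrow_map(f, display_scale = 1)
  am2 <- arrow_map(f, display_scale = 2)
  expect_equal(am2$xend - am2$x, 2 * (am1$xend - am1$x))
  expect_equal(f$u, c(0.5, -1))  # untouched
  zero <- arrow_map(dplyr::mutate(f, u = 0, v = 0))
  expect_equal(zero$xend, zero$x)
  # colours (radial sign) agree with radial_project window-by-window
  fp <- radial_project(f, c(0, 0))
  amp <- arrow_map(fp)
  expect_equal(amp$radial_um_s, fp$radial_um_s[fp$valid])
})
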