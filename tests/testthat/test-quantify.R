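test_that("dice_coefficient matches pixel-count oracles and edge cases", {
  m <- function(idx) { out <- matrix(FALSE, 20, 20); out[idx] <- TRUE; out }
  a <- m(1:100); b <- m(51:100)
  expect_equal(dice_coefficient(a, b), 2 * 50 / 150)     # 100/50/50 case
  expect_equal(dice_coefficient(a, a), 1)
  expect_equal(dice_coefficient(m(1:40), m(41:80)), 0)
  expect_error(dice_coefficient(m(integer(0)), m(integer(0))), "empty")
  expect_error(dice_coefficient(a, matrix(FALSE, 10, 10)), "shape")
})

test_that("dice_coefficient is symmetric and grows with intersection", {
  set.seed(31)
  for (i in 1:100) {
    a <- matrix(runif(256) < 0.4, 16, 16)
    b <- matrix(runif(256) < 0.4, 16, 16)
    if (!any(a) && !any(b)) next
    expect_identical(dice_coefficient(a, b), dice_coefficient(b, a))
  }
  # fixed areas, growing overlap
  base <- matrix(FALSE, 10, 40)
  d <- vapply(0:10, function(k) {
    a <- base; a[1, 1:20] <- TRUE
    b <- base; b[1, (21 - k):(40 - k)] <- TRUE
    dice_coefficient(a, b)
  }, numeric(1))
  expect_true(all(diff(d) > 0))
})

test_that("boundary_apical_ratio recovers constructed means and invariances", {
  sq <- make_rect_roi(5, 5, 45, 45)
  part <- partition_compartment(sq, c(50, 50), 0.1, 0.5)
  img <- matrix(0, 50, 50)
  img[part$boundary_band] <- 200
  img[part$apical] <- 100
  expect_equal(boundary_apical_ratio(img, part), 2)
  expect_equal(boundary_apical_ratio(matrix(7, 50, 50), part), 1)
  # multiplicative gain invariance; additive offset sensitivity
  expect_equal(boundary_apical_ratio(img * 3.7, part), 2)
  expect_lt(boundary_apical_ratio(img + 100, part), 2)
  # invariant under whole-cell normalization
  cell <- part$boundary_band | part$apical
  expect_equal(boundary_apical_ratio(normalize_by_cell_mean(img, cell), part), 2)
  expect_error(boundary_apical_ratio(matrix(0, 50, 50), part), "undefined ratio")
})

test_that("coefficient_of_variation matches the two-value closed form", {
  img <- matrix(c(4, 10), 10, 10)        # half 4s, half 10s under full mask
  mask <- matrix(TRUE, 10, 10)
  v <- c(rep(4, 50), rep(10, 50))
  expect_equal(coefficient_of_variation(img, mask), sd(v) / mean(v))
  expect_equal(coefficient_of_variation(img * 13, mask),
               coefficient_of_variation(img, mask))
  expect_equal(coefficient_of_variation(matrix(5, 4, 4), matrix(TRUE, 4, 4)), 0)
  expect_error(coefficient_of_variation(img, matrix(FALSE, 10, 10)), "2 pixels")
})

test_that("normalize_by_cell_mean yields unit mean over the cell", {
  set.seed(8)
  img <- matrix(runif(400, 10, 200), 20, 20)
  mask <- matrix(runif(400) < 0.6, 20, 20)
  norm <- normalize_by_cell_mean(img, mask)
  expect_equal(mean(norm[mask]), 1, tolerance = 1e-12)
  expect_true(all(normalize_by_cell_mean(matrix(5, 4, 4),
                                         matrix(TRUE, 4, 4)) == 1))
  expect_error(normalize_by_cell_mean(matrix(0, 4, 4), matrix(TRUE, 4, 4)),
               "positive")
})

test_that("line_profile is exact on flat, ramp and step images", {
  flat <- matrix(42, 30, 30)
  p <- line_profile(flat, cbind(c(2, 25), c(10, 20)))
  expect_equal(p$intensity, rep(42, nrow(p)), tolerance = 1e-12)
  # ramp f(x, y) = x: slope 1 per px under bilinear interpolation
  ramp <- matrix(rep(0:29, each = 30), 30, 30)
  p <- line_profile(ramp, cbind(c(2, 27), c(15, 15)))
  expect_equal(p$intensity, 2 + p$arclength_um, tolerance = 1e-12)
  # arclength calibrated in um
  p_um <- line_profile(ramp, cbind(c(2, 27), c(15, 15)), pixel_size_um = 0.2)
  expect_equal(max(p_um$arclength_um), 25 * 0.2)
  # vertical step edge crossed horizontally: transition within 1 px
  step <- cbind(matrix(0, 20, 10), matrix(100, 20, 10))
  p <- line_profile(step, cbind(c(2, 17), c(10, 10)))
  expect_true(all(p$intensity[p$arclength_um <= 6] == 0))
  expect_true(all(p$intensity[p$arclength_um >= 8] == 100))
  expect_error(line_profile(flat, cbind(c(-5, 10), c(5, 5))), "bounds")
  expect_error(line_profile(flat, cbind(c(2, 25), c(10, 20)), width_px = 2),
               "odd")
})

test_that("time_to_fraction inverts an exponential recovery closed form", {
  tau <- 100
  tt <- seq(0, 600, by = 30)
  curve <- tibble::tibble(time_s = tt, ratio = 1 - exp(-tt / tau))
  t90 <- time_to_fraction(curve, 0.9)
  expect_lt(abs(t90 - tau * log(10)), 30)   # within one sample interval
  # monotone in fraction
  fr <- c(0.3, 0.5, 0.7, 0.9)
  expect_true(all(diff(vapply(fr, function(f) time_to_fraction(curve, f),
                              numeric(1))) > 0))
  # starting above the level; never reaching it
  high <- tibble::tibble(time_s = c(0, 10), ratio = c(0.95, 0.97))
  expect_equal(time_to_fraction(high, 0.9), 0)
  low <- tibble::tibble(time_s = c(0, 10), ratio = c(0.1, 0.2))
  expect_true(is.na(time_to_fraction(low, 0.9)))
  expect_error(time_to_fraction(curve, 1.5), "fraction")
})

test_that("recovery_auc integrates constants exactly", {
  flatc <- tibble::tibble(time_s = seq(0, 400, 40), ratio = rep(0.7, 11))
  expect_equal(recovery_auc(flatc), 0.7 * 400)
  tri <- tibble::tibble(time_s = c(0, 10), ratio = c(0, 1))
  expect_equal(recovery_auc(tri), 5)
})

test_that("compare_groups reproduces the hand-computed pooled t test", {
  res <- compare_groups(c(1, 2, 3), c(4, 5, 6))
  # pooled s^2 = 1, se = sqrt(2/3), t = -3 / sqrt(2/3) = -3 sqrt(3/2)
  t_hand <- -3 * sqrt(3 / 2)
  p_hand <- 2 * pt(t_hand, df = 4)
  expect_equal(res$statistic, t_hand, tolerance = 1e-9)
  expect_equal(res$p_value, p_hand, tolerance = 1e-9)
  expect_equal(res$df, 4)
  same <- compare_groups(c(2, 4, 6), c(2, 4, 6))
  expect_equal(same$statistic, 0)
  expect_equal(same$p_value, 1)
  welch <- compare_groups(c(1, 2, 3), c(4, 5, 60), welch = TRUE)
  expect_identical(welch$method, "welch")
  expect_error(compare_groups(1, c(1, 2)), "2 samples")
})

test_that("halfring_recovery is flat at 1 for identical halves", {
  set.seed(12)
  img <- matrix(runif(64 * 64, 50, 60), 64, 64)
  a <- array(0, c(3, 1, 64, 64))
  for (t in 1:3) a[t, 1, , ] <- img
  st <- image_stack(a, 0.1, 10)
  left <- make_rect_roi(0, 0, 32, 64)
  right <- make_rect_roi(32, 0, 64, 64)
  # same distribution both sides: ratio approx 1; identical ROIs: exactly 1
  cur <- halfring_recovery(st, left, left, channel = 1)
  expect_true(all(cur$ratio == 1))
  cur2 <- halfring_recovery(st, left, right, channel = 1)
  expect_equal(cur2$ratio, rep(cur2$ratio[1], 3))  # static scene: constant
  g <- glance(cur)
  expect_equal(g$final_ratio, 1)
  zero <- a; zero[, , , 33:64] <- 0
  stz <- image_stack(zero, 0.1, 10)
  expect_error(halfring_recovery(stz, left, right, channel = 1),
               "denominator")
})
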