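test_that("maxima detection finds planted peaks and nothing on flat images", {
  flat <- matrix(100, 40, 40)
  expect_equal(nrow(detect_maxima(flat, prominence = 1)), 0L)

  one <- simulate_image_stack(dim = c(48, 48, 1),
                              puncta = data.frame(x0 = 20, y0 = 30,
                                                  slice = 1, A = 500,
                                                  sx = 2, sy = 2, theta = 0),
                              baseline = 100, noise_sd = 0, seed = 1)
  det <- detect_maxima(one$stack[, , 1], prominence = 50)
  expect_equal(nrow(det), 1L)
  expect_equal(det$x, 20); expect_equal(det$y, 30)

  # 5 well-separated puncta at SNR ~ 20: all recovered within 1 px
  p5 <- data.frame(x0 = c(15, 50, 85, 25, 70), y0 = c(15, 20, 40, 80, 75),
                   slice = 1, A = 400, sx = 2.5, sy = 2.5, theta = 0)
  img <- simulate_image_stack(dim = c(100, 100, 1), puncta = p5,
                              baseline = 100, noise_sd = 20, seed = 2)
  det <- detect_maxima(img$stack[, , 1])
  expect_equal(nrow(det), 5L)
  d_match <- vapply(seq_len(5), function(i)
    min(sqrt((det$x - p5$x0[i])^2 + (det$y - p5$y0[i])^2)), numeric(1))
  expect_true(all(d_match <= 1))
})

test_that("patch extraction converts physical side length and clips at borders", {
  img <- matrix(seq_len(100 * 100), 100, 100)
  p <- extract_patch(img, c(50, 50), side_um = 4.9, pixel_size = 0.13)
  expect_equal(p$side_px, 38L)
  expect_equal(dim(p$patch), c(38L, 38L))
  expect_false(p$clipped)
  pc <- extract_patch(img, c(1, 1), side_um = 4.9, pixel_size = 0.13)
  expect_true(pc$clipped)
  p1 <- extract_patch(img, c(50, 50), side_um = 0.13, pixel_size = 0.13)
  expect_equal(dim(p1$patch), c(1L, 1L))
  expect_error(extract_patch(img, c(500, 50)), "outside")
})

test_that("background subtraction recovers a constant offset", {
  img <- matrix(42, 60, 60)
  boxes <- list(c(2, 2, 8, 8), c(50, 2, 56, 8), c(2, 50, 8, 56))
  r <- subtract_background(img, boxes)
  expect_equal(r$background, 42)
  expect_true(all(r$image == 0))
  # zero-background boxes leave the image unchanged
  img2 <- img; img2[1:10, 1:10] <- 0
  r2 <- subtract_background(img2, list(c(1, 1, 10, 10)))
  expect_equal(r2$image, img2)
  # noisy offset recovered within the noise sd
  set.seed(3)
  img3 <- matrix(100 + rnorm(3600, 0, 5), 60, 60)
  r3 <- subtract_background(img3, boxes)
  expect_lt(abs(r3$background - 100), 5)
  expect_warning(subtract_background(img, list(c(1, 1, 5, 5), c(3, 3, 8, 8))),
                 "overlap")
})

test_that("the rotated-Gaussian fit is exact on model-generated patches across angles", {
  for (th in seq(0, pi * 11 / 12, length.out = 12)) {
    patch <- render_patch(38, b = 0, A = 18519, x0 = 19.4, y0 = 18.7,
                          sx = 1.1 / 0.13, sy = 1.1 / 0.13, theta = th)
    f <- fit_gaussian2d(patch, pixel_size = 0.13)
    expect_true(f$converged)
    expect_equal(f$A, 18519, tolerance = 1e-6)
    expect_equal(f$x0, 19.4, tolerance = 1e-6)
    expect_equal(f$y0, 18.7, tolerance = 1e-6)
    expect_equal(f$sx_um, 1.1, tolerance = 1e-6)
    expect_equal(f$sy_um, 1.1, tolerance = 1e-6)
    expect_true(f$circular)                     # sx == sy: theta set to 0
    expect_equal(f$theta, 0)
  }
  # anisotropic case: parameters recovered up to the sigma-swap symmetry
  patch <- render_patch(38, 100, 5000, 20, 19, 8, 4, 0.7)
  f <- fit_gaussian2d(patch)
  expect_equal(f$b, 100, tolerance = 1e-6)
  expect_equal(sort(c(f$sx, f$sy)), c(4, 8), tolerance = 1e-6)
  th_eff <- if (f$sx >= f$sy) f$theta else (f$theta + pi / 2) %% pi
  expect_equal(th_eff, 0.7, tolerance = 1e-6)
  expect_error(fit_gaussian2d(matrix(0, 3, 3)), "5x5")
})

test_that("fitting is equivariant under 90-degree patch rotation", {
  patch <- render_patch(39, 50, 2000, 20.2, 19.5, 7, 3.5, 0.4)
  f1 <- fit_gaussian2d(patch)
  f2 <- fit_gaussian2d(t(patch)[, rev(seq_len(39))])  # rotate 90 deg
  expect_equal(sort(c(f1$sx, f1$sy)), sort(c(f2$sx, f2$sy)),
               tolerance = 1e-5)
  canon <- function(f) if (f$sx >= f$sy) f$theta else (f$theta + pi / 2) %% pi
  expect_equal((canon(f2) - canon(f1)) %% pi, pi / 2, tolerance = 1e-4)
})

test_that("integrated fitted intensity matches the summed patch at moderate noise", {
  set.seed(21)
  # the summed-noise contribution scales as noise_sd * side / (2*pi*A*sx*sy),
  # so wide puncta keep the typical deviation well below 3% at SNR 10
  devs <- vapply(1:10, function(i) {
    A <- 1000; sx <- runif(1, 5, 6.5); sy <- runif(1, 5, 6.5)
    clean <- render_patch(38, 100, A, 19, 19, sx, sy, runif(1, 0, pi))
    noisy <- matrix(rpois(length(clean), clean) +
                      rnorm(length(clean), 0, A / 10), 38, 38)
    f <- fit_gaussian2d(noisy)
    abs(2 * pi * f$A * f$sx * f$sy - sum(noisy - f$b)) / sum(noisy - f$b)
  }, numeric(1))
  expect_lt(median(devs), 0.03)
})

test_that("cell classification fractions follow planted counts and sum to one", {
  labels <- matrix(0L, 60, 60)
  for (i in 1:4) labels[(i * 12 - 8):(i * 12), 10:20] <- i
  none <- classify_cells(labels, data.frame(x = numeric(), y = numeric()),
                         warn_min_cells = 0)
  expect_equal(unname(none$fractions), c(0, 0, 1))
  one_each <- data.frame(x = rep(15, 4), y = c(8, 20, 32, 44))
  r1 <- classify_cells(labels, one_each, warn_min_cells = 0)
  expect_equal(unname(r1$fractions), c(1, 0, 0))
  mixed <- data.frame(x = c(15, 15, 15, 50), y = c(8, 8.4, 20, 50))
  rm_ <- classify_cells(labels, mixed, warn_min_cells = 0)
  expect_equal(rm_$per_cell$label, c("multiple", "single", "none", "none"))
  expect_equal(rm_$n_outside, 1L)
  expect_equal(sum(rm_$fractions), 1)
  expect_warning(classify_cells(labels, one_each, warn_min_cells = 100),
                 "cells scored")
})

test_that("condition comparisons apply the Bonferroni correction and detect planted shifts", {
  fr <- data.frame(condition = rep(c("a", "b"), each = 3),
                   replicate = rep(1:3, 2),
                   fraction = c(0.5, 0.5, 0.5, 0.5, 0.5, 0.5))
  res <- compare_conditions(fr)
  expect_equal(res$p_adj, 1)
  # one comparison: adjusted equals raw
  fr2 <- data.frame(condition = rep(c("a", "b"), each = 3),
                    fraction = c(0.52, 0.48, 0.50, 0.61, 0.66, 0.70))
  res2 <- compare_conditions(fr2)
  expect_equal(res2$p_adj, res2$p)
  expect_error(compare_conditions(
    data.frame(condition = c("a", "b"), fraction = c(1, 2))), "replicates")

  # power: 0.6 vs 0.2, sd 0.05, n = 3, m = 4 comparisons
  hits <- 0
  for (seed in 1:40) {
    set.seed(seed)
    fr3 <- data.frame(condition = rep(c("a", "b"), each = 3),
                      fraction = c(rnorm(3, 0.6, 0.05), rnorm(3, 0.2, 0.05)))
    res3 <- compare_conditions(fr3)
    res3$p_adj <- pmin(1, 4 * res3$p)          # m = 4 planned comparisons
    if (res3$p_adj < 0.05) hits <- hits + 1
  }
  expect_gte(hits / 40, 0.95)
})
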