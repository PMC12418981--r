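lag_autocorr <- function(m, lag) {
  a <- as.vector(m[, seq_len(ncol(m) - lag)])
  b <- as.vector(m[, seq_len(ncol(m) - lag) + lag])
  stats::cor(a, b)
}

test_that("texture generator honours its correlation length and seed", {
  w0 <- make_texture(64, 64, 0, rng_seed = 3)
  expect_lt(abs(lag_autocorr(w0, 3)), 0.1)
  w5 <- make_texture(64, 64, 5, rng_seed = 3)
  expect_gt(lag_autocorr(w5, 3), 0.3)
  expect_identical(make_texture(32, 32, 2, rng_seed = 9),
                   make_texture(32, 32, 2, rng_seed = 9))
  expect_equal(range(w5), c(0, 1))
})

test_that("translation scenes roll exactly for integer shifts and carry
           constant truth", {
  tex <- make_texture(32, 32, 2, rng_seed = 4)
  sc0 <- translate_scene(tex, c(0, 0), 4)
  expect_equal(sc0$stack[, , 1], sc0$stack[, , 4], tolerance = 1e-10)
  sc1 <- translate_scene(tex, c(1, 0), 3)
  rolled <- tex[, c(32, 1:31)]
  expect_equal(sc1$stack[, , 2], rolled, tolerance = 1e-9)
  expect_true(all(sc1$velocity[, , 1, ] == 1))
  expect_true(all(sc1$velocity[, , 2, ] == 0))
})

test_that("subpixel translation is recovered by phase correlation", {
  tex <- make_texture(64, 64, 2, rng_seed = 5)
  sc <- translate_scene(tex, c(0.5, 0), 2)
  sh <- phase_corr_shift_x(sc$stack[, , 1], sc$stack[, , 2])
  expect_lt(abs(sh - 0.5), 0.05)
})

test_that("rotation scenes have a fixed centre and rim speed omega * r", {
  tex <- make_texture(110, 110, 2, rng_seed = 6)
  sc <- rotate_scene(tex, 0.02, 3)
  v <- sc$velocity
  cx <- (110 - 1) / 2
  # centre pixel does not move
  expect_lt(sqrt(v[56, 56, 1, 1]^2 + v[56, 56, 2, 1]^2), 0.02)
  # a pixel at radius 50 moves at 1.0 px/frame within 2%
  sp <- sqrt(v[56, 56 + 50, 1, 1]^2 + v[56, 56 + 50, 2, 1]^2)
  expect_equal(sp, 1.0, tolerance = 0.02)
  # omega = 0 -> static
  sc0 <- rotate_scene(tex, 0, 3)
  expect_equal(sc0$stack[, , 1], sc0$stack[, , 3])
})

test_that("grating derivative ratio matches the analytic drift", {
  sc <- grating_scene(48, 48, f = 0.1, orientation = 0, speed = 0.5, T = 2)
  xs <- 0:47
  # analytic derivatives at gradient maxima: gt / gx = -speed
  u <- xs
  I_t <- function(t) 0.5 + 0.4 * sin(2 * pi * 0.1 * (u - 0.5 * t))
  gx <- 0.4 * 2 * pi * 0.1 * cos(2 * pi * 0.1 * u)
  gt <- -0.4 * 2 * pi * 0.1 * 0.5 * cos(2 * pi * 0.1 * u)
  peak <- which.max(abs(gx))
  expect_equal(gt[peak] / gx[peak], -0.5, tolerance = 0.02)
  # orientation 90: gy-dominated discrete field
  sc90 <- grating_scene(32, 32, f = 0.1, orientation = 90, speed = 0.5, T = 2)
  g <- spatiotemporal_gradient(sc90$stack, 1)
  expect_lt(max(abs(g$gx[2:31, 2:31])), 1e-9)
  expect_gt(max(abs(g$gy)), 0.1)
  # speed 0 -> static
  scs <- grating_scene(32, 32, f = 0.1, orientation = 0, speed = 0, T = 3)
  expect_equal(scs$stack[, , 1], scs$stack[, , 3])
})

test_that("fluid fields are divergence-free, deterministic, and consistent
           with their frame warps", {
  sc <- fluid_scene(48, 48, 8, smoothness = 8, speed_scale = 1, rng_seed = 2)
  sp <- sqrt(sc$velocity[, , 1, ]^2 + sc$velocity[, , 2, ]^2)
  expect_equal(mean(sp), 1, tolerance = 1e-9)
  dv <- sapply(seq_len(7), function(t) mean(abs(velocity_divergence(sc, t))))
  expect_lt(max(dv), 1e-3 * mean(sp))
  expect_identical(sc$stack[, , 3],
                   fluid_scene(48, 48, 8, smoothness = 8, speed_scale = 1,
                               rng_seed = 2)$stack[, , 3])

  # independent backtrace warp of frame t by the stored field reproduces
  # frame t+1 (interior NRMSE < 5%)
  for (t in c(1, 4)) {
    f0 <- sc$stack[, , t]
    h <- 48; w <- 48
    pred <- matrix(0, h, w)
    for (r in 1:h) for (cc in 1:w) {
      sx <- (cc - 1) - sc$velocity[r, cc, 1, t]
      sy <- (r - 1) - sc$velocity[r, cc, 2, t]
      x0 <- floor(sx); y0 <- floor(sy)
      fx <- sx - x0; fy <- sy - y0
      iy0 <- (y0 %% h) + 1; iy1 <- ((y0 + 1) %% h) + 1
      ix0 <- (x0 %% w) + 1; ix1 <- ((x0 + 1) %% w) + 1
      pred[r, cc] <- (1 - fx) * (1 - fy) * f0[iy0, ix0] +
        fx * (1 - fy) * f0[iy0, ix1] +
        (1 - fx) * fy * f0[iy1, ix0] + fx * fy * f0[iy1, ix1]
    }
    truth <- sc$stack[, , t + 1]
    inner <- 5:44
    nrmse <- sqrt(mean((pred[inner, inner] - truth[inner, inner])^2)) /
      stats::sd(truth[inner, inner])
    expect_lt(nrmse, 0.05)
  }
})

test_that("translation scenes are warp-consistent too", {
  tex <- make_texture(48, 48, 2, rng_seed = 7)
  sc <- translate_scene(tex, c(0.7, -0.3), 4)
  pred <- pflowr:::warp_frame(sc$stack[, , 2], sc$velocity[, , 1, 2],
                              sc$velocity[, , 2, 2], wrap = TRUE)
  inner <- 5:44
  nrmse <- sqrt(mean((pred[inner, inner] - sc$stack[inner, inner, 3])^2)) /
    stats::sd(sc$stack[inner, inner, 3])
  expect_lt(nrmse, 0.05)
})

test_that("the smoothness parameter is a monotone viscosity proxy", {
  # the domain must comfortably contain the larger smoothing scale
  grad_energy <- function(sm, seed) {
    sc <- fluid_scene(96, 96, 3, smoothness = sm, speed_scale = 1,
                      rng_seed = seed)
    vx <- sc$velocity[, , 1, 1]; vy <- sc$velocity[, , 2, 1]
    mean(sqrt(pflowr:::diff_x_periodic(vx)^2 + pflowr:::diff_y_periodic(vx)^2 +
                pflowr:::diff_x_periodic(vy)^2 + pflowr:::diff_y_periodic(vy)^2))
  }
  for (seed in 1:10) {
    expect_lt(grad_energy(20, seed), grad_energy(5, seed))
  }
})
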