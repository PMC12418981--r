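test_that("good_features ranks a corner first and rejects flat or 1-D input", {
  expect_equal(nrow(good_features(matrix(0.5, 32, 32))), 0)

  # bright quadrant: the only two-directional structure sits at its corner
  fr <- matrix(0, 40, 40)
  fr[20:40, 20:40] <- 1
  fr <- pflowr:::box_blur3(fr)
  gf <- good_features(fr, lk_params(), n_max = 5)
  expect_gt(nrow(gf), 0)
  # localization is limited by the 15 x 15 integration window
  expect_lte(max(abs(gf$x[1] - 19), abs(gf$y[1] - 19)), lk_params()$window)

  # brute-force check: the reported lambda equals the explicit tensor
  # eigenvalue at that pixel
  r <- lk_params()$window
  ix <- pflowr:::diff_x(fr); iy <- pflowr:::diff_y(fr)
  win_y <- (gf$y[1] - r):(gf$y[1] + r) + 1
  win_x <- (gf$x[1] - r):(gf$x[1] + r) + 1
  sxx <- sum(ix[win_y, win_x]^2); sxy <- sum(ix[win_y, win_x] * iy[win_y, win_x])
  syy <- sum(iy[win_y, win_x]^2)
  lam <- min(eigen(matrix(c(sxx, sxy, sxy, syy), 2, 2))$values) / (2 * r + 1)^2
  expect_equal(gf$lambda[1], lam, tolerance = 1e-10)

  gr <- grating_scene(40, 40, f = 0.1, orientation = 0, speed = 0, T = 2)
  expect_equal(nrow(good_features(gr$stack[, , 1])), 0)
})

test_that("lk_step solves the windowed least-squares system", {
  tex <- make_texture(48, 48, 2, rng_seed = 6)
  # no motion
  st0 <- lk_step(tex, tex, c(24, 24))
  expect_equal(st0$status, "converged")
  expect_equal(st0$v, c(0, 0), tolerance = 1e-9)
  # known subpixel-free shift
  sc <- translate_scene(tex, c(1, 0), 2)
  st1 <- lk_step(sc$stack[, , 1], sc$stack[, , 2], c(24, 24))
  expect_equal(st1$status, "converged")
  expect_lt(sqrt(sum((st1$v - c(1, 0))^2)), 0.05)
  # degenerate 1-D window
  gr <- grating_scene(48, 48, f = 0.1, orientation = 0, speed = 0.5, T = 2)
  expect_equal(lk_step(gr$stack[, , 1], gr$stack[, , 2], c(24, 24))$status,
               "degenerate")
  # window outside the frame
  expect_equal(lk_step(tex, tex, c(2, 2))$status, "out_of_bounds")
})

test_that("one LK iteration equals an explicit dense least-squares solve", {
  tex <- make_texture(48, 48, 2, rng_seed = 8)
  sc <- translate_scene(tex, c(0.6, -0.4), 2)
  prev <- sc$stack[, , 1]; nxt <- sc$stack[, , 2]
  p <- c(25, 23); r <- lk_params()$window
  st <- lk_step(prev, nxt, p, lk_params(max_iter = 1))
  # oracle: build the rectangular system A v = b at integer window pixels
  ix <- pflowr:::diff_x(prev); iy <- pflowr:::diff_y(prev)
  ys <- (p[2] - r):(p[2] + r) + 1; xs <- (p[1] - r):(p[1] + r) + 1
  A <- cbind(as.vector(ix[ys, xs]), as.vector(iy[ys, xs]))
  b <- -as.vector(nxt[ys, xs] - prev[ys, xs])
  v_oracle <- qr.solve(crossprod(A), crossprod(A, b))
  expect_equal(st$v, as.vector(v_oracle), tolerance = 1e-6)
})

test_that("track_lk recovers translation and rotation fields", {
  tex <- make_texture(64, 64, 1.5, rng_seed = 2)
  sc <- translate_scene(tex, c(1, 0), 12)
  tr <- track_lk(sc$stack, lk_params(), n_max = 100)
  expect_gt(length(unique(tr$track_id)), 10)
  d <- track_displacements(tr)
  expect_lt(max(sqrt((d$dx - 1)^2 + d$dy^2)), 0.1)

  rot <- rotate_scene(make_texture(96, 96, 1.5, rng_seed = 4), 0.02, 10)
  trr <- track_lk(rot$stack, lk_params(), n_max = 150)
  dr <- track_displacements(trr)
  dr$rad <- sqrt((dr$x - 47.5)^2 + (dr$y - 47.5)^2)
  dr$sp <- sqrt(dr$dx^2 + dr$dy^2)
  per_track <- do.call(rbind, lapply(split(dr, dr$track_id), function(z) {
    data.frame(rad = mean(z$rad), sp = mean(z$sp))
  }))
  # away from the fixed point (relative error meaningful) and from the
  # zero-filled rim that rotates through outer windows
  per_track <- per_track[per_track$rad > 10 & per_track$rad < 35, ]
  expect_gt(nrow(per_track), 20)
  rel <- abs(per_track$sp - 0.02 * per_track$rad) / (0.02 * per_track$rad)
  expect_lt(mean(rel), 0.1)            # tangential speed follows omega * r
  expect_gte(mean(rel <= 0.1), 0.75)   # for the bulk of the tracks
})

test_that("a static scene yields no moving LK dots", {
  tex <- make_texture(48, 48, 1.5, rng_seed = 3)
  fs <- frame_stack(array(rep(tex, 6), c(48, 48, 6)))
  expect_equal(nrow(track_lk(fs)), 0)
})

test_that("LK and p-flow agree on translation; LK rejects the grating that
           p-flow still reports", {
  tex <- make_texture(64, 64, 1.5, rng_seed = 5)
  sc <- translate_scene(tex, c(1, 0), 12)
  stk <- decolorize_and_blur(sc$stack)
  dp <- track_displacements(extract_pflow(stk))
  dl <- track_displacements(track_lk(sc$stack, n_max = 100))
  vp <- c(mean(dp$dx), mean(dp$dy))
  vl <- c(mean(dl$dx), mean(dl$dy))
  expect_lt(sqrt(sum((vp - vl)^2)), 0.2)

  gr <- grating_scene(48, 48, f = 0.05, orientation = 0, speed = 0.5, T = 8)
  expect_equal(nrow(track_lk(gr$stack)), 0)
  expect_gt(nrow(extract_pflow(gr$stack)), 0)
})

test_that("dot-count matching equalizes per-frame means deterministically", {
  stk <- decolorize_and_blur(
    translate_scene(make_texture(64, 64, 1.5, rng_seed = 6), c(1, 0), 12)$stack)
  a <- extract_pflow(stk)
  b <- track_lk(stk, n_max = 20)
  m <- match_dot_counts(a, b, rng_seed = 1)
  T_ <- 12
  expect_lte(abs(mean(dot_counts(m$a, T_)) - mean(dot_counts(m$b, T_))), 1)
  m2 <- match_dot_counts(a, b, rng_seed = 1)
  expect_identical(m, m2)
  # equal inputs pass through unchanged
  m3 <- match_dot_counts(b, b, rng_seed = 1)
  expect_identical(m3$a, b)
})
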