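make_translation_stack <- function(seed = 1, v = c(1, 0), T = 12,
                                   corr = 1.5, blur = TRUE) {
  tex <- make_texture(64, 64, corr, rng_seed = seed)
  sc <- translate_scene(tex, v, T)
  if (blur) decolorize_and_blur(sc$stack) else sc$stack
}

test_that("match_vector accepts the identity case with score 1 and rejects
           zero fields", {
  set.seed(4)
  # static stack: fields of any two transitions are identical
  fs3 <- frame_stack(array(rep(runif(20 * 20), 3), c(20, 20, 3)))
  f2 <- spatiotemporal_gradient(fs3, 2)
  f1 <- spatiotemporal_gradient(fs3, 1)
  i <- which(f1$valid_mask, arr.ind = TRUE)[1, ]
  g <- c(f1$gx[i[1], i[2]], f1$gy[i[1], i[2]], f1$gt[i[1], i[2]])
  r <- match_vector(g, i[2] - 1, i[1] - 1, f2)
  expect_true(r$matched)
  expect_equal(r$position, c(i[2] - 1, i[1] - 1))  # gt = 0: no displacement
  expect_equal(r$score, 1)

  zero_field <- structure(list(gx = matrix(0, 20, 20), gy = matrix(0, 20, 20),
                               gt = matrix(0, 20, 20),
                               valid_mask = matrix(FALSE, 20, 20),
                               frame_index = 2, tau_g = 0.01),
                          class = "gradient_field")
  expect_false(match_vector(g, i[2] - 1, i[1] - 1, zero_field)$matched)
})

test_that("a rotation beyond the angular tolerance is unmatched", {
  params <- pflow_params(theta_tol = 10)
  # constant synthetic field holding g rotated by 2 * theta_tol in (gx, gy)
  g <- c(0.2, 0, 0)  # static vector: implied displacement zero
  th <- 2 * params$theta_tol * pi / 180
  rot <- c(cos(th) * g[1], sin(th) * g[1])
  fld <- structure(list(gx = matrix(rot[1], 9, 9), gy = matrix(rot[2], 9, 9),
                        gt = matrix(0, 9, 9),
                        valid_mask = matrix(TRUE, 9, 9),
                        frame_index = 2, tau_g = 0.01),
                   class = "gradient_field")
  expect_false(match_vector(g, 4, 4, fld, params)$matched)
  # and within tolerance it matches
  th2 <- 0.5 * params$theta_tol * pi / 180
  fld$gx[] <- cos(th2) * g[1]; fld$gy[] <- sin(th2) * g[1]
  expect_true(match_vector(g, 4, 4, fld, params)$matched)
})

test_that("implied positions outside the frame are unmatched, not errors", {
  fld <- structure(list(gx = matrix(0.2, 9, 9), gy = matrix(0, 9, 9),
                        gt = matrix(0, 9, 9),
                        valid_mask = matrix(TRUE, 9, 9),
                        frame_index = 2, tau_g = 0.01),
                   class = "gradient_field")
  g <- c(0.2, 0, -0.5)  # implies +2.5 px in x
  r <- match_vector(g, 7, 4, fld)
  expect_false(r$matched)
})

test_that("tracks on rigid translation concentrate at the true shift", {
  stk <- make_translation_stack(seed = 2)
  tr <- extract_pflow(stk)
  expect_gt(length(unique(tr$track_id)), 30)
  d <- track_displacements(tr)
  per_track <- vapply(split(d, d$track_id), function(z) {
    sqrt((mean(z$dx) - 1)^2 + mean(z$dy)^2)
  }, numeric(1))
  expect_gte(mean(per_track <= 0.5), 0.9)
})

test_that("track displacements project onto the gradient axis as the
           normal-flow component", {
  stk <- make_translation_stack(seed = 3)
  tr <- extract_pflow(stk)
  d <- track_displacements(tr)
  worst <- 0
  for (t in unique(d$frame)) {
    f <- spatiotemporal_gradient(stk, t)
    i <- which(d$frame == t)
    s <- sample_gradient(f, d$x[i], d$y[i])
    gm <- sqrt(s$gx^2 + s$gy^2)
    proj <- (d$dx[i] * s$gx + d$dy[i] * s$gy) / gm
    normal <- -s$gt / gm
    worst <- max(worst, max(abs(proj - normal), na.rm = TRUE))
  }
  expect_lt(worst, 0.25)
})

test_that("a static textured scene yields no moving dots", {
  tex <- make_texture(48, 48, 1.5, rng_seed = 5)
  fs <- frame_stack(array(rep(tex, 6), c(48, 48, 6)))
  tr <- extract_pflow(fs)
  expect_equal(nrow(tr), 0)
  # constant stack: empty, not an error
  fs2 <- frame_stack(array(0.5, c(16, 16, 5)))
  expect_equal(nrow(extract_pflow(fs2)), 0)
})

test_that("temporally independent noise yields almost no accepted tracks", {
  set.seed(9)
  fs <- frame_stack(array(runif(64 * 64 * 8), c(64, 64, 8)))
  params <- pflow_params()
  tr <- extract_pflow(fs, params)
  n_seeded <- 0
  for (t in seq_len(8 - 1 - params$m_min)) {
    f <- spatiotemporal_gradient(fs, t, params$tau_g)
    nf <- normal_flow(f, params$v_max)
    gr <- seq(1, 64, by = params$seed_stride)
    n_seeded <- n_seeded + sum(f$valid_mask[gr, gr] & nf$defined_mask[gr, gr])
  }
  expect_gt(n_seeded, 100)
  expect_lte(length(unique(tr$track_id)) / n_seeded, 0.05)
})

test_that("extraction is deterministic and monotone in the tolerances", {
  stk <- make_translation_stack(seed = 4, corr = 1)
  t1 <- extract_pflow(stk)
  t2 <- extract_pflow(stk)
  expect_identical(t1, t2)
  n_default <- length(unique(t1$track_id))
  n_theta <- length(unique(extract_pflow(stk, pflow_params(theta_tol = 5))$track_id))
  n_rho <- length(unique(extract_pflow(stk, pflow_params(rho_tol = 0.15))$track_id))
  expect_lte(n_theta, n_default)
  expect_lte(n_rho, n_default)
})

test_that("aperture behaviour: grating displacements stay on the gradient
           axis at any orientation", {
  for (o in c(0, 30, 90)) {
    sc <- grating_scene(48, 48, f = 0.05, orientation = o, speed = 0.5, T = 8)
    tr <- extract_pflow(sc$stack)
    d <- track_displacements(tr)
    expect_gt(nrow(d), 0)
    th <- o * pi / 180
    orth <- abs(-sin(th) * d$dx + cos(th) * d$dy)
    expect_lt(max(orth), 0.1)
    along <- cos(th) * d$dx + sin(th) * d$dy
    expect_lt(abs(mean(along) - 0.5), 0.1)
  }
})

test_that("subsampling respects the per-frame budget, determinism and the
           identity cases", {
  stk <- make_translation_stack(seed = 6)
  tr <- extract_pflow(stk)
  T_ <- 12
  expect_identical(subsample_tracks(tr, 1e6, 1), tr)
  expect_equal(nrow(subsample_tracks(tr, 0, 1)), 0)
  s1 <- subsample_tracks(tr, 5, rng_seed = 7)
  s2 <- subsample_tracks(tr, 5, rng_seed = 7)
  expect_identical(s1, s2)
  expect_lte(max(dot_counts(s1, T_)), 5)
  s3 <- subsample_tracks(tr, 5, rng_seed = 8)
  expect_false(identical(s1, s3))
})

test_that("track tables survive a CSV round trip", {
  stk <- make_translation_stack(seed = 7, T = 6)
  tr <- extract_pflow(stk)
  f <- withr::local_tempfile(fileext = ".csv")
  write_tracks(tr, f)
  back <- read_tracks(f)
  expect_equal(as.data.frame(back), as.data.frame(tr), tolerance = 1e-12)
})
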