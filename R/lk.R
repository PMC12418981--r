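#' Parameters for the Lucas-Kanade baseline tracker
#'
#' Defaults follow common practice for desk-scale motions of a few px/frame:
#' a 15 x 15 integration window (`window = 7` half-size), a per-pixel
#' minimum-eigenvalue floor of 1e-4 on `[0, 1]` intensities, and iterative
#' refinement to 0.01 px. Pyramids are omitted.
#'
#' @param window Window half-size in pixels (full window `2*window + 1`).
#' @param lambda_min Minimum smaller eigenvalue of the per-pixel-normalized
#'   structure tensor for a window to be considered well-conditioned.
#' @param max_iter Maximum refinement iterations per transition.
#' @param conv_tol Convergence tolerance on the update step (px).
#' @param v_max Maximum speed (px/frame) before a track is declared lost.
#' @param min_speed Zero-motion suppression threshold on a track's mean
#'   speed (px/frame), matching the p-flow convention.
#' @param reseed_every Re-seed features from [good_features()] every this
#'   many frames to keep dot counts steady.
#' @param rng_seed Integer seed for randomized steps (subsampling).
#' @return An object of class `lk_params`.
#' @export
lk_params <- function(window = 7, lambda_min = 1e-4, max_iter = 20,
                      conv_tol = 0.01, v_max = 3, min_speed = 0.05,
                      reseed_every = 10, rng_seed = 1L) {
  stopifnot(window >= 1, lambda_min > 0, conv_tol > 0, max_iter >= 1)
  structure(list(window = as.integer(window), lambda_min = lambda_min,
                 max_iter = as.integer(max_iter), conv_tol = conv_tol,
                 v_max = v_max, min_speed = min_speed,
                 reseed_every = as.integer(reseed_every),
                 rng_seed = as.integer(rng_seed)),
            class = "lk_params")
}

# Windowed box sum by integral image (zero outside the frame).
box_sum <- function(m, r) {
  h <- nrow(m); w <- ncol(m)
  p <- matrix(0, h + 2 * r + 1, w + 2 * r + 1)
  p[(r + 2):(r + 1 + h), (r + 2):(r + 1 + w)] <- m
  p <- apply(apply(p, 2, cumsum), 1, cumsum)  # transposed integral image
  p <- t(p)
  ii <- function(rr, cc) p[rr, cc, drop = FALSE]
  rows <- seq_len(h); cols <- seq_len(w)
  ii(rows + 2 * r + 1, cols + 2 * r + 1) - ii(rows, cols + 2 * r + 1) -
    ii(rows + 2 * r + 1, cols) + ii(rows, cols)
}

#' Rank trackable features by the structure tensor's smaller eigenvalue
#'
#' The classic "good features to track" criterion: at each pixel the
#' structure tensor `sum(grad I grad I^T)` is accumulated over the window;
#' pixels are ranked by its smaller eigenvalue (normalized per window
#' pixel), non-maximum suppressed at the window radius, and the top `n_max`
#' returned. Rank-deficient neighbourhoods (flat regions, 1-D gratings)
#' fall below `lambda_min` and yield no features.
#'
#' @param frame Numeric matrix (one grayscale frame).
#' @param params [lk_params()].
#' @param n_max Maximum number of features.
#' @return Data frame with `x`, `y` (0-based px) and `lambda` (quality),
#'   strongest first; zero rows when nothing passes.
#' @export
good_features <- function(frame, params = lk_params(), n_max = 200) {
  r <- params$window
  ix <- diff_x(frame); iy <- diff_y(frame)
  npix <- (2 * r + 1)^2
  sxx <- box_sum(ix * ix, r) / npix
  sxy <- box_sum(ix * iy, r) / npix
  syy <- box_sum(iy * iy, r) / npix
  tr <- sxx + syy
  det_disc <- sqrt(pmax((sxx - syy)^2 + 4 * sxy^2, 0))
  lam <- (tr - det_disc) / 2
  h <- nrow(frame); w <- ncol(frame)
  margin <- r + 1L
  ok <- matrix(FALSE, h, w)
  if (h > 2 * margin && w > 2 * margin) {
    ok[(margin + 1):(h - margin), (margin + 1):(w - margin)] <- TRUE
  }
  cand <- which(ok & lam >= params$lambda_min, arr.ind = TRUE)
  if (nrow(cand) == 0) {
    return(data.frame(x = numeric(0), y = numeric(0), lambda = numeric(0)))
  }
  lv <- lam[cand]
  ord <- order(-lv)
  cand <- cand[ord, , drop = FALSE]; lv <- lv[ord]
  sel_x <- numeric(0); sel_y <- numeric(0); sel_l <- numeric(0)
  for (k in seq_len(nrow(cand))) {
    cx <- cand[k, 2] - 1; cy <- cand[k, 1] - 1
    if (length(sel_x) == 0 ||
        all(pmax(abs(sel_x - cx), abs(sel_y - cy)) >= r)) {
      sel_x <- c(sel_x, cx); sel_y <- c(sel_y, cy); sel_l <- c(sel_l, lv[k])
      if (length(sel_x) >= n_max) break
    }
  }
  data.frame(x = sel_x, y = sel_y, lambda = sel_l)
}

# Core LK solve; ix, iy are precomputed gradients of `prev`.
lk_step_impl <- function(prev, nxt, ix, iy, px, py, params) {
  r <- params$window
  off <- expand.grid(ox = -r:r, oy = -r:r)
  wx <- px + off$ox; wy <- py + off$oy
  gx <- bilinear_sample(ix, wx, wy)
  gy <- bilinear_sample(iy, wx, wy)
  i0 <- bilinear_sample(prev, wx, wy)
  if (anyNA(gx) || anyNA(i0)) {
    return(list(v = c(NA_real_, NA_real_), status = "out_of_bounds"))
  }
  sxx <- sum(gx * gx); sxy <- sum(gx * gy); syy <- sum(gy * gy)
  npix <- length(gx)
  tr <- sxx + syy
  lam_min <- (tr - sqrt(max((sxx - syy)^2 + 4 * sxy^2, 0))) / 2 / npix
  if (lam_min < params$lambda_min) {
    return(list(v = c(NA_real_, NA_real_), status = "degenerate"))
  }
  det_g <- sxx * syy - sxy^2
  v <- c(0, 0)
  status <- "max_iter"
  for (it in seq_len(params$max_iter)) {
    i1 <- bilinear_sample(nxt, wx + v[1], wy + v[2])
    if (anyNA(i1)) return(list(v = c(NA_real_, NA_real_),
                               status = "out_of_bounds"))
    it_err <- i1 - i0
    b1 <- -sum(gx * it_err); b2 <- -sum(gy * it_err)
    dv <- c(syy * b1 - sxy * b2, -sxy * b1 + sxx * b2) / det_g
    v <- v + dv
    if (sqrt(sum(v^2)) > params$v_max) {
      return(list(v = v, status = "diverged"))
    }
    if (sqrt(sum(dv^2)) < params$conv_tol) { status <- "converged"; break }
  }
  list(v = v, status = status)
}

#' One Lucas-Kanade displacement estimate
#'
#' Solves the windowed least-squares brightness-constancy system
#' `(sum grad I grad I^T) v = -sum grad I * It` around `p`, iteratively
#' re-warping the next frame until the update falls below `conv_tol` or
#' `max_iter` is reached.
#'
#' @param prev,next_frame Numeric matrices (consecutive grayscale frames).
#' @param p Length-2 position `(x, y)` in 0-based px.
#' @param params [lk_params()].
#' @return List with `v` (displacement `(dx, dy)` in px) and `status`, one
#'   of `"converged"`, `"max_iter"`, `"degenerate"` (smaller eigenvalue
#'   below `lambda_min`), `"out_of_bounds"`, `"diverged"`.
#' @export
lk_step <- function(prev, next_frame, p, params = lk_params()) {
  ix <- diff_x(prev); iy <- diff_y(prev)
  lk_step_impl(prev, next_frame, ix, iy, p[1], p[2], params)
}

#' Track features across a movie with Lucas-Kanade
#'
#' Features are seeded by [good_features()] on the first frame, stepped
#' across each transition by [lk_step()], truncated when a window becomes
#' degenerate or leaves the frame, and re-seeded every `reseed_every`
#' frames away from surviving tracks. Output uses the same `dot_tracks`
#' contract as [extract_pflow()] with `algorithm = "lk"`; tracks whose mean
#' speed falls below `min_speed` are suppressed, matching the p-flow
#' convention for point-light displays.
#'
#' @param stack Grayscale [frame_stack()], at least 2 frames.
#' @param params [lk_params()].
#' @param n_max Maximum simultaneous features.
#' @return A `dot_tracks` data frame.
#' @export
track_lk <- function(stack, params = lk_params(), n_max = 200) {
  assert_gray_stack(stack)
  T_ <- n_frames(stack)
  act <- data.frame(id = integer(0), x = numeric(0), y = numeric(0),
                    lambda = numeric(0))
  pos <- list()
  next_id <- 1L
  seed_now <- function(frame_mat, t) {
    feats <- good_features(frame_mat, params, n_max)
    if (nrow(feats) == 0) return(invisible())
    if (nrow(act) > 0) {
      far <- vapply(seq_len(nrow(feats)), function(k) {
        all(pmax(abs(act$x - feats$x[k]), abs(act$y - feats$y[k])) >=
              params$window)
      }, logical(1))
      feats <- feats[far, , drop = FALSE]
    }
    room <- max(0L, n_max - nrow(act))
    if (nrow(feats) > room) feats <- feats[seq_len(room), , drop = FALSE]
    if (nrow(feats) == 0) return(invisible())
    ids <- seq.int(next_id, length.out = nrow(feats))
    next_id <<- next_id + nrow(feats)
    act <<- rbind(act, data.frame(id = ids, x = feats$x, y = feats$y,
                                  lambda = feats$lambda))
    pos[[length(pos) + 1L]] <<- data.frame(id = ids, frame = t,
                                           x = feats$x, y = feats$y)
  }
  seed_now(get_frame(stack, 1), 1L)
  for (t in seq_len(T_ - 1L)) {
    if (t > 1 && (t - 1) %% params$reseed_every == 0) {
      seed_now(get_frame(stack, t), t)
    }
    if (nrow(act) == 0) next
    prev <- get_frame(stack, t); nxt <- get_frame(stack, t + 1)
    ix <- diff_x(prev); iy <- diff_y(prev)
    keep <- logical(nrow(act))
    for (k in seq_len(nrow(act))) {
      st <- lk_step_impl(prev, nxt, ix, iy, act$x[k], act$y[k], params)
      if (st$status %in% c("converged", "max_iter")) {
        act$x[k] <- act$x[k] + st$v[1]
        act$y[k] <- act$y[k] + st$v[2]
        keep[k] <- TRUE
      }
    }
    act <- act[keep, , drop = FALSE]
    if (nrow(act) > 0) {
      pos[[length(pos) + 1L]] <- data.frame(id = act$id, frame = t + 1L,
                                            x = act$x, y = act$y)
    }
  }
  if (length(pos) == 0) return(empty_tracks())
  df <- do.call(rbind, pos)
  df <- df[order(df$id, df$frame), ]
  lens <- table(df$id)
  keep_ids <- as.integer(names(lens)[lens >= 2])
  df <- df[df$id %in% keep_ids, , drop = FALSE]
  if (nrow(df) == 0) return(empty_tracks())
  # mean-speed suppression
  sp <- vapply(split(df, df$id), function(d) {
    mean(sqrt(diff(d$x)^2 + diff(d$y)^2))
  }, numeric(1))
  keep_ids <- as.integer(names(sp)[sp >= params$min_speed])
  df <- df[df$id %in% keep_ids, , drop = FALSE]
  if (nrow(df) == 0) return(empty_tracks())
  starts <- vapply(split(df$frame, df$id), min, numeric(1))
  ord_ids <- as.integer(names(sort(starts)))
  new_id <- seq_along(ord_ids); names(new_id) <- ord_ids
  out <- data.frame(track_id = new_id[as.character(df$id)],
                    frame = df$frame, x = df$x, y = df$y,
                    score = 1, algorithm = "lk",
                    stringsAsFactors = FALSE)
  out <- out[order(out$track_id, out$frame), ]
  rownames(out) <- NULL
  class(out) <- c("dot_tracks", "data.frame")
  out
}

#' Equalize dot counts between two track sets
#'
#' The comparison between algorithms keeps "motion energy" comparable by
#' matching the number of moving dots: the larger set is randomly
#' subsampled (whole tracks at a time) until its per-frame mean active-dot
#' count is within 1 of the smaller set's.
#'
#' If either set is empty (an algorithm found nothing, e.g. Lucas-Kanade on
#' a pure grating) both sets pass through unchanged: there is no meaningful
#' energy level to equalize to.
#'
#' @param a,b `dot_tracks` data frames.
#' @param rng_seed Integer seed (selection is deterministic under it).
#' @return List with elements `a` and `b`, the count-matched track sets.
#' @export
match_dot_counts <- function(a, b, rng_seed = 1L) {
  tot_a <- nrow(a); tot_b <- nrow(b)
  if (tot_a == 0 || tot_b == 0) return(list(a = a, b = b))
  T_ <- max(1L, max(c(a$frame, b$frame)))
  if (abs(tot_a - tot_b) <= T_) return(list(a = a, b = b))
  if (tot_a > tot_b) {
    list(a = subsample_to_total(a, tot_b, T_, rng_seed), b = b)
  } else {
    list(a = a, b = subsample_to_total(b, tot_a, T_, rng_seed))
  }
}

subsample_to_total <- function(tracks, target_total, T_, rng_seed) {
  ids <- unique(tracks$track_id)
  lens <- vapply(split(tracks$track_id, tracks$track_id), length, numeric(1))
  lens <- lens[as.character(ids)]
  ord <- with_seed(rng_seed, sample(seq_along(ids)))
  tot <- 0; keep <- logical(length(ids))
  for (k in ord) {
    if (tot + lens[k] <= target_total) {
      keep[k] <- TRUE
      tot <- tot + lens[k]
    }
    if (target_total - tot < 2) break
  }
  out <- tracks[tracks$track_id %in% ids[keep], , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("dot_tracks", "data.frame")
  out
}
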