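#' Parameters for p-flow extraction
#'
#' @param tau_g Gradient-magnitude threshold (intensity/pixel) below which a
#'   pixel carries no usable motion constraint.
#' @param theta_tol Angular tolerance (degrees) between the full 3-vectors
#'   `(gx, gy, gt)` for a match.
#' @param rho_tol Relative-magnitude tolerance for a match:
#'   `| ||g'|| - ||g|| | / ||g|| <= rho_tol`.
#' @param m_min Minimum number of matched consecutive transitions for a
#'   track to be accepted (tracks have `m_min + 1` or more positions).
#' @param v_max Maximum speed (px/frame); faster implied displacements are
#'   treated as unmatched.
#' @param seed_stride Spacing (pixels) of the candidate seeding grid.
#' @param min_speed Zero-motion suppression: candidates implying speeds
#'   below this (px/frame) are not seeded, since the point-light display
#'   visualizes motion. Set to 0 to keep static dots.
#' @param match_ref What "the same vector" is matched against as a track is
#'   extended: `"seed"` (default) keeps the vector the track was seeded
#'   with as the reference at every transition, so the implied-position
#'   error of an inconsistent candidate accumulates over time points and
#'   the filter sharpens with track length; `"previous"` re-references to
#'   the vector sampled at the last matched position.
#' @param tangent_search After a successful match, refine the matched
#'   position along the brightness-constancy constraint line (the
#'   direction tangential to the gradient) to wherever the reference
#'   vector is best re-found. A single gradient constrains only the normal
#'   component of motion; the tangential component is exactly the
#'   aperture-ambiguous part, and re-finding the vector along that line is
#'   what resolves it when the surrounding texture permits. Default `TRUE`.
#' @param tangent_step Search grid spacing along the constraint line (px).
#' @param tangent_penalty Dimensionless tie-break penalty on squared
#'   tangential displacement; among near-equivalent re-occurrences the
#'   smaller displacement (closer to pure normal flow) wins.
#' @param tangent_gain Minimum relative improvement (fraction of the
#'   squared reference-vector norm) that the best constraint-line position
#'   must offer over the normal-flow point before the track moves
#'   tangentially. On stimuli where the search objective is flat by
#'   construction — 1-D gratings, the canonical aperture case — no
#'   improvement is possible and the displacement stays pure normal flow.
#' @param rng_seed Seed for the (few) randomized steps, e.g. subsampling.
#' @return An object of class `pflow_params`.
#' @export
pflow_params <- function(tau_g = 0.01, theta_tol = 10, rho_tol = 0.3,
                         m_min = 3, v_max = 3, seed_stride = 4,
                         min_speed = 0.05, match_ref = c("seed", "previous"),
                         tangent_search = TRUE, tangent_step = 0.05,
                         tangent_penalty = 1e-3, tangent_gain = 0.01,
                         rng_seed = 1L) {
  stopifnot(tau_g > 0, theta_tol > 0, rho_tol > 0, m_min >= 1,
            v_max > 0, seed_stride >= 1, min_speed >= 0,
            tangent_step > 0, tangent_penalty >= 0, tangent_gain >= 0)
  match_ref <- match.arg(match_ref)
  structure(list(tau_g = tau_g, theta_tol = theta_tol, rho_tol = rho_tol,
                 m_min = as.integer(m_min), v_max = v_max,
                 seed_stride = as.integer(seed_stride),
                 min_speed = min_speed, match_ref = match_ref,
                 tangent_search = isTRUE(tangent_search),
                 tangent_step = tangent_step,
                 tangent_penalty = tangent_penalty,
                 tangent_gain = tangent_gain,
                 rng_seed = as.integer(rng_seed)),
            class = "pflow_params")
}

# Angle (degrees) and relative magnitude difference between reference
# 3-vectors and sampled 3-vectors; NA-safe.
vector_dissimilarity <- function(rx, ry, rt, sx, sy, st) {
  n1 <- sqrt(rx^2 + ry^2 + rt^2)
  n2 <- sqrt(sx^2 + sy^2 + st^2)
  cosang <- clamp((rx * sx + ry * sy + rt * st) / (n1 * n2), -1, 1)
  list(ang = acos(cosang) * 180 / pi, relmag = abs(n2 - n1) / n1, n2 = n2)
}

# Vectorized matching kernel shared by match_vector() and extract_pflow().
# The current vector (gx, gy, gt) supplies the implied displacement (its
# normal flow); the next transition's field is sampled at the implied
# position and compared against the reference vector (rx, ry, rt) — the
# seed vector in "seed" mode, the current one in "previous" mode — on the
# full 3-vector angle and relative magnitude. With `refine` the matched
# position is then searched along the constraint line (tangential
# direction), where the normal component pins down no motion, for the
# penalized best re-occurrence of the reference vector.
match_vectors_impl <- function(gx, gy, gt, x, y, next_field, params,
                               rx = gx, ry = gy, rt = gt,
                               mode = "bilinear", refine = FALSE) {
  denom <- gx^2 + gy^2
  vx <- -gt * gx / denom
  vy <- -gt * gy / denom
  speed2 <- vx^2 + vy^2
  feasible <- is.finite(vx) & is.finite(vy) & speed2 <= params$v_max^2
  x2 <- x + vx
  y2 <- y + vy
  g2 <- sample_gradient(next_field, x2, y2, mode = mode)
  dis <- vector_dissimilarity(rx, ry, rt, g2$gx, g2$gy, g2$gt)
  h <- nrow(next_field$gx); w <- ncol(next_field$gx)
  interior <- !is.na(x2) & x2 >= 1 & x2 <= w - 2 & y2 >= 1 & y2 <= h - 2
  matched <- feasible & interior & !is.na(g2$gx) & dis$n2 > 0 &
    dis$ang <= params$theta_tol & dis$relmag <= params$rho_tol
  matched[is.na(matched)] <- FALSE
  score <- 0.5 * (1 - dis$ang / params$theta_tol) +
    0.5 * (1 - dis$relmag / params$rho_tol)
  score[!matched] <- NA_real_
  out <- list(matched = matched, x2 = x2, y2 = y2,
              gx2 = g2$gx, gy2 = g2$gy, gt2 = g2$gt,
              vx = vx, vy = vy, score = score)
  if (refine && any(matched)) {
    out <- refine_tangential(out, gx, gy, x, y, next_field, params,
                             rx, ry, rt)
  }
  out
}

# Search along the tangential (constraint-line) direction for the best
# penalized re-occurrence of the reference vector; updates positions,
# sampled vectors and scores of matched candidates in place.
refine_tangential <- function(m, gx, gy, x, y, next_field, params,
                              rx, ry, rt) {
  idx <- which(m$matched)
  gm <- sqrt(gx[idx]^2 + gy[idx]^2)
  tx <- -gy[idx] / gm
  ty <- gx[idx] / gm
  s_grid <- seq(-params$v_max, params$v_max, by = params$tangent_step)
  n <- length(idx); S <- length(s_grid)
  px <- rep(m$x2[idx], S) + rep(s_grid, each = n) * rep(tx, S)
  py <- rep(m$y2[idx], S) + rep(s_grid, each = n) * rep(ty, S)
  sx <- bilinear_sample(next_field$gx, px, py)
  sy <- bilinear_sample(next_field$gy, px, py)
  st <- bilinear_sample(next_field$gt, px, py)
  r2 <- rx[idx]^2 + ry[idx]^2 + rt[idx]^2
  obj0 <- (sx - rep(rx[idx], S))^2 + (sy - rep(ry[idx], S))^2 +
    (st - rep(rt[idx], S))^2
  obj <- obj0 +
    params$tangent_penalty * rep(s_grid^2, each = n) * rep(r2, S)
  # disallow refinements that push the total displacement past v_max or
  # into the border band of one-sided differences
  vnorm2 <- (m$x2[idx] - x[idx])^2 + (m$y2[idx] - y[idx])^2
  tot2 <- rep(vnorm2, S) + rep(s_grid^2, each = n)
  h <- nrow(next_field$gx); w <- ncol(next_field$gx)
  obj[is.na(obj) | tot2 > params$v_max^2 |
        px < 1 | px > w - 2 | py < 1 | py > h - 2] <- Inf
  objm <- matrix(obj, n, S)
  obj0m <- matrix(obj0, n, S)
  best <- max.col(-objm, ties.method = "first")
  s_best <- s_grid[best]
  ok <- is.finite(objm[cbind(seq_len(n), best)])
  s_best[!ok] <- 0
  # move only when the line minimum beats the normal-flow point decisively
  i0 <- which.min(abs(s_grid))
  gain <- obj0m[cbind(seq_len(n), rep(i0, n))] -
    obj0m[cbind(seq_len(n), best)]
  s_best[is.na(gain) | gain < params$tangent_gain * r2] <- 0
  if (any(s_best != 0)) {
    bx <- m$x2[idx] + s_best * tx
    by <- m$y2[idx] + s_best * ty
    g2 <- sample_gradient(next_field, bx, by)
    dis <- vector_dissimilarity(rx[idx], ry[idx], rt[idx],
                                g2$gx, g2$gy, g2$gt)
    accept <- !is.na(g2$gx) & dis$ang <= params$theta_tol &
      dis$relmag <= params$rho_tol & s_best != 0
    accept[is.na(accept)] <- FALSE
    upd <- idx[accept]
    m$x2[upd] <- bx[accept]
    m$y2[upd] <- by[accept]
    m$gx2[upd] <- g2$gx[accept]
    m$gy2[upd] <- g2$gy[accept]
    m$gt2[upd] <- g2$gt[accept]
    m$score[upd] <- 0.5 * (1 - dis$ang[accept] / params$theta_tol) +
      0.5 * (1 - dis$relmag[accept] / params$rho_tol)
  }
  m
}

#' Match one gradient vector at the position it implies
#'
#' The p-flow acceptance rule: a spatiotemporal gradient vector comes from
#' optical flow (rather than noise) if the same vector is found at the
#' position the vector itself implies in the following transition. The
#' implied displacement is the brightness-constancy normal flow of `g`; the
#' next field is sampled there by bilinear interpolation and the match
#' requires the angle between the full 3-vectors to be at most `theta_tol`
#' degrees and the relative magnitude difference at most `rho_tol`.
#'
#' @param g Numeric length-3 vector `(gx, gy, gt)` at position `(x, y)`.
#' @param x,y Position of `g` in the current transition (0-based px).
#' @param next_field `gradient_field` of the following transition.
#' @param params [pflow_params()].
#' @return List with `matched` (flag), `position` (implied `(x, y)`, `NA`
#'   if out of frame), and `score` (normalized similarity in `[0, 1]`,
#'   `NA` when unmatched). An implied position outside the frame is
#'   unmatched, not an error.
#' @export
match_vector <- function(g, x, y, next_field, params = pflow_params()) {
  stopifnot(length(g) == 3, inherits(next_field, "gradient_field"))
  r <- match_vectors_impl(g[1], g[2], g[3], x, y, next_field, params)
  pos <- c(r$x2, r$y2)
  if (!all(is.finite(pos))) pos <- c(NA_real_, NA_real_)
  list(matched = r$matched, position = pos, score = r$score)
}

#' Extract the p-flow from a grayscale movie
#'
#' Candidate gradient vectors are seeded on a `seed_stride` grid at valid
#' pixels of every transition and extended frame-to-frame by the matching
#' rule of [match_vector()]: each accepted match moves the candidate to the
#' implied position and adopts the gradient vector sampled there. Candidates
#' matched over at least `m_min` consecutive transitions become tracks.
#' The procedure is fully deterministic for a given stack and parameters.
#'
#' @param stack Grayscale [frame_stack()] with at least `m_min + 1` frames.
#' @param params [pflow_params()].
#' @return A `dot_tracks` data frame with columns `track_id`, `frame`, `x`,
#'   `y`, `score`, `algorithm` (`"pflow"`), sorted by start frame and then
#'   by descending score. An all-constant stack yields zero rows.
#' @export
extract_pflow <- function(stack, params = pflow_params()) {
  assert_gray_stack(stack, min_frames = params$m_min + 1L)
  T_ <- n_frames(stack)
  h <- dim(stack)[1]; w <- dim(stack)[2]
  fields <- lapply(seq_len(T_ - 1L), function(t)
    spatiotemporal_gradient(stack, t, tau_g = params$tau_g))

  # active candidate state
  act <- list(id = integer(0), x = numeric(0), y = numeric(0),
              gx = numeric(0), gy = numeric(0), gt = numeric(0),
              rx = numeric(0), ry = numeric(0), rt = numeric(0),
              steps = integer(0), ssum = numeric(0), start = integer(0))
  pos_log <- list(id = list(), frame = list(), x = list(), y = list())
  kept <- list(id = integer(0), steps = integer(0), ssum = numeric(0),
               start = integer(0))
  next_id <- 1L

  grid_rows <- seq(1L, h, by = params$seed_stride)
  grid_cols <- seq(1L, w, by = params$seed_stride)
  last_seed_t <- (T_ - 1L) - params$m_min

  log_positions <- function(ids, frame, x, y) {
    k <- length(pos_log$id) + 1L
    pos_log$id[[k]] <<- ids
    pos_log$frame[[k]] <<- rep.int(frame, length(ids))
    pos_log$x[[k]] <<- x
    pos_log$y[[k]] <<- y
  }
  retire <- function(sel) {
    keep_mask <- act$steps[sel] >= params$m_min
    if (any(keep_mask)) {
      kept$id <<- c(kept$id, act$id[sel][keep_mask])
      kept$steps <<- c(kept$steps, act$steps[sel][keep_mask])
      kept$ssum <<- c(kept$ssum, act$ssum[sel][keep_mask])
      kept$start <<- c(kept$start, act$start[sel][keep_mask])
    }
  }

  for (t in seq_len(T_ - 1L)) {
    # seed new candidates at this transition
    if (t <= last_seed_t) {
      fl <- fields[[t]]
      nf <- normal_flow(fl, v_max = params$v_max)
      sub_ok <- fl$valid_mask[grid_rows, grid_cols, drop = FALSE] &
        nf$defined_mask[grid_rows, grid_cols, drop = FALSE]
      spd2 <- nf$vx[grid_rows, grid_cols, drop = FALSE]^2 +
        nf$vy[grid_rows, grid_cols, drop = FALSE]^2
      sub_ok <- sub_ok & !is.na(spd2) & spd2 >= params$min_speed^2
      if (any(sub_ok)) {
        idx <- which(sub_ok, arr.ind = TRUE)
        rr <- grid_rows[idx[, 1]]; cc <- grid_cols[idx[, 2]]
        n_new <- nrow(idx)
        ids <- seq.int(next_id, length.out = n_new)
        next_id <- next_id + n_new
        lin <- cbind(rr, cc)
        act$id <- c(act$id, ids)
        act$x <- c(act$x, as.numeric(cc - 1L))
        act$y <- c(act$y, as.numeric(rr - 1L))
        act$gx <- c(act$gx, fl$gx[lin])
        act$gy <- c(act$gy, fl$gy[lin])
        act$gt <- c(act$gt, fl$gt[lin])
        act$rx <- c(act$rx, fl$gx[lin])
        act$ry <- c(act$ry, fl$gy[lin])
        act$rt <- c(act$rt, fl$gt[lin])
        act$steps <- c(act$steps, rep.int(0L, n_new))
        act$ssum <- c(act$ssum, rep.int(0, n_new))
        act$start <- c(act$start, rep.int(t, n_new))
        log_positions(ids, t, as.numeric(cc - 1L), as.numeric(rr - 1L))
      }
    }
    if (length(act$id) == 0L) next
    if (t == T_ - 1L) {            # no further field to match into
      retire(seq_along(act$id))
      break
    }
    m <- match_vectors_impl(act$gx, act$gy, act$gt, act$x, act$y,
                            fields[[t + 1L]], params,
                            rx = act$rx, ry = act$ry, rt = act$rt,
                            refine = params$tangent_search)
    surv <- m$matched
    retire(which(!surv))
    if (any(surv)) {
      log_positions(act$id[surv], t + 1L, m$x2[surv], m$y2[surv])
    }
    keep_seed_ref <- params$match_ref == "seed"
    act <- list(id = act$id[surv],
                x = m$x2[surv], y = m$y2[surv],
                gx = m$gx2[surv], gy = m$gy2[surv], gt = m$gt2[surv],
                rx = if (keep_seed_ref) act$rx[surv] else m$gx2[surv],
                ry = if (keep_seed_ref) act$ry[surv] else m$gy2[surv],
                rt = if (keep_seed_ref) act$rt[surv] else m$gt2[surv],
                steps = act$steps[surv] + 1L,
                ssum = act$ssum[surv] + m$score[surv],
                start = act$start[surv])
  }

  assemble_tracks(pos_log, kept, algorithm = "pflow")
}

# Build the canonical dot_tracks data frame from the position log and the
# set of accepted candidates; tracks sorted by (start_frame, score desc).
assemble_tracks <- function(pos_log, kept, algorithm) {
  if (length(kept$id) == 0L) return(empty_tracks())
  df <- data.frame(id = unlist(pos_log$id),
                   frame = unlist(pos_log$frame),
                   x = unlist(pos_log$x),
                   y = unlist(pos_log$y))
  df <- df[df$id %in% kept$id, , drop = FALSE]
  score <- kept$ssum / kept$steps
  ord <- order(kept$start, -score)
  new_ids <- integer(max(kept$id))
  new_ids[kept$id[ord]] <- seq_along(ord)
  sc <- numeric(max(kept$id))
  sc[kept$id] <- score
  out <- data.frame(track_id = new_ids[df$id],
                    frame = df$frame,
                    x = df$x, y = df$y,
                    score = sc[df$id],
                    algorithm = algorithm,
                    stringsAsFactors = FALSE)
  out <- out[order(out$track_id, out$frame), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("dot_tracks", "data.frame")
  out
}

empty_tracks <- function() {
  out <- data.frame(track_id = integer(0), frame = integer(0),
                    x = numeric(0), y = numeric(0), score = numeric(0),
                    algorithm = character(0), stringsAsFactors = FALSE)
  class(out) <- c("dot_tracks", "data.frame")
  out
}

#' Per-transition displacements of tracks
#'
#' @param tracks A `dot_tracks` data frame.
#' @return Data frame with one row per track transition: `track_id`,
#'   `frame` (the transition's starting frame), `x`, `y` (position at that
#'   frame), `dx`, `dy` (displacement to the next frame, px/frame).
#' @export
track_displacements <- function(tracks) {
  if (nrow(tracks) == 0) {
    return(data.frame(track_id = integer(0), frame = integer(0),
                      x = numeric(0), y = numeric(0),
                      dx = numeric(0), dy = numeric(0)))
  }
  tracks <- tracks[order(tracks$track_id, tracks$frame), ]
  same <- c(tracks$track_id[-1] == tracks$track_id[-nrow(tracks)], FALSE)
  i <- which(same)
  data.frame(track_id = tracks$track_id[i], frame = tracks$frame[i],
             x = tracks$x[i], y = tracks$y[i],
             dx = tracks$x[i + 1] - tracks$x[i],
             dy = tracks$y[i + 1] - tracks$y[i])
}

#' Active dots per frame
#' @param tracks A `dot_tracks` data frame.
#' @param T Total frame count (frames without dots report 0).
#' @return Integer vector of length `T`.
#' @export
dot_counts <- function(tracks, T) {
  tab <- tabulate(tracks$frame, nbins = T)
  tab
}

#' Subsample tracks to a per-frame dot budget
#'
#' Tracks are visited in a seeded random order and greedily kept while no
#' frame's active-dot count exceeds `n_target`; selection is uniform among
#' tracks and deterministic under the seed, and displacement statistics are
#' preserved in expectation.
#'
#' @param tracks A `dot_tracks` data frame.
#' @param n_target Maximum active dots per frame (`>= 0`).
#' @param rng_seed Integer seed.
#' @return A `dot_tracks` data frame (unchanged if already within budget).
#' @export
subsample_tracks <- function(tracks, n_target, rng_seed = 1L) {
  stopifnot(n_target >= 0)
  if (n_target == 0) return(empty_tracks())
  if (nrow(tracks) == 0) return(tracks)
  T_ <- max(tracks$frame)
  if (max(dot_counts(tracks, T_)) <= n_target) return(tracks)
  ids <- unique(tracks$track_id)
  order_ids <- with_seed(rng_seed, sample(ids))
  counts <- integer(T_)
  frames_by_id <- split(tracks$frame, tracks$track_id)
  keep <- logical(length(order_ids))
  for (k in seq_along(order_ids)) {
    fr <- frames_by_id[[as.character(order_ids[k])]]
    if (all(counts[fr] < n_target)) {
      counts[fr] <- counts[fr] + 1L
      keep[k] <- TRUE
    }
  }
  out <- tracks[tracks$track_id %in% order_ids[keep], , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("dot_tracks", "data.frame")
  out
}

#' Write tracks to CSV
#' @param tracks A `dot_tracks` data frame.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_tracks <- function(tracks, path) {
  utils::write.csv(as.data.frame(tracks), path, row.names = FALSE)
  invisible(path)
}

#' Read tracks from CSV
#' @param path CSV written by [write_tracks()].
#' @return A `dot_tracks` data frame.
#' @export
read_tracks <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("track_id", "frame", "x", "y", "score", "algorithm")
  if (!all(need %in% names(df))) stop("not a track table: missing columns")
  df <- df[need]
  class(df) <- c("dot_tracks", "data.frame")
  df
}
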