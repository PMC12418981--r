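#' Score tracks against ground truth (endpoint error)
#'
#' For every track transition the estimated velocity (the displacement to
#' the next position) is compared with the true velocity bilinearly sampled
#' at the dot's position: EPE is the Euclidean norm of the difference, and
#' the angular error the space-time angle between the homogeneous `(v, 1)`
#' vectors. Coverage is the fraction of frame area within `r_cov` px of
#' any active dot, averaged over frames.
#'
#' @param tracks A `dot_tracks` data frame.
#' @param scene A [ground_truth_scene()] sharing the frame geometry.
#' @param r_cov Coverage radius in px.
#' @return An object of class `flow_error_summary`: list with `mean_epe`,
#'   `median_epe`, `mean_angular_error` (degrees), `n_measurements`,
#'   `coverage`. With no measurements the error fields are `NA` (absent,
#'   not zero).
#' @export
endpoint_error <- function(tracks, scene, r_cov = 10) {
  d <- track_displacements(tracks)
  T_ <- n_frames(scene$stack)
  nmax <- dim(scene$velocity)[4]
  d <- d[d$frame >= 1 & d$frame <= nmax, , drop = FALSE]
  if (nrow(d) == 0) {
    return(structure(list(mean_epe = NA_real_, median_epe = NA_real_,
                          mean_angular_error = NA_real_,
                          n_measurements = 0L, coverage = 0,
                          r_cov = r_cov),
                     class = "flow_error_summary"))
  }
  epe <- numeric(nrow(d)); ang <- numeric(nrow(d)); keep <- logical(nrow(d))
  for (t in unique(d$frame)) {
    i <- which(d$frame == t)
    tv <- sample_velocity(scene, d$x[i], d$y[i], t)
    ok <- !is.na(tv$vx)
    epe[i] <- sqrt((d$dx[i] - tv$vx)^2 + (d$dy[i] - tv$vy)^2)
    ang[i] <- angular_error(cbind(d$dx[i], d$dy[i]), cbind(tv$vx, tv$vy))
    keep[i] <- ok
  }
  epe <- epe[keep]; ang <- ang[keep]
  structure(list(mean_epe = mean(epe), median_epe = stats::median(epe),
                 mean_angular_error = mean(ang),
                 n_measurements = length(epe),
                 coverage = dot_coverage(tracks, dim(scene$stack)[1],
                                         dim(scene$stack)[2], T_, r_cov),
                 r_cov = r_cov),
            class = "flow_error_summary")
}

#' @export
print.flow_error_summary <- function(x, ...) {
  cat(sprintf(paste0("<flow_error_summary> n=%d, mean EPE %.3f px, ",
                     "median %.3f px, mean angular %.2f deg, coverage %.2f\n"),
              x$n_measurements, x$mean_epe, x$median_epe,
              x$mean_angular_error, x$coverage))
  invisible(x)
}

#' Space-time angular error between velocity estimates
#'
#' The standard flow-benchmark angle between homogeneous `(vx, vy, 1)`
#' vectors, well defined even for zero velocities.
#'
#' @param v_hat,v_true Length-2 vectors or 2-column matrices `(vx, vy)`.
#' @return Angle(s) in degrees; 0 when equal.
#' @export
#' @examples
#' angular_error(c(1, 0), c(0, 1))  # 60 degrees
angular_error <- function(v_hat, v_true) {
  if (is.null(dim(v_hat))) v_hat <- matrix(v_hat, ncol = 2)
  if (is.null(dim(v_true))) v_true <- matrix(v_true, ncol = 2)
  num <- v_hat[, 1] * v_true[, 1] + v_hat[, 2] * v_true[, 2] + 1
  den <- sqrt(v_hat[, 1]^2 + v_hat[, 2]^2 + 1) *
    sqrt(v_true[, 1]^2 + v_true[, 2]^2 + 1)
  acos(clamp(num / den, -1, 1)) * 180 / pi
}

# Mean over frames of the fraction of pixels within r_cov of an active dot.
dot_coverage <- function(tracks, h, w, T_, r_cov) {
  if (nrow(tracks) == 0) return(0)
  covs <- numeric(T_)
  for (t in seq_len(T_)) {
    rows <- tracks[tracks$frame == t, , drop = FALSE]
    if (nrow(rows) == 0) next
    mask <- matrix(FALSE, h, w)
    for (k in seq_len(nrow(rows))) {
      cx <- rows$x[k]; cy <- rows$y[k]
      x0 <- max(0, floor(cx - r_cov)); x1 <- min(w - 1, ceiling(cx + r_cov))
      y0 <- max(0, floor(cy - r_cov)); y1 <- min(h - 1, ceiling(cy + r_cov))
      if (x0 > x1 || y0 > y1) next
      xs <- x0:x1; ys <- y0:y1
      d2 <- outer((ys - cy)^2, (xs - cx)^2, "+")
      mask[ys + 1, xs + 1] <- mask[ys + 1, xs + 1] | (d2 <= r_cov^2)
    }
    covs[t] <- mean(mask)
  }
  mean(covs)
}

#' Run and score both extraction algorithms on one scene
#'
#' Extracts the p-flow and the Lucas-Kanade tracks, equalizes dot counts
#' via [match_dot_counts()], and scores both against the scene's ground
#' truth.
#'
#' @param scene A [ground_truth_scene()].
#' @param pparams [pflow_params()].
#' @param lkparams [lk_params()].
#' @param n_max Maximum LK features.
#' @param r_cov Coverage radius for the summaries.
#' @return List with `pflow` and `lk` ([endpoint_error()] summaries),
#'   `dot_counts` (per-frame active-dot counts per algorithm after
#'   matching) and the matched track sets.
#' @export
compare_algorithms <- function(scene, pparams = pflow_params(),
                               lkparams = lk_params(), n_max = 200,
                               r_cov = 10) {
  tr_p <- extract_pflow(scene$stack, pparams)
  tr_l <- track_lk(scene$stack, lkparams, n_max = n_max)
  m <- match_dot_counts(tr_p, tr_l, rng_seed = pparams$rng_seed)
  T_ <- n_frames(scene$stack)
  list(pflow = endpoint_error(m$a, scene, r_cov),
       lk = endpoint_error(m$b, scene, r_cov),
       dot_counts = list(pflow = dot_counts(m$a, T_),
                         lk = dot_counts(m$b, T_)),
       tracks = list(pflow = m$a, lk = m$b))
}
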