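#' Rendering parameters for point-light displays
#'
#' @param height,width Frame size in pixels.
#' @param dot_radius Dot radius in pixels (`>= 1`).
#' @param dot_value,background_value Intensities of dots and background
#'   (must differ); default white dots on black.
#' @param frame_rate Frames per second (metadata).
#' @return An object of class `render_spec`.
#' @export
render_spec <- function(height, width, dot_radius = 2, dot_value = 1,
                        background_value = 0, frame_rate = 30) {
  stopifnot(height >= 3, width >= 3, dot_radius >= 1,
            dot_value != background_value)
  structure(list(height = as.integer(height), width = as.integer(width),
                 dot_radius = dot_radius, dot_value = dot_value,
                 background_value = background_value,
                 frame_rate = frame_rate),
            class = "render_spec")
}

#' Render tracks as a point-light-display movie
#'
#' Every active track position becomes an anti-aliased disc; anti-aliasing
#' uses area-coverage weighting so subpixel positions are preserved (a
#' blob-centroid detector recovers them to well under half a pixel).
#' Positions outside the frame are silently clipped.
#'
#' @param tracks A `dot_tracks` data frame.
#' @param spec A [render_spec()].
#' @param T Number of frames to render (`>= 1`).
#' @return A grayscale [frame_stack()] of `T` frames.
#' @export
render_dots <- function(tracks, spec, T) {
  stopifnot(inherits(spec, "render_spec"), T >= 1)
  h <- spec$height; w <- spec$width; r <- spec$dot_radius
  out <- array(spec$background_value, c(h, w, T))
  if (nrow(tracks) > 0) {
    for (t in seq_len(T)) {
      rows <- tracks[tracks$frame == t, , drop = FALSE]
      if (nrow(rows) == 0) next
      cover <- matrix(0, h, w)
      for (k in seq_len(nrow(rows))) {
        cx <- rows$x[k]; cy <- rows$y[k]
        x0 <- max(0, floor(cx - r - 1)); x1 <- min(w - 1, ceiling(cx + r + 1))
        y0 <- max(0, floor(cy - r - 1)); y1 <- min(h - 1, ceiling(cy + r + 1))
        if (x0 > x1 || y0 > y1) next
        xs <- x0:x1; ys <- y0:y1
        d <- sqrt(outer((ys - cy)^2, (xs - cx)^2, "+"))
        cv <- clamp(r + 0.5 - d, 0, 1)
        blk <- cover[ys + 1, xs + 1, drop = FALSE]
        cover[ys + 1, xs + 1] <- pmax(blk, cv)
      }
      out[, , t] <- spec$background_value +
        (spec$dot_value - spec$background_value) * cover
    }
  }
  frame_stack(out, frame_rate = spec$frame_rate,
              provenance = "point-light render")
}

#' Detect dot centroids in a rendered point-light display
#'
#' Test oracle for render round trips: pixels above half contrast are
#' grouped into connected components and reduced to contrast-weighted
#' centroids.
#'
#' @param stack Grayscale [frame_stack()] rendered with a known spec.
#' @param spec The [render_spec()] used for rendering.
#' @return Data frame with `frame`, `x`, `y` (0-based px), one row per
#'   detected dot; zero rows for blank input.
#' @export
detect_dot_centroids <- function(stack, spec) {
  assert_gray_stack(stack, min_frames = 1L)
  thr <- (spec$dot_value + spec$background_value) / 2
  res <- list()
  for (t in seq_len(n_frames(stack))) {
    fr <- get_frame(stack, t)
    contrast <- (fr - spec$background_value) /
      (spec$dot_value - spec$background_value)
    mask <- if (spec$dot_value > spec$background_value) fr > thr else fr < thr
    if (!any(mask)) next
    lab <- EBImage::bwlabel(mask * 1)
    for (l in seq_len(max(lab))) {
      idx <- which(lab == l, arr.ind = TRUE)
      wgt <- contrast[idx]
      res[[length(res) + 1L]] <- data.frame(
        frame = t,
        x = sum((idx[, 2] - 1) * wgt) / sum(wgt),
        y = sum((idx[, 1] - 1) * wgt) / sum(wgt))
    }
  }
  if (length(res) == 0) {
    return(data.frame(frame = integer(0), x = numeric(0), y = numeric(0)))
  }
  do.call(rbind, res)
}
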