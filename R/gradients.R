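#' Spatiotemporal image gradient for one frame transition
#'
#' Computes the gradient vector field g = (gx, gy, gt) that the p-flow
#' algorithm tracks. Spatial derivatives use central differences within
#' frame `t` (one-sided at borders); the temporal derivative is the forward
#' difference `frame(t+1) - frame(t)`, so a gradient field "belongs to" the
#' earlier frame of the transition. Pixels whose spatial gradient magnitude
#' falls below `tau_g` are masked invalid: a near-zero spatial gradient
#' constrains no motion (the fully aperture-degenerate case).
#'
#' @param stack Grayscale [frame_stack()].
#' @param t Transition index, `1 <= t <= T - 1`; the field describes the
#'   transition from frame `t` to frame `t + 1`.
#' @param tau_g Gradient-magnitude validity threshold (intensity/pixel).
#' @return An object of class `gradient_field`: list with matrices `gx`,
#'   `gy` (intensity/pixel), `gt` (intensity/frame), logical `valid_mask`,
#'   and `frame_index = t`.
#' @export
#' @examples
#' ramp <- matrix(rep(seq(0, 1, length.out = 16), each = 16), 16, 16,
#'                byrow = FALSE)
#' fs <- frame_stack(array(c(ramp, ramp), c(16, 16, 2)))
#' g <- spatiotemporal_gradient(fs, 1)
#' range(g$gt)  # static scene: all zero
spatiotemporal_gradient <- function(stack, t, tau_g = 0.01) {
  assert_gray_stack(stack)
  T_ <- n_frames(stack)
  if (t < 1 || t > T_ - 1) stop("transition index out of range")
  f0 <- get_frame(stack, t)
  f1 <- get_frame(stack, t + 1)
  gx <- diff_x(f0)
  gy <- diff_y(f0)
  gt <- f1 - f0
  valid <- (gx^2 + gy^2) >= tau_g^2
  # border pixels carry one-sided spatial differences whose direction is
  # biased; they are excluded from the usable field
  valid[c(1, nrow(valid)), ] <- FALSE
  valid[, c(1, ncol(valid))] <- FALSE
  structure(list(gx = gx, gy = gy, gt = gt,
                 valid_mask = valid,
                 frame_index = t, tau_g = tau_g),
            class = "gradient_field")
}

#' @export
print.gradient_field <- function(x, ...) {
  cat(sprintf("<gradient_field> transition %d, %d x %d px, %.1f%% valid\n",
              x$frame_index, nrow(x$gx), ncol(x$gx),
              100 * mean(x$valid_mask)))
  invisible(x)
}

#' Normal flow implied by a gradient field
#'
#' Under the brightness-constancy constraint `gx*vx + gy*vy + gt = 0` a
#' single gradient measurement constrains only the motion component along
#' the spatial gradient; the unique such component is
#' `v = -gt * (gx, gy) / (gx^2 + gy^2)`. This is the displacement each
#' gradient vector "implies" and at which the p-flow matching rule looks
#' for the same vector in the next transition.
#'
#' @param field A `gradient_field`.
#' @param v_max Maximum plausible speed (px/frame); faster pixels are
#'   flagged undefined rather than raised.
#' @return An object of class `normal_flow_field`: matrices `vx`, `vy`
#'   (px/frame) and logical `defined_mask` (a subset of the gradient
#'   field's `valid_mask`).
#' @export
normal_flow <- function(field, v_max = 3) {
  stopifnot(inherits(field, "gradient_field"))
  denom <- field$gx^2 + field$gy^2
  vx <- -field$gt * field$gx / denom
  vy <- -field$gt * field$gy / denom
  defined <- field$valid_mask & is.finite(vx) & is.finite(vy)
  speed2 <- vx^2 + vy^2
  defined <- defined & (speed2 <= v_max^2)
  vx[!defined] <- NA_real_
  vy[!defined] <- NA_real_
  structure(list(vx = vx, vy = vy, defined_mask = defined,
                 frame_index = field$frame_index),
            class = "normal_flow_field")
}

#' Sample a gradient field at continuous positions
#'
#' Bilinear interpolation of all three gradient components, the subpixel
#' sampling mode used when vectors are matched at implied positions.
#'
#' @param field A `gradient_field`.
#' @param x,y Positions in pixel units (0-based, x along columns).
#' @param mode `"bilinear"` (default) or `"nearest"` (for oracle
#'   cross-checks).
#' @return A list of vectors `gx`, `gy`, `gt`; `NA` outside the frame.
#' @export
sample_gradient <- function(field, x, y, mode = c("bilinear", "nearest")) {
  mode <- match.arg(mode)
  if (mode == "nearest") {
    h <- nrow(field$gx); w <- ncol(field$gx)
    xi <- round(x); yi <- round(y)
    ok <- xi >= 0 & xi <= w - 1 & yi >= 0 & yi <= h - 1
    pick <- function(m) {
      out <- rep(NA_real_, length(x))
      out[ok] <- m[cbind(yi[ok] + 1, xi[ok] + 1)]
      out
    }
    return(list(gx = pick(field$gx), gy = pick(field$gy), gt = pick(field$gt)))
  }
  list(gx = bilinear_sample(field$gx, x, y),
       gy = bilinear_sample(field$gy, x, y),
       gt = bilinear_sample(field$gt, x, y))
}
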