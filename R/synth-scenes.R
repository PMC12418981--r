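#' Ground-truth scene container
#'
#' Bundles a rendered [frame_stack()] with the per-pixel true velocity of
#' every frame transition, as produced by the scene generators. The truth
#' is what flow extraction is scored against.
#'
#' @param stack A grayscale [frame_stack()] of `T` frames.
#' @param velocity Numeric array `H x W x 2 x (T-1)`; `velocity[, , 1, t]`
#'   is vx and `velocity[, , 2, t]` vy (px/frame) for transition `t`.
#' @param kind Tag: `"translate"`, `"rotate"`, `"grating"` or `"fluid"`.
#' @param params List of generator parameters (including any seed).
#' @return An object of class `ground_truth_scene`.
#' @export
ground_truth_scene <- function(stack, velocity, kind, params = list()) {
  d <- dim(stack); T_ <- n_frames(stack)
  stopifnot(identical(dim(velocity), c(d[1], d[2], 2L, T_ - 1L)))
  structure(list(stack = stack, velocity = velocity, kind = kind,
                 params = params),
            class = "ground_truth_scene")
}

#' @export
print.ground_truth_scene <- function(x, ...) {
  sp <- sqrt(x$velocity[, , 1, ]^2 + x$velocity[, , 2, ]^2)
  cat(sprintf("<ground_truth_scene> kind=%s, %d frames, mean speed %.3f px/frame\n",
              x$kind, n_frames(x$stack), mean(sp)))
  invisible(x)
}

#' Random smooth texture
#'
#' Gaussian-filtered white noise on a periodic domain, min-max normalized
#' to `[0, 1]`. `correlation_length` is the Gaussian sigma in pixels; 0
#' gives raw white noise.
#'
#' @param H,W Size in pixels.
#' @param correlation_length Smoothing sigma (px, `>= 0`).
#' @param rng_seed Integer seed; same seed, same texture.
#' @return `H x W` numeric matrix.
#' @export
make_texture <- function(H, W, correlation_length = 2, rng_seed = 1L) {
  stopifnot(correlation_length >= 0)
  z <- with_seed(rng_seed, matrix(stats::rnorm(H * W), H, W))
  z <- gauss_filter_periodic(z, correlation_length)
  (z - min(z)) / (max(z) - min(z))
}

# Subpixel shift of a periodic image by (sx, sy) px via the Fourier shift
# theorem; exact circular roll for integer shifts.
fourier_shift <- function(m, sx, sy) {
  h <- nrow(m); w <- ncol(m)
  ky <- (((0:(h - 1)) + floor(h / 2)) %% h) - floor(h / 2)
  kx <- (((0:(w - 1)) + floor(w / 2)) %% w) - floor(w / 2)
  phase <- exp(-2i * pi * (outer(ky * sy / h, kx * sx / w, "+")))
  Re(stats::fft(stats::fft(m) * phase, inverse = TRUE)) / (h * w)
}

# Backtrace warp: out(p) = frame(p - v(p)); wrap-around or zero fill.
warp_frame <- function(frame, vx, vy, wrap = TRUE) {
  h <- nrow(frame); w <- ncol(frame)
  xs <- matrix(rep(0:(w - 1), each = h), h, w)
  ys <- matrix(rep(0:(h - 1), w), h, w)
  px <- xs - vx; py <- ys - vy
  if (wrap) {
    matrix(bilinear_sample_wrap(frame, px, py), h, w)
  } else {
    out <- bilinear_sample(frame, px, py)
    out[is.na(out)] <- 0
    matrix(out, h, w)
  }
}

#' Rigid-translation scene
#'
#' Frames are subpixel Fourier-shifted, wrap-around copies of `texture`;
#' the true velocity field is constant.
#'
#' @param texture `H x W` matrix (e.g. from [make_texture()]).
#' @param v Length-2 `(vx, vy)` in px/frame, magnitude at most 3.
#' @param T Number of frames.
#' @param frame_rate Frames per second (metadata).
#' @return A [ground_truth_scene()].
#' @export
translate_scene <- function(texture, v, T, frame_rate = 30) {
  stopifnot(sqrt(sum(v^2)) <= 3, T >= 2)
  h <- nrow(texture); w <- ncol(texture)
  arr <- array(0, c(h, w, T))
  for (t in seq_len(T)) {
    arr[, , t] <- if (t == 1) texture else
      fourier_shift(texture, v[1] * (t - 1), v[2] * (t - 1))
  }
  vel <- array(0, c(h, w, 2L, T - 1L))
  vel[, , 1, ] <- v[1]; vel[, , 2, ] <- v[2]
  ground_truth_scene(frame_stack(arr, frame_rate, "translate_scene"),
                     vel, "translate", list(v = v))
}

#' Rigid-rotation scene
#'
#' Frames are rotated about the frame centre by `omega` radians per frame
#' (bilinear resampling, zero fill outside); the stored truth is the exact
#' per-transition displacement `(R(omega) - I) (p - c)`, tangential with
#' speed `omega * r` to first order.
#'
#' @param texture `H x W` matrix.
#' @param omega Radians/frame; keep the rim speed at or below 3 px/frame.
#' @param T Number of frames.
#' @param frame_rate Frames per second (metadata).
#' @return A [ground_truth_scene()].
#' @export
rotate_scene <- function(texture, omega, T, frame_rate = 30) {
  h <- nrow(texture); w <- ncol(texture)
  cx <- (w - 1) / 2; cy <- (h - 1) / 2
  stopifnot(abs(omega) * sqrt(cx^2 + cy^2) <= 3, T >= 2)
  xs <- matrix(rep(0:(w - 1), each = h), h, w) - cx
  ys <- matrix(rep(0:(h - 1), w), h, w) - cy
  arr <- array(0, c(h, w, T))
  for (t in seq_len(T)) {
    th <- -omega * (t - 1)
    sx <- cos(th) * xs - sin(th) * ys + cx
    sy <- sin(th) * xs + cos(th) * ys + cy
    v <- bilinear_sample(texture, sx, sy)
    v[is.na(v)] <- 0
    arr[, , t] <- matrix(v, h, w)
  }
  vel <- array(0, c(h, w, 2L, T - 1L))
  dvx <- (cos(omega) - 1) * xs - sin(omega) * ys
  dvy <- sin(omega) * xs + (cos(omega) - 1) * ys
  for (t in seq_len(T - 1L)) { vel[, , 1, t] <- dvx; vel[, , 2, t] <- dvy }
  ground_truth_scene(frame_stack(arr, frame_rate, "rotate_scene"),
                     vel, "rotate", list(omega = omega))
}

#' Drifting sinusoidal grating (aperture-problem probe)
#'
#' A pure 1-D grating carries motion information only along its gradient
#' axis; the orthogonal component is unobservable by construction, which is
#' what makes this the canonical aperture-problem stimulus.
#'
#' @param H,W Frame size.
#' @param f Spatial frequency in cycles/px, `0 < f < 0.5`.
#' @param orientation Gradient-axis direction in degrees (0 = x-axis).
#' @param speed Drift speed along the gradient axis (px/frame).
#' @param T Number of frames.
#' @param contrast Amplitude around the 0.5 mean.
#' @param frame_rate Frames per second (metadata).
#' @return A [ground_truth_scene()]; the stored truth is the drift velocity
#'   along the gradient axis.
#' @export
grating_scene <- function(H, W, f, orientation = 0, speed = 0.5, T = 10,
                          contrast = 0.4, frame_rate = 30) {
  stopifnot(f > 0, f < 0.5, T >= 2)
  th <- orientation * pi / 180
  xs <- matrix(rep(0:(W - 1), each = H), H, W)
  ys <- matrix(rep(0:(H - 1), W), H, W)
  u <- cos(th) * xs + sin(th) * ys
  arr <- array(0, c(H, W, T))
  for (t in seq_len(T)) {
    arr[, , t] <- 0.5 + contrast * sin(2 * pi * f * (u - speed * (t - 1)))
  }
  vel <- array(0, c(H, W, 2L, T - 1L))
  vel[, , 1, ] <- speed * cos(th); vel[, , 2, ] <- speed * sin(th)
  ground_truth_scene(frame_stack(arr, frame_rate, "grating_scene"),
                     vel, "grating",
                     list(f = f, orientation = orientation, speed = speed))
}

#' Nonrigid advected-noise "fluid" scene
#'
#' A statistical stand-in for liquid movies of varying viscosity: a scalar
#' stream function per transition is generated as temporally correlated,
#' spatially Gaussian-smoothed noise, and the velocity is its rotated
#' gradient `(d psi/dy, -d psi/dx)` — numerically divergence-free because
#' the periodic central-difference operators commute. A noise texture is
#' advected through this field by semi-Lagrangian backtracing. Larger
#' `smoothness` produces spatially smoother, more slowly varying flow and
#' stands in (rank-order only) for higher viscosity.
#'
#' @param H,W Frame size.
#' @param T Number of frames.
#' @param smoothness Spatial Gaussian scale of the stream function (px,
#'   `> 0`); the viscosity proxy.
#' @param speed_scale Mean speed of the generated field (px/frame).
#' @param rng_seed Integer seed; scenes are deterministic under it.
#' @param temporal_rho AR(1) coefficient of the stream function across
#'   transitions (0 = independent fields, 1 = frozen field).
#' @param texture_corr Correlation length (px) of the advected texture.
#' @param frame_rate Frames per second (metadata).
#' @return A [ground_truth_scene()].
#' @export
fluid_scene <- function(H, W, T, smoothness = 10, speed_scale = 1,
                        rng_seed = 1L, temporal_rho = 0.9,
                        texture_corr = 2, frame_rate = 30) {
  stopifnot(smoothness > 0, T >= 2, speed_scale > 0)
  seeds <- derive_seeds(rng_seed, T)
  psi <- vector("list", T - 1L)
  prev <- NULL
  for (t in seq_len(T - 1L)) {
    z <- with_seed(seeds[t], matrix(stats::rnorm(H * W), H, W))
    z <- gauss_filter_periodic(z, smoothness)
    z <- z / stats::sd(z)
    psi[[t]] <- if (is.null(prev)) z else
      temporal_rho * prev + sqrt(1 - temporal_rho^2) * z
    prev <- psi[[t]]
  }
  vel <- array(0, c(H, W, 2L, T - 1L))
  for (t in seq_len(T - 1L)) {
    vel[, , 1, t] <- diff_y_periodic(psi[[t]])
    vel[, , 2, t] <- -diff_x_periodic(psi[[t]])
  }
  sp <- sqrt(vel[, , 1, ]^2 + vel[, , 2, ]^2)
  vel <- vel * (speed_scale / mean(sp))
  tex <- make_texture(H, W, texture_corr, rng_seed = seeds[T])
  arr <- array(0, c(H, W, T))
  arr[, , 1] <- tex
  for (t in seq_len(T - 1L)) {
    arr[, , t + 1] <- warp_frame(arr[, , t], vel[, , 1, t], vel[, , 2, t],
                                 wrap = TRUE)
  }
  ground_truth_scene(frame_stack(arr, frame_rate, "fluid_scene"),
                     vel, "fluid",
                     list(smoothness = smoothness,
                          speed_scale = speed_scale,
                          temporal_rho = temporal_rho,
                          rng_seed = rng_seed))
}

#' Discrete divergence of a scene's velocity field
#'
#' Periodic central differences, matching the operators used to build the
#' fluid field; for stream-function-derived fields the result is zero to
#' numerical precision.
#'
#' @param scene A [ground_truth_scene()].
#' @param t Transition index.
#' @return `H x W` matrix of divergence values (1/frame).
#' @export
velocity_divergence <- function(scene, t) {
  diff_x_periodic(scene$velocity[, , 1, t]) +
    diff_y_periodic(scene$velocity[, , 2, t])
}

#' Sample a scene's true velocity at continuous positions
#'
#' @param scene A [ground_truth_scene()].
#' @param x,y Positions (0-based px).
#' @param t Transition index.
#' @return List of vectors `vx`, `vy` (bilinear samples; `NA` outside).
#' @export
sample_velocity <- function(scene, x, y, t) {
  list(vx = bilinear_sample(scene$velocity[, , 1, t], x, y),
       vy = bilinear_sample(scene$velocity[, , 2, t], x, y))
}
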