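#' Evaluate code with a temporary RNG seed
#'
#' Runs `code` under `set.seed(seed)` and restores the caller's RNG state
#' afterwards, so that seeded package internals never disturb the global
#' random stream.
#'
#' @param seed Integer seed, or `NULL` to leave the RNG untouched.
#' @param code Expression to evaluate.
#' @return The value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  if (is.null(seed)) return(code)
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  code
}

#' Draw reproducible sub-seeds from a master seed
#'
#' @param seed Master seed.
#' @param n Number of sub-seeds.
#' @return Integer vector of `n` seeds, each below 2^31.
#' @keywords internal
derive_seeds <- function(seed, n) {
  with_seed(seed, sample.int(.Machine$integer.max, n))
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

#' Reflect-pad a matrix by `k` pixels on each side
#' @keywords internal
pad_reflect <- function(m, k = 1L) {
  h <- nrow(m); w <- ncol(m)
  stopifnot(h > k, w > k)
  ri <- c((k + 1):2, 1:h, (h - 1):(h - k))
  ci <- c((k + 1):2, 1:w, (w - 1):(w - k))
  m[ri, ci]
}

#' 3x3 uniform (box) blur with reflective boundary handling
#'
#' Each output pixel is the mean of the 3x3 neighbourhood of the input,
#' with the image reflected at its borders so the output keeps the input
#' size and constant images are preserved exactly.
#'
#' @param m Numeric matrix.
#' @return Blurred matrix of the same dimensions.
#' @keywords internal
box_blur3 <- function(m) {
  p <- pad_reflect(m, 1L)
  h <- nrow(m); w <- ncol(m)
  acc <- matrix(0, h, w)
  for (dy in 0:2) for (dx in 0:2) {
    acc <- acc + p[dy + seq_len(h), dx + seq_len(w)]
  }
  acc / 9
}

#' Separable Gaussian filter on a periodic (wrap-around) domain
#'
#' @param m Numeric matrix.
#' @param sigma Standard deviation in pixels; 0 returns `m` unchanged.
#' @return Filtered matrix.
#' @keywords internal
gauss_filter_periodic <- function(m, sigma) {
  if (sigma <= 0) return(m)
  r <- max(1L, ceiling(3 * sigma))
  k <- exp(-(seq(-r, r))^2 / (2 * sigma^2))
  k <- k / sum(k)
  conv1 <- function(mat, along_rows) {
    n <- if (along_rows) nrow(mat) else ncol(mat)
    out <- 0 * mat
    for (j in seq_along(k)) {
      off <- j - r - 1L
      idx <- ((seq_len(n) - 1L + off) %% n) + 1L
      out <- out + k[j] * (if (along_rows) mat[idx, , drop = FALSE]
                           else mat[, idx, drop = FALSE])
    }
    out
  }
  conv1(conv1(m, TRUE), FALSE)
}

#' Bilinear sampling of a matrix at continuous positions
#'
#' Coordinates follow the package convention: x runs along columns, y along
#' rows, and the origin (0, 0) is the centre of the top-left pixel. Positions
#' outside `[0, W-1] x [0, H-1]` yield `NA`.
#'
#' @param m Numeric matrix (H x W).
#' @param x,y Numeric vectors of positions (0-based pixel units).
#' @return Numeric vector of sampled values.
#' @keywords internal
bilinear_sample <- function(m, x, y) {
  h <- nrow(m); w <- ncol(m)
  out <- rep(NA_real_, length(x))
  ok <- is.finite(x) & is.finite(y) & x >= 0 & x <= w - 1 & y >= 0 & y <= h - 1
  if (!any(ok)) return(out)
  xs <- x[ok]; ys <- y[ok]
  x0 <- pmin(floor(xs), w - 2); y0 <- pmin(floor(ys), h - 2)
  fx <- xs - x0; fy <- ys - y0
  i00 <- (x0) * h + y0 + 1
  v00 <- m[i00];         v01 <- m[i00 + h]
  v10 <- m[i00 + 1];     v11 <- m[i00 + h + 1]
  out[ok] <- (1 - fx) * (1 - fy) * v00 + fx * (1 - fy) * v01 +
    (1 - fx) * fy * v10 + fx * fy * v11
  out
}

#' Bilinear sampling on a periodic domain (positions wrap around)
#' @keywords internal
bilinear_sample_wrap <- function(m, x, y) {
  h <- nrow(m); w <- ncol(m)
  x <- x %% w; y <- y %% h
  x0 <- floor(x); y0 <- floor(y)
  fx <- x - x0; fy <- y - y0
  x1 <- (x0 + 1) %% w; y1 <- (y0 + 1) %% h
  idx <- function(xx, yy) xx * h + yy + 1
  (1 - fx) * (1 - fy) * m[idx(x0, y0)] + fx * (1 - fy) * m[idx(x1, y0)] +
    (1 - fx) * fy * m[idx(x0, y1)] + fx * fy * m[idx(x1, y1)]
}

#' Central difference along x (columns) with one-sided borders
#' @keywords internal
diff_x <- function(m) {
  w <- ncol(m)
  out <- m
  if (w < 2) stop("need at least 2 columns")
  out[, 2:(w - 1)] <- (m[, 3:w] - m[, 1:(w - 2)]) / 2
  out[, 1] <- m[, 2] - m[, 1]
  out[, w] <- m[, w] - m[, w - 1]
  out
}

#' Central difference along y (rows) with one-sided borders
#' @keywords internal
diff_y <- function(m) t(diff_x(t(m)))

#' Central differences on a periodic domain
#' @keywords internal
diff_x_periodic <- function(m) {
  w <- ncol(m)
  (m[, c(2:w, 1), drop = FALSE] - m[, c(w, 1:(w - 1)), drop = FALSE]) / 2
}

#' @rdname diff_x_periodic
#' @keywords internal
diff_y_periodic <- function(m) {
  h <- nrow(m)
  (m[c(2:h, 1), , drop = FALSE] - m[c(h, 1:(h - 1)), , drop = FALSE]) / 2
}
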