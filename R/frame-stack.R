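#' Create a frame stack
#'
#' A frame stack is the package's universal video currency: an ordered set of
#' frames with intensities in a nominal `[0, 1]` range. Grayscale stacks are
#' stored as an `H x W x T` array, colour stacks (only ever produced by
#' [read_movie()] with `as_gray = FALSE`) as `H x W x 3 x T`. All motion
#' operations require grayscale input with at least two frames.
#'
#' @param frames Numeric array, `H x W x T` (grayscale) or `H x W x 3 x T`
#'   (colour). A single matrix is treated as one frame.
#' @param frame_rate Frames per second (metadata only).
#' @param provenance Free-text description of where the frames came from.
#' @return An object of class `frame_stack`.
#' @export
#' @examples
#' fs <- frame_stack(array(runif(8 * 8 * 3), c(8, 8, 3)))
#' n_frames(fs)
frame_stack <- function(frames, frame_rate = 30, provenance = "") {
  if (is.matrix(frames)) frames <- array(frames, c(dim(frames), 1L))
  d <- dim(frames)
  if (!(length(d) %in% c(3L, 4L))) {
    stop("`frames` must be an H x W x T or H x W x 3 x T array")
  }
  if (length(d) == 4L && d[3] != 3L) {
    stop("colour stacks must have exactly 3 channels")
  }
  if (d[1] < 3 || d[2] < 3) stop("frames must be at least 3 x 3 pixels")
  if (!all(is.finite(frames))) stop("all intensities must be finite")
  structure(frames,
            frame_rate = frame_rate,
            provenance = provenance,
            class = "frame_stack")
}

#' @export
print.frame_stack <- function(x, ...) {
  d <- dim(x)
  gray <- length(d) == 3L
  cat(sprintf("<frame_stack> %d frame(s), %d x %d px, %s, %.3g fps\n",
              if (gray) d[3] else d[4], d[1], d[2],
              if (gray) "grayscale" else "colour",
              attr(x, "frame_rate")))
  prov <- attr(x, "provenance")
  if (nzchar(prov)) cat("  provenance:", prov, "\n")
  invisible(x)
}

#' Number of frames in a stack
#' @param stack A [frame_stack()].
#' @return Integer frame count.
#' @export
n_frames <- function(stack) {
  d <- dim(stack)
  if (length(d) == 3L) d[3] else d[4]
}

#' Is the stack grayscale?
#' @param stack A [frame_stack()].
#' @return Logical.
#' @export
is_gray <- function(stack) length(dim(stack)) == 3L

#' Extract one frame as a matrix
#' @param stack A [frame_stack()].
#' @param t Frame index (1-based).
#' @return `H x W` matrix (grayscale) or `H x W x 3` array (colour).
#' @export
get_frame <- function(stack, t) {
  T_ <- n_frames(stack)
  if (t < 1 || t > T_) stop("frame index out of range")
  if (is_gray(stack)) stack[, , t] else stack[, , , t]
}

assert_gray_stack <- function(stack, min_frames = 2L) {
  if (!inherits(stack, "frame_stack")) stop("expected a frame_stack")
  if (!is_gray(stack)) stop("operation requires a grayscale stack; run decolorize_and_blur() first")
  if (n_frames(stack) < min_frames) {
    stop(sprintf("need at least %d frames", min_frames))
  }
  invisible(stack)
}
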