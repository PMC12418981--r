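#' Read a movie from a numbered image-sequence directory
#'
#' Frames are read in lexicographic filename order from a directory of PNG
#' or TIFF images (the lossless path used throughout stimulus preparation
#' and testing). Intensities are rescaled to `[0, 1]`; colour input is
#' collapsed to luminance with Rec.601 weights (0.299, 0.587, 0.114) when
#' `as_gray = TRUE`.
#'
#' @param path Directory containing numbered image frames.
#' @param as_gray Collapse colour frames to luminance? Default `TRUE`.
#' @param frame_rate Frames per second recorded in the result.
#' @return A [frame_stack()].
#' @export
read_movie <- function(path, as_gray = TRUE, frame_rate = 30) {
  if (!dir.exists(path)) {
    stop("cannot read movie: '", path, "' is not a readable directory ",
         "(container formats are not supported; supply an image sequence)")
  }
  files <- sort(list.files(path, pattern = "\\.(png|tif|tiff)$",
                           ignore.case = TRUE, full.names = TRUE))
  if (length(files) == 0) stop("no image frames found in '", path, "'")
  if (length(files) < 2) stop("a movie needs at least 2 frames, found 1")
  frames <- lapply(files, read_image_file)
  dims <- vapply(frames, function(f) dim(f)[1:2], integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1])) {
    stop("mixed frame sizes in '", path, "'")
  }
  has_color <- vapply(frames, function(f) length(dim(f)) == 3L, logical(1))
  if (as_gray) {
    frames <- lapply(frames, to_luminance)
    arr <- array(unlist(frames), c(dim(frames[[1]]), length(frames)))
  } else if (any(has_color)) {
    frames <- lapply(frames, function(f) {
      if (length(dim(f)) == 2L) array(rep(f, 3), c(dim(f), 3L)) else f[, , 1:3]
    })
    arr <- array(unlist(frames), c(dim(frames[[1]]), length(frames)))
  } else {
    arr <- array(unlist(frames), c(dim(frames[[1]]), length(frames)))
  }
  frame_stack(arr, frame_rate = frame_rate, provenance = path)
}

read_image_file <- function(f) {
  ext <- tolower(tools::file_ext(f))
  img <- if (ext == "png") {
    png::readPNG(f)
  } else if (ext %in% c("tif", "tiff")) {
    if (!requireNamespace("tiff", quietly = TRUE)) {
      stop("reading TIFF frames requires the 'tiff' package")
    }
    tiff::readTIFF(f)
  } else {
    stop("unsupported image format: ", ext)
  }
  if (length(dim(img)) == 3L && dim(img)[3] == 4L) img <- img[, , 1:3]
  img
}

to_luminance <- function(img) {
  if (length(dim(img)) == 2L) return(img)
  0.299 * img[, , 1] + 0.587 * img[, , 2] + 0.114 * img[, , 3]
}

#' Write a movie as a numbered PNG image sequence
#'
#' The image-sequence path is lossless up to 8-bit quantization and is what
#' round-trip tests rely on. Intensities are clipped to `[0, 1]` at the file
#' boundary.
#'
#' @param stack A [frame_stack()] (grayscale or colour).
#' @param path Output directory (created if missing).
#' @return `path`, invisibly.
#' @export
write_movie <- function(stack, path) {
  if (!inherits(stack, "frame_stack")) stop("expected a frame_stack")
  T_ <- n_frames(stack)
  if (T_ < 1) stop("empty stack")
  ok <- dir.exists(path) || dir.create(path, recursive = TRUE, showWarnings = FALSE)
  if (!ok) stop("cannot create output directory '", path, "'")
  for (t in seq_len(T_)) {
    f <- file.path(path, sprintf("frame_%05d.png", t))
    res <- try(png::writePNG(clamp(get_frame(stack, t), 0, 1), f), silent = TRUE)
    if (inherits(res, "try-error")) stop("cannot write frame to '", f, "'")
  }
  invisible(path)
}

#' Decolorize and blur a stack (stimulus preprocessing)
#'
#' Collapses colour to Rec.601 luminance and convolves every frame with a
#' 3 x 3 uniform box filter (each weight 1/9), the preprocessing applied to
#' all stimulus movies before motion extraction. Reflective padding keeps
#' the frame size and avoids dark rims that would otherwise seed spurious
#' image gradients.
#'
#' @param stack A [frame_stack()], grayscale or colour.
#' @return A grayscale [frame_stack()] of the same height, width and length.
#' @export
#' @examples
#' fs <- frame_stack(array(0.5, c(8, 8, 2)))
#' all(decolorize_and_blur(fs) == 0.5)
decolorize_and_blur <- function(stack) {
  if (!inherits(stack, "frame_stack")) stop("expected a frame_stack")
  d <- dim(stack)
  if (d[1] < 3 || d[2] < 3) stop("frames smaller than 3 x 3 cannot be blurred")
  T_ <- n_frames(stack)
  out <- array(0, c(d[1], d[2], T_))
  for (t in seq_len(T_)) {
    fr <- get_frame(stack, t)
    if (length(dim(fr)) == 3L) fr <- to_luminance(fr)
    out[, , t] <- box_blur3(fr)
  }
  frame_stack(out, frame_rate = attr(stack, "frame_rate"),
              provenance = paste0(attr(stack, "provenance"), " [gray+box3]"))
}
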