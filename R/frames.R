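# Frame containers and lossless frame I/O.
#
# Frames are stored as a 4-d numeric array with dimensions H x W x 3 x T
# (rows, columns, colour channel, time). The channel order is explicit
# metadata on the object; the default and only built-in convention is "RGB".
# Pixel values are doubles, nominally in [0, 1]; float frames are the default
# throughout so that sub-quantum colour modulations (e.g. a 1% pulse on a
# skin tone) remain representable before magnification.

#' Construct a frame stack
#'
#' Bundles an `H x W x 3 x T` array of video frames with its frame rate and
#' start time. This is the common currency of the video half of the pipeline:
#' the synthetic generator produces one, the ROI stage crops one, and Eulerian
#' magnification maps one to another of identical shape.
#'
#' @param frames Numeric array with dimensions height x width x 3 x n_frames.
#' @param fps Frame rate in Hz (> 0).
#' @param t0 Time of the first frame in seconds (default 0).
#' @param channels Channel order string; only `"RGB"` is used by the package.
#' @return An object of class `frame_stack` with elements `frames`, `fps`,
#'   `t0`, `channels`.
#' @export
frame_stack <- function(frames, fps, t0 = 0, channels = "RGB") {
  if (!is.array(frames) || length(dim(frames)) != 4L)
    stop("frames must be a 4-d array (H x W x 3 x T)", call. = FALSE)
  d <- dim(frames)
  if (d[3L] != 3L) stop("frames must have 3 colour channels", call. = FALSE)
  if (d[4L] < 1L) stop("frame stack must contain at least one frame", call. = FALSE)
  stop_if_not_scalar_pos(fps, "fps")
  structure(list(frames = frames, fps = fps, t0 = t0, channels = channels),
            class = "frame_stack")
}

#' @export
print.frame_stack <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf("<frame_stack> %d frames, %dx%d px, %g fps (%.1f s), channels %s\n",
              d[4L], d[2L], d[1L], x$fps, d[4L] / x$fps, x$channels))
  invisible(x)
}

#' @export
dim.frame_stack <- function(x) dim(x$frames)

n_frames <- function(stack) dim(stack$frames)[4L]

frame_duration_s <- function(stack) n_frames(stack) / stack$fps

#' Construct a region-of-interest box
#'
#' Coordinates are 0-based with the origin at the top-left pixel; the box is
#' half-open, covering columns `[x, x + w)` and rows `[y, y + h)`. Stating the
#' convention explicitly avoids off-by-one drift between detection, cropping
#' and the synthetic generator.
#'
#' @param x,y Top-left corner (0-based pixels; `x` runs along columns).
#' @param w,h Width and height in pixels (> 0).
#' @return An object of class `roi_box`.
#' @export
roi_box <- function(x, y, w, h) {
  vals <- c(x = x, y = y, w = w, h = h)
  if (any(!is.finite(vals))) stop("roi_box coordinates must be finite", call. = FALSE)
  if (w <= 0 || h <= 0) stop("roi_box width and height must be positive", call. = FALSE)
  structure(as.list(round(vals)), class = "roi_box")
}

#' @export
print.roi_box <- function(x, ...) {
  cat(sprintf("<roi_box> x=%d y=%d w=%d h=%d\n", x$x, x$y, x$w, x$h))
  invisible(x)
}

roi_inside_frame <- function(roi, height, width) {
  roi$x >= 0 && roi$y >= 0 && roi$x + roi$w <= width && roi$y + roi$h <= height
}

# 1-based row/column index vectors covered by a roi_box.
roi_rows <- function(roi) (roi$y + 1L):(roi$y + roi$h)
roi_cols <- function(roi) (roi$x + 1L):(roi$x + roi$w)

#' Write a frame stack to a directory of PNG images
#'
#' One 8-bit PNG per frame, named `frame_000001.png`, ... in temporal order.
#' Values are clipped to `[0, 1]` and quantized to 8 bits; a stack whose
#' values are already multiples of 1/255 round-trips exactly through
#' [load_frames()].
#'
#' @param stack A [frame_stack()].
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_frames <- function(stack, dir) {
  stopifnot(inherits(stack, "frame_stack"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  nt <- n_frames(stack)
  for (t in seq_len(nt)) {
    png::writePNG(clamp01(stack$frames[, , , t]),
                  file.path(dir, sprintf("frame_%06d.png", t)))
  }
  invisible(dir)
}

#' Load a frame stack from a directory of images
#'
#' Reads every `.png` file in `path` in lexicographic order. All frames must
#' share the same size; grayscale images are expanded to three equal channels.
#'
#' @param path Directory containing the image sequence.
#' @param fps Frame rate in Hz to attach to the stack.
#' @param t0 Start time in seconds.
#' @return A [frame_stack()].
#' @export
load_frames <- function(path, fps, t0 = 0) {
  if (!dir.exists(path)) stop(sprintf("'%s' is not a directory", path), call. = FALSE)
  files <- sort(list.files(path, pattern = "\\.png$", full.names = TRUE))
  if (length(files) == 0L) stop("no frames found: directory contains no .png files", call. = FALSE)
  imgs <- lapply(files, png::readPNG)
  imgs <- lapply(imgs, function(im) {
    if (length(dim(im)) == 2L) im <- array(rep(im, 3L), dim = c(dim(im), 3L))
    if (dim(im)[3L] > 3L) im <- im[, , 1:3, drop = FALSE]  # drop alpha
    im
  })
  sizes <- vapply(imgs, function(im) dim(im)[1:2], integer(2L))
  if (any(sizes[1L, ] != sizes[1L, 1L]) || any(sizes[2L, ] != sizes[2L, 1L]))
    stop("mixed frame sizes in image sequence", call. = FALSE)
  h <- sizes[1L, 1L]; w <- sizes[2L, 1L]; nt <- length(imgs)
  arr <- array(0, dim = c(h, w, 3L, nt))
  for (t in seq_len(nt)) arr[, , , t] <- imgs[[t]]
  frame_stack(arr, fps = fps, t0 = t0)
}
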