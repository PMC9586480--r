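#' Fluorescence image stack
#'
#' Container for a time-ordered set of 2D grayscale fluorescence frames with
#' physical calibration: pixel size in micrometres per pixel and frame
#' interval in seconds. Frames are stored as a numeric array indexed
#' `[y, x, frame]` (image origin top-left, x rightwards, y downwards,
#' 0-based pixel centres for all geometry).
#'
#' @param data numeric array `[height, width, n_frames]` (a matrix is treated
#'   as a single frame).
#' @param pixel_size micrometres per pixel, > 0.
#' @param frame_interval seconds between frames, > 0.
#' @param t_start acquisition time of the first frame (s), default 0.
#' @return an object of class `image_stack`.
#' @export
image_stack <- function(data, pixel_size, frame_interval, t_start = 0) {
  if (is.matrix(data)) data <- array(data, dim = c(dim(data), 1L))
  if (!is.array(data) || length(dim(data)) != 3L || !is.numeric(data)) {
    stop("data must be a numeric [height, width, frame] array")
  }
  assert_scalar_pos(pixel_size, "pixel_size")
  assert_scalar_pos(frame_interval, "frame_interval")
  structure(
    list(data = data, pixel_size = pixel_size,
         frame_interval = frame_interval, t_start = t_start),
    class = "image_stack")
}

#' @export
dim.image_stack <- function(x) dim(x$data)

#' Number of frames in a stack
#' @param stack an `image_stack`.
#' @export
n_frames <- function(stack) dim(stack$data)[3L]

#' Frame acquisition times (s)
#' @param stack an `image_stack`.
#' @export
frame_times <- function(stack) {
  stack$t_start + (seq_len(n_frames(stack)) - 1L) * stack$frame_interval
}

#' @export
print.image_stack <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf(
    "<image_stack> %d x %d px, %d frame(s), %.3g um/px, dt = %.3g s\n",
    d[2], d[1], d[3], x$pixel_size, x$frame_interval))
  invisible(x)
}
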