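#' Frame stack container
#'
#' A `frame_stack` holds a T x rows x cols intensity movie in digital units
#' together with its frame rate. Frame k (0-based) is timestamped
#' `origin + k / fps` seconds.
#'
#' @param data Numeric array, `c(T, rows, cols)`, non-negative.
#' @param fps Frames per second (> 0).
#' @param origin Acquisition start time in seconds.
#' @return An object of class `frame_stack`.
#' @export
frame_stack <- function(data, fps = 10, origin = 0) {
  if (length(dim(data)) != 3L)
    stop("data must be a T x rows x cols array", call. = FALSE)
  if (dim(data)[1] < 1L) stop("stack needs at least one frame", call. = FALSE)
  if (fps <= 0) stop("fps must be > 0", call. = FALSE)
  if (min(data) < 0) stop("intensities must be >= 0", call. = FALSE)
  structure(list(data = data, fps = fps, origin = origin),
            class = "frame_stack")
}

#' @export
print.frame_stack <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("Frame stack: %d frames of %d x %d px @ %g fps (%.1f s)\n",
              d[1], d[2], d[3], x$fps, d[1] / x$fps))
  cat(sprintf("  intensity range [%.1f, %.1f] DU, origin %g s\n",
              min(x$data), max(x$data), x$origin))
  invisible(x)
}

#' @export
dim.frame_stack <- function(x) dim(x$data)

n_frames <- function(stack) dim(stack$data)[1]

#' Frame timestamps of a stack
#' @param stack A [frame_stack()].
#' @return Numeric vector of per-frame times in seconds.
#' @export
frame_times <- function(stack) {
  stack$origin + (seq_len(n_frames(stack)) - 1) / stack$fps
}
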