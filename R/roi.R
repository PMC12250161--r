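#' Region-of-interest specification
#'
#' 0-based, row-major pixel coordinates; the ROI is the half-open box
#' `[row0, row0 + height) x [col0, col0 + width)`. The default 10 x 10 size
#' matches the analysis convention for this sensor.
#'
#' @param row0,col0 Top-left pixel (0-based).
#' @param height,width ROI extent in pixels.
#' @return An object of class `roi_spec`.
#' @export
roi_spec <- function(row0, col0, height = 10L, width = 10L) {
  if (row0 < 0 || col0 < 0 || height < 1 || width < 1)
    stop("ROI coordinates must be non-negative and dims >= 1", call. = FALSE)
  structure(list(row0 = as.integer(row0), col0 = as.integer(col0),
                 height = as.integer(height), width = as.integer(width)),
            class = "roi_spec")
}

#' @export
print.roi_spec <- function(x, ...) {
  cat(sprintf("ROI: %d x %d px at (row %d, col %d) [0-based]\n",
              x$height, x$width, x$row0, x$col0))
  invisible(x)
}

check_roi <- function(roi, stack) {
  d <- dim(stack$data)
  if (roi$row0 + roi$height > d[2] || roi$col0 + roi$width > d[3])
    stop(sprintf("ROI %dx%d at (%d,%d) exceeds the %d x %d frame",
                 roi$height, roi$width, roi$row0, roi$col0, d[2], d[3]),
         call. = FALSE)
  invisible(roi)
}

#' Automatic ROI selection by fluorescence strength
#'
#' Surrogate for hand selection: among all valid positions, returns the ROI
#' whose time-averaged mean intensity is maximal. Ties (within a 1e-9
#' relative band, so numerically equal regions compare as equal) are broken
#' by the lexicographically smallest `(row0, col0)`. The search uses an
#' integral image over the temporal-mean frame, so it is exact and fast for
#' any frame size.
#'
#' @param stack A [frame_stack()].
#' @param height,width ROI dimensions in pixels (default 10 x 10).
#' @return A [roi_spec()].
#' @export
auto_select_roi <- function(stack, height = 10L, width = 10L) {
  d <- dim(stack$data)
  if (height > d[2] || width > d[3])
    stop(sprintf("ROI %dx%d larger than the %d x %d frame",
                 height, width, d[2], d[3]), call. = FALSE)
  flat <- stack$data
  dim(flat) <- c(d[1], d[2] * d[3])
  pixmean <- matrix(colMeans(flat), d[2], d[3])
  # integral image with zero-padded first row/col
  ii <- matrix(0, d[2] + 1, d[3] + 1)
  ii[-1, -1] <- t(apply(apply(pixmean, 2, cumsum), 1, cumsum))
  n_r <- d[2] - height + 1L
  n_c <- d[3] - width + 1L
  sums <- matrix(0, n_r, n_c)
  for (j in seq_len(n_c)) {
    c0 <- j; c1 <- j + width
    sums[, j] <- ii[(height + 1):(d[2] + 1), c1] - ii[1:n_r, c1] -
      ii[(height + 1):(d[2] + 1), c0] + ii[1:n_r, c0]
  }
  m <- max(sums)
  cand <- which(sums >= m - 1e-9 * abs(m), arr.ind = TRUE)
  cand <- cand[order(cand[, 1], cand[, 2]), , drop = FALSE]
  roi_spec(cand[1, 1] - 1L, cand[1, 2] - 1L, height, width)
}

#' Reduce a stack to a single ROI-mean fluorescence trace
#'
#' `values[k]` is the unweighted arithmetic mean of the ROI pixels of frame
#' k. Because dF/F0 is scale-free, mean versus sum inside the ROI does not
#' affect any downstream normalized quantity.
#'
#' @param stack A [frame_stack()].
#' @param roi A [roi_spec()] lying fully inside the frame.
#' @return A list of class `trace` with `values`, `fps`, `origin`, `roi`.
#' @export
extract_trace <- function(stack, roi) {
  check_roi(roi, stack)
  rows <- roi$row0 + seq_len(roi$height)
  cols <- roi$col0 + seq_len(roi$width)
  sub <- stack$data[, rows, cols, drop = FALSE]
  dim(sub) <- c(dim(stack$data)[1], roi$height * roi$width)
  structure(list(values = rowMeans(sub), fps = stack$fps,
                 origin = stack$origin, roi = roi),
            class = "trace")
}

#' @export
print.trace <- function(x, ...) {
  cat(sprintf("Fluorescence trace: %d frames @ %g fps (%.1f s), mean %.1f DU\n",
              length(x$values), x$fps, length(x$values) / x$fps,
              mean(x$values)))
  invisible(x)
}
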