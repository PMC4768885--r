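#' Build a static-scene background model from a window of frames
#'
#' Computes the pixel-wise weighted mean of the first `window` frames of a
#' stack. The `linear` scheme weights frames proportionally to their position
#' in the window (1 for the earliest, `window` for the latest), so the model
#' tracks slow illumination drift; the `uniform` scheme is the plain
#' arithmetic mean. Weights are normalized to sum to one, so the background
#' intensity at each pixel always lies within the range of the contributing
#' frames.
#'
#' @param stack A [trapcam_stack()] or a `height x width x n` array.
#' @param window Number of frames averaged (default 50).
#' @param scheme `"linear"` (default) or `"uniform"`.
#' @param start Index of the first frame of the window (default 1; a rolling
#'   background is obtained by calling this per frame with varying `start`).
#' @return A numeric matrix of class `background_image` with attributes
#'   `window` and `scheme`.
#' @export
build_background <- function(stack, window = 50L,
                             scheme = c("linear", "uniform"), start = 1L) {
  scheme <- match.arg(scheme)
  frames <- if (inherits(stack, "trapcam_stack")) stack$frames else stack
  stopifnot(is.array(frames), length(dim(frames)) == 3L)
  d <- dim(frames)
  window <- as.integer(window)
  if (window < 1L) stop("window must be >= 1")
  if (start < 1L || start + window - 1L > d[3])
    stop(sprintf("insufficient data: need %d frames from index %d, stack has %d",
                 window, start, d[3]))
  w <- if (scheme == "linear") seq_len(window) else rep(1, window)
  w <- w / sum(w)
  flat <- matrix(frames[, , start:(start + window - 1L)], d[1] * d[2], window)
  bg <- matrix(drop(flat %*% w), d[1], d[2])
  structure(bg, window = window, scheme = scheme, class = "background_image")
}

#' Absolute-difference image of a frame against a background model
#'
#' Pixel-wise `|frame - background|`, clipped to the valid 8-bit intensity
#' range. The absolute value makes segmentation indifferent to whether a fly
#' is darker or lighter than the modelled background.
#'
#' @param frame Numeric matrix, one frame.
#' @param background A [build_background()] result (or any matrix of
#'   matching shape).
#' @param frame_id Optional identifier carried as an attribute.
#' @return Non-negative numeric matrix of class `difference_image`.
#' @export
subtract_background <- function(frame, background, frame_id = NA_integer_) {
  if (!all(dim(frame) == dim(background)))
    stop("shape mismatch between frame and background")
  d <- pmin(abs(unclass(frame) - unclass(background)), 255)
  structure(d, frame_id = frame_id, class = "difference_image")
}
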