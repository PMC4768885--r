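#' Linear rescale of an image to 8-bit
#'
#' Maps the observed intensity range `[min, max]` linearly onto `[0, 255]`
#' and rounds half-up. A constant image has no range and maps to all zeros.
#'
#' @param image Real-valued matrix.
#' @return Matrix of integral values in 0-255.
#' @export
to_8bit <- function(image) {
  image <- unclass(image)
  rng <- range(image)
  if (rng[2] == rng[1]) return(array(0, dim(image)))
  floor(255 * (image - rng[1]) / (rng[2] - rng[1]) + 0.5)
}

#' Otsu threshold of an 8-bit image
#'
#' Exhaustive scan of the 256 candidate thresholds `t`, choosing the one
#' that maximizes the between-class variance of the split
#' `{x < t} | {x >= t}`; ties resolve to the smallest `t`. A degenerate
#' (single-valued) histogram yields threshold 0 with the `degenerate`
#' attribute set.
#'
#' @param image Matrix of integral values in 0-255.
#' @return Integer threshold with attribute `degenerate`.
#' @export
otsu_threshold <- function(image) {
  x <- as.integer(round(unclass(image)))
  if (any(x < 0L | x > 255L)) stop("otsu_threshold expects 8-bit input")
  p <- tabulate(x + 1L, nbins = 256L) / length(x)
  cw <- cumsum(p)
  cm <- cumsum(p * (0:255))
  mu <- cm[256L]
  w0 <- c(0, cw)[1:256]            # P(x < t) for t = 0..255
  m0 <- c(0, cm)[1:256]
  w1 <- 1 - w0
  sb <- numeric(256L)
  ok <- w0 > 0 & w1 > 0
  sb[ok] <- (mu * w0[ok] - m0[ok])^2 / (w0[ok] * w1[ok])
  structure(which.max(sb) - 1L, degenerate = max(sb) <= .Machine$double.eps)
}

#' Threshold segmentation of an 8-bit image
#'
#' Produces the binary mask `image >= threshold`. With `method = "otsu"` the
#' threshold is chosen by [otsu_threshold()]; with `method = "fixed"` it is
#' supplied via `value`. A degenerate (constant) image yields an all-true or
#' all-false mask flagged via the `degenerate` attribute, never an error.
#'
#' @param image Matrix of integral values in 0-255.
#' @param method `"otsu"` (default) or `"fixed"`.
#' @param value Threshold in `[0, 255]`, required iff `method = "fixed"`.
#' @return Logical matrix of class `binary_mask` with attributes
#'   `threshold`, `method`, `degenerate`.
#' @export
threshold_image <- function(image, method = c("otsu", "fixed"), value = NULL) {
  method <- match.arg(method)
  image <- unclass(image)
  degenerate <- FALSE
  if (method == "fixed") {
    if (is.null(value)) stop("method = 'fixed' requires a threshold value")
    if (value < 0 || value > 255) stop("fixed threshold must lie in [0, 255]")
    thr <- value
  } else {
    thr <- otsu_threshold(image)
    degenerate <- attr(thr, "degenerate")
  }
  structure(image >= as.numeric(thr), threshold = as.numeric(thr),
            method = method, degenerate = degenerate, class = "binary_mask")
}

#' Morphological opening followed by closing ("blobbing")
#'
#' Applies a binary opening then a binary closing with a square structuring
#' element of side `2 * radius + 1`, consolidating each insect into a single
#' compact blob (the opening removes sub-element specks, the closing fills
#' pinholes and hairline gaps) so that particle analysis does not overcount.
#' `radius = 0` is the identity.
#'
#' @param mask Logical matrix.
#' @param radius Non-negative integer structuring-element radius (default 1,
#'   i.e. a 3 x 3 square).
#' @return Logical matrix of class `binary_mask`.
#' @export
open_close <- function(mask, radius = 1L) {
  stopifnot(radius >= 0)
  m <- unclass(mask)
  if (radius == 0L)
    return(structure(m, class = "binary_mask"))
  radius <- as.integer(radius)
  k <- EBImage::makeBrush(2L * radius + 1L, shape = "box")
  # pad with background so pixels beyond the frame count as off (plain
  # set-arithmetic semantics, not EBImage's replicated border)
  h <- nrow(m); w <- ncol(m); pad <- 2L * radius
  mp <- matrix(0, h + 2L * pad, w + 2L * pad)
  mp[pad + seq_len(h), pad + seq_len(w)] <- m
  out <- EBImage::imageData(EBImage::closing(EBImage::opening(mp, k), k))
  structure(out[pad + seq_len(h), pad + seq_len(w)] > 0.5,
            class = "binary_mask")
}

#' Label connected components and gate them by area
#'
#' Finds 8-connected foreground components of a binary mask (optionally
#' restricted to a region of interest) and keeps those whose pixel area lies
#' in the closed interval `[min_area, max_area]` -- the particle-analysis
#' gate, defaulting to 150-950 pixels. Coordinates are 0-based, row-major
#' with the origin at the top-left; bounding boxes are half-open.
#'
#' @param mask Logical matrix.
#' @param min_area,max_area Inclusive area gate in pixels (defaults 150,
#'   950).
#' @param roi Optional region of interest: a logical matrix of the same
#'   shape, a length-4 numeric rectangle `c(row0, row1, col0, col1)`
#'   (0-based, half-open), or a polygon as a two-column matrix of
#'   `(row, col)` vertices.
#' @param frame Optional frame identifier copied into each record.
#' @return Data frame of detection records: `frame`, `blob`, `row`, `col`
#'   (centroid), `area`, and half-open bounding box `bb_row0`, `bb_row1`,
#'   `bb_col0`, `bb_col1`.
#' @export
label_and_filter <- function(mask, min_area = 150, max_area = 950,
                             roi = NULL, frame = NA_integer_) {
  if (min_area <= 0 || min_area > max_area)
    stop("need 0 < min_area <= max_area")
  m <- unclass(mask)
  h <- nrow(m); w <- ncol(m)
  if (!is.null(roi)) {
    rmask <- roi_mask(roi, c(h, w))
    if (!any(rmask)) stop("empty region of interest")
    m <- m & rmask
  }
  empty <- data.frame(frame = integer(), blob = integer(), row = numeric(),
                      col = numeric(), area = integer(), bb_row0 = integer(),
                      bb_row1 = integer(), bb_col0 = integer(),
                      bb_col1 = integer())
  if (!any(m)) return(empty)
  lab <- label_components_8(m)
  idx <- which(lab > 0)
  l <- lab[idx]
  r <- (idx - 1L) %% h + 1L
  cl <- (idx - 1L) %/% h + 1L
  areas <- tabulate(l)
  keep <- which(areas >= min_area & areas <= max_area)
  if (length(keep) == 0L) return(empty)
  sel <- l %in% keep
  l <- l[sel]; r <- r[sel]; cl <- cl[sel]
  g <- match(l, keep)
  out <- data.frame(
    frame = frame,
    blob = seq_along(keep),
    row = tapply(r, g, mean) - 1,
    col = tapply(cl, g, mean) - 1,
    area = areas[keep],
    bb_row0 = tapply(r, g, min) - 1L,
    bb_row1 = tapply(r, g, max),
    bb_col0 = tapply(cl, g, min) - 1L,
    bb_col1 = tapply(cl, g, max))
  rownames(out) <- NULL
  out
}

## 8-connected labeling used by label_and_filter: 4-connected bwlabel pass,
## then union-find over labels that touch diagonally, relabelled 1..k in
## first-appearance order.
label_components_8 <- function(m) {
  h <- nrow(m); w <- ncol(m)
  lab <- EBImage::imageData(EBImage::bwlabel(m * 1))
  nlab <- as.integer(max(lab))
  if (nlab <= 1L) return(lab)
  a <- lab[-h, -w]; b <- lab[-1, -1]
  cc <- lab[-1, -w]; d <- lab[-h, -1]
  sel1 <- a > 0 & b > 0 & a != b
  sel2 <- cc > 0 & d > 0 & cc != d
  pairs <- unique(rbind(cbind(a[sel1], b[sel1]), cbind(cc[sel2], d[sel2])))
  parent <- seq_len(nlab)
  find <- function(i) {
    while (parent[i] != i) i <- parent[i]
    i
  }
  if (nrow(pairs) > 0L) {
    for (r in seq_len(nrow(pairs))) {
      ri <- find(pairs[r, 1]); rj <- find(pairs[r, 2])
      if (ri != rj) parent[max(ri, rj)] <- min(ri, rj)
    }
  }
  root <- vapply(seq_len(nlab), find, integer(1))
  newid <- match(root, unique(root))
  map <- c(0L, newid)
  matrix(map[as.integer(lab) + 1L], h, w)
}

#' Run the full detection pipeline over an image stack
#'
#' Per frame: background subtraction against a weighted-average background
#' model, 8-bit conversion, threshold segmentation, binary open/close, and
#' area-gated particle analysis. Returns the per-frame fly count for the
#' stack's surface; individual detection records are attached as the
#' `records` attribute.
#'
#' @param stack A [trapcam_stack()].
#' @param window,scheme Background window and weighting, see
#'   [build_background()].
#' @param method,fixed_value Threshold method, see [threshold_image()].
#' @param radius Structuring-element radius for [open_close()].
#' @param min_area,max_area Particle-analysis area gate.
#' @param roi Optional region of interest (see [label_and_filter()]).
#' @param rolling If `TRUE`, rebuild the background per frame from the most
#'   recent `window` frames ending at that frame (for scenes with strong
#'   drift); default `FALSE` uses the leading window once.
#' @param convert Where the 8-bit conversion is applied: `"difference"`
#'   (default) converts the difference image; `"frames"` converts the raw
#'   frames before the background is built.
#' @return Data frame of class `count_series` with columns `frame`, `time`,
#'   `surface`, `count`, and attribute `records` (all detection records).
#' @export
count_flies <- function(stack, window = 50L, scheme = "linear",
                        method = "otsu", fixed_value = NULL, radius = 1L,
                        min_area = 150, max_area = 950, roi = NULL,
                        rolling = FALSE,
                        convert = c("difference", "frames")) {
  convert <- match.arg(convert)
  stopifnot(inherits(stack, "trapcam_stack"))
  frames <- stack$frames
  n <- dim(frames)[3]
  if (convert == "frames")
    for (t in seq_len(n)) frames[, , t] <- to_8bit(frames[, , t])
  if (!rolling)
    bg <- build_background(frames, window = window, scheme = scheme)
  counts <- integer(n)
  records <- vector("list", n)
  for (t in seq_len(n)) {
    if (rolling) {
      start <- max(1L, t - as.integer(window) + 1L)
      bg <- build_background(frames, window = t - start + 1L,
                             scheme = scheme, start = start)
    }
    d <- subtract_background(frames[, , t], bg, frame_id = t)
    img8 <- if (convert == "difference") to_8bit(d) else round(unclass(d))
    msk <- threshold_image(img8, method = method, value = fixed_value)
    msk <- open_close(msk, radius = radius)
    det <- label_and_filter(msk, min_area = min_area, max_area = max_area,
                            roi = roi, frame = t)
    counts[t] <- nrow(det)
    if (nrow(det) > 0L) records[[t]] <- det
  }
  keep <- !vapply(records, is.null, logical(1))
  recs <- if (any(keep)) do.call(rbind, records[keep]) else
    label_and_filter(matrix(FALSE, 2, 2), 1, 1)
  out <- data.frame(frame = seq_len(n), time = stack$timestamps,
                    surface = stack$surface, count = counts)
  structure(out, records = recs, class = c("count_series", "data.frame"))
}

#' Sum counts across the surfaces of one trap at each time step
#'
#' Combines per-surface count series into per-image-set totals: all
#' simultaneous images of one trap at one time step form an image set, and
#' its count is the sum over surfaces.
#'
#' @param series_list List of `count_series` data frames with identical
#'   frame grids.
#' @return Data frame with columns `frame`, `time`, `count`, `n_surfaces`.
#' @export
image_set_counts <- function(series_list) {
  stopifnot(length(series_list) >= 1L)
  n <- nrow(series_list[[1]])
  for (s in series_list)
    if (nrow(s) != n || any(s$frame != series_list[[1]]$frame))
      stop("count series must share the same frame grid")
  total <- Reduce(`+`, lapply(series_list, function(s) s$count))
  data.frame(frame = series_list[[1]]$frame,
             time = series_list[[1]]$time,
             count = total, n_surfaces = length(series_list))
}
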