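#' Read an image stack from PNG files or a multi-page TIFF
#'
#' Accepts a directory (all PNG/TIFF files inside, lexicographic order), a
#' character vector of files (sorted lexicographically), or a single
#' multi-page TIFF. Frames must share dimensions; color images are reduced
#' to their first channel. Pixel values are returned on the 8-bit scale
#' (0-255), rounded to integers, so a write/read round trip of 8-bit data is
#' bit-identical.
#'
#' @param path Directory, file vector, or single TIFF path.
#' @param interval Seconds between frames (default 6).
#' @param surface Optional surface label.
#' @return A [trapcam_stack()].
#' @export
read_image_stack <- function(path, interval = 6, surface = NA_character_) {
  if (length(path) == 1L && dir.exists(path))
    path <- list.files(path, pattern = "\\.(png|tif|tiff)$",
                       ignore.case = TRUE, full.names = TRUE)
  if (length(path) == 0L) stop("no image files found")
  path <- sort(path)
  read_one <- function(f) {
    ext <- tolower(tools::file_ext(f))
    img <- tryCatch(
      switch(ext,
             png = png::readPNG(f),
             tif = , tiff = tiff::readTIFF(f, all = TRUE),
             stop("unsupported format")),
      error = function(e) stop(sprintf("cannot read '%s': %s", f,
                                       conditionMessage(e)), call. = FALSE))
    if (!is.list(img)) img <- list(img)
    lapply(img, function(m) {
      if (length(dim(m)) == 3L) m <- m[, , 1]
      round(m * 255)
    })
  }
  frames <- unlist(lapply(path, read_one), recursive = FALSE)
  dims <- vapply(frames, dim, integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1]))
    stop("mixed dimensions across frames")
  arr <- array(unlist(frames), c(dims[1, 1], dims[2, 1], length(frames)))
  trapcam_stack(arr, interval = interval, surface = surface)
}

#' Write an image stack as numbered PNGs or one multi-page TIFF
#'
#' @param stack A [trapcam_stack()] with 8-bit-scale intensities.
#' @param path Output directory (`format = "png"`) or file
#'   (`format = "tiff"`).
#' @param format `"png"` (zero-padded numbered frames) or `"tiff"`
#'   (single multi-page file).
#' @param prefix Filename prefix for PNG frames.
#' @return Invisibly, the written path(s).
#' @export
write_image_stack <- function(stack, path, format = c("png", "tiff"),
                              prefix = "frame") {
  format <- match.arg(format)
  stopifnot(inherits(stack, "trapcam_stack"))
  n <- n_frames(stack)
  if (format == "png") {
    dir.create(path, recursive = TRUE, showWarnings = FALSE)
    files <- file.path(path, sprintf("%s_%05d.png", prefix, seq_len(n)))
    for (i in seq_len(n))
      png::writePNG(stack$frames[, , i] / 255, files[i])
    return(invisible(files))
  }
  pages <- lapply(seq_len(n), function(i) stack$frames[, , i] / 255)
  tiff::writeTIFF(pages, path, bits.per.sample = 8L)
  invisible(path)
}

#' Construct/validate a capture table
#'
#' A capture table has one row per replicate date and, for each treatment,
#' columns `<slug>_trapped`, `<slug>_in_tub`, `<slug>_total`; the invariant
#' `total = trapped + in_tub` is enforced.
#'
#' @param df Data frame in the layout above.
#' @return `df` with class `capture_table`.
#' @export
capture_table <- function(df) {
  stopifnot(is.data.frame(df))
  tot_cols <- grep("_total$", names(df), value = TRUE)
  for (tc in tot_cols) {
    slug <- sub("_total$", "", tc)
    trapped <- paste0(slug, "_trapped"); in_tub <- paste0(slug, "_in_tub")
    if (all(c(trapped, in_tub) %in% names(df))) {
      if (any(df[[tc]] != df[[trapped]] + df[[in_tub]]))
        stop(sprintf("capture table invariant violated: %s != %s + %s",
                     tc, trapped, in_tub))
    }
  }
  num <- vapply(df, is.numeric, logical(1))
  if (any(vapply(df[num], function(x) any(x < 0), logical(1))))
    stop("capture counts must be non-negative")
  class(df) <- c("capture_table", "data.frame")
  df
}

#' Read a capture table from CSV
#' @param path CSV file with a header row in the [capture_table()] layout.
#' @return A `capture_table`.
#' @export
read_capture_table <- function(path) {
  capture_table(read.csv(path, check.names = TRUE))
}

#' Write a capture table (or any data frame) to CSV
#' @param x Data frame.
#' @param path Output CSV path.
#' @return Invisibly, `path`.
#' @export
write_table_csv <- function(x, path) {
  write.csv(as.data.frame(x), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a count series from CSV
#' @param path CSV with columns `frame`, `time`, `surface`, `count`.
#' @return A `count_series` data frame.
#' @export
read_count_series <- function(path) {
  x <- read.csv(path)
  stopifnot(all(c("frame", "surface", "count") %in% names(x)))
  if (any(x$count < 0)) stop("counts must be non-negative")
  class(x) <- c("count_series", "data.frame")
  x
}

#' Path to the packaged Jackson-trap capture-count table
#'
#' Seven replicate dates of released counts plus trapped / in-tub / total
#' counts for the TML, TML-DDVP and Control treatments, shipped with the
#' package as a plain CSV.
#'
#' @return File path of the CSV.
#' @export
capture_counts_file <- function() {
  system.file("extdata", "jackson_capture_counts.csv", package = "trapcam",
              mustWork = TRUE)
}

#' Region-of-interest mask
#'
#' Converts an ROI specification into a logical pixel mask. Rectangles are
#' 0-based half-open `c(row0, row1, col0, col1)`; polygons are two-column
#' `(row, col)` vertex matrices in 0-based pixel coordinates, rasterized by
#' the even-odd (ray casting) rule at pixel centers.
#'
#' @param roi Logical matrix, length-4 rectangle, or polygon vertex matrix.
#' @param dim Frame dimensions `c(height, width)`.
#' @return Logical matrix.
#' @export
roi_mask <- function(roi, dim) {
  h <- dim[1]; w <- dim[2]
  if (is.logical(roi)) {
    if (!all(base::dim(roi) == c(h, w))) stop("ROI mask shape mismatch")
    return(roi)
  }
  if (is.numeric(roi) && is.null(base::dim(roi)) && length(roi) == 4L) {
    r0 <- roi[1]; r1 <- roi[2]; c0 <- roi[3]; c1 <- roi[4]
    if (r0 < 0 || c0 < 0 || r1 > h || c1 > w || r0 >= r1 || c0 >= c1)
      stop("ROI rectangle out of frame bounds or empty")
    m <- matrix(FALSE, h, w)
    m[(r0 + 1):r1, (c0 + 1):c1] <- TRUE
    return(m)
  }
  if (is.matrix(roi) && ncol(roi) == 2L && nrow(roi) >= 3L) {
    vy <- roi[, 1]; vx <- roi[, 2]
    if (any(vy < 0) || any(vx < 0) || any(vy > h - 1) || any(vx > w - 1))
      stop("ROI polygon out of frame bounds")
    py <- rep(0:(h - 1), w)
    px <- rep(0:(w - 1), each = h)
    inside <- rep(FALSE, h * w)
    nv <- length(vy)
    j <- nv
    for (i in seq_len(nv)) {
      crosses <- ((vy[i] > py) != (vy[j] > py)) &
        (px < (vx[j] - vx[i]) * (py - vy[i]) / (vy[j] - vy[i]) + vx[i])
      inside <- xor(inside, crosses)
      j <- i
    }
    m <- matrix(inside, h, w)
    if (!any(m)) stop("empty region of interest")
    return(m)
  }
  stop("unrecognized ROI specification")
}

#' Read an ROI file
#'
#' A CSV with columns `row0,row1,col0,col1` (one row) is a rectangle; a CSV
#' with columns `row,col` (three or more rows) is a polygon. Coordinates are
#' 0-based; rectangles are half-open.
#'
#' @param path CSV path.
#' @return A numeric rectangle vector or polygon vertex matrix, suitable for
#'   [roi_mask()] / [label_and_filter()].
#' @export
read_roi <- function(path) {
  x <- read.csv(path)
  if (all(c("row0", "row1", "col0", "col1") %in% names(x)) && nrow(x) == 1L)
    return(c(x$row0, x$row1, x$col0, x$col1))
  if (all(c("row", "col") %in% names(x)) && nrow(x) >= 3L)
    return(cbind(x$row, x$col))
  stop("ROI file must be a one-row rectangle (row0,row1,col0,col1) or a ",
       ">=3-row polygon (row,col)")
}
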