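#' Simulation configuration for a synthetic trap-surface camera
#'
#' Describes one camera viewing one trap surface: frame geometry, the
#' arrival/departure dynamics of flies on the surface, fly appearance, and
#' the nuisance processes (illumination drift and sensor noise) that the
#' detection pipeline must cope with.
#'
#' Flies are rendered as filled dark ellipses (aspect ratio drawn from
#' `aspect_range`, orientation uniform) over a fixed smooth textured
#' background; dark-on-pale matches real insects on trap cardboard. Fly
#' presence evolves as a birth-death chain: at each frame every resident fly
#' departs with probability `departure_rate` and a new fly arrives with
#' probability `arrival_rate` (so the equilibrium mean occupancy is
#' `arrival_rate / departure_rate`). During the first `warmup_frames` frames
#' no arrivals occur, representing cameras that start recording before
#' insects are released; this also provides a clean leading window for
#' background modelling.
#'
#' @param width,height Frame size in pixels (defaults 640 x 480).
#' @param n_frames Number of frames to simulate.
#' @param frame_interval Seconds between frames (default 6).
#' @param fly_area_range Closed interval of rendered blob areas in pixels;
#'   the default `c(150, 950)` matches the particle-analysis gate.
#' @param fly_contrast Intensity units by which a fly is darker than the
#'   background (8-bit scale).
#' @param arrival_rate,departure_rate Per-frame probabilities in `[0, 1]`.
#' @param drift_amplitude Total linear-in-time illumination drift over the
#'   sequence, in intensity units.
#' @param noise_sd Standard deviation of i.i.d. Gaussian pixel noise.
#' @param warmup_frames Leading frames during which no fly arrives.
#' @param aspect_range Range of ellipse aspect ratios (default `c(1, 2.5)`).
#' @param surface Surface label carried into the ground truth.
#' @param background_level,background_sd Mean level and spatial contrast of
#'   the static background texture (8-bit scale).
#' @param seed Integer seed; identical configuration plus seed gives
#'   bit-identical output.
#'
#' @return An object of class `sim_config`.
#' @seealso [simulate_image_sequence()]
#' @export
sim_config <- function(width = 640L, height = 480L, n_frames = 100L,
                       frame_interval = 6, fly_area_range = c(150, 950),
                       fly_contrast = 60, arrival_rate = 0.2,
                       departure_rate = 0.2, drift_amplitude = 10,
                       noise_sd = 2, warmup_frames = 0L,
                       aspect_range = c(1, 2.5), surface = "surface",
                       background_level = 190, background_sd = 12,
                       seed = NULL) {
  width <- as.integer(width); height <- as.integer(height)
  n_frames <- as.integer(n_frames)
  if (is.na(width) || is.na(height) || width < 16L || height < 16L)
    stop("invalid config: frame dimensions must be at least 16 x 16 pixels")
  if (is.na(n_frames) || n_frames < 1L)
    stop("invalid config: n_frames must be a positive integer")
  if (length(fly_area_range) != 2L || any(fly_area_range <= 0) ||
      fly_area_range[1] >= fly_area_range[2])
    stop("invalid config: fly_area_range must be positive with min < max")
  for (r in c(arrival_rate, departure_rate))
    if (r < 0 || r > 1) stop("invalid config: rates must lie in [0, 1]")
  if (noise_sd < 0) stop("invalid config: noise_sd must be >= 0")
  if (drift_amplitude < 0) stop("invalid config: drift_amplitude must be >= 0")
  if (warmup_frames < 0 || warmup_frames > n_frames)
    stop("invalid config: warmup_frames must lie in [0, n_frames]")
  structure(list(width = width, height = height, n_frames = n_frames,
                 frame_interval = frame_interval,
                 fly_area_range = fly_area_range,
                 fly_contrast = fly_contrast, arrival_rate = arrival_rate,
                 departure_rate = departure_rate,
                 drift_amplitude = drift_amplitude, noise_sd = noise_sd,
                 warmup_frames = as.integer(warmup_frames),
                 aspect_range = aspect_range, surface = surface,
                 background_level = background_level,
                 background_sd = background_sd, seed = seed),
            class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf("sim_config: %d x %d px, %d frames @ %gs (surface '%s')\n",
              x$width, x$height, x$n_frames, x$frame_interval, x$surface))
  cat(sprintf("  arrival %.3g, departure %.3g, area [%g, %g] px, contrast %g\n",
              x$arrival_rate, x$departure_rate, x$fly_area_range[1],
              x$fly_area_range[2], x$fly_contrast))
  cat(sprintf("  drift %g, noise sd %g, warmup %d, seed %s\n",
              x$drift_amplitude, x$noise_sd, x$warmup_frames,
              if (is.null(x$seed)) "none" else as.character(x$seed)))
  invisible(x)
}

#' Image stack container
#'
#' Ordered grayscale frames with a fixed acquisition cadence. Frames are
#' stored as a `height x width x n` numeric array of 8-bit-scale intensities
#' (0-255).
#'
#' @param frames 3-D numeric array `height x width x n_frames` (a single
#'   matrix is promoted to one frame).
#' @param interval Seconds between frames.
#' @param surface Optional surface label.
#' @param timestamps Optional vector of frame times in seconds; defaults to
#'   `(0:(n-1)) * interval`.
#' @return An object of class `trapcam_stack`.
#' @export
trapcam_stack <- function(frames, interval = 6, surface = NA_character_,
                          timestamps = NULL) {
  if (is.matrix(frames)) frames <- array(frames, c(dim(frames), 1L))
  stopifnot(is.array(frames), length(dim(frames)) == 3L)
  n <- dim(frames)[3]
  if (is.null(timestamps)) timestamps <- (seq_len(n) - 1) * interval
  stopifnot(length(timestamps) == n)
  structure(list(frames = frames, interval = interval, surface = surface,
                 timestamps = timestamps),
            class = "trapcam_stack")
}

#' @export
print.trapcam_stack <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf("trapcam_stack: %d frames of %d x %d px @ %gs (surface '%s')\n",
              d[3], d[1], d[2], x$interval, x$surface))
  invisible(x)
}

#' Number of frames in a stack
#' @param stack A [trapcam_stack()].
#' @return Integer frame count.
#' @export
n_frames <- function(stack) dim(stack$frames)[3]

## Smooth fixed-seed background texture: Gaussian-blurred white noise,
## standardized and rescaled around `level`.
make_background_field <- function(height, width, level, contrast_sd) {
  z <- matrix(rnorm(height * width), height, width)
  sigma <- max(2, min(height, width) / 24)
  g <- EBImage::imageData(EBImage::gblur(z, sigma = sigma))
  g <- (g - mean(g)) / stats::sd(g)
  pmin(pmax(level + contrast_sd * g, 20), 245)
}

## Attempt to place one fly: sample geometry, paint on a local grid, check
## the painted area falls inside `fly_area_range` and the (padded) bounding
## box does not touch any resident fly or the frame border. Returns NULL if
## no admissible placement is found (the arrival is then skipped).
place_fly <- function(config, flies, id) {
  h <- config$height; w <- config$width
  for (try in seq_len(60L)) {
    area_target <- runif(1, config$fly_area_range[1], config$fly_area_range[2])
    q <- runif(1, config$aspect_range[1], config$aspect_range[2])
    theta <- runif(1, 0, pi)
    a <- sqrt(area_target * q / pi)
    b <- sqrt(area_target / (pi * q))
    ext <- ceiling(a) + 1L                     # conservative half-extent
    if (2L * ext + 6L >= h || 2L * ext + 6L >= w) next
    cy <- runif(1, ext + 2, h - ext - 1)
    cx <- runif(1, ext + 2, w - ext - 1)
    bbox <- c(floor(cy) - ext, ceiling(cy) + ext,
              floor(cx) - ext, ceiling(cx) + ext)
    pad <- 5L                                  # keeps closing from bridging blobs
    clash <- FALSE
    for (f in flies) {
      if (!(bbox[2] + pad < f$bbox[1] || f$bbox[2] + pad < bbox[1] ||
            bbox[4] + pad < f$bbox[3] || f$bbox[4] + pad < bbox[3])) {
        clash <- TRUE; break
      }
    }
    if (clash) next
    rows <- bbox[1]:bbox[2]; cols <- bbox[3]:bbox[4]
    rg <- matrix(rows, length(rows), length(cols))
    cg <- matrix(cols, length(rows), length(cols), byrow = TRUE)
    u <- (cg - cx) * cos(theta) + (rg - cy) * sin(theta)
    v <- -(cg - cx) * sin(theta) + (rg - cy) * cos(theta)
    inside <- (u / a)^2 + (v / b)^2 <= 1
    area <- sum(inside)
    if (area < config$fly_area_range[1] || area > config$fly_area_range[2])
      next
    return(list(id = id,
                idx = (cg[inside] - 1L) * h + rg[inside],  # column-major
                area = area, bbox = bbox,
                row = mean(rg[inside]) - 1, col = mean(cg[inside]) - 1))
  }
  NULL
}

#' Simulate a trap-surface image sequence with exact ground truth
#'
#' Renders `n_frames` grayscale frames of a static textured trap surface with
#' flies arriving and departing according to the configured birth-death
#' dynamics, plus linear illumination drift and Gaussian pixel noise, and
#' records every rendered blob.
#'
#' Blob placement is non-overlapping (padded bounding boxes), so the painted
#' pixel area recorded in the ground truth is exact. An arrival for which no
#' admissible position is found after 60 attempts is skipped.
#'
#' @param config A [sim_config()].
#' @return A list of class `trapcam_sim` with elements
#'   \describe{
#'     \item{`stack`}{a [trapcam_stack()] of rendered frames;}
#'     \item{`truth`}{a data frame of rendered blobs (`frame`, `blob_id`,
#'       `row`, `col` 0-based centroids, `area` painted pixels, `surface`);}
#'     \item{`counts`}{integer vector, the true per-frame fly count.}
#'   }
#' @examples
#' sim <- simulate_image_sequence(sim_config(width = 160, height = 120,
#'                                           n_frames = 5, seed = 1))
#' sim$counts
#' @export
simulate_image_sequence <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  if (!is.null(config$seed)) set.seed(config$seed)
  h <- config$height; w <- config$width; n <- config$n_frames
  bg <- make_background_field(h, w, config$background_level,
                              config$background_sd)
  frames <- array(0, c(h, w, n))
  flies <- list()
  next_id <- 1L
  truth <- vector("list", n)
  counts <- integer(n)
  for (t in seq_len(n)) {
    if (length(flies) > 0L && config$departure_rate > 0) {
      stay <- runif(length(flies)) >= config$departure_rate
      flies <- flies[stay]
    }
    if (t > config$warmup_frames && runif(1) < config$arrival_rate) {
      fly <- place_fly(config, flies, next_id)
      if (!is.null(fly)) {
        flies <- c(flies, list(fly))
        next_id <- next_id + 1L
      }
    }
    fr <- bg
    if (config$drift_amplitude > 0 && n > 1L)
      fr <- fr + config$drift_amplitude * (t - 1) / (n - 1)
    for (f in flies) fr[f$idx] <- fr[f$idx] - config$fly_contrast
    if (config$noise_sd > 0)
      fr <- fr + matrix(rnorm(h * w, 0, config$noise_sd), h, w)
    frames[, , t] <- pmin(pmax(fr, 0), 255)
    counts[t] <- length(flies)
    if (length(flies) > 0L) {
      truth[[t]] <- data.frame(
        frame = t,
        blob_id = vapply(flies, `[[`, integer(1), "id"),
        row = vapply(flies, `[[`, numeric(1), "row"),
        col = vapply(flies, `[[`, numeric(1), "col"),
        area = vapply(flies, `[[`, numeric(1), "area"),
        surface = config$surface)
    }
  }
  truth <- if (all(vapply(truth, is.null, logical(1)))) {
    data.frame(frame = integer(), blob_id = integer(), row = numeric(),
               col = numeric(), area = numeric(), surface = character())
  } else do.call(rbind, truth[!vapply(truth, is.null, logical(1))])
  rownames(truth) <- NULL
  structure(list(stack = trapcam_stack(frames, config$frame_interval,
                                       config$surface),
                 truth = truth, counts = counts, config = config),
            class = "trapcam_sim")
}

#' @export
print.trapcam_sim <- function(x, ...) {
  print(x$stack)
  cat(sprintf("  ground truth: %d blob sightings, mean occupancy %.2f\n",
              nrow(x$truth), mean(x$counts)))
  invisible(x)
}

#' Simulate the fly-occupancy birth-death chain alone
#'
#' The occupancy process used by [simulate_image_sequence()], without
#' rendering: each frame, every resident fly departs with probability
#' `departure_rate`, then one fly arrives with probability `arrival_rate`.
#' Useful for studying the dynamics at frame counts where rendering would be
#' wasteful.
#'
#' @param n_frames Number of frames.
#' @param arrival_rate,departure_rate Per-frame probabilities in `[0, 1]`.
#' @param warmup_frames Leading frames with no arrivals.
#' @param seed Optional integer seed.
#' @return Integer vector of per-frame occupancy counts.
#' @export
simulate_occupancy <- function(n_frames, arrival_rate, departure_rate,
                               warmup_frames = 0L, seed = NULL) {
  stopifnot(arrival_rate >= 0, arrival_rate <= 1,
            departure_rate >= 0, departure_rate <= 1, n_frames >= 1)
  if (!is.null(seed)) set.seed(seed)
  counts <- integer(n_frames)
  n <- 0L
  for (t in seq_len(n_frames)) {
    if (n > 0L && departure_rate > 0)
      n <- n - sum(runif(n) < departure_rate)
    if (t > warmup_frames && runif(1) < arrival_rate) n <- n + 1L
    counts[t] <- n
  }
  counts
}

#' Parameters for simulating capture-count tables
#'
#' Defaults reproduce the structure of a seven-replicate Jackson-trap
#' field-cage experiment with three bait treatments (trimedlure alone,
#' trimedlure plus a DDVP vapor strip, and an unbaited control): per
#' replicate, the number of flies captured on the sticky panel ("trapped")
#' and the number found dead in the collection tub below the trap
#' ("in tub"). Counts are drawn from a negative binomial because observed
#' capture columns are strongly overdispersed (in-tub variance far exceeds
#' the mean); `dispersion` is the NB size parameter (smaller = more
#' overdispersed), with the Poisson recovered as `dispersion -> Inf`.
#'
#' @param treatments Character vector of treatment labels.
#' @param mean_trapped,mean_in_tub Per-treatment mean counts.
#' @param dispersion NB size parameter(s), recycled across treatments.
#' @param n_replicates Number of replicate rows (dates).
#' @param mean_released,released_dispersion NB parameters for the number of
#'   flies released per replicate.
#' @param start_date First replicate date (subsequent rows step by 7 days).
#' @param seed Optional integer seed.
#' @return An object of class `capture_sim_params`.
#' @export
capture_sim_params <- function(treatments = c("TML", "TML-DDVP", "Control"),
                               mean_trapped = c(324.1, 356.1, 50.7),
                               mean_in_tub = c(34.7, 91.6, 2.0),
                               dispersion = 3,
                               n_replicates = 7L,
                               mean_released = 1400.3,
                               released_dispersion = 21,
                               start_date = as.Date("2014-05-23"),
                               seed = NULL) {
  k <- length(treatments)
  stopifnot(length(mean_trapped) == k, length(mean_in_tub) == k)
  if (any(mean_trapped < 0) || any(mean_in_tub < 0) || mean_released < 0)
    stop("invalid params: means must be >= 0")
  if (any(dispersion <= 0) || released_dispersion <= 0)
    stop("invalid params: dispersion must be > 0")
  if (n_replicates < 1L) stop("invalid params: n_replicates must be >= 1")
  structure(list(treatments = treatments, mean_trapped = mean_trapped,
                 mean_in_tub = mean_in_tub,
                 dispersion = rep_len(dispersion, k),
                 n_replicates = as.integer(n_replicates),
                 mean_released = mean_released,
                 released_dispersion = released_dispersion,
                 start_date = start_date, seed = seed),
            class = "capture_sim_params")
}

treatment_slug <- function(x) gsub("[^a-z0-9]+", "_", tolower(x))

#' Simulate a replicate-by-treatment capture-count table
#'
#' Draws `n_replicates` rows of non-negative integer counts from negative
#' binomials with the configured means and dispersion; for every treatment
#' the total column is `trapped + in_tub` by construction.
#'
#' @param params A [capture_sim_params()].
#' @return A `capture_table` data frame with columns `date`, `released`, and
#'   `<treatment>_trapped`, `<treatment>_in_tub`, `<treatment>_total` for
#'   each treatment.
#' @export
simulate_capture_table <- function(params) {
  stopifnot(inherits(params, "capture_sim_params"))
  if (!is.null(params$seed)) set.seed(params$seed)
  n <- params$n_replicates
  tab <- data.frame(
    date = format(params$start_date + 7 * (seq_len(n) - 1)),
    released = rnbinom(n, mu = params$mean_released,
                       size = params$released_dispersion))
  for (i in seq_along(params$treatments)) {
    slug <- treatment_slug(params$treatments[i])
    trapped <- rnbinom(n, mu = params$mean_trapped[i],
                       size = params$dispersion[i])
    in_tub <- rnbinom(n, mu = params$mean_in_tub[i],
                      size = params$dispersion[i])
    tab[[paste0(slug, "_trapped")]] <- trapped
    tab[[paste0(slug, "_in_tub")]] <- in_tub
    tab[[paste0(slug, "_total")]] <- trapped + in_tub
  }
  capture_table(tab)
}
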