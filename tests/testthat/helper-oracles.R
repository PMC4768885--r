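# Independent oracles used across the suite. Each deliberately takes the
# slow, explicit route (loops, set arithmetic, quadrature, chain iteration)
# so it shares no code path with the implementation it checks.

# Breadth-first flood fill, 8-connected, scanning pixels in column-major
# order so component ids appear in first-encounter order.
flood_fill_label <- function(mask) {
  h <- nrow(mask); w <- ncol(mask)
  lab <- matrix(0L, h, w)
  nextid <- 0L
  for (j in seq_len(w)) for (i in seq_len(h)) {
    if (!mask[i, j] || lab[i, j] != 0L) next
    nextid <- nextid + 1L
    queue <- list(c(i, j))
    lab[i, j] <- nextid
    while (length(queue) > 0L) {
      p <- queue[[1]]; queue <- queue[-1]
      for (di in -1:1) for (dj in -1:1) {
        ni <- p[1] + di; nj <- p[2] + dj
        if (ni >= 1 && ni <= h && nj >= 1 && nj <= w &&
            mask[ni, nj] && lab[ni, nj] == 0L) {
          lab[ni, nj] <- nextid
          queue[[length(queue) + 1L]] <- c(ni, nj)
        }
      }
    }
  }
  lab
}

# Exhaustive Otsu: try every threshold t, compute between-class variance of
# the split {x < t} vs {x >= t} directly from the pixel values.
otsu_scan_oracle <- function(img) {
  x <- as.vector(img)
  best_t <- 0L; best_v <- -1
  for (t in 0:255) {
    lo <- x[x < t]; hi <- x[x >= t]
    if (length(lo) == 0L || length(hi) == 0L) v <- 0
    else {
      w0 <- length(lo) / length(x); w1 <- 1 - w0
      v <- w0 * w1 * (mean(lo) - mean(hi))^2
    }
    if (v > best_v + 1e-12) { best_v <- v; best_t <- t }
  }
  best_t
}

# Explicit weighted mean: per-pixel accumulation loop over frames.
weighted_mean_oracle <- function(frames, weights) {
  acc <- matrix(0, dim(frames)[1], dim(frames)[2])
  for (k in seq_along(weights)) acc <- acc + weights[k] * frames[, , k]
  acc / sum(weights)
}

# Erosion/dilation by explicit set arithmetic over a square element.
erode_oracle <- function(mask, radius) {
  h <- nrow(mask); w <- ncol(mask)
  out <- matrix(FALSE, h, w)
  for (i in seq_len(h)) for (j in seq_len(w)) {
    ok <- TRUE
    for (di in -radius:radius) for (dj in -radius:radius) {
      ni <- i + di; nj <- j + dj
      if (ni < 1 || ni > h || nj < 1 || nj > w || !mask[ni, nj]) ok <- FALSE
    }
    out[i, j] <- ok
  }
  out
}

dilate_oracle <- function(mask, radius) {
  h <- nrow(mask); w <- ncol(mask)
  out <- matrix(FALSE, h, w)
  for (i in seq_len(h)) for (j in seq_len(w)) {
    any_on <- FALSE
    for (di in -radius:radius) for (dj in -radius:radius) {
      ni <- i + di; nj <- j + dj
      if (ni >= 1 && ni <= h && nj >= 1 && nj <= w && mask[ni, nj])
        any_on <- TRUE
    }
    out[i, j] <- any_on
  }
  out
}

open_close_oracle <- function(mask, radius) {
  opened <- dilate_oracle(erode_oracle(mask, radius), radius)
  erode_oracle(dilate_oracle(opened, radius), radius)
}

# Two-sided t-tail probability by numerical quadrature of the density.
t_tail_quadrature <- function(tstat, df) {
  dens <- function(x) stats::dt(x, df = df)
  2 * stats::integrate(dens, lower = abs(tstat), upper = Inf,
                       rel.tol = 1e-10)$value
}

# Stationary distribution of the occupancy birth-death chain (departures
# Binomial(N, d) then a Bernoulli(a) arrival), by iterating the transition
# on a truncated state space until convergence.
chain_equilibrium <- function(a, d, max_n = 60L, tol = 1e-13) {
  p <- c(1, rep(0, max_n))
  step <- function(p) {
    survived <- rep(0, max_n + 1L)
    for (n in 0:max_n) {
      if (p[n + 1L] == 0) next
      s <- 0:n
      survived[s + 1L] <- survived[s + 1L] +
        p[n + 1L] * stats::dbinom(s, n, 1 - d)
    }
    out <- (1 - a) * survived
    out[2:(max_n + 1L)] <- out[2:(max_n + 1L)] + a * survived[1:max_n]
    out[max_n + 1L] <- out[max_n + 1L] + a * survived[max_n + 1L]
    out
  }
  repeat {
    p2 <- step(p)
    if (max(abs(p2 - p)) < tol) break
    p <- p2
  }
  n <- 0:max_n
  list(dist = p2, mean = sum(n * p2), var = sum(n^2 * p2) - sum(n * p2)^2)
}

# Rectangle drawn into a mask by 1-based inclusive row/col ranges.
draw_rect <- function(mask, rows, cols) {
  mask[rows, cols] <- TRUE
  mask
}

table2 <- function() read_capture_table(capture_counts_file())
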