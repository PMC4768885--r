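test_that("to_8bit maps the observed range onto 0..255 with half-up rounding", {
  expect_true(all(to_8bit(matrix(5, 4, 4)) == 0))
  expect_equal(as.vector(to_8bit(matrix(c(0, 2, 4), 1))), c(0, 128, 255))
  set.seed(201)
  x <- matrix(runif(60, -3, 17), 6, 10)
  oracle <- matrix(0, 6, 10)
  rng <- range(x)
  for (i in 1:6) for (j in 1:10)
    oracle[i, j] <- floor(255 * (x[i, j] - rng[1]) / diff(rng) + 0.5)
  expect_equal(to_8bit(x), oracle)
})

test_that("otsu matches the exhaustive between-class-variance scan", {
  # two-valued image: foreground must be exactly the bright 10%
  img <- matrix(c(rep(10, 90), rep(200, 10)), 10, 10)
  msk <- threshold_image(img, "otsu")
  expect_equal(unclass(msk), img == 200, ignore_attr = TRUE)
  expect_equal(attr(msk, "threshold"), otsu_scan_oracle(img))
  # random 8-bit images against the oracle
  set.seed(202)
  for (k in 1:5) {
    img <- matrix(sample(0:255, 400, replace = TRUE), 20, 20)
    expect_equal(as.integer(otsu_threshold(img)), otsu_scan_oracle(img))
  }
  # cross-check against the independent EBImage implementation on a
  # well-separated bimodal image (conventions may differ by one level, so
  # compare the resulting masks)
  img <- matrix(round(c(rnorm(300, 60, 6), rnorm(100, 190, 6))), 20, 20)
  img <- pmin(pmax(img, 0), 255)
  eb <- EBImage::otsu(img / 255, range = c(0, 1), levels = 256) * 255
  expect_identical(img >= as.numeric(otsu_threshold(img)), img > eb)
})

test_that("degenerate histograms flag rather than fail", {
  msk <- threshold_image(matrix(42, 5, 5), "otsu")
  expect_true(attr(msk, "degenerate"))
  expect_true(all(msk) || !any(msk))
})

test_that("fixed thresholds respect their bounds", {
  img <- matrix(sample(0:255, 100, replace = TRUE), 10, 10)
  expect_true(all(threshold_image(img, "fixed", value = 0)))
  expect_error(threshold_image(img, "fixed", value = 300), "\\[0, 255\\]")
  expect_error(threshold_image(img, "fixed"), "requires")
})

test_that("open_close is the identity at radius 0 and removes lone pixels", {
  set.seed(203)
  m <- matrix(runif(100) < 0.4, 10, 10)
  expect_equal(unclass(open_close(m, 0)), m, ignore_attr = TRUE)
  lone <- matrix(FALSE, 9, 9); lone[5, 5] <- TRUE
  expect_false(any(open_close(lone, 1)))
})

test_that("closing merges blobs separated by a one-pixel gap", {
  m <- matrix(FALSE, 30, 50)
  m <- draw_rect(m, 5:24, 3:22)    # 20 x 20 square
  m <- draw_rect(m, 5:24, 24:43)   # second square, 1-px gap at col 23
  oc <- open_close(m, 1)
  det <- label_and_filter(oc, min_area = 1, max_area = 1e6)
  expect_equal(nrow(det), 1)
  expect_equal(unclass(oc), open_close_oracle(m, 1), ignore_attr = TRUE)
})

test_that("open_close agrees with explicit erosion/dilation set arithmetic", {
  set.seed(204)
  for (k in 1:10) {
    m <- matrix(runif(24 * 20) < 0.45, 24, 20)
    expect_equal(unclass(open_close(m, 1)), open_close_oracle(m, 1),
                 ignore_attr = TRUE)
  }
})

test_that("open then close is idempotent on random masks", {
  set.seed(205)
  for (k in 1:20) {
    m <- matrix(runif(32 * 32) < runif(1, 0.2, 0.6), 32, 32)
    once <- open_close(m, 1)
    expect_identical(unclass(open_close(once, 1)), unclass(once))
  }
})

test_that("area gating keeps only components inside the closed interval", {
  m <- matrix(FALSE, 40, 40)
  m <- draw_rect(m, 3:12, 3:12)        # 100 px
  expect_equal(nrow(label_and_filter(m)), 0)
  m2 <- matrix(FALSE, 60, 60)
  m2 <- draw_rect(m2, 3:22, 3:27)      # 500 px
  det <- label_and_filter(m2)
  expect_equal(nrow(det), 1)
  expect_equal(det$area, 500)
  # 200, 960 and 150 px components: bounds inclusive, 960 rejected
  m3 <- matrix(FALSE, 100, 120)
  m3 <- draw_rect(m3, 2:11, 2:21)      # 200 px
  m3 <- draw_rect(m3, 30:59, 30:61)    # 960 px
  m3 <- draw_rect(m3, 70:79, 70:84)    # 150 px
  det3 <- label_and_filter(m3)
  expect_equal(nrow(det3), 2)
  expect_setequal(det3$area, c(200, 150))
})

test_that("labeling agrees with a recursive flood fill on random masks", {
  set.seed(206)
  for (k in 1:200) {
    m <- matrix(runif(32 * 32) < runif(1, 0.15, 0.55), 32, 32)
    det <- label_and_filter(m, min_area = 1, max_area = 32 * 32)
    oracle <- flood_fill_label(m)
    n_oracle <- max(oracle)
    expect_equal(nrow(det), n_oracle)
    if (n_oracle > 0)
      expect_equal(sort(det$area), sort(as.integer(tabulate(oracle))))
  }
})

test_that("detection records carry consistent geometry", {
  m <- matrix(FALSE, 50, 70)
  m <- draw_rect(m, 10:24, 20:39)      # 15 x 20 = 300 px at known position
  det <- label_and_filter(m)
  expect_equal(det$row, mean(9:23))    # 0-based centroid
  expect_equal(det$col, mean(19:38))
  expect_equal(c(det$bb_row0, det$bb_row1), c(9, 24))   # half-open
  expect_equal(c(det$bb_col0, det$bb_col1), c(19, 39))
  expect_true(det$row >= det$bb_row0 && det$row < det$bb_row1)
  expect_true(det$col >= det$bb_col0 && det$col < det$bb_col1)
})

test_that("widening the area gate never loses detections", {
  set.seed(207)
  m <- matrix(runif(60 * 60) < 0.45, 60, 60)
  gates <- list(c(20, 100), c(10, 200), c(5, 500), c(1, 3600))
  counts <- vapply(gates, function(g)
    nrow(label_and_filter(m, g[1], g[2])), numeric(1))
  expect_true(all(diff(counts) >= 0))
})

test_that("regions of interest restrict and validate", {
  m <- matrix(FALSE, 40, 40)
  m <- draw_rect(m, 2:21, 2:11)        # 200 px in the top-left
  m <- draw_rect(m, 25:39, 25:39)      # 225 px bottom-right
  all_det <- label_and_filter(m, 100, 900)
  expect_equal(nrow(all_det), 2)
  left <- label_and_filter(m, 100, 900, roi = c(0, 40, 0, 20))
  expect_equal(nrow(left), 1)
  expect_error(label_and_filter(m, 100, 900, roi = c(0, 50, 0, 20)),
               "bounds")
  expect_error(label_and_filter(m, 0, 900), "min_area")
})

test_that("an empty noiseless scene yields all-zero counts", {
  sim <- simulate_image_sequence(
    sim_config(width = 120, height = 90, n_frames = 20, arrival_rate = 0,
               noise_sd = 0, drift_amplitude = 0, seed = 8))
  cs <- count_flies(sim$stack, window = 10)
  expect_true(all(cs$count == 0))
})

test_that("noiseless synthetic stacks are recovered exactly", {
  cfg <- sim_config(width = 200, height = 150, n_frames = 80,
                    arrival_rate = 0.3, departure_rate = 0.2, noise_sd = 0,
                    drift_amplitude = 0, warmup_frames = 25,
                    fly_area_range = c(170, 900), seed = 13)
  sim <- simulate_image_sequence(cfg)
  expect_gt(sum(sim$counts), 0)
  cs <- count_flies(sim$stack, window = 25)
  expect_identical(cs$count, sim$counts)
})

test_that("counts stay accurate under pixel noise", {
  cfg <- sim_config(width = 200, height = 150, n_frames = 150,
                    arrival_rate = 0.3, departure_rate = 0.2, noise_sd = 4,
                    drift_amplitude = 0, warmup_frames = 25,
                    fly_area_range = c(170, 900), seed = 14)
  sim <- simulate_image_sequence(cfg)
  cs <- count_flies(sim$stack, window = 25)
  expect_gte(mean(cs$count == sim$counts), 0.95)
})

test_that("image-set totals sum the per-surface series", {
  cfgs <- lapply(1:3, function(i)
    sim_config(width = 120, height = 90, n_frames = 30, arrival_rate = 0.3,
               noise_sd = 0, drift_amplitude = 0, warmup_frames = 10,
               fly_area_range = c(170, 900), surface = paste0("s", i),
               seed = 40 + i))
  series <- lapply(cfgs, function(cfg)
    count_flies(simulate_image_sequence(cfg)$stack, window = 10))
  tot <- image_set_counts(series)
  expect_equal(tot$count,
               series[[1]]$count + series[[2]]$count + series[[3]]$count)
  expect_equal(tot$n_surfaces[1], 3)
})
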