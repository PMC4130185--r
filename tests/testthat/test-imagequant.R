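test_that("normalization maps the bit-depth range linearly onto [0, 1]", {
  expect_equal(normalize_image(matrix(0), 12), matrix(0))
  expect_equal(normalize_image(matrix(4095), 12), matrix(1))
  expect_equal(normalize_image(matrix(2048), 12), matrix(2048 / 4095))
  raw <- matrix(sort(sample.int(4096, 50) - 1), 5, 10)
  expect_true(all(diff(as.vector(normalize_image(raw, 12))) > 0))
  expect_error(normalize_image(matrix(4096), 12), "4096")
  expect_error(normalize_image(matrix(-1), 12), "-1")
})

test_that("nuclear thresholding gates on intensity then component size", {
  expect_false(any(threshold_nuclei(matrix(0, 20, 20), 0.5, 5)$mask))

  # one noiseless disc: mask equals the rendered disc pixel set
  sim <- gen_image(image_spec(n_cells = 1, image_shape = c(48, 48),
                              nucleus_intensity = c(0.9, 0.9),
                              background = c(nuclear = 0.05, marker = 0.05),
                              noise_sd = 0), seed = 2)
  m <- threshold_nuclei(sim$image$channels$nuclear, 0.5, 5)
  expect_identical(m$mask, sim$image$channels$nuclear >= 0.5)
  ce <- sim$truth$cells
  expect_equal(sum(m$mask),
               sum(outer(seq_len(48), seq_len(48), function(r, c)
                 (r - ce$row)^2 + (c - ce$col)^2 <= ce$nucleus_radius^2)))

  # a 12-px component dies under min_area_px = 20
  small <- matrix(0, 20, 20)
  small[5:8, 5:7] <- 0.9
  expect_false(any(threshold_nuclei(small, 0.5, 20)$mask))
  expect_true(any(threshold_nuclei(small, 0.5, 12)$mask))

  expect_error(threshold_nuclei(matrix(c(NA, 1), 1, 2), 0.5, 1), "non-finite")
})

test_that("soma dilation equals a brute-force disc kernel sweep", {
  m <- matrix(FALSE, 9, 9)
  m[5, 5] <- TRUE
  d1 <- dilate_soma(m, 1)
  expect_identical(d1, bf_dilate(m, 1))
  expect_equal(sum(d1), 5)  # plus-shaped 1-px disc neighbourhood

  expect_identical(dilate_soma(m, 0), m)
  expect_false(any(dilate_soma(matrix(FALSE, 6, 6), 3)))
  expect_error(dilate_soma(m, -1), "0")

  set.seed(31)
  for (i in 1:10) {
    msk <- random_mask(12, 12, 0.2)
    r <- sample(c(1, 2, 2.5, 3), 1)
    got <- dilate_soma(msk, r)
    expect_identical(got, bf_dilate(msk, r))
    expect_true(all(got[msk]))  # dilation contains its input
  }
})

test_that("distance map equals exhaustive nearest-background search", {
  expect_equal(distance_map(matrix(FALSE, 8, 8)), matrix(0, 8, 8))

  single <- matrix(FALSE, 7, 7)
  single[4, 4] <- TRUE
  expect_equal(distance_map(single)[4, 4], 1)

  sq <- matrix(TRUE, 7, 7)  # borders count as background
  expect_equal(distance_map(sq), bf_distance_map(sq))

  set.seed(77)
  for (i in 1:30) {
    m <- random_mask(16, 16, runif(1, 0.2, 0.9))
    d <- distance_map(m)
    expect_equal(d, bf_distance_map(m))
    expect_true(all(d[!m] == 0) && all(d[m] > 0))
  }
})

test_that("watershed separates touching nuclei and filters small objects", {
  # single disc -> one label covering exactly the disc
  sim <- gen_image(image_spec(n_cells = 1, image_shape = c(48, 48),
                              noise_sd = 0), seed = 4)
  mask <- sim$image$channels$nuclear >= 0.5
  ws <- watershed_separate(distance_map(mask), mask)
  expect_equal(max(ws$labels), 1)
  expect_identical(ws$labels > 0, mask)

  # touching pair with separation >= min_distance: two labels, each
  # containing its generating center
  tp <- gen_touching_pair(separation = 14, radius = 8)
  mask <- tp$image$channels$nuclear >= 0.5
  ws <- watershed_separate(distance_map(mask), mask, min_distance_px = 10,
                           min_radius_px = 3)
  expect_equal(max(ws$labels), 2)
  ctr <- round(tp$truth$cells[, c("row", "col")])
  got <- c(ws$labels[ctr$row[1], ctr$col[1]], ws$labels[ctr$row[2], ctr$col[2]])
  expect_setequal(got, 1:2)
  # labels partition the region: every region pixel labelled, none outside
  expect_identical(ws$labels > 0, mask)
  # each label contains exactly one surviving seed
  expect_equal(nrow(ws$seeds), 2)
  expect_setequal(ws$labels[ws$seeds], 1:2)

  # object below the minimum equivalent radius is dropped
  tiny <- matrix(FALSE, 20, 20)
  tiny[9:10, 9:10] <- TRUE  # area 4 -> equivalent radius 1.13
  out <- watershed_separate(distance_map(tiny), tiny, min_distance_px = 2,
                            min_radius_px = 3)
  expect_equal(max(out$labels), 0)

  expect_error(watershed_separate(matrix(0, 4, 4), matrix(FALSE, 5, 5)),
               "shape")
})

test_that("per-cell means equal a pixel-loop oracle and generator truth", {
  # uniform marker raster: every record's mean is that constant
  sim <- gen_image(image_spec(n_cells = 4, image_shape = c(128, 128),
                              noise_sd = 0), seed = 6)
  seg <- segment_image(sim$image)
  uni <- matrix(0.3, 128, 128)
  rec <- measure_cells(seg$soma_labels, seg$nuclear_labels, uni,
                       sim$image$channels$nuclear)
  expect_equal(rec$mean_marker_intensity, rep(0.3, 4))

  # noiseless image: means equal brute-force loops over labelled pixels and
  # the generator truth
  marker <- sim$image$channels$marker
  rec <- seg$cells
  for (id in rec$cell_id) {
    px <- which(seg$soma_labels$labels == id)
    expect_equal(rec$mean_marker_intensity[rec$cell_id == id],
                 sum(marker[px]) / length(px))
  }
  idx <- match_cells(rec, sim$truth$cells)
  expect_equal(rec$mean_marker_intensity,
               sim$truth$cells$marker_intensity[idx], tolerance = 1e-12)
  expect_true(all(rec$soma_area >= rec$nucleus_area))

  # empty label map -> empty record table
  empty <- watershed_separate(matrix(0, 8, 8), matrix(FALSE, 8, 8))
  expect_equal(nrow(measure_cells(empty, empty, matrix(0, 8, 8),
                                  matrix(0, 8, 8))), 0)

  # broken containment invariant is an error
  nuc <- seg$nuclear_labels
  soma_broken <- seg$soma_labels
  soma_broken$labels[soma_broken$labels == 1L] <- 0L
  expect_error(measure_cells(soma_broken, nuc, marker,
                             sim$image$channels$nuclear), "containment")
})

test_that("channel correlation matches closed-form least squares", {
  # exact line
  df <- data.frame(mean_nuclear_intensity = seq(0.1, 0.5, by = 0.1))
  df$mean_marker_intensity <- 2 * df$mean_nuclear_intensity + 0.1
  res <- correlate_channels(df)
  expect_equal(res$r_squared, 1)
  expect_equal(res$slope, 2)
  expect_equal(res$intercept, 0.1)

  # 5-point fixture vs normal equations evaluated independently
  x <- c(0.12, 0.33, 0.41, 0.58, 0.77)
  y <- c(0.20, 0.35, 0.30, 0.62, 0.71)
  res <- correlate_channels(data.frame(mean_nuclear_intensity = x,
                                       mean_marker_intensity = y))
  n <- 5
  slope <- (n * sum(x * y) - sum(x) * sum(y)) / (n * sum(x^2) - sum(x)^2)
  intercept <- mean(y) - slope * mean(x)
  r <- (n * sum(x * y) - sum(x) * sum(y)) /
    sqrt((n * sum(x^2) - sum(x)^2) * (n * sum(y^2) - sum(y)^2))
  expect_equal(res$slope, slope)
  expect_equal(res$intercept, intercept)
  expect_equal(res$r, r)
  expect_equal(res$r_squared, r^2)

  # independent x and y: r^2 tends to zero at large n
  set.seed(8)
  big <- data.frame(mean_nuclear_intensity = runif(4000),
                    mean_marker_intensity = runif(4000))
  expect_lt(correlate_channels(big)$r_squared, 0.01)

  expect_error(correlate_channels(
    data.frame(mean_nuclear_intensity = rep(0.5, 5),
               mean_marker_intensity = runif(5))), "constant")
})
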