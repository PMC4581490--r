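test_that("concentric half-circle segmentation gives symmetric positions", {
  m <- half_circle_morphology(10, 20, n_pairs = 5)
  segs <- segment_cell_layer(m, 4)
  expect_length(segs, 4)
  expect_equal(vapply(segs, `[[`, numeric(1), "position"),
               c(0.125, 0.375, 0.625, 0.875))
  # quad areas match an independent shoelace computation
  for (s in segs) {
    q <- s$quad
    x <- q[, 1]; y <- q[, 2]
    a <- abs(sum(x * c(y[-1], y[1])) - sum(y * c(x[-1], x[1]))) / 2
    expect_equal(s$area, a)
  }
})

test_that("a 3-pair morphology yields exactly 2 quads", {
  m <- half_circle_morphology(10, 20, n_pairs = 3)
  expect_length(segment_cell_layer(m, 2), 2)
})

test_that("quad areas sum to the annulus area (rasterization oracle)", {
  m <- half_circle_morphology(12, 24, n_pairs = 61, center = c(40, 40))
  segs <- segment_cell_layer(m, 60)
  total <- sum(vapply(segs, `[[`, numeric(1), "area"))
  # fine-grid rasterization of the closed region between the polylines
  ring_x <- c(m$outer[, 1], rev(m$inner[, 1]))
  ring_y <- c(m$outer[, 2], rev(m$inner[, 2]))
  step <- 0.25
  gx <- seq(10, 70, by = step); gy <- seq(10, 70, by = step)
  g <- expand.grid(x = gx, y = gy)
  inside <- pracma::inpolygon(g$x, g$y, ring_x, ring_y)
  raster_area <- sum(inside) * step^2
  expect_equal(total, raster_area, tolerance = 0.02)
})

test_that("degenerate quads are an error naming the segment", {
  inner <- cbind(c(0, 1, 1), c(0, 0, 1))
  outer <- cbind(c(0, 1, 2), c(0, 0, 2))  # first quad has zero area
  m <- boundary_morphology(inner, outer)
  expect_error(segment_cell_layer(m, 2), "segment 1")
})

test_that("uniform images give uniform segment means", {
  m <- half_circle_morphology(10, 20, n_pairs = 11)
  segs <- segment_cell_layer(m, 10)
  img <- matrix(0.5, 60, 60)
  raw <- segment_mean_intensity(img, segs)
  expect_true(all(raw$intensities == 0.5))
  expect_true(all(raw$pixel_counts >= 1))
  expect_true(all(diff(raw$positions) > 0))
})

test_that("segment means match brute-force pixel enumeration on a step image", {
  arch <- archetype_spec("blastula",
                         data.frame(name = "Cd", start = 0, end = 0.3,
                                    amplitude = 1))
  sc <- generate_embryo_image(
    shape = embryo_shape(width = 140, height = 140, center = c(45, 70),
                         outer_a = 48, outer_b = 54, layer_thickness = 16),
    archetype = arch, noise_sd = 0, seed = 1)
  segs <- segment_cell_layer(sc$true_morphology, 25)
  raw <- segment_mean_intensity(sc$image, segs)
  oracle <- segment_means_oracle(sc$image, segs)
  expect_equal(raw$positions, oracle$position)
  expect_equal(raw$intensities, oracle$mean)
  expect_equal(raw$pixel_counts, oracle$count)
})

test_that("sub-pixel segments are dropped with a warning, order preserved", {
  m <- half_circle_morphology(10, 11, n_pairs = 201, center = c(30, 30))
  segs <- segment_cell_layer(m, 200)
  img <- matrix(0.5, 60, 60)
  expect_warning(raw <- segment_mean_intensity(img, segs), "dropped")
  expect_true(all(diff(raw$positions) > 0))
})

test_that("morphology fully outside the image is an error", {
  m <- half_circle_morphology(10, 20, n_pairs = 5, center = c(500, 500))
  segs <- segment_cell_layer(m, 4)
  expect_error(segment_mean_intensity(matrix(0, 50, 50), segs),
               "no segment")
})

test_that("profile editing interpolates masked stretches", {
  raw <- raw_profile(seq(0.1, 0.9, by = 0.2), c(1, 1, 9, 1, 1))
  expect_identical(edit_profile(raw, edit_mask(matrix(numeric(0), ncol = 2))),
                   raw)
  fixed <- edit_profile(raw, rbind(c(0.45, 0.55)))
  expect_equal(fixed$intensities, rep(1, 5))
  # runs touching an end take the nearest unmasked value
  endfix <- edit_profile(raw_profile(seq(0.1, 0.9, by = 0.2), c(9, 9, 2, 3, 4)),
                         rbind(c(0, 0.35)))
  expect_equal(endfix$intensities, c(2, 2, 2, 3, 4))
  expect_error(edit_profile(raw, rbind(c(0, 1))), "every profile point")
  expect_error(edit_mask(rbind(c(-0.1, 0.5))), "within")
})

test_that("masking a recorded artifact recovers the artifact-free profile", {
  arch <- archetype_spec("blastula",
                         data.frame(name = "Cd", start = 0, end = 0.3,
                                    amplitude = 0.8))
  art <- data.frame(position = 0.6, delta = 0.5, radius = 6)
  dirty <- generate_embryo_image(archetype = arch, noise_sd = 0,
                                 artifact_spec = art, seed = 2)
  clean <- generate_embryo_image(archetype = arch, noise_sd = 0, seed = 2)
  segs <- segment_cell_layer(clean$true_morphology, 100)
  raw_clean <- segment_mean_intensity(clean$image, segs)
  raw_dirty <- segment_mean_intensity(dirty$image, segs)
  iv <- dirty$artifact_regions[[1]]
  # pad by one segment width: a segment overlapping the interval edge is
  # perturbed even when its midpoint lies just outside
  mask <- edit_mask(rbind(iv + c(-0.01, 0.01)))
  fixed <- edit_profile(raw_dirty, mask)
  expect_lt(max(abs(fixed$intensities - raw_clean$intensities)), 1e-6)
})

test_that("standardization yields 100 points with maximum exactly 1", {
  raw <- raw_profile(c(0.1, 0.5, 0.9), c(0.2, 0.4, 0.2))
  sp <- standardize_profile(raw, gene = "g", stage = "blastula",
                            sample_id = "s1")
  expect_length(sp$values, 100)
  expect_equal(max(sp$values), 1)
  # constant profile scales to all ones
  const <- standardize_profile(raw_profile(c(0.2, 0.8), c(0.37, 0.37)))
  expect_equal(const$values, rep(1, 100))
  expect_error(standardize_profile(raw_profile(c(0.2, 0.8), c(0, 0))),
               "rejected")
})

test_that("a linear ramp standardizes to the closed-form line", {
  pos <- c(0, 0.07, 0.21, 0.4, 0.55, 0.83, 1)
  raw <- raw_profile(pos, 2 + 3 * pos)
  sp <- standardize_profile(raw)
  s <- seq(0, 1, length.out = 100)
  expect_equal(sp$values, (2 + 3 * s) / 5, tolerance = 1e-12)
})

test_that("noise-free extraction round-trips the true profile", {
  arch <- archetype_spec("blastula",
                         data.frame(name = c("Cd", "Er"),
                                    start = c(0, 0.45), end = c(0.3, 0.6),
                                    amplitude = c(0.8, 0.5)))
  for (depth in c(0, 0.3)) {
    sc <- generate_embryo_image(shape = embryo_shape(invagination_depth = depth),
                                archetype = arch, noise_sd = 0, seed = 1)
    p <- extract_profile(sc$image, sc$true_morphology)
    s <- seq(0, 1, length.out = 100)
    truth <- sc$true_profile(s)
    truth <- truth / max(truth)
    expect_lt(max(abs(p$values - truth)), 0.05)
  }
})
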