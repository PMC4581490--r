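arch_cd <- archetype_spec("blastula",
                          data.frame(name = "Cd", start = 0, end = 0.3,
                                     amplitude = 1))

test_that("null archetype with zero noise gives a constant background image", {
  arch0 <- archetype_spec("blastula",
                          data.frame(name = "Cd", start = 0, end = 0.3,
                                     amplitude = 0))
  sc <- generate_embryo_image(archetype = arch0, noise_sd = 0, seed = 1,
                              background = 0.1)
  expect_true(all(sc$image == 0.1))
})

test_that("in-layer staining equals the window function of arc position", {
  sh <- embryo_shape(width = 160, height = 160, center = c(50, 80),
                     outer_a = 55, outer_b = 62, layer_thickness = 18)
  sc <- generate_embryo_image(shape = sh, archetype = arch_cd, noise_sd = 0,
                              seed = 1, background = 0.1)
  # brute-force oracle: point-in-quad pixel enumeration over the true quads
  segs <- segment_cell_layer(sc$true_morphology, 20)
  oracle <- segment_means_oracle(sc$image, segs)
  # deep inside the window: amplitude + background; far outside: background
  deep <- oracle$mean[oracle$position < 0.25]
  out <- oracle$mean[oracle$position > 0.4]
  expect_true(all(abs(deep - 1.1) < 0.02))
  expect_true(all(abs(out - 0.1) < 0.02))
})

test_that("same seed is bit-identical; different seeds differ only in noise", {
  a <- generate_embryo_image(archetype = arch_cd, noise_sd = 0.05, seed = 7)
  b <- generate_embryo_image(archetype = arch_cd, noise_sd = 0.05, seed = 7)
  c <- generate_embryo_image(archetype = arch_cd, noise_sd = 0.05, seed = 8)
  clean <- generate_embryo_image(archetype = arch_cd, noise_sd = 0, seed = 7)
  expect_identical(a$image, b$image)
  expect_false(identical(a$image, c$image))
  # noise fields differ but share the same noise-free component:
  # both noisy images deviate from the clean one with mean ~0
  expect_lt(abs(mean(a$image - clean$image)), 0.005)
  expect_lt(abs(mean(c$image - clean$image)), 0.005)
})

test_that("geometry validation rejects a non-interior inner boundary", {
  expect_error(embryo_shape(layer_thickness = 200), "inner boundary")
})

test_that("profile sets honor count, zero-noise identity and the seed", {
  archs <- planted_archetypes("blastula", 4)
  ps <- generate_profile_set(archs, 3, noise_sd = 0, amplitude_jitter = 0,
                             seed = 1)
  expect_length(ps$profiles, 12)
  pos <- seq(0, 1, length.out = 100)
  for (k in 1:4) {
    expected <- archetype_intensity(archs[[k]], pos)
    expected <- expected / max(expected)
    idx <- which(ps$truth$archetype == paste0("A", k))
    for (i in idx) expect_equal(ps$profiles[[i]]$values, expected)
  }
  ps2 <- generate_profile_set(archs, 3, noise_sd = 0.1, seed = 5)
  ps3 <- generate_profile_set(archs, 3, noise_sd = 0.1, seed = 5)
  expect_identical(profile_matrix(ps2), profile_matrix(ps3))
})

test_that("all-zero archetype with zero noise is rejected", {
  arch0 <- archetype_spec("blastula",
                          data.frame(name = "Cd", start = 0, end = 0.3,
                                     amplitude = 0))
  expect_error(generate_profile_set(list(arch0), 2, noise_sd = 0),
               "cannot scale")
})

test_that("domain tables have full pair structure at availability 1", {
  sim <- generate_domain_table(25, kernel = transition_kernel(availability = 1),
                               seed = 3)
  expect_equal(nrow(sim$truth), 25 * 6)
  expect_equal(nrow(sim$table), 25 * 7)
  sim2 <- generate_domain_table(25, kernel = transition_kernel(availability = 1),
                                seed = 3)
  expect_identical(sim$table, sim2$table)
})

test_that("degenerate all-minor kernel classifies as all minor downstream", {
  sim <- generate_domain_table(40, kernel = transition_kernel(minor = 1, major = 0),
                               seed = 9)
  expect_true(all(sim$truth$category == "minor"))
  m <- build_pairwise_matrix(sim$table, filter = "all")
  expect_equal(sum(m[, , "minor"]), 40 * 6)
  expect_equal(sum(m), 40 * 6)
})

test_that("the downstream classifier reproduces the recorded ground truth", {
  sim <- generate_domain_table(
    60, kernel = transition_kernel(minor = 0.4, major = 0.3, appeared = 0.1,
                                   vanished = 0.1, none = 0.1,
                                   availability = 0.8),
    seed = 21)
  tab <- sim$table
  region_of <- function(gene, stage) {
    row <- tab[tab$gene == gene & tab$stage == stage, ]
    doms <- if (nzchar(row$domains)) strsplit(row$domains, ";")[[1]] else character(0)
    map_domains_to_regions(doms)$regions
  }
  got <- mapply(function(g, i, f) {
    classify_transition(region_of(g, i), region_of(g, f))
  }, sim$truth$gene, sim$truth$initial_stage, sim$truth$final_stage)
  expect_equal(unname(got), sim$truth$category)
})

test_that("invalid kernels are rejected", {
  expect_error(transition_kernel(minor = 0.5, major = 0.4), "sum to 1")
  expect_error(transition_kernel(availability = 1.2), "availability")
})
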