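test_that("sectional volume follows the area x thickness x interval formula", {
  # 8 sections of 1 mm^2 at 40 um thickness, sampling interval 5
  expect_equal(estimate_volume(section_set(rep(1, 8), "cortex")), 1.6)
  expect_equal(estimate_volume(section_set(rep(0, 8), "cortex")), 0)
  # linear in areas
  s1 <- section_set(runif(8, 1, 3), "cortex")
  s2 <- section_set(s1$areas_mm2 * 2, "cortex")
  expect_equal(estimate_volume(s2), 2 * estimate_volume(s1))
  # invariant to section-order reversal
  s3 <- section_set(rev(s1$areas_mm2), "cortex")
  expect_equal(estimate_volume(s3), estimate_volume(s1))
  # unusual section counts only warn
  expect_warning(section_set(rep(1, 5), "cortex"), "8 sections")
})

test_that("missing sections are imputed as the flanking mean", {
  s <- section_set(c(1, 2, NA, 4), "dHPC")
  # imputed section = (2 + 4)/2 = 3; volume = 10 * 0.04 * 5 = 2.0 mm^3
  expect_equal(estimate_volume(s), 2.0)
  expect_equal(mean_section_area(s), 2.5)
  # edge and consecutive gaps cannot be imputed
  expect_error(estimate_volume(section_set(c(NA, 2, 3, 4), "dHPC")),
               "first or last")
  expect_error(estimate_volume(section_set(c(1, NA, NA, 4), "dHPC")),
               "consecutive|tolerance")
  # more missing sections than tolerated
  expect_error(estimate_volume(
    suppressWarnings(section_set(c(1, NA, 3, NA, 5, NA, 7, 8), "cortex"))),
    "tolerance")
})

test_that("mean section area matches the protocol's averaging", {
  expect_equal(mean_section_area(section_set(c(2, 2, 2, 2), "dHPC")), 2)
  expect_equal(mean_section_area(
    suppressWarnings(section_set(3.5, "other"))), 3.5)
})

test_that("thickness aggregation equals independent means", {
  grid <- expand.grid(slice = 1:7, hemisphere = c("left", "right"),
                      point = c("dorsal", "lateral", "ventral"),
                      stringsAsFactors = FALSE)
  uniform <- transform(grid, thickness_mm = 1.2)
  for (by in c("overall", "point", "hemisphere"))
    expect_true(all(abs(aggregate_thickness(uniform, by)$mean_mm - 1.2) < 1e-12))
  # ventral thinnest when constructed so
  graded <- transform(grid, thickness_mm =
                        c(dorsal = 1.4, lateral = 1.2, ventral = 1.0)[point])
  ag <- aggregate_thickness(graded, "point")
  expect_equal(ag$mean_mm[ag$point == "ventral"], min(ag$mean_mm))
  # random table vs spreadsheet-style oracle
  set.seed(9)
  rnd <- transform(grid, thickness_mm = runif(nrow(grid), 0.8, 1.6))
  rnd$thickness_mm[c(3, 17)] <- NA
  ag2 <- aggregate_thickness(rnd, "hemisphere")
  for (h in c("left", "right")) {
    v <- rnd$thickness_mm[rnd$hemisphere == h]
    expect_equal(ag2$mean_mm[ag2$hemisphere == h], mean(v, na.rm = TRUE),
                 tolerance = 1e-12)
    expect_equal(ag2$n_missing[ag2$hemisphere == h], sum(is.na(v)))
  }
  # protocol limit: at most six measurements per section
  too_many <- rbind(uniform, data.frame(slice = 1, hemisphere = "left",
                                        point = "dorsal", thickness_mm = 1.1))
  expect_error(aggregate_thickness(too_many), "six")
})

test_that("particle counting recovers fixture ground truth", {
  blank <- simulate_section_image(0, seed = 1)
  expect_identical(count_particles(blank$image)$count, 0L)
  ten <- simulate_section_image(10, seed = 2)
  expect_identical(count_particles(ten$image)$count, 10L)
  # touching pairs: watershed separates, plain labelling fuses each pair
  mix <- simulate_section_image(0, n_touching_pairs = 3, seed = 4)
  expect_identical(count_particles(mix$image, watershed = TRUE)$count, 6L)
  expect_identical(count_particles(mix$image, watershed = FALSE)$count, 3L)
  expect_error(count_particles(mix$image, low = 200, high = 100), "low")
})

test_that("size and circularity filters act on components", {
  sim <- simulate_section_image(8, radius_px = c(5, 6), seed = 7)
  # a size floor above the disk areas removes everything
  expect_identical(count_particles(sim$image, size_px = c(500, Inf))$count, 0L)
  # disks are round: a high circularity floor keeps them
  expect_identical(count_particles(sim$image, circularity = c(0.7, 1))$count, 8L)
  # an impossible circularity band removes them
  expect_identical(count_particles(sim$image, circularity = c(0, 0.2))$count, 0L)
})

test_that("cell density is count over ROI area", {
  sim <- simulate_section_image(12, seed = 11)
  res <- count_particles(sim$image, roi_area_mm2 = 0.352)
  expect_equal(cell_density(res), res$count / 0.352)
  expect_equal(res$density_per_mm2, cell_density(res))
  # the published dorsal ROI worked example: 352 cells in 0.352 mm^2
  fake <- structure(list(count = 352L, roi_area_mm2 = 0.352,
                         density_per_mm2 = NA_real_, settings = list()),
                    class = "particle_count_result")
  expect_equal(cell_density(fake), 1000)
  expect_error(cell_density(count_particles(sim$image)), "ROI")
})
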