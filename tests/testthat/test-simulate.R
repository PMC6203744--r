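test_that("swim simulation is reproducible and respects trial invariants", {
  cfg <- swim_sim_config("RS")
  a <- simulate_swim(cfg, "N", 4, seed = 42)
  b <- simulate_swim(cfg, "N", 4, seed = 42)
  expect_identical(a, b)
  pool <- pool_arena()
  for (s in c("T", "RS", "C", "FS")) {
    tr <- simulate_swim(swim_sim_config(s), "W", 2, seed = 7)
    r <- sqrt(tr$x^2 + tr$y^2)
    expect_true(all(r <= arena_radius(pool) + 1))
    expect_true(all(diff(tr$t) > 0))
    expect_lte(tr$t[nrow(tr)] - tr$t[1], 60 + 1e-9)
  }
})

test_that("noise-free direct swim is an exact straight segment", {
  cfg <- swim_sim_config("DSw", heading_noise_sd = 0, speed_mps = 0.2)
  tr <- simulate_swim(cfg, "N", 4)
  expect_true(attr(tr, "escaped"))
  expect_equal(path_efficiency_ratio(tr), 1)
  expect_equal(corridor_percent_path(tr), 100)
})

test_that("thigmotaxis archetype hugs the wall", {
  tr <- simulate_swim(swim_sim_config("T"), "E", 1, seed = 11)
  wall_frac <- mean(distance_to_wall(cbind(tr$x, tr$y), pool_arena()) < 8)
  expect_gt(wall_frac, 0.9)
})

test_that("perseverance requires a previous platform position", {
  expect_error(simulate_swim(swim_sim_config("P"), "N", 4, seed = 1),
               "previous platform")
})

test_that("configuration bounds are enforced", {
  expect_error(swim_sim_config("DSw", speed_mps = 0), "speed")
  expect_error(swim_sim_config("DSw", dt_s = 0), "dt")
  expect_error(swim_sim_config("DSw", max_duration_s = 90), "60")
})

test_that("open-field generator emits consistent ground truth", {
  # no pause process -> no stops, and the detector agrees
  quiet <- simulate_open_field(duration_s = 300, pause_rate_hz = 0, seed = 2)
  expect_identical(attr(quiet, "n_true_stops"), 0L)
  expect_identical(count_stops(quiet), 0L)
  # path length equals the sum of step displacements by construction
  expect_equal(path_length(quiet),
               sum(sqrt(diff(quiet$x)^2 + diff(quiet$y)^2)) / 100)
  # detected stops equal emitted pauses
  of <- simulate_open_field(duration_s = 600, seed = 8)
  expect_identical(count_stops(of), attr(of, "n_true_stops"))
})

test_that("hyperactive open-field preset moves faster than control", {
  a <- simulate_open_field(duration_s = 600,
                           speed_mps = open_field_speed_presets()[["control"]],
                           seed = 3)
  b <- simulate_open_field(duration_s = 600,
                           speed_mps = open_field_speed_presets()[["hyperactive"]],
                           seed = 3)
  expect_gt(mean_speed(b), mean_speed(a))
})

test_that("stride series carry exact ground truth", {
  # zero spread: every stride is exactly the mean
  ss <- simulate_stride_series(5, stride_mean_cm = 8, stride_sd_cm = 0,
                               noise_cm = 0, seed = 1)
  expect_equal(attr(ss, "true_strides_cm"), rep(8, 5))
  # landings never pass the beam end
  ss2 <- simulate_stride_series(50, stride_mean_cm = 8, seed = 2)
  expect_lte(max(attr(ss2, "landing_positions_cm")), 92)
  expect_lt(length(attr(ss2, "true_strides_cm")), 50)
  expect_error(simulate_stride_series(0), "n_strides")
})

test_that("section-image fixtures have known counts and in-band intensities", {
  blank <- simulate_section_image(0, seed = 1)
  expect_identical(blank$count, 0L)
  expect_true(all(blank$image == 230))
  sim <- simulate_section_image(10, seed = 3)
  expect_identical(sim$count, 10L)
  fg <- sim$image[sim$image != 230]
  expect_true(all(fg >= 90 & fg <= 180))
  pairs <- simulate_section_image(0, n_touching_pairs = 3, seed = 5)
  expect_identical(pairs$count, 6L)
  expect_equal(sum(!is.na(pairs$pair_id)), 6)
})

test_that("cohort generator follows its mixtures and sizes", {
  # degenerate mixture: all direct swims, zero improvement
  mix <- matrix(0, 2, 8, dimnames = list(NULL, strategy_levels()))
  mix[, "DSw"] <- 1
  cfg <- cohort_sim_config(n_per_group = c(b6 = 2, btbr = 2), days = 2,
                           trials_per_day = 2,
                           mixtures = list(b6 = mix, btbr = mix))
  coh <- simulate_cohort(cfg, seed = 1)
  expect_true(all(coh$true_strategy == "DSw"))
  s <- strategy_summary(coh$true_strategy, coh$day)
  expect_equal(unname(s$spatial_percent_by_day), c(100, 100))
  expect_equal(s$improvement_rate_percent, 0)
  expect_equal(length(unique(coh$subject)), 4)
  # control-like preset: day-5 spatial share in the ground truth exceeds day 1
  coh2 <- simulate_cohort(cohort_sim_config(n_per_group = c(b6 = 6, btbr = 1)),
                          seed = 9)
  b6 <- coh2[coh2$group == "b6", ]
  sp <- strategy_summary(b6$true_strategy, b6$day)$spatial_percent_by_day
  expect_gt(sp[["5"]], sp[["1"]])
})

test_that("cohorts and their on-disk form are byte-identical across runs", {
  cfg <- cohort_sim_config(n_per_group = c(b6 = 2, btbr = 2), days = 2,
                           trials_per_day = 2)
  c1 <- simulate_cohort(cfg, seed = 5)
  c2 <- simulate_cohort(cfg, seed = 5)
  expect_identical(c1, c2)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  write_cohort(c1, d1); write_cohort(c2, d2)
  for (f in list.files(d1)) {
    expect_identical(readBin(file.path(d1, f), "raw", 1e6),
                     readBin(file.path(d2, f), "raw", 1e6))
  }
})
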