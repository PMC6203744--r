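test_that("path length and mean speed follow the polyline definition", {
  pool <- pool_arena()
  still <- trajectory(c(0, 30, 60), rep(10, 3), rep(10, 3), pool)
  expect_equal(path_length(still), 0)
  seg <- straight_trajectory(c(0, 50), c(0, -50), speed_cmps = 20)
  expect_equal(path_length(seg), 1)
  expect_equal(mean_speed(seg), 0.2)
})

test_that("binned speed partitions the session exactly", {
  of <- open_field_arena()
  tr <- straight_trajectory(c(-60, 0), c(60, 0), speed_cmps = 0.1,
                            dt = 30, arena = of)
  b <- binned_speed(tr, bin_s = 300)
  expect_length(b, 4)
  expect_equal(b, rep(0.001, 4), tolerance = 1e-9)
  expect_equal(mean(b), mean_speed(tr), tolerance = 1e-9)
  # partial final bins are rejected
  expect_error(binned_speed(straight_trajectory(c(0, 0), c(0, 50),
                                                speed_cmps = 0.1, arena = of),
                            bin_s = 300), "whole number")
  # mean over equal bins equals the overall mean even with pauses
  of2 <- simulate_open_field(duration_s = 1200, seed = 21)
  expect_equal(mean(binned_speed(of2)), mean_speed(of2), tolerance = 1e-9)
})

test_that("latency is the exact first platform crossing", {
  pool <- pool_arena()
  pl <- platform_center(pool, 4)
  # noise-free kinematics: latency = (direct distance - platform radius)/speed
  cfg <- swim_sim_config("DSw", heading_noise_sd = 0, speed_mps = 0.25)
  tr <- simulate_swim(cfg, "W", 4)
  d <- sqrt(sum((start_position(pool, "W") - pl)^2)) - 12
  expect_equal(as.numeric(latency(tr)), d / 25, tolerance = 1e-9)
  expect_false(attr(latency(tr), "censored"))
  # wall-hugging path never contacts the platform: censored at the cap
  thig <- simulate_swim(swim_sim_config("T"), "N", 4, seed = 3)
  lat <- latency(thig)
  expect_equal(as.numeric(lat), 60)
  expect_true(attr(lat, "censored"))
  # stochastic search path agrees with the dense-sampling first-crossing oracle
  fs <- simulate_swim(swim_sim_config("FS"), "S", 2, seed = 3)
  expect_equal(as.numeric(latency(fs)),
               oracle_first_crossing(fs, platform_center(pool, 2), 12),
               tolerance = 1e-3)
})

test_that("corridor percent path matches construction and oracle", {
  pool <- pool_arena()
  st <- start_position(pool, "N"); pl <- platform_center(pool, 4)
  direct <- straight_trajectory(st, pl, start_position = "N",
                                platform_quadrant = 4)
  expect_equal(corridor_percent_path(direct), 100)
  # a path in the far half of the pool, never in the corridor
  far <- straight_trajectory(c(-60, 10), c(-60, -10), start_position = "N",
                             platform_quadrant = 4)
  expect_equal(corridor_percent_path(far, start = st, platform = pl), 0)
  # wall orbit: small but nonzero, equal to the dense-sampling oracle
  orbit <- circle_trajectory(74, start_position = "N", platform_quadrant = 4)
  got <- corridor_percent_path(orbit, start = st, platform = pl)
  expect_gt(got, 0); expect_lt(got, 15)
  expect_equal(got, oracle_corridor_percent(orbit, st, pl), tolerance = 0.1)
  # in-corridor and off-corridor shares sum to 100 exactly
  rs <- simulate_swim(swim_sim_config("RS"), "N", 4, seed = 6)
  stq <- start_position(pool, "N")
  inpct <- corridor_percent_path(rs, st = stq, platform = pl)
  expect_equal(inpct + (100 - inpct), 100)
  expect_equal(inpct, oracle_corridor_percent(rs, stq, pl), tolerance = 0.1)
})

test_that("path efficiency ratio is the actual-over-direct length", {
  pool <- pool_arena()
  st <- c(0, 75); pl <- platform_center(pool, 4)
  direct <- straight_trajectory(st, pl)
  # measured to the platform centre a straight path scores exactly 1
  expect_equal(path_efficiency_ratio(direct, st, pl, platform_radius_cm = 0), 1)
  # a detour of exactly twice the direct length scores 2
  d <- sqrt(sum((pl - st)^2))
  perp <- c((pl - st)[2], -(pl - st)[1]) / d  # unit normal, pool-interior side
  mid <- (st + pl) / 2 + perp * (d * sqrt(3) / 2)
  dog <- trajectory(c(0, 5, 10), c(st[1], mid[1], pl[1]),
                    c(st[2], mid[2], pl[2]), pool)
  expect_equal(path_efficiency_ratio(dog, st, pl, platform_radius_cm = 0), 2,
               tolerance = 1e-9)
  # invariant under rigid rotation of the arena frame
  rs <- simulate_swim(swim_sim_config("RS"), "E", 2, seed = 31)
  th <- 0.7; Rm <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
  pts <- cbind(rs$x, rs$y) %*% t(Rm)
  rot <- trajectory(rs$t, pts[, 1], pts[, 2], pool)
  st2 <- as.numeric(Rm %*% start_position(pool, "E"))
  pl2 <- as.numeric(Rm %*% platform_center(pool, 2))
  expect_equal(path_efficiency_ratio(rot, st2, pl2, platform_radius_cm = 12),
               path_efficiency_ratio(rs), tolerance = 1e-9)
})

test_that("quadrant occupancy is exact and sums to 100", {
  pool <- pool_arena()
  # a probe path confined to quadrant 4
  q4 <- straight_trajectory(c(10, -40), c(40, -10), speed_cmps = 3)
  expect_equal(quadrant_occupancy(q4), c(0, 0, 0, 100))
  # centred orbit: exact quarter shares by symmetry
  orb <- circle_trajectory(40, n = 721, period_s = 30)
  expect_equal(quadrant_occupancy(orb), rep(25, 4), tolerance = 1e-6)
  # stochastic path: agrees with the dense-sampling oracle
  s <- simulate_swim(swim_sim_config("S"), "N", 4, seed = 12)
  occ <- quadrant_occupancy(s)
  expect_equal(sum(occ), 100, tolerance = 1e-9)
  expect_equal(occ, oracle_quadrant_occupancy(s), tolerance = 0.1)
})

test_that("central-zone path length clips segments at the zone boundary", {
  of <- open_field_arena()
  # chord through the centre: exactly the zone diameter lies inside
  chord <- straight_trajectory(c(-70, 0), c(70, 0), arena = of)
  expect_equal(central_zone_path(chord), 0.52, tolerance = 1e-9)
  # fully outside the zone
  ring <- circle_trajectory(60, arena = of)
  expect_equal(central_zone_path(ring), 0)
  # stochastic walk agrees with the dense-sampling oracle
  walk <- simulate_open_field(duration_s = 120, seed = 14)
  expect_equal(central_zone_path(walk) * 100,
               oracle_disk_path(walk, c(0, 0), 26), tolerance = 0.05)
})

test_that("stop counting finds inserted pauses", {
  of <- open_field_arena()
  tt <- seq(0, 60, by = 0.1)
  # constant walk above the 2 cm/s stop threshold: no stops
  run <- trajectory(tt, 2.2 * tt - 66, rep(0, length(tt)), of)
  expect_identical(count_stops(run), 0L)
  # one inserted 2-s pause
  x2 <- ifelse(tt < 30, 2.2 * tt - 66, ifelse(tt < 32, 0, 2.2 * (tt - 2) - 66))
  pause <- trajectory(tt, x2, rep(0, length(tt)), of)
  expect_identical(count_stops(pause), 1L)
})

test_that("stride extraction recovers generator ground truth", {
  # noise-free: strides recovered to within a hundredth of a centimetre
  ss <- simulate_stride_series(8, stride_mean_cm = 8, stride_sd_cm = 0,
                               noise_cm = 0, seed = 1)
  res <- extract_strides(ss)
  expect_equal(res$stride_lengths_cm, rep(8, 8), tolerance = 0.01 / 8)
  expect_equal(res$n_strides, 8)
  # noisy strides: mean within 0.2 cm of truth
  ss2 <- simulate_stride_series(10, stride_mean_cm = 8, stride_sd_cm = 0.5,
                                seed = 5)
  res2 <- extract_strides(ss2)
  expect_equal(res2$mean_stride_cm, mean(attr(ss2, "true_strides_cm")),
               tolerance = 0.2 / 8)
  expect_equal(res2$latency_s, ss2$t[nrow(ss2)] - ss2$t[1])
  # a continuous slide has no stance plateaus
  slide <- data.frame(t = seq(0, 3, by = 1 / 60))
  slide$x <- 2 + 25 * slide$t
  expect_error(extract_strides(slide), "stance")
})

test_that("metrics are stable across tracker sampling rates", {
  # resample one continuous path at different rates; headline metrics must
  # agree within 2%
  pool <- pool_arena()
  base <- simulate_swim(swim_sim_config("C", dt_s = 0.02,
                                        heading_noise_sd = 0), "N", 4,
                        seed = 8)
  st <- start_position(pool, "N"); pl <- platform_center(pool, 4)
  vals <- sapply(c(0.04, 0.1, 0.2), function(dt) {
    tt <- seq(base$t[1], base$t[nrow(base)], by = dt)
    tt <- unique(c(tt, base$t[nrow(base)]))
    tr <- trajectory(tt, approx(base$t, base$x, tt)$y,
                     approx(base$t, base$y, tt)$y, pool)
    c(len = path_length(tr),
      cor = corridor_percent_path(tr, st, pl),
      eff = path_efficiency_ratio(tr, st, pl, platform_radius_cm = 12))
  })
  for (i in 1:3)
    expect_lt(diff(range(vals[i, ])) / mean(vals[i, ]), 0.02)
})
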