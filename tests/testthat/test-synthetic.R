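test_that("simulation is deterministic and respects zero motion", {
  cfg <- sim_config(seed = 2, duration = 2)
  s1 <- simulate_larva(cfg)
  s2 <- simulate_larva(cfg)
  expect_identical(s1$keypoints, s2$keypoints)
  expect_identical(s1$bladder, s2$bladder)

  still <- simulate_larva(sim_config(seed = 2, duration = 1,
                                     speed_scale = 0,
                                     tail_beat_amplitude = 0))
  expect_true(all(apply(still$head, 2, function(x) diff(range(x))) == 0))
  expect_equal(max(abs(sweep(still$keypoints[, , "x"], 2,
                             still$keypoints[1, , "x"]))), 0)
})

test_that("trajectories stay inside the well and follow the depth prior", {
  cfg <- sim_config(seed = 4, duration = 20, depth_prior = "bottom")
  sim <- simulate_larva(cfg)
  g <- cfg$well
  expect_true(all(abs(sim$head[, 1]) <= g$well_footprint[1] / 2))
  expect_true(all(abs(sim$head[, 2]) <= g$well_footprint[2] / 2))
  expect_true(all(sim$head[, 3] >= 0 & sim$head[, 3] <= g$well_depth))
  # bottom prior: most frames in the lowest z quartile
  expect_gte(mean(sim$head[, 3] <= g$well_depth / 4), 0.9)
})

test_that("generated skeletons have near-constant body length", {
  sim <- simulate_larva(sim_config(seed = 6, duration = 5))
  expect_true(all(abs(sim$truth_length - sim$config$body_length) <
                    0.02 * sim$config$body_length))
})

test_that("noise-free rendering inverts exactly through triangulation", {
  cfg <- sim_config(seed = 10, duration = 2, pixel_sigma = 0, drop_rate = 0)
  sim <- simulate_larva(cfg)
  ct <- fixture_calib("top"); cs <- fixture_calib("side")
  rv <- render_views(sim, ct, cs)
  sk <- fuse_skeletons(rv$keypoints, ct, cs)
  for (i in seq_along(sim$frames)) {
    s <- sk[sk$frame == sim$frames[i], ]
    expect_equal(s$x, unname(sim$keypoints[i, , "x"]), tolerance = 1e-9)
    expect_equal(s$y, unname(sim$keypoints[i, , "y"]), tolerance = 1e-9)
    expect_equal(s$z, unname(sim$keypoints[i, , "z"]), tolerance = 1e-9)
  }
})

test_that("full pipeline closure reproduces generator kinematics", {
  cfg <- sim_config(seed = 12, duration = 5, pixel_sigma = 0, drop_rate = 0)
  sim <- simulate_larva(cfg)
  ct <- fixture_calib("top"); cs <- fixture_calib("side")
  rv <- render_views(sim, ct, cs)
  fk <- filter_keypoints(rv$keypoints)
  expect_false(fk$qc$excluded)
  sk <- fuse_skeletons(rv$keypoints, ct, cs)
  kin <- kinematics_summary(sk, cfg$fps, "3d")
  # generator-side reference speeds from the true eye midpoints
  ref <- (sim$keypoints[, "eye_left", ] + sim$keypoints[, "eye_right", ]) / 2
  truth_speed <- sqrt(rowSums(diff(ref)^2)) * cfg$fps
  expect_equal(unname(kin$speed_series), unname(truth_speed),
               tolerance = 1e-9)
})

test_that("likelihood demotion matches its binomial expectation", {
  cfg <- sim_config(seed = 20, duration = 50, drop_rate = 0.2)
  sim <- simulate_larva(cfg)
  ct <- fixture_calib("top"); cs <- fixture_calib("side")
  rv <- render_views(sim, ct, cs)
  fk <- filter_keypoints(rv$keypoints)
  n <- fk$qc$n_frames
  expect_equal(n, 1000)
  # a frame is invalid when any of its 16 keypoint-views was demoted
  p_invalid <- 1 - (1 - 0.2)^16
  n_invalid <- n - fk$qc$n_valid_frames
  ci <- stats::qbinom(c(0.005, 0.995), n, p_invalid)
  expect_gte(n_invalid, ci[1])
  expect_lte(n_invalid, ci[2])
})

test_that("edge targets are hard without blur and degrade with blur", {
  img <- make_edge_target(64, 5, 0)
  expect_equal(sort(unique(as.vector(img))), c(0.2, 0.8))
  b1 <- make_edge_target(64, 5, 1)
  expect_gt(length(unique(as.vector(b1))), 2)
  m0 <- mtf_from_edge(img, pixel_size = 10)
  m1 <- mtf_from_edge(b1, pixel_size = 10)
  at10 <- function(m) stats::approx(m$frequencies, m$modulation, 10)$y
  expect_lt(at10(m1), at10(m0))
})
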