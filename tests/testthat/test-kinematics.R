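test_that("reference point is the eye midpoint and rotation-equivariant", {
  xyz <- straight_fish_mm()
  s <- skeleton_from_mm(xyz)
  rp <- reference_point(s)
  eye <- (xyz[2, ] + xyz[3, ]) / 2
  expect_equal(unname(rp), unname(eye))

  # rotate the whole skeleton about z: midpoint rotates with it
  th <- 0.7
  Rz <- matrix(c(cos(th), sin(th), 0, -sin(th), cos(th), 0, 0, 0, 1), 3, 3)
  s2 <- skeleton_from_mm(xyz %*% t(Rz))
  expect_equal(unname(reference_point(s2)), unname(as.numeric(eye %*% t(Rz))),
               tolerance = 1e-12)

  bad <- s
  bad$valid[bad$keypoint == "eye_left"] <- FALSE
  expect_error(reference_point(bad), "eyes")
})

test_that("displacement, speed and acceleration follow the frame rate", {
  # stationary
  tr <- trajectory(matrix(rep(c(1, 2, 3), 10), ncol = 3, byrow = TRUE), 20)
  ds <- displacement_series(tr)
  expect_true(all(ds$speed == 0))
  expect_equal(ds$total_distance, 0)

  # uniform 0.1 mm/frame at 20 fps -> 2 mm/s, zero acceleration
  p <- cbind(seq(0, 0.9, by = 0.1), 0, 0)
  ds2 <- displacement_series(trajectory(p, 20))
  expect_equal(ds2$speed, rep(2, 9), tolerance = 1e-12)
  expect_equal(ds2$acceleration, rep(0, 8), tolerance = 1e-9)
  expect_equal(ds2$total_distance, 0.9, tolerance = 1e-12)

  expect_error(displacement_series(trajectory(matrix(1:3, 1), 20)),
               "at least 2")
})

test_that("helix mean speed matches the closed-form arc speed", {
  fps <- 20; R <- 2; omega <- 2; c_ <- 0.5
  t <- seq(0, 10, by = 1 / fps)
  p <- cbind(R * cos(omega * t), R * sin(omega * t), c_ * t)
  ds <- displacement_series(trajectory(p, fps))
  expect_equal(mean(ds$speed), sqrt(R^2 * omega^2 + c_^2),
               tolerance = 0.01)
})

test_that("tail angle matches plane geometry and collapses under projection", {
  xyz <- straight_fish_mm()
  expect_equal(tail_angle(skeleton_from_mm(xyz)), 0, tolerance = 1e-9)

  # nostril (0,0), reference (1,0), tail4 (1,1): 45 degrees
  xyz45 <- xyz
  xyz45[1, ] <- c(0, 0, 0)            # nostril
  xyz45[2, ] <- c(1, 0.24, 0)         # eyes straddle the reference (1,0,0)
  xyz45[3, ] <- c(1, -0.24, 0)
  xyz45[8, ] <- c(1, 1, 0)            # tail tip
  expect_equal(tail_angle(skeleton_from_mm(xyz45)), 45, tolerance = 1e-9)

  # purely vertical bend: 3D angle exceeds the top-view 2D angle
  xyzv <- xyz
  xyzv[8, 3] <- xyzv[8, 3] + 1.5
  s <- skeleton_from_mm(xyzv)
  expect_gt(tail_angle(s, "3d"), tail_angle(s, "top"))

  # rigid rotation invariance in 3D
  th <- 0.5
  Rz <- matrix(c(cos(th), sin(th), 0, -sin(th), cos(th), 0, 0, 0, 1), 3, 3)
  expect_equal(tail_angle(skeleton_from_mm(xyzv %*% t(Rz)), "3d"),
               tail_angle(s, "3d"), tolerance = 1e-9)
})

test_that("bout counting matches a brute-force run-length oracle", {
  expect_equal(count_moves(rep(0, 50)), 0)
  burst <- c(rep(0, 5), rep(5, 5), rep(0, 5))
  expect_equal(count_moves(burst), 1)
  # one-frame spikes are discarded by the minimum-duration rule
  expect_equal(count_moves(c(0, 5, 0, 5, 0)), 0)

  set.seed(21)
  for (rep_i in 1:5) {
    sp <- runif(200, 0, 5)
    got <- count_moves(sp, 2, 3)
    # independent oracle: explicit scan
    cnt <- 0L; run <- 0L
    for (v in sp) {
      if (v > 2) run <- run + 1L
      else { if (run >= 3) cnt <- cnt + 1L; run <- 0L }
    }
    if (run >= 3) cnt <- cnt + 1L
    expect_equal(got, cnt)
  }
})

test_that("occupancy heatmap conserves counts and localizes mass", {
  g <- plate_geometry()
  p1 <- matrix(c(0, 0, 6), 1)
  h1 <- occupancy_heatmap(trajectory(p1, 20), c(4, 4, 6), g)
  expect_equal(sum(h1), 1)
  expect_equal(sum(h1 > 0), 1)

  set.seed(3)
  p <- cbind(runif(500, -3.9, 3.9), runif(500, -3.9, 3.9),
             runif(500, 0.1, 11.9))
  h <- occupancy_heatmap(trajectory(p, 20), c(8, 8, 12), g)
  expect_equal(sum(h), 500)

  # bottom-dwelling fixture concentrates in the lowest z quartile
  pb <- cbind(runif(400, -3, 3), runif(400, -3, 3), runif(400, 0.2, 2.5))
  hb <- occupancy_heatmap(trajectory(pb, 20), c(4, 4, 12), g)
  expect_gt(sum(hb[, , 1:3]) / sum(hb), 0.9)
})

test_that("depth profile reports per-time mean and sample SD", {
  t1 <- trajectory(cbind(0, 0, rep(2, 10)), 20)
  t2 <- trajectory(cbind(0, 0, rep(4, 10)), 20)
  dp <- depth_profile(list(t1, t2))
  expect_equal(dp$mean_z, rep(3, 10))
  expect_equal(dp$sd_z, rep(sqrt(2), 10), tolerance = 1e-12)
  dp_same <- depth_profile(list(t1, t1, t1))
  expect_equal(dp_same$sd_z, rep(0, 10))
  expect_error(depth_profile(list()), "empty")
})

test_that("groups with distinct simulated depth priors separate clearly", {
  cfg_b <- sim_config(seed = 5, duration = 10, depth_prior = "bottom")
  cfg_s <- sim_config(seed = 6, duration = 10, depth_prior = "surface")
  zb <- simulate_larva(cfg_b)$head[, 3]
  zs <- simulate_larva(cfg_s)$head[, 3]
  expect_gt(mean(zs) - mean(zb), 2 * max(sd(zb), sd(zs)))
})

test_that("Mann-Whitney comparison matches the exact small-sample test", {
  set.seed(9)
  a <- rnorm(8); b <- rnorm(8) + 10
  gc <- group_compare(a, b)
  expect_equal(gc$U, 0)
  expect_equal(gc$p, 2 / choose(16, 8), tolerance = 1e-12)

  same <- group_compare(1:8, 1:8)
  expect_gt(same$p, 0.9)

  # exact and normal-approximation paths agree for untied n = 8
  a2 <- rnorm(8); b2 <- rnorm(8) + 0.8
  p_exact <- group_compare(a2, b2)$p
  p_norm <- stats::wilcox.test(a2, b2, exact = FALSE, correct = TRUE)$p.value
  expect_lt(abs(p_exact - p_norm), 0.01)
  expect_error(group_compare(1, 1:4), ">= 2")
})
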