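test_that("likelihood QC counts valid frames and applies the 1/3 rule", {
  # 30 frames, 12 carrying a 0.5-likelihood keypoint: 18 valid, and
  # 12 invalid > 30/3 = 10, so the video is excluded
  tab <- make_qc_table(30, bad_frames = 0:11)
  fk <- filter_keypoints(tab)
  expect_equal(fk$qc$n_valid_frames, 18)
  expect_true(fk$qc$excluded)
  expect_equal(sort(fk$valid_frames), 12:29)

  # all likelihoods 1: nothing excluded
  fk2 <- filter_keypoints(make_qc_table(30))
  expect_equal(fk2$qc$n_valid_frames, 30)
  expect_false(fk2$qc$excluded)

  # brute-force recount on a mixed fixture
  set.seed(11)
  tab3 <- make_qc_table(50, bad_frames = sample(0:49, 15))
  fk3 <- filter_keypoints(tab3)
  recount <- sum(vapply(0:49, function(f) {
    all(tab3$likelihood[tab3$frame == f] > 0.7)
  }, logical(1)))
  expect_equal(fk3$qc$n_valid_frames, recount)
})

test_that("retention is strict: likelihood exactly 0.70 is invalid", {
  tab <- make_qc_table(3, bad_frames = 1, bad_value = 0.70)
  fk <- filter_keypoints(tab, threshold = 0.7)
  expect_false(1 %in% fk$valid_frames)
  expect_equal(fk$qc$n_valid_frames, 2)
})

test_that("QC rejects empty and malformed tables", {
  expect_error(filter_keypoints(data.frame()), "columns")
  tab <- make_qc_table(2)
  tab$keypoint[1] <- "dorsal_fin"
  expect_error(filter_keypoints(tab), "dorsal_fin")
})

test_that("triangulation fuses x/z and averages the shared y", {
  ct <- fixture_calib("top"); cs <- fixture_calib("side")
  xyz <- straight_fish_mm(z = 3, y = 2)
  top <- kp_frame(0, "top", cbind(xyz[, 1], xyz[, 2]), 1, ct)
  side <- kp_frame(0, "side", cbind(xyz[, 2], xyz[, 3]), 1, cs)
  s <- triangulate(top, side, ct, cs)
  expect_equal(s$x, unname(xyz[, 1]), tolerance = 1e-9)
  expect_equal(s$y, unname(xyz[, 2]), tolerance = 1e-9)
  expect_equal(s$z, unname(xyz[, 3]), tolerance = 1e-9)
  expect_equal(s$y_residual, rep(0, 8), tolerance = 1e-9)

  # y disagreement between views: mean and residual
  side2 <- kp_frame(0, "side", cbind(xyz[, 2] + 0.4, xyz[, 3]), 1, cs)
  s2 <- triangulate(top, side2, ct, cs)
  expect_equal(s2$y, unname(xyz[, 2]) + 0.2, tolerance = 1e-9)
  expect_equal(s2$y_residual, rep(0.4, 8), tolerance = 1e-9)

  side3 <- side2
  side3$frame <- 5
  expect_error(triangulate(top, side3, ct, cs), "frame_index")
})

test_that("a large y residual triggers the consistency warning", {
  ct <- fixture_calib("top"); cs <- fixture_calib("side")
  xyz <- straight_fish_mm()
  top <- kp_frame(0, "top", cbind(xyz[, 1], xyz[, 2]), 1, ct)
  side <- kp_frame(0, "side", cbind(xyz[, 2] + 0.8, xyz[, 3]), 1, cs)
  expect_warning(triangulate(top, side, ct, cs), "residual")
})

test_that("skeleton length follows the body polyline and contracts under projection", {
  # straight fish on the x axis spanning 4 mm
  s <- skeleton_from_mm(straight_fish_mm(z = 6))
  expect_equal(skeleton_length(s, "3d"), 4, tolerance = 1e-12)
  expect_equal(skeleton_length(s, "top"), 4, tolerance = 1e-12)

  # tilted fish: projections are strictly shorter
  xyz <- straight_fish_mm()
  tilt <- xyz
  tilt[, 3] <- tilt[, 3] + 0.5 * tilt[, 1]
  st <- skeleton_from_mm(tilt)
  l3 <- skeleton_length(st, "3d")
  expect_lt(skeleton_length(st, "top"), l3)
  expect_lte(skeleton_length(st, "side"), l3)

  bad <- skeleton_from_mm(xyz)
  bad$valid[bad$keypoint == "tail2"] <- FALSE
  expect_error(skeleton_length(bad), "tail2")
})

test_that("keypoint evaluation matches a direct-sum oracle", {
  truth <- make_qc_table(5)
  ev0 <- evaluate_keypoints(truth, truth)
  expect_equal(ev0$rmse_px, 0)
  expect_true(all(ev0$detection_rates == 1))

  off <- truth
  off$u <- off$u + 3
  ev3 <- evaluate_keypoints(off, truth)
  expect_equal(ev3$rmse_px, 3, tolerance = 1e-12)
  expect_equal(unname(ev3$detection_rates), c(1, 1, 1))

  set.seed(4)
  pred <- truth
  n <- nrow(pred)
  pred$u <- pred$u + rnorm(n, 0, 2)
  pred$v <- pred$v + rnorm(n, 0, 2)
  ev <- evaluate_keypoints(pred, truth)
  # brute-force accumulation over the same samples
  du <- pred$u - truth$u; dv <- pred$v - truth$v
  expect_equal(ev$rmse_px, sqrt(sum(du^2 + dv^2) / n), tolerance = 1e-12)
  err <- sqrt(du^2 + dv^2)
  expect_equal(unname(ev$detection_rates),
               c(mean(err <= 3), mean(err <= 5), mean(err <= 10)))

  expect_error(evaluate_keypoints(truth, transform(truth, frame = frame + 99)),
               "overlapping")
})
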