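# Shared fixtures: a calibration with a round object pixel size
# (m = 0.11 with 1.1 um pitch gives exactly 10 um/px = 0.01 mm/px),
# and builders for keypoint tables with prescribed likelihoods.

fixture_cam <- function() {
  camera_model(focal_length = 25.05, nominal_object_distance = 240,
               sensor_pixel_pitch = 1.1)
}

# object distance chosen so that magnification is exactly 0.11
fixture_calib <- function(view = "top") {
  cam <- fixture_cam()
  d <- cam$focal_length / 0.11 + cam$focal_length
  view_calibration(view, cam, object_distance = d)
}

mm_per_px <- function(calib) calib$object_pixel_size / 1000

# one frame-view keypoint table; positions mm -> px via the calibration
kp_frame <- function(frame, view, xy_mm, likelihood = 1, calib = NULL) {
  if (is.null(calib)) calib <- fixture_calib(view)
  px <- world_to_pixel(calib, xy_mm[, 1], xy_mm[, 2])
  data.frame(frame = frame, view = view, keypoint = larva_keypoints,
             u = px[, 1], v = px[, 2],
             likelihood = rep_len(likelihood, 8))
}

# a straight larva skeleton lying along +x at height z, length 4 mm
straight_fish_mm <- function(z = 6, y = 0) {
  s <- c(0, 0.35, 0.35, 1.2, 1.9, 2.6, 3.3, 4.0)
  lat <- c(0, 0.24, -0.24, 0, 0, 0, 0, 0)
  cbind(x = 4 - s, y = y + lat, z = z)
}

# build a skeleton3d data frame directly from 3D mm coordinates
skeleton_from_mm <- function(xyz, frame = 0, valid = TRUE) {
  out <- data.frame(frame = frame, keypoint = larva_keypoints,
                    x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
                    valid = rep_len(valid, 8), y_residual = 0)
  class(out) <- c("skeleton3d", class(out))
  out
}

# n-frame dual-view table where selected frames carry one sub-threshold
# keypoint in the top view
make_qc_table <- function(n_frames, bad_frames = integer(0),
                          bad_value = 0.5) {
  do.call(rbind, lapply(seq_len(n_frames) - 1L, function(f) {
    lik_top <- rep(1, 8)
    if (f %in% bad_frames) lik_top[3] <- bad_value
    xyz <- straight_fish_mm()
    rbind(kp_frame(f, "top", cbind(xyz[, 1], xyz[, 2]), lik_top),
          kp_frame(f, "side", cbind(xyz[, 2], xyz[, 3]), 1))
  }))
}

# dual-view keypoint table for a 3D skeleton (exact projection, no noise)
dual_view_kps <- function(xyz, frame = 0, likelihood = 1,
                          calib_top = fixture_calib("top"),
                          calib_side = fixture_calib("side")) {
  rbind(
    kp_frame(frame, "top", cbind(xyz[, 1], xyz[, 2]), likelihood, calib_top),
    kp_frame(frame, "side", cbind(xyz[, 2], xyz[, 3]), likelihood, calib_side)
  )
}
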