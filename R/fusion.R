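#' Larva keypoint names
#'
#' The eight tracked landmarks: one midline nostril point, both eyes, the
#' swim bladder, and four points along the tail.
#' @export
larva_keypoints <- c("nostril", "eye_left", "eye_right", "swim_bladder",
                     "tail1", "tail2", "tail3", "tail4")

check_keypoint_table <- function(keypoints) {
  need <- c("frame", "view", "keypoint", "u", "v", "likelihood")
  if (!is.data.frame(keypoints) || !all(need %in% names(keypoints))) {
    stop("keypoints must be a data frame with columns ",
         paste(need, collapse = ", "))
  }
  if (nrow(keypoints) == 0) stop("empty keypoint table")
  bad_kp <- setdiff(unique(keypoints$keypoint), larva_keypoints)
  if (length(bad_kp)) stop("unknown keypoint name(s): ",
                           paste(bad_kp, collapse = ", "))
  bad_v <- setdiff(unique(keypoints$view), c("top", "side"))
  if (length(bad_v)) stop("unknown view name(s): ",
                          paste(bad_v, collapse = ", "))
  if (any(keypoints$likelihood < 0 | keypoints$likelihood > 1, na.rm = TRUE)) {
    stop("likelihood must lie in [0, 1]")
  }
  invisible(keypoints)
}

#' Likelihood-based keypoint quality control
#'
#' A frame-view passes QC only when all eight keypoints have detector
#' likelihood strictly greater than the threshold; a frame is valid when it
#' passes in every view present. The whole video is flagged for exclusion
#' when more than one-third of its frames are invalid.
#'
#' @param keypoints Data frame with columns `frame`, `view`, `keypoint`,
#'   `u`, `v`, `likelihood` (the keypoint CSV dialect).
#' @param threshold Likelihood threshold; retention requires likelihood
#'   `> threshold` (strict). Default 0.7.
#' @return A list with `valid_frames` (sorted frame indices valid in all
#'   views), `frame_view_valid` (data frame `frame`, `view`, `valid`), and
#'   `qc`, an object of class `track_qc` with fields `n_frames`,
#'   `n_valid_frames`, `excluded` and `per_keypoint_pass_rate`.
#' @export
filter_keypoints <- function(keypoints, threshold = 0.7) {
  check_keypoint_table(keypoints)
  stopifnot(threshold >= 0, threshold <= 1)
  pass <- keypoints$likelihood > threshold
  key <- paste(keypoints$frame, keypoints$view)
  fv_valid <- tapply(pass, key, function(p) length(p) == 8L && all(p))
  fv <- unique(keypoints[c("frame", "view")])
  fv$valid <- as.logical(fv_valid[paste(fv$frame, fv$view)])

  frames <- sort(unique(keypoints$frame))
  frame_valid <- tapply(fv$valid, factor(fv$frame, levels = frames), all)
  valid_frames <- frames[as.logical(frame_valid)]

  n_frames <- length(frames)
  n_valid <- length(valid_frames)
  rate <- tapply(pass, keypoints$keypoint, mean)
  qc <- structure(list(
    n_frames = n_frames,
    n_valid_frames = n_valid,
    excluded = (n_frames - n_valid) > n_frames / 3,
    per_keypoint_pass_rate = rate[larva_keypoints]
  ), class = "track_qc")
  list(valid_frames = valid_frames, frame_view_valid = fv, qc = qc)
}

#' @export
print.track_qc <- function(x, ...) {
  cat(sprintf("Track QC: %d/%d frames valid (%.1f%%)%s\n",
              x$n_valid_frames, x$n_frames,
              100 * x$n_valid_frames / max(1, x$n_frames),
              if (x$excluded) " -- video EXCLUDED (>1/3 invalid)" else ""))
  invisible(x)
}

frame_view_subset <- function(keypoints, frame, view) {
  out <- keypoints[keypoints$frame == frame & keypoints$view == view, ]
  out[match(larva_keypoints, out$keypoint), ]
}

#' Fuse one pair of top/side keypoint frames into a 3D skeleton
#'
#' Converts pixel detections of both views to millimetres through the view
#' calibrations and assigns world coordinates: x from the top view, z from
#' the side view, and y as the unweighted mean of the two views' shared y
#' readings. The per-keypoint gap between the two y readings is recorded as
#' a consistency residual; a warning is raised when it exceeds 0.5 mm.
#'
#' @param top,side Keypoint tables for one frame and one view each (8 rows,
#'   same `frame` value).
#' @param calib_top,calib_side [view_calibration()] objects.
#' @param threshold Likelihood threshold for per-keypoint validity
#'   (strict `>`).
#' @param residual_warn_mm Warn when any y residual exceeds this (mm).
#' @return A data frame of class `skeleton3d`: `frame`, `keypoint`, `x`,
#'   `y`, `z` (mm), `valid`, `y_residual` (mm).
#' @export
triangulate <- function(top, side, calib_top, calib_side,
                        threshold = 0.7, residual_warn_mm = 0.5) {
  stopifnot(nrow(top) == 8L, nrow(side) == 8L)
  if (length(unique(c(top$frame, side$frame))) != 1L) {
    stop("top and side frames have mismatched frame_index")
  }
  top <- top[match(larva_keypoints, top$keypoint), ]
  side <- side[match(larva_keypoints, side$keypoint), ]
  tp <- pixel_to_world(calib_top, top$u, top$v)
  sp <- pixel_to_world(calib_side, side$u, side$v)
  wf <- world_frame_assign(tp, sp)
  y_res <- abs(wf[, "y_top"] - wf[, "y_side"])
  valid <- top$likelihood > threshold & side$likelihood > threshold
  if (any(y_res[valid] > residual_warn_mm)) {
    warning(sprintf("y-consistency residual exceeds %.1f mm for: %s",
                    residual_warn_mm,
                    paste(larva_keypoints[valid & y_res > residual_warn_mm],
                          collapse = ", ")))
  }
  out <- data.frame(
    frame = top$frame[1],
    keypoint = larva_keypoints,
    x = wf[, "x"],
    y = (wf[, "y_top"] + wf[, "y_side"]) / 2,
    z = wf[, "z"],
    valid = valid,
    y_residual = y_res,
    row.names = NULL
  )
  class(out) <- c("skeleton3d", class(out))
  out
}

#' Fuse a full keypoint table into a 3D skeleton series
#'
#' Applies [triangulate()] to every frame present in both views.
#'
#' @inheritParams filter_keypoints
#' @inheritParams triangulate
#' @return A `skeleton3d` data frame over all common frames.
#' @export
fuse_skeletons <- function(keypoints, calib_top, calib_side,
                           threshold = 0.7) {
  check_keypoint_table(keypoints)
  frames <- intersect(unique(keypoints$frame[keypoints$view == "top"]),
                      unique(keypoints$frame[keypoints$view == "side"]))
  if (!length(frames)) stop("no frames present in both views")
  out <- do.call(rbind, lapply(sort(frames), function(f) {
    triangulate(frame_view_subset(keypoints, f, "top"),
                frame_view_subset(keypoints, f, "side"),
                calib_top, calib_side, threshold = threshold)
  }))
  class(out) <- c("skeleton3d", class(out))
  out
}

skeleton_one_frame <- function(s) {
  if (length(unique(s$frame)) != 1L) {
    stop("expected a single-frame skeleton; got ",
         length(unique(s$frame)), " frames")
  }
  s[match(larva_keypoints, s$keypoint), ]
}

#' Skeleton polyline length
#'
#' Body length along the polyline nostril -> eye midpoint -> swim bladder ->
#' tail1 -> tail2 -> tail3 -> tail4, in 3D or projected to one view plane.
#' A 2D projected length never exceeds the 3D length.
#'
#' @param s A single-frame `skeleton3d` (from [triangulate()]).
#' @param mode `"3d"`, `"top"` (x-y plane) or `"side"` (y-z plane).
#' @return Length in mm.
#' @export
skeleton_length <- function(s, mode = c("3d", "top", "side")) {
  mode <- match.arg(mode)
  s <- skeleton_one_frame(s)
  need <- c("nostril", "eye_left", "eye_right", "swim_bladder",
            "tail1", "tail2", "tail3", "tail4")
  miss <- need[!s$valid[match(need, s$keypoint)] |
                 is.na(s$valid[match(need, s$keypoint)])]
  if (length(miss)) stop("invalid keypoint(s) on the length path: ",
                         paste(miss, collapse = ", "))
  pt <- function(name) unlist(s[s$keypoint == name, c("x", "y", "z")])
  eye_mid <- (pt("eye_left") + pt("eye_right")) / 2
  path <- rbind(pt("nostril"), eye_mid, pt("swim_bladder"),
                pt("tail1"), pt("tail2"), pt("tail3"), pt("tail4"))
  path <- switch(mode,
                 "3d" = path,
                 "top" = path[, c(1, 2)],
                 "side" = path[, c(2, 3)])
  sum(sqrt(rowSums(diff(path)^2)))
}

#' Keypoint accuracy against ground truth
#'
#' Matches predicted and true detections on (frame, view, keypoint) and
#' reports the Euclidean pixel RMSE plus distance-threshold detection rates
#' (fraction of keypoints within 3, 5 and 10 px of truth). The detection
#' rates are deliberately not called mAP/mAR: they are plain distance
#' thresholds, not an average-precision matching rule.
#'
#' @param predicted,truth Keypoint tables (columns `frame`, `view`,
#'   `keypoint`, `u`, `v`).
#' @param tolerances_px Pixel radii for the detection rates.
#' @return List with `rmse_px`, `detection_rates` (named by tolerance) and
#'   `n_matched`.
#' @export
evaluate_keypoints <- function(predicted, truth,
                               tolerances_px = c(3, 5, 10)) {
  key <- function(d) paste(d$frame, d$view, d$keypoint, sep = "\r")
  m <- match(key(predicted), key(truth))
  ok <- !is.na(m)
  if (!any(ok)) stop("no overlapping (frame, view, keypoint) entries")
  du <- predicted$u[ok] - truth$u[m[ok]]
  dv <- predicted$v[ok] - truth$v[m[ok]]
  err <- sqrt(du^2 + dv^2)
  rates <- vapply(tolerances_px, function(tol) mean(err <= tol), numeric(1))
  names(rates) <- paste0("within_", tolerances_px, "px")
  list(rmse_px = sqrt(mean(err^2)), detection_rates = rates,
       n_matched = sum(ok))
}
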