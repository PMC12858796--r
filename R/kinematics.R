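#' Larva reference point
#'
#' The midpoint of the line connecting the two eyes, used as the kinematic
#' reference point: the head is the only rigid part of the larva's body.
#'
#' @param s A single-frame `skeleton3d`.
#' @return Named numeric (x, y, z) in mm.
#' @export
reference_point <- function(s) {
  s <- skeleton_one_frame(s)
  el <- s[s$keypoint == "eye_left", ]
  er <- s[s$keypoint == "eye_right", ]
  if (!isTRUE(el$valid) || !isTRUE(er$valid)) {
    stop("both eyes must be valid to form the reference point")
  }
  c(x = (el$x + er$x) / 2, y = (el$y + er$y) / 2, z = (el$z + er$z) / 2)
}

#' Trajectory container
#'
#' A per-frame reference-point track at a fixed frame rate. For 2D mode the
#' z column is dropped from all computations (top-view projection).
#'
#' @param positions Numeric matrix, one row per frame, columns x, y, z
#'   (mm); for 2D mode a 2-column (x, y) matrix is also accepted.
#' @param fps Frame rate in Hz.
#' @param mode `"3d"` or `"2d"`.
#' @param frames Optional frame indices (default `0:(n-1)`).
#' @return Object of class `trajectory` with fields `times` (s),
#'   `positions`, `fps`, `mode`.
#' @export
trajectory <- function(positions, fps, mode = c("3d", "2d"), frames = NULL) {
  mode <- match.arg(mode)
  positions <- as.matrix(positions)
  stopifnot(fps > 0, nrow(positions) >= 1)
  if (mode == "2d" && ncol(positions) == 3) positions <- positions[, 1:2]
  if (is.null(frames)) frames <- seq_len(nrow(positions)) - 1L
  stopifnot(!is.unsorted(frames, strictly = TRUE))
  structure(list(times = frames / fps, positions = positions,
                 fps = fps, mode = mode),
            class = "trajectory")
}

#' Displacement, speed and acceleration series
#'
#' Inter-frame Euclidean displacement of the reference point; speed is
#' displacement times frame rate; acceleration is the signed forward
#' difference of the speed series times frame rate (a scalar rate of change
#' of speed, not a vector second derivative). Total travel distance is the
#' sum of displacements. Frames with non-finite positions are treated as
#' QC failures: only consecutive valid pairs contribute.
#'
#' @param traj A [trajectory()].
#' @return List with `displacement` (mm, length n-1), `speed` (mm/s,
#'   length n-1), `acceleration` (mm/s^2, length n-2) and
#'   `total_distance` (mm).
#' @export
displacement_series <- function(traj) {
  stopifnot(inherits(traj, "trajectory"))
  p <- traj$positions
  if (nrow(p) < 2) stop("need at least 2 frames for displacement")
  d <- sqrt(rowSums(diff(p)^2))
  valid_pair <- apply(is.finite(diff(p)), 1, all)
  d[!valid_pair] <- NA_real_
  speed <- d * traj$fps
  accel <- diff(speed) * traj$fps
  list(displacement = d,
       speed = speed,
       acceleration = accel,
       total_distance = sum(d, na.rm = TRUE))
}

#' Tail angle
#'
#' The forward vector runs from the nostril to the reference point (eye
#' midpoint); the tail angle is the angle between this vector and the line
#' from the nostril to the tail tip, in degrees in `[0, 180]`. 2D mode
#' projects both vectors to a view plane first, which collapses vertical
#' bending.
#'
#' @param s A single-frame `skeleton3d`.
#' @param mode `"3d"`, `"top"` (x-y) or `"side"` (y-z).
#' @param tail_keypoint Which tail point defines the tail line (default the
#'   tip, `"tail4"`).
#' @return Angle in degrees.
#' @export
tail_angle <- function(s, mode = c("3d", "top", "side"),
                       tail_keypoint = "tail4") {
  mode <- match.arg(mode)
  s <- skeleton_one_frame(s)
  nos <- s[s$keypoint == "nostril", ]
  tl <- s[s$keypoint == tail_keypoint, ]
  if (!isTRUE(nos$valid) || !isTRUE(tl$valid)) {
    stop("nostril and ", tail_keypoint, " must be valid")
  }
  ref <- reference_point(s)
  n <- c(nos$x, nos$y, nos$z)
  v1 <- ref - n
  v2 <- c(tl$x, tl$y, tl$z) - n
  proj <- switch(mode, "3d" = 1:3, "top" = 1:2, "side" = 2:3)
  v1 <- v1[proj]; v2 <- v2[proj]
  n1 <- sqrt(sum(v1^2)); n2 <- sqrt(sum(v2^2))
  if (n1 == 0 || n2 == 0) stop("zero-length vector in tail angle")
  acos(pmin(1, pmax(-1, sum(v1 * v2) / (n1 * n2)))) * 180 / pi
}

#' Count movement bouts
#'
#' A "move" is a maximal contiguous run of frames with speed above a
#' threshold, lasting at least a minimum number of frames. Both settings
#' are analysis choices (the bout rule is not a measured quantity) and are
#' configurable.
#'
#' @param speed_series Speed in mm/s (NAs break runs).
#' @param speed_threshold Speed threshold in mm/s (default 2).
#' @param min_duration_frames Minimum run length in frames (default 2).
#' @return Integer bout count.
#' @export
count_moves <- function(speed_series, speed_threshold = 2.0,
                        min_duration_frames = 2L) {
  stopifnot(speed_threshold > 0, min_duration_frames >= 1)
  above <- !is.na(speed_series) & speed_series > speed_threshold
  r <- rle(above)
  sum(r$values & r$lengths >= min_duration_frames)
}

#' 3D occupancy heatmap
#'
#' Bins the trajectory's valid frames into a 3D grid spanning the well
#' volume. Counts over all bins sum to the number of valid frames.
#'
#' @param traj A 3D [trajectory()].
#' @param bins Integer length-3 bin counts (nx, ny, nz).
#' @param geom A [plate_geometry()] giving the well bounds; the well spans
#'   `[-fx/2, fx/2] x [-fy/2, fy/2] x [0, depth]` in the per-well frame.
#' @return 3D integer array of counts with bin-edge attributes `x_edges`,
#'   `y_edges`, `z_edges`.
#' @export
occupancy_heatmap <- function(traj, bins = c(8, 8, 12),
                              geom = plate_geometry()) {
  stopifnot(inherits(traj, "trajectory"), traj$mode == "3d",
            length(bins) == 3, all(bins >= 1))
  p <- traj$positions
  ok <- apply(is.finite(p), 1, all)
  p <- p[ok, , drop = FALSE]
  ex <- seq(-geom$well_footprint[1] / 2, geom$well_footprint[1] / 2,
            length.out = bins[1] + 1)
  ey <- seq(-geom$well_footprint[2] / 2, geom$well_footprint[2] / 2,
            length.out = bins[2] + 1)
  ez <- seq(0, geom$well_depth, length.out = bins[3] + 1)
  ix <- findInterval(p[, 1], ex, rightmost.closed = TRUE, all.inside = TRUE)
  iy <- findInterval(p[, 2], ey, rightmost.closed = TRUE, all.inside = TRUE)
  iz <- findInterval(p[, 3], ez, rightmost.closed = TRUE, all.inside = TRUE)
  h <- array(0L, dim = bins)
  for (i in seq_len(nrow(p))) {
    h[ix[i], iy[i], iz[i]] <- h[ix[i], iy[i], iz[i]] + 1L
  }
  attr(h, "x_edges") <- ex
  attr(h, "y_edges") <- ey
  attr(h, "z_edges") <- ez
  h
}

#' Group depth profile
#'
#' Per-time mean and sample standard deviation of z across a group of
#' trajectories (aligned by frame index; the common time base is the
#' longest member's).
#'
#' @param trajs List of 3D [trajectory()] objects.
#' @return Data frame `time`, `mean_z`, `sd_z`, `n`.
#' @export
depth_profile <- function(trajs) {
  if (!length(trajs)) stop("empty trajectory group")
  stopifnot(all(vapply(trajs, inherits, logical(1), "trajectory")))
  n_t <- max(vapply(trajs, function(t) nrow(t$positions), integer(1)))
  fps <- trajs[[1]]$fps
  zmat <- vapply(trajs, function(t) {
    z <- t$positions[, 3]
    c(z, rep(NA_real_, n_t - length(z)))
  }, numeric(n_t))
  zmat <- matrix(zmat, nrow = n_t)
  data.frame(
    time = (seq_len(n_t) - 1) / fps,
    mean_z = rowMeans(zmat, na.rm = TRUE),
    sd_z = apply(zmat, 1, stats::sd, na.rm = TRUE),
    n = rowSums(is.finite(zmat))
  )
}

#' Mann-Whitney U group comparison
#'
#' Two-sided Mann-Whitney U test between two groups of per-larva summary
#' statistics. Uses the exact distribution when both groups have at most 10
#' observations and there are no ties, and the normal approximation with
#' continuity and tie correction otherwise.
#'
#' @param a,b Numeric samples (each of length >= 2).
#' @return List with `U` (statistic for group `a`), `p` (two-sided) and
#'   `method`.
#' @export
group_compare <- function(a, b) {
  if (length(a) < 2 || length(b) < 2) stop("each group needs >= 2 observations")
  ties <- anyDuplicated(c(a, b)) > 0
  exact <- length(a) <= 10 && length(b) <= 10 && !ties
  wt <- stats::wilcox.test(a, b, exact = exact, correct = TRUE)
  list(U = unname(wt$statistic), p = wt$p.value,
       method = if (exact) "exact" else "normal approximation")
}

#' Kinematics summary for one larva
#'
#' Convenience wrapper computing the standard per-larva summary: total
#' travel distance, mean speed, mean absolute acceleration, bout count and
#' mean tail angle, from a skeleton series.
#'
#' @param skeletons A multi-frame `skeleton3d` (from [fuse_skeletons()]).
#' @param fps Frame rate in Hz.
#' @param mode `"3d"` or `"top"` (2D top-view projection).
#' @param speed_threshold,min_duration_frames Bout settings for
#'   [count_moves()].
#' @return Object of class `kinematics_summary`.
#' @export
kinematics_summary <- function(skeletons, fps, mode = c("3d", "top"),
                               speed_threshold = 2.0,
                               min_duration_frames = 2L) {
  mode <- match.arg(mode)
  frames <- sort(unique(skeletons$frame))
  refs <- t(vapply(frames, function(f) {
    s <- skeletons[skeletons$frame == f, ]
    el <- s[s$keypoint == "eye_left", ]
    er <- s[s$keypoint == "eye_right", ]
    if (!isTRUE(el$valid) || !isTRUE(er$valid)) return(rep(NA_real_, 3))
    c((el$x + er$x) / 2, (el$y + er$y) / 2, (el$z + er$z) / 2)
  }, numeric(3)))
  traj <- trajectory(refs, fps,
                     mode = if (mode == "3d") "3d" else "2d",
                     frames = frames)
  ds <- displacement_series(traj)
  angles <- vapply(frames, function(f) {
    s <- skeletons[skeletons$frame == f, ]
    tryCatch(tail_angle(s, mode = if (mode == "3d") "3d" else "top"),
             error = function(e) NA_real_)
  }, numeric(1))
  structure(list(
    mode = mode,
    n_frames = length(frames),
    total_distance = ds$total_distance,
    mean_speed = mean(ds$speed, na.rm = TRUE),
    mean_acceleration = mean(abs(ds$acceleration), na.rm = TRUE),
    n_moves = count_moves(ds$speed, speed_threshold, min_duration_frames),
    mean_tail_angle = mean(angles, na.rm = TRUE),
    depth_series = if (mode == "3d") refs[, 3] else NULL,
    speed_series = ds$speed,
    tail_angle_series = angles
  ), class = "kinematics_summary")
}

#' @export
print.kinematics_summary <- function(x, ...) {
  cat(sprintf("Kinematics summary (%s, %d frames)\n", x$mode, x$n_frames))
  cat(sprintf("  distance %.2f mm | speed %.2f mm/s | |accel| %.2f mm/s^2\n",
              x$total_distance, x$mean_speed, x$mean_acceleration))
  cat(sprintf("  moves %d | tail angle %.1f deg\n",
              x$n_moves, x$mean_tail_angle))
  invisible(x)
}
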