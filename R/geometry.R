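#' Mirrored well-plate geometry
#'
#' Geometric description of the mirrored multi-well plate: square wells
#' imaged from above, with alternate wells replaced by 45-degree mirrors so
#' that one camera simultaneously sees a well's top view and its neighbour's
#' side view.
#'
#' @param well_footprint Numeric length-2, well footprint in mm (x, y).
#' @param well_depth Well depth in mm.
#' @param well_pitch Center-to-center well spacing in mm.
#' @param mirror_angle Mirror inclination in degrees, strictly between 0
#'   and 90.
#' @param n_wells Number of imaged wells on the plate.
#' @param wall_thickness Plastic side-wall thickness in mm (crossed by
#'   side-view rays; not by top-view rays, which enter through the open
#'   well top).
#'
#' @return An object of class `plate_geometry`.
#' @examples
#' plate_geometry()
#' @export
plate_geometry <- function(well_footprint = c(8, 8),
                           well_depth = 12,
                           well_pitch = 9,
                           mirror_angle = 45,
                           n_wells = 48,
                           wall_thickness = 1.0) {
  if (length(well_footprint) == 1L) well_footprint <- rep(well_footprint, 2L)
  stopifnot(
    length(well_footprint) == 2L, all(well_footprint > 0),
    well_depth > 0, well_pitch > 0, wall_thickness > 0,
    mirror_angle > 0, mirror_angle < 90,
    n_wells >= 1
  )
  if (well_pitch < max(well_footprint)) {
    stop("well_pitch must be at least the largest well footprint side")
  }
  structure(
    list(
      well_footprint = as.numeric(well_footprint),
      well_depth = as.numeric(well_depth),
      well_pitch = as.numeric(well_pitch),
      mirror_angle = as.numeric(mirror_angle),
      n_wells = as.integer(n_wells),
      wall_thickness = as.numeric(wall_thickness)
    ),
    class = "plate_geometry"
  )
}

#' @export
print.plate_geometry <- function(x, ...) {
  cat("Mirrored well-plate geometry\n")
  cat(sprintf("  wells: %d, footprint %.1f x %.1f mm, depth %.1f mm\n",
              x$n_wells, x$well_footprint[1], x$well_footprint[2],
              x$well_depth))
  cat(sprintf("  pitch: %.1f mm, mirror angle %.0f deg, wall %.2f mm\n",
              x$well_pitch, x$mirror_angle, x$wall_thickness))
  invisible(x)
}

#' Camera model
#'
#' Thin-lens camera description for one micro-camera of the array.
#'
#' @param focal_length Lens focal length in mm.
#' @param nominal_object_distance Nominal object distance in mm; must exceed
#'   the focal length.
#' @param sensor_pixels Integer length-2, sensor size in pixels (rows, cols).
#' @param sensor_pixel_pitch Sensor pixel pitch in micrometres.
#'
#' @return An object of class `camera_model`.
#' @examples
#' camera_model()
#' @export
camera_model <- function(focal_length = 25.05,
                         nominal_object_distance = 240,
                         sensor_pixels = c(3120, 4208),
                         sensor_pixel_pitch = 1.1) {
  stopifnot(
    focal_length > 0,
    nominal_object_distance > focal_length,
    length(sensor_pixels) == 2L, all(sensor_pixels > 0),
    sensor_pixel_pitch > 0
  )
  structure(
    list(
      focal_length = as.numeric(focal_length),
      nominal_object_distance = as.numeric(nominal_object_distance),
      sensor_pixels = as.integer(sensor_pixels),
      sensor_pixel_pitch = as.numeric(sensor_pixel_pitch)
    ),
    class = "camera_model"
  )
}

#' @export
print.camera_model <- function(x, ...) {
  cat("Camera model (thin lens)\n")
  cat(sprintf("  f = %.2f mm, nominal object distance %.1f mm\n",
              x$focal_length, x$nominal_object_distance))
  cat(sprintf("  sensor %d x %d px, pitch %.2f um, magnification %.4f\n",
              x$sensor_pixels[1], x$sensor_pixels[2], x$sensor_pixel_pitch,
              magnification(x$nominal_object_distance, x$focal_length)))
  invisible(x)
}

#' Thin-lens magnification
#'
#' Transverse magnification of a thin lens focused at a given object
#' distance, `m = f / (d - f)`. Strictly decreasing in the object distance.
#'
#' @param object_distance Object distance in mm; must exceed `focal_length`.
#' @param focal_length Focal length in mm.
#' @return Dimensionless magnification.
#' @examples
#' magnification(240, 25.05)   # ~0.1165
#' magnification(2 * 25, 25)   # exactly 1 at 2f
#' @export
magnification <- function(object_distance, focal_length) {
  stopifnot(all(focal_length > 0))
  if (any(object_distance <= focal_length)) {
    stop("object_distance must exceed focal_length")
  }
  focal_length / (object_distance - focal_length)
}

#' Per-view calibration
#'
#' Links pixel coordinates of one view (top or side) to object-space
#' millimetres through the thin-lens magnification. The side view has a
#' longer optical path because of the mirror fold; by default its object
#' distance is the nominal distance plus one well footprint.
#'
#' @param view `"top"` or `"side"`.
#' @param cam A [camera_model()].
#' @param object_distance Object distance for this view in mm. Default: the
#'   camera's nominal distance for the top view, nominal + 8 mm for the side
#'   view (the folded mirror path is longer by about one well footprint).
#' @param image_origin_offset Length-2 pixel coordinates (u0, v0) that map to
#'   the world origin of this view's plane.
#'
#' @return An object of class `view_calibration` with fields `view`,
#'   `object_distance`, `magnification`, `object_pixel_size` (um/px) and
#'   `image_origin_offset`.
#' @examples
#' cam <- camera_model()
#' view_calibration("top", cam)
#' @export
view_calibration <- function(view = c("top", "side"),
                             cam = camera_model(),
                             object_distance = NULL,
                             image_origin_offset = c(0, 0)) {
  view <- match.arg(view)
  if (is.null(object_distance)) {
    object_distance <- cam$nominal_object_distance +
      if (view == "side") 8 else 0
  }
  m <- magnification(object_distance, cam$focal_length)
  structure(
    list(
      view = view,
      object_distance = as.numeric(object_distance),
      focal_length = cam$focal_length,
      magnification = m,
      object_pixel_size = cam$sensor_pixel_pitch / m,
      image_origin_offset = as.numeric(image_origin_offset)
    ),
    class = "view_calibration"
  )
}

#' @export
print.view_calibration <- function(x, ...) {
  cat(sprintf("View calibration [%s]: d = %.1f mm, m = %.4f, %.2f um/px\n",
              x$view, x$object_distance, x$magnification,
              x$object_pixel_size))
  invisible(x)
}

#' Pixel to world-plane conversion
#'
#' Maps pixel coordinates of a calibrated view to object-space millimetres in
#' that view's image plane (and back). The map is linear:
#' `mm = (px - origin) * object_pixel_size / 1000`.
#'
#' @param calib A [view_calibration()].
#' @param u,v Pixel coordinates (vectors of equal length).
#' @return `pixel_to_world`: a matrix with columns `h`, `w` (mm in the view
#'   plane). `world_to_pixel`: a matrix with columns `u`, `v` (px).
#' @examples
#' cal <- view_calibration("top")
#' p <- pixel_to_world(cal, 1000, 500)
#' world_to_pixel(cal, p[, 1], p[, 2])  # round trip
#' @export
pixel_to_world <- function(calib, u, v) {
  stopifnot(inherits(calib, "view_calibration"),
            is.finite(calib$magnification), calib$magnification > 0)
  s <- calib$object_pixel_size / 1000  # mm per pixel
  cbind(h = (u - calib$image_origin_offset[1]) * s,
        w = (v - calib$image_origin_offset[2]) * s)
}

#' @rdname pixel_to_world
#' @param h,w Object-space coordinates in mm.
#' @export
world_to_pixel <- function(calib, h, w) {
  stopifnot(inherits(calib, "view_calibration"),
            is.finite(calib$magnification), calib$magnification > 0)
  s <- calib$object_pixel_size / 1000
  cbind(u = h / s + calib$image_origin_offset[1],
        v = w / s + calib$image_origin_offset[2])
}

#' Assign dual-view plane coordinates to the world frame
#'
#' World frame convention: per-well, origin at the well-bottom center,
#' x and y horizontal (x along the plate long axis), z vertical upward.
#' The top-view image plane maps (u, v) -> (x, y); the mirror folds the
#' horizontal side path into a vertical view sharing the y axis, so the
#' side-view image plane maps (u, v) -> (y, z).
#'
#' @param top_point Length-2 (or n x 2) top-view plane coordinates (mm).
#' @param side_point Length-2 (or n x 2) side-view plane coordinates (mm).
#' @return A matrix with columns `x`, `y_top`, `y_side`, `z` (mm). The two y
#'   readings are reported separately; fusion averages them (see
#'   [triangulate()]).
#' @examples
#' world_frame_assign(c(1, 2), c(2, 3))
#' @export
world_frame_assign <- function(top_point, side_point) {
  top_point <- matrix(top_point, ncol = 2)
  side_point <- matrix(side_point, ncol = 2)
  stopifnot(nrow(top_point) == nrow(side_point),
            all(is.finite(top_point)), all(is.finite(side_point)))
  cbind(x = top_point[, 1], y_top = top_point[, 2],
        y_side = side_point[, 1], z = side_point[, 2])
}
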