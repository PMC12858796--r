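#' Snell refraction
#'
#' Refracts a ray at a planar interface: `n1 sin(theta_in) = n2 sin(theta_out)`.
#'
#' @param theta_in Incidence angle in degrees, in `[0, 90)`.
#' @param n1,n2 Refractive indices of the incidence and transmission media.
#' @return Refraction angle in degrees.
#' @examples
#' snell_refract(30, 1.0, 1.33)  # 22.082 deg
#' @export
snell_refract <- function(theta_in, n1, n2) {
  stopifnot(all(theta_in >= 0), all(theta_in < 90), n1 > 0, n2 > 0)
  s <- n1 * sin(theta_in * pi / 180) / n2
  if (any(s > 1)) stop("total internal reflection: n1*sin(theta_in) > n2")
  asin(s) * 180 / pi
}

# Slab displacement relative to an all-air trace: a ray at incidence theta_in
# crossing a slab of thickness t at refracted angle theta_t lands
# t*(tan theta_in - tan theta_t) short of the straight-line air ray.
slab_shift <- function(theta_in_deg, theta_t_deg, thickness) {
  thickness * (tan(theta_in_deg * pi / 180) - tan(theta_t_deg * pi / 180))
}

# 1D cross-section through the centers of the two wells seen by one camera
# (the four-well real+virtual model is a 2x2 block; its cross-section holds
# two wells centered at +/- pitch/2). Returns the well interval containing a
# lateral field position, or NULL when the position falls on the wall/gap.
well_interval <- function(geom, x) {
  half <- geom$well_footprint[1] / 2
  for (ctr in c(-1, 1) * geom$well_pitch / 2) {
    if (x >= ctr - half && x <= ctr + half) return(c(ctr - half, ctr + half))
  }
  NULL
}

#' Trace one ray through the well refraction model
#'
#' Traces a chief (or marginal) ray from the camera, through the layered
#' media of the mirrored-plate model, to an object point at a given lateral
#' field position, and reports the lateral shift of the apparent object
#' position relative to an identical all-air trace. The top view crosses a
#' single air-water interface (wells are open on top); the side view,
#' unfolded through the mirror, crosses the plastic side wall and then
#' water. Rays travelling through water are terminated when they reach a
#' well boundary; the shift is then reported up to the termination point.
#'
#' @param geom A [plate_geometry()].
#' @param cam A [camera_model()].
#' @param view `"top"` or `"side"`.
#' @param lateral_offset Field position of the traced point, mm from the
#'   optical axis (may be negative; the shift is odd in the offset).
#' @param water_path_depth Water path length to the object in mm. Default:
#'   half the well depth for the top view (larva mid-column), half the well
#'   footprint for the side view. Must not exceed the well depth.
#' @param n_water,n_plastic Refractive indices (defaults 1.33 and 1.5).
#' @param ray `"chief"` (through the aperture center) or `"marginal"`
#'   (through the aperture edge, which steepens the incidence angle).
#' @param aperture_diameter Aperture diameter in mm, used only for marginal
#'   rays. The default (25 mm) is chosen so the worst-case marginal
#'   incidence over the field stays near 5 degrees; the true f-number is a
#'   configuration input, so marginal results are configuration-dependent.
#'
#' @return A list of class `ray_trace` with elements `lateral_offset`,
#'   `theta_in` (air incidence, deg: the air-water angle for the top view,
#'   air-plastic for the side), `theta_water`, `theta_plastic` (deg, `NA`
#'   when the medium is not crossed), `shift_mm`, `shift_px`,
#'   `relative_distortion`, `in_well`, `terminated`.
#' @examples
#' trace_chief_ray(plate_geometry(), camera_model(), "top", 4.5)
#' @export
trace_chief_ray <- function(geom, cam, view = c("top", "side"),
                            lateral_offset,
                            water_path_depth = NULL,
                            n_water = 1.33, n_plastic = 1.5,
                            ray = c("chief", "marginal"),
                            aperture_diameter = 25) {
  view <- match.arg(view)
  ray <- match.arg(ray)
  stopifnot(inherits(geom, "plate_geometry"), inherits(cam, "camera_model"))
  if (is.null(water_path_depth)) {
    water_path_depth <- if (view == "top") geom$well_depth / 2 else
      geom$well_footprint[1] / 2
  }
  stopifnot(water_path_depth >= 0, water_path_depth <= geom$well_depth)

  d <- cam$nominal_object_distance +
    if (view == "side") geom$well_footprint[1] else 0
  x <- lateral_offset
  ax <- abs(x)
  reach <- if (ray == "chief") ax else ax + aperture_diameter / 2
  theta_in <- atan2(reach, d) * 180 / pi

  iv <- well_interval(geom, ax)   # geometry is mirror-symmetric in x
  in_well <- !is.null(iv)
  theta_w <- snell_refract(theta_in, 1, n_water)
  theta_p <- if (view == "side") snell_refract(theta_in, 1, n_plastic) else NA_real_

  shift <- 0
  terminated <- FALSE
  if (in_well && ax > 0) {
    t_w <- water_path_depth
    if (view == "side") {
      # plastic wall first, then water along the horizontal (unfolded) path
      shift <- shift + slab_shift(theta_in, theta_p, geom$wall_thickness)
    }
    # terminate in water at the outward well boundary (the ray tilts away
    # from the optical axis as it advances)
    room <- max(iv) - ax
    lateral_travel <- t_w * tan(theta_w * pi / 180)
    if (lateral_travel > room) {
      terminated <- TRUE
      t_w <- room / tan(theta_w * pi / 180)
    }
    shift <- shift + slab_shift(theta_in, theta_w, t_w)
    shift <- sign(x) * shift
  }

  m <- magnification(d, cam$focal_length)
  structure(list(
    lateral_offset = x,
    view = view,
    ray = ray,
    theta_in = theta_in,
    theta_water = theta_w,
    theta_plastic = theta_p,
    shift_mm = shift,
    shift_px = shift * m * 1000 / cam$sensor_pixel_pitch,
    relative_distortion = if (ax > 0) abs(shift) / ax else 0,
    in_well = in_well,
    terminated = terminated
  ), class = "ray_trace")
}

#' Refractive distortion profile across the field
#'
#' Scans rays in fixed lateral increments from the optical axis to the
#' farthest field point of the real+virtual well region and tabulates the
#' refraction-induced apparent-position shift at each field position.
#' Relative distortion is shift divided by lateral field position (defined
#' as 0 on axis); the maximum over in-well rows is the headline distortion
#' figure.
#'
#' @inheritParams trace_chief_ray
#' @param scan_step Lateral scan increment in mm (default 0.1).
#' @return A data frame of class `distortion_profile` with one row per
#'   scanned offset: `lateral_distance`, `theta_in_deg`, `shift_mm`,
#'   `shift_px`, `relative_distortion`, `in_well`, `terminated`. Attributes
#'   `max_relative_distortion`, `max_theta_in_deg` and `max_shift_px` hold
#'   the in-well maxima.
#' @examples
#' dp <- distortion_profile(plate_geometry(), camera_model(), "top")
#' attr(dp, "max_relative_distortion")
#' @export
distortion_profile <- function(geom, cam, view = c("top", "side"),
                               scan_step = 0.1,
                               water_path_depth = NULL,
                               n_water = 1.33, n_plastic = 1.5,
                               ray = c("chief", "marginal"),
                               aperture_diameter = 25) {
  view <- match.arg(view)
  ray <- match.arg(ray)
  stopifnot(scan_step > 0)
  farthest <- geom$well_pitch / 2 + geom$well_footprint[1] / 2
  offsets <- seq(0, farthest, by = scan_step)
  rows <- lapply(offsets, function(x) {
    r <- trace_chief_ray(geom, cam, view, x,
                         water_path_depth = water_path_depth,
                         n_water = n_water, n_plastic = n_plastic,
                         ray = ray, aperture_diameter = aperture_diameter)
    data.frame(lateral_distance = x,
               theta_in_deg = r$theta_in,
               shift_mm = r$shift_mm,
               shift_px = r$shift_px,
               relative_distortion = r$relative_distortion,
               in_well = r$in_well,
               terminated = r$terminated)
  })
  out <- do.call(rbind, rows)
  iw <- out[out$in_well, , drop = FALSE]
  attr(out, "max_relative_distortion") <-
    if (nrow(iw)) max(iw$relative_distortion) else 0
  attr(out, "max_theta_in_deg") <- if (nrow(iw)) max(iw$theta_in_deg) else 0
  attr(out, "max_shift_px") <- if (nrow(iw)) max(abs(iw$shift_px)) else 0
  attr(out, "view") <- view
  attr(out, "ray") <- ray
  class(out) <- c("distortion_profile", class(out))
  out
}
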