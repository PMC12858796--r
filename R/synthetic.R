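#' Simulator configuration
#'
#' Study conditions for the virtual larva: a 7 dpf larva (body about 4 mm)
#' swimming in one 8 x 8 x 12 mm well, recorded at 20 fps for 30 s — the
#' recording conditions of the behavioral experiments the simulator stands
#' in for. All randomness in the simulator flows through `seed`.
#'
#' @param seed Integer RNG seed.
#' @param fps Frame rate, Hz.
#' @param duration Recording duration, s.
#' @param well A [plate_geometry()].
#' @param speed_scale Typical cruise speed, mm/s.
#' @param depth_prior `"uniform"`, `"bottom"` or `"surface"` swimming-depth
#'   preference.
#' @param tail_beat_amplitude Peak tail-bend amplitude, degrees.
#' @param tail_beat_hz Tail-beat frequency, Hz.
#' @param bend_plane_mix Weight in `[0, 1]` mixing horizontal (1) and
#'   vertical (0) tail bending.
#' @param body_length Larva body length (nostril to tail tip), mm.
#' @param pixel_sigma Gaussian keypoint noise added in the rendered views,
#'   px.
#' @param drop_rate Probability a rendered keypoint is demoted to low
#'   likelihood. The default 0.004 per keypoint per view reproduces the
#'   roughly 94% all-keypoint per-frame success rate typical of trained
#'   detectors on this instrument class.
#' @param low_likelihood Likelihood value assigned to demoted keypoints.
#' @param bladder_axes Length-3 swim-bladder semi-axes (a, b, c), mm.
#' @return Object of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       fps = 20,
                       duration = 30,
                       well = plate_geometry(),
                       speed_scale = 3,
                       depth_prior = c("uniform", "bottom", "surface"),
                       tail_beat_amplitude = 25,
                       tail_beat_hz = 2,
                       bend_plane_mix = 0.5,
                       body_length = 4,
                       pixel_sigma = 0.5,
                       drop_rate = 0.004,
                       low_likelihood = 0.3,
                       bladder_axes = c(0.45, 0.3, 0.28)) {
  depth_prior <- match.arg(depth_prior)
  stopifnot(fps > 0, duration > 0, speed_scale >= 0,
            bend_plane_mix >= 0, bend_plane_mix <= 1,
            body_length > 0, pixel_sigma >= 0,
            drop_rate >= 0, drop_rate <= 1,
            length(bladder_axes) == 3, all(bladder_axes > 0))
  structure(list(
    seed = as.integer(seed), fps = fps, duration = duration, well = well,
    speed_scale = speed_scale, depth_prior = depth_prior,
    tail_beat_amplitude = tail_beat_amplitude, tail_beat_hz = tail_beat_hz,
    bend_plane_mix = bend_plane_mix, body_length = body_length,
    pixel_sigma = pixel_sigma, drop_rate = drop_rate,
    low_likelihood = low_likelihood, bladder_axes = as.numeric(bladder_axes)
  ), class = "sim_config")
}

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  }
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  code
}

# unit vector, with a fallback for near-zero input
unitv <- function(v, fallback = c(1, 0, 0)) {
  n <- sqrt(sum(v^2))
  if (n < 1e-12) fallback else v / n
}

#' Simulate a swimming larva
#'
#' Generates the ground-truth 3D skeleton time series of one larva: a
#' smoothed random-walk head trajectory (Ornstein-Uhlenbeck velocity,
#' specular reflection at well walls, optional depth bias), a rigid head
#' (nostril, eyes, swim bladder at fixed body-frame offsets) and four tail
#' points following a circular-arc bend with sinusoidal time modulation in
#' a configurable mix of the horizontal and vertical bend planes. The swim
#' bladder ellipsoid rides at the swim-bladder keypoint, aligned with the
#' body axis. Deterministic given the config seed.
#'
#' @param config A [sim_config()].
#' @return Object of class `larva_sim`: list with `config`, `frames`,
#'   `keypoints` (n x 8 x 3 array, mm, dimnames by keypoint), `head`
#'   (n x 3), `heading` (n x 3 unit vectors), `truth_length` (per-frame
#'   skeleton polyline length, mm), `bladder` (data frame of per-frame
#'   ellipsoid center/axes/rotations).
#' @export
simulate_larva <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(config$seed, {
    n <- max(2L, round(config$fps * config$duration))
    dt <- 1 / config$fps
    w <- config$well
    half <- w$well_footprint / 2
    margin <- 0.5
    lo <- c(-half[1] + margin, -half[2] + margin, margin)
    hi <- c(half[1] - margin, half[2] - margin, w$well_depth - margin)

    z_target <- switch(config$depth_prior,
                       uniform = NA_real_,
                       bottom = lo[3] + 0.05 * (hi[3] - lo[3]),
                       surface = hi[3] - 0.05 * (hi[3] - lo[3]))
    pos <- matrix(0, n, 3)
    vel <- matrix(0, n, 3)
    pos[1, ] <- c(0, 0, if (is.na(z_target)) mean(c(lo[3], hi[3])) else z_target)
    v <- c(config$speed_scale, 0, 0)
    tau <- 0.5                                    # velocity relaxation, s
    sig <- config$speed_scale                     # excitation scale, mm/s
    for (i in seq_len(n)) {
      vel[i, ] <- v
      if (i == n) break
      drift <- c(0, 0, 0)
      if (!is.na(z_target)) {
        drift[3] <- 4 * (z_target - pos[i, 3])    # depth bias, mm/s^2-ish
      }
      noise <- if (config$speed_scale > 0) {
        stats::rnorm(3, 0, sig * sqrt(2 * dt / tau))
      } else c(0, 0, 0)
      v <- v * (1 - dt / tau) + drift * dt + noise
      if (config$speed_scale == 0) v <- c(0, 0, 0)
      p <- pos[i, ] + v * dt
      for (k in 1:3) {                            # specular wall reflection
        if (p[k] < lo[k]) { p[k] <- 2 * lo[k] - p[k]; v[k] <- -v[k] }
        if (p[k] > hi[k]) { p[k] <- 2 * hi[k] - p[k]; v[k] <- -v[k] }
        p[k] <- min(max(p[k], lo[k]), hi[k])
      }
      pos[i + 1, ] <- p
    }

    # body-frame axes per frame: forward from velocity (persisted when still)
    heading <- matrix(0, n, 3)
    fwd <- c(1, 0, 0)
    for (i in seq_len(n)) {
      if (sqrt(sum(vel[i, ]^2)) > 1e-9) fwd <- unitv(vel[i, ], fwd)
      heading[i, ] <- fwd
    }

    L <- config$body_length
    s_off <- L / 4 * c(nostril = 0, eye = 0.35, swim_bladder = 1.2,
                       tail1 = 1.9, tail2 = 2.6, tail3 = 3.3, tail4 = 4.0)
    eye_lat <- 0.06 * L
    amp <- config$tail_beat_amplitude * pi / 180
    mix <- config$bend_plane_mix
    tm <- (seq_len(n) - 1) * dt
    bend_t <- amp * sin(2 * pi * config$tail_beat_hz * tm)

    kp <- array(NA_real_, dim = c(n, 8, 3),
                dimnames = list(NULL, larva_keypoints, c("x", "y", "z")))
    truth_len <- numeric(n)
    blad <- data.frame(frame = seq_len(n) - 1L, cx = 0, cy = 0, cz = 0,
                       a = config$bladder_axes[1], b = config$bladder_axes[2],
                       c = config$bladder_axes[3], phi = 0, psi = 0, theta = 0)
    for (i in seq_len(n)) {
      f <- heading[i, ]
      lat <- unitv(c(-f[2], f[1], 0), c(0, 1, 0))
      vert <- unitv(c(f[2] * lat[3] - f[3] * lat[2],
                      f[3] * lat[1] - f[1] * lat[3],
                      f[1] * lat[2] - f[2] * lat[1]), c(0, 0, 1))
      u_bend <- unitv(mix * lat + (1 - mix) * vert, lat)
      head_p <- pos[i, ]
      body_pt <- function(s, bend = FALSE) {
        p <- head_p - f * s
        if (bend && s > s_off["swim_bladder"]) {
          # circular-arc lateral displacement beyond the bladder
          ds <- s - s_off[["swim_bladder"]]
          Lt <- s_off[["tail4"]] - s_off[["swim_bladder"]]
          kappa <- bend_t[i] / Lt
          p <- p + u_bend * (ds^2 * kappa / 2)
        }
        p
      }
      kp[i, "nostril", ] <- body_pt(s_off[["nostril"]])
      kp[i, "eye_left", ] <- body_pt(s_off[["eye"]]) + lat * eye_lat
      kp[i, "eye_right", ] <- body_pt(s_off[["eye"]]) - lat * eye_lat
      kp[i, "swim_bladder", ] <- body_pt(s_off[["swim_bladder"]])
      for (tj in 1:4) {
        kp[i, paste0("tail", tj), ] <-
          body_pt(s_off[[paste0("tail", tj)]], bend = TRUE)
      }
      path <- rbind(kp[i, "nostril", ],
                    (kp[i, "eye_left", ] + kp[i, "eye_right", ]) / 2,
                    kp[i, "swim_bladder", ],
                    kp[i, "tail1", ], kp[i, "tail2", ],
                    kp[i, "tail3", ], kp[i, "tail4", ])
      truth_len[i] <- sum(sqrt(rowSums(diff(path)^2)))
      blad[i, c("cx", "cy", "cz")] <- kp[i, "swim_bladder", ]
      blad$psi[i] <- atan2(f[2], f[1])
      blad$theta[i] <- asin(max(-1, min(1, -f[3])))
    }

    structure(list(config = config, frames = seq_len(n) - 1L,
                   keypoints = kp, head = pos, heading = heading,
                   truth_length = truth_len, bladder = blad),
              class = "larva_sim")
  })
}

#' @export
print.larva_sim <- function(x, ...) {
  cat(sprintf("Simulated larva: %d frames @ %g fps, depth prior '%s', seed %d\n",
              length(x$frames), x$config$fps, x$config$depth_prior,
              x$config$seed))
  invisible(x)
}

#' Render dual-view keypoint detections (and bladder masks)
#'
#' Projects the simulated 3D skeleton to the top (x, y) and side (y, z)
#' views through the view calibrations, adds Gaussian pixel noise, and
#' randomly demotes keypoints to a low likelihood at the configured rate —
#' the inverse of the fusion stage, emulating what a trained detector
#' emits. Optionally rasterizes the swim-bladder shadow masks (the exact
#' Schur-complement shadows of the true ellipsoid) for a subset of frames.
#'
#' @param sim A [simulate_larva()] result.
#' @param calib_top,calib_side [view_calibration()] objects.
#' @param mask_frames Optional integer frame indices (0-based) for which to
#'   rasterize bladder shadow masks.
#' @param mask_size Mask crop side length, px.
#' @return List with `keypoints` (the keypoint CSV dialect data frame) and,
#'   when requested, `masks`: per frame a list with `top`/`side` binary
#'   matrices and their crop `offset` (pixel coordinates of mask element
#'   [1,1]).
#' @export
render_views <- function(sim, calib_top, calib_side,
                         mask_frames = NULL, mask_size = 96) {
  stopifnot(inherits(sim, "larva_sim"))
  cfg <- sim$config
  with_seed(cfg$seed + 1000003L, {
    n <- length(sim$frames)
    kp <- sim$keypoints
    rows <- vector("list", 2L * n)
    for (i in seq_len(n)) {
      tp <- world_to_pixel(calib_top, kp[i, , "x"], kp[i, , "y"])
      sp <- world_to_pixel(calib_side, kp[i, , "y"], kp[i, , "z"])
      noise <- function(m) m + matrix(stats::rnorm(length(m), 0,
                                                   cfg$pixel_sigma),
                                      nrow(m), ncol(m))
      lik <- function() ifelse(stats::runif(8) < cfg$drop_rate,
                               cfg$low_likelihood, 1.0)
      tp <- noise(tp); sp <- noise(sp)
      rows[[2 * i - 1]] <- data.frame(
        frame = sim$frames[i], view = "top", keypoint = larva_keypoints,
        u = tp[, 1], v = tp[, 2], likelihood = lik())
      rows[[2 * i]] <- data.frame(
        frame = sim$frames[i], view = "side", keypoint = larva_keypoints,
        u = sp[, 1], v = sp[, 2], likelihood = lik())
    }
    out <- list(keypoints = do.call(rbind, rows))

    if (!is.null(mask_frames)) {
      masks <- lapply(mask_frames, function(f) {
        i <- match(f, sim$frames)
        if (is.na(i)) stop("mask frame ", f, " not in simulation")
        b <- sim$bladder[i, ]
        mod <- ellipsoid_model(b$a, b$b, b$c, b$phi, b$psi, b$theta,
                               center = c(b$cx, b$cy, b$cz))
        list(
          top = rasterize_shadow(mod, "top", calib_top, mask_size),
          side = rasterize_shadow(mod, "side", calib_side, mask_size)
        )
      })
      names(masks) <- as.character(mask_frames)
      out$masks <- masks
    }
    out
  })
}

# Rasterize the orthogonal shadow of an ellipsoid into a binary crop.
rasterize_shadow <- function(model, plane, calib, size = 96) {
  M_mm <- project_ellipsoid(model, plane)
  ctr_mm <- if (plane == "top") model$center[1:2] else model$center[2:3]
  s <- calib$object_pixel_size / 1000            # mm per px
  M_px <- M_mm * s^2
  ctr_px <- world_to_pixel(calib, ctr_mm[1], ctr_mm[2])
  off <- floor(ctr_px - size / 2)
  us <- off[1] + seq_len(size) - 1
  vs <- off[2] + seq_len(size) - 1
  du <- us - ctr_px[1]
  dv <- vs - ctr_px[2]
  q <- outer(dv^2 * M_px[2, 2], du^2 * M_px[1, 1], "+") +
    2 * M_px[1, 2] * outer(dv, du)
  mask <- (q <= 1) * 1L                          # rows = v, cols = u
  attr(mask, "offset") <- c(u = off[1], v = off[2])
  mask
}

#' Synthetic slanted-edge target
#'
#' Two-level slanted step edge, optionally blurred with a Gaussian; the
#' standard input for slanted-edge MTF estimation.
#'
#' @param size Image side length, px.
#' @param angle Edge slant from vertical, degrees (about 5 is typical).
#' @param blur_sigma Gaussian blur sigma, px (0 gives a hard edge).
#' @param levels Length-2 low/high intensity levels.
#' @return `size` x `size` numeric matrix (rows = image rows).
#' @export
make_edge_target <- function(size = 64, angle = 5, blur_sigma = 0,
                             levels = c(0.2, 0.8)) {
  stopifnot(size >= 8, angle > 0, angle < 90, blur_sigma >= 0)
  r <- matrix(seq_len(size), size, size)
  c_ <- matrix(seq_len(size), size, size, byrow = TRUE)
  edge <- size / 2 + tan(angle * pi / 180) * (r - size / 2)
  img <- ifelse(c_ > edge, levels[2], levels[1])
  if (blur_sigma > 0) img <- gaussian_blur(img, blur_sigma)
  img
}

# separable Gaussian blur with replicate padding
gaussian_blur <- function(img, sigma) {
  rad <- max(1L, ceiling(4 * sigma))
  k <- stats::dnorm(seq(-rad, rad), sd = sigma)
  k <- k / sum(k)
  conv1 <- function(x) {
    n <- length(x)
    xp <- c(rep(x[1], rad), x, rep(x[n], rad))
    vapply(seq_len(n), function(i) sum(xp[i:(i + 2 * rad)] * k), numeric(1))
  }
  img <- apply(img, 2, conv1)
  t(apply(img, 1, conv1))
}
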