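#' Read a keypoint CSV
#'
#' Reads the keypoint dialect `frame,view,keypoint,u,v,likelihood` (header
#' mandatory; views `top`/`side`; the eight [larva_keypoints] names; u, v
#' in px; likelihood in `[0, 1]`). An optional leading `well` column is
#' preserved for multi-well files.
#'
#' @param path CSV file path.
#' @return Validated keypoint data frame.
#' @export
read_keypoints <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (nrow(df) == 0) stop("empty keypoint file: ", path)
  need <- c("frame", "view", "keypoint", "u", "v", "likelihood")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("missing column(s): ", paste(miss, collapse = ", "))
  for (col in c("frame", "u", "v", "likelihood")) {
    v <- suppressWarnings(as.numeric(df[[col]]))
    bad <- which(is.na(v) & !is.na(df[[col]]))
    if (length(bad)) {
      stop(sprintf("malformed numeric value in column '%s' at data line %d",
                   col, bad[1]))
    }
    df[[col]] <- v
  }
  check_keypoint_table(df)
  df
}

#' @rdname read_keypoints
#' @param keypoints Keypoint data frame to write.
#' @export
write_keypoints <- function(keypoints, path) {
  check_keypoint_table(keypoints)
  utils::write.csv(keypoints, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read/write fused skeleton CSV
#'
#' Dialect: `frame,keypoint,x_mm,y_mm,z_mm,valid,y_residual_mm`; all
#' coordinates in mm in the per-well world frame.
#'
#' @param skeletons A `skeleton3d` data frame.
#' @param path CSV path.
#' @export
write_skeletons <- function(skeletons, path) {
  out <- data.frame(frame = skeletons$frame, keypoint = skeletons$keypoint,
                    x_mm = skeletons$x, y_mm = skeletons$y,
                    z_mm = skeletons$z, valid = skeletons$valid,
                    y_residual_mm = skeletons$y_residual)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_skeletons
#' @export
read_skeletons <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  out <- data.frame(frame = df$frame, keypoint = df$keypoint,
                    x = df$x_mm, y = df$y_mm, z = df$z_mm,
                    valid = as.logical(df$valid),
                    y_residual = df$y_residual_mm)
  class(out) <- c("skeleton3d", class(out))
  out
}

#' Read a geometry/camera config file
#'
#' YAML config with optional sections `plate`, `camera` and `views`; keys
#' mirror the [plate_geometry()] and [camera_model()] arguments (lengths in
#' mm, sensor pitch in um). Missing keys fall back to the defaults.
#'
#' @param path YAML file path (NULL for all defaults).
#' @return List with `geom`, `cam`, `calib_top`, `calib_side`.
#' @export
read_geometry_config <- function(path = NULL) {
  cfg <- if (is.null(path)) list() else yaml::read_yaml(path)
  geom <- do.call(plate_geometry, cfg$plate %||% list())
  cam <- do.call(camera_model, cfg$camera %||% list())
  vt <- cfg$views$top %||% list()
  vs <- cfg$views$side %||% list()
  list(
    geom = geom, cam = cam,
    calib_top = view_calibration("top", cam,
                                 object_distance = vt$object_distance,
                                 image_origin_offset =
                                   vt$image_origin_offset %||% c(0, 0)),
    calib_side = view_calibration("side", cam,
                                  object_distance = vs$object_distance,
                                  image_origin_offset =
                                    vs$image_origin_offset %||% c(0, 0))
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read/write binary mask PNG
#'
#' Masks are 8-bit PNGs with foreground > 0, named
#' `<well>_<view>_<frame>.png`.
#'
#' @param mask Binary matrix (rows = image rows).
#' @param path PNG path.
#' @export
write_mask_png <- function(mask, path) {
  png::writePNG(matrix(as.numeric(mask > 0), nrow(mask), ncol(mask)), path)
  invisible(path)
}

#' @rdname write_mask_png
#' @export
read_mask_png <- function(path) {
  img <- png::readPNG(path)
  if (length(dim(img)) == 3) img <- img[, , 1]
  (img > 0) * 1L
}

#' Run manifest
#'
#' Records everything needed to reproduce a pipeline run: input paths, a
#' checksum of the geometry config, every threshold actually applied, the
#' package version and the seed. Serialized as JSON alongside every output.
#'
#' @param keypoints_csv Path to the keypoint CSV.
#' @param geometry_config Optional geometry YAML path.
#' @param masks_dir Optional directory of bladder mask PNGs.
#' @param fps Frame rate, Hz.
#' @param likelihood_threshold,visibility_threshold,speed_threshold,min_duration_frames
#'   Stage parameters (defaults: 0.7 strict likelihood, 0.5 visibility
#'   ratio, 2 mm/s bouts of >= 2 frames; video exclusion above 1/3 invalid
#'   frames is fixed).
#' @param seed Integer seed for any stochastic stage.
#' @return Object of class `run_manifest`.
#' @export
run_manifest <- function(keypoints_csv, geometry_config = NULL,
                         masks_dir = NULL, fps = 20,
                         likelihood_threshold = 0.7,
                         visibility_threshold = 0.5,
                         speed_threshold = 2.0,
                         min_duration_frames = 2L,
                         seed = 1L) {
  structure(list(
    keypoints_csv = keypoints_csv,
    geometry_config = geometry_config,
    geometry_config_checksum = file_checksum(geometry_config),
    masks_dir = masks_dir,
    fps = fps,
    likelihood_threshold = likelihood_threshold,
    video_exclusion_fraction = 1 / 3,
    visibility_threshold = visibility_threshold,
    speed_threshold = speed_threshold,
    min_duration_frames = as.integer(min_duration_frames),
    tool_version = as.character(utils::packageVersion("mirrorwell")),
    seed = as.integer(seed)
  ), class = "run_manifest")
}

# FNV-1a checksum of a file's bytes (hex string); NULL-safe.
file_checksum <- function(path) {
  if (is.null(path)) return(NA_character_)
  bytes <- as.integer(readBin(path, "raw", file.info(path)$size))
  h <- 2166136261
  for (b in bytes) {
    h <- bitwXor(as.integer(h %% 2^31), b) * 16777619
    h <- h %% 2^31
  }
  sprintf("%08x", as.integer(h))
}

#' Run the full analysis pipeline
#'
#' Executes the stages in order for every well in the keypoint file:
#' likelihood QC -> triangulation -> kinematics (2D and 3D) -> visibility
#' filtering -> (when masks are present) ellipse fitting -> ellipsoid
#' reconstruction -> height-corrected volume. Wells flagged as excluded
#' (over one-third invalid frames) get a QC record but no kinematics. A
#' stage error in one well is recorded and the pipeline continues with the
#' others. The manifest is written alongside every output.
#'
#' @param manifest A [run_manifest()].
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, a list with per-well results and the QC summary data
#'   frame; outputs are written under `out_dir`.
#' @export
run_pipeline <- function(manifest, out_dir) {
  stopifnot(inherits(manifest, "run_manifest"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  geo <- read_geometry_config(manifest$geometry_config)
  kps <- read_keypoints(manifest$keypoints_csv)
  if (!"well" %in% names(kps)) kps$well <- "well01"
  wells <- sort(unique(kps$well))

  jsonlite::write_json(unclass(manifest),
                       file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")

  qc_rows <- list()
  results <- list()
  for (wl in wells) {
    res <- tryCatch({
      kw <- kps[kps$well == wl, ]
      fk <- filter_keypoints(kw, manifest$likelihood_threshold)
      qc <- fk$qc
      well_res <- list(qc = qc)
      if (!qc$excluded && length(fk$valid_frames) >= 2) {
        kv <- kw[kw$frame %in% fk$valid_frames, ]
        sk <- fuse_skeletons(kv, geo$calib_top, geo$calib_side,
                             threshold = manifest$likelihood_threshold)
        write_skeletons(sk, file.path(out_dir,
                                      paste0(wl, "_skeletons.csv")))
        kin3 <- kinematics_summary(sk, manifest$fps, "3d",
                                   manifest$speed_threshold,
                                   manifest$min_duration_frames)
        kin2 <- kinematics_summary(sk, manifest$fps, "top",
                                   manifest$speed_threshold,
                                   manifest$min_duration_frames)
        vis <- visibility_filter(sk, manifest$visibility_threshold)
        jsonlite::write_json(
          list(well = wl,
               kinematics_3d = unclass(kin3)[c("total_distance",
                                               "mean_speed",
                                               "mean_acceleration",
                                               "n_moves",
                                               "mean_tail_angle")],
               kinematics_2d = unclass(kin2)[c("total_distance",
                                               "mean_speed",
                                               "mean_acceleration",
                                               "n_moves",
                                               "mean_tail_angle")],
               visibility_pass_rate = mean(vis$passed)),
          file.path(out_dir, paste0(wl, "_kinematics.json")),
          auto_unbox = TRUE, digits = NA)
        well_res$skeletons <- sk
        well_res$kinematics_3d <- kin3
        well_res$kinematics_2d <- kin2
        well_res$visibility <- vis
        if (!is.null(manifest$masks_dir)) {
          well_res$bladder <- pipeline_bladder_stage(
            wl, vis, sk, manifest, geo, out_dir)
        }
      }
      well_res
    }, error = function(e) list(error = conditionMessage(e)))
    results[[wl]] <- res
    qc_rows[[wl]] <- data.frame(
      well = wl,
      n_frames = if (!is.null(res$qc)) res$qc$n_frames else NA,
      n_valid_frames = if (!is.null(res$qc)) res$qc$n_valid_frames else NA,
      excluded = if (!is.null(res$qc)) res$qc$excluded else NA,
      error = if (!is.null(res$error)) res$error else "")
  }
  qc_summary <- do.call(rbind, qc_rows)
  utils::write.csv(qc_summary, file.path(out_dir, "qc_summary.csv"),
                   row.names = FALSE)
  invisible(list(wells = results, qc_summary = qc_summary))
}

# Bladder stage: fit ellipses to mask pairs on visibility-passed frames,
# reconstruct the ellipsoid and apply the height correction.
pipeline_bladder_stage <- function(well, vis, skeletons, manifest, geo,
                                   out_dir) {
  frames <- vis$frame[vis$passed]
  rows <- list()
  for (f in frames) {
    ft <- file.path(manifest$masks_dir, sprintf("%s_top_%d.png", well, f))
    fs <- file.path(manifest$masks_dir, sprintf("%s_side_%d.png", well, f))
    if (!file.exists(ft) || !file.exists(fs)) next
    row <- tryCatch({
      et_px <- fit_ellipse(mask_to_contour(read_mask_png(ft)))
      es_px <- fit_ellipse(mask_to_contour(read_mask_png(fs)))
      st <- geo$calib_top$object_pixel_size / 1000
      ss <- geo$calib_side$object_pixel_size / 1000
      et <- ellipse_shape(et_px$semi_axes[1] * st, et_px$semi_axes[2] * st,
                          et_px$rotation, et_px$center * st)
      es <- ellipse_shape(es_px$semi_axes[1] * ss, es_px$semi_axes[2] * ss,
                          es_px$rotation, es_px$center * ss)
      mod <- fit_ellipsoid(et, es)
      s <- skeletons[skeletons$frame == f, ]
      z <- mean(s$z[s$valid], na.rm = TRUE)
      bv <- bladder_volume(mod, z, geo$calib_top)
      data.frame(frame = f, passed_visibility = TRUE,
                 j_top = et$semi_axes[1], k_top = et$semi_axes[2],
                 phi_top = et$rotation,
                 j_side = es$semi_axes[1], k_side = es$semi_axes[2],
                 phi_side = es$rotation,
                 a = mod$semi_axes[1], b = mod$semi_axes[2],
                 c = mod$semi_axes[3],
                 volume_mm3 = bv$volume_mm3,
                 residual = attr(mod, "residual"))
    }, error = function(e) NULL)
    if (!is.null(row)) rows[[length(rows) + 1]] <- row
  }
  if (!length(rows)) return(NULL)
  out <- do.call(rbind, rows)
  utils::write.csv(out, file.path(out_dir, paste0(well, "_bladder.csv")),
                   row.names = FALSE)
  out
}
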