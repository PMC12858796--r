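#' Ellipsoid model container
#'
#' A swim-bladder ellipsoid in matrix form: points v satisfy
#' `t(v - center) %*% M3 %*% (v - center) = 1` with
#' `M3 = t(R) %*% B %*% R`, `B = diag(1/a^2, 1/b^2, 1/c^2)` and
#' `R = Rx(phi) %*% Rz(psi) %*% Ry(theta)` (the composition order of the
#' rotation blocks as used throughout this package: tilt about x, then the
#' z-type block, then the y-type block).
#'
#' @param a,b,c Semi-axes in mm (x-, y-, z-aligned at zero rotation).
#' @param phi,psi,theta Rotations in radians for the three blocks of `R`.
#' @param center Length-3 center (mm).
#' @return Object of class `ellipsoid_model` with fields `semi_axes`,
#'   `rotations`, `center`, `M3`, `volume` (mm^3).
#' @export
ellipsoid_model <- function(a, b, c, phi = 0, psi = 0, theta = 0,
                            center = c(0, 0, 0)) {
  stopifnot(a > 0, b > 0, c > 0)
  a <- unname(a); b <- unname(b); c <- unname(c)
  phi <- unname(phi); psi <- unname(psi); theta <- unname(theta)
  R <- rot3(phi, psi, theta)
  M3 <- t(R) %*% diag(1 / c(a, b, c)^2) %*% R
  structure(list(
    semi_axes = c(a = a, b = b, c = c),
    rotations = c(phi = phi, psi = psi, theta = theta),
    center = as.numeric(center),
    M3 = M3,
    volume = 4 / 3 * pi * a * b * c
  ), class = "ellipsoid_model")
}

rot3 <- function(phi, psi, theta) {
  Rx <- matrix(c(1, 0, 0,
                 0, cos(phi), sin(phi),
                 0, -sin(phi), cos(phi)), 3, 3)
  Rz <- matrix(c(cos(psi), sin(psi), 0,
                 -sin(psi), cos(psi), 0,
                 0, 0, 1), 3, 3)
  Ry <- matrix(c(cos(theta), 0, -sin(theta),
                 0, 1, 0,
                 sin(theta), 0, cos(theta)), 3, 3)
  Rx %*% Rz %*% Ry
}

#' @export
print.ellipsoid_model <- function(x, ...) {
  cat(sprintf(
    "Ellipsoid: semi-axes (%.3f, %.3f, %.3f) mm, volume %.4f mm^3\n",
    x$semi_axes[1], x$semi_axes[2], x$semi_axes[3], x$volume))
  cat(sprintf("  rotations (phi, psi, theta) = (%.1f, %.1f, %.1f) deg\n",
              x$rotations[1] * 180 / pi, x$rotations[2] * 180 / pi,
              x$rotations[3] * 180 / pi))
  if (!is.null(attr(x, "residual"))) {
    cat(sprintf("  projection residual = %.3g\n", attr(x, "residual")))
  }
  invisible(x)
}

#' Orthogonal shadow of an ellipsoid
#'
#' The silhouette of an ellipsoid under orthogonal projection onto a
#' coordinate plane is an ellipse whose matrix is the Schur complement of
#' the out-of-plane entry of M3: partition M3 into the in-plane block S,
#' cross vector w and out-of-plane scalar q; the shadow matrix is
#' `S - w %*% t(w) / q`.
#'
#' @param model An [ellipsoid_model()] or a 3x3 SPD matrix.
#' @param plane `"top"` (x-y plane, projecting out z) or `"side"` (y-z
#'   plane, projecting out x).
#' @return 2x2 SPD shadow-ellipse matrix.
#' @export
project_ellipsoid <- function(model, plane = c("top", "side")) {
  plane <- match.arg(plane)
  M3 <- if (inherits(model, "ellipsoid_model")) model$M3 else as.matrix(model)
  stopifnot(identical(dim(M3), c(3L, 3L)))
  idx <- if (plane == "top") c(1L, 2L) else c(2L, 3L)
  out <- setdiff(1:3, idx)
  q <- M3[out, out]
  if (q <= 0) stop("invalid ellipsoid: out-of-plane entry not positive")
  S <- M3[idx, idx]
  w <- M3[idx, out]
  S - tcrossprod(w) / q
}

ellipse_matrix_of <- function(x) {
  if (inherits(x, "ellipse_fit")) x$M2 else as.matrix(x)
}

# Construct the unique ellipsoid matrix matching five of the six shadow
# constraints for a given xz entry u = m13: m11 and m33 follow in closed
# form from the top xx and side zz entries, (m12, m23) from a 2x2 linear
# system, and m22 from the average of the top/side yy expressions. Returns
# NULL when the construction leaves the SPD cone. `g` is the yy
# consistency gap (zero along the exact solution family).
shadow_family_member <- function(Mt, Ms, u) {
  T11 <- Mt[1, 1]; T12 <- Mt[1, 2]; T22 <- Mt[2, 2]
  S11 <- Ms[1, 1]; S12 <- Ms[1, 2]; S22 <- Ms[2, 2]
  m11 <- T11 / 2 * (1 + sqrt(1 + 4 * u^2 / (S22 * T11)))
  m33 <- S22 * m11 / T11
  det2 <- 1 - u^2 / (m11 * m33)
  if (det2 <= 1e-9) return(NULL)
  m12 <- (T12 + (u / m33) * S12) / det2
  m23 <- (S12 + (u / m11) * T12) / det2
  yy_top <- T22 + m23^2 / m33
  yy_side <- S11 + m12^2 / m11
  M <- matrix(c(m11, m12, u, m12, (yy_top + yy_side) / 2, m23,
                u, m23, m33), 3, 3)
  if (any(eigen(M, symmetric = TRUE, only.values = TRUE)$values <= 0)) {
    return(NULL)
  }
  list(M = M, g = abs(yy_top - yy_side))
}

# scale-invariant measure of how far M3 is from axis-aligned
offdiag_score <- function(M) {
  M[1, 2]^2 / (M[1, 1] * M[2, 2]) + M[1, 3]^2 / (M[1, 1] * M[3, 3]) +
    M[2, 3]^2 / (M[2, 2] * M[3, 3])
}

# Decompose an SPD M3 into semi-axes and the (phi, psi, theta) rotation of
# rot3(), choosing the eigenvector assignment closest to the identity.
extract_ellipsoid_params <- function(M3) {
  e <- eigen((M3 + t(M3)) / 2, symmetric = TRUE)
  best <- Inf; bestR <- NULL; bestperm <- NULL
  perms <- list(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3),
                c(2, 3, 1), c(3, 1, 2), c(3, 2, 1))
  for (p in perms) for (s1 in c(-1, 1)) for (s2 in c(-1, 1)) {
    for (s3 in c(-1, 1)) {
      R <- rbind(s1 * e$vectors[, p[1]], s2 * e$vectors[, p[2]],
                 s3 * e$vectors[, p[3]])
      if (det(R) < 0) next
      d <- sum((R - diag(3))^2)
      if (d < best) { best <- d; bestR <- R; bestperm <- p }
    }
  }
  R <- bestR
  psi <- asin(max(-1, min(1, -R[1, 2])))
  theta <- atan2(R[1, 3], R[1, 1])
  phi <- atan2(R[3, 2], R[2, 2])
  axes <- 1 / sqrt(e$values[bestperm])
  list(axes = axes, angles = c(phi = phi, psi = psi, theta = theta))
}

#' Reconstruct a 3D ellipsoid from two orthogonal projected ellipses
#'
#' Recovers a swim-bladder ellipsoid whose top-view (x-y) and side-view
#' (y-z) orthogonal shadows match two fitted ellipses, minimizing the
#' elementwise absolute difference between the model shadow matrices and
#' the fitted ellipse matrices over the six shape parameters
#' (a, b, c, phi, psi, theta).
#'
#' Two orthogonal shadows do not determine an ellipsoid uniquely: the
#' shadow matrices of any ellipsoid satisfy the compatibility identity
#' `det(T) * S[2,2] = det(S) * T[1,1]`, so the pair carries only five
#' degrees of freedom and a one-parameter family of ellipsoids — with
#' different volumes — shares both silhouettes exactly. The fit therefore
#' proceeds in two stages: (1) an algebraic sweep over the family
#' (parameterized by the xz entry of the quadric matrix) picks the member
#' that minimizes the residual together with a minimal-rotation selection
#' rule — among near-equally consistent members, the one closest to
#' axis-aligned is preferred, which reflects the near-horizontal posture
#' of a swimming larva; (2) a derivative-free simplex polish of the full
#' L1 objective from that member (and from the axis-aligned closed-form
#' start and any user init, keeping the best). The reported residual makes
#' near-degenerate fits visible; see the methods vignette for the
#' identifiability analysis.
#'
#' @param top,side `ellipse_fit` objects (or 2x2 matrices) in mm for the
#'   top (x-y) and side (y-z) views.
#' @param init Optional [ellipsoid_model()] used as an extra start.
#' @param maxit Simplex iteration cap per start.
#' @param ambiguity_noise Assumed relative noise of the shadow matrices,
#'   used to weigh residual against rotation in the family selection
#'   (default 0.02).
#' @return An [ellipsoid_model()] with attribute `residual` (the final L1
#'   mismatch) and attribute `init_residual` (the residual of the
#'   axis-aligned initialization).
#' @examples
#' tr <- ellipsoid_model(1, 0.6, 0.4)
#' fit <- fit_ellipsoid(project_ellipsoid(tr, "top"),
#'                      project_ellipsoid(tr, "side"))
#' fit$volume  # ~ tr$volume
#' @export
fit_ellipsoid <- function(top, side, init = NULL, maxit = 1000,
                          ambiguity_noise = 0.02) {
  M2t <- ellipse_matrix_of(top)
  M2s <- ellipse_matrix_of(side)
  check_spd2 <- function(M, what) {
    if (any(eigen((M + t(M)) / 2, symmetric = TRUE,
                  only.values = TRUE)$values <= 0)) {
      stop(what, " ellipse matrix is not positive definite")
    }
  }
  check_spd2(M2t, "top"); check_spd2(M2s, "side")

  scale <- mean(abs(c(M2t[1, 1], M2t[2, 2], M2s[1, 1], M2s[2, 2])))
  lim <- pi / 4
  objective <- function(par) {
    ang <- par[4:6]
    pen <- sum(pmax(0, abs(ang) - lim))
    if (pen > 0) return(1e6 * (1 + pen))
    R <- rot3(ang[1], ang[2], ang[3])
    M3 <- t(R) %*% (exp(-2 * par[1:3]) * R)
    sum(abs(project_ellipsoid(M3, "top") - M2t)) +
      sum(abs(project_ellipsoid(M3, "side") - M2s))
  }

  # stage 1: sweep the shadow-consistent family over u = m13
  sel_score <- function(u) {
    b <- shadow_family_member(M2t, M2s, u)
    if (is.null(b)) return(Inf)
    (b$g / (ambiguity_noise * scale))^2 + offdiag_score(b$M)
  }
  U <- sqrt(M2t[1, 1] * M2s[2, 2])
  us <- seq(-0.95 * U, 0.95 * U, length.out = 201)
  vs <- vapply(us, sel_score, numeric(1))
  starts <- list()
  if (any(is.finite(vs))) {
    u0 <- us[which.min(vs)]
    opt_u <- stats::optimize(sel_score, c(u0 - 0.05 * U, u0 + 0.05 * U))
    memb <- shadow_family_member(M2t, M2s, opt_u$minimum)
    if (!is.null(memb)) {
      pr <- extract_ellipsoid_params(memb$M)
      starts <- list(c(log(pr$axes), pr$angles))
    }
  }

  # axis-aligned closed-form initialization
  a0 <- 1 / sqrt(M2t[1, 1])
  b0 <- (1 / sqrt(M2t[2, 2]) + 1 / sqrt(M2s[1, 1])) / 2
  c0 <- 1 / sqrt(M2s[2, 2])
  base <- c(log(a0), log(b0), log(c0), 0, 0, 0)
  init_residual <- objective(base)
  starts <- c(starts, list(base))
  if (!is.null(init)) {
    stopifnot(inherits(init, "ellipsoid_model"))
    starts <- c(starts, list(c(log(init$semi_axes), init$rotations)))
  }

  # stage 2: simplex polish of the L1 objective
  best <- NULL
  for (s in starts) {
    v0 <- objective(s)
    res <- tryCatch(
      stats::optim(s, objective, method = "Nelder-Mead",
                   control = list(maxit = maxit, reltol = 1e-12)),
      error = function(e) NULL)
    if (is.null(res) || res$value > v0) res <- list(par = s, value = v0)
    if (is.null(best) || res$value < best$value) best <- res
  }
  if (is.null(best)) stop("ellipsoid optimization failed for all starts")

  axes <- exp(best$par[1:3])
  ang <- best$par[4:6]
  ctr <- c(if (inherits(top, "ellipse_fit")) top$center else c(0, 0),
           if (inherits(side, "ellipse_fit")) side$center[2] else 0)
  out <- ellipsoid_model(axes[1], axes[2], axes[3],
                         ang[1], ang[2], ang[3], center = ctr)
  attr(out, "residual") <- best$value
  attr(out, "init_residual") <- init_residual
  out
}

#' @export
summary.ellipsoid_model <- function(object, ...) {
  print(object)
  ev <- eigen(object$M3, symmetric = TRUE, only.values = TRUE)$values
  cat(sprintf("  principal semi-axes from M3: %s mm\n",
              paste(sprintf("%.3f", sort(1 / sqrt(ev), decreasing = TRUE)),
                    collapse = ", ")))
  invisible(object)
}

#' Height-corrected swim-bladder volume
#'
#' Lengths measured through the top view assume the nominal object
#' distance; a larva swimming at height z above the well bottom is closer
#' to the camera, so its top-view-derived axes are rescaled by the
#' magnification ratio `m(d) / m(d - z)` before the volume is computed.
#' The side-view-derived axis (c) is unaffected.
#'
#' @param model An [ellipsoid_model()] with axes in mm.
#' @param fish_height_z Height of the larva above the reference (well
#'   bottom) plane, mm.
#' @param calib The top-view [view_calibration()].
#' @return List with `volume_mm3`, `correction_factor` and the corrected
#'   `model`.
#' @export
bladder_volume <- function(model, fish_height_z, calib) {
  stopifnot(inherits(model, "ellipsoid_model"),
            inherits(calib, "view_calibration"))
  d <- calib$object_distance
  f <- calib$focal_length
  if (d - fish_height_z <= f) {
    stop("corrected object distance is at or below the focal length")
  }
  fac <- magnification(d, f) / magnification(d - fish_height_z, f)
  a <- model$semi_axes[1] * fac
  b <- model$semi_axes[2] * fac
  c_ <- model$semi_axes[3]
  corrected <- ellipsoid_model(a, b, c_,
                               model$rotations[1], model$rotations[2],
                               model$rotations[3], model$center)
  list(volume_mm3 = corrected$volume, correction_factor = fac,
       model = corrected)
}

#' Visibility filtering of skeleton frames
#'
#' When a larva faces a camera, its projected body length collapses and the
#' swim bladder hides behind the eyes. Each frame's visibility ratio is the
#' smaller of the two view-projected skeleton lengths divided by the true
#' 3D length; frames with ratio below the threshold are excluded.
#'
#' @param skeletons A multi-frame `skeleton3d`.
#' @param ratio_threshold Minimum acceptable ratio (default 0.5); a frame
#'   passes iff `ratio >= ratio_threshold`.
#' @return Data frame `frame`, `proj_length_top`, `proj_length_side`,
#'   `true_length_3d`, `ratio`, `passed`. Frames whose lengths are not
#'   computable (invalid keypoints) get `NA` ratio and `passed = FALSE`.
#' @export
visibility_filter <- function(skeletons, ratio_threshold = 0.5) {
  frames <- sort(unique(skeletons$frame))
  rows <- lapply(frames, function(f) {
    s <- skeletons[skeletons$frame == f, ]
    l3 <- tryCatch(skeleton_length(s, "3d"), error = function(e) NA_real_)
    lt <- tryCatch(skeleton_length(s, "top"), error = function(e) NA_real_)
    ls <- tryCatch(skeleton_length(s, "side"), error = function(e) NA_real_)
    if (isTRUE(l3 == 0)) stop("zero 3D skeleton length at frame ", f)
    ratio <- if (is.na(l3)) NA_real_ else min(lt, ls) / l3
    data.frame(frame = f, proj_length_top = lt, proj_length_side = ls,
               true_length_3d = l3, ratio = ratio,
               passed = isTRUE(ratio >= ratio_threshold))
  })
  do.call(rbind, rows)
}

#' Bladder volume vs swimming height correlation
#'
#' Pearson correlation between per-frame swim-bladder volume and larva
#' height, on frame-aligned pairs (optionally restricted to
#' visibility-passed frames).
#'
#' @param volumes Numeric volume series (mm^3), aligned by frame.
#' @param heights Numeric z series (mm), same length.
#' @param passed Optional logical mask of frames to keep.
#' @return List with `r`, `p`, `n`, and the paired data frame `pairs`.
#' @export
volume_height_correlation <- function(volumes, heights, passed = NULL) {
  stopifnot(length(volumes) == length(heights))
  keep <- is.finite(volumes) & is.finite(heights)
  if (!is.null(passed)) keep <- keep & passed
  v <- volumes[keep]; h <- heights[keep]
  if (length(v) < 3) stop("need at least 3 paired valid frames")
  if (stats::sd(v) == 0 || stats::sd(h) == 0) {
    stop("correlation undefined for a constant series")
  }
  ct <- stats::cor.test(v, h)
  list(r = unname(ct$estimate), p = ct$p.value, n = length(v),
       pairs = data.frame(volume = v, height = h))
}
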