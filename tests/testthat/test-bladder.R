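test_that("direct least-squares ellipse fit recovers exact samples", {
  # circle
  circ <- fit_ellipse(ellipse_points(ellipse_shape(3, 3), 100))
  expect_equal(unname(circ$semi_axes), c(3, 3), tolerance = 1e-6)

  # axis-aligned ellipse
  ax <- fit_ellipse(ellipse_points(ellipse_shape(3, 1, 0, c(5, -2)), 80))
  expect_equal(unname(ax$semi_axes), c(3, 1), tolerance = 1e-6)
  expect_equal(unname(ax$center), c(5, -2), tolerance = 1e-6)
  expect_true(min(abs(c(ax$rotation, ax$rotation - pi))) < 1e-6)

  # rotated ellipse, partial arc
  rot <- ellipse_shape(2, 0.8, 0.6, c(-1, 3))
  p <- ellipse_points(rot, 40)[1:25, ]
  fr <- fit_ellipse(p)
  expect_equal(unname(fr$semi_axes), c(2, 0.8), tolerance = 1e-6)
  expect_equal(fr$rotation, 0.6, tolerance = 1e-6)

  expect_error(fit_ellipse(cbind(1:10, 2 * (1:10))), "ellipse")
  expect_error(fit_ellipse(cbind(1:4, c(1, 2, 1, 2))), "at least 5")
})

test_that("noisy ellipse fits stay within 2% over repeated draws", {
  set.seed(17)
  truth <- ellipse_shape(3, 1.5, 0.9, c(2, 2))
  rel_err <- replicate(100, {
    p <- ellipse_points(truth, 200, jitter_sd = 0.05)
    f <- fit_ellipse(p)
    max(abs(f$semi_axes - truth$semi_axes) / truth$semi_axes)
  })
  expect_lt(stats::median(rel_err), 0.02)
  expect_lt(mean(rel_err > 0.02), 0.1)
})

test_that("mask contour extraction feeds accurate ellipse fits", {
  # filled disk of radius 12: contour points within 1 px of the radius
  n <- 41
  ctr <- (n + 1) / 2
  d <- sqrt(outer((1:n - ctr)^2, (1:n - ctr)^2, "+"))
  disk <- (d <= 12) * 1
  pts <- mask_to_contour(disk)
  r <- sqrt((pts[, 1] - ctr)^2 + (pts[, 2] - ctr)^2)
  expect_true(all(abs(r - 12) <= 1))

  # filled rectangle: boundary spans its corners
  rect <- matrix(0, 30, 40)
  rect[10:20, 5:35] <- 1
  pb <- mask_to_contour(rect)
  expect_equal(range(pb[, 1]), c(4.5, 35.5), tolerance = 0.1)
  expect_equal(range(pb[, 2]), c(9.5, 20.5), tolerance = 0.1)

  expect_error(mask_to_contour(matrix(0, 10, 10)), "empty")
  two <- matrix(0, 40, 40)
  two[5:25, 5:25] <- 1
  two[30:35, 30:35] <- 1
  expect_warning(mask_to_contour(two), "largest")
})

test_that("rendered bladder shadow masks round-trip through the ellipse fit", {
  cfg <- sim_config(seed = 3, duration = 0.5, speed_scale = 0,
                    pixel_sigma = 0, drop_rate = 0)
  sim <- simulate_larva(cfg)
  ct <- fixture_calib("top"); cs <- fixture_calib("side")
  rv <- render_views(sim, ct, cs, mask_frames = 0)
  mk <- rv$masks[["0"]]$top
  f <- fit_ellipse(mask_to_contour(mk))
  # stationary larva heads along +x: top shadow semi-axes are (a, b) in px
  s <- mm_per_px(ct)
  expect_equal(unname(f$semi_axes) * s,
               unname(cfg$bladder_axes[1:2]), tolerance = 0.03)
})

test_that("visibility ratio flags camera-facing postures", {
  # fish lying flat in the top plane: top ratio 1
  s <- skeleton_from_mm(straight_fish_mm(z = 6))
  vis <- visibility_filter(rbind(s))
  expect_equal(vis$proj_length_top / vis$true_length_3d, 1,
               tolerance = 1e-12)

  # ratio 1.8/4.0 = 0.45 < 0.5: excluded
  xyz <- straight_fish_mm()
  shrunk <- xyz
  shrunk[, 1] <- shrunk[, 1] * 1.8 / 4          # top projection 1.8 mm
  shrunk[, 3] <- 6 + sqrt(pmax(0, xyz[, 1]^2 - shrunk[, 1]^2))
  sv <- skeleton_from_mm(shrunk)
  v2 <- visibility_filter(sv)
  expect_lt(v2$ratio, 0.5)
  expect_false(v2$passed)

  # fish pointing straight down the top-view axis: excluded (near) always
  set.seed(8)
  frames <- lapply(0:19, function(f) {
    down <- cbind(x = rnorm(8, 0, 0.02), y = rnorm(8, 0, 0.02),
                  z = 10 - c(0, 0.35, 0.35, 1.2, 1.9, 2.6, 3.3, 4.0))
    skeleton_from_mm(down, frame = f)
  })
  vd <- visibility_filter(do.call(rbind, frames))
  expect_gte(mean(!vd$passed), 0.95)
})

test_that("ellipsoid shadows follow the Schur-complement geometry", {
  # sphere: circular shadow of the same radius in both planes
  sp <- ellipsoid_model(2, 2, 2)
  for (pl in c("top", "side")) {
    sh <- project_ellipsoid(sp, pl)
    expect_equal(sh, diag(1 / 4, 2), tolerance = 1e-12)
  }
  # axis-aligned: block-diagonal shadows pick the in-plane axes
  ax <- ellipsoid_model(1, 0.6, 0.4)
  expect_equal(project_ellipsoid(ax, "top"),
               diag(1 / c(1, 0.6)^2), tolerance = 1e-12)
  expect_equal(project_ellipsoid(ax, "side"),
               diag(1 / c(0.6, 0.4)^2), tolerance = 1e-12)
})

test_that("shadow matrix matches a surface-point projection oracle", {
  set.seed(12)
  for (rep_i in 1:3) {
    axes <- runif(3, 0.3, 1)
    ang <- runif(3, -0.6, 0.6)
    m <- ellipsoid_model(axes[1], axes[2], axes[3], ang[1], ang[2], ang[3])
    # sample the surface, project, and check the shadow boundary
    n <- 1e5
    u <- matrix(rnorm(3 * n), n)
    u <- u / sqrt(rowSums(u^2))
    E <- eigen(m$M3, symmetric = TRUE)
    half <- E$vectors %*% diag(1 / sqrt(E$values)) %*% t(E$vectors)
    pts <- u %*% half                       # surface points of the quadric
    for (pl in c("top", "side")) {
      idx <- if (pl == "top") 1:2 else 2:3
      sh <- project_ellipsoid(m, pl)
      q <- rowSums((pts[, idx] %*% sh) * pts[, idx])
      expect_lte(max(q), 1 + 1e-9)          # all projections inside
      expect_gte(max(q), 1 - 0.005)         # boundary is attained
    }
  }
})

test_that("ellipsoid reconstruction is exact in identifiable regimes", {
  # sphere
  sp <- ellipsoid_model(2, 2, 2)
  f <- fit_ellipsoid(project_ellipsoid(sp, "top"),
                     project_ellipsoid(sp, "side"))
  expect_lt(attr(f, "residual"), 1e-6)
  expect_equal(unname(f$semi_axes), rep(2, 3), tolerance = 1e-4)

  # axis-aligned (1, 0.6, 0.4): volume within 1%
  tr <- ellipsoid_model(1, 0.6, 0.4)
  f2 <- fit_ellipsoid(project_ellipsoid(tr, "top"),
                      project_ellipsoid(tr, "side"))
  expect_equal(f2$volume, 4 / 3 * pi * 0.24, tolerance = 0.01)
  expect_lte(attr(f2, "residual"), attr(f2, "init_residual") + 1e-12)

  # single in-plane rotations are recovered through the selection rule
  for (ang in list(c(0.2, 0, 0), c(0, 0.25, 0))) {
    tr3 <- ellipsoid_model(0.8, 0.5, 0.3, ang[1], ang[2], ang[3])
    f3 <- fit_ellipsoid(project_ellipsoid(tr3, "top"),
                        project_ellipsoid(tr3, "side"))
    expect_lt(attr(f3, "residual"), 1e-6)
    expect_equal(f3$volume, tr3$volume, tolerance = 0.01)
  }
})

test_that("the two shadows of any ellipsoid satisfy the rank-5 identity", {
  # det(T) * S[2,2] = det(S) * T[1,1]: the shadow pair carries only five
  # degrees of freedom, which is why the fit needs a selection rule
  set.seed(30)
  for (i in 1:20) {
    m <- ellipsoid_model(runif(1, 0.1, 1), runif(1, 0.1, 1),
                         runif(1, 0.1, 1), runif(1, -0.7, 0.7),
                         runif(1, -0.7, 0.7), runif(1, -0.7, 0.7))
    Tm <- project_ellipsoid(m, "top")
    Sm <- project_ellipsoid(m, "side")
    expect_equal(det(Tm) * Sm[2, 2], det(Sm) * Tm[1, 1],
                 tolerance = 1e-9)
  }
})

test_that("volume is invariant across parameterizations reaching one M3", {
  m1 <- ellipsoid_model(0.9, 0.5, 0.3, 0.3, 0.1, -0.2)
  ev <- eigen(m1$M3, symmetric = TRUE, only.values = TRUE)$values
  expect_equal(4 / 3 * pi / sqrt(prod(ev)), m1$volume, tolerance = 1e-12)
  # axis permutation with compensating rotation leaves M3 and volume alone
  m2 <- ellipsoid_model(0.5, 0.9, 0.3, 0, pi / 2 - 1e-12, 0)
  expect_equal(sort(eigen(m2$M3, symmetric = TRUE,
                          only.values = TRUE)$values),
               sort(eigen(ellipsoid_model(0.9, 0.5, 0.3)$M3,
                          symmetric = TRUE, only.values = TRUE)$values),
               tolerance = 1e-6)
  expect_equal(m2$volume, m1$volume, tolerance = 1e-12)
})

test_that("height correction rescales top-view axes by the magnification ratio", {
  cal <- fixture_calib("top")
  m <- ellipsoid_model(0.45, 0.3, 0.28)
  bv0 <- bladder_volume(m, 0, cal)
  expect_equal(bv0$volume_mm3, m$volume, tolerance = 1e-12)
  expect_equal(bv0$correction_factor, 1)

  z <- 6
  bv <- bladder_volume(m, z, cal)
  fac <- magnification(cal$object_distance, cal$focal_length) /
    magnification(cal$object_distance - z, cal$focal_length)
  expect_equal(bv$volume_mm3, m$volume * fac^2, tolerance = 1e-12)
  expect_lt(fac, 1)
  expect_error(bladder_volume(m, cal$object_distance - 10, cal))
})

test_that("dice coefficient handles the canonical overlap cases", {
  a <- matrix(0, 10, 10); a[2:5, 2:5] <- 1
  expect_equal(dice(a, a), 1)
  b <- matrix(0, 10, 10); b[7:9, 7:9] <- 1
  expect_equal(dice(a, b), 0)
  # two unit squares overlapping half their area
  sq1 <- matrix(0, 10, 20); sq1[1:10, 1:10] <- 1
  sq2 <- matrix(0, 10, 20); sq2[1:10, 6:15] <- 1
  expect_equal(dice(sq1, sq2), 0.5)
  expect_equal(dice(matrix(0, 3, 3), matrix(0, 3, 3)), 1)
  expect_equal(dice(a, b), dice(b, a))
  expect_error(dice(a, matrix(0, 5, 5)), "shapes")
})

test_that("volume-height correlation recovers planted association", {
  v <- seq(1, 2, length.out = 50)
  expect_equal(volume_height_correlation(v, v)$r, 1, tolerance = 1e-12)
  expect_equal(volume_height_correlation(v, -v)$r, -1, tolerance = 1e-12)
  expect_error(volume_height_correlation(rep(1, 10), 1:10), "constant")

  set.seed(14)
  ok <- replicate(20, {
    h <- rnorm(200)
    vv <- 0.8 * h + sqrt(1 - 0.64) * rnorm(200)
    r <- volume_height_correlation(vv, h)$r
    r >= 0.7 && r <= 0.9
  })
  expect_gte(mean(ok), 0.9)
})
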