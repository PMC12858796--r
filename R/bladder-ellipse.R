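#' Ellipse shape container
#'
#' An ellipse in matrix form: points u on the ellipse satisfy
#' `t(u - center) %*% M2 %*% (u - center) = 1`, with
#' `M2 = t(Q) %*% A %*% Q`, `A = diag(1/j^2, 1/k^2)` and `Q` the rotation
#' matrix of angle `phi`.
#'
#' @param j,k Semi-axes, `j >= k > 0` (same units as the points).
#' @param phi Rotation in radians, reported in `[0, pi)`.
#' @param center Length-2 center.
#' @return Object of class `ellipse_fit` with fields `center`, `semi_axes`,
#'   `rotation`, `M2`.
#' @export
ellipse_shape <- function(j, k, phi = 0, center = c(0, 0)) {
  stopifnot(j > 0, k > 0)
  if (k > j) { tmp <- j; j <- k; k <- tmp; phi <- phi + pi / 2 }
  phi <- phi %% pi
  Q <- matrix(c(cos(phi), sin(phi), -sin(phi), cos(phi)), 2, 2)
  M2 <- t(Q) %*% diag(c(1 / j^2, 1 / k^2)) %*% Q
  structure(list(center = as.numeric(center), semi_axes = c(j = j, k = k),
                 rotation = phi, M2 = M2),
            class = "ellipse_fit")
}

#' @export
print.ellipse_fit <- function(x, ...) {
  cat(sprintf(
    "Ellipse: center (%.3f, %.3f), semi-axes j = %.3f, k = %.3f, phi = %.1f deg\n",
    x$center[1], x$center[2], x$semi_axes[1], x$semi_axes[2],
    x$rotation * 180 / pi))
  invisible(x)
}

# Recover (j, k, phi) from a centered SPD ellipse matrix.
matrix_to_ellipse <- function(M2, center = c(0, 0)) {
  e <- eigen((M2 + t(M2)) / 2, symmetric = TRUE)
  if (any(e$values <= 0)) stop("matrix is not positive definite")
  # smallest eigenvalue -> major axis
  j <- 1 / sqrt(min(e$values))
  k <- 1 / sqrt(max(e$values))
  v <- e$vectors[, which.min(e$values)]
  # M2 = t(Q) A Q: the major-axis direction is (cos phi, -sin phi)
  phi <- atan2(-v[2], v[1]) %% pi
  ellipse_shape(j, k, phi, center)
}

#' Sample points on an ellipse
#'
#' @param fit An [ellipse_shape()] / `ellipse_fit`.
#' @param n Number of points.
#' @param jitter_sd Optional Gaussian radial jitter (same units).
#' @return n x 2 matrix.
#' @export
ellipse_points <- function(fit, n = 100, jitter_sd = 0) {
  t <- seq(0, 2 * pi, length.out = n + 1)[-1]
  phi <- fit$rotation
  Qt <- matrix(c(cos(phi), -sin(phi), sin(phi), cos(phi)), 2, 2)
  w <- rbind(fit$semi_axes[1] * cos(t), fit$semi_axes[2] * sin(t))
  p <- t(Qt %*% w) + rep(fit$center, each = n)
  if (jitter_sd > 0) p <- p + matrix(stats::rnorm(2 * n, 0, jitter_sd), n, 2)
  p
}

#' Direct least-squares ellipse fit
#'
#' Fits an ellipse to scattered 2D points by the numerically stable direct
#' conic least-squares method with the ellipse-specific constraint
#' (4AC - B^2 = 1), so the result is always an ellipse. Returns the
#' geometric parameters with `j >= k` and rotation in `[0, pi)`.
#'
#' @param contour_points n x 2 matrix of points, n >= 5, not collinear.
#' @return An `ellipse_fit` (see [ellipse_shape()]).
#' @examples
#' p <- ellipse_points(ellipse_shape(3, 1, 0.4, c(1, 2)), 50)
#' fit_ellipse(p)
#' @export
fit_ellipse <- function(contour_points) {
  p <- as.matrix(contour_points)
  stopifnot(ncol(p) == 2)
  p <- p[stats::complete.cases(p), , drop = FALSE]
  if (nrow(p) < 5) stop("need at least 5 points to fit an ellipse")
  # center/scale for conditioning
  mu <- colMeans(p)
  sc <- max(apply(p, 2, stats::sd))
  if (!is.finite(sc) || sc == 0) stop("degenerate point set")
  x <- (p[, 1] - mu[1]) / sc
  y <- (p[, 2] - mu[2]) / sc
  D1 <- cbind(x^2, x * y, y^2)
  D2 <- cbind(x, y, 1)
  S1 <- crossprod(D1)
  S2 <- crossprod(D1, D2)
  S3 <- crossprod(D2)
  T_ <- tryCatch(-solve(S3, t(S2)), error = function(e)
    stop("degenerate or collinear points: cannot fit an ellipse"))
  M <- S1 + S2 %*% T_
  M <- rbind(M[3, ] / 2, -M[2, ], M[1, ] / 2)
  ev <- eigen(M)
  evec <- Re(ev$vectors)
  cond <- 4 * evec[1, ] * evec[3, ] - evec[2, ]^2
  ok <- which(cond > 0)
  if (!length(ok)) stop("degenerate or collinear points: no ellipse solution")
  a1 <- evec[, ok[1]]
  coef <- c(a1, T_ %*% a1)  # A B C D E F on scaled coords
  A <- coef[1]; B <- coef[2]; C <- coef[3]
  D <- coef[4]; E <- coef[5]; F_ <- coef[6]
  ctr <- solve(matrix(c(2 * A, B, B, 2 * C), 2, 2), -c(D, E))
  kval <- A * ctr[1]^2 + B * ctr[1] * ctr[2] + C * ctr[2]^2 +
    D * ctr[1] + E * ctr[2] + F_
  M2s <- matrix(c(A, B / 2, B / 2, C), 2, 2) / (-kval)
  if (any(eigen(M2s, symmetric = TRUE, only.values = TRUE)$values <= 0)) {
    stop("degenerate fit: not an ellipse")
  }
  # undo scaling: x_orig = mu + sc * x_s  =>  M2_orig = M2s / sc^2
  fit <- matrix_to_ellipse(M2s / sc^2, center = mu + sc * ctr)
  fit
}

#' Extract the outer contour of a binary mask
#'
#' Labels the foreground (4-connected), keeps the largest component (with a
#' warning when several exist), and extracts its outer boundary as the 0.5
#' level set of the indicator image, giving half-pixel-accurate contour
#' points suitable for [fit_ellipse()].
#'
#' @param mask Binary/logical/numeric matrix; foreground is `> 0`. Rows are
#'   image rows (v), columns are image columns (u).
#' @param min_size Minimum component size in pixels (default 20).
#' @return n x 2 matrix of (u, v) contour points in pixel coordinates.
#' @export
mask_to_contour <- function(mask, min_size = 20) {
  m <- (as.matrix(mask) > 0)
  if (!any(m)) stop("empty mask: no foreground pixels")
  lab <- label_components(m)
  sizes <- tabulate(lab[lab > 0])
  if (length(sizes) > 1) {
    warning(sprintf("mask has %d components; using the largest", length(sizes)))
  }
  big <- which.max(sizes)
  if (sizes[big] < min_size) {
    stop(sprintf("largest component has %d px (< %d)", sizes[big], min_size))
  }
  keep <- (lab == big) * 1
  # pad so the level set closes at image borders
  z <- matrix(0, nrow(keep) + 2, ncol(keep) + 2)
  z[2:(nrow(keep) + 1), 2:(ncol(keep) + 1)] <- keep
  cl <- grDevices::contourLines(x = seq_len(nrow(z)) - 1,
                                y = seq_len(ncol(z)) - 1, z = z,
                                levels = 0.5)
  if (!length(cl)) stop("no contour found")
  cl <- cl[[which.max(vapply(cl, function(c) length(c$x), numeric(1)))]]
  cbind(u = cl$y, v = cl$x)  # x indexes rows (v), y indexes columns (u)
}

# 4-connected component labeling by flood fill.
label_components <- function(m) {
  nr <- nrow(m); nc <- ncol(m)
  lab <- matrix(0L, nr, nc)
  cur <- 0L
  for (start in which(m)) {
    if (lab[start] != 0L) next
    cur <- cur + 1L
    queue <- start
    lab[start] <- cur
    while (length(queue)) {
      i <- queue[[length(queue)]]
      queue <- queue[-length(queue)]
      r <- ((i - 1L) %% nr) + 1L
      c <- ((i - 1L) %/% nr) + 1L
      for (d in list(c(r - 1L, c), c(r + 1L, c), c(r, c - 1L), c(r, c + 1L))) {
        if (d[1] < 1L || d[1] > nr || d[2] < 1L || d[2] > nc) next
        j <- (d[2] - 1L) * nr + d[1]
        if (m[j] && lab[j] == 0L) {
          lab[j] <- cur
          queue <- c(queue, j)
        }
      }
    }
  }
  lab
}

#' Dice overlap coefficient
#'
#' `2 |A intersect B| / (|A| + |B|)` between two equally shaped binary
#' masks; defined as 1 when both masks are empty.
#'
#' @param mask_a,mask_b Binary matrices of identical shape (foreground
#'   `> 0`).
#' @return Dice coefficient in `[0, 1]`.
#' @export
dice <- function(mask_a, mask_b) {
  a <- as.matrix(mask_a) > 0
  b <- as.matrix(mask_b) > 0
  if (!identical(dim(a), dim(b))) stop("mask shapes differ")
  denom <- sum(a) + sum(b)
  if (denom == 0) return(1)
  2 * sum(a & b) / denom
}
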