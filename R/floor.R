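#' Construct a floor plane
#'
#' A plane `Ax + By + Cz + D = 0` with a unit normal oriented so that
#' `B >= 0` (normal on the camera-up side). `tilt_cos` is the cosine of the
#' angle between the camera's vertical axis (0, 1, 0) and the floor normal,
#' i.e. simply `B`; it enters the altitude measure of the foot- and
#' head-altitude modules.
#'
#' @param A,B,C,D Plane coefficients (any scale; normalized internally).
#' @param inlier_count Optional number of RANSAC inliers supporting the fit.
#' @return An object of class `floor_plane`.
#' @export
#' @examples
#' floor_plane(0, 1, 0, 0)  # a horizontal floor through the origin
floor_plane <- function(A, B, C, D, inlier_count = NA_integer_) {
  n <- c(A, B, C)
  len <- sqrt(sum(n^2))
  if (len <= .Machine$double.eps) stop("degenerate plane normal")
  n <- n / len
  D <- D / len
  if (n[2] < 0) {
    n <- -n
    D <- -D
  }
  structure(
    list(A = n[1], B = n[2], C = n[3], D = D,
         inlier_count = as.integer(inlier_count),
         tilt_cos = n[2]),
    class = "floor_plane"
  )
}

#' @export
print.floor_plane <- function(x, ...) {
  cat(sprintf(
    "<floor_plane> %.4fx + %.4fy + %.4fz + %.4f = 0 (tilt_cos %.4f, %s inliers)\n",
    x$A, x$B, x$C, x$D, x$tilt_cos,
    ifelse(is.na(x$inlier_count), "?", x$inlier_count)))
  invisible(x)
}

plane_normal <- function(plane) c(plane$A, plane$B, plane$C)

as_point_matrix <- function(points) {
  if (is.data.frame(points)) {
    points <- as.matrix(points[, c("x", "y", "z")])
  } else if (is.null(dim(points))) {
    points <- matrix(points, ncol = 3)
  }
  storage.mode(points) <- "double"
  points
}

# Total-least-squares plane through a point set: normal = singular vector of
# the smallest singular value of the centered cloud.
fit_plane_tls <- function(pts) {
  ctr <- colMeans(pts)
  sv <- svd(sweep(pts, 2, ctr))
  n <- sv$v[, 3]
  floor_plane(n[1], n[2], n[3], -sum(n * ctr), inlier_count = nrow(pts))
}

plane_from_triple <- function(p1, p2, p3) {
  n <- pracma_cross(p2 - p1, p3 - p1)
  if (sqrt(sum(n^2)) <= 1e-12) return(NULL)  # collinear sample
  floor_plane(n[1], n[2], n[3], -sum(n * p1))
}

pracma_cross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' Fit the floor plane by RANSAC
#'
#' Repeatedly samples 3-point plane hypotheses, scores them by the number of
#' points within `inlier_tol` perpendicular distance, keeps the best, and
#' refits the final plane to its inliers by total least squares. On small
#' clouds (when every 3-point subset fits inside the iteration budget) the
#' hypotheses are enumerated exhaustively instead of sampled.
#'
#' @param cloud A data frame with columns `x`, `y`, `z`, or an n x 3 matrix
#'   (meters). At least 3 non-collinear points.
#' @param inlier_tol Inlier distance tolerance in meters (default 0.02).
#' @param iters Number of RANSAC hypotheses (default 500).
#' @param seed Integer seed for the hypothesis sampler.
#' @return A [floor_plane()] with `inlier_count` filled in.
#' @export
fit_floor_ransac <- function(cloud, inlier_tol = 0.02, iters = 500, seed = 1) {
  pts <- as_point_matrix(cloud)
  if (nrow(pts) < 3) stop("no plane: need at least 3 points")
  if (inlier_tol <= 0) stop("inlier_tol must be positive")
  n <- nrow(pts)

  triples <- if (choose(n, 3) <= iters) {
    utils::combn(n, 3, simplify = FALSE)
  } else {
    with_seed(seed, lapply(seq_len(iters), function(i) sample.int(n, 3)))
  }

  best <- NULL
  best_count <- -1L
  for (tri in triples) {
    pl <- plane_from_triple(pts[tri[1], ], pts[tri[2], ], pts[tri[3], ])
    if (is.null(pl)) next
    d <- abs(pts %*% plane_normal(pl) + pl$D)
    count <- sum(d <= inlier_tol)
    if (count > best_count) {
      best_count <- count
      best <- pl
    }
  }
  if (is.null(best)) stop("no plane: all hypotheses degenerate")

  inl <- abs(pts %*% plane_normal(best) + best$D) <= inlier_tol
  if (sum(inl) >= 3) best <- fit_plane_tls(pts[inl, , drop = FALSE])
  best$inlier_count <- as.integer(sum(inl))
  best
}

#' Altitude of a point over the floor plane
#'
#' The module's altitude measure: the absolute plane equation residual
#' `|Ax + By + Cz + D|` multiplied by the tilt cosine between the camera's
#' vertical axis and the floor normal. With `strict = FALSE` the tilt factor
#' is dropped and the plain perpendicular distance is returned (the two
#' coincide exactly on a horizontal floor).
#'
#' @param p A point (xyz vector) or n x 3 matrix.
#' @param plane A [floor_plane()].
#' @param strict Keep the tilt-cosine factor (default TRUE).
#' @return Distance(s) in meters.
#' @export
point_plane_distance <- function(p, plane, strict = TRUE) {
  pts <- as_point_matrix(p)
  d <- abs(as.vector(pts %*% plane_normal(plane) + plane$D))
  if (strict) d <- d * plane$tilt_cos
  d
}

# Deterministic orthonormal in-plane basis (u, v): u is the unit projection
# of the camera x axis onto the plane (z axis if degenerate), v = u x n.
# On an exactly horizontal floor this reproduces raw (x, z) coordinates.
plane_basis <- function(plane) {
  n <- plane_normal(plane)
  u <- c(1, 0, 0) - sum(c(1, 0, 0) * n) * n
  if (sqrt(sum(u^2)) < 1e-8) u <- c(0, 0, 1) - sum(c(0, 0, 1) * n) * n
  u <- u / sqrt(sum(u^2))
  v <- pracma_cross(u, n)
  list(u = u, v = v, n = n, origin = -plane$D * n)
}

#' Project points onto the floor plane
#'
#' Perpendicular projection onto the plane, expressed in a fixed orthonormal
#' in-plane basis derived deterministically from the plane normal. For a
#' horizontal floor `y = 0` the result is exactly the raw `(x, z)` pair.
#'
#' @inheritParams point_plane_distance
#' @return A matrix with columns `u`, `v` (floor coordinates in meters); a
#'   named vector if `p` was a single point.
#' @export
ground_project <- function(p, plane) {
  single <- is.null(dim(p)) && !is.data.frame(p)
  pts <- as_point_matrix(p)
  b <- plane_basis(plane)
  resid <- as.vector(pts %*% b$n + plane$D)
  proj <- pts - outer(resid, b$n)
  rel <- sweep(proj, 2, b$origin)
  out <- cbind(u = as.vector(rel %*% b$u), v = as.vector(rel %*% b$v))
  if (single) out[1, ] else out
}

#' Distance from a floor point to the base-of-support line
#'
#' Perpendicular distance from the ground-projected body centroid to the 2D
#' line through the two ground-projected foot positions — the body-sway
#' stimulus. When the two foot points coincide (within `tol`) the point-line
#' distance degenerates and the plain Euclidean distance to the common foot
#' point is used.
#'
#' @param pc Ground-projected centroid, length-2 (u, v).
#' @param left_foot,right_foot Ground-projected foot points, length-2.
#' @param tol Foot-coincidence tolerance in meters (default 0.01).
#' @return Distance in meters.
#' @export
base_of_support_distance <- function(pc, left_foot, right_foot, tol = 0.01) {
  dx <- right_foot[1] - left_foot[1]
  dz <- right_foot[2] - left_foot[2]
  len <- sqrt(dx^2 + dz^2)
  if (len < tol) {
    return(unname(sqrt(sum((pc - (left_foot + right_foot) / 2)^2))))
  }
  unname(abs(-dz * pc[1] + dx * pc[2] + dz * left_foot[1] -
               dx * left_foot[2]) / len)
}
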