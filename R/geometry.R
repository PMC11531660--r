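# Basic 3D primitives: points are numeric length-3 vectors (mm), directions are
# unit length-3 vectors. Lines and planes are lightweight S3 records.

#' Normalize a 3-vector to unit length
#'
#' @param v numeric length-3 vector.
#' @return unit vector with the same direction.
#' @keywords internal
unit3 <- function(v) {
  n <- sqrt(sum(v^2))
  if (!is.finite(n) || n < .Machine$double.eps * 100)
    stop("cannot normalize a (near-)zero vector", call. = FALSE)
  v / n
}

#' Cross product of two 3-vectors
#' @keywords internal
cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

dot3 <- function(a, b) sum(a * b)

norm3 <- function(v) sqrt(sum(v^2))

#' Construct an infinite 3D line
#'
#' A line is stored as an anchor point and a unit direction; any point on the
#' line is `anchor + k * direction` for real `k`.
#'
#' @param anchor numeric length-3 point on the line (mm).
#' @param direction numeric length-3 direction; normalized internally.
#' @return an object of class `line3` with fields `anchor` and `direction`.
#' @export
line3 <- function(anchor, direction) {
  stopifnot(length(anchor) == 3, length(direction) == 3,
            all(is.finite(anchor)), all(is.finite(direction)))
  structure(list(anchor = as.numeric(anchor), direction = unit3(as.numeric(direction))),
            class = "line3")
}

#' @export
print.line3 <- function(x, ...) {
  cat(sprintf("<line3> anchor (%.3f, %.3f, %.3f)  direction (%.4f, %.4f, %.4f)\n",
              x$anchor[1], x$anchor[2], x$anchor[3],
              x$direction[1], x$direction[2], x$direction[3]))
  invisible(x)
}

#' Construct a plane from an anchor point and a normal
#'
#' @param anchor numeric length-3 point on the plane (mm).
#' @param normal numeric length-3 normal; normalized internally.
#' @return an object of class `plane3` with fields `anchor` and `normal`.
#' @export
plane3 <- function(anchor, normal) {
  stopifnot(length(anchor) == 3, length(normal) == 3,
            all(is.finite(anchor)), all(is.finite(normal)))
  structure(list(anchor = as.numeric(anchor), normal = unit3(as.numeric(normal))),
            class = "plane3")
}

#' Angle between two directions in degrees
#'
#' The dot product is clamped to \[-1, 1\] before `acos`, so rounding noise on
#' (anti)parallel inputs cannot produce `NaN`.
#'
#' @param d1,d2 unit 3-vectors.
#' @return angle in degrees, in \[0, 180\].
#' @export
angle_deg <- function(d1, d2) {
  acos(max(-1, min(1, dot3(unit3(d1), unit3(d2))))) * 180 / pi
}

#' Project a direction into a plane
#'
#' Returns the normalized component of `d` lying within the plane. Fails when
#' `d` is within `tol_deg` of the plane normal, where the projection is
#' degenerate.
#'
#' @param d direction (3-vector, need not be unit).
#' @param plane a [plane3()].
#' @param tol_deg degeneracy tolerance: minimum allowed angle (degrees)
#'   between `d` and the plane normal. Default 0.1.
#' @return unit 3-vector in the plane.
#' @export
project_direction <- function(d, plane, tol_deg = 0.1) {
  d <- unit3(d)
  n <- plane$normal
  if (min(angle_deg(d, n), angle_deg(d, -n)) < tol_deg)
    stop("degenerate projection: direction is (anti)parallel to the plane normal",
         call. = FALSE)
  unit3(d - dot3(d, n) * n)
}

#' Signed angle between the in-plane projections of two directions
#'
#' Right-hand-rule angle about the oriented plane normal `n`, measured from
#' `from` to `to` after projecting both into the plane.
#'
#' @param from,to 3-vectors.
#' @param n oriented unit plane normal.
#' @return signed angle in degrees, in (-180, 180].
#' @keywords internal
signed_angle_in_plane <- function(from, to, n) {
  n <- unit3(n)
  u <- from - dot3(from, n) * n
  v <- to - dot3(to, n) * n
  nu <- norm3(u); nv <- norm3(v)
  if (nu < 1e-12 || nv < 1e-12)
    stop("degenerate in-plane projection in signed angle", call. = FALSE)
  u <- u / nu; v <- v / nv
  atan2(dot3(n, cross3(u, v)), dot3(u, v)) * 180 / pi
}

# --- rigid transforms (used heavily by the invariance tests) ---------------

#' Create a rigid transform (rotation + translation)
#'
#' @param rotation 3x3 rotation matrix.
#' @param translation numeric length-3 translation (mm).
#' @return object of class `rigid3`.
#' @export
rigid3 <- function(rotation = diag(3), translation = c(0, 0, 0)) {
  stopifnot(is.matrix(rotation), all(dim(rotation) == c(3, 3)))
  if (max(abs(crossprod(rotation) - diag(3))) > 1e-9 || det(rotation) < 0)
    stop("rotation must be a proper orthogonal 3x3 matrix", call. = FALSE)
  structure(list(R = rotation, t = as.numeric(translation)), class = "rigid3")
}

#' Random rigid transform from a uniform rotation
#'
#' Rotation drawn uniformly (QR of a Gaussian matrix, sign-corrected);
#' translation components uniform in `[-t_max, t_max]`.
#'
#' @param t_max maximum absolute translation per component (mm).
#' @return a [rigid3()].
#' @export
random_rigid3 <- function(t_max = 50) {
  M <- matrix(stats::rnorm(9), 3, 3)
  qr_ <- qr(M)
  Q <- qr.Q(qr_)
  Q <- Q %*% diag(sign(diag(qr.R(qr_))))
  if (det(Q) < 0) Q[, 1] <- -Q[, 1]
  rigid3(Q, stats::runif(3, -t_max, t_max))
}

#' Apply a rigid transform to points, directions, lines, planes or meshes
#'
#' @param tf a [rigid3()].
#' @param x a length-3 point, an n x 3 matrix of points, a `line3`, a
#'   `plane3`, a `bone_mesh` or a `landmark_set`.
#' @param type for bare vectors/matrices: `"point"` (rotate + translate) or
#'   `"direction"` (rotate only).
#' @return the transformed object, same class as `x`.
#' @export
apply_rigid <- function(tf, x, type = c("point", "direction")) {
  type <- match.arg(type)
  if (inherits(x, "line3"))
    return(line3(drop(tf$R %*% x$anchor) + tf$t, drop(tf$R %*% x$direction)))
  if (inherits(x, "plane3"))
    return(plane3(drop(tf$R %*% x$anchor) + tf$t, drop(tf$R %*% x$normal)))
  if (inherits(x, "bone_mesh")) {
    m <- x
    m$vertices <- t(tf$R %*% t(x$vertices)) +
      matrix(tf$t, nrow(x$vertices), 3, byrow = TRUE)
    return(m)
  }
  if (inherits(x, "landmark_set")) {
    lm <- x
    for (f in c("medial_picks", "lateral_picks", "groove_points"))
      lm[[f]] <- t(tf$R %*% t(x[[f]])) + matrix(tf$t, nrow(x[[f]]), 3, byrow = TRUE)
    return(lm)
  }
  if (is.matrix(x)) {
    y <- t(tf$R %*% t(x))
    if (type == "point") y <- y + matrix(tf$t, nrow(x), 3, byrow = TRUE)
    return(y)
  }
  y <- drop(tf$R %*% x)
  if (type == "point") y <- y + tf$t
  y
}

#' Rotation matrix about an arbitrary axis
#'
#' @param axis 3-vector rotation axis (normalized internally).
#' @param angle_deg rotation angle in degrees (right-hand rule).
#' @return 3x3 rotation matrix.
#' @export
rotation_about <- function(axis, angle_deg) {
  a <- unit3(axis)
  th <- angle_deg * pi / 180
  K <- matrix(c(0, a[3], -a[2], -a[3], 0, a[1], a[2], -a[1], 0), 3, 3)
  diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
}
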