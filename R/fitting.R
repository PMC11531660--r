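# Least-squares fitting primitives: total-least-squares lines, planar
# ellipses (geometric radial deviation), and 3D circles (Gauss-Newton).

#' Total-least-squares line fit
#'
#' Fits the infinite line minimizing the sum of squared perpendicular
#' distances to the points (first principal direction of the centered
#' scatter). The anchor is the centroid.
#'
#' @param points n x 3 matrix of points (mm), n >= 2.
#' @param orient reference direction; the fitted direction is flipped if
#'   needed so its component along `orient` is >= 0. Default the global
#'   distal-to-proximal +z.
#' @return a [line3()].
#' @export
fit_line_tls <- function(points, orient = c(0, 0, 1)) {
  points <- as.matrix(points)
  stopifnot(ncol(points) == 3, nrow(points) >= 2)
  ctr <- colMeans(points)
  X <- sweep(points, 2, ctr)
  if (max(abs(X)) < 1e-12)
    stop("degenerate input: all points coincide", call. = FALSE)
  sv <- svd(X, nu = 0, nv = 3)
  d <- sv$v[, 1]
  if (dot3(d, orient) < 0) d <- -d
  line3(ctr, d)
}

# Shared Gauss-Newton driver with Levenberg-Marquardt damping on a residual
# function. fn(p) returns the residual vector; the Jacobian is computed by
# central differences. The damping factor is adapted by the gain ratio
# (actual vs model-predicted decrease), so pure Gauss-Newton steps are taken
# whenever they perform well and damping only grows when they overshoot.
gauss_newton <- function(p, fn, max_iter = 100, obj_tol = 1e-14, step_tol = 1e-12) {
  r <- fn(p)
  obj <- sum(r^2)
  lambda <- 1e-8
  iter <- 0
  converged <- FALSE
  slow <- 0L      # consecutive iterations with negligible relative progress
  hist <- numeric(0)
  np <- length(p)
  while (iter < max_iter && !converged) {
    iter <- iter + 1
    J <- matrix(0, length(r), np)
    for (j in seq_len(np)) {
      h <- 1e-6 * max(1, abs(p[j]))
      pp <- p; pp[j] <- pp[j] + h
      pm <- p; pm[j] <- pm[j] - h
      J[, j] <- (fn(pp) - fn(pm)) / (2 * h)
    }
    A <- crossprod(J)
    g <- crossprod(J, r)
    dscale <- pmax(diag(A), 1e-12)
    # model-predicted decrease still available from this point (stationarity
    # measure, reported to callers for budget-capped runs)
    pred_rel <- tryCatch(
      drop(crossprod(g, solve(A + 1e-8 * diag(dscale, np), g))) /
        max(obj, .Machine$double.xmin),
      error = function(e) Inf)
    improved <- FALSE
    for (try in 1:40) {
      step <- tryCatch(-solve(A + lambda * diag(dscale, np), g),
                       error = function(e) NULL)
      if (!is.null(step)) {
        step <- drop(step)
        pn <- p + step
        rn <- fn(pn)
        objn <- sum(rn^2)
        if (is.finite(objn) && objn <= obj) {
          pred <- -(2 * sum(g * step) + drop(crossprod(step, A %*% step)))
          rho <- (obj - objn) / max(pred, .Machine$double.xmin)
          rel <- (obj - objn) / max(obj, .Machine$double.xmin)
          p <- pn; r <- rn
          small_step <- sqrt(sum(step^2)) < step_tol
          obj_done <- rel < obj_tol || objn < 1e-24
          slow <- if (rel < 1e-12) slow + 1L else 0L
          obj <- objn
          lambda <- if (rho > 0.75) lambda / 3 else if (rho < 0.25) lambda * 2 else lambda
          lambda <- max(lambda, 1e-12)
          improved <- TRUE
          if (small_step || obj_done || slow >= 3L) converged <- TRUE
          break
        }
      }
      lambda <- lambda * 3
    }
    if (!improved) {
      # no decreasing step exists: converged if the gradient has vanished
      converged <- sqrt(sum(g^2)) < 1e-7 * max(1, obj)
      break
    }
    hist <- c(hist, obj)
    nh <- length(hist)
    if (nh >= 10 &&
        (hist[nh - 9] - obj) < 1e-8 * max(hist[nh - 9], .Machine$double.xmin)) {
      converged <- TRUE   # stagnated: < 1e-8 relative progress over 10 iterations
    }
  }
  if (!exists("pred_rel", inherits = FALSE)) pred_rel <- Inf
  list(p = p, residuals = r, objective = obj, iterations = iter,
       converged = converged || obj < 1e-24, pred_rel = pred_rel)
}

# Kasa algebraic circle fit in 2D: linear least squares on
# x^2 + y^2 + D x + E y + F = 0. Used only for initialization.
kasa_circle_2d <- function(xy) {
  A <- cbind(xy, 1)
  b <- rowSums(xy^2)
  sol <- qr.solve(A, b)
  ctr <- sol[1:2] / 2
  r <- sqrt(max(sol[3] + sum(ctr^2), 1e-12))
  list(center = ctr, radius = r)
}

#' Fit a circle to 3D points by Gauss-Newton
#'
#' Minimizes the sum of squared 3D distances from the points to the circle,
#' `sum_i d_i^2` with `d_i^2 = (rho_i - r)^2 + h_i^2`, where `rho_i` is the
#' in-plane distance of point i from the center and `h_i` its out-of-plane
#' distance. Parameters are the center (3), the normal (2 local tilt
#' parameters, re-orthogonalized every iteration) and the radius, which is
#' profiled out in closed form (its optimum given center and normal is the
#' mean in-plane distance). Initialization uses the principal plane of the
#' points and a Kasa algebraic circle fit within it; Levenberg damping is
#' applied only when a pure Gauss-Newton step fails to decrease the
#' objective.
#'
#' @param points n x 3 matrix, n >= 4, not all collinear.
#' @param init optional `circle3d` used as the starting point.
#' @param orient reference direction for the canonical normal hemisphere: the
#'   returned normal has non-negative dot product with it. In the pipeline
#'   this is the lateral-to-medial epicondylar direction; default global +x.
#' @param max_iter maximum Gauss-Newton iterations (default 100).
#' @return object of class `circle3d`: fields `center`, `radius`, `normal`,
#'   `radial_residuals` (signed, mm; positive = outside the circle within its
#'   plane), `axial_residuals` (out-of-plane component, diagnostics),
#'   `objective`, `converged`, `iterations`. Non-convergence is flagged, not
#'   an error.
#' @export
fit_circle_3d <- function(points, init = NULL, orient = c(1, 0, 0), max_iter = 100) {
  points <- as.matrix(points)
  stopifnot(ncol(points) == 3)
  if (nrow(points) < 4)
    stop("fit_circle_3d needs at least 4 points", call. = FALSE)
  ctr0 <- colMeans(points)
  X <- sweep(points, 2, ctr0)
  sv <- svd(X, nu = 0, nv = 3)
  if (sv$d[2] < 1e-9 * max(sv$d[1], 1))
    stop("degenerate input: points are collinear", call. = FALSE)

  if (is.null(init)) {
    n <- sv$v[, 3]                      # principal-plane normal
    e1 <- sv$v[, 1]; e2 <- sv$v[, 2]
    k2 <- kasa_circle_2d(cbind(X %*% e1, X %*% e2))
    center <- ctr0 + k2$center[1] * e1 + k2$center[2] * e2
    radius <- k2$radius
  } else {
    n <- unit3(init$normal); center <- init$center; radius <- init$radius
  }

  # The radius is profiled out: given center and normal its optimum is the
  # mean in-plane distance, so Gauss-Newton runs on center (3) + normal
  # (2 local tilt parameters, chart re-centered on the current normal each
  # outer pass). This removes the worst-conditioned parameter coupling on
  # partial arcs while leaving the minimized objective unchanged.
  iter_total <- 0
  converged <- FALSE
  for (outer in 1:8) {
    b <- normal_basis(n)
    fn <- function(p) {
      cen <- p[1:3]
      nn <- unit3(n + p[4] * b$u + p[5] * b$v)
      D <- sweep(points, 2, cen)
      h <- D %*% nn
      rho <- sqrt(pmax(rowSums(D^2) - h^2, 0))
      sqrt((rho - mean(rho))^2 + h^2 + 1e-300)
    }
    res <- gauss_newton(c(center, 0, 0), fn, max_iter = max_iter)
    iter_total <- iter_total + res$iterations
    center <- res$p[1:3]
    n <- unit3(n + res$p[4] * b$u + res$p[5] * b$v)
    D <- sweep(points, 2, center)
    radius <- mean(sqrt(pmax(rowSums(D^2) - drop(D %*% n)^2, 0)))
    if (res$converged && sqrt(res$p[4]^2 + res$p[5]^2) < 1e-6) {
      converged <- TRUE
      break
    }
    if (iter_total >= max_iter) {
      # budget-capped: accept as converged when the model-predicted
      # remaining decrease is negligible (flat-valley partial-arc fits)
      converged <- converged || res$pred_rel < 1e-5
      break
    }
  }

  if (dot3(n, orient) < 0) n <- -n
  D <- sweep(points, 2, center)
  h <- drop(D %*% n)
  rho <- sqrt(pmax(rowSums(D^2) - h^2, 0))
  structure(list(center = center, radius = radius, normal = n,
                 radial_residuals = rho - radius,
                 axial_residuals = h,
                 objective = sum((rho - radius)^2 + h^2),
                 converged = converged, iterations = iter_total),
            class = "circle3d")
}

# Orthonormal basis (u, v) spanning the plane orthogonal to n.
normal_basis <- function(n) {
  n <- unit3(n)
  a <- if (abs(n[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  u <- unit3(cross3(n, a))
  v <- cross3(n, u)
  list(u = u, v = v)
}

#' @export
print.circle3d <- function(x, ...) {
  cat(sprintf("<circle3d> r = %.4f mm, center (%.3f, %.3f, %.3f), %s in %d iterations\n",
              x$radius, x$center[1], x$center[2], x$center[3],
              if (x$converged) "converged" else "NOT converged", x$iterations))
  cat(sprintf("  signed radial residuals: [%.4f, %.4f] mm\n",
              min(x$radial_residuals), max(x$radial_residuals)))
  invisible(x)
}

#' Fit a planar ellipse minimizing radial deviation
#'
#' The points must lie (numerically) in `slicing_plane`. The fit is carried
#' out in 2D plane coordinates with parameters center (2), radii `a >= b`,
#' and orientation angle; the residual of a point is its radial deviation,
#' i.e. the distance from the point to the ellipse boundary measured along
#' the ray from the center: `rho_i - r_ell(psi_i)` with
#' `r_ell(psi) = a b / sqrt((b cos psi)^2 + (a sin psi)^2)` and `psi_i` the
#' ray angle relative to the major axis.
#'
#' @param points n x 3 matrix, n >= 5, within `plane_tol` of the plane.
#' @param slicing_plane a [plane3()]; its normal becomes the ellipse normal.
#' @param orientation `"free"` fits the major-axis angle; `"axis_aligned"`
#'   fixes it to the plane's first basis vector.
#' @param plane_tol maximum allowed out-of-plane distance (mm), default 1e-6.
#' @return object of class `ellipse3d_fit`: fields `center` (3D), `a`, `b`
#'   (mm, `a >= b`), `normal`, `major_dir` (3D unit, in-plane),
#'   `rms_residual`, `radial_residuals`, `objective`, `converged`.
#' @export
fit_ellipse_planar <- function(points, slicing_plane,
                               orientation = c("free", "axis_aligned"),
                               plane_tol = 1e-6) {
  orientation <- match.arg(orientation)
  points <- as.matrix(points)
  stopifnot(ncol(points) == 3)
  if (nrow(points) < 5)
    stop("fit_ellipse_planar needs at least 5 points", call. = FALSE)
  n <- slicing_plane$normal
  offp <- drop(sweep(points, 2, slicing_plane$anchor) %*% n)
  if (max(abs(offp)) > plane_tol)
    stop(sprintf("points are not in the slicing plane (max |offset| = %.3g mm)",
                 max(abs(offp))), call. = FALSE)
  b3 <- normal_basis(n)
  P0 <- sweep(points, 2, slicing_plane$anchor)
  xy <- cbind(P0 %*% b3$u, P0 %*% b3$v)

  ctr <- colMeans(xy)
  Xc <- sweep(xy, 2, ctr)
  ev <- eigen(crossprod(Xc) / nrow(xy), symmetric = TRUE)
  if (ev$values[2] < 1e-12 * max(ev$values[1], 1))
    stop("degenerate input: points are collinear", call. = FALSE)
  phi0 <- atan2(ev$vectors[2, 1], ev$vectors[1, 1])
  a0 <- sqrt(2 * ev$values[1]); b0 <- sqrt(2 * ev$values[2])

  resid_fn <- function(p) {
    cx <- p[1]; cy <- p[2]; a <- abs(p[3]); b <- abs(p[4])
    phi <- if (orientation == "free") p[5] else 0
    dx <- xy[, 1] - cx; dy <- xy[, 2] - cy
    rho <- sqrt(dx^2 + dy^2)
    psi <- atan2(dy, dx) - phi
    rell <- a * b / sqrt((b * cos(psi))^2 + (a * sin(psi))^2)
    rho - rell
  }
  p0 <- if (orientation == "free") c(ctr, a0, b0, phi0) else c(ctr, a0, b0)
  fit <- gauss_newton(p0, resid_fn)

  cx <- fit$p[1]; cy <- fit$p[2]
  a <- abs(fit$p[3]); b <- abs(fit$p[4])
  phi <- if (orientation == "free") fit$p[5] else 0
  if (b > a) { tmp <- a; a <- b; b <- tmp; phi <- phi + pi / 2 }
  major <- unit3(cos(phi) * b3$u + sin(phi) * b3$v)
  center <- slicing_plane$anchor + cx * b3$u + cy * b3$v
  rr <- fit$residuals
  structure(list(center = center, a = a, b = b, normal = n, major_dir = major,
                 rms_residual = sqrt(mean(rr^2)), radial_residuals = rr,
                 objective = fit$objective, converged = fit$converged,
                 iterations = fit$iterations),
            class = "ellipse3d_fit")
}

#' @export
print.ellipse3d_fit <- function(x, ...) {
  cat(sprintf("<ellipse3d_fit> a = %.4f, b = %.4f mm, center (%.3f, %.3f, %.3f), rms %.4g mm\n",
              x$a, x$b, x$center[1], x$center[2], x$center[3], x$rms_residual))
  invisible(x)
}
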