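# Independent brute-force oracles for the fitting routines. These never call
# the package's Gauss-Newton path: coarse grid searches (global) polished by
# Nelder-Mead (stats::optim, local), with the circle radius eliminated in
# closed form (optimal r given center and normal is the mean in-plane
# distance).

oracle_circle_objective <- function(points) {
  points <- as.matrix(points)
  obj <- function(cen, nrm) {
    D <- sweep(points, 2, cen)
    h <- drop(D %*% nrm)
    rho <- sqrt(pmax(rowSums(D^2) - h^2, 0))
    sum((rho - mean(rho))^2 + h^2)
  }
  ctr <- colMeans(points)
  sv <- svd(sweep(points, 2, ctr), nu = 0, nv = 3)
  n0 <- sv$v[, 3]
  b1 <- sv$v[, 1]; b2 <- sv$v[, 2]
  # global pass: center grid +-1.5 mm, normal tilt grid +-0.25 rad
  best <- Inf; best_p <- NULL
  cg <- seq(-1.5, 1.5, length.out = 7)
  tg <- seq(-0.25, 0.25, length.out = 5)
  for (dx in cg) for (dy in cg) for (dz in cg) {
    cen <- ctr + dx * b1 + dy * b2 + dz * n0
    for (t1 in tg) for (t2 in tg) {
      nrm <- n0 + t1 * b1 + t2 * b2
      nrm <- nrm / sqrt(sum(nrm^2))
      o <- obj(cen, nrm)
      if (o < best) { best <- o; best_p <- c(cen, nrm) }
    }
  }
  # local polish (normal kept as a free 3-vector, normalized inside)
  f <- function(q) obj(q[1:3], q[4:6] / sqrt(sum(q[4:6]^2)))
  for (start in list(best_p, best_p + c(stats::rnorm(3, 0, 0.05), stats::rnorm(3, 0, 0.01)))) {
    o <- stats::optim(start, f, control = list(reltol = 1e-15, maxit = 50000))
    if (o$value < best) best <- o$value
  }
  best
}

oracle_ellipse_objective <- function(xy) {
  xy <- as.matrix(xy)
  obj <- function(p) {
    dx <- xy[, 1] - p[1]; dy <- xy[, 2] - p[2]
    rho <- sqrt(dx^2 + dy^2)
    psi <- atan2(dy, dx) - p[5]
    a <- abs(p[3]); b <- abs(p[4])
    rell <- a * b / sqrt((b * cos(psi))^2 + (a * sin(psi))^2)
    sum((rho - rell)^2)
  }
  ctr <- colMeans(xy)
  Xc <- sweep(xy, 2, ctr)
  ev <- eigen(crossprod(Xc) / nrow(xy), symmetric = TRUE)
  phi0 <- atan2(ev$vectors[2, 1], ev$vectors[1, 1])
  a0 <- sqrt(2 * ev$values[1]); b0 <- sqrt(2 * ev$values[2])
  best <- Inf; best_p <- NULL
  for (dx in seq(-1, 1, by = 0.2)) for (dy in seq(-1, 1, by = 0.2)) {
    p <- c(ctr[1] + dx, ctr[2] + dy, a0, b0, phi0)
    o <- obj(p)
    if (o < best) { best <- o; best_p <- p }
  }
  for (start in list(best_p, best_p + stats::rnorm(5, 0, 0.02))) {
    o <- stats::optim(start, obj, control = list(reltol = 1e-15, maxit = 50000))
    if (o$value < best) best <- o$value
  }
  best
}

# spectral total-least-squares line oracle: minimizes the perpendicular
# scatter via the eigen-decomposition of the centered second-moment matrix
oracle_tls_direction <- function(points) {
  points <- as.matrix(points)
  X <- sweep(points, 2, colMeans(points))
  ev <- eigen(crossprod(X), symmetric = TRUE)
  ev$vectors[, 1]
}

# in-plane circle sample helper
circle_points <- function(n, center, radius, normal, arc_deg = 360,
                          jitter_sd = 0) {
  normal <- normal / sqrt(sum(normal^2))
  b <- elbowaxes:::normal_basis(normal)
  arc <- arc_deg * pi / 180
  th <- seq(-arc / 2, arc / 2, length.out = n + 1)[seq_len(n)]
  P <- matrix(center, n, 3, byrow = TRUE) +
    radius * (outer(cos(th), b$u) + outer(sin(th), b$v))
  if (jitter_sd > 0) P <- P + matrix(stats::rnorm(3 * n, 0, jitter_sd), n, 3)
  P
}
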