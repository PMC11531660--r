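# Construction of the three specimen axes: epicondylar, long (intramedullary)
# and true flexion-extension.

#' Epicondylar axis from manual picks
#'
#' Each epicondyle is the arithmetic mean of its three picks; the axis is the
#' line through the two means, oriented lateral-to-medial.
#'
#' @param landmarks a [landmark_set()].
#' @return list with `axis` ([line3()], direction lateral-to-medial),
#'   `medial_epicondyle`, `lateral_epicondyle` (length-3 points).
#' @export
epicondylar_axis <- function(landmarks) {
  med <- colMeans(landmarks$medial_picks)
  lat <- colMeans(landmarks$lateral_picks)
  if (norm3(med - lat) < 1e-9)
    stop("degenerate epicondylar axis: averaged epicondyles coincide", call. = FALSE)
  list(axis = line3(lat, med - lat),
       medial_epicondyle = med, lateral_epicondyle = lat)
}

#' Long (intramedullary) axis of the distal humerus
#'
#' Five slicing planes are placed at fractions 0.1, 0.3, 0.5, 0.7 and 0.9 of
#' the shaft band (`landmarks$shaft_zrange`, fractions of the mesh extent
#' along the provisional shaft direction), normal to that direction. The
#' primary contour of each slice is fitted by [fit_ellipse_planar()] and the
#' long axis is the total-least-squares line through the five ellipse
#' centers, oriented distal-to-proximal. The provisional direction joins the
#' centroids of the most distal and most proximal 10% of mesh vertices; one
#' re-slicing pass using the fitted axis (default on) removes most of the
#' dependence on it.
#'
#' @param mesh a [bone_mesh()].
#' @param landmarks a [landmark_set()] (only `shaft_zrange` is used).
#' @param reslice logical: perform the fixed-point re-slicing pass.
#' @param slice_fractions placement of the five planes within the band.
#' @return list with `axis` ([line3()]), `ellipses` (list of 5
#'   `ellipse3d_fit`), `provisional` (the provisional direction used last).
#' @export
distal_humeral_axis <- function(mesh, landmarks, reslice = TRUE,
                                slice_fractions = c(0.1, 0.3, 0.5, 0.7, 0.9)) {
  dir <- provisional_shaft_direction(mesh, colMeans(landmarks$groove_points))
  fit <- slice_and_fit(mesh, landmarks$shaft_zrange, dir, slice_fractions)
  if (reslice) fit <- slice_and_fit(mesh, landmarks$shaft_zrange,
                                    fit$axis$direction, slice_fractions)
  fit
}

# Provisional shaft direction from the centroids of the most distal and most
# proximal 10% vertex slabs. The slab axis is anchored on the trochlear
# groove: the shaft points from the groove centroid toward the vertices
# farthest from it, which is robust to any orientation of the input mesh
# (the wide articular mass would otherwise dominate a plain principal-axis
# heuristic). Falls back to the dominant principal axis (+z hemisphere) when
# no groove reference is supplied.
provisional_shaft_direction <- function(mesh, groove_center = NULL) {
  V <- mesh$vertices
  if (is.null(groove_center)) {
    ctr <- colMeans(V)
    sv <- svd(sweep(V, 2, ctr), nu = 0, nv = 3)
    d0 <- sv$v[, 1]
    if (d0[3] < 0) d0 <- -d0
  } else {
    dist2 <- rowSums(sweep(V, 2, groove_center)^2)
    far <- colMeans(V[dist2 >= stats::quantile(dist2, 0.9), , drop = FALSE])
    d0 <- unit3(far - groove_center)
  }
  s <- drop(V %*% d0)
  qs <- stats::quantile(s, c(0.1, 0.9))
  lo <- colMeans(V[s <= qs[1], , drop = FALSE])
  hi <- colMeans(V[s >= qs[2], , drop = FALSE])
  unit3(hi - lo) * sign(dot3(unit3(hi - lo), d0))
}

slice_and_fit <- function(mesh, zrange, dir, fractions) {
  s <- drop(mesh$vertices %*% dir)
  smin <- min(s); smax <- max(s)
  lo <- smin + zrange[1] * (smax - smin)
  hi <- smin + zrange[2] * (smax - smin)
  if (hi - lo < 20)
    stop(sprintf("shaft band spans only %.1f mm (< 20 mm) along the shaft direction",
                 hi - lo), call. = FALSE)
  ellipses <- vector("list", length(fractions))
  for (i in seq_along(fractions)) {
    off <- lo + fractions[i] * (hi - lo)
    pl <- plane3(off * dir, dir)
    sec <- plane_mesh_section(mesh, pl)
    ellipses[[i]] <- fit_ellipse_planar(sec$contours[[sec$primary]], pl,
                                        plane_tol = 1e-5)
  }
  if (length(ellipses) < 5)
    stop("fewer than 5 usable shaft contours", call. = FALSE)
  centers <- t(vapply(ellipses, `[[`, numeric(3), "center"))
  list(axis = fit_line_tls(centers, orient = dir), ellipses = ellipses)
}

#' True flexion-extension axis from trochlear-groove points
#'
#' Fits a 3D circle to the groove points by Gauss-Newton
#' ([fit_circle_3d()]); the flexion-extension axis is the line through the
#' circle center along the circle normal, with the normal oriented into the
#' lateral-to-medial hemisphere.
#'
#' @param landmarks a [landmark_set()] (>= 4 groove points).
#' @param lateral_to_medial reference direction fixing the normal hemisphere
#'   (typically the epicondylar direction).
#' @return list with `axis` ([line3()]), `circle` (`circle3d`), `converged`.
#'   Non-convergence is flagged, not an error.
#' @export
true_fe_axis <- function(landmarks, lateral_to_medial = c(1, 0, 0)) {
  circ <- fit_circle_3d(landmarks$groove_points, orient = lateral_to_medial)
  if (!circ$converged)
    warning("trochlear-groove circle fit did not converge; axis flagged",
            call. = FALSE)
  list(axis = line3(circ$center, circ$normal), circle = circ,
       converged = circ$converged)
}

#' Construct all three axes of one specimen
#'
#' Convenience wrapper running [epicondylar_axis()],
#' [distal_humeral_axis()] and [true_fe_axis()] and bundling the results.
#'
#' @param mesh a [bone_mesh()].
#' @param landmarks a [landmark_set()].
#' @param reslice passed to [distal_humeral_axis()].
#' @return object of class `specimen_axes`: `epicondylar`, `long_axis`,
#'   `fe_axis` ([line3()]s), `medial_epicondyle`, `lateral_epicondyle`,
#'   `trochlear_circle`, `shaft_ellipses`.
#' @export
build_axes <- function(mesh, landmarks, reslice = TRUE) {
  epi <- epicondylar_axis(landmarks)
  long <- distal_humeral_axis(mesh, landmarks, reslice = reslice)
  fe <- true_fe_axis(landmarks, lateral_to_medial = epi$axis$direction)
  structure(list(epicondylar = epi$axis,
                 long_axis = long$axis,
                 fe_axis = fe$axis,
                 medial_epicondyle = epi$medial_epicondyle,
                 lateral_epicondyle = epi$lateral_epicondyle,
                 trochlear_circle = fe$circle,
                 shaft_ellipses = long$ellipses,
                 fe_converged = fe$converged),
            class = "specimen_axes")
}
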