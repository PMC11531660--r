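# Anatomical frame construction and per-plane rotational differences.

#' Build the anatomical coronal/sagittal/axial frame
#'
#' The coronal plane is parallel to both the long axis and the F-E axis (its
#' normal is their cross product, oriented anteriorly); the sagittal plane is
#' perpendicular to the coronal plane and as close to perpendicular to the
#' F-E axis as orthogonality allows (normal = in-plane component of the F-E
#' direction, i.e. lateral-to-medial); the axial plane transects the long
#' axis (normal = distal-to-proximal direction). The three normals are
#' mutually orthogonal by construction; this is asserted to 1e-9 on every
#' call. Signed directions: `medial` is lateral-to-medial, `distal` is
#' proximal-to-distal, `anterior` completes the triad, with the sense flipped
#' for left-side specimens so that mirrored specimens report consistent
#' clinical signs.
#'
#' @param long_axis [line3()], direction distal-to-proximal.
#' @param fe_axis [line3()], direction lateral-to-medial.
#' @param side `"right"` or `"left"`.
#' @param min_angle_deg degeneracy guard: minimum angle between the axes.
#' @return object of class `anatomical_frame`: planes `coronal`, `sagittal`,
#'   `axial` ([plane3()]) and `signed_dirs` (list `anterior`, `medial`,
#'   `distal`).
#' @export
build_frame <- function(long_axis, fe_axis, side = c("right", "left"),
                        min_angle_deg = 5) {
  side <- match.arg(side)
  p <- unit3(long_axis$direction)
  fe <- unit3(fe_axis$direction)
  ang <- angle_deg(p, fe)
  if (min(ang, 180 - ang) < min_angle_deg)
    stop(sprintf("degenerate frame: long and F-E axes are within %.2f deg of parallel",
                 min(ang, 180 - ang)), call. = FALSE)
  med <- unit3(fe - dot3(fe, p) * p)              # lateral-to-medial, in axial plane
  ant <- unit3(cross3(p, fe))
  if (side == "left") ant <- -ant
  anchor <- fe_axis$anchor
  frame <- structure(list(coronal = plane3(anchor, ant),
                          sagittal = plane3(anchor, med),
                          axial = plane3(anchor, p),
                          signed_dirs = list(anterior = ant, medial = med,
                                             distal = -p),
                          side = side),
                     class = "anatomical_frame")
  assert_frame_orthogonal(frame)
  frame
}

# built-in invariant: plane normals mutually orthogonal to 1e-9
assert_frame_orthogonal <- function(frame) {
  n1 <- frame$coronal$normal; n2 <- frame$sagittal$normal; n3 <- frame$axial$normal
  m <- max(abs(dot3(n1, n2)), abs(dot3(n1, n3)), abs(dot3(n2, n3)))
  if (m > 1e-9)
    stop(sprintf("anatomical frame normals are not orthogonal (max |dot| = %.2e)", m),
         call. = FALSE)
  invisible(TRUE)
}

#' Per-plane rotational difference between epicondylar and F-E axes
#'
#' Absolute angles: `alpha` = angle(long axis, F-E axis), `beta` =
#' angle(long axis, epicondylar axis), `absolute_diff = |alpha - beta|`.
#' Per-plane signed differences are right-hand-rule angles measured FROM the
#' projected F-E axis TO the projected epicondylar axis about the oriented
#' plane normals: sagittal plane about `medial` (flexion +), axial plane
#' about `distal` (varus +), coronal plane about `anterior` (external +).
#' Both axis directions are canonically oriented lateral-to-medial first so
#' no 180-degree ambiguity arises. The plane-to-clinical-label mapping is
#' coronal = external/internal rotation, sagittal = flexion/extension,
#' axial = varus/valgus.
#'
#' In the sagittal plane the F-E direction is nearly normal to the plane, so
#' its projection can vanish; in that degenerate case the flexion component
#' is reconstructed from the in-plane projection of the axes' difference
#' vector. A component that cannot be computed at all is returned as `NA`
#' with the others still reported.
#'
#' @param frame an [build_frame()] result.
#' @param axes a `specimen_axes` (from [build_axes()]) or any list with
#'   `long_axis`, `fe_axis`, `epicondylar` [line3()] fields.
#' @return object of class `axis_comparison`: `alpha`, `beta`,
#'   `absolute_diff`, `flexion_extension`, `varus_valgus`,
#'   `external_internal` (all degrees).
#' @export
rotational_difference <- function(frame, axes) {
  med <- frame$signed_dirs$medial
  ant <- frame$signed_dirs$anterior
  dst <- frame$signed_dirs$distal
  p <- unit3(axes$long_axis$direction)
  fe <- orient_towards(unit3(axes$fe_axis$direction), med)
  epi <- orient_towards(unit3(axes$epicondylar$direction), med)

  alpha <- angle_deg(p, fe)
  beta <- angle_deg(p, epi)

  # left-side specimens are mirror images: the rotation sense is reversed so
  # that mirrored anatomy reports identical clinical signs
  sgn <- if (identical(frame$side, "left")) -1 else 1
  comp <- function(n) {
    sgn * tryCatch(signed_angle_in_plane(fe, epi, n),
                   error = function(e) sagittal_fallback(fe, epi, n))
  }
  structure(list(alpha = alpha, beta = beta,
                 absolute_diff = abs(alpha - beta),
                 flexion_extension = comp(med),
                 varus_valgus = comp(dst),
                 external_internal = comp(ant)),
            class = "axis_comparison")
}

orient_towards <- function(d, ref) if (dot3(d, ref) < 0) -d else d

# Degenerate sagittal projection: reconstruct the vanishing projection from
# the difference vector of the two (unit) axis directions.
sagittal_fallback <- function(fe, epi, n) {
  proj <- function(v) v - dot3(v, n) * n
  u_epi <- proj(epi)
  u_fe <- proj(fe)
  if (norm3(u_fe) < 1e-9) u_fe <- u_epi + proj(fe - epi)
  if (norm3(u_epi) < 1e-9) u_epi <- u_fe - proj(fe - epi)
  if (norm3(u_fe) < 1e-12 || norm3(u_epi) < 1e-12) return(NA_real_)
  atan2(dot3(n, cross3(unit3(u_fe), unit3(u_epi))),
        dot3(unit3(u_fe), unit3(u_epi))) * 180 / pi
}

#' @export
print.axis_comparison <- function(x, ...) {
  cat(sprintf("<axis_comparison> alpha %.2f, beta %.2f, |alpha-beta| %.2f deg\n",
              x$alpha, x$beta, x$absolute_diff))
  cat(sprintf("  flexion(+)/extension(-): %+.3f deg\n", x$flexion_extension))
  cat(sprintf("  varus(+)/valgus(-):      %+.3f deg\n", x$varus_valgus))
  cat(sprintf("  external(+)/internal(-): %+.3f deg\n", x$external_internal))
  invisible(x)
}
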