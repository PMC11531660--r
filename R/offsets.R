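# Translational offsets of the F-E axis relative to the epicondyles.

#' Resolve an offset vector into signed anatomical components
#'
#' Components follow the sign conventions anterior (+) / posterior (-),
#' medial (+) / lateral (-), distal (+) / proximal (-). The inferior-superior
#' direction coincides with distal-proximal; the component is reported under
#' both names. The absolute offset is the Euclidean norm; the Pythagorean
#' identity `absolute^2 = sum(components^2)` is asserted to 1e-6 mm^2 on
#' every call.
#'
#' @param v length-3 offset vector (mm).
#' @param frame an [build_frame()] result.
#' @return object of class `offset_record` with fields `absolute`,
#'   `anterior_posterior`, `medial_lateral`, `inferior_superior`,
#'   `distal_proximal`.
#' @export
offset_record <- function(v, frame) {
  sd_ <- frame$signed_dirs
  ap <- dot3(v, sd_$anterior)
  ml <- dot3(v, sd_$medial)
  is_ <- dot3(v, sd_$distal)
  abs_ <- norm3(v)
  if (abs(abs_^2 - (ap^2 + ml^2 + is_^2)) > 1e-6)
    stop("offset components violate the Pythagorean identity", call. = FALSE)
  structure(list(absolute = abs_, anterior_posterior = ap, medial_lateral = ml,
                 inferior_superior = is_, distal_proximal = is_),
            class = "offset_record")
}

#' @export
print.offset_record <- function(x, ...) {
  cat(sprintf("<offset_record> |d| %.2f mm; A-P %+.2f, M-L %+.2f, D-P %+.2f mm\n",
              x$absolute, x$anterior_posterior, x$medial_lateral, x$inferior_superior))
  invisible(x)
}

#' Exit points of the F-E axis through the humeral surface
#'
#' The most medial line-surface intersection (along the frame's medial
#' direction) is the trochlear point; the most lateral is the capitellum
#' point.
#'
#' @param fe_axis [line3()].
#' @param mesh [bone_mesh()].
#' @param frame [build_frame()] result (supplies the medial direction).
#' @return list with `trochlear_point` and `capitellum_point`.
#' @export
axis_exit_points <- function(fe_axis, mesh, frame) {
  hits <- line_mesh_intersections(fe_axis, mesh)
  if (nrow(hits) < 2)
    stop(sprintf("F-E axis intersects the surface at %d point(s); need at least 2 (axis through (%.2f, %.2f, %.2f) direction (%.3f, %.3f, %.3f))",
                 nrow(hits), fe_axis$anchor[1], fe_axis$anchor[2], fe_axis$anchor[3],
                 fe_axis$direction[1], fe_axis$direction[2], fe_axis$direction[3]),
         call. = FALSE)
  P <- as.matrix(hits[, c("x", "y", "z")])
  m <- drop(P %*% frame$signed_dirs$medial)
  list(trochlear_point = P[which.max(m), ],
       capitellum_point = P[which.min(m), ])
}

#' Point translational offsets from the epicondyles
#'
#' The medial offset is the displacement of the trochlear point from the
#' medial epicondyle; the lateral offset that of the capitellum point from
#' the lateral epicondyle (the pairing is structural, but a warning is
#' issued when the distance-nearest pairing disagrees).
#'
#' @param exits result of [axis_exit_points()].
#' @param medial_epi,lateral_epi epicondyle points.
#' @param frame [build_frame()] result.
#' @return list with `medial` and `lateral` [offset_record()]s.
#' @export
point_offsets <- function(exits, medial_epi, lateral_epi, frame) {
  d_tm <- norm3(exits$trochlear_point - medial_epi)
  d_tl <- norm3(exits$trochlear_point - lateral_epi)
  d_cl <- norm3(exits$capitellum_point - lateral_epi)
  d_cm <- norm3(exits$capitellum_point - medial_epi)
  if (d_tl < d_tm || d_cm < d_cl)
    warning("distance-nearest epicondyle pairing disagrees with the structural trochlear<->medial, capitellum<->lateral pairing",
            call. = FALSE)
  list(medial = offset_record(exits$trochlear_point - medial_epi, frame),
       lateral = offset_record(exits$capitellum_point - lateral_epi, frame))
}

#' Axis translational offset via the medial humerus intersection point
#'
#' The F-E axis is translated (perpendicular to its direction) so that it
#' passes through the lateral epicondyle instead of the capitellum point;
#' the most medial intersection of the translated line with the surface is
#' the medial humerus intersection point, and its displacement from the
#' medial epicondyle is the axis offset. The component of the translation
#' parallel to the axis direction is irrelevant (it preserves the line as a
#' set) and is removed.
#'
#' @param fe_axis [line3()].
#' @param lateral_epi,medial_epi epicondyle points.
#' @param mesh [bone_mesh()].
#' @param frame [build_frame()] result.
#' @return list with `record` ([offset_record()]),
#'   `medial_intersection_point`, and `translated_axis` ([line3()]).
#' @export
axis_translational_offset <- function(fe_axis, lateral_epi, medial_epi, mesh, frame) {
  exits <- axis_exit_points(fe_axis, mesh, frame)
  shift <- lateral_epi - exits$capitellum_point
  shift <- shift - dot3(shift, fe_axis$direction) * fe_axis$direction
  tl <- line3(fe_axis$anchor + shift, fe_axis$direction)
  hits <- line_mesh_intersections(tl, mesh)
  if (nrow(hits) == 0)
    stop(sprintf("translated F-E axis (through (%.2f, %.2f, %.2f)) does not intersect the medial humerus",
                 tl$anchor[1], tl$anchor[2], tl$anchor[3]), call. = FALSE)
  P <- as.matrix(hits[, c("x", "y", "z")])
  m <- drop(P %*% frame$signed_dirs$medial)
  mip <- P[which.max(m), ]
  list(record = offset_record(mip - medial_epi, frame),
       medial_intersection_point = mip,
       translated_axis = tl)
}
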