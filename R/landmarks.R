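# Landmark container and file dialects (JSON and CSV).

#' Picked landmarks for one specimen
#'
#' @param medial_picks,lateral_picks 3 x 3 matrices: three manual picks per
#'   epicondyle (rows are points, mm).
#' @param groove_points n x 3 matrix of points on the deepest part of the
#'   trochlear groove (canonically 20, minimum 4).
#' @param shaft_zrange length-2 numeric, fractions in \[0, 1\] of the mesh
#'   extent along the provisional shaft direction (0 = distal end): the band
#'   of the distal diaphysis/metaphysis used for the shaft cross-sections.
#' @return object of class `landmark_set`.
#' @export
landmark_set <- function(medial_picks, lateral_picks, groove_points,
                         shaft_zrange = c(0.55, 0.95)) {
  medial_picks <- as.matrix(medial_picks)
  lateral_picks <- as.matrix(lateral_picks)
  groove_points <- as.matrix(groove_points)
  stopifnot(nrow(medial_picks) == 3, ncol(medial_picks) == 3,
            nrow(lateral_picks) == 3, ncol(lateral_picks) == 3,
            nrow(groove_points) >= 4, ncol(groove_points) == 3,
            length(shaft_zrange) == 2,
            shaft_zrange[1] >= 0, shaft_zrange[2] <= 1,
            shaft_zrange[1] < shaft_zrange[2])
  structure(list(medial_picks = medial_picks, lateral_picks = lateral_picks,
                 groove_points = groove_points,
                 shaft_zrange = as.numeric(shaft_zrange)),
            class = "landmark_set")
}

#' @export
print.landmark_set <- function(x, ...) {
  cat(sprintf("<landmark_set> 3+3 epicondyle picks, %d groove points, shaft band [%.2f, %.2f]\n",
              nrow(x$groove_points), x$shaft_zrange[1], x$shaft_zrange[2]))
  invisible(x)
}

#' Read landmarks from JSON or CSV
#'
#' JSON dialect: keys `medial_picks`, `lateral_picks`, `groove_points`
#' (arrays of `[x, y, z]` in mm) and `shaft_zrange` (two extent fractions).
#' CSV dialect: columns `point_role` (`medial_pick`, `lateral_pick`,
#' `groove`), `x`, `y`, `z`; the shaft band is given on two extra rows with
#' roles `shaft_zmin` / `shaft_zmax` (fraction stored in `x`).
#'
#' @param path file path (`.json` or `.csv`).
#' @return a [landmark_set()].
#' @export
read_landmarks <- function(path) {
  if (!file.exists(path)) stop("landmark file not found: ", path, call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  if (ext == "json") {
    j <- jsonlite::fromJSON(path)
    landmark_set(j$medial_picks, j$lateral_picks, j$groove_points,
                 as.numeric(j$shaft_zrange))
  } else if (ext == "csv") {
    d <- utils::read.csv(path, stringsAsFactors = FALSE)
    need <- c("point_role", "x", "y", "z")
    if (!all(need %in% names(d)))
      stop("landmark CSV must have columns ", paste(need, collapse = ", "),
           call. = FALSE)
    pick <- function(role) as.matrix(d[d$point_role == role, c("x", "y", "z")])
    zr <- c(d$x[d$point_role == "shaft_zmin"], d$x[d$point_role == "shaft_zmax"])
    landmark_set(pick("medial_pick"), pick("lateral_pick"), pick("groove"), zr)
  } else stop("unsupported landmark format '", ext, "'", call. = FALSE)
}

#' Write landmarks to JSON or CSV
#'
#' @param landmarks a [landmark_set()].
#' @param path output path; extension selects the dialect.
#' @return `path`, invisibly.
#' @export
write_landmarks <- function(landmarks, path) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "json") {
    jsonlite::write_json(list(medial_picks = landmarks$medial_picks,
                              lateral_picks = landmarks$lateral_picks,
                              groove_points = landmarks$groove_points,
                              shaft_zrange = landmarks$shaft_zrange),
                         path, digits = NA, auto_unbox = FALSE)
  } else if (ext == "csv") {
    rows <- rbind(
      data.frame(point_role = "medial_pick", x = landmarks$medial_picks[, 1],
                 y = landmarks$medial_picks[, 2], z = landmarks$medial_picks[, 3]),
      data.frame(point_role = "lateral_pick", x = landmarks$lateral_picks[, 1],
                 y = landmarks$lateral_picks[, 2], z = landmarks$lateral_picks[, 3]),
      data.frame(point_role = "groove", x = landmarks$groove_points[, 1],
                 y = landmarks$groove_points[, 2], z = landmarks$groove_points[, 3]),
      data.frame(point_role = c("shaft_zmin", "shaft_zmax"),
                 x = landmarks$shaft_zrange, y = NA_real_, z = NA_real_))
    utils::write.csv(rows, path, row.names = FALSE)
  } else stop("unsupported landmark format '", ext, "'", call. = FALSE)
  invisible(path)
}

# Warn when landmarks sit far from the surface (nearest-vertex distance);
# groove points and epicondyle picks should be on or very near the mesh.
check_landmarks_on_surface <- function(landmarks, mesh, tol = 2) {
  P <- rbind(landmarks$medial_picks, landmarks$lateral_picks, landmarks$groove_points)
  V <- mesh$vertices
  dmax <- 0
  for (i in seq_len(nrow(P))) {
    d2 <- (V[, 1] - P[i, 1])^2 + (V[, 2] - P[i, 2])^2 + (V[, 3] - P[i, 3])^2
    dmax <- max(dmax, sqrt(min(d2)))
  }
  if (dmax > tol)
    warning(sprintf("landmarks up to %.2f mm from the mesh surface (tolerance %g mm)",
                    dmax, tol), call. = FALSE)
  invisible(dmax)
}
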