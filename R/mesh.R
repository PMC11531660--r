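# Triangulated surface handling: container, ASCII STL / PLY input-output,
# plane sectioning and ray intersection. Units are mm throughout.

#' Triangulated bone surface
#'
#' @param vertices n x 3 numeric matrix of vertex coordinates (mm).
#' @param faces m x 3 integer matrix of 1-based vertex indices.
#' @param specimen_id specimen identifier (text).
#' @param side `"right"` or `"left"`.
#' @return object of class `bone_mesh`.
#' @export
bone_mesh <- function(vertices, faces, specimen_id = "specimen", side = "right") {
  vertices <- as.matrix(vertices)
  faces <- matrix(as.integer(as.matrix(faces)), ncol = 3)
  stopifnot(ncol(vertices) == 3, ncol(faces) == 3,
            all(is.finite(vertices)),
            min(faces) >= 1, max(faces) <= nrow(vertices))
  side <- match.arg(side, c("right", "left"))
  structure(list(vertices = vertices, faces = faces,
                 specimen_id = specimen_id, side = side),
            class = "bone_mesh")
}

#' @export
print.bone_mesh <- function(x, ...) {
  cat(sprintf("<bone_mesh> '%s' (%s side): %d vertices, %d triangles\n",
              x$specimen_id, x$side, nrow(x$vertices), nrow(x$faces)))
  invisible(x)
}

#' Read a surface mesh (ASCII STL or PLY)
#'
#' The format is chosen from the file extension (`.stl` / `.ply`). STL stores
#' a triangle soup; vertices shared between facets are merged by exact
#' coordinate match after rounding to 1e-9 mm. Units are assumed mm. The
#' specimen id defaults to the file name without extension.
#'
#' @param path file path.
#' @param side anatomical side, recorded on the mesh.
#' @param specimen_id optional id override.
#' @return a [bone_mesh()].
#' @export
read_mesh <- function(path, side = "right", specimen_id = NULL) {
  if (!file.exists(path)) stop("mesh file not found: ", path, call. = FALSE)
  if (file.size(path) == 0) stop("mesh file is empty: ", path, call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  id <- specimen_id %||% sub("\\.[^.]*$", "", basename(path))
  m <- switch(ext,
              stl = read_stl_ascii(path),
              ply = read_ply_ascii(path),
              stop("unsupported mesh format '", ext, "' (use ASCII STL or PLY)",
                   call. = FALSE))
  mesh <- bone_mesh(m$vertices, m$faces, specimen_id = id, side = side)
  check_mesh_sanity(mesh)
  mesh
}

`%||%` <- function(a, b) if (is.null(a)) b else a

read_stl_ascii <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (!length(lines) || !grepl("^\\s*solid", lines[1]))
    stop("not an ASCII STL file: ", path, call. = FALSE)
  vl <- grep("^\\s*vertex", lines, value = TRUE)
  if (length(vl) == 0 || length(vl) %% 3 != 0)
    stop("malformed STL: vertex count not a multiple of 3 in ", path, call. = FALSE)
  coords <- matrix(as.numeric(unlist(strsplit(trimws(sub("^\\s*vertex\\s+", "", vl)),
                                              "\\s+"))),
                   ncol = 3, byrow = TRUE)
  if (any(!is.finite(coords))) stop("malformed STL: non-numeric vertex", call. = FALSE)
  key <- apply(round(coords, 9), 1, paste, collapse = ",")
  idx <- match(key, unique(key))
  verts <- coords[!duplicated(key), , drop = FALSE]
  faces <- matrix(idx, ncol = 3, byrow = TRUE)
  list(vertices = verts, faces = faces)
}

read_ply_ascii <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (!length(lines) || trimws(lines[1]) != "ply")
    stop("not a PLY file: ", path, call. = FALSE)
  endh <- match("end_header", trimws(lines))
  if (is.na(endh)) stop("malformed PLY: no end_header", call. = FALSE)
  head <- lines[1:endh]
  if (!any(grepl("^format ascii", trimws(head))))
    stop("only ASCII PLY is supported", call. = FALSE)
  nv <- as.integer(sub("^element vertex\\s+", "", grep("^element vertex", trimws(head), value = TRUE)[1]))
  nf <- as.integer(sub("^element face\\s+", "", grep("^element face", trimws(head), value = TRUE)[1]))
  if (is.na(nv) || is.na(nf)) stop("malformed PLY header", call. = FALSE)
  body <- lines[(endh + 1):length(lines)]
  vrows <- strsplit(trimws(body[seq_len(nv)]), "\\s+")
  verts <- matrix(as.numeric(unlist(lapply(vrows, `[`, 1:3))), ncol = 3, byrow = TRUE)
  frows <- strsplit(trimws(body[nv + seq_len(nf)]), "\\s+")
  faces <- t(vapply(frows, function(r) {
    if (as.integer(r[1]) != 3) stop("only triangular PLY faces are supported", call. = FALSE)
    as.integer(r[2:4]) + 1L
  }, integer(3)))
  list(vertices = verts, faces = faces)
}

#' Write a surface mesh (ASCII STL or PLY)
#'
#' @param mesh a [bone_mesh()].
#' @param path output path; extension selects the format.
#' @return `path`, invisibly.
#' @export
write_mesh <- function(mesh, path) {
  ext <- tolower(tools::file_ext(path))
  V <- mesh$vertices; F <- mesh$faces
  if (ext == "stl") {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(sprintf("solid %s", mesh$specimen_id), con)
    for (i in seq_len(nrow(F))) {
      tri <- V[F[i, ], , drop = FALSE]
      nrm <- cross3(tri[2, ] - tri[1, ], tri[3, ] - tri[1, ])
      nn <- sqrt(sum(nrm^2)); if (nn > 0) nrm <- nrm / nn
      writeLines(c(sprintf("  facet normal %.9g %.9g %.9g", nrm[1], nrm[2], nrm[3]),
                   "    outer loop",
                   sprintf("      vertex %.9g %.9g %.9g", tri[, 1], tri[, 2], tri[, 3]),
                   "    endloop", "  endfacet"), con)
    }
    writeLines(sprintf("endsolid %s", mesh$specimen_id), con)
  } else if (ext == "ply") {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(c("ply", "format ascii 1.0",
                 sprintf("comment specimen %s side %s", mesh$specimen_id, mesh$side),
                 sprintf("element vertex %d", nrow(V)),
                 "property double x", "property double y", "property double z",
                 sprintf("element face %d", nrow(F)),
                 "property list uchar int vertex_indices", "end_header"), con)
    writeLines(sprintf("%.12g %.12g %.12g", V[, 1], V[, 2], V[, 3]), con)
    writeLines(sprintf("3 %d %d %d", F[, 1] - 1L, F[, 2] - 1L, F[, 3] - 1L), con)
  } else stop("unsupported mesh format '", ext, "'", call. = FALSE)
  invisible(path)
}

# Cheap sanity check: warn on edges not shared by exactly two triangles
# (sampled), which indicates a non-manifold or open surface.
check_mesh_sanity <- function(mesh) {
  F <- mesh$faces
  e <- rbind(F[, 1:2], F[, 2:3], F[, c(3, 1)])
  key <- paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  tab <- table(key)
  bad <- sum(tab != 2)
  if (bad > 0)
    warning(sprintf("mesh '%s': %d edges are not shared by exactly 2 triangles (non-manifold or multi-component surface)",
                    mesh$specimen_id, bad), call. = FALSE)
  invisible(bad == 0)
}

#' Intersect a mesh with a plane
#'
#' Computes the intersection polylines of the plane with the triangulated
#' surface and chains them into closed contours. If any vertex lies exactly
#' in the plane the plane is nudged by 1e-6 mm along its normal so every
#' intersection is a clean edge crossing (deterministic).
#'
#' @param mesh a [bone_mesh()].
#' @param plane a [plane3()].
#' @return list with `contours` (list of k x 3 matrices, each an ordered
#'   closed polyline, first point not repeated), `perimeters`, and `primary`
#'   (index of the largest-perimeter contour).
#' @export
plane_mesh_section <- function(mesh, plane) {
  V <- mesh$vertices
  n <- plane$normal
  d <- drop(V %*% n) - dot3(plane$anchor, n)
  if (any(abs(d) < 1e-9)) d <- d - 1e-6      # nudge plane off exact vertices
  F <- mesh$faces
  d1 <- d[F[, 1]]; d2 <- d[F[, 2]]; d3 <- d[F[, 3]]
  cut <- !((d1 > 0 & d2 > 0 & d3 > 0) | (d1 < 0 & d2 < 0 & d3 < 0))
  if (!any(cut))
    stop(sprintf("plane at offset %.3f mm does not intersect the mesh",
                 dot3(plane$anchor, n)), call. = FALSE)
  Fc <- F[cut, , drop = FALSE]
  segs <- matrix(NA_real_, sum(cut), 6)
  for (i in seq_len(nrow(Fc))) {
    vi <- Fc[i, ]
    dv <- d[vi]
    pts <- list()
    for (e in list(c(1, 2), c(2, 3), c(3, 1))) {
      a <- dv[e[1]]; b <- dv[e[2]]
      if ((a > 0) != (b > 0)) {
        t <- a / (a - b)
        pts[[length(pts) + 1]] <- V[vi[e[1]], ] + t * (V[vi[e[2]], ] - V[vi[e[1]], ])
      }
    }
    if (length(pts) == 2) segs[i, ] <- c(pts[[1]], pts[[2]])
  }
  segs <- segs[stats::complete.cases(segs), , drop = FALSE]
  contours <- chain_segments(segs)
  perim <- vapply(contours, function(cc) {
    cc2 <- rbind(cc, cc[1, ])
    sum(sqrt(rowSums(diff(cc2)^2)))
  }, numeric(1))
  list(contours = contours, perimeters = perim, primary = which.max(perim))
}

# Chain unordered segments (p1 -> p2 per row) into closed polylines by
# matching endpoints within a tolerance.
chain_segments <- function(segs, tol = 1e-7) {
  n <- nrow(segs)
  if (n == 0) return(list())
  ends <- rbind(segs[, 1:3], segs[, 4:6])
  key <- apply(round(ends / tol) * tol, 1, paste, collapse = ",")
  uid <- match(key, unique(key))
  a <- uid[seq_len(n)]; b <- uid[n + seq_len(n)]
  coords <- ends[!duplicated(key), , drop = FALSE]
  nbr <- vector("list", nrow(coords))
  for (i in seq_len(n)) {
    nbr[[a[i]]] <- c(nbr[[a[i]]], i)
    nbr[[b[i]]] <- c(nbr[[b[i]]], i)
  }
  used <- logical(n)
  loops <- list()
  for (s in seq_len(n)) {
    if (used[s]) next
    used[s] <- TRUE
    path <- c(a[s], b[s])
    cur <- b[s]
    repeat {
      nxt_seg <- nbr[[cur]][!used[nbr[[cur]]]]
      if (length(nxt_seg) == 0) break
      i <- nxt_seg[1]
      used[i] <- TRUE
      cur <- if (a[i] == cur) b[i] else a[i]
      if (cur == path[1]) break
      path <- c(path, cur)
    }
    loops[[length(loops) + 1]] <- coords[path, , drop = FALSE]
  }
  loops
}

#' Intersect a line with a mesh
#'
#' Moller-Trumbore ray-triangle intersection applied along the full infinite
#' line; intersections closer than 1e-6 mm along the line are merged (hits on
#' shared edges/vertices are reported once).
#'
#' @param line a [line3()].
#' @param mesh a [bone_mesh()].
#' @return data.frame with columns `x`, `y`, `z`, `k` (line parameter),
#'   sorted by `k`. Zero rows when the line misses the mesh.
#' @export
line_mesh_intersections <- function(line, mesh) {
  V <- mesh$vertices; F <- mesh$faces
  o <- line$anchor; dir <- line$direction
  v0 <- V[F[, 1], , drop = FALSE]
  e1 <- V[F[, 2], , drop = FALSE] - v0
  e2 <- V[F[, 3], , drop = FALSE] - v0
  # h = dir x e2 (row-wise)
  h1 <- dir[2] * e2[, 3] - dir[3] * e2[, 2]
  h2 <- dir[3] * e2[, 1] - dir[1] * e2[, 3]
  h3 <- dir[1] * e2[, 2] - dir[2] * e2[, 1]
  det <- e1[, 1] * h1 + e1[, 2] * h2 + e1[, 3] * h3
  ok <- abs(det) > 1e-12
  s1 <- o[1] - v0[, 1]; s2 <- o[2] - v0[, 2]; s3 <- o[3] - v0[, 3]
  u <- (s1 * h1 + s2 * h2 + s3 * h3) / det
  q1 <- s2 * e1[, 3] - s3 * e1[, 2]
  q2 <- s3 * e1[, 1] - s1 * e1[, 3]
  q3 <- s1 * e1[, 2] - s2 * e1[, 1]
  v <- (dir[1] * q1 + dir[2] * q2 + dir[3] * q3) / det
  k <- (e2[, 1] * q1 + e2[, 2] * q2 + e2[, 3] * q3) / det
  tol <- 1e-9
  hit <- ok & u >= -tol & v >= -tol & (u + v) <= 1 + tol & is.finite(k)
  if (!any(hit))
    return(data.frame(x = numeric(0), y = numeric(0), z = numeric(0), k = numeric(0)))
  kk <- sort(k[hit])
  keep <- c(TRUE, diff(kk) > 1e-6)
  kk <- kk[keep]
  pts <- matrix(o, length(kk), 3, byrow = TRUE) + outer(kk, dir)
  data.frame(x = pts[, 1], y = pts[, 2], z = pts[, 3], k = kk)
}
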