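# Shared synthetic-specimen fixtures, built in code at test time.

table_mean_spec <- function(...) synthetic_spec(...)

null_spec <- function(...) {
  synthetic_spec(rot_offsets = c(flexion = 0, varus = 0, external = 0),
                 medial_offset = c(ap = 0, ml = 0, is = 0),
                 lateral_offset = c(ap = 0, ml = 0, is = 0), ...)
}

# cached default specimens (generation is deterministic, ~0.2 s)
local_specimen <- local({
  cache <- new.env(parent = emptyenv())
  function(which = c("table", "null"), ...) {
    which <- match.arg(which)
    key <- paste(which, paste(deparse(list(...)), collapse = ""), sep = "|")
    if (is.null(cache[[key]])) {
      spec <- if (which == "table") table_mean_spec(...) else null_spec(...)
      cache[[key]] <- generate_specimen(spec)
    }
    cache[[key]]
  }
})

# simple standalone elliptical-cylinder mesh along a given axis
cylinder_mesh <- function(a = 10, b = 10, len = 60, n_theta = 64, n_rings = 31,
                          base = c(0, 0, 0), axis = c(0, 0, 1)) {
  axis <- axis / sqrt(sum(axis^2))
  bb <- elbowaxes:::normal_basis(axis)
  th <- seq(0, 2 * pi, length.out = n_theta + 1)[-(n_theta + 1)]
  zs <- seq(0, len, length.out = n_rings)
  V <- matrix(0, n_rings * n_theta, 3)
  for (i in seq_len(n_rings)) {
    idx <- (i - 1) * n_theta + seq_len(n_theta)
    V[idx, ] <- matrix(base + zs[i] * axis, n_theta, 3, byrow = TRUE) +
      a * outer(cos(th), bb$u) + b * outer(sin(th), bb$v)
  }
  F <- elbowaxes:::tube_faces(n_rings, n_theta)
  closed <- elbowaxes:::close_tube(V, F, n_rings, n_theta,
                                   bottom_center = base,
                                   top_center = base + len * axis)
  bone_mesh(closed$vertices, closed$faces, specimen_id = "cylinder")
}

# icosphere-free UV sphere mesh fixture
sphere_mesh <- function(center = c(0, 0, 0), r = 10, n_lon = 48, n_lat = 24) {
  p <- elbowaxes:::sphere_part(center, r, pole_dir = c(0, 0, 1),
                               n_lon = n_lon, n_lat = n_lat)
  bone_mesh(p$vertices, p$faces, specimen_id = "sphere")
}
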