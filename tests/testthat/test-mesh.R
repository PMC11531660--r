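test_that("cylinder section yields one loop with the right perimeter", {
  cyl <- cylinder_mesh(a = 1, b = 1, len = 4, n_theta = 128)
  sec <- plane_mesh_section(cyl, plane3(c(0, 0, 2), c(0, 0, 1)))
  expect_length(sec$contours, 1)
  expect_lt(abs(sec$perimeters[1] - 2 * pi), 2 * pi * 1e-3)
  expect_error(plane_mesh_section(cyl, plane3(c(0, 0, 50), c(0, 0, 1))),
               "does not intersect")
})

test_that("line-mesh intersection handles crossing, tangent and missing lines", {
  sph <- sphere_mesh(center = c(1, 2, 3), r = 5)
  hits <- line_mesh_intersections(line3(c(1, 2, 3), c(1, 0, 0)), sph)
  expect_equal(nrow(hits), 2)
  expect_lt(abs(hits$k[1] + hits$k[2]), 1e-6)      # symmetric about the center
  expect_lt(abs(hits$k[2] - 5), 0.05)
  tangent <- line_mesh_intersections(line3(c(1, 2, 8), c(1, 0, 0)), sph)
  expect_lte(nrow(tangent), 2)                      # grazing: no crash
  miss <- line_mesh_intersections(line3(c(1, 2, 30), c(1, 0, 0)), sph)
  expect_equal(nrow(miss), 0)
})

test_that("mid-shaft section of the synthetic humerus recovers the shaft radii", {
  s <- local_specimen("table")
  pl <- plane3(c(0, 0, 60), c(0, 0, 1))
  sec <- plane_mesh_section(s$mesh, pl)
  e <- fit_ellipse_planar(sec$contours[[sec$primary]], pl, plane_tol = 1e-6)
  expect_lt(abs(e$a - 11) / 11, 0.02)
  expect_lt(abs(e$b - 9) / 9, 0.02)
})

test_that("ground-truth F-E line exits the synthetic trochlea at the known points", {
  s <- local_specimen("table")
  hits <- line_mesh_intersections(s$truth$fe_axis, s$mesh)
  expect_gte(nrow(hits), 2)
  P <- as.matrix(hits[, c("x", "y", "z")])
  mdir <- s$truth$fe_axis$direction
  med <- P[which.max(P %*% mdir), ]
  lat <- P[which.min(P %*% mdir), ]
  expect_lt(max(abs(med - s$truth$trochlear_point)), 1e-6)
  expect_lt(max(abs(lat - s$truth$capitellum_point)), 1e-6)
})

test_that("STL and PLY round-trips preserve geometry and pipeline output", {
  s <- local_specimen("table")
  td <- withr::local_tempdir()
  stl <- file.path(td, "spec.stl"); ply <- file.path(td, "spec.ply")
  write_mesh(s$mesh, stl)
  write_mesh(s$mesh, ply)
  m_ply <- read_mesh(ply)
  expect_equal(dim(m_ply$vertices), dim(s$mesh$vertices))
  expect_lt(max(abs(m_ply$vertices - s$mesh$vertices)), 1e-9)
  m_stl <- suppressWarnings(read_mesh(stl))
  # STL merges coincident vertices: counts match the unique positions and
  # the geometry agrees within write precision
  expect_equal(nrow(m_stl$vertices),
               nrow(unique(round(s$mesh$vertices, 7))))
  expect_lt(max(abs(apply(m_stl$vertices, 2, range) -
                    apply(s$mesh$vertices, 2, range))), 1e-6)

  r_ply <- run_specimen(m_ply, s$landmarks)
  r_stl <- suppressWarnings(run_specimen(m_stl, s$landmarks))
  for (f in c("varus_valgus", "external_internal", "flexion_extension"))
    expect_lt(abs(r_ply$rotation[[f]] - r_stl$rotation[[f]]), 1e-6)
  expect_lt(abs(r_ply$medial$absolute - r_stl$medial$absolute), 1e-6)

  empty <- file.path(td, "empty.stl"); file.create(empty)
  expect_error(read_mesh(empty), "empty")
})
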