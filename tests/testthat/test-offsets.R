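simple_frame <- function()
  build_frame(line3(c(0, 0, 0), c(0, 0, 1)), line3(c(0, 0, 0), c(1, 0, 0.15)))

test_that("offset records resolve components with the stated sign conventions", {
  fr <- simple_frame()
  r <- offset_record(5 * fr$signed_dirs$anterior, fr)
  expect_equal(r$anterior_posterior, 5)
  expect_lt(abs(r$medial_lateral), 1e-12)
  expect_lt(abs(r$inferior_superior), 1e-12)
  expect_equal(r$absolute, 5)
  expect_equal(r$distal_proximal, r$inferior_superior)

  set.seed(15)
  for (i in 1:25) {
    v <- rnorm(3, 0, 10)
    r <- offset_record(v, fr)
    expect_lt(abs(r$absolute^2 - (r$anterior_posterior^2 + r$medial_lateral^2 +
                                  r$inferior_superior^2)), 1e-6)
  }
})

test_that("exit points of a line through a sphere are antipodal", {
  sph <- sphere_mesh(center = c(0, 0, 0), r = 8)
  fr <- simple_frame()
  ex <- axis_exit_points(line3(c(0, 0, 0), c(1, 0, 0)), sph, fr)
  expect_lt(max(abs(ex$trochlear_point + ex$capitellum_point)), 1e-6)
  expect_gt(ex$trochlear_point[1], 0)   # most medial along +x-ish
  miss <- line3(c(0, 0, 30), c(1, 0, 0))
  expect_error(axis_exit_points(miss, sph, fr), "at least 2")
})

test_that("trivial point offsets vanish when exits coincide with epicondyles", {
  fr <- simple_frame()
  ex <- list(trochlear_point = c(10, 1, 2), capitellum_point = c(-10, 0, 0))
  off <- point_offsets(ex, medial_epi = c(10, 1, 2), lateral_epi = c(-10, 0, 0), fr)
  expect_equal(off$medial$absolute, 0)
  expect_equal(off$lateral$absolute, 0)
})

test_that("synthetic exit points and offsets round-trip through the mesh", {
  s <- local_specimen("table")
  rep <- run_specimen(s$mesh, s$landmarks)
  expect_lt(max(abs(rep$exits$trochlear_point - s$truth$trochlear_point)), 1e-6)
  expect_lt(max(abs(rep$exits$capitellum_point - s$truth$capitellum_point)), 1e-6)
  err <- compare_to_truth(rep, s$truth)
  expect_lt(max(err[c("medial_ap", "medial_ml", "medial_is")]), 0.2)
  expect_lt(max(err[c("lateral_ap", "lateral_ml", "lateral_is")]), 0.2)
  expect_lt(max(err[c("axis_ap", "axis_ml", "axis_is")]), 0.3)
})

test_that("axis offset ignores the along-axis component of the translation", {
  s <- local_specimen("table")
  rep <- run_specimen(s$mesh, s$landmarks)
  fe <- rep$axes$fe_axis
  # same line expressed with a shifted anchor: identical result set
  fe2 <- line3(fe$anchor + 7.3 * fe$direction, fe$direction)
  a1 <- axis_translational_offset(fe, rep$axes$lateral_epicondyle,
                                  rep$axes$medial_epicondyle, s$mesh, rep$frame)
  a2 <- axis_translational_offset(fe2, rep$axes$lateral_epicondyle,
                                  rep$axes$medial_epicondyle, s$mesh, rep$frame)
  expect_lt(abs(a1$record$absolute - a2$record$absolute), 1e-9)
  expect_lt(max(abs(a1$medial_intersection_point - a2$medial_intersection_point)),
            1e-9)
})

test_that("null specimen yields an exactly vanishing axis offset", {
  s0 <- local_specimen("null")
  r0 <- run_specimen(s0$mesh, s0$landmarks)
  expect_lt(r0$axis_offset$absolute, 0.1)
})

test_that("all offsets are invariant under rigid motion of the specimen", {
  s <- local_specimen("table")
  r0 <- run_specimen(s$mesh, s$landmarks)
  set.seed(16)
  for (i in 1:3) {
    tf <- random_rigid3()
    r1 <- run_specimen(apply_rigid(tf, s$mesh), apply_rigid(tf, s$landmarks))
    for (rec in c("medial", "lateral", "axis_offset"))
      for (f in c("absolute", "anterior_posterior", "medial_lateral",
                  "inferior_superior"))
        expect_lt(abs(r1[[rec]][[f]] - r0[[rec]][[f]]), 1e-6)
  }
})
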