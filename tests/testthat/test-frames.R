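frame_of_dirs <- function(long, fe, side = "right")
  build_frame(line3(c(0, 0, 0), long), line3(c(0, 0, 0), fe), side = side)

test_that("canonical frame matches the simple configuration", {
  fr <- frame_of_dirs(c(0, 0, 1), c(1, 0, 0))
  expect_equal(abs(fr$coronal$normal), c(0, 1, 0))
  expect_equal(fr$axial$normal, c(0, 0, 1))
  expect_equal(fr$signed_dirs$medial, c(1, 0, 0))
  expect_equal(fr$signed_dirs$distal, c(0, 0, -1))
})

test_that("frame normals are mutually orthogonal for random axis pairs", {
  set.seed(9)
  for (i in 1:50) {
    long <- elbowaxes:::unit3(rnorm(3))
    fe <- elbowaxes:::unit3(rnorm(3))
    if (min(angle_deg(long, fe), 180 - angle_deg(long, fe)) < 6) next
    fr <- frame_of_dirs(long, fe)
    n <- list(fr$coronal$normal, fr$sagittal$normal, fr$axial$normal)
    expect_lt(abs(sum(n[[1]] * n[[2]])), 1e-9)
    expect_lt(abs(sum(n[[1]] * n[[3]])), 1e-9)
    expect_lt(abs(sum(n[[2]] * n[[3]])), 1e-9)
  }
  expect_error(frame_of_dirs(c(0, 0, 1), c(0, 0.05, 1)), "degenerate frame")
})

test_that("identical axes give zero rotational difference", {
  fe <- elbowaxes:::unit3(c(1, 0.1, 0.12))
  fr <- frame_of_dirs(c(0, 0, 1), fe)
  axes <- list(long_axis = line3(c(0, 0, 0), c(0, 0, 1)),
               fe_axis = line3(c(0, 0, 0), fe),
               epicondylar = line3(c(5, 0, 0), fe))
  rd <- rotational_difference(fr, axes)
  expect_equal(rd$absolute_diff, 0)
  expect_lt(abs(rd$flexion_extension), 1e-9)
  expect_lt(abs(rd$varus_valgus), 1e-9)
  expect_lt(abs(rd$external_internal), 1e-9)
})

test_that("single-plane rotations are recovered exactly in their own channel", {
  fe <- elbowaxes:::unit3(c(1, 0.10, 0.11))
  long <- c(0, 0, 1)
  fr <- frame_of_dirs(long, fe)
  channels <- list(varus_valgus = fr$signed_dirs$distal,
                   external_internal = fr$signed_dirs$anterior,
                   flexion_extension = fr$signed_dirs$medial)
  for (ch in names(channels)) {
    for (ang in c(-10, -3, 1, 5, 10)) {
      epi <- drop(rotation_about(channels[[ch]], ang) %*% fe)
      rd <- rotational_difference(fr, list(long_axis = line3(c(0, 0, 0), long),
                                           fe_axis = line3(c(0, 0, 0), fe),
                                           epicondylar = line3(c(0, 0, 0), epi)))
      expect_lt(abs(rd[[ch]] - ang), 1e-6)
    }
  }
})

test_that("cross-talk into the well-conditioned axial and coronal channels is small", {
  # the sagittal (flexion) channel is excluded as a receiver: its projections
  # are quotients of small axis components, so cross-talk into it is
  # intrinsically amplified (see the methods vignette)
  fe <- elbowaxes:::unit3(c(1, 0.10, 0.11))
  long <- c(0, 0, 1)
  fr <- frame_of_dirs(long, fe)
  senders <- list(varus_valgus = fr$signed_dirs$distal,
                  external_internal = fr$signed_dirs$anterior)
  for (ch in names(senders)) {
    other <- setdiff(names(senders), ch)
    for (ang in c(-10, -3, 3, 10)) {
      epi <- drop(rotation_about(senders[[ch]], ang) %*% fe)
      rd <- rotational_difference(fr, list(long_axis = line3(c(0, 0, 0), long),
                                           fe_axis = line3(c(0, 0, 0), fe),
                                           epicondylar = line3(c(0, 0, 0), epi)))
      expect_lt(abs(rd[[ch]] - ang), 0.2)
      expect_lt(abs(rd[[other]]), 0.2)
    }
  }
})

test_that("absolute difference equals |alpha - beta|", {
  set.seed(10)
  for (i in 1:20) {
    long <- elbowaxes:::unit3(rnorm(3))
    fe <- elbowaxes:::unit3(rnorm(3))
    epi <- elbowaxes:::unit3(fe + rnorm(3, 0, 0.05))
    if (min(angle_deg(long, fe), 180 - angle_deg(long, fe)) < 6) next
    fr <- frame_of_dirs(long, fe)
    rd <- rotational_difference(fr, list(long_axis = line3(c(0, 0, 0), long),
                                         fe_axis = line3(c(0, 0, 0), fe),
                                         epicondylar = line3(c(0, 0, 0), epi)))
    expect_lt(abs(rd$absolute_diff - abs(rd$alpha - rd$beta)), 1e-9)
  }
})

test_that("mirrored left-side specimens report identical signed values", {
  sr <- local_specimen("table")
  sl <- generate_specimen(synthetic_spec(side = "left"))
  rr <- run_specimen(sr$mesh, sr$landmarks)
  rl <- run_specimen(sl$mesh, sl$landmarks)
  for (f in c("flexion_extension", "varus_valgus", "external_internal"))
    expect_lt(abs(rr$rotation[[f]] - rl$rotation[[f]]), 1e-6)
  for (f in c("anterior_posterior", "medial_lateral", "inferior_superior")) {
    expect_lt(abs(rr$medial[[f]] - rl$medial[[f]]), 1e-6)
    expect_lt(abs(rr$lateral[[f]] - rl$lateral[[f]]), 1e-6)
  }
})

test_that("rotational difference is invariant under rigid motion of the axes", {
  set.seed(13)
  fe <- elbowaxes:::unit3(c(1, 0.08, 0.13))
  epi <- elbowaxes:::unit3(c(1, 0.05, 0.18))
  long <- c(0, 0, 1)
  axes0 <- list(long_axis = line3(c(0, -4, 0), long),
                fe_axis = line3(c(0, 0, 0), fe),
                epicondylar = line3(c(0, 0, 0), epi))
  rd0 <- rotational_difference(frame_of_dirs(long, fe), axes0)
  for (i in 1:10) {
    tf <- random_rigid3()
    axes1 <- lapply(axes0, function(l) apply_rigid(tf, l))
    fr1 <- build_frame(axes1$long_axis, axes1$fe_axis)
    rd1 <- rotational_difference(fr1, axes1)
    for (f in c("alpha", "beta", "flexion_extension", "varus_valgus",
                "external_internal"))
      expect_lt(abs(rd1[[f]] - rd0[[f]]), 1e-6)
  }
})
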