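test_that("epicondylar axis averages picks and ignores pick order", {
  med <- rbind(c(10, 0, 0), c(10, 0, 0), c(10, 0, 0))
  lat <- rbind(c(-10, 0, 0), c(-10, 0, 0), c(-10, 0, 0))
  lm <- landmark_set(med, lat, circle_points(8, c(0, 0, 0), 5, c(1, 0, 0)))
  e <- epicondylar_axis(lm)
  expect_equal(e$medial_epicondyle, c(10, 0, 0))
  expect_equal(e$axis$direction, c(1, 0, 0))

  med2 <- rbind(c(10, 1, 0), c(10, -1, 1), c(10, 0, -1))
  lm2 <- landmark_set(med2, lat, lm$groove_points)
  lm3 <- landmark_set(med2[c(3, 1, 2), ], lat, lm$groove_points)
  expect_equal(epicondylar_axis(lm2)$medial_epicondyle,
               epicondylar_axis(lm3)$medial_epicondyle)
  expect_equal(epicondylar_axis(lm2)$medial_epicondyle, c(10, 0, 0))

  lmX <- landmark_set(med, med, lm$groove_points)
  expect_error(epicondylar_axis(lmX), "coincide")
})

test_that("jittered epicondyle picks recover the apex within the sampling bound", {
  set.seed(71)
  sd_ <- 0.5
  errs <- replicate(20, {
    s <- generate_specimen(synthetic_spec(landmark_jitter_sd = sd_,
                                          seed = sample.int(1e6, 1)))
    e <- epicondylar_axis(s$landmarks)
    max(elbowaxes:::norm3(e$medial_epicondyle - s$truth$medial_epicondyle),
        elbowaxes:::norm3(e$lateral_epicondyle - s$truth$lateral_epicondyle))
  })
  # mean of 3 picks: error scale sd/sqrt(3) per axis; allow 3 sigma
  expect_lt(stats::median(errs), 3 * sd_ / sqrt(3))
})

test_that("long axis of a straight elliptical cylinder is exact and equivariant", {
  cyl <- cylinder_mesh(a = 11, b = 9, len = 80, n_theta = 96, n_rings = 41)
  lm_z <- c(0.15, 0.85)
  lm <- landmark_set(rbind(c(11, 0, 10), c(11, 0, 10), c(11, 0, 10)),
                     rbind(c(-11, 0, 10), c(-11, 0, 10), c(-11, 0, 10)),
                     circle_points(8, c(0, 0, 5), 9, c(1, 0, 0)),
                     shaft_zrange = lm_z)
  fit <- distal_humeral_axis(cyl, lm)
  expect_lt(angle_deg(fit$axis$direction, c(0, 0, 1)), 1e-3)
  expect_length(fit$ellipses, 5)

  set.seed(8)
  tf <- random_rigid3()
  cylt <- apply_rigid(tf, cyl)
  fitt <- distal_humeral_axis(cylt, apply_rigid(tf, lm))
  expect_lt(angle_deg(fitt$axis$direction,
                      apply_rigid(tf, fit$axis$direction, type = "direction")),
            1e-3)
})

test_that("a bowed shaft still yields the nominal long axis within a degree", {
  s <- generate_specimen(synthetic_spec(shaft_bow_deg = 2))
  fit <- distal_humeral_axis(s$mesh, s$landmarks)
  expect_lt(angle_deg(fit$axis$direction, c(0, 0, 1)), 1)
})

test_that("true F-E axis is exact on clean groove points and robust to jitter", {
  s <- local_specimen("table")
  fe <- true_fe_axis(s$landmarks, lateral_to_medial = s$truth$fe_axis$direction)
  expect_lt(angle_deg(fe$axis$direction, s$truth$fe_axis$direction), 1e-7)
  expect_lt(elbowaxes:::norm3(fe$circle$center - s$truth$groove_circle$center), 1e-8)

  set.seed(77)
  errs <- replicate(10, {
    sj <- generate_specimen(synthetic_spec(landmark_jitter_sd = 0.3,
                                           seed = sample.int(1e6, 1)))
    fej <- true_fe_axis(sj$landmarks, sj$truth$fe_axis$direction)
    c(angle_deg(fej$axis$direction, sj$truth$fe_axis$direction),
      elbowaxes:::norm3(fej$circle$center - sj$truth$groove_circle$center))
  })
  expect_lt(stats::median(errs[1, ]), 1.5)   # direction, degrees
  expect_lt(stats::median(errs[2, ]), 0.5)   # center, mm
})

test_that("a 90-degree groove arc still converges with bounded error", {
  set.seed(78)
  s <- generate_specimen(synthetic_spec(groove_arc_deg = 90,
                                        landmark_jitter_sd = 0.2, seed = 5))
  fe <- true_fe_axis(s$landmarks, s$truth$fe_axis$direction)
  expect_true(fe$converged)
  expect_lt(angle_deg(fe$axis$direction, s$truth$fe_axis$direction), 10)
})
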