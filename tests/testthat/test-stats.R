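test_that("cohort summary computes mean and sample SD", {
  t1 <- data.frame(a = c(1, 2, 3), b = c(5, 5, 5))
  s <- cohort_summary(t1)
  expect_equal(s$mean[s$parameter == "a"], 2)
  expect_equal(s$sd[s$parameter == "a"], 1)
  expect_equal(s$sd[s$parameter == "b"], 0)
  expect_error(cohort_summary(data.frame(a = 1)), "at least 2")

  set.seed(41)
  x <- rnorm(1000, 2.2, 4.8)
  s2 <- cohort_summary(data.frame(x = x))
  expect_lt(abs(s2$mean - 2.2), 3 * 4.8 / sqrt(1000))
})

test_that("Shapiro-Wilk wrapper is calibrated and powered", {
  set.seed(42)
  p_norm <- replicate(1000, shapiro_wilk(rnorm(15))$p_value)
  expect_gte(mean(p_norm > 0.05), 0.90)
  p_exp <- replicate(400, shapiro_wilk(rexp(100))$p_value)
  expect_gte(mean(p_exp < 0.05), 0.95)
  d <- shapiro_wilk(rep(3, 10))
  expect_true(d$degenerate)
  expect_error(shapiro_wilk(c(1, 2)), "3 <= n")
})

test_that("t-test wrapper matches the closed-form pooled computation", {
  x <- c(5.1, 4.9, 6.2, 5.8, 5.5, 6.0)
  y <- c(4.2, 4.8, 5.0, 4.6, 4.4, 4.9)
  r <- t_test(x, y, paired = FALSE)
  nx <- length(x); ny <- length(y)
  sp2 <- ((nx - 1) * var(x) + (ny - 1) * var(y)) / (nx + ny - 2)
  t_hand <- (mean(x) - mean(y)) / sqrt(sp2 * (1 / nx + 1 / ny))
  p_hand <- 2 * pt(-abs(t_hand), nx + ny - 2)
  expect_lt(abs(r$t - t_hand), 1e-10)
  expect_lt(abs(r$p_value - p_hand), 1e-10)

  rp <- t_test(x, x, paired = TRUE)
  expect_equal(rp$t, 0)
  expect_equal(rp$p_value, 1)
  expect_true(rp$degenerate)
})

test_that("t-test power and size behave as expected under simulation", {
  set.seed(43)
  # paired design (the medial-vs-lateral comparison): difference ~ N(3, 1.6)
  p_alt <- replicate(2000, t_test(rnorm(15, 3, 1.6), rep(0, 15),
                                  paired = TRUE)$p_value)
  expect_gte(mean(p_alt < 0.001), 0.99)

  p_null <- replicate(2000, t_test(rnorm(15), rnorm(15), paired = TRUE)$p_value)
  rate <- mean(p_null < 0.05)
  ci_half <- 1.96 * sqrt(0.05 * 0.95 / 2000)
  expect_lt(abs(rate - 0.05), ci_half + 1e-9)
})

test_that("ICC formulas agree with an independent ANOVA mean-squares oracle", {
  set.seed(44)
  for (i in 1:10) {
    M <- matrix(rnorm(18, 10, 2), 6, 3) + outer(rnorm(6, 0, 3), rep(1, 3))
    r2 <- icc(M, "ICC2"); r3 <- icc(M, "ICC3")
    d <- data.frame(y = as.vector(M),
                    subj = factor(rep(1:6, 3)), rater = factor(rep(1:3, each = 6)))
    a <- stats::aov(y ~ subj + rater, data = d)
    ms <- summary(a)[[1]][["Mean Sq"]]
    MSR <- ms[1]; MSC <- ms[2]; MSE <- ms[3]
    icc2_o <- (MSR - MSE) / (MSR + 2 * MSE + 3 * (MSC - MSE) / 6)
    icc3_o <- (MSR - MSE) / (MSR + 2 * MSE)
    expect_lt(abs(r2$icc - icc2_o), 1e-10)
    expect_lt(abs(r3$icc - icc3_o), 1e-10)
    Fo <- MSR / MSE
    expect_lt(abs(r2$F - Fo), 1e-8)
  }
})

test_that("ICC degenerate and shift properties hold", {
  base <- matrix(rnorm(12, 50, 5), 6, 2)
  identical_raters <- cbind(base[, 1], base[, 1], base[, 1])
  expect_equal(icc(identical_raters, "ICC2")$icc, 1)
  expect_equal(icc(identical_raters, "ICC3")$icc, 1)

  shifted <- cbind(base[, 1], base[, 1] + 4)
  expect_equal(icc(shifted, "ICC3")$icc, 1)
  expect_lt(icc(shifted, "ICC2")$icc, 1)

  # invariance to subject relabeling; ICC3 invariance to per-rater shifts
  set.seed(45)
  M <- matrix(rnorm(24, 0, 1), 8, 3) + outer(rnorm(8, 0, 2), rep(1, 3))
  perm <- sample(8)
  expect_equal(icc(M[perm, ], "ICC2")$icc, icc(M, "ICC2")$icc)
  M2 <- sweep(M, 2, c(1, -2, 0.5), `+`)
  expect_equal(icc(M2, "ICC3")$icc, icc(M, "ICC3")$icc, tolerance = 1e-12)
})

test_that("observer-reliability report reproduces perfect agreement", {
  coords <- expand.grid(specimen = 1:6, rater = 1:3, session = 1:5,
                        parameter = c("med_x", "med_y", "med_z",
                                      "lat_x", "lat_y", "lat_z"))
  true_vals <- matrix(rnorm(36, 20, 8), 6, 6)
  coords$value <- true_vals[cbind(coords$specimen,
                                  as.integer(coords$parameter))]
  rep <- icc_report(coords)
  expect_true(all(abs(rep$inter$icc2 - 1) < 1e-12))
  expect_true(all(abs(rep$intra$icc3 - 1) < 1e-12))
  expect_error(icc_report(coords[, -5]), "columns")
})
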