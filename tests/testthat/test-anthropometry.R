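test_that("subject_statics enforces positivity and sex levels", {
  expect_s3_class(ref_subject(), "subject_statics")
  expect_error(subject_statics("male", -1.7, 75, 47, 26, 9.5, 32), "positive")
  expect_error(subject_statics("male", 1.7, 75, 0, 26, 9.5, 32), "positive")
  expect_error(subject_statics("other", 1.7, 75, 47, 26, 9.5, 32))
})

test_that("simulated cohort stays inside the 5th-95th percentile band", {
  ref <- anthro_reference()
  cohort <- sample_simulated_cohort(300, seed = 0)
  h <- vapply(cohort, `[[`, 0, "height")
  m <- vapply(cohort, `[[`, 0, "mass")
  h_lim <- qnorm(c(0.05, 0.95), ref$height_mean, ref$height_sd)
  m_lim <- qnorm(c(0.05, 0.95), ref$mass_mean, ref$mass_sd)
  expect_true(all(h >= h_lim[1] & h <= h_lim[2]))
  expect_true(all(m >= m_lim[1] & m <= m_lim[2]))
})

test_that("degenerate reference SDs give the reference means exactly", {
  ref <- anthro_reference(height_sd = 0, mass_sd = 0, mvc_sd = 0,
                          forearm_sd = 0, elbow_width_sd = 0,
                          upper_arm_sd = 0)
  s <- sample_simulated_cohort(1, seed = 1, ref = ref, derived_cv = 0)[[1]]
  expect_equal(s$height, ref$height_mean)
  expect_equal(s$mass, ref$mass_mean)
  expect_equal(s$mvc_torque, ref$mvc_mean)
  r <- sample_recorded_style_cohort(2, seed = 1, ref = ref)
  expect_equal(r[[1]]$mass, ref$mass_mean)
  expect_equal(r[[2]]$mvc_torque, ref$mvc_mean)
})

test_that("large-sample moments match the configured reference", {
  ref <- anthro_reference()
  sim <- sample_simulated_cohort(10000, seed = 1)
  m <- vapply(sim, `[[`, 0, "mass")
  expect_lt(abs(mean(m) - ref$mass_mean), 4 * sd(m) / sqrt(length(m)))
  rec <- sample_recorded_style_cohort(10000, seed = 2)
  v <- vapply(rec, `[[`, 0, "mvc_torque")
  expect_lt(abs(mean(v) - ref$mvc_mean), 4 * sd(v) / sqrt(length(v)))
  # recorded-style draws live within +/- 3 SD
  mm <- vapply(rec, `[[`, 0, "mass")
  expect_true(all(mm >= ref$mass_mean - 3 * ref$mass_sd &
                    mm <= ref$mass_mean + 3 * ref$mass_sd))
})

test_that("truncated sampling never leaves its bounds over many draws", {
  x <- flexfatigue:::rnorm_trunc(1e5, 0, 1, 0.05, 0.95)
  lim <- qnorm(c(0.05, 0.95))
  expect_true(all(x >= lim[1] & x <= lim[2]))
})

test_that("cohorts are bitwise reproducible per seed", {
  expect_identical(sample_simulated_cohort(50, seed = 9),
                   sample_simulated_cohort(50, seed = 9))
  expect_identical(sample_recorded_style_cohort(25, seed = 9),
                   sample_recorded_style_cohort(25, seed = 9))
  expect_false(identical(sample_simulated_cohort(50, seed = 9),
                         sample_simulated_cohort(50, seed = 10)))
})

test_that("cohort sampling rejects non-positive n", {
  expect_error(sample_simulated_cohort(0, seed = 1), "positive")
  expect_error(sample_recorded_style_cohort(-3, seed = 1), "positive")
})

test_that("scale_model is the identity at the reference subject", {
  m <- scale_model(generic_actuators(), ref_subject())
  expect_equal(m$actuators$fmax, generic_actuators()$fmax)
  expect_equal(m$actuators$moment_arm, generic_actuators()$moment_arm)
})

test_that("scale_model is multiplicative and sign-preserving", {
  ref <- anthro_reference()
  tall <- subject_statics("male", 2 * ref$height_mean, ref$mass_mean,
                          46.9, 25.9, 9.5, 31.6)
  m <- scale_model(generic_actuators(), tall)
  expect_equal(m$actuators$moment_arm, 2 * generic_actuators()$moment_arm)
  expect_equal(m$actuators$fmax, generic_actuators()$fmax)
  expect_true(all(sign(m$actuators$moment_arm) ==
                    sign(generic_actuators()$moment_arm)))

  heavy <- subject_statics("male", ref$height_mean, 1.21 * ref$mass_mean,
                           46.9, 25.9, 9.5, 31.6)
  one_flexor <- data.frame(
    name = c("TRI_long", "TRI_lat", "TRI_med", "BIC_long", "BIC_short",
             "BRA", "BRD"),
    group = c("TRI", "TRI", "TRI", "BIC", "BIC", "BRA", "BRD"),
    fmax = c(100, 100, 100, 1000, 1, 1, 1),
    moment_arm = c(-0.02, -0.02, -0.02, 0.05, 0.01, 0.01, 0.01))
  m2 <- scale_model(one_flexor, heavy)
  expect_equal(m2$actuators$fmax[4], 1210)
})

test_that("scaling round-trips through the inverse subject", {
  ref <- anthro_reference()
  s <- subject_statics("female", 1.62, 58.3, 40, 24, 9, 30)
  inv <- subject_statics("female", ref$height_mean^2 / s$height,
                         ref$mass_mean^2 / s$mass, 40, 24, 9, 30)
  back <- scale_model(scale_model(generic_actuators(), s)$actuators, inv)
  expect_equal(back$actuators$fmax, generic_actuators()$fmax,
               tolerance = 1e-12)
  expect_equal(back$actuators$moment_arm, generic_actuators()$moment_arm,
               tolerance = 1e-12)
})

test_that("generic actuator defaults put ramp targets astride the ceiling", {
  ceiling_T <- strength_ceiling(ref_model())
  expect_gt(ceiling_T, 50)
  expect_lt(ceiling_T, 100)
})

test_that("cohort CSV round-trips", {
  cohort <- sample_recorded_style_cohort(5, seed = 3)
  names(cohort) <- sprintf("R%02d", 1:5)
  path <- withr::local_tempfile(fileext = ".csv")
  write_cohort_csv(cohort, path)
  back <- read_cohort_csv(path)
  expect_equal(names(back), names(cohort))
  expect_equal(vapply(back, `[[`, 0, "mass"),
               vapply(cohort, `[[`, 0, "mass"), tolerance = 1e-12)
})
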