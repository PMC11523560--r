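test_that("target profiles ramp, plateau and hold", {
  tt <- build_target_profile(torque_target(60), dt = 0.25)
  expect_equal(tt$values[tt$times == 0], 10)
  expect_true(all(tt$values[tt$times >= 1.5] == 60))
  expect_equal(tt$values[tt$times == 0.75], 35)  # ramp midpoint
  expect_equal(length(tt$values), 121)
  expect_equal(length(build_target_profile(torque_target(60), 0.1)$values),
               301)

  flat <- build_target_profile(torque_target(10, ramp_start = 10), dt = 0.1)
  expect_true(all(flat$values == 10))
  expect_error(torque_target(5, ramp_start = 10), "peak")
  expect_error(build_target_profile(torque_target(40), dt = 0), "positive")
})

test_that("forward torque is the activation-weighted fmax-moment-arm sum", {
  m <- ref_model()
  zero <- activation_trace(0:9, matrix(0, 10, 7), m$actuators$name)
  expect_true(all(forward_torque(m, zero)$values == 0))

  # single active flexor: closed form fmax * a * r
  one <- structure(list(statics = ref_subject(), actuators = data.frame(
    name = c("TRI_long", "TRI_lat", "TRI_med", "BIC_long", "BIC_short",
             "BRA", "BRD"),
    group = c("TRI", "TRI", "TRI", "BIC", "BIC", "BRA", "BRD"),
    fmax = c(1, 1, 1, 1000, 1, 1, 1),
    moment_arm = c(-0.01, -0.01, -0.01, 0.05, 0.01, 0.01, 0.01))),
    class = "scaled_elbow_model")
  act <- matrix(0, 10, 7, dimnames = list(NULL, one$actuators$name))
  act[, "BIC_long"] <- 0.5
  tq <- forward_torque(one, activation_trace(0:9, act, one$actuators$name))
  expect_equal(tq$values, rep(25, 10))

  expect_error(forward_torque(m, activation_trace(0:9, matrix(0, 10, 5))),
               "channels")
})

test_that("4-group activations broadcast to member actuators", {
  m <- ref_model()
  act4 <- activation_trace(0:4, matrix(0.3, 5, 4),
                           c("bra", "tri", "bic", "brd"))
  act7 <- activation_trace(0:4, matrix(0.3, 5, 7), m$actuators$name)
  expect_equal(forward_torque(m, act4)$values, forward_torque(m, act7)$values)
})

test_that("inverse solve reproduces feasible targets through the forward map", {
  m <- ref_model()
  for (peak in c(30, 50, 70)) {
    tt <- build_target_profile(torque_target(peak), dt = 0.1)
    sol <- solve_activations(m, tt)
    expect_true(sol$converged)
    tq <- forward_torque(m, sol$activations)
    expect_lt(max(abs(tq$values - tt$values)), 1e-6)
  }
})

test_that("least-norm closed form and infeasibility flags are exact", {
  # two effective flexors with c = (50, 25): lambda = 25/3125
  a <- flexfatigue:::solve_step(25, c(50, 25))
  expect_equal(a, c(0.4, 0.2))
  expect_equal(sum(c(50, 25) * a), 25)

  m <- ref_model()
  ceiling_T <- strength_ceiling(m)
  tt <- torque_trace(c(0, 1), rep(1.05 * ceiling_T, 2))
  expect_false(solve_activations(m, tt)$converged)
  expect_true(solve_activations(m, torque_trace(c(0, 1), rep(0, 2)))$converged)

  zero <- solve_activations(m, torque_trace(c(0, 1), c(0, 0)))
  expect_true(all(zero$activations$values == 0))
  expect_error(solve_activations(m, torque_trace(c(0, 1), c(-1, 0))),
               "non-negative")
})

test_that("solver matches a one-dimensional multiplier grid oracle", {
  # independent oracle: the KKT solution is a_i = clamp(lambda * c_i, 0, 1);
  # brute-force lambda on a fine grid and keep the best torque match
  set.seed(11)
  for (rep in 1:5) {
    cvec <- sort(runif(5, 5, 60), decreasing = TRUE)
    Tfeas <- runif(1, 0.2, 0.95) * sum(cvec)
    lam_grid <- seq(0, 1.2 / min(cvec), length.out = 2e5)
    best <- NULL
    best_err <- Inf
    for (lam in lam_grid) {
      a <- pmin(lam * cvec, 1)
      err <- abs(sum(a * cvec) - Tfeas)
      if (err < best_err) {
        best_err <- err
        best <- a
      }
    }
    sol <- flexfatigue:::solve_step(Tfeas, cvec)
    expect_lt(max(abs(sol - best)), 2e-3)
  }
})

test_that("solutions are minimum-norm under feasible perturbations", {
  m <- ref_model()
  tt <- torque_trace(c(0, 1), rep(45, 2))
  sol <- solve_activations(m, tt)
  coefs <- m$actuators$fmax * m$actuators$moment_arm
  flex <- which(coefs > 0)
  a <- sol$activations$values[1, flex]
  cf <- coefs[flex]
  set.seed(3)
  base <- sum(a^2)
  for (i in 1:1000) {
    pair <- sample(length(a), 2)
    d <- c(cf[pair[2]], -cf[pair[1]])   # torque-neutral direction
    eps <- runif(1, -0.05, 0.05)
    a2 <- a
    a2[pair] <- a2[pair] + eps * d / sqrt(sum(d^2))
    if (any(a2 < 0 | a2 > 1)) next
    expect_gte(sum(a2^2), base - 1e-12)
  }
})

test_that("extensors sit at the co-activation floor and activations are monotone in torque", {
  m <- ref_model()
  sol <- solve_activations(m, torque_trace(c(0, 1), rep(40, 2)))
  tri <- grepl("^TRI", colnames(sol$activations$values))
  expect_true(all(sol$activations$values[, tri] == 0))

  sol_f <- solve_activations(m, torque_trace(c(0, 1), rep(40, 2)),
                             coactivation_floor = 0.05)
  expect_true(all(sol_f$activations$values[, tri] == 0.05))
  expect_lt(max(abs(forward_torque(m, sol_f$activations)$values - 40)), 1e-6)

  lo <- solve_activations(m, torque_trace(c(0, 1), rep(30, 2)))
  hi <- solve_activations(m, torque_trace(c(0, 1), rep(60, 2)))
  expect_true(all(hi$activations$values >= lo$activations$values - 1e-12))
})
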