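test_that("rmse and mae match hand arithmetic and the Jensen ordering", {
  e <- rmse_mae(c(0, 2, 4), c(1, 2, 3))
  expect_equal(e$rmse, sqrt(2 / 3))
  expect_equal(e$mae, 2 / 3)
  expect_equal(rmse_mae(1:5, 1:5), list(rmse = 0, mae = 0))
  expect_error(rmse_mae(1:3, 1:4), "same length")

  set.seed(9)
  for (i in 1:20) {
    a <- rnorm(50)
    p <- rnorm(50)
    e <- rmse_mae(a, p)
    expect_gte(e$rmse, e$mae)
  }

  # constant-zero predictor: rmse^2 = mean^2 + population variance
  a <- rnorm(1000, 30, 5)
  e0 <- rmse_mae(a, rep(0, 1000))
  expect_equal(e0$rmse, sqrt(mean(a^2)), tolerance = 1e-12)
})

test_that("leave-out splits are disjoint, exhaustive and seeded", {
  ids <- sprintf("S%02d", 1:25)
  sp <- make_split(ids, 5, seed = 3)
  expect_length(sp$leaveout_subjects, 5)
  expect_length(sp$train_subjects, 20)
  expect_length(intersect(sp$train_subjects, sp$leaveout_subjects), 0)
  expect_setequal(c(sp$train_subjects, sp$leaveout_subjects), ids)
  expect_identical(sp, make_split(ids, 5, seed = 3))
  expect_false(identical(sp$leaveout_subjects,
                         make_split(ids, 5, seed = 4)$leaveout_subjects))
  empty <- make_split(ids, 0, seed = 1)
  expect_length(empty$leaveout_subjects, 0)
  expect_error(make_split(ids, 25, seed = 1), "smaller")
})

test_that("three-way evaluation reports pooled errors and parity pairs", {
  trials <- toy_recorded_trials(8)
  tiny <- arch_config(lstm_layers = 2L, lstm_width = 6L, ff_layers = 1L,
                      ff_width = 6L)
  cfg <- train_config(5e-3, 1e-4, epochs = 3L, batch_size = 4L, seed = 1)
  sim <- lapply(trials[1:4], function(tr) {
    flex_trial(tr$subject_id, tr$activations, tr$torque,
               provenance = "simulated")
  })
  bb <- pretrain_backbone(sim, tiny, cfg)
  tm <- finetune_transfer(bb, trials[1:6], tiny, cfg)
  dm <- train_direct(trials[1:6], tiny, cfg)
  leaveout <- trials[7:8]

  rep <- evaluate_three_way(tm, dm, leaveout)
  for (ap in c("transfer", "direct", "simulation")) {
    expect_true(all(c("rmse", "mae", "prediction_sd", "actual_sd",
                      "parity", "per_subject") %in% names(rep[[ap]])))
    expect_gte(rep[[ap]]$rmse, rep[[ap]]$mae)
    expect_equal(nrow(rep[[ap]]$parity), 2 * 300)
  }

  # a perfect baseline scores zero
  actual <- t(vapply(leaveout, `[[`, numeric(300), "torque"))
  perfect <- evaluate_three_way(tm, dm, leaveout, baseline_pred = actual)
  expect_equal(perfect$simulation$rmse, 0)
  expect_error(evaluate_three_way(tm, dm, leaveout,
                                  baseline_pred = actual[, 1:10]),
               "misaligned")

  dir <- withr::local_tempdir()
  write_eval_report(rep, dir)
  js <- jsonlite::read_json(file.path(dir, "report.json"))
  expect_equal(js$transfer$rmse, rep$transfer$rmse, tolerance = 1e-9)
  expect_true(file.exists(file.path(dir, "parity_simulation.csv")))
})

test_that("evaluation is pure: identical inputs give identical reports", {
  trials <- toy_recorded_trials(6)
  tiny <- arch_config(lstm_layers = 2L, lstm_width = 6L, ff_layers = 1L,
                      ff_width = 6L)
  cfg <- train_config(5e-3, 1e-4, epochs = 2L, batch_size = 4L, seed = 1)
  dm <- train_direct(trials[1:4], tiny, cfg)
  r1 <- evaluate_three_way(dm, dm, trials[5:6])
  r2 <- evaluate_three_way(dm, dm, trials[5:6])
  expect_identical(r1[c("transfer", "direct", "simulation")],
                   r2[c("transfer", "direct", "simulation")])
})

test_that("Tukey fences follow the declared quantile convention exactly", {
  st <- tukey_stats(1:100)
  expect_equal(st$q1, quantile(1:100, 0.25, type = 7, names = FALSE))
  expect_equal(st$q1, 25.75)
  expect_equal(st$fence_low, st$q1 - 1.5 * st$iqr)
  expect_equal(st$fence_high, st$q3 + 1.5 * st$iqr)

  same <- tukey_stats(rep(3, 50))
  expect_equal(same$iqr, 0)
  expect_equal(same$n_outliers, 0)
})

test_that("standard-normal outlier fraction sits near the Tukey expectation", {
  set.seed(123)
  st <- tukey_stats(rnorm(1e5))
  expect_gt(st$outlier_fraction, 0.004)
  expect_lt(st$outlier_fraction, 0.010)
})

test_that("distribution summaries cover all channels and torque", {
  trials <- toy_recorded_trials(4)
  ds <- distribution_summary(trials)
  expect_equal(ds$variable, c("bra", "tri", "bic", "brd", "torque"))
  expect_true(all(ds$n == 4 * 300))
  expect_error(distribution_summary(list()), "empty")
})
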