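#' Root-mean-square and mean-absolute error
#'
#' @param actual,predicted Equal-length numeric vectors (newton-meters).
#' @return A list with `rmse` and `mae`. `rmse >= mae` for any error vector.
#' @export
#' @examples
#' rmse_mae(c(0, 2, 4), c(1, 2, 3))  # sqrt(2/3), 2/3
rmse_mae <- function(actual, predicted) {
  if (length(actual) != length(predicted)) {
    stop("`actual` and `predicted` must have the same length", call. = FALSE)
  }
  if (length(actual) < 1L) stop("need at least one value", call. = FALSE)
  e <- actual - predicted
  list(rmse = sqrt(mean(e^2)), mae = mean(abs(e)))
}

#' Leave-out split of a subject cohort
#'
#' Seeded uniform sample of `n_leaveout` subjects without replacement; the
#' complement forms the training set.
#'
#' @param subject_ids Character vector of subject identifiers.
#' @param n_leaveout Number of leave-out subjects (default 5).
#' @param seed Integer seed.
#' @return An object of class `dataset_split`: list with `train_subjects`
#'   and `leaveout_subjects`.
#' @export
make_split <- function(subject_ids, n_leaveout = 5L, seed = 0L) {
  subject_ids <- unique(subject_ids)
  if (n_leaveout >= length(subject_ids)) {
    stop("`n_leaveout` must be smaller than the cohort", call. = FALSE)
  }
  old <- .Random.seed_guard(seed)
  on.exit(old())
  leaveout <- if (n_leaveout > 0) sample(subject_ids, n_leaveout)
              else character(0)
  structure(list(train_subjects = setdiff(subject_ids, leaveout),
                 leaveout_subjects = leaveout),
            class = "dataset_split")
}

#' Physics-based forward-simulation baseline
#'
#' For each leave-out trial: scale the generic elbow model to the subject's
#' anthropometry, smooth the processed activations with the 25-sample
#' moving average, and evaluate the forward torque map.
#'
#' @param trials List of [flex_trial()]s carrying statics.
#' @param window Moving-average window (default 25 samples).
#' @param ref An [anthro_reference()].
#' @return A matrix of predicted torques (trials x time steps).
#' @export
simulation_baseline <- function(trials, window = 25L, ref = anthro_reference()) {
  generic <- generic_actuators()
  preds <- t(vapply(trials, function(tr) {
    if (is.null(tr$statics)) {
      stop("baseline requires trials with static features", call. = FALSE)
    }
    model <- scale_model(generic, tr$statics, ref = ref)
    act <- activation_trace(seq_len(nrow(tr$activations)), tr$activations)
    sm <- prepare_for_simulation(act, window = window)
    forward_torque(model, sm)$values
  }, numeric(length(trials[[1]]$torque))))
  preds
}

approach_summary <- function(actual, pred, trials) {
  subs <- vapply(trials, `[[`, "", "subject_id")
  err <- rmse_mae(as.numeric(actual), as.numeric(pred))
  parity <- lapply(unique(subs), function(s) {
    rows <- which(subs == s)
    data.frame(subject_id = s,
               actual = as.numeric(t(actual[rows, , drop = FALSE])),
               predicted = as.numeric(t(pred[rows, , drop = FALSE])))
  })
  per_subject <- do.call(rbind, lapply(unique(subs), function(s) {
    rows <- which(subs == s)
    e <- rmse_mae(as.numeric(actual[rows, , drop = FALSE]),
                  as.numeric(pred[rows, , drop = FALSE]))
    data.frame(subject_id = s, rmse = e$rmse, mae = e$mae)
  }))
  list(rmse = err$rmse, mae = err$mae,
       prediction_sd = sd(as.numeric(pred)),
       actual_sd = sd(as.numeric(actual)),
       parity = do.call(rbind, parity),
       per_subject = per_subject)
}

#' Compare transfer, direct and simulation approaches on leave-out subjects
#'
#' Computes pooled RMSE and MAE (over all time steps of all leave-out
#' subjects), the prediction and actual standard deviations, per-subject
#' errors and parity pairs for the transfer model, the direct model and the
#' physics-based forward-simulation baseline.
#'
#' @param transfer,direct Trained `flex_model`s.
#' @param leaveout List of leave-out [flex_trial()]s.
#' @param baseline_pred Optional precomputed baseline prediction matrix; by
#'   default [simulation_baseline()] is run on `leaveout`.
#' @param split Optional [make_split()] recorded in the report.
#' @param seeds Optional seeds recorded in the report.
#' @return An object of class `eval_report`: list of per-approach summaries
#'   (`transfer`, `direct`, `simulation`).
#' @export
evaluate_three_way <- function(transfer, direct, leaveout,
                               baseline_pred = NULL, split = NULL,
                               seeds = NULL) {
  actual <- trials_to_xy(leaveout)$Y
  if (is.null(baseline_pred)) baseline_pred <- simulation_baseline(leaveout)
  if (!all(dim(baseline_pred) == dim(actual))) {
    stop("baseline predictions misaligned with leave-out trials", call. = FALSE)
  }
  report <- list(
    transfer = approach_summary(actual, predict(transfer, leaveout), leaveout),
    direct = approach_summary(actual, predict(direct, leaveout), leaveout),
    simulation = approach_summary(actual, baseline_pred, leaveout),
    split = split, seeds = seeds)
  class(report) <- "eval_report"
  report
}

#' @export
print.eval_report <- function(x, ...) {
  cat("<eval_report> pooled leave-out errors (Nm)\n")
  for (ap in c("transfer", "direct", "simulation")) {
    cat(sprintf("  %-10s RMSE %6.2f  MAE %6.2f  pred SD %6.2f\n",
                ap, x[[ap]]$rmse, x[[ap]]$mae, x[[ap]]$prediction_sd))
  }
  cat(sprintf("  actual SD %.2f\n", x$transfer$actual_sd))
  invisible(x)
}

#' Write an evaluation report
#'
#' Summary statistics as JSON; parity pairs as one CSV per approach.
#'
#' @param report An [evaluate_three_way()] result.
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
write_eval_report <- function(report, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  summ <- lapply(report[c("transfer", "direct", "simulation")], function(a) {
    list(rmse = a$rmse, mae = a$mae, prediction_sd = a$prediction_sd,
         actual_sd = a$actual_sd)
  })
  summ$quantile_convention <- "linear interpolation between order statistics (type 7)"
  jsonlite::write_json(summ, file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA)
  for (ap in c("transfer", "direct", "simulation")) {
    write.csv(report[[ap]]$parity,
              file.path(dir, sprintf("parity_%s.csv", ap)), row.names = FALSE)
  }
  invisible(dir)
}

#' Boxplot statistics with Tukey fences
#'
#' Per activation channel and for torque: quartiles (linear interpolation
#' between order statistics, quantile type 7), the interquartile range,
#' Tukey fences at 1.5 IQR, and the count and fraction of outliers beyond
#' the fences. Used to compare the simulated and recorded-style datasets.
#'
#' @param trials List of [flex_trial()]s.
#' @return A data frame, one row per variable.
#' @export
distribution_summary <- function(trials) {
  if (length(trials) == 0L) stop("empty dataset", call. = FALSE)
  pools <- list(
    bra = unlist(lapply(trials, function(t) t$activations[, "bra"])),
    tri = unlist(lapply(trials, function(t) t$activations[, "tri"])),
    bic = unlist(lapply(trials, function(t) t$activations[, "bic"])),
    brd = unlist(lapply(trials, function(t) t$activations[, "brd"])),
    torque = unlist(lapply(trials, `[[`, "torque")))
  do.call(rbind, lapply(names(pools), function(nm) {
    tukey_stats(pools[[nm]], nm)
  }))
}

#' @rdname distribution_summary
#' @param values Numeric vector.
#' @param name Variable label.
#' @export
tukey_stats <- function(values, name = "x") {
  q <- quantile(values, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
  iqr <- q[3] - q[1]
  lo <- q[1] - 1.5 * iqr
  hi <- q[3] + 1.5 * iqr
  out <- sum(values < lo | values > hi)
  data.frame(variable = name, q1 = q[1], median = q[2], q3 = q[3],
             iqr = iqr, fence_low = lo, fence_high = hi,
             n = length(values), n_outliers = out,
             outlier_fraction = out / length(values))
}
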