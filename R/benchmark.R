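#' Fully synthetic transfer-learning benchmark
#'
#' The package's end-to-end study at desk scale: per seed, (1) simulate a
#' pre-training dataset (a cohort of musculoskeletal models crossed with the
#' 30--90 Nm peak-torque grid, convergence-filtered), (2) pre-train the LSTM
#' backbone on it, (3) synthesize a recorded-style cohort (raw EMG, noisy
#' torque, task-failure truncation, with the generator's EMG amplitude
#' drift as the simulation-to-reality gap), (4) fine-tune the transfer model
#' and train the direct model on the same training subjects, and (5)
#' evaluate both plus the physics-based forward-simulation baseline on the
#' leave-out subjects.
#'
#' @param seeds Integer seeds; one full replicate per seed.
#' @param n_sim_models Simulated cohort size (40 models x 7 peaks gives
#'   roughly 200 converged pre-training trials).
#' @param n_subjects,n_leaveout Recorded-style cohort size and leave-out
#'   count.
#' @param pretrain_cfg,transfer_cfg,direct_cfg [train_config()]s (the
#'   transfer/direct defaults are the selected fine-tuning
#'   hyperparameters; epochs are desk-scale).
#' @param transfer_arch,direct_arch [arch_config()]s (defaults follow the
#'   selected architectures: both 3 x 24 LSTM; feedforward width 18 with 2
#'   unfrozen backend layers for transfer, width 23 for direct).
#' @param session_cfg A [session_config()]; set `emg_drift = 0` to disable
#'   the reality gap.
#' @param sim_peaks Peak-torque grid for the simulated dataset.
#' @return A list with `results` (data frame: seed, approach, rmse, mae,
#'   prediction_sd) and `reports` (per-seed [evaluate_three_way()] output).
#' @export
run_transfer_benchmark <- function(seeds = 1:3,
                                   n_sim_models = 40L,
                                   n_subjects = 25L,
                                   n_leaveout = 5L,
                                   pretrain_cfg = train_config(
                                     learning_rate = 5e-3,
                                     weight_decay = 1e-4,
                                     epochs = 150L, batch_size = 16L),
                                   transfer_cfg = train_config(
                                     learning_rate = 9.0e-3,
                                     weight_decay = 9.4e-2,
                                     epochs = 150L, batch_size = 4L),
                                   direct_cfg = train_config(
                                     learning_rate = 6.4e-3,
                                     weight_decay = 4.5e-2,
                                     epochs = 150L, batch_size = 4L),
                                   transfer_arch = arch_config(
                                     ff_width = 18L,
                                     unfrozen_backend_layers = 2L),
                                   direct_arch = arch_config(ff_width = 23L),
                                   session_cfg = session_config(),
                                   sim_peaks = seq(30, 90, by = 10)) {
  reports <- list()
  rows <- list()
  for (seed in seeds) {
    sim <- simulate_dataset(n_sim_models, sim_peaks, seed = seed)
    backbone <- pretrain_backbone(
      sim$trials, arch_config(lstm_layers = transfer_arch$lstm_layers,
                              lstm_width = transfer_arch$lstm_width),
      modifyList_cfg(pretrain_cfg, seed = seed))
    sessions <- synthesize_recorded_cohort(n_subjects, seed = seed + 1L,
                                           cfg = session_cfg)
    trials <- trials_from_sessions(sessions)
    split <- make_split(names(trials), n_leaveout, seed = seed + 2L)
    train_tr <- trials[split$train_subjects]
    test_tr <- trials[split$leaveout_subjects]
    transfer <- finetune_transfer(backbone, train_tr, transfer_arch,
                                  modifyList_cfg(transfer_cfg, seed = seed))
    direct <- train_direct(train_tr, direct_arch,
                           modifyList_cfg(direct_cfg, seed = seed))
    rep <- evaluate_three_way(transfer, direct, test_tr, split = split,
                              seeds = seed)
    reports[[as.character(seed)]] <- rep
    for (ap in c("transfer", "direct", "simulation")) {
      rows[[length(rows) + 1L]] <- data.frame(
        seed = seed, approach = ap, rmse = rep[[ap]]$rmse,
        mae = rep[[ap]]$mae, prediction_sd = rep[[ap]]$prediction_sd)
    }
  }
  list(results = do.call(rbind, rows), reports = reports)
}

## train_config copy with replaced fields
modifyList_cfg <- function(cfg, ...) {
  upd <- list(...)
  for (nm in names(upd)) cfg[[nm]] <- upd[[nm]]
  cfg
}

#' Median benchmark summary across seeds
#'
#' @param results The `results` data frame of [run_transfer_benchmark()].
#' @return A data frame with the median (over seeds) RMSE, MAE and
#'   prediction SD per approach.
#' @export
summarize_benchmark <- function(results) {
  do.call(rbind, lapply(split(results, results$approach), function(d) {
    data.frame(approach = d$approach[1],
               rmse = median(d$rmse), mae = median(d$mae),
               prediction_sd = median(d$prediction_sd))
  }))
}
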