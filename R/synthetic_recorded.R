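#' Synthetic recording-session configuration
#'
#' Parameters of the synthetic stand-in for the human experiment: a
#' sustained elbow-flexion task at 80% of the subject's peak MVC torque,
#' terminated when torque stays below 70% MVC for 3 of the trailing 5
#' seconds, with raw EMG at 3000 Hz and torque at 100 Hz.
#'
#' @param target_fraction Task target as a fraction of MVC (0.80).
#' @param stop_fraction Termination threshold fraction of MVC (0.70).
#' @param stop_window Trailing window, seconds (5).
#' @param stop_count Below-threshold time inside the window that terminates
#'   the task, seconds (3).
#' @param emg_rate,torque_rate Sampling rates, hertz.
#' @param envelope_jitter_sd SD of the slow multiplicative jitter on the EMG
#'   amplitude envelope (0 disables).
#' @param torque_sd_base Baseline torque noise SD, newton-meters.
#' @param torque_sd_end_multiplier Factor by which the torque noise SD grows
#'   as the subject approaches task failure (end-of-task variability).
#' @param emg_drift Fractional upward drift of EMG amplitude over the task
#'   (fatigue-related amplitude growth; this is the generator's
#'   simulation-to-reality gap). 0 disables.
#' @param carrier_band EMG carrier bandpass, hertz.
#' @param emg_gain Envelope-to-signal gain, arbitrary units.
#' @param baseline_noise_sd Additive broadband EMG noise SD.
#' @param dc_offset Constant offset added to each raw EMG channel.
#' @param mvc_noise_sd Multiplicative noise SD on MVC plateaus.
#' @param fatigue_jitter_sd SD of the per-subject log-normal jitter on the
#'   fatigue rate (population variability in time to task failure).
#' @param ramp_up_s Ramp from rest to the target at task start, seconds.
#' @param max_duration Simulated task cap, seconds.
#' @return An object of class `session_config`.
#' @export
session_config <- function(target_fraction = 0.80, stop_fraction = 0.70,
                           stop_window = 5, stop_count = 3,
                           emg_rate = 3000, torque_rate = 100,
                           envelope_jitter_sd = 0.03,
                           torque_sd_base = 0.8,
                           torque_sd_end_multiplier = 3,
                           emg_drift = 0.10,
                           carrier_band = c(20, 450),
                           emg_gain = 0.5,
                           baseline_noise_sd = 0.01,
                           dc_offset = 0.02,
                           mvc_noise_sd = 0.02,
                           fatigue_jitter_sd = 0.3,
                           ramp_up_s = 2, max_duration = 120) {
  if (!(stop_fraction > 0 && stop_fraction < target_fraction &&
        target_fraction <= 1)) {
    stop("need 0 < stop_fraction < target_fraction <= 1", call. = FALSE)
  }
  structure(list(target_fraction = target_fraction,
                 stop_fraction = stop_fraction, stop_window = stop_window,
                 stop_count = stop_count, emg_rate = emg_rate,
                 torque_rate = torque_rate,
                 envelope_jitter_sd = envelope_jitter_sd,
                 torque_sd_base = torque_sd_base,
                 torque_sd_end_multiplier = torque_sd_end_multiplier,
                 emg_drift = emg_drift, carrier_band = carrier_band,
                 emg_gain = emg_gain, baseline_noise_sd = baseline_noise_sd,
                 dc_offset = dc_offset, mvc_noise_sd = mvc_noise_sd,
                 fatigue_jitter_sd = fatigue_jitter_sd,
                 ramp_up_s = ramp_up_s, max_duration = max_duration),
            class = "session_config")
}

#' Task-termination rule
#'
#' Returns the first sample index at which, within the trailing
#' `cfg$stop_window` seconds, the torque has spent at least
#' `cfg$stop_count` cumulative seconds below `cfg$stop_fraction * mvc`.
#' Returns the final index when the rule never triggers.
#'
#' @param torque A [torque_trace()] on a uniform grid.
#' @param mvc MVC torque, newton-meters.
#' @param cfg A [session_config()].
#' @return Integer truncation index.
#' @export
#' @examples
#' tt <- torque_trace(seq(0, 10, 0.01), rep(30, 1001))
#' apply_termination_rule(tt, mvc = 50, session_config())  # triggers at 3 s
apply_termination_rule <- function(torque, mvc, cfg = session_config()) {
  stopifnot(inherits(torque, "torque_trace"))
  dt <- torque$times[2] - torque$times[1]
  below <- as.integer(torque$values < cfg$stop_fraction * mvc)
  w <- max(1L, round(cfg$stop_window / dt))
  need <- ceiling(cfg$stop_count / dt)
  cs <- cumsum(below)
  n <- length(below)
  # count of below-threshold samples in the trailing window (i - w, i]
  lag <- c(rep(0L, min(w, n)), cs[seq_len(max(0L, n - w))])
  cnt <- cs - lag
  hit <- which(cnt >= need)
  if (length(hit)) hit[1] else n
}

## per-subject model whose flexor strength matches the measured MVC torque:
## muscle forces are calibrated so the model's strength ceiling equals the
## subject's recorded maximum, the standard way measured strength enters a
## subject-specific model
calibrate_to_mvc <- function(model) {
  k <- model$statics$mvc_torque / strength_ceiling(model)
  model$actuators$fmax <- model$actuators$fmax * k
  model
}

## band-limited unit-RMS Gaussian carrier
emg_carrier <- function(n, rate, band) {
  bf <- signal::butter(2, band / (rate / 2), type = "pass")
  x <- as.numeric(signal::filter(bf, rnorm(n)))
  x / sd(x)
}

## slow multiplicative jitter: unit-mean, lognormal-ish, piecewise linear
## between 2 Hz knots
slow_jitter <- function(n, rate, sd) {
  if (sd <= 0) return(rep(1, n))
  knots <- max(2L, ceiling(n / rate * 2) + 1L)
  j <- exp(rnorm(knots, 0, sd) - sd^2 / 2)
  approx(seq(0, 1, length.out = knots), j, xout = seq(0, 1, length.out = n))$y
}

#' Generate one synthetic recording session
#'
#' Emulates a subject's visit: three 5 s MVC trials (noisy plateaus at the
#' subject's MVC torque, 10 s rest between them is implicit), then a
#' sustained elbow flexion at 80% of the peak MVC plateau. The subject's
#' muscle forces are calibrated so the model's strength ceiling equals the
#' measured MVC; target loads per muscle come from the static-optimization
#' inverse solve, ramp up over `cfg$ramp_up_s`, and are processed through
#' the three-compartment fatigue model (with per-subject log-normal jitter
#' on the fatigue rate). The achieved torque is the forward map of the
#' fatigued activations plus heteroscedastic noise whose SD grows from
#' `torque_sd_base` toward `torque_sd_base * torque_sd_end_multiplier` as
#' the torque decays toward the termination threshold. Raw EMG per muscle is
#' a band-limited Gaussian carrier amplitude-modulated by the fatigued
#' activation envelope (with optional upward amplitude drift -- the
#' generator's reality gap), plus baseline noise and a DC offset. The task
#' is truncated by [apply_termination_rule()].
#'
#' @param statics A [subject_statics()].
#' @param fatigue A [fatigue_params()].
#' @param cfg A [session_config()].
#' @param seed Integer seed; sessions are bitwise reproducible.
#' @param ref Reference anthropometry for model scaling.
#' @return An object of class `flex_session`: list with `statics`, `raw`
#'   (a [raw_emg()], 4 channels, truncated at task failure), `torque`
#'   (a [torque_trace()] at 100 Hz), `mvc_trials` (3 [torque_trace()]s),
#'   `mvc_est` (peak MVC used for the task), `time_to_failure` (s), `truth`
#'   (noise-free fatigued 4-group activations and clean torque on the
#'   torque grid) and the scaled `model`.
#' @export
generate_session <- function(statics, fatigue = fatigue_params(),
                             cfg = session_config(), seed = 0L,
                             ref = anthro_reference()) {
  stopifnot(inherits(statics, "subject_statics"),
            inherits(fatigue, "fatigue_params"),
            inherits(cfg, "session_config"))
  if (statics$mvc_torque <= 0) stop("MVC torque must be positive", call. = FALSE)
  old <- .Random.seed_guard(seed)
  on.exit(old())

  model <- scale_model(generic_actuators(), statics, ref = ref)
  calib <- calibrate_to_mvc(model)

  # --- MVC trials: 5 s plateaus with 0.5 s ramps and multiplicative noise
  mvc <- statics$mvc_torque
  tm <- seq(0, 5, by = 1 / cfg$torque_rate)
  shape <- pmin(1, pmin(tm, 5 - tm) / 0.5)
  mvc_trials <- lapply(1:3, function(i) {
    torque_trace(tm, mvc * shape * (1 + rnorm(length(tm), 0, cfg$mvc_noise_sd)))
  })
  mvc_est <- max(vapply(mvc_trials, function(tr) max(tr$values), 0))

  # --- per-subject fatigue-rate jitter (population time-to-failure spread)
  fat <- fatigue
  fat$F <- fat$F * exp(rnorm(1, 0, cfg$fatigue_jitter_sd))

  # --- sustained task: target loads from the inverse solve at 80% MVC
  target_T <- cfg$target_fraction * mvc_est
  dt <- 0.01
  grid <- seq(0, cfg$max_duration, by = dt)
  sol <- solve_activations(
    calib, torque_trace(range(grid), rep(target_T, 2)))
  a0 <- sol$activations$values[1, ]
  ramp <- pmin(grid / cfg$ramp_up_s, 1)
  exc <- activation_trace(grid, outer(ramp, a0),
                          colnames(sol$activations$values))
  fatigued <- apply_fatigue(exc, fat, dt = dt)
  clean <- forward_torque(calib, fatigued)

  # --- achieved torque at 100 Hz with end-of-task variability growth
  tq_times <- seq(0, cfg$max_duration, by = 1 / cfg$torque_rate)
  clean100 <- approx(clean$times, clean$values, xout = tq_times)$y
  stop_T <- cfg$stop_fraction * mvc_est
  prox <- pmin(pmax((target_T - clean100) / max(target_T - stop_T, 1e-9), 0), 1)
  sd_t <- cfg$torque_sd_base * (1 + (cfg$torque_sd_end_multiplier - 1) * prox)
  noisy <- clean100 + rnorm(length(clean100), 0, sd_t)
  idx <- apply_termination_rule(torque_trace(tq_times, noisy), mvc_est, cfg)
  t_end <- tq_times[idx]
  torque <- torque_trace(tq_times[1:idx], noisy[1:idx])

  # --- raw EMG at 3000 Hz over the truncated task
  act4 <- aggregate_groups(fatigued, calib$actuators)
  n_emg <- floor(t_end * cfg$emg_rate) + 1L
  emg_times <- seq(0, by = 1 / cfg$emg_rate, length.out = n_emg)
  drift <- 1 + cfg$emg_drift * emg_times / max(t_end, 1e-9)
  signals <- sapply(colnames(act4$values), function(ch) {
    env <- approx(act4$times, act4$values[, ch], xout = emg_times, rule = 2)$y
    env <- env * drift * slow_jitter(n_emg, cfg$emg_rate, cfg$envelope_jitter_sd)
    cfg$emg_gain * env * emg_carrier(n_emg, cfg$emg_rate, cfg$carrier_band) +
      rnorm(n_emg, 0, cfg$baseline_noise_sd) + cfg$dc_offset
  })
  truth_idx <- act4$times <= t_end + 1e-9
  structure(list(
    statics = statics, model = model,
    raw = raw_emg(signals, cfg$emg_rate),
    torque = torque, mvc_trials = mvc_trials, mvc_est = mvc_est,
    time_to_failure = t_end,
    truth = list(
      activations = activation_trace(act4$times[truth_idx],
                                     act4$values[truth_idx, , drop = FALSE],
                                     colnames(act4$values)),
      clean_torque = torque_trace(tq_times[1:idx], clean100[1:idx])),
    cfg = cfg, seed = seed), class = "flex_session")
}

#' @export
print.flex_session <- function(x, ...) {
  cat(sprintf("<flex_session> MVC %.1f Nm, time to failure %.1f s\n",
              x$mvc_est, x$time_to_failure))
  invisible(x)
}

#' Generate a cohort of synthetic sessions
#'
#' Samples a recorded-style cohort and generates one session per subject
#' with independent sub-seeds derived from `seed`.
#'
#' @param n Number of subjects (default 25).
#' @param seed Integer seed.
#' @param fatigue A [fatigue_params()].
#' @param cfg A [session_config()].
#' @param ref An [anthro_reference()].
#' @return A named list of [generate_session()] results, names `REC001`...
#' @export
synthesize_recorded_cohort <- function(n = 25L, seed = 0L,
                                       fatigue = fatigue_params(),
                                       cfg = session_config(),
                                       ref = anthro_reference()) {
  cohort <- sample_recorded_style_cohort(n, seed, ref)
  old <- .Random.seed_guard(seed + 1L)
  sub_seeds <- sample.int(.Machine$integer.max, n)
  old()
  sessions <- lapply(seq_len(n), function(i) {
    generate_session(cohort[[i]], fatigue, cfg, seed = sub_seeds[i], ref = ref)
  })
  names(sessions) <- sprintf("REC%03d", seq_len(n))
  sessions
}

#' Process a session into a trial
#'
#' Runs the EMG pipeline on a session's raw signals (normalizing by the
#' session's own envelope peaks, the subject's cross-trial maxima) and
#' resamples the recorded torque to the trial grid.
#'
#' @param session A [generate_session()] result.
#' @param subject_id Identifier stored on the trial.
#' @param settings An [envelope_settings()].
#' @return A [flex_trial()] with provenance `"synthetic_recorded"`.
#' @export
process_session <- function(session, subject_id = "REC000",
                            settings = envelope_settings()) {
  stopifnot(inherits(session, "flex_session"))
  env <- emg_envelope(session$raw, settings)
  peaks <- apply(env$values, 2, max)
  peaks[peaks <= 0] <- 1  # silent channel: leave it at zero activation
  act <- process_emg(session$raw, settings, subject_peak = peaks)
  tq <- resample_to_grid(session$torque, settings$output_steps)
  flex_trial(subject_id, act$values, tq$values, statics = session$statics,
             provenance = "synthetic_recorded", converged = TRUE,
             n_steps = settings$output_steps)
}

#' @rdname process_session
#' @param sessions Named list of sessions.
#' @export
trials_from_sessions <- function(sessions, settings = envelope_settings()) {
  ids <- names(sessions)
  if (is.null(ids)) ids <- sprintf("REC%03d", seq_along(sessions))
  out <- lapply(seq_along(sessions), function(i) {
    process_session(sessions[[i]], ids[i], settings)
  })
  names(out) <- ids
  out
}

#' Write a session directory
#'
#' One directory per subject: `mvc_1.csv` ... `mvc_3.csv` (100 Hz torque),
#' `task_emg.csv` (3000 Hz raw EMG), `task_torque.csv` (100 Hz torque) and
#' `statics.json`.
#'
#' @param session A [generate_session()] result.
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
write_session <- function(session, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  for (i in 1:3) {
    tr <- session$mvc_trials[[i]]
    write.csv(data.frame(t_s = tr$times, torque_Nm = tr$values),
              file.path(dir, sprintf("mvc_%d.csv", i)), row.names = FALSE)
  }
  write_raw_emg_csv(session$raw, file.path(dir, "task_emg.csv"))
  write.csv(data.frame(t_s = session$torque$times,
                       torque_Nm = session$torque$values),
            file.path(dir, "task_torque.csv"), row.names = FALSE)
  jsonlite::write_json(
    c(unclass(session$statics),
      list(mvc_est = session$mvc_est,
           time_to_failure = session$time_to_failure, seed = session$seed)),
    file.path(dir, "statics.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
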