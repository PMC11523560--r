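#' Trial container
#'
#' A time-normalized trial: 300-step, 4-channel muscle activations (columns
#' ordered BRA, TRI, BIC, BRD), a 300-step elbow-flexion torque sequence,
#' the subject statics (absent for simulated trials) and provenance.
#'
#' @param subject_id Subject identifier.
#' @param activations 300 x 4 numeric matrix, values in \[0, 1\].
#' @param torque Numeric vector of length 300, newton-meters.
#' @param statics A [subject_statics()] or `NULL` (simulated trials).
#' @param provenance One of `"simulated"`, `"recorded"`,
#'   `"synthetic_recorded"`.
#' @param converged Convergence flag of the inverse solve.
#' @param n_steps Required sequence length (default 300).
#' @return An object of class `flex_trial`.
#' @export
flex_trial <- function(subject_id, activations, torque, statics = NULL,
                       provenance = c("simulated", "recorded",
                                      "synthetic_recorded"),
                       converged = TRUE, n_steps = 300L) {
  provenance <- match.arg(provenance)
  activations <- as.matrix(activations)
  rownames(activations) <- NULL
  if (nrow(activations) != n_steps || length(torque) != n_steps) {
    stop(sprintf("activations and torque must have exactly %d steps", n_steps),
         call. = FALSE)
  }
  if (ncol(activations) != 4L) {
    stop("activations must have 4 channels (BRA, TRI, BIC, BRD)", call. = FALSE)
  }
  if (any(activations < -1e-9 | activations > 1 + 1e-9)) {
    stop("activations must lie in [0, 1]", call. = FALSE)
  }
  colnames(activations) <- c("bra", "tri", "bic", "brd")
  if (!is.null(statics)) stopifnot(inherits(statics, "subject_statics"))
  structure(list(subject_id = subject_id,
                 activations = pmin(pmax(activations, 0), 1),
                 torque = as.numeric(torque),
                 statics = statics, provenance = provenance,
                 converged = isTRUE(converged)),
            class = "flex_trial")
}

#' @export
print.flex_trial <- function(x, ...) {
  cat(sprintf("<flex_trial> %s [%s] %d steps, torque %.1f-%.1f Nm\n",
              x$subject_id, x$provenance, length(x$torque),
              min(x$torque), max(x$torque)))
  invisible(x)
}

#' Enumerate simulation configurations
#'
#' Cartesian product of subjects and peak torques, subject-major, each with
#' the default ramp-and-hold profile. The default grid (300 subjects, peaks
#' 30 to 90 Nm in 10 Nm steps) yields 2,100 configurations.
#'
#' @param cohort List of [subject_statics()] (optionally named).
#' @param peaks Peak torque grid, newton-meters (default `seq(30, 90, 10)`).
#' @param ... Passed to [torque_target()] (ramp/plateau settings).
#' @return A list of configurations, each a list with `subject_id`,
#'   `statics` and `target`.
#' @export
#' @examples
#' length(enumerate_configurations(sample_simulated_cohort(3, 1)))  # 21
enumerate_configurations <- function(cohort, peaks = seq(30, 90, by = 10), ...) {
  if (length(cohort) == 0L) stop("empty cohort", call. = FALSE)
  if (length(peaks) == 0L) stop("empty peak grid", call. = FALSE)
  ids <- if (is.null(names(cohort))) sprintf("S%03d", seq_along(cohort))
         else names(cohort)
  out <- vector("list", length(cohort) * length(peaks))
  k <- 1L
  for (i in seq_along(cohort)) {
    for (p in peaks) {
      out[[k]] <- list(subject_id = ids[i], statics = cohort[[i]],
                       target = torque_target(p, ...))
      k <- k + 1L
    }
  }
  out
}

#' Resample a trace onto an equally spaced grid
#'
#' Linear interpolation onto `n_points` equally spaced samples spanning the
#' full duration of the trace, endpoints inclusive. A 30 s trace resampled
#' to the default 10 Hz output grid yields 300 samples.
#'
#' @param trace An [activation_trace()] or [torque_trace()].
#' @param n_points Number of output samples (>= 2; default 300).
#' @return A trace of the same class on the new grid.
#' @export
resample_to_grid <- function(trace, n_points = 300L) {
  if (n_points < 2) stop("`n_points` must be at least 2", call. = FALSE)
  times <- trace$times
  if (length(times) < 2) stop("trace must have at least 2 samples", call. = FALSE)
  grid <- seq(times[1], times[length(times)], length.out = n_points)
  if (inherits(trace, "torque_trace")) {
    return(torque_trace(grid, approx(times, trace$values, xout = grid)$y))
  }
  vals <- apply(trace$values, 2, function(v) approx(times, v, xout = grid)$y)
  activation_trace(grid, matrix(vals, nrow = n_points),
                   colnames(trace$values))
}

#' Aggregate the 7 actuator channels into 4 muscle groups
#'
#' Per group, the fmax-weighted mean of the member actuators' activations
#' (or the simple mean with `weighted = FALSE`); single-member groups pass
#' through. Output channel order is BRA, TRI, BIC, BRD.
#'
#' @param act7 An [activation_trace()] with the 7 actuator channels, named.
#' @param actuators Actuator table supplying group labels and weights.
#' @param weighted Use fmax weights (default) or a simple mean.
#' @return An [activation_trace()] with 4 channels.
#' @export
aggregate_groups <- function(act7, actuators = generic_actuators(),
                             weighted = TRUE) {
  stopifnot(inherits(act7, "activation_trace"))
  if (ncol(act7$values) != 7L || is.null(colnames(act7$values))) {
    stop("expected 7 named actuator channels", call. = FALSE)
  }
  if (!setequal(colnames(act7$values), actuators$name)) {
    stop("unknown actuator labels", call. = FALSE)
  }
  groups <- c("BRA", "TRI", "BIC", "BRD")
  out <- sapply(groups, function(g) {
    members <- actuators$name[actuators$group == g]
    w <- if (weighted) actuators$fmax[actuators$group == g]
         else rep(1, length(members))
    drop(act7$values[, members, drop = FALSE] %*% (w / sum(w)))
  })
  activation_trace(act7$times, out, tolower(groups))
}

#' Run the simulation pipeline
#'
#' End-to-end assembly of the simulated dataset: for each configuration,
#' build the 30 s ramp-and-hold target, solve the pre-fatigue activations by
#' static optimization, drop configurations whose peak exceeds the subject's
#' strength ceiling (the convergence surrogate), process the pre-fatigue
#' excitations through the three-compartment fatigue model, evaluate the
#' fatigued torque with the forward map, resample activations and torque to
#' `n_steps` samples and aggregate the 7 actuators into 4 muscle groups.
#'
#' The pipeline is deterministic given the configurations; `seed` is
#' reserved for configurable stochastic extensions and recorded in
#' manifests.
#'
#' @param configs Output of [enumerate_configurations()].
#' @param fatigue A [fatigue_params()].
#' @param seed Integer seed recorded with the dataset.
#' @param dt Solver/integrator step, seconds (default 0.01).
#' @param n_steps Output sequence length (default 300).
#' @param coactivation_floor Extensor co-activation floor for the inverse
#'   solve (default 0).
#' @param ref Reference anthropometry used for scaling.
#' @return A list of converged [flex_trial()] objects (statics omitted, as
#'   simulated trials carry no static features).
#' @export
run_simulation_pipeline <- function(configs, fatigue = fatigue_params(),
                                    seed = 0L, dt = 0.01, n_steps = 300L,
                                    coactivation_floor = 0,
                                    ref = anthro_reference()) {
  generic <- generic_actuators()
  trials <- vector("list", length(configs))
  n_out <- 0L
  for (cfg in configs) {
    model <- scale_model(generic, cfg$statics, ref = ref)
    target <- build_target_profile(cfg$target, dt)
    sol <- solve_activations(model, target,
                             coactivation_floor = coactivation_floor)
    if (!sol$converged) next
    # the pool starts tracking the 10 Nm baseline hold, not from full rest
    fat <- apply_fatigue(sol$activations, fatigue, dt = dt,
                         start_at_target = TRUE)
    torq <- forward_torque(model, fat)
    act4 <- aggregate_groups(resample_to_grid(fat, n_steps), generic)
    torq300 <- resample_to_grid(torq, n_steps)
    n_out <- n_out + 1L
    trials[[n_out]] <- flex_trial(cfg$subject_id, act4$values, torq300$values,
                                  statics = NULL, provenance = "simulated",
                                  converged = TRUE, n_steps = n_steps)
  }
  trials[seq_len(n_out)]
}

#' Simulate a full pre-training dataset
#'
#' Convenience wrapper: sample a simulated cohort, enumerate the
#' subject-by-peak grid and run the simulation pipeline.
#'
#' @param n_models Number of musculoskeletal models (default 300).
#' @param peaks Peak torque grid (default 30--90 Nm in 10 Nm steps).
#' @param seed Integer seed.
#' @param ... Passed to [run_simulation_pipeline()].
#' @return A list with `trials` (converged [flex_trial()]s), `cohort`, and
#'   `n_configurations`.
#' @export
simulate_dataset <- function(n_models = 300L, peaks = seq(30, 90, by = 10),
                             seed = 0L, ...) {
  cohort <- sample_simulated_cohort(n_models, seed)
  names(cohort) <- sprintf("SIM%03d", seq_along(cohort))
  configs <- enumerate_configurations(cohort, peaks)
  trials <- run_simulation_pipeline(configs, seed = seed, ...)
  list(trials = trials, cohort = cohort, n_configurations = length(configs))
}

#' Write / read a trial set as CSV
#'
#' Long format with columns `trial_id, step, t_s, bra, tri, bic, brd,
#' torque_Nm`; a sidecar JSON manifest records counts, provenance,
#' convergence flags, subjects and the seed.
#'
#' @param trials List of [flex_trial()].
#' @param dir Output directory (created if missing).
#' @param seed Seed recorded in the manifest.
#' @param duration_s Trial duration represented by the 300 steps.
#' @return The directory, invisibly.
#' @export
write_trials <- function(trials, dir, seed = NA_integer_, duration_s = 30) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  n_steps <- length(trials[[1]]$torque)
  t_s <- seq(0, duration_s, length.out = n_steps)
  rows <- lapply(seq_along(trials), function(i) {
    tr <- trials[[i]]
    data.frame(trial_id = sprintf("T%05d", i), step = seq_len(n_steps),
               t_s = t_s, bra = tr$activations[, "bra"],
               tri = tr$activations[, "tri"], bic = tr$activations[, "bic"],
               brd = tr$activations[, "brd"], torque_Nm = tr$torque)
  })
  write.csv(do.call(rbind, rows), file.path(dir, "trials.csv"),
            row.names = FALSE)
  meta <- data.frame(
    trial_id = sprintf("T%05d", seq_along(trials)),
    subject_id = vapply(trials, `[[`, "", "subject_id"),
    provenance = vapply(trials, `[[`, "", "provenance"),
    converged = vapply(trials, `[[`, TRUE, "converged"))
  write.csv(meta, file.path(dir, "trial_meta.csv"), row.names = FALSE)
  statics <- Filter(Negate(is.null), lapply(trials, `[[`, "statics"))
  if (length(statics)) {
    names(statics) <- meta$subject_id[!vapply(trials, function(t)
      is.null(t$statics), TRUE)]
    write_cohort_csv(statics[!duplicated(names(statics))],
                     file.path(dir, "subjects.csv"))
  }
  manifest <- list(n_trials = length(trials), n_steps = n_steps,
                   duration_s = duration_s, seed = seed)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @rdname write_trials
#' @export
read_trials <- function(dir) {
  long <- read.csv(file.path(dir, "trials.csv"), stringsAsFactors = FALSE)
  meta <- read.csv(file.path(dir, "trial_meta.csv"), stringsAsFactors = FALSE)
  statics_path <- file.path(dir, "subjects.csv")
  statics <- if (file.exists(statics_path)) read_cohort_csv(statics_path)
             else list()
  lapply(seq_len(nrow(meta)), function(i) {
    sub <- long[long$trial_id == meta$trial_id[i], ]
    sub <- sub[order(sub$step), ]
    st <- statics[[meta$subject_id[i]]]
    flex_trial(meta$subject_id[i],
               as.matrix(sub[, c("bra", "tri", "bic", "brd")]),
               sub$torque_Nm, statics = st,
               provenance = meta$provenance[i],
               converged = meta$converged[i],
               n_steps = nrow(sub))
  })
}
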