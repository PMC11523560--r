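#' Run configuration
#'
#' A single serializable container for every tunable of a full run: the
#' global seed, cohort sizes, the peak-torque grid, fatigue parameters,
#' envelope settings, session-generator settings and the output directory.
#' All randomness in a workflow flows from `seed`.
#'
#' @param seed Global integer seed.
#' @param n_sim_models Simulated cohort size.
#' @param n_subjects Recorded-style cohort size.
#' @param n_leaveout Leave-out subjects.
#' @param peaks Peak-torque grid, newton-meters.
#' @param fatigue A [fatigue_params()].
#' @param envelope An [envelope_settings()].
#' @param session A [session_config()].
#' @param out_dir Output directory for workflow products.
#' @return An object of class `run_config`.
#' @export
run_config <- function(seed = 0L, n_sim_models = 300L, n_subjects = 25L,
                       n_leaveout = 5L, peaks = seq(30, 90, by = 10),
                       fatigue = fatigue_params(),
                       envelope = envelope_settings(),
                       session = session_config(), out_dir = "flexfatigue_out") {
  structure(list(seed = as.integer(seed),
                 n_sim_models = as.integer(n_sim_models),
                 n_subjects = as.integer(n_subjects),
                 n_leaveout = as.integer(n_leaveout), peaks = peaks,
                 fatigue = fatigue, envelope = envelope, session = session,
                 out_dir = out_dir),
            class = "run_config")
}

#' Read / write a run configuration as YAML
#'
#' @param cfg A [run_config()].
#' @param path YAML file path.
#' @return `write_run_config` returns `path` invisibly; `read_run_config`
#'   returns a [run_config()].
#' @export
write_run_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "run_config"))
  plain <- lapply(cfg, function(x) if (is.list(x)) unclass(x) else x)
  yaml::write_yaml(plain, path)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  run_config(seed = y$seed, n_sim_models = y$n_sim_models,
             n_subjects = y$n_subjects, n_leaveout = y$n_leaveout,
             peaks = unlist(y$peaks),
             fatigue = do.call(fatigue_params, y$fatigue),
             envelope = do.call(envelope_settings, y$envelope),
             session = do.call(session_config,
                               lapply(y$session, function(v)
                                 if (length(v) > 1) unlist(v) else v)),
             out_dir = y$out_dir)
}

#' Hash a configuration
#'
#' MD5 of the canonical JSON serialization; recorded in output manifests so
#' reruns with identical configuration are recognizable.
#'
#' @param cfg Any serializable object.
#' @return A 32-character hex string.
#' @export
config_hash <- function(cfg) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  plain <- rapply(list(cfg), unclass, how = "replace")
  jsonlite::write_json(plain, tmp, auto_unbox = TRUE, digits = 12,
                       force = TRUE)
  unname(tools::md5sum(tmp))
}
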