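# shared fixtures: the reference subject, a scaled reference model, and
# small trial builders used across test files

ref_subject <- function() {
  subject_statics("male", 1.7, 75.1, 46.9, 25.9, 9.5, 31.6)
}

ref_model <- function() {
  scale_model(generic_actuators(), ref_subject())
}

# a hand-built trial with known content (constant activations and torque)
constant_trial <- function(id = "S001", act = 0.4, torque = 20,
                           statics = ref_subject(),
                           provenance = "synthetic_recorded") {
  flex_trial(id, matrix(act, 300, 4), rep(torque, 300), statics = statics,
             provenance = provenance)
}

# a small cohort of quick synthetic-recorded trials with varied torques,
# cheap enough for training smoke tests (random shapes, valid ranges)
toy_recorded_trials <- function(n_subjects = 6, seed = 1) {
  set.seed(seed)
  cohort <- sample_recorded_style_cohort(n_subjects, seed)
  lapply(seq_len(n_subjects), function(i) {
    tgrid <- seq(0, 1, length.out = 300)
    act <- sapply(1:4, function(k) {
      pmin(pmax(0.5 + 0.3 * sin(2 * pi * (k + i) * tgrid) +
                  rnorm(300, 0, 0.02), 0), 1)
    })
    torque <- 30 + 10 * act[, 1] + 5 * act[, 3] + rnorm(300, 0, 0.5)
    flex_trial(sprintf("S%03d", i), act, torque, statics = cohort[[i]],
               provenance = "synthetic_recorded")
  })
}
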