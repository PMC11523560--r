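#' Per-subject static features
#'
#' Bundle of the seven static subject features used throughout the package:
#' sex, height, mass, maximum voluntary elbow-flexion torque (MVC), forearm
#' length, elbow width and upper-arm length.
#'
#' @param sex `"female"` or `"male"`.
#' @param height Standing height in meters.
#' @param mass Body mass in kilograms.
#' @param mvc_torque Maximum voluntary elbow-flexion torque in newton-meters.
#' @param forearm_length Forearm length in centimeters.
#' @param elbow_width Elbow width in centimeters.
#' @param upper_arm_length Upper-arm length in centimeters.
#'
#' @return An object of class `subject_statics` (a named list).
#' @export
#' @examples
#' subject_statics("female", 1.65, 62, 40, 24.5, 9.0, 30.2)
subject_statics <- function(sex, height, mass, mvc_torque,
                            forearm_length, elbow_width, upper_arm_length) {
  sex <- match.arg(sex, c("female", "male"))
  num <- c(height = height, mass = mass, mvc_torque = mvc_torque,
           forearm_length = forearm_length, elbow_width = elbow_width,
           upper_arm_length = upper_arm_length)
  if (any(!is.finite(num)) || any(num <= 0)) {
    stop("all static measurements must be finite and strictly positive",
         call. = FALSE)
  }
  structure(list(sex = sex, height = height, mass = mass,
                 mvc_torque = mvc_torque, forearm_length = forearm_length,
                 elbow_width = elbow_width, upper_arm_length = upper_arm_length),
            class = "subject_statics")
}

#' @export
print.subject_statics <- function(x, ...) {
  cat(sprintf(
    "<subject_statics> %s, %.2f m, %.1f kg, MVC %.1f Nm\n",
    x$sex, x$height, x$mass, x$mvc_torque))
  invisible(x)
}

#' Reference anthropometric distributions
#'
#' Means and standard deviations of the reference population from which
#' cohorts are sampled. Defaults are the recorded cohort of healthy young
#' adults: height 1.7 (0.07) m, mass 75.1 (12.2) kg, MVC torque 46.9 (14.0)
#' Nm, forearm length 25.9 (1.7) cm, elbow width 9.5 (0.9) cm, upper-arm
#' length 31.6 (2.5) cm, and 9:16 female:male.
#'
#' @param height_mean,height_sd Height moments, meters.
#' @param mass_mean,mass_sd Mass moments, kilograms.
#' @param mvc_mean,mvc_sd MVC torque moments, newton-meters.
#' @param forearm_mean,forearm_sd Forearm length moments, centimeters.
#' @param elbow_width_mean,elbow_width_sd Elbow width moments, centimeters.
#' @param upper_arm_mean,upper_arm_sd Upper-arm length moments, centimeters.
#' @param p_female Probability that a sampled subject is female.
#'
#' @return A named list of class `anthro_reference`.
#' @export
anthro_reference <- function(height_mean = 1.7, height_sd = 0.07,
                             mass_mean = 75.1, mass_sd = 12.2,
                             mvc_mean = 46.9, mvc_sd = 14.0,
                             forearm_mean = 25.9, forearm_sd = 1.7,
                             elbow_width_mean = 9.5, elbow_width_sd = 0.9,
                             upper_arm_mean = 31.6, upper_arm_sd = 2.5,
                             p_female = 9 / 25) {
  structure(list(
    height_mean = height_mean, height_sd = height_sd,
    mass_mean = mass_mean, mass_sd = mass_sd,
    mvc_mean = mvc_mean, mvc_sd = mvc_sd,
    forearm_mean = forearm_mean, forearm_sd = forearm_sd,
    elbow_width_mean = elbow_width_mean, elbow_width_sd = elbow_width_sd,
    upper_arm_mean = upper_arm_mean, upper_arm_sd = upper_arm_sd,
    p_female = p_female), class = "anthro_reference")
}

## inverse-CDF sampler for a normal truncated to [p_lo, p_hi] percentiles;
## exact and reproducible (no rejection loop). sd = 0 degenerates to the mean.
rnorm_trunc <- function(n, mean, sd, p_lo, p_hi) {
  if (sd == 0) return(rep(mean, n))
  qnorm(runif(n, p_lo, p_hi), mean, sd)
}

#' Sample a simulated cohort
#'
#' Draws `n` synthetic young-adult subjects for the simulated dataset.
#' Heights and masses are drawn independently from the reference normal
#' distributions truncated to the 5th--95th percentile band; sex is drawn
#' with `ref$p_female` probability of female. The remaining statics are
#' derived from height and mass through fixed allometric ratios (the
#' reference ratios) with a small multiplicative jitter, and MVC torque
#' scales with body mass.
#'
#' @param n Number of subjects (>= 1).
#' @param seed Integer seed; cohorts are bitwise reproducible per seed.
#' @param ref An [anthro_reference()].
#' @param derived_cv Coefficient of variation of the jitter on derived
#'   statics (default 0.02).
#'
#' @return A list of [subject_statics()].
#' @export
#' @examples
#' cohort <- sample_simulated_cohort(5, seed = 1)
#' sapply(cohort, `[[`, "height")
sample_simulated_cohort <- function(n, seed, ref = anthro_reference(),
                                    derived_cv = 0.02) {
  if (!is.numeric(n) || length(n) != 1L || n < 1) {
    stop("`n` must be a positive count", call. = FALSE)
  }
  n <- as.integer(n)
  old <- .Random.seed_guard(seed)
  on.exit(old())
  height <- rnorm_trunc(n, ref$height_mean, ref$height_sd, 0.05, 0.95)
  mass <- rnorm_trunc(n, ref$mass_mean, ref$mass_sd, 0.05, 0.95)
  sex <- ifelse(runif(n) < ref$p_female, "female", "male")
  jit <- function() exp(rnorm(n, 0, derived_cv))
  mvc <- ref$mvc_mean * (mass / ref$mass_mean) * jit()
  forearm <- ref$forearm_mean * (height / ref$height_mean) * jit()
  elbow_w <- ref$elbow_width_mean * (height / ref$height_mean) * jit()
  upper_arm <- ref$upper_arm_mean * (height / ref$height_mean) * jit()
  lapply(seq_len(n), function(i) {
    subject_statics(sex[i], height[i], mass[i], mvc[i],
                    forearm[i], elbow_w[i], upper_arm[i])
  })
}

#' Sample a recorded-style cohort
#'
#' Draws `n` subjects mimicking the recorded cohort: every static feature is
#' drawn from its reference normal distribution truncated at +/- 3 SD, with a
#' 9:16 female:male ratio in expectation.
#'
#' @inheritParams sample_simulated_cohort
#' @return A list of [subject_statics()].
#' @export
sample_recorded_style_cohort <- function(n, seed, ref = anthro_reference()) {
  if (!is.numeric(n) || length(n) != 1L || n < 1) {
    stop("`n` must be a positive count", call. = FALSE)
  }
  n <- as.integer(n)
  old <- .Random.seed_guard(seed)
  on.exit(old())
  p3 <- pnorm(c(-3, 3))
  draw <- function(m, s) rnorm_trunc(n, m, s, p3[1], p3[2])
  height <- draw(ref$height_mean, ref$height_sd)
  mass <- draw(ref$mass_mean, ref$mass_sd)
  mvc <- draw(ref$mvc_mean, ref$mvc_sd)
  forearm <- draw(ref$forearm_mean, ref$forearm_sd)
  elbow_w <- draw(ref$elbow_width_mean, ref$elbow_width_sd)
  upper_arm <- draw(ref$upper_arm_mean, ref$upper_arm_sd)
  sex <- ifelse(runif(n) < ref$p_female, "female", "male")
  lapply(seq_len(n), function(i) {
    subject_statics(sex[i], height[i], mass[i], mvc[i],
                    forearm[i], elbow_w[i], upper_arm[i])
  })
}

## seed scoping: set the seed for the duration of a sampler and restore the
## caller's RNG state afterwards, so cohort generation never perturbs an
## enclosing simulation stream.
.Random.seed_guard <- function(seed) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  set.seed(seed)
  function() {
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  }
}

#' Generic elbow actuator set
#'
#' The seven muscle-tendon actuators of the generic elbow model: three
#' triceps heads (elbow extensors, negative moment arm), two biceps heads,
#' brachialis and brachioradialis (elbow flexors, positive moment arm).
#' Moment arms are taken at the task posture (90 degrees elbow flexion,
#' forearm supinated). The defaults give the reference subject a summed
#' flexor strength (sum of fmax * |moment arm|) of about 74 Nm, so ramp
#' targets between 30 and 90 Nm span feasible to infeasible.
#'
#' @return A data frame with columns `name`, `group`, `fmax` (N) and
#'   `moment_arm` (m, signed: flexors positive).
#' @export
#' @examples
#' g <- generic_actuators()
#' sum(g$fmax[g$moment_arm > 0] * g$moment_arm[g$moment_arm > 0])
generic_actuators <- function() {
  data.frame(
    name = c("TRI_long", "TRI_lat", "TRI_med",
             "BIC_long", "BIC_short", "BRA", "BRD"),
    group = c("TRI", "TRI", "TRI", "BIC", "BIC", "BRA", "BRD"),
    fmax = c(800, 620, 620, 620, 435, 990, 260),
    moment_arm = c(-0.021, -0.021, -0.021, 0.036, 0.036, 0.022, 0.054),
    stringsAsFactors = FALSE
  )
}

validate_actuators <- function(actuators) {
  need <- c("name", "group", "fmax", "moment_arm")
  if (!is.data.frame(actuators) || !all(need %in% names(actuators))) {
    stop("actuators must be a data frame with columns ",
         paste(need, collapse = ", "), call. = FALSE)
  }
  if (nrow(actuators) != 7L) {
    stop("the elbow model has exactly 7 actuators", call. = FALSE)
  }
  if (any(actuators$fmax <= 0)) stop("fmax must be positive", call. = FALSE)
  tri <- actuators$group == "TRI"
  if (any(actuators$moment_arm[tri] >= 0) || any(actuators$moment_arm[!tri] <= 0)) {
    stop("TRI moment arms must be negative and flexor moment arms positive",
         call. = FALSE)
  }
  invisible(actuators)
}

#' Scale the generic elbow model to a subject
#'
#' Applies the package's scaling law: moment arms scale with height and
#' maximum isometric forces scale with mass, relative to the reference
#' subject. Signs of moment arms are preserved, so flexors stay flexors.
#'
#' @param generic Actuator table, as from [generic_actuators()].
#' @param statics A [subject_statics()].
#' @param ref An [anthro_reference()] supplying the reference height/mass.
#'
#' @return An object of class `scaled_elbow_model`: list with `statics` and
#'   the scaled `actuators` table.
#' @export
#' @examples
#' s <- subject_statics("male", 1.8, 90, 55, 27, 10, 33)
#' m <- scale_model(generic_actuators(), s)
#' m$actuators$fmax / generic_actuators()$fmax  # mass ratio
scale_model <- function(generic, statics, ref = anthro_reference()) {
  validate_actuators(generic)
  stopifnot(inherits(statics, "subject_statics"))
  act <- generic
  act$moment_arm <- act$moment_arm * (statics$height / ref$height_mean)
  act$fmax <- act$fmax * (statics$mass / ref$mass_mean)
  structure(list(statics = statics, actuators = act),
            class = "scaled_elbow_model")
}

#' @export
print.scaled_elbow_model <- function(x, ...) {
  cat("<scaled_elbow_model>\n")
  print(x$actuators)
  invisible(x)
}

#' Maximum isometric flexion torque of a scaled model
#'
#' Sum of `fmax * moment_arm` over the flexor actuators: the strength
#' ceiling above which an inverse solve cannot converge.
#'
#' @param model A [scale_model()] result.
#' @return Torque in newton-meters.
#' @export
strength_ceiling <- function(model) {
  a <- model$actuators
  flex <- a$moment_arm > 0
  sum(a$fmax[flex] * a$moment_arm[flex])
}

#' Write / read a cohort as CSV
#'
#' One row per subject with columns `subject_id, sex, height_m, mass_kg,
#' mvc_Nm, forearm_cm, elbow_width_cm, upper_arm_cm`.
#'
#' @param cohort List of [subject_statics()].
#' @param path File path.
#' @return `write_cohort_csv` returns `path` invisibly; `read_cohort_csv`
#'   returns a list of [subject_statics()] with names from `subject_id`.
#' @export
write_cohort_csv <- function(cohort, path) {
  df <- data.frame(
    subject_id = if (is.null(names(cohort))) sprintf("S%03d", seq_along(cohort))
                 else names(cohort),
    sex = vapply(cohort, `[[`, "", "sex"),
    height_m = vapply(cohort, `[[`, 0, "height"),
    mass_kg = vapply(cohort, `[[`, 0, "mass"),
    mvc_Nm = vapply(cohort, `[[`, 0, "mvc_torque"),
    forearm_cm = vapply(cohort, `[[`, 0, "forearm_length"),
    elbow_width_cm = vapply(cohort, `[[`, 0, "elbow_width"),
    upper_arm_cm = vapply(cohort, `[[`, 0, "upper_arm_length"),
    stringsAsFactors = FALSE
  )
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_cohort_csv
#' @export
read_cohort_csv <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  cohort <- lapply(seq_len(nrow(df)), function(i) {
    subject_statics(df$sex[i], df$height_m[i], df$mass_kg[i], df$mvc_Nm[i],
                    df$forearm_cm[i], df$elbow_width_cm[i], df$upper_arm_cm[i])
  })
  names(cohort) <- df$subject_id
  cohort
}
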