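#' Time-series containers
#'
#' `activation_trace` holds per-channel muscle activations in \[0, 1\] on a
#' common time grid; `torque_trace` holds an elbow-flexion torque signal in
#' newton-meters.
#'
#' @param times Strictly increasing sample times, seconds.
#' @param values For `activation_trace`, a numeric matrix (rows = time steps,
#'   columns = channels) or a vector for a single channel; for
#'   `torque_trace`, a numeric vector.
#' @param channels Optional channel names.
#' @return An object of class `activation_trace` or `torque_trace`.
#' @export
activation_trace <- function(times, values, channels = NULL) {
  values <- as.matrix(values)
  if (length(times) != nrow(values)) {
    stop("`times` and `values` must have the same length", call. = FALSE)
  }
  if (any(diff(times) <= 0)) stop("`times` must be strictly increasing", call. = FALSE)
  if (any(values < -1e-9 | values > 1 + 1e-9)) {
    stop("activations must lie in [0, 1]", call. = FALSE)
  }
  values <- pmin(pmax(values, 0), 1)
  if (!is.null(channels)) colnames(values) <- channels
  structure(list(times = as.numeric(times), values = values),
            class = "activation_trace")
}

#' @rdname activation_trace
#' @export
torque_trace <- function(times, values) {
  if (length(times) != length(values)) {
    stop("`times` and `values` must have the same length", call. = FALSE)
  }
  if (any(diff(times) <= 0)) stop("`times` must be strictly increasing", call. = FALSE)
  structure(list(times = as.numeric(times), values = as.numeric(values)),
            class = "torque_trace")
}

#' @export
print.activation_trace <- function(x, ...) {
  cat(sprintf("<activation_trace> %d steps x %d channels, %.2f-%.2f s\n",
              nrow(x$values), ncol(x$values), min(x$times), max(x$times)))
  invisible(x)
}

#' @export
print.torque_trace <- function(x, ...) {
  cat(sprintf("<torque_trace> %d steps, %.2f-%.2f s, %.1f-%.1f Nm\n",
              length(x$values), min(x$times), max(x$times),
              min(x$values), max(x$values)))
  invisible(x)
}

#' Ramp-and-hold torque target
#'
#' The simulated task profile: a linear ramp from `ramp_start` to `peak`
#' over `ramp_duration`, a plateau at `peak` for `plateau_duration`, then the
#' final value held constant out to `extended_duration`. Defaults follow the
#' simulated protocol: 1.5 s ramp starting at 10 Nm, 1.5 s plateau, extended
#' to 30 s.
#'
#' @param peak Peak torque, newton-meters.
#' @param ramp_start Torque at t = 0, newton-meters.
#' @param ramp_duration,plateau_duration,extended_duration Seconds.
#' @return An object of class `torque_target`.
#' @export
torque_target <- function(peak, ramp_start = 10, ramp_duration = 1.5,
                          plateau_duration = 1.5, extended_duration = 30) {
  if (!(peak >= ramp_start && ramp_start > 0)) {
    stop("need peak >= ramp_start > 0", call. = FALSE)
  }
  if (any(c(ramp_duration, plateau_duration, extended_duration) <= 0)) {
    stop("durations must be positive", call. = FALSE)
  }
  structure(list(peak = peak, ramp_start = ramp_start,
                 ramp_duration = ramp_duration,
                 plateau_duration = plateau_duration,
                 extended_duration = extended_duration),
            class = "torque_target")
}

#' Discretize a torque target
#'
#' @param target A [torque_target()].
#' @param dt Time step, seconds (> 0).
#' @return A [torque_trace()] on the grid `seq(0, extended_duration, dt)`.
#' @export
#' @examples
#' tt <- build_target_profile(torque_target(60), dt = 0.1)
#' tt$values[tt$times == 0.75]  # midpoint of the ramp: 35 Nm
build_target_profile <- function(target, dt) {
  stopifnot(inherits(target, "torque_target"))
  if (dt <= 0) stop("`dt` must be positive", call. = FALSE)
  times <- seq(0, target$extended_duration, by = dt)
  ramp_end <- target$ramp_duration
  vals <- ifelse(
    times < ramp_end,
    target$ramp_start + (target$peak - target$ramp_start) * times / ramp_end,
    target$peak)
  torque_trace(times, vals)
}

## map a 4-group activation matrix onto the 7 actuators (group value
## broadcast to members), or validate a 7-channel matrix.
expand_channels <- function(values, actuators) {
  k <- ncol(values)
  if (k == 7L) {
    if (!is.null(colnames(values))) {
      if (!setequal(colnames(values), actuators$name)) {
        stop("7-channel activations must be named by actuator", call. = FALSE)
      }
      values <- values[, actuators$name, drop = FALSE]
    }
    return(values)
  }
  if (k == 4L) {
    groups <- if (!is.null(colnames(values))) toupper(colnames(values))
              else c("BRA", "TRI", "BIC", "BRD")
    if (!setequal(groups, c("BRA", "TRI", "BIC", "BRD"))) {
      stop("4-channel activations must be the groups BRA, TRI, BIC, BRD",
           call. = FALSE)
    }
    idx <- match(actuators$group, groups)
    return(values[, idx, drop = FALSE])
  }
  stop("activations must have 4 (group) or 7 (actuator) channels", call. = FALSE)
}

#' Forward torque from activations
#'
#' Isometric forward map at the fixed task posture (45 degrees shoulder
#' flexion, 90 degrees elbow flexion, forearm supinated): the elbow-flexion
#' torque is the activation-weighted sum of each actuator's maximum force
#' times its signed moment arm, `T(t) = sum_i fmax_i a_i(t) r_i`. No joint
#' dynamics are involved.
#'
#' @param model A [scale_model()] result.
#' @param act An [activation_trace()] with 7 actuator channels or 4 group
#'   channels (group values broadcast to member actuators).
#' @return A [torque_trace()] on `act$times`.
#' @export
forward_torque <- function(model, act) {
  stopifnot(inherits(model, "scaled_elbow_model"),
            inherits(act, "activation_trace"))
  a <- expand_channels(act$values, model$actuators)
  coef <- model$actuators$fmax * model$actuators$moment_arm
  torque_trace(act$times, drop(a %*% coef))
}

## least-norm activation for one time step: minimize sum(a^2) subject to
## sum(c_i a_i) = Tnet, 0 <= a_i <= 1, over flexors only (c_i > 0).
## Interior solution a_i = T c_i / sum(c^2); channels saturating at 1 are
## clamped (largest c first, ties by actuator-name order pre-sorted by the
## caller) and the residual torque re-solved on the remainder.
solve_step <- function(Tnet, cvec) {
  a <- rep(0, length(cvec))
  if (Tnet <= 0) return(a)
  free <- seq_along(cvec)
  repeat {
    lam <- Tnet / sum(cvec[free]^2)
    trial <- lam * cvec[free]
    if (all(trial <= 1)) {
      a[free] <- trial
      return(a)
    }
    # clamp the channel with the largest c (first to hit the bound)
    worst <- free[which.max(cvec[free])]
    a[worst] <- 1
    Tnet <- Tnet - cvec[worst]
    free <- setdiff(free, worst)
    if (length(free) == 0L) {
      return(a)
    }
  }
}

#' Inverse solve: activations tracking a torque target
#'
#' Static-optimization stand-in for computed muscle control: at each time
#' step the flexor activations minimize the summed squared activation
#' subject to reproducing the target torque, with activations bounded to
#' \[0, 1\] and the extensor (triceps) channels fixed at a co-activation
#' floor. The solve is flagged non-converged when the target exceeds the
#' model's strength ceiling at any step.
#'
#' @param model A [scale_model()] result.
#' @param target A [torque_trace()] with non-negative values.
#' @param coactivation_floor Constant activation of the extensor actuators
#'   (default 0); their (negative) torque is compensated by the flexors.
#' @return A list with `activations` (an [activation_trace()], 7 actuator
#'   channels in `model$actuators$name` order) and `converged` (logical).
#' @export
#' @examples
#' m <- scale_model(generic_actuators(),
#'                  subject_statics("male", 1.7, 75.1, 46.9, 25.9, 9.5, 31.6))
#' sol <- solve_activations(m, build_target_profile(torque_target(40), 0.1))
#' sol$converged
solve_activations <- function(model, target, coactivation_floor = 0) {
  stopifnot(inherits(model, "scaled_elbow_model"),
            inherits(target, "torque_trace"))
  if (any(target$values < 0)) {
    stop("target torque must be non-negative", call. = FALSE)
  }
  act <- model$actuators
  coefs <- act$fmax * act$moment_arm
  flex <- which(coefs > 0)
  ext <- which(coefs < 0)
  # extensors held at the floor; flexors must supply the compensation
  ext_torque <- sum(coefs[ext]) * coactivation_floor
  Tnet <- target$values - ext_torque
  ceiling_T <- sum(coefs[flex])
  converged <- all(Tnet <= ceiling_T + 1e-9)

  # sort flexors by descending c with name order breaking ties, so the
  # clamp order inside solve_step is deterministic
  flex_sorted <- flex[order(-coefs[flex], act$name[flex])]
  cvec <- coefs[flex_sorted]
  amat <- matrix(0, length(target$values), 7L,
                 dimnames = list(NULL, act$name))
  amat[, ext] <- coactivation_floor
  # ramp-and-hold targets repeat values; solve each distinct level once
  uT <- unique(Tnet)
  usol <- vapply(uT, solve_step, numeric(length(cvec)), cvec = cvec)
  usol <- if (is.matrix(usol)) t(usol) else matrix(usol, ncol = length(cvec))
  amat[, flex_sorted] <- pmin(usol[match(Tnet, uT), , drop = FALSE], 1)
  list(activations = activation_trace(target$times, amat, act$name),
       converged = converged)
}
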