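#' Three-compartment fatigue parameters
#'
#' Rates of the three-compartment motor-unit model in which a muscle's motor
#' units are partitioned into rested (MR), active (MA) and fatigued (MF)
#' fractions. `F` moves active units to fatigued, `R` recovers fatigued
#' units, and `LD`/`LR` are the (fast) activation and deactivation drive
#' rates that move units between rested and active to track the target load.
#' Defaults: F = 0.00912 and R = 0.00094 per second (the elbow
#' parameterization), LD = LR = 10 per second.
#'
#' @param F Fatigue rate, 1/s.
#' @param R Recovery rate, 1/s.
#' @param LD Activation drive rate, 1/s.
#' @param LR Deactivation drive rate, 1/s.
#' @return An object of class `fatigue_params`.
#' @export
fatigue_params <- function(F = 0.00912, R = 0.00094, LD = 10, LR = 10) {
  vals <- c(F = F, R = R, LD = LD, LR = LR)
  if (any(!is.finite(vals)) || any(vals <= 0)) {
    stop("all fatigue rates must be finite and strictly positive", call. = FALSE)
  }
  structure(as.list(vals), class = "fatigue_params")
}

#' Motor-unit state
#'
#' @param MR,MA,MF Rested, active and fatigued fractions; must lie in
#'   \[0, 1\] and sum to 1.
#' @return An object of class `fatigue_state`.
#' @export
fatigue_state <- function(MR = 1, MA = 0, MF = 0) {
  v <- c(MR, MA, MF)
  if (any(v < -1e-9 | v > 1 + 1e-9) || abs(sum(v) - 1) > 1e-9) {
    stop("compartments must lie in [0,1] and sum to 1", call. = FALSE)
  }
  structure(list(MR = MR, MA = MA, MF = MF), class = "fatigue_state")
}

#' Motor-unit drive
#'
#' The piecewise drive `C` moving motor units between the rested and active
#' compartments so that the active fraction tracks the target load `TL`:
#' when under-activated (`MA < TL`) units are recruited at rate `LD` from
#' the rested pool, limited by what remains rested; when over-activated
#' units are released back to rest at rate `LR` (the drive is then
#' negative, the flow being active to rested).
#'
#' @param state A [fatigue_state()].
#' @param TL Target load in \[0, 1\].
#' @param params A [fatigue_params()].
#' @return The drive, units of fraction per second.
#' @export
#' @examples
#' fatigue_drive(fatigue_state(0.5, 0.2, 0.3), 0.4, fatigue_params(LD = 10))
fatigue_drive <- function(state, TL, params) {
  stopifnot(inherits(state, "fatigue_state"), inherits(params, "fatigue_params"))
  if (TL < 0 || TL > 1) stop("`TL` must lie in [0, 1]", call. = FALSE)
  drive_vec(state$MR, state$MA, TL, params$LD, params$LR)
}

## vectorized drive over channels; sign convention: positive = recruitment
## (rested -> active), negative = deactivation (active -> rested)
drive_vec <- function(MR, MA, TL, LD, LR) {
  gap <- TL - MA
  ifelse(MA < TL,
         ifelse(MR >= gap, LD * gap, LD * MR),
         LR * (TL - MA))
}

#' Integrate the fatigue model over a target-load trace
#'
#' Forward-Euler integration of the compartment flows
#' `dMR/dt = -C + R MF`, `dMA/dt = C - F MA`, `dMF/dt = F MA - R MF`,
#' where `C` is the drive of [fatigue_drive()]. The achievable (fatigued)
#' excitation is the active fraction `MA(t)`.
#'
#' @param initial A [fatigue_state()].
#' @param TL Numeric vector of target loads in \[0, 1\], sampled at `dt`.
#' @param params A [fatigue_params()].
#' @param dt Time step, seconds; must satisfy `dt * max(LD, LR) < 1` for
#'   stability.
#' @return A data frame with columns `t`, `MR`, `MA`, `MF` (length
#'   `length(TL)`, the state after each step, with the initial state at
#'   `t = 0` as the first row).
#' @export
fatigue_integrate <- function(initial, TL, params, dt) {
  stopifnot(inherits(initial, "fatigue_state"),
            inherits(params, "fatigue_params"))
  if (dt * max(params$LD, params$LR) >= 1) {
    stop("unstable step: need dt * max(LD, LR) < 1", call. = FALSE)
  }
  if (any(TL < -1e-12 | TL > 1 + 1e-12)) {
    stop("target loads must lie in [0, 1]", call. = FALSE)
  }
  n <- length(TL)
  out <- integrate_channels(matrix(TL, ncol = 1),
                            c(initial$MR, initial$MA, initial$MF), params, dt)
  data.frame(t = seq(0, by = dt, length.out = n),
             MR = out$MR[, 1], MA = out$MA[, 1], MF = out$MF[, 1])
}

## Euler integration of independent channels in lockstep. TLmat: steps x
## channels. init: length-3 (MR, MA, MF) shared by all channels, or a 3 x k
## matrix of per-channel states. The state at row i corresponds to time
## (i-1)*dt; TL[i, ] drives the step from row i to i+1.
integrate_channels <- function(TLmat, init, params, dt) {
  if (!is.matrix(init)) init <- matrix(init, 3, ncol(TLmat))
  integrate_channels_cpp(TLmat, init, params$F, params$R, params$LD,
                         params$LR, dt)
}

#' Apply fatigue to multi-channel excitations
#'
#' Treats each channel of `excitations` as the target-load trace of an
#' independent muscle, integrates the three-compartment model per channel
#' (internally on a fine Euler grid of step `dt`), and returns the active
#' fractions `MA(t)` -- the fatigued excitations -- resampled onto the input
#' time grid.
#'
#' @param excitations An [activation_trace()] (any number of channels).
#' @param params A [fatigue_params()].
#' @param dt Euler step, seconds (default 0.01).
#' @param initial A [fatigue_state()] shared by all channels.
#' @param start_at_target Start each channel with its initial target load
#'   already active (`MA = TL(0)`, the pool tracking an ongoing hold)
#'   instead of from `initial`; used for ramp targets that begin at a
#'   nonzero torque.
#' @return An [activation_trace()] with the same times and channels.
#' @export
#' @examples
#' exc <- activation_trace(seq(0, 30, 0.1), matrix(0.8, 301, 1))
#' fat <- apply_fatigue(exc, fatigue_params())
#' max(fat$values)  # capped by the fatigued pool
apply_fatigue <- function(excitations, params, dt = 0.01,
                          initial = fatigue_state(),
                          start_at_target = FALSE) {
  stopifnot(inherits(excitations, "activation_trace"),
            inherits(params, "fatigue_params"))
  times <- excitations$times
  grid <- seq(times[1], times[length(times)], by = dt)
  TLmat <- apply(excitations$values, 2, function(v) {
    approx(times, v, xout = grid, rule = 2)$y
  })
  TLmat <- matrix(TLmat, nrow = length(grid))
  init <- if (start_at_target) {
    rbind(1 - TLmat[1, ], TLmat[1, ], 0)
  } else {
    c(initial$MR, initial$MA, initial$MF)
  }
  out <- integrate_channels(TLmat, init, params, dt)
  MA <- apply(out$MA, 2, function(v) approx(grid, v, xout = times, rule = 2)$y)
  MA <- matrix(MA, nrow = length(times))
  activation_trace(times, pmin(pmax(MA, 0), 1), colnames(excitations$values))
}
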