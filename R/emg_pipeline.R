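#' Raw multi-channel EMG container
#'
#' @param signals Numeric matrix, one column per muscle channel (named
#'   `bra`, `tri`, `bic`, `brd`), arbitrary units.
#' @param rate Sampling rate, hertz (default 3000).
#' @return An object of class `raw_emg`.
#' @export
raw_emg <- function(signals, rate = 3000) {
  signals <- as.matrix(signals)
  if (rate <= 0) stop("`rate` must be positive", call. = FALSE)
  if (is.null(colnames(signals))) {
    colnames(signals) <- c("bra", "tri", "bic", "brd")[seq_len(ncol(signals))]
  }
  structure(list(signals = signals, rate = rate,
                 duration = nrow(signals) / rate),
            class = "raw_emg")
}

#' @export
print.raw_emg <- function(x, ...) {
  cat(sprintf("<raw_emg> %d channels, %.1f s @ %g Hz\n",
              ncol(x$signals), x$duration, x$rate))
  invisible(x)
}

#' Envelope-extraction settings
#'
#' Defaults follow the recorded-data processing chain: 4th-order Butterworth
#' bandpass 10--500 Hz, full-wave rectification, 4th-order Butterworth
#' lowpass at 5 Hz, a 0.5 s median filter, normalization by the subject's
#' cross-trial peak, and interpolation to 300 time instances. Both
#' Butterworth filters are applied forward-backward (zero phase).
#'
#' @param bandpass Length-2 bandpass cutoffs, hertz.
#' @param bp_order,lp_order Butterworth orders.
#' @param lowpass Envelope lowpass cutoff, hertz.
#' @param median_window_s Median-filter window, seconds.
#' @param output_steps Output sequence length.
#' @return An object of class `envelope_settings`.
#' @export
envelope_settings <- function(bandpass = c(10, 500), bp_order = 4,
                              lowpass = 5, lp_order = 4,
                              median_window_s = 0.5, output_steps = 300L) {
  if (bandpass[1] <= 0 || bandpass[1] >= bandpass[2]) {
    stop("bandpass cutoffs must satisfy 0 < low < high", call. = FALSE)
  }
  structure(list(bandpass = bandpass, bp_order = bp_order, lowpass = lowpass,
                 lp_order = lp_order, median_window_s = median_window_s,
                 output_steps = as.integer(output_steps)),
            class = "envelope_settings")
}

#' Median-filter window length in samples
#'
#' The largest odd number of samples not exceeding the requested window
#' duration. At the 3000 Hz EMG rate and a 0.5 s window this is 1499
#' samples.
#'
#' @param window_s Window duration, seconds.
#' @param rate Sampling rate, hertz.
#' @return An odd integer sample count.
#' @export
#' @examples
#' median_window_samples(0.5, 3000)  # 1499
median_window_samples <- function(window_s, rate) {
  n <- floor(window_s * rate)
  if (n < 1) stop("window shorter than one sample", call. = FALSE)
  n <- as.integer(n)
  if (n %% 2L == 0L) n - 1L else n
}

## zero-phase Butterworth via forward-backward filtering with reflect
## padding at both ends to suppress filtfilt edge transients
zero_phase <- function(x, filt, pad = min(length(x) - 1L, 3000L)) {
  n <- length(x)
  xp <- c(2 * x[1] - rev(x[2:(pad + 1)]), x,
          2 * x[n] - rev(x[(n - pad):(n - 1)]))
  y <- signal::filtfilt(filt, xp)
  y[(pad + 1):(pad + n)]
}

## running median with reflect padding (runmed keeps endpoints otherwise)
median_smooth <- function(x, k) {
  if (k <= 1) return(x)
  half <- (k - 1L) %/% 2L
  n <- length(x)
  half <- min(half, n - 1L)
  xp <- c(rev(x[2:(half + 1)]), x, rev(x[(n - half):(n - 1)]))
  y <- runmed(xp, 2L * half + 1L, endrule = "keep")
  y[(half + 1):(half + n)]
}

#' Process raw EMG into normalized activation envelopes
#'
#' The full recorded-signal chain: mean subtraction, zero-phase 4th-order
#' Butterworth bandpass (10--500 Hz), full-wave rectification, zero-phase
#' 4th-order Butterworth lowpass (5 Hz), a 0.5 s running-median filter,
#' division by the subject's cross-trial peak, clipping to \[0, 1\], and
#' linear interpolation to 300 time instances across the trial.
#'
#' @param raw A [raw_emg()].
#' @param settings An [envelope_settings()].
#' @param subject_peak Per-channel peak envelope values observed across all
#'   of the subject's trials (recycled if scalar); must be positive.
#' @return An [activation_trace()] with `settings$output_steps` steps and
#'   one channel per raw channel.
#' @export
process_emg <- function(raw, settings = envelope_settings(),
                        subject_peak) {
  stopifnot(inherits(raw, "raw_emg"), inherits(settings, "envelope_settings"))
  if (missing(subject_peak)) {
    stop("`subject_peak` (cross-trial envelope maxima) is required",
         call. = FALSE)
  }
  k <- ncol(raw$signals)
  subject_peak <- rep_len(subject_peak, k)
  if (any(subject_peak <= 0)) stop("`subject_peak` must be positive",
                                   call. = FALSE)
  env <- emg_envelope(raw, settings)
  scaled <- sweep(env$values, 2, subject_peak, "/")
  scaled <- pmin(pmax(scaled, 0), 1)
  resample_to_grid(activation_trace(env$times, scaled, colnames(raw$signals)),
                   settings$output_steps)
}

#' Unnormalized EMG envelope
#'
#' The processing chain of [process_emg()] up to (but not including)
#' normalization: useful for computing a subject's cross-trial peak.
#'
#' @inheritParams process_emg
#' @return A list with `times` and `values` (matrix, arbitrary units).
#' @export
emg_envelope <- function(raw, settings = envelope_settings()) {
  rate <- raw$rate
  if (settings$bandpass[2] >= rate / 2) {
    stop("bandpass high cutoff must be below the Nyquist frequency",
         call. = FALSE)
  }
  kmed <- median_window_samples(settings$median_window_s, rate)
  if (nrow(raw$signals) <= kmed) {
    stop("signal shorter than the median-filter window", call. = FALSE)
  }
  bp <- signal::butter(settings$bp_order, settings$bandpass / (rate / 2),
                       type = "pass")
  lp <- signal::butter(settings$lp_order, settings$lowpass / (rate / 2),
                       type = "low")
  vals <- apply(raw$signals, 2, function(x) {
    x <- x - mean(x)
    x <- zero_phase(x, bp)
    x <- abs(x)
    x <- zero_phase(x, lp)
    median_smooth(x, kmed)
  })
  vals <- matrix(vals, nrow = nrow(raw$signals),
                 dimnames = list(NULL, colnames(raw$signals)))
  list(times = seq(0, by = 1 / rate, length.out = nrow(raw$signals)),
       values = vals)
}

#' Centered moving average with reflect padding
#'
#' @param x Numeric vector.
#' @param window Window size in samples (>= 1); even windows are applied
#'   with symmetric (reflect) padding like odd ones.
#' @return Smoothed vector, same length.
#' @export
moving_average <- function(x, window) {
  if (window < 1) stop("`window` must be at least 1", call. = FALSE)
  window <- as.integer(window)
  if (window == 1L) return(x)
  n <- length(x)
  left <- (window - 1L) %/% 2L
  right <- window - 1L - left
  xp <- c(rev(x[seq_len(left) + 1L]), x, rev(x[(n - right):(n - 1L)]))
  as.numeric(stats::filter(xp, rep(1 / window, window),
                           sides = 2))[(left + 1L):(left + n)]
}

#' Sum of absolute successive differences after smoothing
#'
#' @param signal Numeric vector.
#' @param window Moving-average window, samples.
#' @return The SAD of the smoothed signal.
#' @export
smoothing_sad <- function(signal, window) {
  sum(abs(diff(moving_average(signal, window))))
}

#' Select a moving-average window from the SAD curve
#'
#' Computes the sum of absolute successive differences (SAD) of the signal
#' after moving-average smoothing for each candidate window (default 5 to 50
#' samples in steps of 5). The chosen window is the configured default (25)
#' unless the elbow rule fires earlier: the first candidate whose SAD
#' improves on its predecessor by less than 5% is returned instead. The SAD
#' table is attached for visual inspection, mirroring how the window was
#' originally chosen by eye.
#'
#' @param signal Numeric vector.
#' @param candidates Candidate window sizes (samples).
#' @param default Window returned when the elbow rule never fires (25).
#' @param rel_tol Elbow threshold on the relative SAD improvement (0.05).
#' @return The selected window (integer) with attribute `sad_table`, a data
#'   frame of `window` and `sad`.
#' @export
select_smoothing_window <- function(signal, candidates = seq(5, 50, by = 5),
                                    default = 25, rel_tol = 0.05) {
  if (length(candidates) == 0L) stop("no candidate windows", call. = FALSE)
  if (any(candidates >= length(signal))) {
    stop("candidate window not smaller than the signal", call. = FALSE)
  }
  sad <- vapply(candidates, smoothing_sad, 0, signal = signal)
  tab <- data.frame(window = candidates, sad = sad)
  chosen <- as.integer(default)
  if (all(sad == 0)) {
    chosen <- as.integer(min(candidates))
  } else if (length(candidates) > 1L) {
    rel_drop <- 1 - sad[-1] / sad[-length(sad)]
    hit <- which(rel_drop < rel_tol)
    if (length(hit) && candidates[hit[1] + 1L] < default) {
      chosen <- as.integer(candidates[hit[1] + 1L])
    }
  }
  structure(chosen, sad_table = tab)
}

#' Prepare activations for forward simulation
#'
#' The physics-baseline preparation step: each activation channel is
#' smoothed with a centered moving average (default window 25 samples,
#' reflect padding). Values remain in \[0, 1\].
#'
#' @param act An [activation_trace()].
#' @param window Moving-average window, samples (default 25).
#' @return An [activation_trace()].
#' @export
prepare_for_simulation <- function(act, window = 25L) {
  stopifnot(inherits(act, "activation_trace"))
  vals <- apply(act$values, 2, moving_average, window = window)
  activation_trace(act$times, pmin(pmax(matrix(vals, nrow = nrow(act$values)), 0), 1),
                   colnames(act$values))
}

#' Write / read raw EMG as CSV
#'
#' Multi-channel CSV with a `t_s` column plus one column per channel; the
#' sampling rate is stored in a `# rate_hz:` header comment.
#'
#' @param raw A [raw_emg()].
#' @param path File path.
#' @return `write_raw_emg_csv` returns `path` invisibly; `read_raw_emg_csv`
#'   returns a [raw_emg()].
#' @export
write_raw_emg_csv <- function(raw, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# rate_hz: %g", raw$rate), con)
  df <- data.frame(t_s = seq(0, by = 1 / raw$rate,
                             length.out = nrow(raw$signals)))
  df <- cbind(df, as.data.frame(raw$signals))
  write.csv(df, con, row.names = FALSE)
  invisible(path)
}

#' @rdname write_raw_emg_csv
#' @export
read_raw_emg_csv <- function(path) {
  header <- readLines(path, n = 1L)
  rate <- as.numeric(sub("# rate_hz:\\s*", "", header))
  df <- read.csv(path, comment.char = "#")
  raw_emg(as.matrix(df[, setdiff(names(df), "t_s"), drop = FALSE]), rate)
}
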