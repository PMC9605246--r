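## Feature pipeline: 42 derived signals x 10 sliding-window statistics
## = 420 columns per window.

#' Accelerometer magnitude
#'
#' Element-wise Euclidean norm of the three acceleration axes,
#' `sqrt(ax^2 + ay^2 + az^2)`.
#'
#' @param ax,ay,az Numeric vectors of equal length.
#' @return Non-negative numeric vector.
#' @export
acc_magnitude <- function(ax, ay, az) {
  if (length(ay) != length(ax) || length(az) != length(ax)) {
    stop_with("stressfl_length_mismatch",
              "accelerometer axes must have equal lengths")
  }
  sqrt(ax^2 + ay^2 + az^2)
}

#' Finite-difference derivative of a sampled signal
#'
#' Central differences at interior points, one-sided differences at the two
#' endpoints, scaled by the sampling interval so the result has units of
#' signal per second.  Length is preserved, keeping all derived signals
#' aligned to window boundaries.  `order = 2` applies the operator twice.
#'
#' @param signal Numeric vector, length >= 3.
#' @param rate Sampling rate in Hz (> 0).
#' @param order 1 or 2.
#' @return Numeric vector, same length as `signal`.
#' @export
finite_derivative <- function(signal, rate, order = 1) {
  n <- length(signal)
  if (n < 3) {
    stop_with("stressfl_short_signal",
              "finite_derivative needs at least 3 samples")
  }
  stopifnot(rate > 0, order %in% c(1, 2))
  dt <- 1 / rate
  d <- numeric(n)
  d[2:(n - 1)] <- (signal[3:n] - signal[1:(n - 2)]) / (2 * dt)
  d[1] <- (signal[2] - signal[1]) / dt
  d[n] <- (signal[n] - signal[n - 1]) / dt
  if (order == 2) d <- finite_derivative(d, rate, order = 1)
  d
}

#' Haar wavelet approximation at a target rate
#'
#' Applies `log2(native_rate / target_rate)` levels of single-level Haar
#' decomposition, keeping the approximation coefficients at each level.
#' One level maps adjacent pairs `(a, b)` to `(a + b) / sqrt(2)`, halving
#' the length and the effective sampling rate (a trailing unpaired sample
#' is dropped).  Zero levels return the signal unchanged.
#'
#' @param signal Numeric vector.
#' @param native_rate Sampling rate of `signal`, Hz.
#' @param target_rate Desired effective rate, Hz; `native_rate /
#'   target_rate` must be a power of two >= 1.
#' @return Numeric vector of approximation coefficients with attribute
#'   `effective_rate = target_rate`.
#' @export
haar_approximation <- function(signal, native_rate, target_rate) {
  if (target_rate > native_rate) {
    stop_with("stressfl_bad_rate",
              "target rate %g exceeds native rate %g", target_rate,
              native_rate)
  }
  ratio <- native_rate / target_rate
  levels <- log2(ratio)
  if (abs(levels - round(levels)) > 1e-9) {
    stop_with("stressfl_bad_rate",
              "native/target rate ratio %g is not a power of two", ratio)
  }
  levels <- as.integer(round(levels))
  x <- signal
  for (l in seq_len(levels)) {
    m <- length(x) %/% 2
    if (m == 0) {
      stop_with("stressfl_short_signal",
                "signal too short for %d Haar levels", levels)
    }
    x <- (x[2 * seq_len(m) - 1] + x[2 * seq_len(m)]) / sqrt(2)
  }
  attr(x, "effective_rate") <- target_rate
  x
}

#' Derive the 42 registry signals from a recording
#'
#' For each base stream (ST, ACCx, ACCy, ACCz, ACCnorm, EDA, BVP):
#' the original samples, first and second derivatives at the native rate,
#' and Haar approximations at 4, 2 and 1 Hz.  For the 4 Hz streams (ST,
#' EDA) the 4 Hz wavelet variant is the zero-level identity.
#'
#' @param recording A `sensor_recording`.
#' @return A `derived_signal_set`: named list of 42 entries (registry
#'   order), each `list(samples, rate)`, with the participant id attached.
#' @export
derive_signals <- function(recording) {
  ch <- recording$channels
  missing_ch <- setdiff(E4_CHANNELS, names(ch))
  if (length(missing_ch) > 0) {
    stop_with("stressfl_missing_channel", "missing channel(s): %s",
              toString(missing_ch))
  }
  streams <- list()
  for (s in c("ST", "ACCx", "ACCy", "ACCz")) {
    streams[[s]] <- list(samples = ch[[s]]$samples, rate = ch[[s]]$rate)
  }
  streams$ACCnorm <- list(
    samples = acc_magnitude(ch$ACCx$samples, ch$ACCy$samples,
                            ch$ACCz$samples),
    rate = ch$ACCx$rate
  )
  streams$EDA <- list(samples = ch$EDA$samples, rate = ch$EDA$rate)
  streams$BVP <- list(samples = ch$BVP$samples, rate = ch$BVP$rate)

  out <- list()
  for (s in BASE_STREAMS) {
    x <- streams[[s]]$samples
    r <- streams[[s]]$rate
    out[[signal_name(s, "orig")]] <- list(samples = x, rate = r)
    out[[signal_name(s, "d1")]] <- list(
      samples = finite_derivative(x, r, 1), rate = r)
    out[[signal_name(s, "d2")]] <- list(
      samples = finite_derivative(x, r, 2), rate = r)
    for (tr in c(4, 2, 1)) {
      nm <- signal_name(s, sprintf("dwt_%dHz", tr))
      a <- haar_approximation(x, r, tr)
      out[[nm]] <- list(samples = as.numeric(a), rate = tr)
    }
  }
  structure(out, class = "derived_signal_set",
            participant_id = recording$participant_id)
}

#' Sliding-window index over a session
#'
#' 60-second windows stepping by 0.25 s from time 0; the last window ends
#' at or before the session end.  A window is labelled stress when strictly
#' more than half of the seconds it covers are labelled stress (neutral and
#' amusement both count as non-stress; ties go to non-stress).
#'
#' @param session_duration Session length in seconds (>= 60).
#' @param labels Per-second condition strings, length `floor(duration)`.
#' @return A tibble with `window_id`, `start_time`, `end_time` and binary
#'   `label` (1 = stress, 0 = non-stress).
#' @export
segment_windows <- function(session_duration, labels) {
  if (session_duration < 60) {
    stop_with("stressfl_short_session",
              "session must be at least one 60 s window")
  }
  stopifnot(length(labels) == floor(session_duration),
            all(labels %in% CONDITIONS))
  n_windows <- floor((session_duration - 60) / 0.25 + 1e-9) + 1
  starts <- (seq_len(n_windows) - 1) * 0.25
  ends <- starts + 60
  ## seconds covered by [start, end): indices floor(start)..ceiling(end)-1
  first_sec <- floor(starts)
  last_sec <- pmin(ceiling(ends - 1e-9) - 1, length(labels) - 1)
  cs <- c(0, cumsum(labels == "stress"))
  n_stress <- cs[last_sec + 2] - cs[first_sec + 1]
  n_cov <- last_sec - first_sec + 1
  lab <- as.integer(n_stress > n_cov / 2)
  tibble::tibble(
    window_id = seq_len(n_windows),
    start_time = starts,
    end_time = ends,
    label = lab
  )
}

#' The 10 window statistics
#'
#' In fixed order: mean, minimum, maximum, median, maximum amplitude
#' (max absolute value), variance, standard deviation, absolute deviation
#' (mean absolute deviation about the mean), kurtosis (Fisher excess) and
#' skewness.  Moments use population normalization; zero-variance input
#' yields kurtosis and skewness 0 by convention.
#'
#' @param samples Non-empty numeric vector.
#' @return Named numeric vector of length 10.
#' @export
window_statistics <- function(samples) {
  if (length(samples) == 0) {
    stop_with("stressfl_empty_window", "window statistics need samples")
  }
  n <- length(samples)
  m <- mean(samples)
  d <- samples - m
  m2 <- mean(d^2)
  out <- c(
    mean = m,
    min = min(samples),
    max = max(samples),
    median = median(samples),
    maxamp = max(abs(samples)),
    var = m2,
    sd = sqrt(m2),
    absdev = mean(abs(d)),
    kurtosis = if (m2 > 0) mean(d^4) / m2^2 - 3 else 0,
    skewness = if (m2 > 0) mean(d^3) / m2^1.5 else 0
  )
  out
}

## 1-based sample index range of window [start, end) for a signal whose
## k-th sample (0-based) sits at time k / rate.
window_sample_range <- function(starts, ends, rate) {
  lo <- ceiling(starts * rate - 1e-9) + 1
  hi <- ceiling(ends * rate - 1e-9)
  list(lo = as.integer(lo), hi = as.integer(hi))
}

#' Build the 420-column feature matrix for one recording
#'
#' Derives the 42 registry signals, slides 60 s / 0.25 s-step windows over
#' the session, and computes the 10 statistics of each signal's samples
#' falling in `[start, start + 60)` (wavelet variants are placed on their
#' effective-rate grid).  Columns are signal-major, statistic-minor in
#' registry order.
#'
#' @param recording A `sensor_recording` of duration >= 60 s.
#' @return A tibble with `participant`, `window_id`, `start_time`, binary
#'   `label` and the 420 feature columns.
#' @export
build_feature_matrix <- function(recording) {
  duration <- length(recording$labels)
  windows <- segment_windows(duration, recording$labels)
  signals <- derive_signals(recording)
  blocks <- vector("list", length(signals))
  for (i in seq_along(signals)) {
    sig <- signals[[i]]
    rng <- window_sample_range(windows$start_time, windows$end_time,
                               sig$rate)
    if (any(rng$hi < rng$lo) || max(rng$hi) > length(sig$samples)) {
      stop_with("stressfl_empty_window",
                "signal %s has a window with no samples", names(signals)[i])
    }
    stats_mat <- window_stats_cpp(sig$samples, rng$lo, rng$hi)
    colnames(stats_mat) <- paste(names(signals)[i], STAT_NAMES, sep = "_")
    blocks[[i]] <- stats_mat
  }
  feat <- do.call(cbind, blocks)
  out <- tibble::tibble(
    participant = recording$participant_id,
    window_id = windows$window_id,
    start_time = windows$start_time,
    label = windows$label
  )
  out <- cbind(out, tibble::as_tibble(feat))
  tibble::as_tibble(out)
}

## Columns of a feature matrix that are features (not metadata).
feature_columns <- function(fm) {
  setdiff(names(fm), c("participant", "window_id", "start_time", "label"))
}
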