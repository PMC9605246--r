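## Channel and feature registries.
##
## The Empatica E4 export rates are adopted for the four smartwatch sensors:
## ST 4 Hz, EDA 4 Hz, ACC 32 Hz (three axes), BVP 64 Hz.  These divide the
## 4/2/1 Hz wavelet targets evenly, so every Haar cascade has an integer
## level count.

E4_CHANNELS <- c("ST", "ACCx", "ACCy", "ACCz", "EDA", "BVP")

E4_RATES <- c(ST = 4, ACCx = 32, ACCy = 32, ACCz = 32, EDA = 4, BVP = 64)

CONDITIONS <- c("neutral", "stress", "amusement")

## Base streams feeding the feature pipeline: the six raw channels plus the
## accelerometer magnitude, each expanded into 6 variants (original, two
## derivatives, Haar approximations at 4/2/1 Hz) = 42 derived signals.
BASE_STREAMS <- c("ST", "ACCx", "ACCy", "ACCz", "ACCnorm", "EDA", "BVP")

SIGNAL_VARIANTS <- c("orig", "d1", "d2", "dwt_4Hz", "dwt_2Hz", "dwt_1Hz")

STAT_NAMES <- c("mean", "min", "max", "median", "maxamp", "var", "sd",
                "absdev", "kurtosis", "skewness")

stream_rate <- function(stream) {
  if (stream == "ACCnorm") return(unname(E4_RATES[["ACCx"]]))
  unname(E4_RATES[[stream]])
}

signal_name <- function(stream, variant) {
  if (variant == "orig") stream else paste(stream, variant, sep = "_")
}

#' Registry of the 42 derived signals
#'
#' Each of the 7 base streams (6 raw channels plus the accelerometer
#' magnitude `ACCnorm`) contributes 6 variants: the original signal, its
#' first and second finite-difference derivatives, and Haar wavelet
#' approximations at 4, 2 and 1 Hz.  Signals are listed stream-major in
#' sensor order (ST, ACC, EDA, BVP), so the set partitions as 6 ST + 24 ACC
#' + 6 EDA + 6 BVP.
#'
#' @return A data frame with columns `name`, `stream`, `variant`,
#'   `native_rate` (Hz of the stream) and `effective_rate` (Hz of the
#'   derived signal), one row per signal in registry order.
#' @export
signal_registry <- function() {
  rows <- lapply(BASE_STREAMS, function(stream) {
    rate <- stream_rate(stream)
    eff <- c(rate, rate, rate, 4, 2, 1)
    data.frame(
      name = vapply(SIGNAL_VARIANTS, signal_name, "", stream = stream),
      stream = stream,
      variant = SIGNAL_VARIANTS,
      native_rate = rate,
      effective_rate = eff,
      stringsAsFactors = FALSE, row.names = NULL
    )
  })
  do.call(rbind, rows)
}

#' Names of the 420 feature columns
#'
#' Signal-major, statistic-minor: for each of the 42 registry signals, the
#' 10 window statistics in fixed order (mean, min, max, median, maxamp,
#' var, sd, absdev, kurtosis, skewness).
#'
#' @return Character vector of length 420.
#' @export
feature_names <- function() {
  sig <- signal_registry()$name
  as.vector(t(outer(sig, STAT_NAMES, paste, sep = "_")))
}
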