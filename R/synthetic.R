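## Synthetic multimodal smartwatch cohort generator.
##
## The generator emulates the structure of a single-session lab protocol:
## a long neutral block, a stress-induction block and an amusement block,
## recorded on four wrist sensors at Empatica E4 export rates, with
## per-second condition labels.  Signal morphology is deliberately minimal
## (every stress response is analytically checkable at zero noise):
##   ST  = baseline + slow linear drift + smoothed stress decrement + noise
##   EDA = smoothed tonic level (elevated under stress) + phasic
##         skin-conductance responses from a Poisson process (higher rate
##         under stress), each a fast-rise/exponential-decay bump + noise
##   BVP = unit sinusoid at a smoothed instantaneous heart rate (elevated
##         under stress) + noise
##   ACC = gravity-offset constants + condition-independent movement bursts
##         + noise
## Participant heterogeneity (baselines, response scale, responder type)
## induces the non-IID client structure that makes the individual vs.
## centralized vs. federated comparison meaningful.

RESPONDER_TYPES <- c("typical", "weak", "atypical")

## Stress-response magnitudes per unit stress_effect_scale (typical
## responder): tonic EDA +1.5 uS, phasic SCR rate +5 events/min over a
## 3/min base, heart rate +20 bpm, skin temperature -0.2 degC.
STRESS_EFFECTS <- list(
  eda_tonic = 1.5,     # uS
  scr_rate_base = 3,   # events/min, neutral
  scr_rate_delta = 5,  # events/min added under stress
  hr_delta = 20,       # bpm
  st_delta = -0.2      # degC
)

#' Session plan for one recording
#'
#' An ordered list of (condition, duration) segments describing the lab
#' protocol of a single session.
#'
#' @param segments Data frame with columns `condition` (one of `"neutral"`,
#'   `"stress"`, `"amusement"`) and `duration` (seconds, > 0).
#' @return A `session_plan` object.
#' @export
session_plan <- function(segments) {
  stopifnot(is.data.frame(segments),
            all(c("condition", "duration") %in% names(segments)))
  if (!all(segments$condition %in% CONDITIONS)) {
    stop_with("stressfl_bad_plan", "conditions must be one of: %s",
              toString(CONDITIONS))
  }
  if (!all(segments$duration > 0)) {
    stop_with("stressfl_bad_plan", "segment durations must be positive")
  }
  out <- segments[, c("condition", "duration")]
  class(out) <- c("session_plan", "data.frame")
  out
}

#' Default single-session protocol
#'
#' 20 min neutral, 10 min stress, 6.5 min amusement: 2190 s in total, one
#' segment per condition.
#'
#' @return A `session_plan` with segments (neutral, 1200 s),
#'   (stress, 600 s), (amusement, 390 s).
#' @export
default_session_plan <- function() {
  session_plan(data.frame(
    condition = c("neutral", "stress", "amusement"),
    duration = c(1200, 600, 390)
  ))
}

plan_duration <- function(plan) sum(plan$duration)

## Per-second condition labels implied by a plan.
plan_labels <- function(plan) {
  rep(plan$condition, times = plan$duration)
}

## Condition at arbitrary times (used to evaluate targets on sample grids).
plan_condition_at <- function(plan, times) {
  breaks <- c(0, cumsum(plan$duration))
  idx <- findInterval(times, breaks, rightmost.closed = TRUE,
                      left.open = FALSE)
  idx[idx < 1] <- 1L
  idx[idx > nrow(plan)] <- nrow(plan)
  plan$condition[idx]
}

#' Participant profile for the synthetic generator
#'
#' @param participant_id Integer >= 1.
#' @param st_baseline Skin-temperature baseline, degrees C.
#' @param eda_tonic_baseline Tonic electrodermal level, microsiemens.
#' @param heart_rate_baseline Resting heart rate, beats/min (40--200).
#' @param stress_effect_scale Non-negative multiplier applied to every
#'   channel-level stress response.
#' @param responder_type `"typical"` (full response), `"weak"` (halved) or
#'   `"atypical"` (sign-flipped EDA/heart-rate/ST responses).
#' @param noise_scales Named non-negative vector of per-channel Gaussian
#'   noise standard deviations (names `ST`, `ACC`, `EDA`, `BVP`).
#' @param rng_seed Integer seed making the participant's recording
#'   reproducible.
#' @return A `participant_profile` object.
#' @export
participant_profile <- function(participant_id,
                                st_baseline = 33,
                                eda_tonic_baseline = 2,
                                heart_rate_baseline = 70,
                                stress_effect_scale = 1,
                                responder_type = "typical",
                                noise_scales = c(ST = 0.05, ACC = 0.05,
                                                 EDA = 0.05, BVP = 0.1),
                                rng_seed = 1L) {
  if (!responder_type %in% RESPONDER_TYPES) {
    stop_with("stressfl_bad_responder", "unknown responder_type '%s'",
              responder_type)
  }
  stopifnot(participant_id >= 1,
            stress_effect_scale >= 0,
            all(noise_scales >= 0),
            all(c("ST", "ACC", "EDA", "BVP") %in% names(noise_scales)))
  if (heart_rate_baseline < 40 || heart_rate_baseline > 200) {
    stop_with("stressfl_bad_profile",
              "heart_rate_baseline must lie in [40, 200]")
  }
  structure(list(
    participant_id = as.integer(participant_id),
    st_baseline = st_baseline,
    eda_tonic_baseline = eda_tonic_baseline,
    heart_rate_baseline = heart_rate_baseline,
    stress_effect_scale = stress_effect_scale,
    responder_type = responder_type,
    noise_scales = noise_scales,
    rng_seed = as.integer(rng_seed)
  ), class = "participant_profile")
}

## Signed response multiplier for the responder type.
responder_sign <- function(responder_type) {
  switch(responder_type, typical = 1, weak = 0.5, atypical = -1,
         stop_with("stressfl_bad_responder", "unknown responder_type '%s'",
                   responder_type))
}

## First-order exponential smoothing of a piecewise-constant target,
## time constant tau seconds, sampled at `rate` Hz.
smooth_target <- function(target, rate, tau) {
  alpha <- (1 / rate) / tau
  alpha <- min(alpha, 1)
  as.numeric(stats::filter(alpha * target, 1 - alpha, method = "recursive",
                           init = target[1]))
}

## Phasic skin-conductance response kernel at `rate` Hz: fast rise
## (tau_r = 0.7 s), exponential decay (tau_d = 3 s), unit peak.
scr_kernel <- function(rate, tau_r = 0.7, tau_d = 3, span = 15) {
  t <- seq(0, span, by = 1 / rate)
  k <- exp(-t / tau_d) - exp(-t / tau_r)
  k / max(k)
}

#' Generate one participant's synthetic recording
#'
#' @param profile A [participant_profile()].
#' @param plan A [session_plan()]; defaults to [default_session_plan()].
#' @param amusement_effect Fraction of the stress response applied during
#'   amusement segments (default 0: amusement is physiologically
#'   neutral-like, so the binary stress vs. non-stress task is well posed).
#' @return A `sensor_recording`: list with `participant_id`, `channels`
#'   (per-channel `rate` and `samples`; ACC axes are separate channels) and
#'   `labels` (per-second condition strings).
#' @export
generate_participant <- function(profile, plan = default_session_plan(),
                                 amusement_effect = 0) {
  stopifnot(inherits(profile, "participant_profile"),
            inherits(plan, "session_plan"))
  duration <- plan_duration(plan)
  eff <- STRESS_EFFECTS
  sgn <- responder_sign(profile$responder_type)
  scale <- profile$stress_effect_scale
  ns <- profile$noise_scales

  ## 0 on neutral, 1 on stress, amusement_effect on amusement
  drive_at <- function(times) {
    cond <- plan_condition_at(plan, times)
    ifelse(cond == "stress", 1, ifelse(cond == "amusement",
                                       amusement_effect, 0))
  }

  with_seed(profile$rng_seed, {
    channels <- list()

    ## --- Skin temperature, 4 Hz ---
    r <- E4_RATES[["ST"]]
    n <- round(r * duration)
    t <- (seq_len(n) - 1) / r
    drift <- -0.3 * t / duration
    st_target <- profile$st_baseline + drift +
      sgn * scale * eff$st_delta * drive_at(t)
    st <- smooth_target(st_target, r, tau = 20) + rnorm(n, 0, ns[["ST"]])
    channels$ST <- list(rate = r, samples = st)

    ## --- Accelerometer, 32 Hz, gravity offsets + movement bursts ---
    r <- E4_RATES[["ACCx"]]
    n <- round(r * duration)
    t <- (seq_len(n) - 1) / r
    n_bursts <- rpois(1, duration / 60)  # ~1 burst/min, any condition
    burst_env <- numeric(n)
    if (n_bursts > 0) {
      onsets <- runif(n_bursts, 0, max(duration - 3, 0))
      for (o in onsets) {
        idx <- which(t >= o & t < o + 2)
        burst_env[idx] <- pmax(burst_env[idx], 1)
      }
    }
    osc <- sin(2 * pi * 3 * t)
    channels$ACCx <- list(rate = r, samples = 0.02 +
                            0.4 * burst_env * osc + rnorm(n, 0, ns[["ACC"]]))
    channels$ACCy <- list(rate = r, samples = -0.01 +
                            0.3 * burst_env * cos(2 * pi * 3 * t) +
                            rnorm(n, 0, ns[["ACC"]]))
    channels$ACCz <- list(rate = r, samples = 1 +
                            0.2 * burst_env * osc + rnorm(n, 0, ns[["ACC"]]))

    ## --- Electrodermal activity, 4 Hz ---
    r <- E4_RATES[["EDA"]]
    n <- round(r * duration)
    t <- (seq_len(n) - 1) / r
    tonic_target <- profile$eda_tonic_baseline +
      sgn * scale * eff$eda_tonic * drive_at(t)
    tonic <- smooth_target(tonic_target, r, tau = 10)
    ## Poisson SCR events: per-second rate from the (possibly sign-flipped,
    ## clamped at zero) events/min intensity
    sec_drive <- drive_at(seq_len(duration) - 0.5)
    rate_per_min <- pmax(eff$scr_rate_base +
                           sgn * scale * eff$scr_rate_delta * sec_drive, 0)
    events_per_sec <- rpois(duration, rate_per_min / 60)
    impulses <- numeric(n)
    ev_sec <- rep(seq_len(duration) - 1L, times = events_per_sec)
    if (length(ev_sec) > 0) {
      ev_time <- ev_sec + runif(length(ev_sec))
      ev_idx <- pmin(floor(ev_time * r) + 1, n)
      amp <- runif(length(ev_sec), 0.2, 0.8)
      for (k in seq_along(ev_idx)) {
        impulses[ev_idx[k]] <- impulses[ev_idx[k]] + amp[k]
      }
    }
    kern <- scr_kernel(r)
    phasic <- stats::convolve(c(impulses, numeric(length(kern))),
                              rev(kern), type = "open")
    phasic <- phasic[seq_len(n)]
    channels$EDA <- list(rate = r,
                         samples = tonic + phasic + rnorm(n, 0, ns[["EDA"]]))

    ## --- Blood volume pulse, 64 Hz ---
    r <- E4_RATES[["BVP"]]
    n <- round(r * duration)
    t <- (seq_len(n) - 1) / r
    hr_target <- profile$heart_rate_baseline +
      sgn * scale * eff$hr_delta * drive_at(t)
    hr <- pmin(pmax(smooth_target(hr_target, r, tau = 15), 40), 200)
    phase <- cumsum(hr / 60) / r
    channels$BVP <- list(rate = r,
                         samples = sin(2 * pi * phase) +
                           rnorm(n, 0, ns[["BVP"]]))

    structure(list(
      participant_id = profile$participant_id,
      channels = channels,
      labels = plan_labels(plan),
      profile = profile
    ), class = "sensor_recording")
  })
}

#' Cohort heterogeneity spreads
#'
#' Gaussian spreads (center, sd) for the per-participant baselines and the
#' stress-response scale, plus the fraction of non-atypical participants
#' that respond weakly.
#'
#' @param st_baseline,eda_tonic_baseline,heart_rate_baseline,stress_effect_scale
#'   Length-2 numeric `(center, sd)`.
#' @param weak_fraction Proportion of non-atypical participants sampled as
#'   weak responders.
#' @param noise_scales Per-channel noise standard deviations shared by the
#'   cohort.
#' @return A list of spread parameters for [generate_cohort()].
#' @export
cohort_spreads <- function(st_baseline = c(33, 0.5),
                           eda_tonic_baseline = c(2, 0.5),
                           heart_rate_baseline = c(70, 6),
                           stress_effect_scale = c(1, 0.3),
                           weak_fraction = 0.2,
                           noise_scales = c(ST = 0.05, ACC = 0.05,
                                            EDA = 0.05, BVP = 0.1)) {
  list(st_baseline = st_baseline,
       eda_tonic_baseline = eda_tonic_baseline,
       heart_rate_baseline = heart_rate_baseline,
       stress_effect_scale = stress_effect_scale,
       weak_fraction = weak_fraction,
       noise_scales = noise_scales)
}

#' Generate a synthetic cohort
#'
#' Draws participant profiles from Gaussian spreads around cohort centers,
#' samples responder types with the requested atypical fraction, and
#' generates one recording per participant.  Fully reproducible under
#' `seed`.
#'
#' @param n_participants Number of participants (>= 1); ids are 1..n.
#' @param heterogeneity Spread parameters from [cohort_spreads()].
#' @param atypical_fraction Proportion of participants whose EDA/heart-rate
#'   stress responses are sign-flipped (0--1).
#' @param seed Integer seed for profile draws and per-participant streams.
#' @param plan Session plan shared by the cohort.
#' @return List of `sensor_recording`, one per participant.
#' @export
generate_cohort <- function(n_participants = 15,
                            heterogeneity = cohort_spreads(),
                            atypical_fraction = 0.2,
                            seed = 1L,
                            plan = default_session_plan()) {
  if (n_participants < 1) {
    stop_with("stressfl_bad_cohort", "n_participants must be >= 1")
  }
  stopifnot(atypical_fraction >= 0, atypical_fraction <= 1)
  h <- heterogeneity
  profiles <- with_seed(seed, {
    n <- n_participants
    n_atypical <- round(atypical_fraction * n)
    types <- rep("typical", n)
    if (n_atypical > 0) {
      types[sample.int(n, n_atypical)] <- "atypical"
    }
    non_at <- which(types == "typical")
    n_weak <- round(h$weak_fraction * length(non_at))
    if (n_weak > 0) {
      types[sample(non_at, n_weak)] <- "weak"
    }
    seeds <- sample.int(2^31 - 2, n)
    lapply(seq_len(n), function(i) {
      participant_profile(
        participant_id = i,
        st_baseline = rnorm(1, h$st_baseline[1], h$st_baseline[2]),
        eda_tonic_baseline = max(rnorm(1, h$eda_tonic_baseline[1],
                                       h$eda_tonic_baseline[2]), 0.2),
        heart_rate_baseline = min(max(rnorm(1, h$heart_rate_baseline[1],
                                            h$heart_rate_baseline[2]), 40),
                                  200),
        stress_effect_scale = max(rnorm(1, h$stress_effect_scale[1],
                                        h$stress_effect_scale[2]), 0.1),
        responder_type = types[i],
        noise_scales = h$noise_scales,
        rng_seed = seeds[i]
      )
    })
  })
  lapply(profiles, generate_participant, plan = plan)
}
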