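# Independent brute-force oracles and shared fixtures.  Oracles are
# written as explicit-loop definitions so they share no code with the
# implementation paths they check.

## --- statistics oracle: explicit loops, population moments ---
oracle_statistics <- function(x) {
  n <- length(x)
  s <- 0
  for (v in x) s <- s + v
  m <- s / n
  mn <- x[1]; mx <- x[1]; ma <- abs(x[1])
  for (v in x) {
    if (v < mn) mn <- v
    if (v > mx) mx <- v
    if (abs(v) > ma) ma <- abs(v)
  }
  m2 <- 0; m3 <- 0; m4 <- 0; ad <- 0
  for (v in x) {
    d <- v - m
    m2 <- m2 + d^2; m3 <- m3 + d^3; m4 <- m4 + d^4; ad <- ad + abs(d)
  }
  m2 <- m2 / n; m3 <- m3 / n; m4 <- m4 / n; ad <- ad / n
  xs <- sort(x)
  med <- if (n %% 2 == 1) xs[(n + 1) / 2] else (xs[n / 2] + xs[n / 2 + 1]) / 2
  c(mean = m, min = mn, max = mx, median = med, maxamp = ma,
    var = m2, sd = sqrt(m2), absdev = ad,
    kurtosis = if (m2 > 0) m4 / m2^2 - 3 else 0,
    skewness = if (m2 > 0) m3 / m2^1.5 else 0)
}

## --- Haar oracle: analysis-filter convolution + dyadic downsampling ---
oracle_haar_multilevel <- function(x, levels) {
  h <- c(1, 1) / sqrt(2)
  for (l in seq_len(levels)) {
    n2 <- length(x) %/% 2
    out <- numeric(n2)
    for (k in seq_len(n2)) {
      acc <- 0
      for (j in 1:2) acc <- acc + h[j] * x[2 * (k - 1) + j]
      out[k] <- acc
    }
    x <- out
  }
  x
}

## --- metric oracle: explicit pair enumeration ---
oracle_metrics <- function(truth, pred) {
  tp <- 0; fp <- 0; fn <- 0; tn <- 0
  for (i in seq_along(truth)) {
    if (truth[i] == 1 && pred[i] == 1) tp <- tp + 1
    else if (truth[i] == 0 && pred[i] == 1) fp <- fp + 1
    else if (truth[i] == 1 && pred[i] == 0) fn <- fn + 1
    else tn <- tn + 1
  }
  p <- if (tp + fp > 0) tp / (tp + fp) else 0
  r <- if (tp + fn > 0) tp / (tp + fn) else 0
  c(tp = tp, fp = fp, fn = fn, tn = tn,
    acc = (tp + tn) / length(truth), precision = p, recall = r,
    f1 = if (p + r > 0) 2 * p * r / (p + r) else 0)
}

## --- shared fixtures (cached across tests within a run) ---
.fixture_cache <- new.env(parent = emptyenv())

cached_fixture <- function(name, expr) {
  if (!exists(name, envir = .fixture_cache)) {
    assign(name, force(expr), envir = .fixture_cache)
  }
  get(name, envir = .fixture_cache)
}

short_plan <- function(neutral = 150, stress = 90, amusement = 60) {
  session_plan(data.frame(
    condition = c("neutral", "stress", "amusement"),
    duration = c(neutral, stress, amusement)))
}

## quiet 5-minute recording for feature-shape tests
tiny_recording <- function(seed = 11, responder = "typical",
                           noise = c(ST = 0.05, ACC = 0.05, EDA = 0.05,
                                     BVP = 0.1)) {
  generate_participant(
    participant_profile(1, responder_type = responder,
                        noise_scales = noise, rng_seed = seed),
    short_plan())
}

## 3-participant cohort + feature matrices, reused by strategy tests
tiny_cohort_matrices <- function() {
  cached_fixture("tiny_cohort_matrices", {
    coh <- generate_cohort(3, atypical_fraction = 0, seed = 42,
                           plan = short_plan())
    lapply(coh, build_feature_matrix)
  })
}

## small random logistic problem with a linear signal
random_logistic_data <- function(n = 50, p = 5, seed = 1) {
  set.seed(seed)
  X <- matrix(rnorm(n * p), n, p)
  colnames(X) <- paste0("f", seq_len(p))
  beta <- seq_len(p) / p
  y <- as.integer(plogis(X %*% beta) > runif(n))
  if (length(unique(y)) < 2) y[1:2] <- c(0L, 1L)
  list(X = X, y = y)
}
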