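test_that("accelerometer magnitude is the element-wise Euclidean norm", {
  expect_equal(acc_magnitude(3, 4, 0), 5)
  expect_equal(acc_magnitude(1, 0, 0), 1)
  expect_equal(acc_magnitude(1, 1, 1), sqrt(3))
  expect_equal(acc_magnitude(c(3, 1), c(4, 1), c(0, 1)),
               c(5, sqrt(3)))
  expect_error(acc_magnitude(1:3, 1:2, 1:3),
               class = "stressfl_length_mismatch")
})

test_that("finite derivative matches hand-computed central differences", {
  expect_equal(finite_derivative(rep(2.5, 10), 4, 1), rep(0, 10))
  ## ramp k*t sampled at rate r: derivative k everywhere (one-sided ends
  ## of a linear sequence coincide with the slope)
  r <- 8; k <- 3
  t <- (0:19) / r
  expect_equal(finite_derivative(k * t, r, 1), rep(k, 20))
  d2 <- finite_derivative(k * t, r, 2)
  expect_equal(d2[3:18], rep(0, 16))
  expect_error(finite_derivative(c(1, 2), 4, 1),
               class = "stressfl_short_signal")
})

test_that("Haar approximation follows the pairwise (a+b)/sqrt(2) cascade", {
  expect_equal(as.numeric(haar_approximation(c(3, 5), 2, 1)),
               8 / sqrt(2))
  ## constant signal through L levels scales by sqrt(2)^L
  x <- rep(2, 32)
  a <- haar_approximation(x, 32, 4)
  expect_equal(as.numeric(a), rep(2 * 2^(3 / 2), 4))
  expect_equal(attr(a, "effective_rate"), 4)
  ## zero levels is the identity
  y <- rnorm(16)
  expect_equal(as.numeric(haar_approximation(y, 4, 4)), y)
  expect_error(haar_approximation(y, 4, 8), class = "stressfl_bad_rate")
  expect_error(haar_approximation(y, 12, 4), class = "stressfl_bad_rate")
})

test_that("Haar cascade agrees with the filter-bank oracle and composes", {
  set.seed(31)
  for (len in c(64, 96)) {
    x <- rnorm(len)
    for (L in 1:3) {
      mine <- as.numeric(haar_approximation(x, 2^L, 1))
      expect_equal(mine, oracle_haar_multilevel(x, L), tolerance = 1e-10)
    }
    ## composing single levels equals the multi-level decomposition
    one <- as.numeric(haar_approximation(x, 8, 4))
    two <- as.numeric(haar_approximation(one, 4, 2))
    expect_equal(two, as.numeric(haar_approximation(x, 8, 2)),
                 tolerance = 1e-12)
  }
})

test_that("Haar cascade reproduces reference wavelet coefficients", {
  ## level-2 approximation coefficients computed with an independent
  ## wavelet library on this frozen input
  x <- c(0.304717, -1.039984, 0.750451, 0.940565, -1.951035, -1.30218,
         0.12784, -0.316243, -0.016801, -0.853044, 0.879398, 0.777792,
         0.066031, 1.127241, 0.467509, -0.859292)
  expect_equal(as.numeric(haar_approximation(x, 4, 1)),
               c(0.4778745, -1.720809, 0.3936725, 0.4007445),
               tolerance = 1e-10)
  expect_equal(as.numeric(haar_approximation(x, 8, 1)),
               c(-0.878887413521, 0.561737647790), tolerance = 1e-10)
})

test_that("the derived signal set has the 42 registry entries in order", {
  reg <- signal_registry()
  expect_equal(nrow(reg), 42)
  expect_equal(sum(startsWith(reg$name, "ACC")), 24)
  expect_equal(sum(startsWith(reg$name, "ST")), 6)
  expect_equal(sum(startsWith(reg$name, "EDA")), 6)
  expect_equal(sum(startsWith(reg$name, "BVP")), 6)

  rec <- tiny_recording()
  sigs <- derive_signals(rec)
  expect_equal(names(sigs), reg$name)
  rates <- vapply(sigs, `[[`, 0, "rate")
  expect_equal(unname(rates), reg$effective_rate)
  ## wavelet variants carry effective-rate sample counts
  expect_length(sigs$BVP_dwt_1Hz$samples, 300)
  expect_length(sigs$ST_dwt_4Hz$samples, 1200)
  ## the 4 Hz variant of a 4 Hz stream is the identity
  expect_equal(sigs$ST_dwt_4Hz$samples, sigs$ST$samples)

  broken <- rec
  broken$channels$EDA <- NULL
  expect_error(derive_signals(broken), class = "stressfl_missing_channel")
})

test_that("derivative signals of constant channels are identically zero", {
  rec <- tiny_recording()
  for (ch in names(rec$channels)) {
    rec$channels[[ch]]$samples <- rep(1, length(rec$channels[[ch]]$samples))
  }
  sigs <- derive_signals(rec)
  for (nm in grep("_d[12]$", names(sigs), value = TRUE)) {
    expect_equal(max(abs(sigs[[nm]]$samples)), 0, info = nm)
  }
})

test_that("window segmentation counts and labels windows correctly", {
  labs <- c(rep("neutral", 80), rep("stress", 90), rep("amusement", 61))
  w <- segment_windows(231, labs)
  expect_equal(nrow(w), (231 - 60) / 0.25 + 1)
  expect_equal(w$start_time[1:3], c(0, 0.25, 0.5))
  expect_equal(w$end_time - w$start_time, rep(60, nrow(w)))
  ## fully neutral window is non-stress; fully stress window is stress
  expect_equal(w$label[w$end_time <= 80], rep(0L, sum(w$end_time <= 80)))
  mid <- w$start_time >= 80 & w$end_time <= 170
  expect_equal(w$label[mid], rep(1L, sum(mid)))
  ## default-protocol session yields 8521 windows
  w2 <- segment_windows(2190, rep(c("neutral", "stress", "amusement"),
                                  c(1200, 600, 390)))
  expect_equal(nrow(w2), 8521)
  ## single-window session
  expect_equal(nrow(segment_windows(60, rep("neutral", 60))), 1)
  expect_error(segment_windows(59, rep("neutral", 59)),
               class = "stressfl_short_session")
})

test_that("a window is stress only under a strict majority of stress seconds", {
  ## 120 s: 60 neutral then 60 stress; the window starting at s covers
  ## seconds s..s+59 with 60 - s of them stress at integer starts
  labs <- rep(c("neutral", "stress"), each = 60)
  w <- segment_windows(120, labs)
  at <- function(s) w$label[abs(w$start_time - s) < 1e-9]
  expect_equal(at(30), 0L)  # exactly half stress: tie goes non-stress
  expect_equal(at(30.25), 1L)
  expect_equal(at(29.75), 0L)
})

test_that("stress window count is monotone in stress segment duration", {
  counts <- vapply(c(60, 90, 120, 150), function(d) {
    labs <- rep(c("neutral", "stress", "amusement"), c(120, d, 60))
    sum(segment_windows(180 + d, labs)$label)
  }, 0)
  expect_true(all(diff(counts) >= 0))
  expect_gt(counts[4], counts[1])
})

test_that("the ten window statistics match hand and brute-force values", {
  s <- window_statistics(c(1, 2, 3, 4))
  expect_equal(unname(s[c("mean", "min", "max", "median", "var")]),
               c(2.5, 1, 4, 2.5, 1.25))
  expect_length(s, 10)
  expect_named(s, c("mean", "min", "max", "median", "maxamp", "var", "sd",
                    "absdev", "kurtosis", "skewness"))
  const <- window_statistics(rep(7, 5))
  expect_equal(unname(const[c("var", "sd", "skewness", "kurtosis")]),
               rep(0, 4))
  expect_error(window_statistics(numeric(0)),
               class = "stressfl_empty_window")

  set.seed(17)
  for (i in 1:20) {
    x <- rnorm(sample(3:200, 1), sd = runif(1, 0.1, 10))
    expect_equal(window_statistics(x), oracle_statistics(x),
                 tolerance = 1e-12)
  }
})

test_that("the compiled window-statistics kernel matches the R definition", {
  set.seed(23)
  x <- rnorm(500)
  lo <- as.integer(seq(1, 401, by = 40))
  hi <- as.integer(lo + sample(c(49L, 50L, 99L), length(lo),
                               replace = TRUE))
  mat <- stressfl:::window_stats_cpp(x, lo, hi)
  for (i in seq_along(lo)) {
    expect_equal(unname(mat[i, ]),
                 unname(window_statistics(x[lo[i]:hi[i]])),
                 tolerance = 1e-12)
  }
})

test_that("feature matrices have 420 deterministic, complete columns", {
  rec <- tiny_recording()
  fm <- build_feature_matrix(rec)
  feats <- setdiff(names(fm), c("participant", "window_id", "start_time",
                                "label"))
  expect_length(feats, 420)
  expect_equal(feats, feature_names())
  expect_equal(nrow(fm), (300 - 60) / 0.25 + 1)
  expect_false(anyNA(fm))
  expect_true(all(fm$label %in% 0:1))
  ## bit-stable across rebuilds
  expect_identical(fm, build_feature_matrix(rec))
})

test_that("feature rows agree with statistics computed directly", {
  rec <- tiny_recording()
  fm <- build_feature_matrix(rec)
  sigs <- derive_signals(rec)
  for (nm in c("EDA", "BVP_dwt_1Hz", "ACCnorm_d1", "ST_dwt_2Hz")) {
    sig <- sigs[[nm]]
    for (row in c(1, 57, nrow(fm))) {
      s0 <- fm$start_time[row]
      idx <- which((seq_along(sig$samples) - 1) / sig$rate >= s0 - 1e-9 &
                     (seq_along(sig$samples) - 1) / sig$rate < s0 + 60 - 1e-9)
      want <- window_statistics(sig$samples[idx])
      got <- unlist(fm[row, paste(nm, names(want), sep = "_")])
      expect_equal(unname(got), unname(want), tolerance = 1e-12,
                   info = paste(nm, row))
    }
  }
})

test_that("constant channels propagate zeros into derivative features", {
  rec <- tiny_recording()
  for (ch in names(rec$channels)) {
    rec$channels[[ch]]$samples <- rep(2, length(rec$channels[[ch]]$samples))
  }
  fm <- build_feature_matrix(rec)
  d_cols <- grep("_d[12]_", names(fm), value = TRUE)
  expect_gt(length(d_cols), 0)
  expect_equal(max(abs(as.matrix(fm[d_cols]))), 0)
})
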