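test_that("splits honour the 80:20 ratio and stratification arithmetic", {
  fm <- tibble::tibble(
    participant = 1L, window_id = 1:100, start_time = (1:100) / 4,
    label = rep(c(1L, 0L), c(60, 40)),
    f1 = rnorm(100), f2 = rnorm(100))
  sp <- split_spec(seed = 3)
  out <- split_train_test(fm, sp)
  expect_equal(nrow(out$train), 80)
  expect_equal(nrow(out$test), 20)
  expect_equal(sum(out$test$label == 1), 12)
  expect_equal(sum(out$test$label == 0), 8)
  ## deterministic under the same seed
  out2 <- split_train_test(fm, sp)
  expect_identical(out$test$window_id, out2$test$window_id)
  ## chronological mode takes the final fifth by start time
  chron <- split_train_test(fm, split_spec(mode = "chronological"))
  expect_equal(chron$test$window_id, 81:100)
  ## stratified mode rejects single-class participants
  fm$label <- 1L
  expect_error(split_train_test(fm, sp),
               class = "stressfl_degenerate_labels")
})

test_that("individual learning trains one isolated model per participant", {
  fms <- tiny_cohort_matrices()
  sp <- split_spec(seed = 5)
  res <- run_individual(fms, sp)
  expect_s3_class(res, "strategy_result")
  expect_length(res$models, 3)
  expect_length(res$predictions, 3)
  ## removing other participants changes nothing for participant 1
  solo <- run_individual(fms[1], sp)
  expect_equal(solo$models[["1"]]$weights, res$models[["1"]]$weights)
  expect_identical(solo$predictions[["1"]], res$predictions[["1"]])
  ## cohort of one reduces to fit_batch + predict
  s1 <- split_train_test(fms[[1]], sp)
  feats <- setdiff(names(fms[[1]]),
                   c("participant", "window_id", "start_time", "label"))
  direct <- fit_batch(s1$train[feats], s1$train$label, train_config())
  expect_equal(direct$weights, solo$models[["1"]]$weights)
  expect_equal(predict_label(direct, s1$test[feats]),
               solo$predictions[["1"]]$predicted)
})

test_that("centralized learning pools training rows into one model", {
  fms <- tiny_cohort_matrices()
  sp <- split_spec(seed = 5)
  res <- run_centralized(fms, sp)
  expect_length(res$models, 1)
  expect_length(res$predictions, 3)
  ## pooling a cohort of one equals individual learning on it
  solo_c <- run_centralized(fms[1], sp)
  solo_i <- run_individual(fms[1], sp)
  expect_equal(solo_c$models$global$weights,
               solo_i$models[["1"]]$weights, tolerance = 1e-8)
  expect_equal(solo_c$predictions[["1"]], solo_i$predictions[["1"]])
})

test_that("duplicated participants leave the centralized fit unchanged", {
  ## identical data on every client: the pooled likelihood is a scaled
  ## copy of the single-participant likelihood (same optimum up to the
  ## penalty-to-data ratio, so compare at matched effective strength)
  fms <- tiny_cohort_matrices()
  base <- fms[[1]]
  clone2 <- base; clone2$participant <- 2L
  clone3 <- base; clone3$participant <- 3L
  sp <- split_spec(mode = "chronological")
  single <- run_centralized(list(base), sp,
                            train_config(l2_strength = 1,
                                         tolerance = 1e-9))
  trip <- run_centralized(list(base, clone2, clone3), sp,
                          train_config(l2_strength = 3, tolerance = 1e-9))
  expect_equal(trip$models$global$weights, single$models$global$weights,
               tolerance = 1e-4)
})

test_that("FedAvg aggregation is the count-weighted mean", {
  sc <- list(center = c(0, 0), scale = c(1, 1))
  mk <- function(w, b) lr_model(w, b, sc, c("f1", "f2"))
  ms <- list(mk(c(0, 0), 0), mk(c(4, 4), 2))
  agg <- fedavg_aggregate(ms, c(1, 3))
  expect_equal(agg$weights, c(3, 3))
  expect_equal(agg$intercept, 1.5)
  ## identical clients reproduce themselves; single client passes through
  same <- fedavg_aggregate(list(mk(c(1, 2), 3), mk(c(1, 2), 3)), c(5, 7))
  expect_equal(same$weights, c(1, 2))
  expect_equal(fedavg_aggregate(ms[2], 10)$weights, c(4, 4))
  expect_error(fedavg_aggregate(ms, c(0, 3)),
               class = "stressfl_bad_counts")
  expect_error(
    fedavg_aggregate(list(mk(c(1, 2), 0),
                          lr_model(1, 0, list(center = 0, scale = 1),
                                   "f1")), c(1, 1)),
    class = "stressfl_dim_mismatch")
})

test_that("aggregated weights lie in the convex hull of client weights", {
  set.seed(44)
  sc <- list(center = numeric(4), scale = rep(1, 4))
  for (rep_i in 1:10) {
    k <- sample(2:5, 1)
    ms <- lapply(seq_len(k), function(i) {
      lr_model(rnorm(4), rnorm(1), sc, paste0("f", 1:4))
    })
    cnt <- sample(1:50, k, replace = TRUE)
    agg <- fedavg_aggregate(ms, cnt)
    W <- vapply(ms, `[[`, numeric(4), "weights")
    expect_true(all(agg$weights >= apply(W, 1, min) - 1e-12))
    expect_true(all(agg$weights <= apply(W, 1, max) + 1e-12))
  }
})

test_that("a single federated client converges to its batch fit", {
  d <- random_logistic_data(200, 3, seed = 6)
  fm <- tibble::tibble(participant = 1L, window_id = 1:200,
                       start_time = (1:200) / 4, label = d$y,
                       f1 = d$X[, 1], f2 = d$X[, 2], f3 = d$X[, 3])
  sp <- split_spec(seed = 1)
  cfg <- train_config(l2_strength = 1, learning_rate = 0.5,
                      batch_size = 160, tolerance = 1e-10)
  fed <- run_federated(list(fm), sp,
                       federated_config(rounds = 400, local_epochs = 1,
                                        train = cfg, seed = 2))
  s <- split_train_test(fm, sp)
  batch <- fit_batch(s$train[c("f1", "f2", "f3")], s$train$label, cfg)
  ## the client scaler (pooled = own) matches, so the optima coincide
  expect_lt(sqrt(sum((fed$models$global$weights - batch$weights)^2) +
                   (fed$models$global$intercept - batch$intercept)^2),
            1e-2)
})

test_that("identical full-batch clients take one centralized gradient step", {
  d <- random_logistic_data(100, 3, seed = 13)
  mk_fm <- function(pid) tibble::tibble(
    participant = pid, window_id = 1:100, start_time = (1:100) / 4,
    label = d$y, f1 = d$X[, 1], f2 = d$X[, 2], f3 = d$X[, 3])
  fms <- lapply(1:3, mk_fm)
  sp <- split_spec(mode = "chronological")
  lr <- 0.2
  cfg <- train_config(l2_strength = 0, learning_rate = lr,
                      batch_size = 100)
  fed <- run_federated(fms, sp,
                       federated_config(rounds = 1, local_epochs = 1,
                                        train = cfg, seed = 3))
  ## every client holds the same 80 training rows, so each local update
  ## equals the same single full-batch step from zero weights, and the
  ## average reproduces it: w = lr * Z^T (y - 0.5) / n
  s <- split_train_test(fms[[1]], sp)
  Z <- scale(as.matrix(s$train[c("f1", "f2", "f3")]), center = TRUE,
             scale = FALSE)
  spread <- sqrt(colMeans(Z^2))
  Z <- sweep(Z, 2, spread, "/")
  resid0 <- 0.5 - s$train$label
  expect_equal(fed$models$global$weights,
               unname(-lr * drop(crossprod(Z, resid0)) / nrow(Z)),
               tolerance = 1e-10)
  expect_equal(fed$models$global$intercept, -lr * mean(resid0),
               tolerance = 1e-12)
})

test_that("federated runs are deterministic and clients reveal only models", {
  fms <- tiny_cohort_matrices()
  sp <- split_spec(seed = 9)
  fc <- federated_config(rounds = 3, seed = 11)
  seen <- list()
  cb <- function(round, payloads) seen[[round]] <<- payloads
  r1 <- run_federated(fms, sp, fc, round_callback = cb)
  r2 <- run_federated(fms, sp, fc)
  expect_identical(r1$models$global, r2$models$global)
  expect_identical(r1$predictions, r2$predictions)
  ## privacy contract: payloads carry exactly a model and a count
  expect_length(seen, 3)
  for (round in seen) {
    for (pl in round) {
      expect_setequal(names(pl), c("model", "n"))
      expect_s3_class(pl$model, "lr_model")
      expect_true(is.numeric(pl$n) && length(pl$n) == 1)
    }
  }
  expect_error(federated_config(rounds = 0),
               class = "stressfl_bad_config")
})

test_that("homogeneous cohorts close the centralized-federated gap", {
  ## with zero heterogeneity spread the clients are IID, so the averaged
  ## model should track the pooled-data model closely
  h <- cohort_spreads(st_baseline = c(33, 0), eda_tonic_baseline = c(2, 0),
                      heart_rate_baseline = c(70, 0),
                      stress_effect_scale = c(1, 0), weak_fraction = 0)
  coh <- generate_cohort(3, heterogeneity = h, atypical_fraction = 0,
                         seed = 77, plan = short_plan())
  fms <- lapply(coh, build_feature_matrix)
  sp <- split_spec(seed = 77)
  cen <- evaluate_strategy(run_centralized(fms, sp))
  fed <- evaluate_strategy(run_federated(fms, sp,
                                         federated_config(seed = 77)))
  acc_cen <- cen$rows$accuracy[cen$rows$participant == "Average"]
  acc_fed <- fed$rows$accuracy[fed$rows$participant == "Average"]
  expect_lt(abs(acc_cen - acc_fed), 0.05)
})
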