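## The three learning topologies over a cohort of per-participant feature
## matrices: individual (one model per participant, no data flow),
## centralized (one model on pooled training rows), federated (FedAvg:
## clients exchange only locally updated models and example counts).
## All three are evaluated on identical per-participant test splits.

#' Train/test split specification
#'
#' @param train_fraction Fraction of each participant's windows used for
#'   training (0 < f < 1; default 0.8 for an 80:20 split).
#' @param mode `"stratified_random"` (class proportions preserved within
#'   rounding, seed-deterministic) or `"chronological"` (the final windows
#'   by start time form the test set; overlapping sliding windows make
#'   random splits optimistic, so a leakage-free alternative is provided).
#' @param seed Integer seed for the random mode.
#' @return A `split_spec` list.
#' @export
split_spec <- function(train_fraction = 0.8,
                       mode = c("stratified_random", "chronological"),
                       seed = 1L) {
  stopifnot(train_fraction > 0, train_fraction < 1)
  mode <- match.arg(mode)
  structure(list(train_fraction = train_fraction, mode = mode,
                 seed = as.integer(seed)),
            class = "split_spec")
}

#' Federated learning configuration
#'
#' @param rounds Number of server aggregation rounds (>= 1; default 20).
#' @param local_epochs Local SGD passes per client per round (default 1).
#' @param client_fraction Fraction of clients sampled each round
#'   (0 < f <= 1; default 1: every client participates).
#' @param train A [train_config()] for the local SGD steps.
#' @param seed Integer seed for client sampling and local shuffles.
#' @return A `federated_config` list.
#' @export
federated_config <- function(rounds = 20, local_epochs = 1,
                             client_fraction = 1,
                             train = train_config(), seed = 1L) {
  if (rounds < 1) {
    stop_with("stressfl_bad_config", "rounds must be >= 1")
  }
  stopifnot(local_epochs >= 1, client_fraction > 0, client_fraction <= 1)
  structure(list(rounds = as.integer(rounds),
                 local_epochs = as.integer(local_epochs),
                 client_fraction = client_fraction,
                 train = train, seed = as.integer(seed)),
            class = "federated_config")
}

#' Split one participant's windows into train and test rows
#'
#' Splitting is per participant: for each participant in the matrix, a
#' `train_fraction` share of windows goes to training.  Stratified random
#' mode allocates `round((1 - f) * n_class)` test rows per class;
#' chronological mode takes the final share of windows by start time.
#'
#' @param matrix A feature matrix from [build_feature_matrix()] (may
#'   contain several participants).
#' @param spec A [split_spec()].
#' @return `list(train, test)` of tibbles.
#' @export
split_train_test <- function(matrix, spec = split_spec()) {
  parts <- split(seq_len(nrow(matrix)), matrix$participant)
  test_idx <- integer(0)
  with_seed(spec$seed, {
    for (pid in names(parts)) {
      rows <- parts[[pid]]
      y <- matrix$label[rows]
      if (spec$mode == "stratified_random") {
        if (length(unique(y)) < 2) {
          stop_with("stressfl_degenerate_labels",
                    "participant %s has a single class; %s",
                    pid, "stratified splitting needs both")
        }
        for (cls in unique(y)) {
          cls_rows <- rows[y == cls]
          n_test <- round((1 - spec$train_fraction) * length(cls_rows))
          if (n_test > 0) {
            test_idx <- c(test_idx,
                          sample(cls_rows, n_test))
          }
        }
      } else {
        ord <- rows[order(matrix$start_time[rows])]
        n_test <- round((1 - spec$train_fraction) * length(ord))
        if (n_test > 0) {
          test_idx <- c(test_idx, ord[seq.int(length(ord) - n_test + 1,
                                              length(ord))])
        }
      }
    }
  })
  test_idx <- sort(test_idx)
  if (length(test_idx) == 0) {
    stop_with("stressfl_bad_split", "split leaves no test rows")
  }
  list(train = matrix[-test_idx, , drop = FALSE],
       test = matrix[test_idx, , drop = FALSE])
}

new_strategy_result <- function(strategy, models, predictions) {
  structure(list(strategy = strategy, models = models,
                 predictions = predictions),
            class = "strategy_result")
}

predict_split <- function(model, test) {
  feats <- feature_columns(test)
  tibble::tibble(
    window_id = test$window_id,
    truth = test$label,
    predicted = predict_label(model, test[feats])
  )
}

split_cohort <- function(matrices, spec) {
  lapply(matrices, split_train_test, spec = spec)
}

cohort_ids <- function(matrices) {
  vapply(matrices, function(m) as.character(m$participant[1]), "")
}

#' Individual learning: one model per participant
#'
#' Each participant's model is fitted on that participant's training rows
#' only and evaluated on their own test rows; no data crosses participant
#' boundaries.
#'
#' @param matrices List of per-participant feature matrices.
#' @param split A [split_spec()].
#' @param config A [train_config()].
#' @return A `strategy_result` with one model and one prediction set per
#'   participant.
#' @export
run_individual <- function(matrices, split = split_spec(),
                           config = train_config()) {
  ids <- cohort_ids(matrices)
  splits <- split_cohort(matrices, split)
  models <- list()
  preds <- list()
  for (i in seq_along(matrices)) {
    pid <- ids[i]
    feats <- feature_columns(splits[[i]]$train)
    model <- tryCatch(
      fit_batch(splits[[i]]$train[feats], splits[[i]]$train$label, config),
      stressfl_degenerate_labels = function(e) {
        stop_with("stressfl_degenerate_labels",
                  "participant %s: %s", pid, conditionMessage(e))
      })
    models[[pid]] <- model
    preds[[pid]] <- predict_split(model, splits[[i]]$test)
  }
  new_strategy_result("individual", models, preds)
}

#' Centralized learning: one model on pooled data
#'
#' Splits per participant first (so all strategies share test rows), pools
#' every participant's training rows, fits a single model, and evaluates
#' it on each participant's test rows.
#'
#' @inheritParams run_individual
#' @return A `strategy_result` with one global model and per-participant
#'   predictions.
#' @export
run_centralized <- function(matrices, split = split_spec(),
                            config = train_config()) {
  ids <- cohort_ids(matrices)
  splits <- split_cohort(matrices, split)
  pooled <- do.call(rbind, lapply(splits, `[[`, "train"))
  feats <- feature_columns(pooled)
  model <- fit_batch(pooled[feats], pooled$label, config)
  preds <- list()
  for (i in seq_along(matrices)) {
    preds[[ids[i]]] <- predict_split(model, splits[[i]]$test)
  }
  new_strategy_result("centralized", list(global = model), preds)
}

#' Federated averaging of client models
#'
#' The server replaces the global weights and intercept with the
#' client-example-count-weighted arithmetic mean of the locally updated
#' models: `w_global = sum_k (n_k / sum(n)) w_k`.
#'
#' @param client_models List of `lr_model`s sharing dimension and scaler.
#' @param client_counts Positive integer example counts, one per client.
#' @return The aggregated `lr_model`.
#' @export
fedavg_aggregate <- function(client_models, client_counts) {
  stopifnot(length(client_models) == length(client_counts))
  if (any(client_counts <= 0)) {
    stop_with("stressfl_bad_counts", "client counts must be positive")
  }
  dims <- vapply(client_models, function(m) length(m$weights), 0L)
  if (length(unique(dims)) != 1) {
    stop_with("stressfl_dim_mismatch", "client models differ in dimension")
  }
  ref <- client_models[[1]]$scaler
  for (m in client_models[-1]) {
    if (max(abs(m$scaler$center - ref$center),
            abs(m$scaler$scale - ref$scale)) > 1e-8) {
      stop_with("stressfl_scaler_mismatch",
                "client models must share the global scaler")
    }
  }
  wts <- client_counts / sum(client_counts)
  w <- Reduce(`+`, Map(function(m, a) a * m$weights, client_models, wts))
  b <- sum(vapply(client_models, `[[`, 0, "intercept") * wts)
  lr_model(w, b, ref, client_models[[1]]$feature_names)
}

#' Federated learning via simulated FedAvg
#'
#' The server initializes a zero-weight global model with a scaler pooled
#' from per-client feature moments (no raw rows cross the client
#' boundary), then for each round every sampled client runs
#' [fit_local_sgd()] from the current global model on its own training
#' rows and returns only `(model, n)`; the server aggregates with
#' [fedavg_aggregate()].  The final global model is evaluated on each
#' participant's test rows.
#'
#' @inheritParams run_individual
#' @param fed_config A [federated_config()].
#' @param round_callback Optional `function(round, payloads)` observing
#'   exactly what clients transmit each round (used to audit the privacy
#'   contract).
#' @return A `strategy_result` with the final global model and
#'   per-participant predictions.
#' @export
run_federated <- function(matrices, split = split_spec(),
                          fed_config = federated_config(),
                          round_callback = NULL) {
  ids <- cohort_ids(matrices)
  splits <- split_cohort(matrices, split)
  feats <- feature_columns(splits[[1]]$train)
  cfg <- fed_config$train

  ## Clients expose only moments (for the broadcast scaler) and
  ## (model, n) payloads; the server closure never touches rows.
  clients <- lapply(seq_along(matrices), function(i) {
    X <- as_feature_matrix(splits[[i]]$train[feats])
    y <- splits[[i]]$train$label
    check_binary(y)
    list(
      moments = function() client_moments(X),
      update = function(global, round_seed) {
        local_cfg <- cfg
        local_cfg$local_epochs <- fed_config$local_epochs
        local_cfg$seed <- round_seed
        fit <- fit_local_sgd(global, X, y, local_cfg)
        list(model = fit$model, n = fit$n)
      }
    )
  })

  scaler <- pool_scalers(lapply(clients, function(cl) cl$moments()),
                         cfg$standardize)
  global <- lr_model(numeric(length(feats)), 0, scaler, feats)

  n_clients <- length(clients)
  n_sample <- max(1, round(fed_config$client_fraction * n_clients))
  for (r in seq_len(fed_config$rounds)) {
    chosen <- if (n_sample == n_clients) seq_len(n_clients) else
      with_seed(fed_config$seed * 1000L + r, sample.int(n_clients, n_sample))
    payloads <- lapply(seq_along(chosen), function(j) {
      round_seed <- fed_config$seed + 7919L * r + chosen[j]
      clients[[chosen[j]]]$update(global, round_seed)
    })
    if (!is.null(round_callback)) round_callback(r, payloads)
    global <- fedavg_aggregate(lapply(payloads, `[[`, "model"),
                               vapply(payloads, `[[`, 0, "n"))
  }

  preds <- list()
  for (i in seq_along(matrices)) {
    preds[[ids[i]]] <- predict_split(global, splits[[i]]$test)
  }
  new_strategy_result("federated", list(global = global), preds)
}
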