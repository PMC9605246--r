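## L2-regularized binary logistic regression, written out in full because
## the federated strategy needs direct access to weights, gradients and
## local-epoch SGD updates.  Objective (batch fitting):
##
##   f(w, b) = sum_i [log(1 + exp(eta_i)) - y_i * eta_i] + lambda/2 ||w||^2
##
## with eta = Z w + b on standardized features Z; the intercept is not
## penalized.  fit_batch minimizes f by damped Newton (step-halving line
## search, so the loss history is monotone); fit_local_sgd takes
## mini-batch gradient steps on the per-example-mean of the same
## objective, which shares its stationary point.

#' Training configuration
#'
#' @param l2_strength Non-negative L2 penalty `lambda` (default 1,
#'   matching the common unit-inverse-regularization library default).
#' @param max_iterations Newton iteration cap for [fit_batch()].
#' @param tolerance Convergence threshold on the infinity norm of the
#'   per-example-mean gradient.
#' @param learning_rate Step size for [fit_local_sgd()].
#' @param local_epochs Number of local passes in [fit_local_sgd()].
#' @param batch_size Mini-batch size for [fit_local_sgd()].
#' @param seed Seed for the mini-batch shuffle.
#' @param standardize Standardize features from the training pool
#'   (default TRUE; stored in the model so prediction reuses it).
#' @return A `train_config` list.
#' @export
train_config <- function(l2_strength = 1, max_iterations = 100,
                         tolerance = 1e-6, learning_rate = 0.1,
                         local_epochs = 1, batch_size = 32, seed = 1L,
                         standardize = TRUE) {
  stopifnot(l2_strength >= 0, max_iterations > 0, tolerance > 0,
            learning_rate >= 0, local_epochs >= 0, batch_size > 0)
  structure(list(l2_strength = l2_strength,
                 max_iterations = max_iterations,
                 tolerance = tolerance,
                 learning_rate = learning_rate,
                 local_epochs = local_epochs,
                 batch_size = batch_size,
                 seed = as.integer(seed),
                 standardize = standardize),
            class = "train_config")
}

#' Construct a logistic model object
#'
#' @param weights Numeric weight vector (standardized-feature scale).
#' @param intercept Scalar intercept.
#' @param scaler List with `center` and `scale` vectors (a feature with
#'   zero spread gets scale 1 and, after centering, contributes 0).
#' @param feature_names Character vector naming the weight entries.
#' @return An `lr_model` object.
#' @export
lr_model <- function(weights, intercept, scaler, feature_names) {
  stopifnot(length(weights) == length(feature_names),
            length(scaler$center) == length(weights),
            length(scaler$scale) == length(weights),
            all(scaler$scale > 0))
  structure(list(weights = as.numeric(weights),
                 intercept = as.numeric(intercept),
                 scaler = list(center = as.numeric(scaler$center),
                               scale = as.numeric(scaler$scale)),
                 feature_names = as.character(feature_names)),
            class = "lr_model")
}

## Population-sd standardizer fitted from a training matrix.
fit_scaler <- function(X, standardize = TRUE) {
  p <- ncol(X)
  if (!standardize) {
    return(list(center = numeric(p), scale = rep(1, p)))
  }
  ctr <- colMeans(X)
  spread <- sqrt(colMeans(sweep(X, 2, ctr)^2))
  spread[spread <= 0] <- 1
  list(center = ctr, scale = spread)
}

apply_scaler <- function(X, scaler) {
  sweep(sweep(X, 2, scaler$center), 2, scaler$scale, "/")
}

## Pool per-client first/second moments into one cohort scaler without
## any raw rows leaving the clients (used by the federated strategy).
pool_scalers <- function(moments, standardize = TRUE) {
  p <- length(moments[[1]]$mean)
  if (!standardize) {
    return(list(center = numeric(p), scale = rep(1, p)))
  }
  n_tot <- sum(vapply(moments, `[[`, 0, "n"))
  grand <- Reduce(`+`, lapply(moments, function(m) m$n * m$mean)) / n_tot
  second <- Reduce(`+`, lapply(moments, function(m) {
    m$n * (m$var + m$mean^2)
  })) / n_tot
  spread <- sqrt(pmax(second - grand^2, 0))
  spread[spread <= 0] <- 1
  list(center = grand, scale = spread)
}

client_moments <- function(X) {
  ctr <- colMeans(X)
  list(n = nrow(X), mean = ctr, var = colMeans(sweep(X, 2, ctr)^2))
}

## Coerce features to a numeric matrix in the model's column order.
as_feature_matrix <- function(features, feature_names = NULL) {
  if (is.data.frame(features)) {
    if (!is.null(feature_names)) {
      missing_f <- setdiff(feature_names, names(features))
      if (length(missing_f) > 0) {
        stop_with("stressfl_dim_mismatch",
                  "features lack %d model column(s)", length(missing_f))
      }
      features <- features[feature_names]
    }
    features <- as.matrix(features)
  }
  if (is.null(dim(features))) features <- matrix(features, nrow = 1)
  storage.mode(features) <- "double"
  features
}

#' Predicted stress probabilities
#'
#' Standardizes the input with the model's stored scaler and applies the
#' logistic function to `Z w + b`; numerically stable for extreme logits.
#'
#' @param model An `lr_model`.
#' @param features Numeric matrix/row, or a data frame containing the
#'   model's feature columns.
#' @return Probabilities in (0, 1).
#' @export
predict_proba <- function(model, features) {
  X <- as_feature_matrix(features, model$feature_names)
  if (ncol(X) != length(model$weights)) {
    stop_with("stressfl_dim_mismatch",
              "feature dimension %d does not match model dimension %d",
              ncol(X), length(model$weights))
  }
  Z <- apply_scaler(X, model$scaler)
  eta <- drop(Z %*% model$weights) + model$intercept
  ## clamp away from exactly 0/1 so extreme logits keep finite log-loss
  pmin(pmax(plogis(eta), 1e-15), 1 - 1e-15)
}

#' Predicted binary labels
#'
#' Label 1 (stress) when the predicted probability is at or above the
#' threshold; the 0.5 boundary goes to stress.
#'
#' @inheritParams predict_proba
#' @param threshold Decision threshold (default 0.5).
#' @return Integer vector of 0/1 labels.
#' @export
predict_label <- function(model, features, threshold = 0.5) {
  as.integer(predict_proba(model, features) >= threshold)
}

## Objective and gradient on standardized features Za = [Z 1].
lr_loss <- function(theta, Za, y, lambda) {
  eta <- drop(Za %*% theta)
  p <- length(theta) - 1
  ## log(1 + exp(eta)) - y*eta, stably
  sum(pmax(eta, 0) + log1p(exp(-abs(eta))) - y * eta) +
    lambda / 2 * sum(theta[seq_len(p)]^2)
}

lr_grad <- function(theta, Za, y, lambda) {
  pr <- plogis(drop(Za %*% theta))
  g <- drop(crossprod(Za, pr - y))
  p <- length(theta) - 1
  g[seq_len(p)] <- g[seq_len(p)] + lambda * theta[seq_len(p)]
  g
}

check_binary <- function(y) {
  if (!all(y %in% c(0L, 1L))) {
    stop_with("stressfl_bad_labels", "labels must be 0/1")
  }
  if (length(unique(y)) < 2) {
    stop_with("stressfl_degenerate_labels",
              "training labels contain a single class")
  }
}

#' Batch fit by damped Newton iteration
#'
#' Minimizes the L2-regularized negative log-likelihood to within
#' `config$tolerance` on the per-example-mean gradient infinity norm.
#' The standardizer is fitted from the training features and stored in the
#' model; a step-halving line search makes the recorded loss history
#' monotone non-increasing.
#'
#' @param features Numeric matrix or data frame of training features.
#' @param labels Binary 0/1 vector (1 = stress); both classes required.
#' @param config A [train_config()].
#' @return An `lr_model` with attributes `loss_history` and `converged`.
#' @export
fit_batch <- function(features, labels, config = train_config()) {
  X <- as_feature_matrix(features)
  y <- as.integer(labels)
  stopifnot(nrow(X) == length(y))
  if (any(!is.finite(X))) {
    stop_with("stressfl_bad_features", "features must be finite")
  }
  check_binary(y)
  n <- nrow(X)
  p <- ncol(X)
  scaler <- fit_scaler(X, config$standardize)
  Za <- cbind(apply_scaler(X, scaler), 1)
  lambda <- config$l2_strength
  theta <- numeric(p + 1)
  loss <- lr_loss(theta, Za, y, lambda)
  history <- loss
  converged <- FALSE
  for (it in seq_len(config$max_iterations)) {
    eta <- drop(Za %*% theta)
    pr <- plogis(eta)
    g <- drop(crossprod(Za, pr - y))
    g[seq_len(p)] <- g[seq_len(p)] + lambda * theta[seq_len(p)]
    if (max(abs(g)) / n < config$tolerance) {
      converged <- TRUE
      break
    }
    wgt <- pmax(pr * (1 - pr), 1e-10)
    H <- crossprod(Za, Za * wgt)
    diag(H)[seq_len(p)] <- diag(H)[seq_len(p)] + lambda
    diag(H) <- diag(H) + 1e-10
    step <- solve(H, g)
    ## step halving keeps the objective monotone
    t_step <- 1
    repeat {
      cand <- theta - t_step * step
      new_loss <- lr_loss(cand, Za, y, lambda)
      if (new_loss <= loss + 1e-12 || t_step < 1e-8) break
      t_step <- t_step / 2
    }
    theta <- cand
    loss <- new_loss
    history <- c(history, loss)
  }
  model <- lr_model(theta[seq_len(p)], theta[p + 1], scaler,
                    colnames(X) %||% paste0("x", seq_len(p)))
  attr(model, "loss_history") <- history
  attr(model, "converged") <- converged
  model
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Local mini-batch SGD from a starting model
#'
#' Runs `config$local_epochs` shuffled passes of mini-batch gradient
#' descent on the per-example-mean regularized log-loss, starting from
#' `start`'s weights and keeping `start`'s (global) scaler unchanged --
#' the update a federated client performs on its own rows.  Deterministic
#' under `config$seed`.
#'
#' @param start An `lr_model` providing the initial weights and the shared
#'   scaler.
#' @param features,labels Local training rows (both classes required).
#' @param config A [train_config()].
#' @return `list(model, n)`: the updated model and the local example
#'   count.
#' @export
fit_local_sgd <- function(start, features, labels, config = train_config()) {
  X <- as_feature_matrix(features, start$feature_names)
  y <- as.integer(labels)
  stopifnot(nrow(X) == length(y))
  check_binary(y)
  if (ncol(X) != length(start$weights)) {
    stop_with("stressfl_dim_mismatch", "start model dimension mismatch")
  }
  n <- nrow(X)
  Z <- apply_scaler(X, start$scaler)
  w <- start$weights
  b <- start$intercept
  lambda <- config$l2_strength
  lr <- config$learning_rate
  if (config$local_epochs > 0 && lr > 0) {
    with_seed(config$seed, {
      for (ep in seq_len(config$local_epochs)) {
        ord <- sample.int(n)
        batches <- split(ord, ceiling(seq_along(ord) / config$batch_size))
        for (idx in batches) {
          Zb <- Z[idx, , drop = FALSE]
          pr <- plogis(drop(Zb %*% w) + b)
          resid <- pr - y[idx]
          gw <- drop(crossprod(Zb, resid)) / length(idx) + (lambda / n) * w
          gb <- mean(resid)
          w <- w - lr * gw
          b <- b - lr * gb
        }
      }
    })
  }
  model <- lr_model(w, b, start$scaler, start$feature_names)
  list(model = model, n = n)
}

#' Serialize a model to JSON
#'
#' Writes weights, intercept, scaler and feature names (plus an optional
#' config echo) at full double precision; [model_from_json()] restores the
#' model losslessly.
#'
#' @param model An `lr_model`.
#' @param path Output file path.
#' @param config Optional [train_config()] echoed into the document.
#' @return `path`, invisibly.
#' @export
model_to_json <- function(model, path, config = NULL) {
  doc <- list(weights = model$weights,
              intercept = model$intercept,
              scaler = model$scaler,
              feature_names = model$feature_names)
  if (!is.null(config)) doc$config <- unclass(config)
  ## 17 significant digits round-trip IEEE doubles exactly
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = I(17),
                       pretty = TRUE)
  invisible(path)
}

#' @rdname model_to_json
#' @export
model_from_json <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  lr_model(doc$weights, doc$intercept, doc$scaler, doc$feature_names)
}
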