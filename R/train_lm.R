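#' Levenberg-Marquardt training configuration
#'
#' The damping parameter lambda interpolates between Gauss-Newton (small
#' lambda) and small-step gradient descent (large lambda). After an accepted
#' step lambda is multiplied by `lambda_decrease`; a rejected step multiplies
#' it by `lambda_increase` and the step is retried within the same epoch.
#'
#' @param lambda0 Initial damping (default 0.001).
#' @param lambda_decrease Factor applied after an accepted step (default 0.1).
#' @param lambda_increase Factor applied after a rejected step (default 10).
#' @param max_epochs Maximum accepted steps (default 1000).
#' @param patience Consecutive epochs without validation improvement before
#'   stopping (default 6).
#' @param lambda_max Damping above which training stops (default 1e10).
#' @param seed Integer seed controlling weight initialization.
#' @return A `training_config` list.
#' @export
training_config <- function(lambda0 = 0.001, lambda_decrease = 0.1,
                            lambda_increase = 10, max_epochs = 1000,
                            patience = 6, lambda_max = 1e10, seed = 1L) {
  stopifnot(lambda0 > 0, lambda_decrease > 0, lambda_decrease < 1,
            lambda_increase > 1, max_epochs >= 1, patience >= 1, lambda_max > 0)
  structure(list(lambda0 = lambda0, lambda_decrease = lambda_decrease,
                 lambda_increase = lambda_increase,
                 max_epochs = as.integer(max_epochs),
                 patience = as.integer(patience), lambda_max = lambda_max,
                 seed = as.integer(seed)),
            class = "training_config")
}

#' Train an MLP one-step predictor with Levenberg-Marquardt
#'
#' Full-batch damped Gauss-Newton on the sum of squared TRAIN residuals: each
#' epoch computes the Jacobian of the network output by backpropagation and
#' solves `(J'J + lambda I) delta = J'r`. A candidate step is accepted only if
#' it reduces the TRAIN SSE, so the accepted-step SSE sequence is
#' non-increasing by construction. Validation MSE is monitored every epoch;
#' the weights with the best validation error are returned (early stopping
#' with the configured patience).
#'
#' @param data A `windowed_dataset` (>= 10 TRAIN pairs).
#' @param tconfig A [training_config].
#' @param hidden Number of hidden units (default 10).
#' @return A trained `mlp_model` with attributes filled in: `norm_stats` from
#'   the dataset, and a `trace` element: data.frame of per-epoch `lambda`,
#'   `train_sse`, `val_mse`, plus `stop_reason` and `epochs`.
#' @export
train_lm <- function(data, tconfig = training_config(), hidden = 10) {
  stopifnot(inherits(data, "windowed_dataset"), inherits(tconfig, "training_config"))
  tr <- subset_pairs(data, "TRAIN")
  va <- subset_pairs(data, "VAL")
  if (nrow(tr$X) < 10L) stop("need at least 10 TRAIN pairs, got ", nrow(tr$X))
  if (nrow(va$X) < 1L) stop("need at least 1 VAL pair for early stopping")

  model <- mlp_model(k = data$k, hidden = hidden, seed = tconfig$seed)
  theta <- pack_params(model)
  p <- length(theta)
  lambda <- tconfig$lambda0

  sse_of <- function(th) {
    r <- tr$y - mlp_forward(unpack_params(model, th), tr$X)
    sum(r * r)
  }
  val_mse_of <- function(th) {
    r <- va$y - mlp_forward(unpack_params(model, th), va$X)
    mean(r * r)
  }

  sse <- sse_of(theta)
  if (!is.finite(sse)) stop("non-finite training loss at initialization")
  best_theta <- theta
  best_val <- val_mse_of(theta)
  bad_epochs <- 0L
  stop_reason <- "max_epochs"
  trace <- vector("list", tconfig$max_epochs)
  epoch <- 0L

  while (epoch < tconfig$max_epochs) {
    epoch <- epoch + 1L
    jb <- mlp_jacobian(unpack_params(model, theta), tr$X)
    r <- tr$y - jb$yhat
    JtJ <- crossprod(jb$J)
    Jtr <- crossprod(jb$J, r)
    accepted <- FALSE
    while (!accepted) {
      delta <- tryCatch(
        solve(JtJ + diag(lambda, p), Jtr),
        error = function(e) NULL  # degenerate normal equations: damp harder
      )
      if (!is.null(delta)) {
        cand <- theta + as.numeric(delta)
        sse_cand <- sse_of(cand)
        if (is.finite(sse_cand) && sse_cand < sse) {
          theta <- cand
          sse <- sse_cand
          lambda <- lambda * tconfig$lambda_decrease
          accepted <- TRUE
          break
        }
      }
      lambda <- lambda * tconfig$lambda_increase
      if (lambda > tconfig$lambda_max) break
    }
    if (!accepted) {
      stop_reason <- "lambda_max"
      epoch <- epoch - 1L
      break
    }
    val <- val_mse_of(theta)
    trace[[epoch]] <- c(lambda = lambda, train_sse = sse, val_mse = val)
    if (is.finite(val) && val < best_val) {
      best_val <- val
      best_theta <- theta
      bad_epochs <- 0L
    } else {
      bad_epochs <- bad_epochs + 1L
      if (bad_epochs >= tconfig$patience) {
        stop_reason <- "patience"
        break
      }
    }
  }

  out <- unpack_params(model, best_theta)
  out$norm_stats <- data$norm_stats
  tr_df <- as.data.frame(do.call(rbind, trace[seq_len(epoch)]))
  out$trace <- list(epochs = epoch, stop_reason = stop_reason,
                    history = tr_df, best_val_mse = best_val)
  out
}

#' Evaluate a trained model on the test split
#'
#' Predictions are de-normalized back to sample units before errors are
#' computed; only TEST pairs (never used during training or validation) enter
#' the record. Errors follow the convention `error = true - predicted`, so a
#' positive error means the next interval was underestimated.
#'
#' @param model A trained `mlp_model`.
#' @param data The `windowed_dataset` the model was trained on.
#' @return An `error_record`: list with `signed_errors` and `abs_errors` in
#'   sample units, and `predictions`/`truth` (de-normalized).
#' @export
evaluate <- function(model, data) {
  stopifnot(inherits(model, "mlp_model"), inherits(data, "windowed_dataset"))
  te <- subset_pairs(data, "TEST")
  if (nrow(te$X) == 0L) stop("dataset has no TEST pairs")
  m <- data$norm_stats[["mean"]]; s <- data$norm_stats[["sd"]]
  pred <- mlp_forward(model, te$X) * s + m
  truth <- te$y * s + m
  signed <- truth - pred
  structure(list(signed_errors = signed, abs_errors = abs(signed),
                 predictions = pred, truth = truth, unit_ms = data$unit_ms),
            class = "error_record")
}

#' @export
print.error_record <- function(x, ...) {
  cat(sprintf("<error_record> %d TEST errors: mean |e| = %.3f samples (%.1f ms), mean signed = %+.3f\n",
              length(x$signed_errors), mean(x$abs_errors),
              mean(x$abs_errors) * x$unit_ms, mean(x$signed_errors)))
  invisible(x)
}

#' Serialize a model to a plain-text JSON file
#'
#' Stores shapes, flat weight vectors and normalization statistics so a run
#' can be reproduced or a model re-used without retraining.
#'
#' @param model An `mlp_model`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_model <- function(model, path) {
  stopifnot(inherits(model, "mlp_model"))
  obj <- list(
    architecture = list(k = model$k, hidden = model$hidden,
                        hidden_activation = "tanh", output_activation = "linear"),
    weights = list(W1 = as.numeric(t(model$W1)), b1 = model$b1,
                   w2 = model$w2, b2 = model$b2),
    norm_stats = as.list(model$norm_stats)
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read a model written by [write_model]
#'
#' @param path Path to the JSON weight file.
#' @return An `mlp_model`.
#' @export
read_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  k <- obj$architecture$k; H <- obj$architecture$hidden
  model <- mlp_model(k = k, hidden = H, seed = 1L)
  model <- unpack_params(model, c(obj$weights$W1, obj$weights$b1,
                                  obj$weights$w2, obj$weights$b2))
  model$norm_stats <- c(mean = obj$norm_stats$mean, sd = obj$norm_stats$sd)
  model
}
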