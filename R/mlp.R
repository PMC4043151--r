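# Feed-forward network k -> H (tanh) -> 1 (linear), parameterized as a flat
# vector for damped Gauss-Newton updates: c(W1 (H x k, row-major by hidden
# unit), b1 (H), w2 (H), b2 (1)).

#' Construct an MLP model
#'
#' A single-hidden-layer perceptron with tanh hidden units and a linear output,
#' the standard function-approximation architecture for least-squares trained
#' networks.
#'
#' @param k Number of inputs (window length).
#' @param hidden Number of hidden units (default 10).
#' @param seed Integer seed for weight initialization.
#' @return An `mlp_model`: list with `W1` (hidden x k), `b1`, `w2`, `b2`, `k`,
#'   `hidden`, and `norm_stats` (filled in by training).
#' @export
mlp_model <- function(k = 10, hidden = 10, seed = 1L) {
  stopifnot(k >= 1, hidden >= 1)
  set.seed(seed)
  # uniform [-0.5, 0.5] scaled by 1/sqrt(fan-in)
  W1 <- matrix(stats::runif(hidden * k, -0.5, 0.5) / sqrt(k), hidden, k)
  b1 <- stats::runif(hidden, -0.5, 0.5) / sqrt(k)
  w2 <- stats::runif(hidden, -0.5, 0.5) / sqrt(hidden)
  b2 <- stats::runif(1, -0.5, 0.5) / sqrt(hidden)
  structure(list(W1 = W1, b1 = b1, w2 = w2, b2 = b2, k = as.integer(k),
                 hidden = as.integer(hidden),
                 norm_stats = c(mean = 0, sd = 1)),
            class = "mlp_model")
}

#' @export
print.mlp_model <- function(x, ...) {
  cat(sprintf("<mlp_model> %d-%d-1 (tanh hidden, linear output), %d parameters\n",
              x$k, x$hidden, n_params(x)))
  invisible(x)
}

n_params <- function(model) {
  model$hidden * model$k + model$hidden + model$hidden + 1L
}

pack_params <- function(model) {
  c(as.numeric(t(model$W1)), model$b1, model$w2, model$b2)
}

unpack_params <- function(model, theta) {
  k <- model$k; H <- model$hidden
  model$W1 <- matrix(theta[seq_len(H * k)], H, k, byrow = TRUE)
  off <- H * k
  model$b1 <- theta[off + seq_len(H)]
  model$w2 <- theta[off + H + seq_len(H)]
  model$b2 <- theta[off + 2L * H + 1L]
  model
}

#' Forward pass of an MLP
#'
#' @param model An `mlp_model`.
#' @param X Input matrix, one window per row (in the model's normalized space).
#' @return Numeric vector of outputs.
#' @export
mlp_forward <- function(model, X) {
  Z <- tanh(sweep(X %*% t(model$W1), 2L, model$b1, "+"))
  as.numeric(Z %*% model$w2 + model$b2)
}

# Jacobian of the network output wrt the flat parameter vector, by
# backpropagation; rows are observations, columns follow pack_params order.
mlp_jacobian <- function(model, X) {
  n <- nrow(X); k <- model$k; H <- model$hidden
  A <- sweep(X %*% t(model$W1), 2L, model$b1, "+")
  Z <- tanh(A)
  G <- (1 - Z^2) * matrix(model$w2, n, H, byrow = TRUE)  # d out / d a_j
  J <- matrix(0, n, H * k + 2L * H + 1L)
  for (j in seq_len(H)) {
    J[, (j - 1L) * k + seq_len(k)] <- G[, j] * X       # d out / d W1[j, ]
  }
  J[, H * k + seq_len(H)] <- G                          # d out / d b1
  J[, H * k + H + seq_len(H)] <- Z                      # d out / d w2
  J[, H * k + 2L * H + 1L] <- 1                         # d out / d b2
  list(J = J, yhat = as.numeric(Z %*% model$w2 + model$b2))
}
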