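#' Initialize a permutation-invariant Deep Sets aggregation model
#'
#' The aggregator is `f(X) = rho(sum_m phi(x_m))`: a per-cell encoder `phi`
#' (one fully connected layer of `phi_dim` units with leaky ReLU), sum pooling
#' over the cell dimension, and a projection `rho` of two fully connected
#' layers (`hidden_dim` then `out_dim` units, each with leaky ReLU). Weights
#' and biases are drawn from the uniform fan-in scheme
#' `U(-1/sqrt(fan_in), 1/sqrt(fan_in))` under the recorded seed.
#'
#' Sum pooling (not mean) is used, so the pooled representation scales with
#' the number of cells; the training augmentation's variable set sizes expose
#' the model to that variation.
#'
#' @param D Number of input features per cell.
#' @param phi_dim,hidden_dim,out_dim Layer widths; defaults 2048, 512, 2048.
#' @param leaky_slope Negative-region slope of the leaky ReLU.
#' @param feature_names Optional feature-name vector bound to the model.
#' @param seed Integer seed for weight initialization (recorded on the model).
#' @return An object of class `set_model`.
#' @export
set_model <- function(D, phi_dim = 2048, hidden_dim = 512, out_dim = 2048,
                      leaky_slope = 0.01, feature_names = NULL, seed = 1L) {
  stopifnot(D >= 1, phi_dim >= 1, hidden_dim >= 1, out_dim >= 1)
  if (!is.null(feature_names) && length(feature_names) != D)
    stop("feature_names length must equal D", call. = FALSE)
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
  set.seed(seed)
  init <- function(n_in, n_out) {
    b <- 1 / sqrt(n_in)
    list(W = matrix(runif(n_in * n_out, -b, b), n_in, n_out),
         b = runif(n_out, -b, b))
  }
  l1 <- init(D, phi_dim)
  l2 <- init(phi_dim, hidden_dim)
  l3 <- init(hidden_dim, out_dim)
  if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv)
  structure(list(D = D, phi_dim = phi_dim, hidden_dim = hidden_dim,
                 out_dim = out_dim, leaky_slope = leaky_slope,
                 feature_names = feature_names, init_seed = as.integer(seed),
                 W1 = l1$W, b1 = l1$b, W2 = l2$W, b2 = l2$b,
                 W3 = l3$W, b3 = l3$b),
            class = "set_model")
}

#' @export
print.set_model <- function(x, ...) {
  cat(sprintf(
    "<set_model> phi: %d -> %d, pool: sum, rho: %d -> %d -> %d (leaky slope %g)\n",
    x$D, x$phi_dim, x$phi_dim, x$hidden_dim, x$out_dim, x$leaky_slope))
  invisible(x)
}

as_feature_matrix <- function(x) {
  if (inherits(x, "cell_table")) x$features else as.matrix(x)
}

#' Per-cell encoder activations
#'
#' Applies `phi` to every cell row independently:
#' `leakyReLU(x_m W + b)`.
#'
#' @param model A [set_model()].
#' @param x A [cell_table()] or cells x features matrix.
#' @return Cells x `phi_dim` activation matrix.
#' @export
phi_forward <- function(model, x) {
  X <- as_feature_matrix(x)
  if (ncol(X) != model$D)
    stop("input has ", ncol(X), " features but model expects ", model$D,
         call. = FALSE)
  A1 <- sweep(X %*% model$W1, 2, model$b1, "+")
  leaky_relu(A1, model$leaky_slope)
}

#' Sum-pool per-cell activations into a set representation
#'
#' @param activations Cells x `phi_dim` matrix from [phi_forward()].
#' @return Numeric vector `z` of length `phi_dim`, invariant to row order.
#' @export
aggregate_cells <- function(activations) {
  activations <- as.matrix(activations)
  if (nrow(activations) < 1) stop("cannot pool an empty set", call. = FALSE)
  colSums(activations)
}

# Full forward pass for one set, optionally retaining intermediates for
# backpropagation. Internal; forward() is the public surface.
forward_set <- function(model, x, keep_cache = FALSE) {
  X <- as_feature_matrix(x)
  if (ncol(X) != model$D)
    stop("input has ", ncol(X), " features but model expects ", model$D,
         call. = FALSE)
  if (nrow(X) < 1) stop("cannot aggregate an empty set", call. = FALSE)
  s <- model$leaky_slope
  A1 <- sweep(X %*% model$W1, 2, model$b1, "+")
  H1 <- leaky_relu(A1, s)
  z <- colSums(H1)
  A2 <- drop(z %*% model$W2) + model$b2
  H2 <- leaky_relu(A2, s)
  A3 <- drop(H2 %*% model$W3) + model$b3
  v <- leaky_relu(A3, s)
  if (!keep_cache) return(v)
  list(v = v, X = X, A1 = A1, H1 = H1, z = z, A2 = A2, H2 = H2, A3 = A3)
}

#' Aggregate one well into a learned profile
#'
#' `forward(model, X) = rho(sum_m phi(x_m))`; permutation invariant in the
#' cells, defined for any set size `M >= 1`.
#'
#' @inheritParams phi_forward
#' @return Numeric profile vector of length `out_dim`.
#' @export
forward <- function(model, x) {
  forward_set(model, x, keep_cache = FALSE)
}

# Backward pass through one set given the gradient dv at the output.
# Returns parameter gradients and, when want_input, the gradient with
# respect to the input cell matrix (needed for sensitivity analysis).
backward_set <- function(model, cache, dv, want_input = FALSE) {
  s <- model$leaky_slope
  dA3 <- dv * leaky_relu_grad(cache$A3, s)
  dW3 <- outer(cache$H2, dA3)
  db3 <- dA3
  dH2 <- drop(model$W3 %*% dA3)
  dA2 <- dH2 * leaky_relu_grad(cache$A2, s)
  dW2 <- outer(cache$z, dA2)
  db2 <- dA2
  dz <- drop(model$W2 %*% dA2)
  # sum pooling broadcasts dz to every cell row
  dA1 <- leaky_relu_grad(cache$A1, s) *
    matrix(dz, nrow(cache$A1), length(dz), byrow = TRUE)
  dW1 <- crossprod(cache$X, dA1)
  db1 <- colSums(dA1)
  out <- list(W1 = dW1, b1 = db1, W2 = dW2, b2 = db2, W3 = dW3, b3 = db3)
  if (want_input) out$X <- tcrossprod(dA1, model$W1)
  out
}

#' Save / load a model checkpoint
#'
#' The checkpoint is a single file holding the weights, input dimension,
#' feature names, activation slope and the training configuration, written
#' with [saveRDS()] so that a load round-trips bit-exactly.
#'
#' @param model A [set_model()] (or a training result list containing one).
#' @param path File path.
#' @param extra Optional named list stored alongside the model (e.g. training
#'   config and seed).
#' @return `path`, invisibly (`save_checkpoint`); the checkpoint list with
#'   elements `model` and `extra` (`load_checkpoint`).
#' @export
save_checkpoint <- function(model, path, extra = list()) {
  stopifnot(inherits(model, "set_model"))
  saveRDS(list(model = model, extra = extra,
               package_version = as.character(utils::packageVersion("cytosets"))),
          path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  ck <- readRDS(path)
  stopifnot(inherits(ck$model, "set_model"))
  ck
}
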