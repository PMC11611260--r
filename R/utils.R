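#' @keywords internal
"_PACKAGE"

#' @importFrom stats cor median rnorm runif quantile sd setNames
#' @importFrom utils head modifyList
NULL

# Leaky rectified linear unit, elementwise.
leaky_relu <- function(x, slope = 0.01) {
  ifelse(x >= 0, x, slope * x)
}

# Derivative of leaky ReLU evaluated at the pre-activation. The kink at 0 is
# assigned the positive-side slope 1 (subgradient convention).
leaky_relu_grad <- function(x, slope = 0.01) {
  ifelse(x >= 0, 1, slope)
}

# Min-max normalization to [0, 1]. A constant vector (max == min) maps to all
# zeros rather than dividing by zero; callers can detect this via attribute.
minmax_scale <- function(x) {
  rng <- range(x)
  if (!all(is.finite(rng))) stop("minmax_scale: non-finite values", call. = FALSE)
  if (rng[2] - rng[1] <= 0) {
    out <- rep(0, length(x))
    attr(out, "degenerate") <- TRUE
    return(out)
  }
  out <- (x - rng[1]) / (rng[2] - rng[1])
  attr(out, "degenerate") <- FALSE
  out
}

# Row-wise L2 normalization with a floor to avoid division by zero.
l2_normalize_rows <- function(m, eps = 1e-12) {
  nrm <- sqrt(rowSums(m^2))
  m / pmax(nrm, eps)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
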