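#' Supervised contrastive (SupCon) loss over a batch of embeddings
#'
#' Embeddings are L2-normalized internally so that dot products are cosine
#' similarities. For each anchor `i` with positive set `P(i)` (other samples
#' sharing its label),
#' \deqn{L_i = \frac{-1}{|P(i)|} \sum_{p \in P(i)}
#'   \log \frac{\exp(v_i \cdot v_p / \tau)}{\sum_{a \in A(i)} \exp(v_i \cdot v_a / \tau)}}
#' where `A(i)` is every sample except the anchor (`denominator = "all"`, the
#' standard formulation) or only the anchor's negatives
#' (`denominator = "negatives_only"`). Anchors with no positive are skipped;
#' the per-anchor terms are then summed (`anchor_reduction = "sum"`, the form
#' as printed) or averaged over contributing anchors (`"mean"`, scale-free in
#' batch size, the training default).
#'
#' @param embeddings I x L numeric matrix of sample embeddings.
#' @param labels Length-I vector of class labels (perturbation ids).
#' @param temperature Positive temperature `tau`.
#' @param anchor_reduction `"mean"` or `"sum"` over contributing anchors.
#' @param denominator `"all"` or `"negatives_only"`.
#' @param grad If `TRUE`, also return the gradient of the loss with respect
#'   to the (unnormalized) embeddings.
#' @return The loss (nonnegative scalar); with `grad = TRUE`, a list with
#'   `loss` and `grad` (same shape as `embeddings`).
#' @export
supcon_loss <- function(embeddings, labels, temperature = 0.1,
                        anchor_reduction = c("mean", "sum"),
                        denominator = c("all", "negatives_only"),
                        grad = FALSE) {
  anchor_reduction <- match.arg(anchor_reduction)
  denominator <- match.arg(denominator)
  if (temperature <= 0) stop("temperature must be positive", call. = FALSE)
  V <- as.matrix(embeddings)
  I <- nrow(V)
  if (I < 2) stop("a batch needs at least two samples", call. = FALSE)
  if (length(labels) != I)
    stop("labels length must match the number of embeddings", call. = FALSE)

  nrm <- pmax(sqrt(rowSums(V^2)), 1e-12)
  U <- V / nrm
  S <- tcrossprod(U) / temperature

  same <- outer(labels, labels, "==")
  pos_mask <- same; diag(pos_mask) <- FALSE
  den_mask <- if (denominator == "all") {
    m <- matrix(TRUE, I, I); diag(m) <- FALSE; m
  } else {
    !same
  }
  n_pos <- rowSums(pos_mask)
  contributing <- which(n_pos > 0 & rowSums(den_mask) > 0)
  if (length(contributing) == 0)
    stop("no anchor has a positive pair; loss undefined", call. = FALSE)

  # log-sum-exp over each anchor's denominator set, stabilized per row
  loss_terms <- numeric(I)
  Q <- matrix(0, I, I)  # softmax over the denominator set, per anchor row
  for (i in contributing) {
    d <- which(den_mask[i, ])
    m <- max(S[i, d])
    e <- exp(S[i, d] - m)
    lse <- m + log(sum(e))
    Q[i, d] <- e / sum(e)
    p <- which(pos_mask[i, ])
    loss_terms[i] <- mean(lse - S[i, p])
  }
  w <- if (anchor_reduction == "mean") 1 / length(contributing) else 1
  loss <- w * sum(loss_terms[contributing])
  if (!grad) return(loss)

  # dL/dS for anchor rows: softmax minus the positive-indicator distribution
  P <- pos_mask / pmax(n_pos, 1)
  G <- matrix(0, I, I)
  G[contributing, ] <- (Q - P)[contributing, , drop = FALSE]
  G <- G * w
  dU <- (G + t(G)) %*% U / temperature
  # back through row-wise L2 normalization
  dV <- (dU - U * rowSums(dU * U)) / nrm
  list(loss = loss, grad = dV)
}
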