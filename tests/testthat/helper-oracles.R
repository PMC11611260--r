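# Independent oracles and small fixture builders shared across tests.
# These deliberately use naive loops so they stay independent of the
# vectorized implementations they check.

# Brute-force double-loop evaluation of the supervised contrastive loss.
oracle_supcon <- function(V, labels, tau = 0.1,
                          anchor_reduction = "mean", denominator = "all") {
  V <- as.matrix(V)
  U <- V / pmax(sqrt(rowSums(V^2)), 1e-12)
  I <- nrow(V)
  total <- 0
  n_contrib <- 0
  for (i in seq_len(I)) {
    P <- setdiff(which(labels == labels[i]), i)
    A <- if (denominator == "all") setdiff(seq_len(I), i) else
      which(labels != labels[i])
    if (length(P) == 0 || length(A) == 0) next
    n_contrib <- n_contrib + 1
    denom <- 0
    for (a in A) denom <- denom + exp(sum(U[i, ] * U[a, ]) / tau)
    s <- 0
    for (p in P) s <- s + log(exp(sum(U[i, ] * U[p, ]) / tau) / denom)
    total <- total - s / length(P)
  }
  if (anchor_reduction == "mean") total / n_contrib else total
}

# Precision-recall staircase evaluation of average precision:
# AP = sum_k (r(k) - r(k-1)) * p(k).
oracle_ap_staircase <- function(relevant) {
  relevant <- as.logical(relevant)
  n_pos <- sum(relevant)
  stopifnot(n_pos > 0)
  ap <- 0
  r_prev <- 0
  hits <- 0
  for (k in seq_along(relevant)) {
    hits <- hits + relevant[k]
    p_k <- hits / k
    r_k <- hits / n_pos
    ap <- ap + (r_k - r_prev) * p_k
    r_prev <- r_k
  }
  ap
}

# A small model with hand-settable weights.
tiny_model <- function(D = 2, phi_dim = 4, hidden_dim = 3, out_dim = 4,
                       slope = 0.01, seed = 42) {
  set_model(D, phi_dim, hidden_dim, out_dim, leaky_slope = slope, seed = seed)
}

zero_model <- function(...) {
  m <- tiny_model(...)
  for (nm in c("W1", "b1", "W2", "b2", "W3", "b3")) m[[nm]] <- m[[nm]] * 0
  m
}

random_cells <- function(M, D, seed = 1) {
  set.seed(seed)
  matrix(rnorm(M * D), M, D,
         dimnames = list(NULL, sprintf("feat_%03d", seq_len(D))))
}

# Two-plate fixture with controls, built directly in code.
fixture_plates <- function(seed = 5) {
  set.seed(seed)
  ids <- c("w1", "w2", "w3", "w4", "c1", "c2")
  tabs <- lapply(ids, function(id)
    cell_table(id, matrix(rnorm(5 * 3, mean = match(id, ids)), 5, 3,
                          dimnames = list(NULL, c("a", "b", "c")))))
  names(tabs) <- ids
  wr <- well_records(
    well_id = ids,
    plate_id = c("P1", "P1", "P2", "P2", "P1", "P2"),
    well_position = c("A01", "A02", "A01", "A02", "B01", "B01"),
    perturbation_id = c("cmpdA", "cmpdA", "cmpdB", "cmpdB", "DMSO", "DMSO"),
    role = c(rep("treatment", 4), rep("negative_control", 2)))
  list(cell_tables = tabs, well_records = wr)
}

well_positions_for_test <- function(n) {
  grid <- expand.grid(col = 1:24, row = LETTERS[1:16])
  sprintf("%s%02d", grid$row[seq_len(n)], grid$col[seq_len(n)])
}
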