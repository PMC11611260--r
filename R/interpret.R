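#' Sensitivity-analysis relevance of every cell
#'
#' Backpropagates the supervised contrastive loss, taken over the supplied
#' batch of wells with their perturbation ids as labels, down to each input
#' entry: `R[m, d] = |dL / dx[m, d]|`. The per-cell relevance is the sum of
#' `R[m, d]` over the feature dimension. An alternative mode backpropagates
#' the model output instead of the loss (summing `|dv_l / dx[m, d]|` over the
#' output dimensions).
#'
#' @param model A [set_model()].
#' @param tables List of [cell_table()] wells forming the analysis batch.
#' @param labels Perturbation id per well; at least one must repeat so the
#'   loss is defined (ignored in `"output"` mode).
#' @param temperature SupCon temperature.
#' @param mode `"loss"` (default) or `"output"`.
#' @param anchor_reduction,denominator Passed to [supcon_loss()].
#' @return Named list, one element per well, each a list with `raw`
#'   (per-cell score vector) and `matrix` (the M x D `R[m, d]` values).
#' @export
sensitivity_relevance <- function(model, tables, labels, temperature = 0.1,
                                  mode = c("loss", "output"),
                                  anchor_reduction = "mean",
                                  denominator = "all") {
  mode <- match.arg(mode)
  caches <- lapply(tables, function(ct) forward_set(model, ct, TRUE))
  out <- vector("list", length(tables))
  names(out) <- vapply(tables, `[[`, "", "well_id")
  if (mode == "loss") {
    V <- t(vapply(caches, `[[`, numeric(model$out_dim), "v"))
    res <- supcon_loss(V, labels, temperature = temperature,
                       anchor_reduction = anchor_reduction,
                       denominator = denominator, grad = TRUE)
    for (i in seq_along(caches)) {
      dX <- backward_set(model, caches[[i]], res$grad[i, ],
                         want_input = TRUE)$X
      R <- abs(dX)
      out[[i]] <- list(raw = rowSums(R), matrix = R)
    }
  } else {
    for (i in seq_along(caches)) {
      R <- 0
      for (l in seq_len(model$out_dim)) {
        dv <- rep(0, model$out_dim); dv[l] <- 1
        R <- R + abs(backward_set(model, caches[[i]], dv,
                                  want_input = TRUE)$X)
      }
      out[[i]] <- list(raw = rowSums(R), matrix = R)
    }
  }
  out
}

#' Critical-point relevance of every cell
#'
#' Because the pooled representation is a sum over cells, cells whose
#' first-layer activations are large dominate it. The score is the L1 norm
#' of each cell's first fully connected layer activations, post-activation
#' by default (that is what enters the sum); `pre_activation = TRUE` uses the
#' affine outputs before the leaky ReLU.
#'
#' @param model A [set_model()].
#' @param x A [cell_table()] or matrix of cells.
#' @param pre_activation Use activations before the nonlinearity.
#' @return Numeric vector of per-cell scores (nonnegative).
#' @export
critical_point_relevance <- function(model, x, pre_activation = FALSE) {
  X <- as_feature_matrix(x)
  A1 <- sweep(X %*% model$W1, 2, model$b1, "+")
  H <- if (pre_activation) A1 else leaky_relu(A1, model$leaky_slope)
  rowSums(abs(H))
}

#' Combine sensitivity and critical-point scores into per-cell relevance
#'
#' Each raw score vector is min-max normalized per well, the two are added,
#' and the sum is min-max normalized again, giving combined scores in
#' `[0, 1]`. A constant raw vector (degenerate min-max) maps to all zeros and
#' is flagged.
#'
#' @param sa_raw,cpa_raw Raw score vectors over the same cells of one well.
#' @param well_id Optional well identifier recorded in the output.
#' @return A `data.frame` of class `relevance_table` with columns `cell`,
#'   `sa_raw`, `cpa_raw`, `sa`, `cpa`, `combined`, `class`; degenerate
#'   normalizations are flagged in attribute `"degenerate"`.
#' @export
combined_relevance <- function(sa_raw, cpa_raw, well_id = NA_character_) {
  stopifnot(length(sa_raw) == length(cpa_raw))
  sa <- minmax_scale(sa_raw)
  cpa <- minmax_scale(cpa_raw)
  comb <- minmax_scale(as.numeric(sa) + as.numeric(cpa))
  degenerate <- c(sa = isTRUE(attr(sa, "degenerate")),
                  cpa = isTRUE(attr(cpa, "degenerate")),
                  combined = isTRUE(attr(comb, "degenerate")))
  df <- data.frame(cell = seq_along(sa_raw), sa_raw = sa_raw,
                   cpa_raw = cpa_raw, sa = as.numeric(sa),
                   cpa = as.numeric(cpa), combined = as.numeric(comb),
                   stringsAsFactors = FALSE)
  df$class <- classify_cells(df$combined)
  attr(df, "well_id") <- well_id
  attr(df, "degenerate") <- degenerate
  class(df) <- c("relevance_table", "data.frame")
  df
}

#' Classify cells by combined relevance
#'
#' Strict thresholds: scores above 0.8 are `most_relevant`, below 0.2
#' `least_relevant`, all others `neither`.
#'
#' @param combined Numeric vector of combined relevance scores in `[0, 1]`.
#' @return Character vector of classes.
#' @export
classify_cells <- function(combined) {
  ifelse(combined > 0.8, "most_relevant",
         ifelse(combined < 0.2, "least_relevant", "neither"))
}

#' Correlate per-cell relevance with the input features
#'
#' Pools the supplied cells (typically all analyzed wells of one plate) and
#' computes one Pearson correlation per feature between the feature values
#' and the combined relevance scores, returned sorted by the coefficient.
#' Constant features get `r = 0` and are flagged.
#'
#' @param combined Numeric vector of combined relevance scores over cells.
#' @param features Cells x features matrix aligned with `combined`.
#' @return `data.frame` with columns `feature`, `r`, `constant`, sorted by
#'   `r` descending; at least 3 cells required.
#' @export
relevance_feature_correlation <- function(combined, features) {
  features <- as_feature_matrix(features)
  if (length(combined) != nrow(features))
    stop("scores and features cover different numbers of cells",
         call. = FALSE)
  if (nrow(features) < 3)
    stop("need at least 3 cells to correlate", call. = FALSE)
  const <- apply(features, 2, function(x) sd(x) == 0) | sd(combined) == 0
  r <- rep(0, ncol(features))
  ok <- !const
  if (any(ok))
    r[ok] <- drop(cor(features[, ok, drop = FALSE], combined))
  df <- data.frame(feature = colnames(features), r = r, constant = const,
                   stringsAsFactors = FALSE)
  df <- df[order(-df$r, df$feature), , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Per-cell relevance for a batch of wells, end to end
#'
#' Convenience wrapper: computes sensitivity and critical-point scores for
#' every well in the batch (labels = perturbation ids) and combines them per
#' well.
#'
#' @inheritParams sensitivity_relevance
#' @param records Well metadata supplying the perturbation labels.
#' @return Named list of [combined_relevance()] tables, one per well.
#' @export
relevance_tables <- function(model, tables, records, temperature = 0.1) {
  ids <- vapply(tables, `[[`, "", "well_id")
  labels <- records$perturbation_id[match(ids, records$well_id)]
  sa <- sensitivity_relevance(model, tables, labels,
                              temperature = temperature)
  out <- lapply(seq_along(tables), function(i) {
    cpa <- critical_point_relevance(model, tables[[i]])
    combined_relevance(sa[[i]]$raw, cpa, well_id = ids[i])
  })
  names(out) <- ids
  out
}
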