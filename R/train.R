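#' Training configuration for the contrastive set aggregator
#'
#' Defaults follow the published recipe where one is stated (AdamW with
#' learning rate 5e-4 and weight decay 1e-2, up to 100 epochs with
#' best-validation-mAP checkpointing, well-mixing coin flip probability 0.5)
#' and desk-scale choices elsewhere (temperature 0.1; two sampled views per
#' perturbation per epoch; sampled set sizes from a Gaussian with mean 400
#' and sd 100, floored at one cell).
#'
#' @param temperature SupCon temperature `tau` (> 0).
#' @param learning_rate,weight_decay AdamW settings.
#' @param max_epochs Maximum training epochs; the checkpoint with the best
#'   validation mAP is returned.
#' @param sets_per_perturbation_per_epoch Augmented views drawn per
#'   perturbation per epoch.
#' @param cell_count_mean,cell_count_std Gaussian for the sampled set size.
#' @param mix_probability Probability that a sampled set pools cells from two
#'   replicate wells rather than one.
#' @param perturbations_per_batch Perturbations per contrastive batch.
#' @param anchor_reduction,denominator Passed to [supcon_loss()].
#' @param seed Integer seed driving every random draw of the run.
#' @return A list of class `train_config`.
#' @export
train_config <- function(temperature = 0.1, learning_rate = 5e-4,
                         weight_decay = 1e-2, max_epochs = 100,
                         sets_per_perturbation_per_epoch = 2,
                         cell_count_mean = 400, cell_count_std = 100,
                         mix_probability = 0.5, perturbations_per_batch = 10,
                         anchor_reduction = "mean", denominator = "all",
                         seed = 1L) {
  stopifnot(temperature > 0, cell_count_mean > 0, max_epochs >= 0,
            mix_probability >= 0, mix_probability <= 1,
            sets_per_perturbation_per_epoch >= 2 || max_epochs == 0)
  structure(list(temperature = temperature, learning_rate = learning_rate,
                 weight_decay = weight_decay, max_epochs = max_epochs,
                 sets_per_perturbation_per_epoch =
                   sets_per_perturbation_per_epoch,
                 cell_count_mean = cell_count_mean,
                 cell_count_std = cell_count_std,
                 mix_probability = mix_probability,
                 perturbations_per_batch = perturbations_per_batch,
                 anchor_reduction = anchor_reduction,
                 denominator = denominator, seed = as.integer(seed)),
            class = "train_config")
}

#' Sample an augmented training set for one perturbation
#'
#' Draws a set size `k = max(1, round(Normal(cell_count_mean,
#' cell_count_std)))`, then samples `k` cell rows with replacement from one
#' replicate well of the perturbation — or, on a coin flip with probability
#' `mix_probability` (and at least two wells available), from the pooled rows
#' of two distinct replicate wells. Mixing counteracts well-position effects
#' by composing sets across plate positions.
#'
#' Uses R's global random number generator; seed it via the training loop.
#'
#' @param tables List of [cell_table()] replicate wells of one perturbation.
#' @param config A [train_config()].
#' @return A [cell_table()] with the sampled rows (well id records the
#'   source wells).
#' @export
sample_training_set <- function(tables, config) {
  if (length(tables) == 0) stop("no replicate wells supplied", call. = FALSE)
  k <- max(1L, as.integer(round(rnorm(1, config$cell_count_mean,
                                      config$cell_count_std))))
  mix <- length(tables) >= 2 && runif(1) < config$mix_probability
  if (mix) {
    pick <- sample(length(tables), 2)
    pool <- rbind(tables[[pick[1]]]$features, tables[[pick[2]]]$features)
    wid <- paste(tables[[pick[1]]]$well_id, tables[[pick[2]]]$well_id,
                 sep = "+")
  } else {
    pick <- sample(length(tables), 1)
    pool <- tables[[pick]]$features
    wid <- tables[[pick]]$well_id
  }
  cell_table(wid, pool[sample(nrow(pool), k, replace = TRUE), , drop = FALSE])
}

# One AdamW update; state holds first/second moment estimates and step count.
adamw_step <- function(params, grads, state, lr, wd,
                       beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  for (nm in names(grads)) {
    g <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
    mhat <- state$m[[nm]] / (1 - beta1^state$t)
    vhat <- state$v[[nm]] / (1 - beta2^state$t)
    # decoupled weight decay
    params[[nm]] <- params[[nm]] - lr * (mhat / (sqrt(vhat) + eps)) -
      lr * wd * params[[nm]]
  }
  list(params = params, state = state)
}

param_names <- c("W1", "b1", "W2", "b2", "W3", "b3")

zero_like_params <- function(model) {
  setNames(lapply(param_names, function(nm) model[[nm]] * 0), param_names)
}

# Validation replicate-retrieval mAP on full, un-augmented wells. Queries are
# the validation wells; the candidate pool also contains the training wells
# as distractors, so the score does not saturate on a small held-out set.
validation_map <- function(model, val_tables, val_records,
                           extra_tables = list(), extra_records = NULL) {
  tables <- c(val_tables, extra_tables)
  records <- rbind(
    val_records[, c("well_id", "plate_id", "well_position",
                    "perturbation_id", "moa", "role")],
    if (!is.null(extra_records))
      extra_records[, c("well_id", "plate_id", "well_position",
                        "perturbation_id", "moa", "role")])
  prof <- t(vapply(tables, function(ct) forward(model, ct),
                   numeric(model$out_dim)))
  ps <- profile_set(prof, records[match(vapply(tables, `[[`, "", "well_id"),
                                        records$well_id), , drop = FALSE],
                    provenance = "model")
  res <- replicate_retrieval_map(ps)
  pq <- res$per_query[res$per_query$well_id %in% val_records$well_id, ,
                      drop = FALSE]
  per_compound <- stats::aggregate(ap ~ perturbation_id, pq, mean)
  mean(per_compound$ap)
}

#' Train the set aggregator with supervised contrastive learning
#'
#' Each epoch draws `sets_per_perturbation_per_epoch` augmented views per
#' perturbation ([sample_training_set()]), groups shuffled perturbations into
#' batches of `perturbations_per_batch` (every anchor therefore has at least
#' one positive), minimizes the SupCon loss with AdamW, then scores
#' replicate-retrieval mAP on the un-augmented validation wells. The
#' checkpoint with the highest validation mAP is returned.
#'
#' @param model A [set_model()].
#' @param train_tables,train_records Treatment wells for training
#'   (plate-standardized, controls removed).
#' @param val_tables,val_records Held-out wells with replicate structure for
#'   model selection; must be disjoint from the training wells.
#' @param config A [train_config()].
#' @return List of class `train_result` with `model` (best checkpoint),
#'   `final_model`, `log` (data.frame epoch/loss/val_map), `best_epoch`,
#'   `best_val_map`, `config`.
#' @export
train_deepsets <- function(model, train_tables, train_records,
                           val_tables, val_records, config = train_config()) {
  stopifnot(inherits(model, "set_model"), inherits(config, "train_config"))
  if (length(intersect(vapply(train_tables, `[[`, "", "well_id"),
                       vapply(val_tables, `[[`, "", "well_id"))))
    stop("training and validation wells overlap", call. = FALSE)

  perts <- unique(train_records$perturbation_id)
  by_pert <- lapply(perts, function(p) {
    ids <- train_records$well_id[train_records$perturbation_id == p]
    Filter(function(ct) ct$well_id %in% ids, train_tables)
  })
  names(by_pert) <- perts
  if (config$max_epochs > 0 && length(perts) < 2)
    stop("need at least two perturbations to form negative pairs",
         call. = FALSE)

  log_rows <- list()
  if (config$max_epochs == 0) {
    return(structure(list(model = model, final_model = model,
                          log = data.frame(epoch = integer(0),
                                           loss = numeric(0),
                                           val_map = numeric(0)),
                          best_epoch = NA_integer_, best_val_map = NA_real_,
                          config = config),
                     class = "train_result"))
  }

  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(config$seed)

  state <- list(t = 0L, m = zero_like_params(model),
                v = zero_like_params(model))
  best <- list(map = -Inf, model = model, epoch = NA_integer_)
  views <- config$sets_per_perturbation_per_epoch

  for (epoch in seq_len(config$max_epochs)) {
    pert_order <- sample(perts)
    n_batches <- max(1L, ceiling(length(perts) /
                                   config$perturbations_per_batch))
    batch_of <- rep(seq_len(n_batches), length.out = length(perts))
    epoch_losses <- numeric(0)
    for (b in seq_len(n_batches)) {
      batch_perts <- pert_order[batch_of == b]
      if (length(batch_perts) < 2) next
      sets <- list(); labels <- character(0)
      for (p in batch_perts) for (k in seq_len(views)) {
        sets[[length(sets) + 1L]] <- sample_training_set(by_pert[[p]], config)
        labels <- c(labels, p)
      }
      caches <- lapply(sets, function(ct) forward_set(model, ct, TRUE))
      V <- t(vapply(caches, `[[`, numeric(model$out_dim), "v"))
      res <- supcon_loss(V, labels, temperature = config$temperature,
                         anchor_reduction = config$anchor_reduction,
                         denominator = config$denominator, grad = TRUE)
      if (!is.finite(res$loss))
        stop("non-finite loss at epoch ", epoch, " batch ", b,
             "; reduce the learning rate or inspect the inputs",
             call. = FALSE)
      grads <- zero_like_params(model)
      for (i in seq_along(caches)) {
        g <- backward_set(model, caches[[i]], res$grad[i, ])
        for (nm in param_names) grads[[nm]] <- grads[[nm]] + g[[nm]]
      }
      upd <- adamw_step(model[param_names], grads, state,
                        lr = config$learning_rate, wd = config$weight_decay)
      model[param_names] <- upd$params
      state <- upd$state
      epoch_losses <- c(epoch_losses, res$loss)
    }
    vmap <- validation_map(model, val_tables, val_records,
                           train_tables, train_records)
    log_rows[[epoch]] <- data.frame(epoch = epoch,
                                    loss = mean(epoch_losses),
                                    val_map = vmap)
    # ties in validation mAP favor the later epoch: at equal validation
    # performance additional epochs continue to reduce the contrastive loss
    if (vmap >= best$map) best <- list(map = vmap, model = model,
                                       epoch = epoch)
  }

  structure(list(model = best$model, final_model = model,
                 log = do.call(rbind, log_rows), best_epoch = best$epoch,
                 best_val_map = best$map, config = config),
            class = "train_result")
}

#' @export
print.train_result <- function(x, ...) {
  cat(sprintf("<train_result> %d epochs, best val mAP %.4f at epoch %s\n",
              nrow(x$log), x$best_val_map, x$best_epoch))
  invisible(x)
}
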