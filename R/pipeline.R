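#' Aggregate an experiment's wells into model-based profiles
#'
#' Applies the same preprocessing as training — restriction to the model's
#' feature set (intersection by name), plate-level standardization, removal
#' of negative controls — then runs every treatment well through the
#' aggregator.
#'
#' @param model A [set_model()] (or a checkpoint list from
#'   [load_checkpoint()]).
#' @param cell_tables Named list of [cell_table()] (raw, NaN-cleaned).
#' @param well_records Metadata covering the wells.
#' @param preprocess Set `FALSE` if the tables are already standardized and
#'   control-free.
#' @return A [profile_set()] with provenance `"model"`.
#' @export
aggregate_dataset <- function(model, cell_tables, well_records,
                              preprocess = TRUE) {
  if (!inherits(model, "set_model") && !is.null(model$model))
    model <- model$model
  if (!is.null(model$feature_names)) {
    have <- colnames(cell_tables[[1]]$features)
    common <- intersect(model$feature_names, have)
    if (length(common) != model$D)
      stop("input features cover only ", length(common), " of the model's ",
           model$D, " features", call. = FALSE)
    cell_tables <- lapply(cell_tables, function(ct)
      cell_table(ct$well_id, ct$features[, model$feature_names,
                                         drop = FALSE]))
  }
  if (preprocess) {
    cell_tables <- standardize_all_plates(cell_tables, well_records)
    trt <- drop_negative_controls(cell_tables, well_records)
    cell_tables <- trt$cell_tables
    well_records <- trt$well_records
  }
  prof <- t(vapply(cell_tables, function(ct) forward(model, ct),
                   numeric(model$out_dim)))
  wr <- well_records[match(vapply(cell_tables, `[[`, "", "well_id"),
                           well_records$well_id), , drop = FALSE]
  rownames(wr) <- NULL
  profile_set(prof, wr, provenance = "model")
}

#' Compare model-based against average profiling on the same wells
#'
#' Builds both profile variants from identical input wells — the learned
#' aggregation and the classical average/RobustMAD/feature-selection baseline
#' — and scores each on replicate retrieval and (when MoA annotations are
#' present) mechanism-of-action retrieval.
#'
#' @inheritParams aggregate_dataset
#' @return List of class `baseline_comparison` with elements `summary` (a
#'   `data.frame` of task x method mAP plus absolute and relative deltas),
#'   `model_results`, `baseline_results`, `model_profiles`,
#'   `baseline_profiles`.
#' @export
compare_baselines <- function(model, cell_tables, well_records) {
  model_ps <- aggregate_dataset(model, cell_tables, well_records)
  base_ps <- average_baseline_profiles(cell_tables, well_records)

  tasks <- list(replicate = replicate_retrieval_map)
  have_moa <- any(!is.na(base_ps$well_records$moa) &
                    nzchar(base_ps$well_records$moa))
  if (have_moa) tasks$moa <- moa_retrieval_map

  model_res <- lapply(tasks, function(f) f(model_ps))
  base_res <- lapply(tasks, function(f) f(base_ps))

  summary <- do.call(rbind, lapply(names(tasks), function(tk) {
    m <- model_res[[tk]]$map; b <- base_res[[tk]]$map
    data.frame(task = tk, model_map = m, average_map = b, delta = m - b,
               relative_delta = (m - b) / b, stringsAsFactors = FALSE)
  }))
  structure(list(summary = summary, model_results = model_res,
                 baseline_results = base_res, model_profiles = model_ps,
                 baseline_profiles = base_ps),
            class = "baseline_comparison")
}

#' @export
print.baseline_comparison <- function(x, ...) {
  cat("<baseline_comparison>\n")
  print(x$summary, row.names = FALSE)
  invisible(x)
}

#' Split perturbations into training and validation sets
#'
#' Holds out a fraction of the perturbations (not wells) for validation, so
#' model selection measures generalization to unseen compounds.
#'
#' @param well_records Treatment-well metadata.
#' @param val_fraction Fraction of perturbations held out (default 0.2).
#' @param seed Integer seed.
#' @return List with character vectors `train_perts` and `val_perts`.
#' @export
split_perturbations <- function(well_records, val_fraction = 0.2, seed = 1L) {
  perts <- sort(unique(well_records$perturbation_id[
    well_records$role == "treatment"]))
  n_val <- max(2L, round(val_fraction * length(perts)))
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
  set.seed(seed)
  val <- sort(sample(perts, n_val))
  if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv)
  list(train_perts = setdiff(perts, val), val_perts = val)
}

#' Run the full desk-scale experiment: simulate, train, compare
#'
#' Convenience driver used by the worked examples and the command-line
#' interface: simulates a screen, preprocesses it, trains the aggregator on
#' one split of perturbations with validation-mAP checkpointing, and compares
#' model-based against average profiling on all treatment wells.
#'
#' @param scfg A [sim_config()].
#' @param tcfg A [train_config()].
#' @param model_dims Widths `c(phi, hidden, out)` of the aggregator.
#' @param val_fraction Fraction of perturbations held out for validation.
#' @return List with `comparison` ([compare_baselines()] output), `fit`
#'   (the training result), `data` (the simulated experiment) and the
#'   train/validation split.
#' @export
run_experiment <- function(scfg = sim_config(), tcfg = train_config(),
                           model_dims = c(256, 64, 256),
                           val_fraction = 0.2) {
  data <- simulate_profiling_plates(scfg)
  tabs <- standardize_all_plates(data$cell_tables, data$well_records)
  trt <- drop_negative_controls(tabs, data$well_records)

  split <- split_perturbations(trt$well_records, val_fraction,
                               seed = tcfg$seed)
  in_train <- trt$well_records$perturbation_id %in% split$train_perts
  tr_ids <- trt$well_records$well_id[in_train]
  va_ids <- trt$well_records$well_id[!in_train]
  pick <- function(ids) Filter(function(ct) ct$well_id %in% ids,
                               trt$cell_tables)

  model <- set_model(D = scfg$D, phi_dim = model_dims[1],
                     hidden_dim = model_dims[2], out_dim = model_dims[3],
                     feature_names = colnames(trt$cell_tables[[1]]$features),
                     seed = tcfg$seed)
  fit <- train_deepsets(model, pick(tr_ids),
                        trt$well_records[in_train, , drop = FALSE],
                        pick(va_ids),
                        trt$well_records[!in_train, , drop = FALSE],
                        config = tcfg)
  comparison <- compare_baselines(fit$model, data$cell_tables,
                                  data$well_records)
  list(comparison = comparison, fit = fit, data = data, split = split)
}
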