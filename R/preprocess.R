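#' Standardize all wells of one plate to pooled zero mean and unit variance
#'
#' Per-feature statistics are computed by pooling the cells of every well on
#' the plate — including negative-control wells, which are removed only after
#' standardization. The population (divide-by-n) standard deviation is used so
#' that the realized cell population has exactly unit variance. Features that
#' are constant across the plate (sd below `1e-12`) are mapped to zero.
#'
#' @param cell_tables Named list of [cell_table()] objects.
#' @param well_records Metadata `data.frame` covering the tables.
#' @param plate_id Plate whose wells are standardized.
#' @return The input list with the plate's tables standardized in place.
#' @export
standardize_plate <- function(cell_tables, well_records, plate_id) {
  wells <- well_records$well_id[well_records$plate_id == plate_id]
  wells <- intersect(wells, vapply(cell_tables, `[[`, "", "well_id"))
  if (length(wells) == 0)
    stop("plate '", plate_id, "' has no wells with cell data", call. = FALSE)
  idx <- which(vapply(cell_tables, `[[`, "", "well_id") %in% wells)
  pooled <- do.call(rbind, lapply(cell_tables[idx], `[[`, "features"))
  if (nrow(pooled) == 0)
    stop("plate '", plate_id, "' has zero cells", call. = FALSE)
  mu <- colMeans(pooled)
  n <- nrow(pooled)
  sdev <- sqrt(colMeans(sweep(pooled, 2, mu)^2))  # population sd
  const <- sdev < 1e-12
  sdev[const] <- 1
  for (i in idx) {
    f <- sweep(sweep(cell_tables[[i]]$features, 2, mu), 2, sdev, "/")
    f[, const] <- 0
    cell_tables[[i]] <- cell_table(cell_tables[[i]]$well_id, f)
  }
  cell_tables
}

#' Standardize every plate of an experiment
#'
#' Applies [standardize_plate()] independently to each plate found in the
#' metadata, so plates never share statistics.
#'
#' @inheritParams standardize_plate
#' @return The standardized list of cell tables.
#' @export
standardize_all_plates <- function(cell_tables, well_records) {
  for (p in unique(well_records$plate_id))
    cell_tables <- standardize_plate(cell_tables, well_records, p)
  cell_tables
}

#' Remove negative-control wells
#'
#' Controls inform the plate-level standardization statistics but are excluded
#' from aggregation, training and retrieval; call this after standardization.
#'
#' @inheritParams standardize_plate
#' @return List with filtered `cell_tables` and `well_records`.
#' @export
drop_negative_controls <- function(cell_tables, well_records) {
  keep_ids <- well_records$well_id[well_records$role == "treatment"]
  ct <- Filter(function(x) x$well_id %in% keep_ids, cell_tables)
  wr <- well_records[well_records$well_id %in%
                       vapply(ct, `[[`, "", "well_id"), , drop = FALSE]
  wr <- wr[match(vapply(ct, `[[`, "", "well_id"), wr$well_id), , drop = FALSE]
  rownames(wr) <- NULL
  list(cell_tables = ct, well_records = wr)
}

#' Average-aggregate one well into a profile vector
#'
#' The classical profiling baseline: each feature is averaged over the well's
#' cells, collapsing the cell dimension.
#'
#' @param ct A [cell_table()] with at least one cell.
#' @return Named numeric vector of length `D`.
#' @export
average_profile <- function(ct) {
  if (nrow(ct$features) < 1) stop("empty cell table", call. = FALSE)
  colMeans(ct$features)
}

#' RobustMAD-normalize a matrix of well profiles
#'
#' Per feature, subtracts the median over wells and divides by the scaled
#' median absolute deviation, `(x - median) / (c * MAD + eps)` with
#' consistency constant `c = 1.4826` (making MAD estimate the standard
#' deviation under normality) and `eps = 1e-18` guarding constant features.
#' `deviation = "mean"` selects the mean absolute deviation from the median
#' instead of the median absolute deviation.
#'
#' @param profile_matrix Wells x features numeric matrix (one plate).
#' @param deviation `"median"` (default) or `"mean"` absolute deviation.
#' @param consistency Scale constant applied to the deviation.
#' @param eps Additive floor on the denominator.
#' @return Normalized matrix of the same shape.
#' @export
robust_mad_normalize <- function(profile_matrix, deviation = c("median", "mean"),
                                 consistency = 1.4826, eps = 1e-18) {
  deviation <- match.arg(deviation)
  m <- as.matrix(profile_matrix)
  med <- apply(m, 2, median)
  dev <- sweep(m, 2, med)
  mad_col <- switch(deviation,
                    median = apply(abs(dev), 2, median),
                    mean = colMeans(abs(dev)))
  sweep(dev, 2, consistency * mad_col + eps, "/")
}

#' Variance- and correlation-based feature selection for well profiles
#'
#' Drops features whose pooled variance falls below `variance_threshold`, then
#' walks the remaining features in name order and keeps a feature only if its
#' absolute Pearson correlation with every already-kept feature is at most
#' `correlation_threshold` — so of a correlated pair the later name is removed,
#' deterministically.
#'
#' @param profile_matrix Wells x features numeric matrix.
#' @param variance_threshold Features with variance below this are dropped.
#' @param correlation_threshold Pairs with `|r|` above this lose one member.
#' @return List with `profiles` (reduced matrix, original column order) and
#'   `kept` (character vector of surviving feature names).
#' @export
select_features <- function(profile_matrix, variance_threshold = 1e-8,
                            correlation_threshold = 0.9) {
  m <- as.matrix(profile_matrix)
  v <- apply(m, 2, function(x) sum((x - mean(x))^2) / length(x))
  keep <- colnames(m)[v >= variance_threshold]
  if (length(keep) == 0)
    stop("all features removed by the variance threshold; lower it",
         call. = FALSE)
  ord <- sort(keep)
  kept <- character(0)
  for (f in ord) {
    if (length(kept) == 0) { kept <- f; next }
    r <- abs(suppressWarnings(cor(m[, f], m[, kept, drop = FALSE])))
    r[is.na(r)] <- 0
    if (all(r <= correlation_threshold)) kept <- c(kept, f)
  }
  if (length(kept) == 0)
    stop("all features removed by the correlation threshold; raise it",
         call. = FALSE)
  kept <- colnames(m)[colnames(m) %in% kept]  # restore original order
  list(profiles = m[, kept, drop = FALSE], kept = kept)
}

#' Build average-profiling baseline profiles for an experiment
#'
#' The full baseline path on already NaN-cleaned tables: plate-level
#' standardization, removal of negative controls, per-well feature averaging,
#' per-plate RobustMAD normalization, then variance/correlation feature
#' selection over all wells.
#'
#' @inheritParams standardize_plate
#' @param standardized Set `TRUE` if the tables are already plate-standardized
#'   (controls already removed).
#' @param variance_threshold,correlation_threshold Passed to
#'   [select_features()].
#' @param deviation Passed to [robust_mad_normalize()].
#' @return A [profile_set()] with provenance `"average_baseline"`, carrying
#'   the kept feature names as attribute `"kept_features"`.
#' @export
average_baseline_profiles <- function(cell_tables, well_records,
                                      standardized = FALSE,
                                      variance_threshold = 1e-8,
                                      correlation_threshold = 0.9,
                                      deviation = "median") {
  if (!standardized) {
    cell_tables <- standardize_all_plates(cell_tables, well_records)
    trt <- drop_negative_controls(cell_tables, well_records)
    cell_tables <- trt$cell_tables
    well_records <- trt$well_records
  }
  prof <- t(vapply(cell_tables, average_profile,
                   numeric(ncol(cell_tables[[1]]$features))))
  rownames(prof) <- vapply(cell_tables, `[[`, "", "well_id")
  wr <- well_records[match(rownames(prof), well_records$well_id), ,
                     drop = FALSE]
  for (p in unique(wr$plate_id)) {
    rows <- wr$plate_id == p
    prof[rows, ] <- robust_mad_normalize(prof[rows, , drop = FALSE],
                                         deviation = deviation)
  }
  sel <- select_features(prof, variance_threshold, correlation_threshold)
  ps <- profile_set(sel$profiles, wr, provenance = "average_baseline")
  attr(ps, "kept_features") <- sel$kept
  ps
}
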