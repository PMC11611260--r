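#' Construct a per-well single-cell feature table
#'
#' A `cell_table` holds the feature matrix of one well: `M` cells (rows) by
#' `D` morphological features (columns), plus the well identifier. It is the
#' set that the permutation-invariant aggregator consumes; row order carries
#' no meaning.
#'
#' @param well_id Character scalar identifying the well.
#' @param features Numeric matrix, cells x features. Column names are the
#'   feature names; if absent they are taken from `feature_names`.
#' @param feature_names Optional character vector of column names.
#' @return An object of class `cell_table` with elements `well_id` and
#'   `features` (a named numeric matrix).
#' @export
cell_table <- function(well_id, features, feature_names = NULL) {
  features <- as.matrix(features)
  storage.mode(features) <- "double"
  if (!is.null(feature_names)) colnames(features) <- feature_names
  if (is.null(colnames(features)))
    colnames(features) <- sprintf("feat_%03d", seq_len(ncol(features)))
  if (nrow(features) < 1)
    stop("cell_table for well '", well_id, "' must contain at least one cell",
         call. = FALSE)
  structure(list(well_id = as.character(well_id), features = features),
            class = "cell_table")
}

#' @export
print.cell_table <- function(x, ...) {
  cat(sprintf("<cell_table> well '%s': %d cells x %d features\n",
              x$well_id, nrow(x$features), ncol(x$features)))
  invisible(x)
}

#' Construct a table of well metadata records
#'
#' One row per well, binding each well to its plate, position on the plate,
#' perturbation (compound) identifier, optional mechanism-of-action labels and
#' its role (treatment or negative control).
#'
#' @param well_id,plate_id,well_position,perturbation_id Character vectors.
#' @param moa Character vector of mechanism-of-action annotations; multiple
#'   labels for one compound are separated by `"|"`. `NA` when unannotated.
#' @param role `"treatment"` or `"negative_control"` per well.
#' @param dose Optional numeric dose.
#' @return A `data.frame` with one row per well.
#' @export
well_records <- function(well_id, plate_id, well_position, perturbation_id,
                         moa = NA_character_, role = "treatment",
                         dose = NA_real_) {
  df <- data.frame(well_id = as.character(well_id),
                   plate_id = as.character(plate_id),
                   well_position = as.character(well_position),
                   perturbation_id = as.character(perturbation_id),
                   moa = as.character(moa),
                   role = as.character(role),
                   dose = as.numeric(dose),
                   stringsAsFactors = FALSE)
  validate_well_records(df)
  df
}

validate_well_records <- function(df) {
  req <- c("well_id", "plate_id", "well_position", "perturbation_id",
           "moa", "role")
  missing_cols <- setdiff(req, names(df))
  if (length(missing_cols))
    stop("well records missing columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  key <- paste(df$plate_id, df$well_position)
  if (anyDuplicated(key))
    stop("duplicated (plate_id, well_position): ",
         paste(unique(key[duplicated(key)]), collapse = "; "), call. = FALSE)
  bad_role <- setdiff(unique(df$role), c("treatment", "negative_control"))
  if (length(bad_role))
    stop("unknown role(s): ", paste(bad_role, collapse = ", "), call. = FALSE)
  trt <- df$role == "treatment"
  if (any(trt & (is.na(df$perturbation_id) | df$perturbation_id == "")))
    stop("treatment wells without perturbation_id: ",
         paste(df$well_id[trt & (is.na(df$perturbation_id) |
                                   df$perturbation_id == "")],
               collapse = ", "), call. = FALSE)
  invisible(df)
}

#' Load single-cell feature tables and well metadata from disk
#'
#' Reads one CSV per well (file name stem used as the `well_id`), or a single
#' long CSV carrying a `well_id` column, together with a metadata CSV with
#' columns `well_id, plate_id, well_position, perturbation_id, moa, role` and
#' optionally `dose`. Rows containing any missing value are dropped. Feature
#' columns must be identical (same names, same order after reordering) across
#' wells, and every well must be covered by the metadata.
#'
#' @param paths Character vector of per-well CSV paths, or a single long-table
#'   CSV path containing a `well_id` column.
#' @param metadata_path Path to the metadata CSV.
#' @return A list with `cell_tables` (named list of [cell_table()]) and
#'   `well_records` (metadata `data.frame`, aligned to the tables by
#'   `well_id`).
#' @export
load_cell_tables <- function(paths, metadata_path) {
  meta <- as.data.frame(data.table::fread(metadata_path))
  if (!"dose" %in% names(meta)) meta$dose <- NA_real_
  validate_well_records(meta)

  read_one <- function(p) {
    dt <- data.table::fread(p)
    if (nrow(dt) == 0) stop("empty cell table file: ", p, call. = FALSE)
    dt
  }

  tables <- list()
  if (length(paths) == 1) {
    dt <- read_one(paths)
    if ("well_id" %in% names(dt)) {
      for (wid in unique(dt$well_id)) {
        sub <- dt[dt$well_id == wid, setdiff(names(dt), "well_id"),
                  with = FALSE]
        tables[[wid]] <- as.matrix(sub)
      }
    } else {
      wid <- sub("\\.[^.]+$", "", basename(paths))
      tables[[wid]] <- as.matrix(dt)
    }
  } else {
    for (p in paths) {
      wid <- sub("\\.[^.]+$", "", basename(p))
      tables[[wid]] <- as.matrix(read_one(p))
    }
  }

  ref_cols <- colnames(tables[[1]])
  for (wid in names(tables)) {
    cols <- colnames(tables[[wid]])
    if (!setequal(cols, ref_cols)) {
      off <- c(setdiff(cols, ref_cols), setdiff(ref_cols, cols))
      stop("feature columns of well '", wid, "' do not match: ",
           paste(off, collapse = ", "), call. = FALSE)
    }
    tables[[wid]] <- tables[[wid]][, ref_cols, drop = FALSE]
  }

  missing_meta <- setdiff(names(tables), meta$well_id)
  if (length(missing_meta))
    stop("wells without metadata: ", paste(missing_meta, collapse = ", "),
         call. = FALSE)

  out <- lapply(names(tables), function(wid) {
    m <- tables[[wid]]
    keep <- stats::complete.cases(m)
    m <- m[keep, , drop = FALSE]
    if (nrow(m) == 0)
      stop("well '", wid, "' has no complete cell rows after NaN removal",
           call. = FALSE)
    cell_table(wid, m)
  })
  names(out) <- names(tables)
  meta <- meta[match(names(out), meta$well_id), , drop = FALSE]
  rownames(meta) <- NULL
  list(cell_tables = out, well_records = meta)
}

#' Drop cells with missing feature values
#'
#' @param ct A [cell_table()].
#' @return The table with incomplete rows removed; errors if no row survives.
#' @export
drop_incomplete_cells <- function(ct) {
  keep <- stats::complete.cases(ct$features)
  if (!any(keep))
    stop("well '", ct$well_id, "' has no complete cell rows", call. = FALSE)
  cell_table(ct$well_id, ct$features[keep, , drop = FALSE])
}

#' Restrict all wells to their shared features
#'
#' Mirrors the fixed-feature-subset requirement of a trained aggregator:
#' the intersection of feature names across wells is taken, in the order of
#' the first well, and every table is subset to it.
#'
#' @param cell_tables List of [cell_table()].
#' @return List of tables over the common feature set.
#' @export
intersect_features <- function(cell_tables) {
  common <- Reduce(intersect, lapply(cell_tables, function(ct)
    colnames(ct$features)))
  if (length(common) == 0)
    stop("no features shared across all wells", call. = FALSE)
  lapply(cell_tables, function(ct)
    cell_table(ct$well_id, ct$features[, common, drop = FALSE]))
}

#' Construct a set of aggregated well-level profiles
#'
#' @param profiles Numeric matrix, wells x dimensions; row names are well ids.
#' @param well_records Metadata `data.frame`, one row per profile row, aligned.
#' @param provenance `"model"` or `"average_baseline"`.
#' @return An object of class `profile_set`.
#' @export
profile_set <- function(profiles, well_records,
                        provenance = c("model", "average_baseline")) {
  provenance <- match.arg(provenance)
  profiles <- as.matrix(profiles)
  if (nrow(profiles) != nrow(well_records))
    stop("profiles and well_records have different numbers of wells",
         call. = FALSE)
  if (anyNA(profiles)) stop("profiles contain missing values", call. = FALSE)
  rownames(profiles) <- well_records$well_id
  structure(list(profiles = profiles, well_records = well_records,
                 provenance = provenance),
            class = "profile_set")
}

#' @export
print.profile_set <- function(x, ...) {
  cat(sprintf("<profile_set> %d wells x %d dims (%s)\n",
              nrow(x$profiles), ncol(x$profiles), x$provenance))
  invisible(x)
}

#' Write a profile set to CSV with metadata columns prepended
#'
#' @param ps A [profile_set()].
#' @param path Output CSV path.
#' @export
write_profile_set <- function(ps, path) {
  df <- cbind(ps$well_records,
              as.data.frame(ps$profiles, row.names = NULL))
  data.table::fwrite(df, path)
  invisible(path)
}
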