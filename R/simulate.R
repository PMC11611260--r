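#' Configuration for the synthetic profiling-data generator
#'
#' The generator emulates the structure of multi-well Cell Painting screens:
#' plates of replicate wells, thousands of cells per well, CellProfiler-style
#' feature columns, classes (perturbations) that differ in their mean and/or
#' in second- or third-order moments only, optional additive plate and
#' well-position effects, and an optional class-independent "debris"
#' subpopulation.
#'
#' @param n_perturbations Number of perturbation classes.
#' @param replicates_per_perturbation Replicate wells per perturbation
#'   (>= 2, required by the contrastive objective).
#' @param cells_per_well_mean,cells_per_well_std Gaussian for per-well cell
#'   counts (floored at 1).
#' @param D Features per cell (>= 2; >= 4 when plates carry marker columns).
#' @param class_signal Where the class information lives: `"mean"`,
#'   `"covariance"` (rotation of a shared anisotropic Gaussian, identical
#'   means), `"skewness"` (identical mean and variance, differing third
#'   moment), or `"mixed"` (mean + covariance).
#' @param effect_size Strength of the class signal: sd of class mean shifts
#'   (`mean`), log-anisotropy of the rotated covariance (`covariance`), or
#'   half-range of the sinh-arcsinh skew parameter (`skewness`).
#' @param plate_effect_sd,well_effect_sd SDs of additive per-plate and
#'   per-well-position feature shifts.
#' @param debris_fraction Fraction of each well's cells drawn from the shared
#'   uninformative debris distribution.
#' @param n_plates Number of plates; replicates are spread across plates.
#' @param controls_per_plate Negative-control (DMSO-like) wells per plate.
#' @param n_singleton_moa Number of compounds assigned a mechanism-of-action
#'   label shared with no other compound (exercises the exclusion rule).
#' @param seed Integer seed; generation is bit-reproducible given the config.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_perturbations = 10, replicates_per_perturbation = 4,
                       cells_per_well_mean = 500, cells_per_well_std = 50,
                       D = 20, class_signal = c("covariance", "mean",
                                                "skewness", "mixed"),
                       effect_size = 1, plate_effect_sd = 0,
                       well_effect_sd = 0, debris_fraction = 0,
                       n_plates = 1, controls_per_plate = 4,
                       n_singleton_moa = 1, seed = 1L) {
  class_signal <- match.arg(class_signal)
  stopifnot(n_perturbations >= 2, replicates_per_perturbation >= 2,
            cells_per_well_mean > 0, D >= 2, effect_size >= 0,
            debris_fraction >= 0, debris_fraction < 1, n_plates >= 1)
  if (class_signal %in% c("covariance", "mixed") && D < 2)
    stop("covariance (rotation) signal needs D >= 2", call. = FALSE)
  structure(list(n_perturbations = n_perturbations,
                 replicates_per_perturbation = replicates_per_perturbation,
                 cells_per_well_mean = cells_per_well_mean,
                 cells_per_well_std = cells_per_well_std, D = D,
                 class_signal = class_signal, effect_size = effect_size,
                 plate_effect_sd = plate_effect_sd,
                 well_effect_sd = well_effect_sd,
                 debris_fraction = debris_fraction, n_plates = n_plates,
                 controls_per_plate = controls_per_plate,
                 n_singleton_moa = n_singleton_moa, seed = as.integer(seed)),
            class = "sim_config")
}

# Moments of sinh(asinh(Z) + delta) for Z ~ N(0,1), by numerical integration;
# used to recenter/rescale the skew-warped marginal to mean 0, variance 1.
sinh_arcsinh_moments <- function(delta) {
  mom <- function(k) stats::integrate(function(z)
    sinh(asinh(z) + delta)^k * stats::dnorm(z), -Inf, Inf,
    rel.tol = 1e-10)$value
  m1 <- mom(1); m2 <- mom(2); m3 <- mom(3)
  var <- m2 - m1^2
  skew <- (m3 - 3 * m1 * var - m1^3) / var^1.5
  list(mean = m1, sd = sqrt(var), skewness = skew)
}

# Draw n skew-warped standardized values with sinh-arcsinh skew delta.
rskewed <- function(n, delta, moments = sinh_arcsinh_moments(delta)) {
  (sinh(asinh(rnorm(n)) + delta) - moments$mean) / moments$sd
}

# Per-class generating parameters for each signal mode.
class_parameters <- function(config) {
  C <- config$n_perturbations
  ids <- sprintf("pert_%02d", seq_len(C))
  out <- list(perturbation_id = ids, signal = config$class_signal)
  if (config$class_signal %in% c("mean", "mixed"))
    out$mu <- lapply(seq_len(C), function(c)
      rnorm(config$D, 0, config$effect_size))
  if (config$class_signal %in% c("covariance", "mixed")) {
    out$angle <- (seq_len(C) - 1) * pi / C
    out$eigenvalues <- c(exp(config$effect_size), exp(-config$effect_size))
  }
  if (config$class_signal == "skewness") {
    out$delta <- seq(-config$effect_size, config$effect_size, length.out = C)
    out$moments <- lapply(out$delta, sinh_arcsinh_moments)
    out$skewness <- vapply(out$moments, `[[`, numeric(1), "skewness")
  }
  out
}

# Sample n cells of class index c over feature columns `cols` of a D-wide
# matrix; remaining columns are standard normal noise.
sample_class_cells <- function(n, c_idx, pars, config, signal_cols) {
  D <- config$D
  X <- matrix(rnorm(n * D), n, D)
  sc <- signal_cols
  switch(pars$signal,
    mean = {
      X <- X + matrix(pars$mu[[c_idx]], n, D, byrow = TRUE)
    },
    covariance = {
      th <- pars$angle[c_idx]
      R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
      L <- R %*% diag(sqrt(pars$eigenvalues)) %*% t(R)
      X[, sc[1:2]] <- matrix(rnorm(n * 2), n, 2) %*% L
    },
    skewness = {
      X[, sc[1]] <- rskewed(n, pars$delta[c_idx], pars$moments[[c_idx]])
    },
    mixed = {
      th <- pars$angle[c_idx]
      R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
      L <- R %*% diag(sqrt(pars$eigenvalues)) %*% t(R)
      X[, sc[1:2]] <- matrix(rnorm(n * 2), n, 2) %*% L
      X <- X + matrix(pars$mu[[c_idx]], n, D, byrow = TRUE)
    })
  X
}

well_positions <- function(n) {
  grid <- expand.grid(col = 1:24, row = LETTERS[1:16])
  sprintf("%s%02d", grid$row[seq_len(n)], grid$col[seq_len(n)])
}

#' Simulate replicate wells whose classes differ only in chosen moments
#'
#' Ten (by default) perturbation classes with `replicates_per_perturbation`
#' wells each, all on one plate. In `covariance` mode every class shares the
#' eigenvalue spectrum and the zero mean; only the rotation of the
#' anisotropic component (features 1-2) identifies the class, so average
#' profiles are uninformative by construction. In `skewness` mode classes
#' match in mean and variance and differ only in the third moment of feature
#' 1, induced by a monotone sinh-arcsinh warp of a normal variate with
#' numerically matched first two moments.
#'
#' @param config A [sim_config()].
#' @return List with `cell_tables`, `well_records` and `ground_truth`
#'   (generating parameters, incl. theoretical skewness per class where
#'   applicable).
#' @export
simulate_moment_classes <- function(config = sim_config()) {
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(config$seed)

  pars <- class_parameters(config)
  C <- config$n_perturbations
  R <- config$replicates_per_perturbation
  feature_names <- sprintf("feat_%03d", seq_len(config$D))
  signal_cols <- seq_len(min(2, config$D))

  tables <- list(); wid <- character(0); pid <- character(0)
  for (c_idx in seq_len(C)) for (r in seq_len(R)) {
    n <- max(1L, as.integer(round(rnorm(1, config$cells_per_well_mean,
                                        config$cells_per_well_std))))
    X <- sample_class_cells(n, c_idx, pars, config, signal_cols)
    colnames(X) <- feature_names
    id <- sprintf("%s_r%d", pars$perturbation_id[c_idx], r)
    tables[[id]] <- cell_table(id, X)
    wid <- c(wid, id); pid <- c(pid, pars$perturbation_id[c_idx])
  }
  wr <- well_records(well_id = wid, plate_id = "plate_01",
                     well_position = well_positions(length(wid)),
                     perturbation_id = pid)
  list(cell_tables = tables, well_records = wr,
       ground_truth = list(config = config, classes = pars,
                           signal_cols = signal_cols))
}

#' Simulate a multi-plate profiling screen with controls, debris and MoAs
#'
#' Lays wells out on `n_plates` plates with negative-control wells, additive
#' per-plate and per-well-position feature shifts, mechanism-of-action
#' annotations (including singleton MoAs to exercise the exclusion rule), and
#' an optional class-independent debris subpopulation.
#'
#' The first two feature columns are designated morphology markers,
#' `AreaShape_Area` and `Intensity_MeanEdge`: ordinary cells score high on
#' area and low on edge intensity, debris cells the reverse, and debris
#' carries no class signal in the remaining features — so debris is
#' uninformative for perturbation identity by construction. Class signal
#' lives in columns 3 onward. Negative-control cells are signal-free like
#' debris but carry ordinary marker values.
#'
#' @param config A [sim_config()] with `D >= 4`.
#' @return List with `cell_tables`, `well_records`, `ground_truth`;
#'   `ground_truth$debris` holds a logical vector per well flagging its
#'   debris cells (row-aligned with the cell table).
#' @export
simulate_profiling_plates <- function(config = sim_config(plate_effect_sd = 0.1,
                                                          debris_fraction = 0.2)) {
  if (config$D < 4)
    stop("plate simulation needs D >= 4 (two marker + two signal columns)",
         call. = FALSE)
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(config$seed)

  pars <- class_parameters(config)
  C <- config$n_perturbations
  R <- config$replicates_per_perturbation
  D <- config$D
  feature_names <- c("AreaShape_Area", "Intensity_MeanEdge",
                     sprintf("feat_%03d", seq_len(D - 2) + 2L))
  signal_cols <- c(3L, 4L)
  marker_mu <- c(0.5, -0.5)          # ordinary cells
  debris_mu <- c(-2, 2)              # small area, bright edges

  # MoA assignment: pairs of compounds share one MoA; the last
  # n_singleton_moa compounds get labels of their own.
  moa_of <- character(C)
  n_single <- min(config$n_singleton_moa, C)
  paired <- seq_len(C - n_single)
  if (length(paired)) {
    grp <- ceiling(paired / 2)
    # an odd leftover compound joins the previous group so that every
    # non-singleton MoA really has >= 2 compounds
    if (length(paired) %% 2 == 1 && length(paired) > 1)
      grp[length(paired)] <- grp[length(paired)] - 1L
    moa_of[paired] <- sprintf("moa_%02d", grp)
  }
  if (n_single > 0)
    moa_of[(C - n_single + 1):C] <-
      sprintf("moa_single_%02d", seq_len(n_single))

  plate_ids <- sprintf("plate_%02d", seq_len(config$n_plates))
  plate_shift <- lapply(plate_ids, function(p)
    rnorm(D, 0, config$plate_effect_sd))
  names(plate_shift) <- plate_ids
  pos_shift_cache <- new.env(parent = emptyenv())
  pos_shift <- function(pos) {
    if (is.null(pos_shift_cache[[pos]]))
      pos_shift_cache[[pos]] <- rnorm(D, 0, config$well_effect_sd)
    pos_shift_cache[[pos]]
  }

  # round-robin replicate placement across plates
  plate_of_rep <- function(r) plate_ids[((r - 1) %% config$n_plates) + 1]
  next_pos <- setNames(rep(1L, length(plate_ids)), plate_ids)
  all_pos <- well_positions(384)

  tables <- list(); debris_flags <- list()
  wid <- pid <- plid <- wpos <- role <- moa <- character(0)

  draw_cells <- function() max(1L, as.integer(round(
    rnorm(1, config$cells_per_well_mean, config$cells_per_well_std))))

  make_well <- function(id, plate, c_idx, is_control) {
    n <- draw_cells()
    n_deb <- if (is_control) 0L else
      as.integer(round(config$debris_fraction * n))
    n_ord <- n - n_deb
    X <- matrix(rnorm(n * D), n, D)
    if (n_ord > 0 && !is_control)
      X[seq_len(n_ord), ] <- sample_class_cells(n_ord, c_idx, pars, config,
                                                signal_cols)
    X[seq_len(n_ord), 1:2] <- X[seq_len(n_ord), 1:2, drop = FALSE] +
      matrix(marker_mu, max(n_ord, 0), 2, byrow = TRUE)
    if (n_deb > 0) {
      deb <- n_ord + seq_len(n_deb)
      X[deb, ] <- matrix(rnorm(n_deb * D), n_deb, D)  # no class signal
      X[deb, 1:2] <- X[deb, 1:2, drop = FALSE] * 0.5 +
        matrix(debris_mu, n_deb, 2, byrow = TRUE)
    }
    pos <- all_pos[next_pos[[plate]]]
    next_pos[[plate]] <<- next_pos[[plate]] + 1L
    X <- X + matrix(plate_shift[[plate]] + pos_shift(pos), n, D, byrow = TRUE)
    colnames(X) <- feature_names
    tables[[id]] <<- cell_table(id, X)
    debris_flags[[id]] <<- c(rep(FALSE, n_ord), rep(TRUE, n_deb))
    wid <<- c(wid, id); plid <<- c(plid, plate); wpos <<- c(wpos, pos)
  }

  for (c_idx in seq_len(C)) for (r in seq_len(R)) {
    id <- sprintf("%s_r%d", pars$perturbation_id[c_idx], r)
    make_well(id, plate_of_rep(r), c_idx, is_control = FALSE)
    pid <- c(pid, pars$perturbation_id[c_idx])
    role <- c(role, "treatment"); moa <- c(moa, moa_of[c_idx])
  }
  for (p in plate_ids) for (k in seq_len(config$controls_per_plate)) {
    id <- sprintf("DMSO_%s_c%d", p, k)
    make_well(id, p, c_idx = 1L, is_control = TRUE)
    pid <- c(pid, "DMSO"); role <- c(role, "negative_control")
    moa <- c(moa, NA_character_)
  }

  wr <- well_records(well_id = wid, plate_id = plid, well_position = wpos,
                     perturbation_id = pid, moa = moa, role = role)
  list(cell_tables = tables, well_records = wr,
       ground_truth = list(config = config, classes = pars,
                           moa_of = setNames(moa_of, pars$perturbation_id),
                           plate_shift = plate_shift,
                           signal_cols = signal_cols,
                           marker_mu = marker_mu, debris_mu = debris_mu,
                           debris = debris_flags))
}
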