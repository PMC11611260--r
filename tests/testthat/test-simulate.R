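test_that("covariance-mode classes share the zero mean but differ in rotation", {
  scfg <- sim_config(n_perturbations = 4, replicates_per_perturbation = 2,
                     cells_per_well_mean = 5000, cells_per_well_std = 0,
                     D = 6, class_signal = "covariance", effect_size = 1,
                     seed = 3)
  sim <- simulate_moment_classes(scfg)
  gt <- sim$ground_truth
  for (c_idx in 1:4) {
    pert <- gt$classes$perturbation_id[c_idx]
    ids <- sim$well_records$well_id[sim$well_records$perturbation_id == pert]
    X <- do.call(rbind, lapply(sim$cell_tables[ids], `[[`, "features"))
    n <- nrow(X)
    # class means within 3 standard errors of zero (features carry sd <= e)
    se <- apply(X, 2, sd) / sqrt(n)
    expect_true(all(abs(colMeans(X)) < 3 * se + 1e-12))
    # leading eigenvector of the 2x2 signal block recovers the angle to 5 deg
    S <- cov(X[, gt$signal_cols])
    ev <- eigen(S)$vectors[, 1]
    ang <- atan2(ev[2], ev[1]) %% pi
    diff <- min(abs(ang - gt$classes$angle[c_idx]),
                pi - abs(ang - gt$classes$angle[c_idx]))
    expect_lt(diff * 180 / pi, 5)
  }
})

test_that("skewness-mode classes match first two moments and differ in the third", {
  scfg <- sim_config(n_perturbations = 5, replicates_per_perturbation = 2,
                     cells_per_well_mean = 20000, cells_per_well_std = 0,
                     D = 3, class_signal = "skewness", effect_size = 1,
                     seed = 4)
  sim <- simulate_moment_classes(scfg)
  gt <- sim$ground_truth
  skews <- numeric(5)
  for (c_idx in 1:5) {
    pert <- gt$classes$perturbation_id[c_idx]
    ids <- sim$well_records$well_id[sim$well_records$perturbation_id == pert]
    x <- do.call(rbind, lapply(sim$cell_tables[ids],
                               `[[`, "features"))[, gt$signal_cols[1]]
    n <- length(x)
    expect_lt(abs(mean(x)), 3 / sqrt(n) * sd(x))
    expect_lt(abs(var(x) - 1), 0.1)
    skews[c_idx] <- mean((x - mean(x))^3) / sd(x)^3
  }
  # sample skewness tracks the configured theoretical values
  expect_equal(skews, gt$classes$skewness, tolerance = 0.15)
  expect_true(all(diff(gt$classes$delta) > 0))
})

test_that("generation is bit-reproducible and passes input validation", {
  s1 <- simulate_profiling_plates(sim_config(seed = 7, D = 6,
                                             cells_per_well_mean = 40,
                                             cells_per_well_std = 5,
                                             debris_fraction = 0.2,
                                             plate_effect_sd = 0.2,
                                             n_plates = 2))
  s2 <- simulate_profiling_plates(sim_config(seed = 7, D = 6,
                                             cells_per_well_mean = 40,
                                             cells_per_well_std = 5,
                                             debris_fraction = 0.2,
                                             plate_effect_sd = 0.2,
                                             n_plates = 2))
  expect_identical(lapply(s1$cell_tables, `[[`, "features"),
                   lapply(s2$cell_tables, `[[`, "features"))
  expect_identical(s1$well_records, s2$well_records)

  # metadata validates and covers every table; feature names consistent
  expect_silent(cytosets:::validate_well_records(s1$well_records))
  expect_setequal(names(s1$cell_tables), s1$well_records$well_id)
  fn <- lapply(s1$cell_tables, function(ct) colnames(ct$features))
  expect_length(unique(fn), 1)
  expect_false(any(vapply(s1$cell_tables,
                          function(ct) anyNA(ct$features), logical(1))))
})

test_that("debris and plate-effect switches act as documented", {
  clean <- simulate_profiling_plates(sim_config(seed = 9, D = 6,
                                                cells_per_well_mean = 30,
                                                debris_fraction = 0))
  expect_false(any(unlist(clean$ground_truth$debris)))

  deb <- simulate_profiling_plates(sim_config(seed = 9, D = 6,
                                              cells_per_well_mean = 30,
                                              cells_per_well_std = 3,
                                              debris_fraction = 0.3))
  trt <- deb$well_records$well_id[deb$well_records$role == "treatment"]
  expect_true(all(vapply(deb$ground_truth$debris[trt], any, logical(1))))

  flat <- simulate_profiling_plates(sim_config(seed = 9, D = 6,
                                               plate_effect_sd = 0,
                                               n_plates = 2))
  expect_true(all(vapply(flat$ground_truth$plate_shift,
                         function(s) all(s == 0), logical(1))))
})

test_that("singleton MoAs flow through to the exclusion report end to end", {
  sim <- simulate_profiling_plates(sim_config(n_perturbations = 6, seed = 13,
                                              D = 8, cells_per_well_mean = 60,
                                              n_singleton_moa = 1))
  ps <- average_baseline_profiles(sim$cell_tables, sim$well_records)
  res <- moa_retrieval_map(ps)
  singles <- names(sim$ground_truth$moa_of)[
    grepl("single", sim$ground_truth$moa_of)]
  expect_setequal(res$excluded, singles)
})

test_that("a strong mean signal makes the average baseline near-perfect", {
  # calibration: the simulator is not trivially hard
  sim <- simulate_moment_classes(sim_config(n_perturbations = 6,
                                            replicates_per_perturbation = 3,
                                            cells_per_well_mean = 200,
                                            cells_per_well_std = 10,
                                            D = 10, class_signal = "mean",
                                            effect_size = 2, seed = 17))
  ps <- average_baseline_profiles(sim$cell_tables, sim$well_records)
  expect_gt(replicate_retrieval_map(ps)$map, 0.95)
})
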