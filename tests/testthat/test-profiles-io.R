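test_that("loading drops NaN-containing cell rows and validates schema", {
  d <- withr::local_tempdir()
  m1 <- cbind(a = c(1, 2, NA), b = c(4, 5, 6))
  m2 <- cbind(a = c(7, 8), b = c(9, 10))
  write.csv(m1, file.path(d, "w1.csv"), row.names = FALSE)
  write.csv(m2, file.path(d, "w2.csv"), row.names = FALSE)
  meta <- data.frame(well_id = c("w1", "w2"), plate_id = "P1",
                     well_position = c("A01", "A02"),
                     perturbation_id = c("x", "y"), moa = NA, role = "treatment")
  write.csv(meta, file.path(d, "meta.csv"), row.names = FALSE)

  res <- load_cell_tables(file.path(d, c("w1.csv", "w2.csv")),
                          file.path(d, "meta.csv"))
  expect_equal(nrow(res$cell_tables$w1$features), 2)  # NaN row dropped
  expect_equal(nrow(res$cell_tables$w2$features), 2)
  expect_identical(colnames(res$cell_tables$w1$features),
                   colnames(res$cell_tables$w2$features))

  # the same file under two well ids yields equal matrices
  file.copy(file.path(d, "w2.csv"), file.path(d, "w3.csv"))
  meta3 <- rbind(meta, data.frame(well_id = "w3", plate_id = "P1",
                                  well_position = "A03",
                                  perturbation_id = "y", moa = NA,
                                  role = "treatment"))
  write.csv(meta3, file.path(d, "meta3.csv"), row.names = FALSE)
  res3 <- load_cell_tables(file.path(d, c("w2.csv", "w3.csv")),
                           file.path(d, "meta3.csv"))
  expect_equal(res3$cell_tables$w2$features, res3$cell_tables$w3$features,
               ignore_attr = FALSE)

  # empty file errors rather than producing an empty table
  writeLines("a,b", file.path(d, "empty.csv"))
  expect_error(load_cell_tables(file.path(d, c("empty.csv")),
                                file.path(d, "meta.csv")), "empty")

  # mismatched feature sets name the offending column
  write.csv(cbind(a = 1:2, z = 3:4), file.path(d, "w4.csv"),
            row.names = FALSE)
  meta4 <- meta; meta4$well_id <- c("w1", "w4")
  write.csv(meta4, file.path(d, "meta4.csv"), row.names = FALSE)
  expect_error(load_cell_tables(file.path(d, c("w1.csv", "w4.csv")),
                                file.path(d, "meta4.csv")), "z")

  # well without metadata
  expect_error(load_cell_tables(file.path(d, c("w1.csv", "w3.csv")),
                                file.path(d, "meta.csv")), "metadata")
})

test_that("long-table input with a well_id column splits into wells", {
  d <- withr::local_tempdir()
  long <- data.frame(well_id = rep(c("w1", "w2"), each = 3),
                     a = rnorm(6), b = rnorm(6))
  write.csv(long, file.path(d, "cells.csv"), row.names = FALSE)
  meta <- data.frame(well_id = c("w1", "w2"), plate_id = "P1",
                     well_position = c("A01", "A02"),
                     perturbation_id = "x", moa = NA, role = "treatment")
  write.csv(meta, file.path(d, "meta.csv"), row.names = FALSE)
  res <- load_cell_tables(file.path(d, "cells.csv"), file.path(d, "meta.csv"))
  expect_named(res$cell_tables, c("w1", "w2"))
  expect_equal(nrow(res$cell_tables$w1$features), 3)
})

test_that("plate standardization pools all wells and hits zero mean, unit variance", {
  # single feature pooled over the plate: [1,2,3] -> +/-1.2247, 0
  tabs <- list(w1 = cell_table("w1", matrix(c(1, 2), 2, 1,
                                            dimnames = list(NULL, "f"))),
               w2 = cell_table("w2", matrix(3, 1, 1,
                                            dimnames = list(NULL, "f"))))
  wr <- well_records(c("w1", "w2"), "P1", c("A01", "A02"), c("x", "y"))
  out <- standardize_plate(tabs, wr, "P1")
  pooled <- c(out$w1$features, out$w2$features)
  expect_equal(pooled, c(-1.224744871, 0, 1.224744871), tolerance = 1e-8)

  # pooled moments over a bigger random plate
  set.seed(1)
  tabs2 <- list(a = cell_table("a", random_cells(40, 5, 1) * 3 + 2),
                b = cell_table("b", random_cells(25, 5, 2) * 0.5 - 1))
  wr2 <- well_records(c("a", "b"), "P1", c("A01", "A02"), c("x", "y"))
  out2 <- standardize_plate(tabs2, wr2, "P1")
  pooled2 <- rbind(out2$a$features, out2$b$features)
  expect_lt(max(abs(colMeans(pooled2))), 1e-6)
  expect_lt(max(abs(colMeans(pooled2^2) - 1)), 1e-6)

  # idempotence
  out3 <- standardize_plate(out2, wr2, "P1")
  expect_equal(out3$a$features, out2$a$features, tolerance = 1e-6)

  # constant features map to zero
  tabs3 <- list(w = cell_table("w", matrix(5, 4, 1,
                                           dimnames = list(NULL, "f"))))
  wr3 <- well_records("w", "P1", "A01", "x")
  expect_true(all(standardize_plate(tabs3, wr3, "P1")$w$features == 0))

  # plate locality: editing plate B leaves plate A untouched
  fx <- fixture_plates()
  s1 <- standardize_all_plates(fx$cell_tables, fx$well_records)
  fx2 <- fx
  fx2$cell_tables$w3$features <- fx2$cell_tables$w3$features * 10
  s2 <- standardize_all_plates(fx2$cell_tables, fx2$well_records)
  expect_identical(s1$w1$features, s2$w1$features)
  expect_false(identical(s1$w3$features, s2$w3$features))

  expect_error(standardize_plate(tabs, wr, "nope"), "no wells")
})

test_that("average profile is the column mean and permutation invariant", {
  ct <- cell_table("w", rbind(c(1, 2), c(3, 4)))
  expect_equal(unname(average_profile(ct)), c(2, 3))
  single <- cell_table("w", matrix(c(7, 8), 1, 2))
  expect_equal(unname(average_profile(single)), c(7, 8))
  X <- random_cells(50, 6)
  perm <- sample(50)
  expect_equal(average_profile(cell_table("w", X)),
               average_profile(cell_table("w", X[perm, ])))
})

test_that("RobustMAD normalization matches the hand computation", {
  m <- matrix(c(1, 2, 3, 4, 100), 5, 1, dimnames = list(NULL, "f"))
  out <- robust_mad_normalize(m)
  # median 3, MAD 1: value 4 -> 1 / 1.4826
  expect_equal(unname(out[4, 1]), 1 / 1.4826, tolerance = 1e-9)

  # symmetric column stays antisymmetric around 0
  s <- matrix(c(-2, 0, 2), 3, 1, dimnames = list(NULL, "f"))
  outs <- robust_mad_normalize(s)
  expect_equal(unname(outs[1, 1]), -unname(outs[3, 1]))
  expect_equal(unname(outs[2, 1]), 0)

  # constant column collapses to ~0 under the epsilon guard
  cst <- matrix(7, 4, 1, dimnames = list(NULL, "f"))
  expect_true(all(abs(robust_mad_normalize(cst)) < 1e-6))

  # row (well) permutation commutes
  m2 <- matrix(rnorm(30), 10, 3)
  perm <- sample(10)
  expect_equal(robust_mad_normalize(m2)[perm, ],
               robust_mad_normalize(m2[perm, ]))

  # mean-absolute-deviation variant: column [1,2,3,4,100], mean |dev| = 20.2
  out_mean <- robust_mad_normalize(m, deviation = "mean")
  expect_equal(unname(out_mean[4, 1]), 1 / (1.4826 * 20.2), tolerance = 1e-9)
})

test_that("feature selection drops constant and correlated features deterministically", {
  set.seed(9)
  base <- matrix(rnorm(60), 20, 3,
                 dimnames = list(NULL, c("a", "b", "c")))
  m <- cbind(base, a_copy = base[, "a"], flat = rep(1, 20))
  sel <- select_features(m, correlation_threshold = 0.9)
  expect_false("flat" %in% sel$kept)         # zero variance
  expect_true("a" %in% sel$kept)             # earlier name survives
  expect_false("a_copy" %in% sel$kept)       # |r| = 1 duplicate removed

  # independent columns below the threshold are all retained
  set.seed(10)
  ind <- matrix(rnorm(500 * 4), 500, 4,
                dimnames = list(NULL, c("p", "q", "r", "s")))
  stopifnot(max(abs(cor(ind)[upper.tri(diag(4))])) < 0.9)
  expect_setequal(select_features(ind)$kept, c("p", "q", "r", "s"))

  expect_error(select_features(matrix(1, 5, 2,
                                      dimnames = list(NULL, c("x", "y")))),
               "threshold")
})

test_that("baseline profile construction follows the documented order", {
  fx <- fixture_plates()
  ps <- average_baseline_profiles(fx$cell_tables, fx$well_records)
  expect_s3_class(ps, "profile_set")
  expect_identical(ps$provenance, "average_baseline")
  # controls removed
  expect_true(all(ps$well_records$role == "treatment"))
  expect_equal(nrow(ps$profiles), 4)
  expect_false(anyNA(ps$profiles))
  expect_type(attr(ps, "kept_features"), "character")
})
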