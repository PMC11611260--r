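test_that("cosine similarity matrix has the expected geometry", {
  m <- rbind(e1 = c(1, 0), e2 = c(0, 1), scaled = c(3, 0), neg = c(-1, 0))
  wr <- well_records(rownames(m), "P1", c("A01", "A02", "A03", "A04"),
                     c("a", "b", "a", "c"))
  s <- cosine_similarity_matrix(profile_set(m, wr, "model"))
  expect_equal(s["e1", "e2"], 0)
  expect_equal(s["e1", "scaled"], 1)     # scale invariance
  expect_equal(s["e1", "neg"], -1)
  expect_equal(s, t(s))
  expect_true(all(diag(s) == 1))

  m0 <- rbind(ok = c(1, 0), zero = c(0, 0))
  wr0 <- well_records(c("ok", "zero"), "P1", c("A01", "A02"), c("a", "b"))
  expect_error(cosine_similarity_matrix(profile_set(m0, wr0, "model")),
               "zero")
})

test_that("average precision matches closed forms and the staircase oracle", {
  expect_equal(average_precision(c(TRUE, TRUE, TRUE, FALSE)), 1)  # perfect
  for (k in 1:8) {
    flags <- rep(FALSE, 8); flags[k] <- TRUE
    expect_equal(average_precision(flags), 1 / k)  # single positive at rank k
  }
  f1 <- rep(FALSE, 10); f1[c(1, 2, 4)] <- TRUE
  expect_equal(average_precision(f1), (1 + 1 + 3 / 4) / 3)
  f2 <- c(FALSE, FALSE, FALSE, TRUE, TRUE)
  expect_equal(average_precision(f2), (1 / 4 + 2 / 5) / 2)

  expect_error(average_precision(rep(FALSE, 3)), "positive")

  # exhaustive agreement with the precision-recall staircase, lengths <= 12
  for (n in 1:12) {
    combos <- as.matrix(expand.grid(rep(list(c(FALSE, TRUE)), n)))
    for (r in seq_len(nrow(combos))) {
      flags <- combos[r, ]
      if (!any(flags)) next
      expect_equal(average_precision(flags), oracle_ap_staircase(flags))
    }
  }
})

test_that("replicate retrieval scores equality structure correctly", {
  # identical within compound, orthogonal across -> perfect mAP
  m <- rbind(a1 = c(1, 0, 0), a2 = c(1, 0, 0),
             b1 = c(0, 1, 0), b2 = c(0, 1, 0))
  wr <- well_records(rownames(m), "P1", sprintf("A%02d", 1:4),
                     c("a", "a", "b", "b"))
  res <- replicate_retrieval_map(profile_set(m, wr, "model"))
  expect_equal(res$map, 1)
  expect_equal(nrow(res$per_compound), 2)
  expect_equal(mean(res$per_compound$ap), res$map)  # internal consistency

  # compound A's profiles nearer to B's than to each other -> mAP < 0.5
  m2 <- rbind(a1 = c(1, 0), a2 = c(-1, 0.02),
              b1 = c(0.9, 0.1), b2 = c(-0.9, 0.1))
  wr2 <- well_records(rownames(m2), "P1", sprintf("A%02d", 1:4),
                      c("a", "a", "b", "b"))
  expect_lt(replicate_retrieval_map(profile_set(m2, wr2, "model"))$map, 0.5)

  # no replicated perturbation -> error
  wr3 <- well_records(rownames(m), "P1", sprintf("A%02d", 1:4),
                      c("a", "b", "c", "d"))
  expect_error(replicate_retrieval_map(profile_set(m, wr3, "model")),
               "replicate")
})

test_that("random profiles score at the permutation-null level", {
  set.seed(31)
  W <- 48
  m <- matrix(rnorm(W * 10), W, 10)
  wr <- well_records(sprintf("w%02d", 1:W), "P1", well_positions_for_test(W),
                     rep(sprintf("c%02d", 1:12), each = 4))
  ps <- profile_set(m, wr, "model")
  obs <- replicate_retrieval_map(ps)$map
  null <- permutation_null_replicate_map(ps, n_perm = 1000, seed = 4)
  expect_gt(obs, null$ci[1])
  expect_lt(obs, null$ci[2])
})

test_that("similarity ties break deterministically by well id and are counted", {
  m <- rbind(q = c(1, 0), dup1 = c(1, 1), dup2 = c(1, 1), far = c(0, 1))
  wr <- well_records(rownames(m), "P1", sprintf("A%02d", 1:4),
                     c("x", "x", "y", "y"))
  res1 <- replicate_retrieval_map(profile_set(m, wr, "model"))
  res2 <- replicate_retrieval_map(profile_set(m, wr, "model"))
  expect_identical(res1$per_query, res2$per_query)
  expect_true(any(res1$per_query$n_ties > 0))
  # dup1 ranks before dup2 for the query despite equal similarity
  expect_equal(res1$per_query$ap[res1$per_query$well_id == "q"], 1)
})

test_that("mAP is invariant to rotation and scaling of the profiles", {
  set.seed(12)
  m <- matrix(rnorm(20 * 6), 20, 6)
  wr <- well_records(sprintf("w%02d", 1:20), "P1", well_positions_for_test(20),
                     rep(sprintf("c%d", 1:5), each = 4))
  ps1 <- profile_set(m, wr, "model")
  Q <- qr.Q(qr(matrix(rnorm(36), 6, 6)))
  ps2 <- profile_set(m %*% Q * 7, wr, "model")
  expect_equal(replicate_retrieval_map(ps1)$map,
               replicate_retrieval_map(ps2)$map, tolerance = 1e-10)
})

test_that("MoA retrieval excludes own-compound profiles and singleton MoAs", {
  # two sister compounds with one shared MoA, identical profiles within the
  # MoA and orthogonal to everything else -> mAP 1
  m <- rbind(a1 = c(1, 0, 0), a2 = c(1, 0, 0),
             b1 = c(1, 0, 0), b2 = c(1, 0, 0),
             s1 = c(0, 1, 0), s2 = c(0, 0.9, 0.1))
  wr <- well_records(rownames(m), "P1", sprintf("A%02d", 1:6),
                     c("a", "a", "b", "b", "solo", "solo"),
                     moa = c("m1", "m1", "m1", "m1", "m_single", "m_single"))
  res <- moa_retrieval_map(profile_set(m, wr, "model"))
  expect_equal(res$map, 1)
  expect_identical(res$excluded, "solo")
  expect_false("solo" %in% res$per_compound$perturbation_id)
  expect_true("m1" %in% res$per_moa$moa)

  # multi-label positives: labels intersect counts as positive
  wr2 <- wr
  wr2$moa <- c("m1|extra", "m1|extra", "m1", "m1", "other", "other")
  expect_equal(moa_retrieval_map(profile_set(m, wr2, "model"))$map, 1)

  # no shared MoA anywhere -> error
  wr3 <- wr
  wr3$moa <- c("u1", "u1", "u2", "u2", "u3", "u3")
  expect_error(moa_retrieval_map(profile_set(m, wr3, "model")), "mechanism")
})
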