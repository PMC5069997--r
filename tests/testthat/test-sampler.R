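test_that("sampling matches the exact dual Boltzmann distribution", {
  tgt <- parse_target("(....).")
  for (m in c("d0", "d2")) {
    st <- dual_pf(tgt, TP, m)
    rec <- sample_sequences(st, 20000L, seed = 17L)
    ex <- exact_distribution(tgt, TP, m)
    expect_gt(chisq_pvalue(rec$sequence, ex), 0.001)
    # mean sampled energy within 3 standard errors of the exact mean
    mu <- sum(ex$E * ex$p)
    se <- sqrt(sum((ex$E - mu)^2 * ex$p) / nrow(rec))
    expect_lt(abs(mean(rec$energy) - mu), 3 * se)
    # recorded log-probabilities are the exact conditional masses
    expect_equal(rec$ln_p,
                 -rec$energy / TP$RT - log_dual_partition(st),
                 tolerance = 1e-12)
  }
})

test_that("constrained sampling respects the allowed sets", {
  tgt <- parse_target("((...)).", "NNSNNNNW")
  st <- dual_pf(tgt, TP, "d2")
  rec <- sample_sequences(st, 4000L, seed = 3L)
  ex <- exact_distribution(tgt, TP, "d2")
  expect_gt(chisq_pvalue(rec$sequence, ex), 0.001)
  expect_true(all(substr(rec$sequence, 3L, 3L) %in% c("C", "G")))
  expect_true(all(substr(rec$sequence, 8L, 8L) %in% c("A", "U")))
})

test_that("GC-conditioned sampling is exact in count and distribution", {
  tgt <- parse_target("(....).")
  st <- dual_pf(tgt, TP, "d0", gc_resolved = TRUE)
  rec <- sample_sequences(st, 8000L, seed = 23L, gc = 3L)
  expect_true(all(rec$gc == 3L))
  ex <- exact_distribution(tgt, TP, "d0", gc = 3L)
  expect_gt(chisq_pvalue(rec$sequence, ex), 0.001)
  # fractional GC targets round half-up to a count
  rec2 <- sample_sequences(st, 50L, seed = 1L, gc = 3 / 7)
  expect_true(all(rec2$gc == 3L))
  expect_error(sample_sequences(st, 5L, seed = 1L, gc = 8L), "infeasible")
})

test_that("sampling is deterministic and scale-invariant", {
  tgt <- parse_target("((....)).")
  a <- sample_sequences(dual_pf(tgt, TP, "d2"), 200L, seed = 11L)
  b <- sample_sequences(dual_pf(tgt, TP, "d2"), 200L, seed = 11L)
  expect_identical(a, b)
  s1 <- sample_sequences(dual_pf(tgt, TP, "d2", scale = 1), 300L, seed = 4L)
  s2 <- sample_sequences(dual_pf(tgt, TP, "d2", scale = 2.5), 300L, seed = 4L)
  s3 <- sample_sequences(dual_pf(tgt, TP, "d2", scale = 5), 300L, seed = 4L)
  expect_identical(s1$sequence, s2$sequence)
  expect_identical(s1$sequence, s3$sequence)
})

test_that("fully constrained targets sample the single feasible sequence", {
  tgt <- parse_target("(....).", "GAAAACU")
  st <- dual_pf(tgt, TP, "d2")
  rec <- sample_sequences(st, 20L, seed = 2L)
  expect_true(all(rec$sequence == "GAAAACU"))
  expect_equal(rec$ln_p, rep(0, 20L), tolerance = 1e-12)
})

test_that("MFE filtering keeps exactly the sequences that fold to target", {
  be <- fold_backend_exhaustive(TP, "d2")
  tgt <- parse_target("((((....))))")
  st <- dual_pf(tgt, TP, "d2")
  rec <- sample_sequences(st, 40L, seed = 9L)
  kept <- filter_mfe(rec, tgt, be)
  manual <- vapply(rec$sequence, function(s)
    identical(mfe_fold(be, s)$structure, tgt$db), TRUE)
  expect_identical(kept$sequence, rec$sequence[manual])
  # integrated rejection sampling returns only exact folders
  rec2 <- sample_sequences(st, 5L, seed = 13L, filter_mfe = TRUE,
                           backend = be, max_attempts = 200L)
  expect_true(all(vapply(rec2$sequence, function(s)
    identical(mfe_fold(be, s)$structure, tgt$db), TRUE)))
  expect_true(all(rec2$attempts >= nrow(rec2)))
})
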