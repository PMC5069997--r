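test_that("GC counting and constrained assignment counts are exact", {
  expect_equal(gc_count("GCGC"), 4L)
  expect_equal(gc_count("AUAU"), 0L)
  expect_equal(gc_count("GAUC"), 2L)
  # unconstrained: choose(m,k) * 2^m
  expect_equal(count_constrained_assignments(rep(list(1:4), 3L), 1L),
               choose(3, 1) * 2^3)
  expect_equal(count_constrained_assignments(list(c(2L, 3L), c(1L, 4L)), 1L), 4)
  expect_equal(count_constrained_assignments(rep(list(1:4), 2L), 5L), 0)
  expect_equal(count_constrained_assignments(list("S", "W", "N"), 2L),
               2 * 2 * 2)   # S forced GC, one of {W fails}, N supplies the 2nd
})

test_that("GC-resolved values marginalise to the plain partition function", {
  for (q in 1:6) {
    tgt <- random_small_instance(700L + q, n = 12L, max_count = 4e4)
    for (m in c("d0", "d2")) {
      st <- dual_pf(tgt, TP, m, gc_resolved = TRUE)
      z <- exp(log_dual_partition(dual_pf(tgt, TP, m)))
      zk <- st$Z_total * st$scale^tgt$n
      expect_equal(sum(zk), z, tolerance = 1e-9, label = tgt$db)
    }
  }
})

test_that("GC-resolved values equal the GC-filtered enumeration oracle", {
  for (q in 1:4) {
    tgt <- random_small_instance(900L + q, n = 11L, max_count = 2e4)
    for (m in c("d0", "d2")) {
      st <- dual_pf(tgt, TP, m, gc_resolved = TRUE)
      zk <- st$Z_total * st$scale^tgt$n
      M <- dualpf:::.enumerate_compatible(tgt)
      E <- dualpf:::.seq_energies(M, tgt, TP, m, dualpf:::.resolve_opts())
      gcv <- rowSums(matrix(dualpf:::NT_GC[M], nrow(M)))
      bfk <- vapply(0:tgt$n, function(k) sum(exp(-E[gcv == k] / TP$RT)), 0)
      expect_equal(zk, bfk, tolerance = 1e-9, label = paste(tgt$db, m))
      # support equals the constraint-implied feasible GC range
      expect_identical(zk > 0, bfk > 0)
    }
  }
})

test_that("zero-energy GC profile is a pure compatible-sequence count", {
  tgt <- parse_target("(....)")
  st <- dual_pf(tgt, ZP, "d0", gc_resolved = TRUE, scale = 1)
  # k = 0: pairs {AU, UA} times binom(4,0) * 2^4
  expect_equal(st$Z_total[1L], 2 * 16)
  expect_equal(sum(st$Z_total), 6 * 4^4)
  pr <- gc_profile(st)
  expect_equal(pr$k, 0:6)
  expect_equal(sum(pr$p), 1, tolerance = 1e-12)
})

test_that("forced-GC constraints shift the feasible support", {
  tgt <- parse_target("(....).", "SSSNNNN")   # three forced strong positions
  st <- dual_pf(tgt, TP, "d2", gc_resolved = TRUE)
  zk <- st$Z_total
  expect_equal(which(zk > 0)[1L] - 1L, 3L)    # minimum GC count is 3
})
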