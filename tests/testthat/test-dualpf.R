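test_that("per-pair values reproduce the published worked-example table", {
  st <- dual_pf(worked_example(), TP, mode = "d0", scale = 1)
  tb <- bp_table(st)
  row <- function(i, j) tb[tb$i == i & tb$j == j, ]
  pc <- c("AU", "CG", "GC", "UA", "GU", "UG")
  # triloop row, per pair and sum
  expect_equal(round(unlist(row(6, 10)[pc]), 3),
               c(AU = 0.004, CG = 0.010, GC = 0.010, UA = 0.004,
                 GU = 0.004, UG = 0.004))
  expect_equal(round(row(6, 10)$Z, 3), 0.038)
  # constrained tetraloop: all mass on GC
  expect_equal(round(row(18, 23)$GC, 3), 0.364)
  expect_equal(unlist(row(18, 23)[c("AU", "CG", "UA", "GU", "UG")]),
               c(AU = 0, CG = 0, UA = 0, GU = 0, UG = 0))
  # stacks, bulge, interior loop, multiloop row sums and the total
  expect_equal(round(row(17, 24)$Z, 3), 131.238)
  expect_equal(round(row(5, 11)$Z, 3), 11.120)
  expect_equal(round(row(16, 26)$Z, 3), 297.160)
  expect_equal(round(row(3, 13)$Z, 3), 1126.330)
  expect_equal(round(row(1, 27)$Z, 3), 22025.464)
  expect_equal(exp(log_dual_partition(st)), 88101.856, tolerance = 1e-8)
})

test_that("dynamic programming equals brute-force enumeration", {
  for (q in 1:12) {
    tgt <- random_small_instance(300L + q, n = 12L, max_count = 4e4)
    for (m in c("d0", "d2")) {
      bf <- brute_force_dual_pf(tgt, TP, m)
      z <- exp(log_dual_partition(dual_pf(tgt, TP, m)))
      expect_equal(z, bf, tolerance = 1e-9,
                   label = sprintf("%s %s [%s]", tgt$db, tgt$iupac, m))
    }
  }
  # both interior-loop pathways agree with their own oracle
  tgt <- parse_target("((.((...)).))", "NNNSNNNNNNNWN")
  for (si in c("tables", "generic")) {
    bf <- brute_force_dual_pf(tgt, TP, "d2", small_internal = si)
    z <- exp(log_dual_partition(dual_pf(tgt, TP, "d2", small_internal = si)))
    expect_equal(z, bf, tolerance = 1e-9)
  }
  # and the two pathways genuinely differ (1x1 loop, real tables)
  z1 <- log_dual_partition(dual_pf(tgt, TP, "d0", small_internal = "tables"))
  z2 <- log_dual_partition(dual_pf(tgt, TP, "d0", small_internal = "generic"))
  expect_gt(abs(z1 - z2), 1e-6)
})

test_that("zero-energy model counts compatible sequences exactly", {
  for (db in c("....", "(....).", "((...))((....))")) {
    tgt <- parse_target(db)
    np <- nrow(tgt$pairs)
    u <- sum(tgt$pair_table == 0L)
    for (m in c("d0", "d2"))
      expect_equal(exp(log_dual_partition(dual_pf(tgt, ZP, m))), 6^np * 4^u,
                   tolerance = 1e-12)
  }
  # with constraints: product of allowed-set sizes
  tgt <- parse_target("(....).", "SNNNNNY")
  expect_equal(exp(log_dual_partition(dual_pf(tgt, ZP, "d0"))),
               3 * 4^4 * 2, tolerance = 1e-12)
})

test_that("row sums, scaling invariance and constraint monotonicity hold", {
  tgt <- worked_example()
  st <- dual_pf(tgt, TP, "d0")
  tb <- bp_table(st)
  expect_equal(tb$Z, rowSums(tb[, c("AU", "CG", "GC", "UA", "GU", "UG")]),
               tolerance = 1e-12)
  for (m in c("d0", "d2")) {
    ls <- vapply(c(1, 2.5, 5), function(C)
      log_dual_partition(dual_pf(tgt, TP, m, scale = C)), 0)
    expect_lt(max(abs(ls - ls[1L])), 1e-9)
  }
  z_free <- log_dual_partition(dual_pf(parse_target(tgt$db), TP, "d2"))
  z_con <- log_dual_partition(dual_pf(tgt, TP, "d2"))
  expect_lte(z_con, z_free)
})

test_that("infeasible constraints yield Z*=0 with a diagnostic", {
  tgt <- parse_target("(....)", "ANNNNC")    # A-C cannot pair
  st <- dual_pf(tgt, TP, "d2")
  expect_false(st$feasible)
  expect_match(st$diagnostic, "no allowed pair")
  lz <- log_dual_partition(st)
  expect_identical(as.numeric(lz), -Inf)
  expect_true(attr(lz, "infeasible"))
  expect_error(sample_sequences(st, 5L, seed = 1), "cannot sample")
})

test_that("open chains have ln Z* = n ln 4 under the zero model", {
  st <- dual_pf(parse_target("........"), ZP, "d2")
  expect_equal(log_dual_partition(st), 8 * log(4), tolerance = 1e-12)
})
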