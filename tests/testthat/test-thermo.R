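test_that("finite-difference expected energy matches the enumeration mean", {
  for (q in 1:4) {
    tgt <- random_small_instance(1100L + q, n = 11L, max_count = 2e4)
    for (m in c("d0", "d2")) {
      ex <- exact_distribution(tgt, TP, m)
      mu <- sum(ex$E * ex$p)
      fd <- dual_expected_energy(tgt, TP, m, h = 0.01)
      expect_equal(fd, mu, tolerance = 1e-3, label = paste(tgt$db, m))
    }
  }
})

test_that("thermodynamic identities hold to machine precision", {
  tgt <- worked_example()
  th <- dual_thermo(tgt, TP, "d2")
  expect_equal(th$G, -TP$RT * th$ln_Z, tolerance = 1e-14)
  expect_equal(th$S * TP$temperature, th$E - th$G, tolerance = 1e-12)
  expect_true(is.finite(th$Cp))
})

test_that("central differences converge quadratically in h", {
  tgt <- parse_target("((....)).")
  e1 <- dual_expected_energy(tgt, TP, "d2", h = 0.08)
  e2 <- dual_expected_energy(tgt, TP, "d2", h = 0.04)
  e0 <- dual_expected_energy(tgt, TP, "d2", h = 0.005)
  # halving h shrinks the error by about 4
  expect_lt(abs(e2 - e0), 0.6 * abs(e1 - e0) + 1e-12)
})

test_that("degenerate and zero-energy limits are exact", {
  tgt1 <- parse_target("(....)", "GAAAAC")
  E0 <- energy_of_structure("GAAAAC", "(....)", TP, "d2")
  expect_equal(dual_expected_energy(tgt1, TP, "d2"), E0, tolerance = 1e-6)
  th1 <- dual_thermo(tgt1, TP, "d2")
  expect_equal(th1$S, 0, tolerance = 1e-8)
  # zero-energy open chain: <E*> = 0, S* = R n ln 4
  open <- parse_target(".......")
  expect_equal(dual_expected_energy(open, ZP, "d0"), 0, tolerance = 1e-9)
  th0 <- dual_thermo(open, ZP, "d0")
  expect_equal(th0$S, ZP$gas_constant * 7 * log(4), tolerance = 1e-9)
})

test_that("GC-resolved expected energies decompose the global mean", {
  tgt <- parse_target("((....)).", "NNSNNNNNN")
  ek <- dual_expected_energy(tgt, TP, "d2", gc_resolved = TRUE)
  st <- dual_pf(tgt, TP, "d2", gc_resolved = TRUE)
  w <- st$Z_total / sum(st$Z_total)
  keep <- w > 0
  expect_equal(sum(ek[keep] * w[keep]),
               dual_expected_energy(tgt, TP, "d2"), tolerance = 1e-6)
})

test_that("dual probabilities normalise and flag incompatibility", {
  tgt <- parse_target("(....).", "NNSNNNN")
  st <- dual_pf(tgt, TP, "d2")
  M <- dualpf:::.enumerate_compatible(tgt)
  lp <- vapply(seq_len(nrow(M)), function(r)
    dual_probability(dualpf:::int_to_nt(M[r, ]), st), 0)
  expect_equal(sum(exp(lp)), 1, tolerance = 1e-9)
  bad <- dual_probability("AAAAAAA", st)    # A-A cannot pair
  expect_identical(as.numeric(bad), -Inf)
})

test_that("fold change is the plain energy ratio", {
  expect_equal(fold_change(-20, -10), 2)
  expect_equal(fold_change(-3.2, -3.2), 1)
  expect_error(fold_change(-1, 0), "zero")
  tgt <- parse_target("((....))")
  eE <- dual_expected_energy(tgt, TP, "d2")
  eR <- energy_of_structure("GGGAAACC", tgt, TP, "d2")
  expect_equal(fold_change(eE, eR), eE / eR)
})
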