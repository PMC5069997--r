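test_that("closed forms equal the brute-force double sums on toy ensembles", {
  a <- toy_ensemble(c("((....))", "(.....).", "........"), c(0.5, 0.3, 0.2))
  b <- toy_ensemble(c("((....))", ".(....).", "(......)"), c(0.25, 0.5, 0.25))
  # ensemble diversity = expected pairwise distance within the ensemble
  expect_equal(ensemble_diversity(a$pm), cross_expected_distance(a, a),
               tolerance = 1e-12)
  # d1 = expected cross distance minus the diversity of the first argument
  expect_equal(d1_distance(a$pm, b$pm),
               cross_expected_distance(a, b) - ensemble_diversity(a$pm),
               tolerance = 1e-12)
  expect_equal(d1_distance(a$pm, a$pm), 0, tolerance = 1e-12)
  expect_gt(abs(d1_distance(a$pm, b$pm) - d1_distance(b$pm, a$pm)), 1e-6)
  # the two forms of the ensemble distance agree
  dv2 <- cross_expected_distance(a, b) -
    (ensemble_diversity(a$pm) + ensemble_diversity(b$pm)) / 2
  expect_equal(ensemble_distance(a$pm, b$pm), sqrt(dv2), tolerance = 1e-9)
})

test_that("ensemble distance behaves as a metric on random matrices", {
  set.seed(42)
  rand_pm <- function(n) {
    p <- matrix(0, n, n)
    for (i in 1:(n - 1)) {
      j <- sample((i + 1):n, 1L)
      p[i, j] <- stats::runif(1, 0, 0.5 / n)
    }
    bpp_matrix(p * n / 2)
  }
  for (rep in 1:20) {
    x <- rand_pm(9L); y <- rand_pm(9L); z <- rand_pm(9L)
    expect_equal(ensemble_distance(x, y), ensemble_distance(y, x))
    expect_equal(ensemble_distance(x, x), 0)
    expect_lte(ensemble_distance(x, z),
               ensemble_distance(x, y) + ensemble_distance(y, z) + 1e-12)
  }
})

test_that("diversity and plasticity have the documented limits", {
  det <- toy_ensemble("((....))", 1)$pm
  expect_equal(ensemble_diversity(det), 0)
  expect_equal(plasticity(det), 0)
  half <- bpp_matrix({p <- matrix(0, 2, 2); p[1, 2] <- 0.5; p})
  expect_equal(ensemble_diversity(half), 0.5)
  expect_equal(plasticity(half), 0.5)
  expect_error(bpp_matrix(matrix(2, 2, 2)), "probabilities|exceeds")
})

test_that("robustness and neutrality reduce to hand values on stub backends", {
  # backend returning identical matrices: perfectly robust
  pm0 <- matrix(0, 5, 5); pm0[1, 5] <- 0.8
  be_const <- fold_backend_stub(
    mfe = function(s) list(structure = "(...)", energy = -1),
    bpp = function(s) pm0)
  expect_equal(mutational_robustness("GGAAC", be_const), 1)
  expect_equal(neutrality("GGAAC", be_const), 1)
  # backend whose matrix depends on the first nucleotide: hand-computed
  be_var <- fold_backend_stub(
    mfe = function(s) if (substr(s, 1, 1) == "G")
      list(structure = "(...)", energy = -1) else
      list(structure = ".....", energy = 0),
    bpp = function(s) {
      p <- matrix(0, 5, 5)
      if (substr(s, 1, 1) == "G") p[1, 5] <- 1
      bpp_matrix(p)
    })
  # wild type GAAAA: mutants at position 1 (3 of them, non-G) differ by
  # D_V = 1; the other 12 mutants keep the matrix
  r <- mutational_robustness("GAAAA", be_var, variant = "dv")
  expect_equal(r, 1 - (3 * 1 / 15) / 5)
  # neutrality: the same 3 mutants lose one base pair (distance 1)
  expect_equal(neutrality("GAAAA", be_var), 1 - (3 * 1 / 15) / 5)
  expect_error(mutational_robustness("GGXAA", be_const), "letters")
})

test_that("measure battery is exact on a deterministic ensemble", {
  det <- matrix(0, 8, 8); det[2, 7] <- 1
  be <- fold_backend_stub(
    mfe = function(s) list(structure = ".(....).", energy = -2),
    bpp = function(s) det)
  mb <- measure_battery("AGAAAACA", ".(....).", be)
  expect_equal(mb$ensemble_defect, 0)
  expect_equal(mb$expected_bp_distance, 0)
  expect_equal(mb$native_contacts, 1)
  expect_equal(mb$positional_entropy, 0)
  expect_equal(mb$diversity, 0)
  # against a different target the defect counts the mismatched positions
  mb2 <- measure_battery("AGAAAACA", "(......)", be)
  expect_gt(mb2$ensemble_defect, 0)
  expect_equal(mb2$native_contacts, 0)
})

test_that("Z-scores use the sample standard deviation", {
  expect_equal(zscore_report(2, c(0, 2)), (2 - 1) / sqrt(2))
  expect_equal(zscore_report(5, c(5, 5, 5) + c(-1, 0, 1)), 0)
  expect_error(zscore_report(1, c(3, 3)), "zero standard deviation")
  expect_error(zscore_report(1, 3), "at least 2")
})

test_that("base pair distance is the symmetric difference size", {
  expect_equal(base_pair_distance("((....))", "((....))"), 0)
  expect_equal(base_pair_distance("((....))", "........"), 2)
  expect_equal(base_pair_distance("((...).)", "(......)"), 1)
  expect_error(base_pair_distance("(....)", "(.....)"), "length")
  set.seed(7)
  for (q in 1:10) {
    s <- generate_random_structure(15L, 0.6, seed = q)
    t <- generate_random_structure(15L, 0.6, seed = q + 50L)
    ps <- dualpf:::parse_target_lenient(s)$pairs
    pt <- dualpf:::parse_target_lenient(t)$pairs
    key <- function(m) if (nrow(m)) paste(m[, 1], m[, 2]) else character(0)
    expect_equal(base_pair_distance(s, t),
                 length(setdiff(key(ps), key(pt))) +
                   length(setdiff(key(pt), key(ps))))
  }
})
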